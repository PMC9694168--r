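#' Absolute-deviation validation report
#'
#' Computes `|DTV| = |predicted - experimental|` pGI50 per (compound, cell
#' line) pair where both values are present, and aggregates it at four
#' granularities: per compound, per cell line, per subpanel (the unweighted
#' mean of the member cell-line means) and overall (the mean over all
#' pairs).  Also reports the fraction of pairs within one log unit.
#'
#' @param predicted either a prediction data.frame from [predict_batch()]
#'   (columns `query_id`, `cell_line` and a prediction column named by
#'   `value_col`) or a numeric matrix, compounds x cell lines.
#' @param experimental an [activity_matrix()] of experimental values.
#' @param value_col prediction column used when `predicted` is a
#'   data.frame (default `"gi50"`; use `"gi50_cl"` or `"gi50_fp"` to score
#'   one module alone).
#' @return an `aap_validation` list: `pairs` (long data.frame with `dtv`),
#'   `per_compound`, `per_cell_line`, `per_panel`, `overall`,
#'   `within1_fraction`, `n_pairs`.
#' @export
dtv_report <- function(predicted, experimental, value_col = "gi50") {
  panels <- panel_of(experimental)
  exp_m <- act_values(experimental)
  if (is.data.frame(predicted)) {
    need <- c("query_id", "cell_line", value_col)
    if (!all(need %in% names(predicted)))
      stop("prediction frame must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    df <- data.frame(compound = predicted$query_id,
                     cell_line = predicted$cell_line,
                     predicted = predicted[[value_col]],
                     stringsAsFactors = FALSE)
  } else {
    m <- as.matrix(predicted)
    df <- data.frame(compound = rep(rownames(m), ncol(m)),
                     cell_line = rep(colnames(m), each = nrow(m)),
                     predicted = as.vector(m),
                     stringsAsFactors = FALSE)
  }
  ok_key <- df$compound %in% rownames(exp_m) & df$cell_line %in% colnames(exp_m)
  df <- df[ok_key, , drop = FALSE]
  df$experimental <- exp_m[cbind(match(df$compound, rownames(exp_m)),
                                 match(df$cell_line, colnames(exp_m)))]
  df <- df[!is.na(df$predicted) & !is.na(df$experimental), , drop = FALSE]
  if (!nrow(df))
    stop("no (compound, cell line) pair with both predicted and experimental values",
         call. = FALSE)
  df$panel <- unname(panels[df$cell_line])
  df$dtv <- abs(df$predicted - df$experimental)
  per_compound <- c(tapply(df$dtv, df$compound, mean))
  per_cell_line <- c(tapply(df$dtv, df$cell_line, mean))
  cl_panel <- panels[names(per_cell_line)]
  per_panel <- c(tapply(as.numeric(per_cell_line), cl_panel, mean))
  structure(list(
    pairs = df[, c("compound", "cell_line", "panel",
                   "predicted", "experimental", "dtv")],
    per_compound = per_compound,
    per_cell_line = per_cell_line,
    per_panel = per_panel,
    overall = mean(df$dtv),
    within1_fraction = mean(df$dtv <= 1),
    n_pairs = nrow(df)), class = "aap_validation")
}

#' @export
print.aap_validation <- function(x, ...) {
  cat(sprintf("validation over %d (compound, cell line) pairs\n", x$n_pairs))
  cat(sprintf("  mean |DTV(pGI50)|: %.4f   within +/-1 log unit: %.1f%%\n",
              x$overall, 100 * x$within1_fraction))
  cat("  per-panel mean |DTV|:\n")
  p <- sort(x$per_panel)
  for (nm in names(p)) cat(sprintf("    %-12s %.4f\n", nm, p[nm]))
  invisible(x)
}

#' Validation report for the similarity module alone
#'
#' Predicts every validation compound purely by activity transfer from its
#' best training match (missing where the match was not tested) and scores
#' the result against the experimental values.
#'
#' @param queries [descriptor_matrix()] of the validation compounds.
#' @param model an `aap_model`.
#' @param experimental [activity_matrix()] of their experimental values.
#' @return an `aap_validation` (see [dtv_report()]).
#' @export
fp_only_report <- function(queries, model, experimental) {
  preds <- predict_batch(queries, model)
  dtv_report(preds, experimental, value_col = "gi50_fp")
}

#' The default 18-run tuning grid
#'
#' Six descriptor counts crossed with the three smoothing modes at a fixed
#' zero-filter level: `N` in \{240, 360, 480, 600, 720, 800\} x `G` in
#' \{a, b, c\}, `Z` = 50.  Run 1 is (N = 240, Z = 50, G = a).
#'
#' @return data.frame with columns `run_id`, `N`, `Z`, `G`.
#' @export
default_tuning_grid <- function() {
  g <- expand.grid(N = c(240L, 360L, 480L, 600L, 720L, 800L),
                   G = c("a", "b", "c"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(run_id = seq_len(nrow(g)), N = g$N, Z = 50, G = g$G,
             stringsAsFactors = FALSE)
}

#' Tune template-module parameters over a grid
#'
#' For each grid row, the descriptor matrix is re-filtered at that `Z`,
#' templates are rebuilt with that `N`, the validation compounds are
#' predicted by the template module alone in mode `G`, and an
#' absolute-deviation report is computed against their experimental
#' values.  The best run is the argmin of the mean `|DTV|` at each
#' granularity (overall, per panel, per cell line); ties go to the lower
#' `run_id`.
#'
#' @param grid data.frame with columns `run_id`, `N`, `Z`, `G` (see
#'   [default_tuning_grid()]).
#' @param desc training [descriptor_matrix()].
#' @param act training [activity_matrix()].
#' @param validation_ids compound ids (subset of the training rows) used
#'   for internal validation.
#' @param min_members passed to [cl_params()].
#' @return an `aap_tuning` list: `runs` (grid plus `mean_dtv`,
#'   `within1_fraction`, `n_pairs`), `reports` (one `aap_validation` per
#'   run), `best_overall` (run id), `best_per_panel` and
#'   `best_per_cell_line` (data.frames with run id and mean `|DTV|`).
#' @export
tune <- function(grid, desc, act, validation_ids, min_members = 1L) {
  if (is.null(grid) || !nrow(grid)) stop("empty tuning grid", call. = FALSE)
  need <- c("run_id", "N", "Z", "G")
  if (!all(need %in% names(grid)))
    stop("grid must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(grid$run_id)) stop("duplicate run_id", call. = FALSE)
  ids <- intersect(rownames(desc), rownames(act))
  if (!length(ids))
    stop("descriptor and activity matrices share no compound ids",
         call. = FALSE)
  desc <- desc[ids, , drop = FALSE]
  act <- act[ids, , drop = FALSE]
  unknown <- setdiff(validation_ids, ids)
  if (length(unknown))
    stop("validation id(s) not in the training descriptors: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  exp_val <- act[validation_ids, , drop = FALSE]
  reports <- vector("list", nrow(grid))
  names(reports) <- as.character(grid$run_id)
  per_cl <- per_pn <- list()
  runs <- grid
  runs$mean_dtv <- NA_real_
  runs$within1_fraction <- NA_real_
  runs$n_pairs <- NA_integer_
  for (r in seq_len(nrow(grid))) {
    params <- cl_params(N = grid$N[r], Z = grid$Z[r], G = grid$G[r],
                        min_members = min_members)
    fdesc <- zero_filter(desc, params$Z)
    templates <- suppressWarnings(build_templates(fdesc, act, params))
    pred <- do.call(rbind, lapply(validation_ids, function(id) {
      p <- cl_predict(fdesc[id, ], templates, params)
      p$query_id <- id
      p
    }))
    rep_r <- dtv_report(pred, exp_val, value_col = "gi50_cl")
    reports[[r]] <- rep_r
    runs$mean_dtv[r] <- rep_r$overall
    runs$within1_fraction[r] <- rep_r$within1_fraction
    runs$n_pairs[r] <- rep_r$n_pairs
    per_cl[[r]] <- rep_r$per_cell_line
    per_pn[[r]] <- rep_r$per_panel
  }
  best_overall <- grid$run_id[which.min(runs$mean_dtv)]
  best_per_panel <- best_by_group(per_pn, grid$run_id)
  best_per_cell_line <- best_by_group(per_cl, grid$run_id)
  structure(list(runs = runs, reports = reports,
                 best_overall = best_overall,
                 best_per_panel = best_per_panel,
                 best_per_cell_line = best_per_cell_line),
            class = "aap_tuning")
}

# per group (cell line or panel), the run with minimal mean |DTV|;
# which.min takes the first minimum, i.e. the lower run_id on ties
best_by_group <- function(means_by_run, run_ids) {
  groups <- sort(unique(unlist(lapply(means_by_run, names))))
  rows <- lapply(groups, function(g) {
    v <- vapply(means_by_run, function(m)
      if (g %in% names(m)) as.numeric(m[g]) else NA_real_, 0)
    best <- which.min(v)
    data.frame(group = g, run_id = run_ids[best], mean_dtv = v[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.aap_tuning <- function(x, ...) {
  cat(sprintf("tuning over %d runs; best overall: run %d (mean |DTV| = %.4f)\n",
              nrow(x$runs), x$best_overall,
              x$runs$mean_dtv[x$runs$run_id == x$best_overall]))
  print(x$runs[, c("run_id", "N", "Z", "G", "mean_dtv", "within1_fraction")])
  invisible(x)
}

#' Draw a reproducible internal-validation sample
#'
#' Selects a random fraction of the training compounds (by default 5 per
#' mille, the conventional internal-validation share for this protocol)
#' under an explicit seed so the draw is auditable.
#'
#' @param ids training compound ids.
#' @param fraction share of ids to draw (default 0.005).
#' @param seed integer seed recorded with the draw.
#' @param min_n lower bound on the sample size.
#' @return list with `ids`, `fraction`, `seed`.
#' @export
validation_sample <- function(ids, fraction = 0.005, seed = 1L,
                              min_n = 1L) {
  n <- max(min_n, round(length(ids) * fraction))
  n <- min(n, length(ids))
  set.seed(seed)
  list(ids = sample(ids, n), fraction = fraction, seed = seed)
}
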