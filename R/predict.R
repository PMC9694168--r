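#' Combine similarity-transferred and template pGI50 predictions
#'
#' The final prediction is the convex combination
#' `gi50 = S * gi50_fp + (1 - S) * gi50_cl`, weighted by the similarity
#' score S of the best training match.  When the best match carries no
#' experimental value for a cell line (`gi50_fp` missing), the template
#' value is used unchanged.  The result always lies between its two
#' parents; at S = 1 it equals the transferred experimental value, at
#' S = 0 the template value.
#'
#' @param gi50_fp transferred pGI50 (may be `NA`); vectorized.
#' @param gi50_cl template pGI50 (must be present where used).
#' @param S similarity weight in \[0, 1\].
#' @return combined pGI50.
#' @export
combine_gi50 <- function(gi50_fp, gi50_cl, S) {
  if (any(is.na(S)) || any(S < 0 | S > 1))
    stop("S must lie in [0, 1]", call. = FALSE)
  ifelse(is.na(gi50_fp), gi50_cl, S * gi50_fp + (1 - S) * gi50_cl)
}

#' Build a trained model from descriptors and activities
#'
#' Applies the zero filter at `params$Z`, builds the per-cell-line
#' templates and bundles everything needed for prediction: the filtered
#' training descriptors (used by the similarity module), the training
#' activities, the template set and the parameters.
#'
#' @param desc training [descriptor_matrix()].
#' @param act training [activity_matrix()] with the same row ids.
#' @param params a [cl_params()].
#' @param backend_id identifier of the descriptor backend that produced
#'   `desc` (bookkeeping only; `"precomputed"` when the matrix was imported).
#' @param exclude cell-line ids to drop before training.
#' @return an `aap_model`.
#' @export
build_model <- function(desc, act, params = cl_params(),
                        backend_id = "precomputed",
                        exclude = character()) {
  ids <- intersect(rownames(desc), rownames(act))
  if (!length(ids))
    stop("descriptor and activity matrices share no compound ids",
         call. = FALSE)
  desc <- desc[ids, , drop = FALSE]
  act <- act[ids, , drop = FALSE]
  if (length(exclude))
    act <- act[, setdiff(colnames(act), exclude), drop = FALSE]
  desc <- zero_filter(desc, params$Z)
  templates <- build_templates(desc, act, params)
  structure(list(backend_id = backend_id,
                 descriptor_list = colnames(desc),
                 train_desc = desc,
                 train_act = act,
                 templates = templates,
                 params = params,
                 excluded = union(exclude, templates$excluded)),
            class = "aap_model")
}

#' @export
print.aap_model <- function(x, ...) {
  cat(sprintf("activity prediction model: %d training compounds, %d descriptors (backend '%s'), %d cell lines\n",
              nrow(x$train_desc), length(x$descriptor_list), x$backend_id,
              length(x$templates$mu)))
  cat(sprintf("params: N = %d, Z = %g, G = '%s'\n",
              x$params$N, x$params$Z, x$params$G))
  if (length(x$excluded))
    cat("excluded cell lines:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Predict pGI50 profiles for a batch of query compounds
#'
#' Each query gets one similarity pass (best training match and its S
#' score), one template pass per cell line, and the convex combination of
#' the two.  One output row is emitted per (query, active cell line).
#'
#' @param queries [descriptor_matrix()] of query compounds; must contain
#'   every model descriptor (extra columns are ignored).
#' @param model an `aap_model`.
#' @param params optional [cl_params()] overriding the model's smoothing
#'   mode at prediction time.
#' @return data.frame with columns `query_id`, `cell_line`, `panel`, `S`,
#'   `best_match_id`, `gi50_fp`, `gi50_cl`, `gi50`, `cl_bin`, `cl_score`.
#' @export
predict_batch <- function(queries, model, params = model$params) {
  stopifnot(inherits(model, "aap_model"))
  miss <- setdiff(model$descriptor_list, colnames(queries))
  if (length(miss))
    stop("query matrix lacks model descriptor(s): ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) ", ..." else "", call. = FALSE)
  queries <- queries[, model$descriptor_list, drop = FALSE]
  panels <- panel_of(model$train_act)
  out <- vector("list", nrow(queries))
  for (k in seq_len(nrow(queries))) {
    q <- queries[k, ]
    fp <- fp_predict(q, model$train_desc, model$train_act)
    cl <- cl_predict(q, model$templates, params)
    gi50_fp <- fp$gi50_fp[cl$cell_line]
    gi50 <- ifelse(is.na(cl$gi50_cl) & is.na(gi50_fp), NA_real_,
            ifelse(is.na(cl$gi50_cl), gi50_fp,
                   combine_gi50(gi50_fp, cl$gi50_cl, fp$S)))
    out[[k]] <- data.frame(
      query_id = rownames(queries)[k],
      cell_line = cl$cell_line,
      panel = unname(panels[cl$cell_line]),
      S = unname(fp$S),
      best_match_id = unname(fp$best_match_id),
      gi50_fp = unname(gi50_fp),
      gi50_cl = cl$gi50_cl,
      gi50 = unname(gi50),
      cl_bin = cl$bin,
      cl_score = cl$score,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
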