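#' The 42 pGI50 activity bins
#'
#' Bin 0 collects values below 4, bins 1..40 tile \[4, 8\] in 0.1-unit
#' steps, and bin 41 collects values above 8.  Regular bins are half-open
#' `[lower, upper)` except the last regular bin `[7.9, 8.0]`, which is
#' closed: 8.0 belongs to the regular range, not to the overflow bin.
#' Each bin carries the representative pGI50 assigned to a query matched to
#' it: the bin midpoint for regular bins, and the assay clamp values 4.0 /
#' 8.0 for the underflow / overflow bins.
#'
#' @return data.frame with columns `index` (0..41), `lower`, `upper`,
#'   `assigned`.
#' @export
activity_bins <- function() {
  idx <- 0:41
  lower <- c(-Inf, 4 + (0:39) / 10, 8)
  upper <- c(4, 4 + (1:40) / 10, Inf)
  assigned <- c(4, 4 + (0:39) / 10 + 0.05, 8)
  data.frame(index = idx, lower = lower, upper = upper, assigned = assigned)
}

#' Assign pGI50 values to activity bins
#'
#' @param value numeric vector of finite pGI50 values (missing values are an
#'   error; callers must skip them).
#' @return integer bin indices in 0..41.
#' @examples
#' assign_bin(c(3.2, 5.25, 8.0, 8.1))  # 0, 13, 40, 41
#' @export
assign_bin <- function(value) {
  if (anyNA(value))
    stop("assign_bin: missing pGI50 value (callers must skip missing entries)",
         call. = FALSE)
  # the 1e-9 nudge keeps values that are exact bin edges up to representation
  # error (e.g. 4.3 stored as 4.2999999999999998) in their intended bin
  idx <- 1L + as.integer(floor((value - 4) * 10 + 1e-9))
  idx <- pmin(idx, 40L)
  idx[value < 4] <- 0L
  idx[value > 8] <- 41L
  idx
}

#' Build per-cell-line activity-bin templates
#'
#' For each cell line, every training compound with a measured activity is
#' assigned to one of the 42 bins; per (bin, descriptor), the mean and
#' population standard deviation of the member compounds' non-missing
#' descriptor values are computed.  Standard deviations are floored at
#' `1e-6 * max(|mu|, 1)` so single-member and constant templates remain
#' usable in every smoothing mode.  Empty templates are retained with a
#' member count of 0.  Cell lines with no measured activity at all are
#' excluded with a warning.  Finally the top-`N` descriptors are selected
#' per cell line (see [select_top_descriptors()]).
#'
#' @param desc training [descriptor_matrix()], already zero-filtered.
#' @param act training [activity_matrix()], row-aligned with `desc`.
#' @param params a [cl_params()] object.
#' @return an `aap_templates` object: per-cell-line 42 x D `mu` and `sigma`
#'   matrices, member counts, selected descriptor lists, the bin table and
#'   the excluded cell lines.
#' @export
build_templates <- function(desc, act, params = cl_params()) {
  stopifnot(inherits(params, "cl_params"))
  if (!identical(rownames(desc), rownames(act)))
    stop("descriptor and activity matrices are not row-aligned", call. = FALSE)
  bins <- activity_bins()
  a <- act_values(act)
  cls <- colnames(a)
  n_meas <- colSums(!is.na(a))
  excluded <- cls[n_meas == 0L]
  if (length(excluded))
    warning("cell line(s) excluded for lack of activity data: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  active <- setdiff(cls, excluded)
  D <- ncol(desc)
  mu_l <- sigma_l <- counts_l <- sel_l <- list()
  present <- !is.na(desc)
  desc0 <- desc; desc0[!present] <- 0
  desc0sq <- desc0^2
  for (cl in active) {
    v <- a[, cl]
    keep <- !is.na(v)
    bin <- assign_bin(v[keep])
    grp <- factor(bin, levels = 0:41)
    cnt <- as.integer(table(grp))
    # per (bin, descriptor) counts / sums / sums of squares over members
    n_bd <- rowsum_by(present[keep, , drop = FALSE] * 1, grp)
    s_bd <- rowsum_by(desc0[keep, , drop = FALSE], grp)
    q_bd <- rowsum_by(desc0sq[keep, , drop = FALSE], grp)
    mu <- ifelse(n_bd > 0, s_bd / pmax(n_bd, 1), NA_real_)
    variance <- ifelse(n_bd > 0, pmax(q_bd / pmax(n_bd, 1) - mu^2, 0), NA_real_)
    sigma <- sqrt(variance)
    floor_ <- 1e-6 * pmax(abs(mu), 1)
    sigma <- ifelse(!is.na(sigma), pmax(sigma, floor_), NA_real_)
    dimnames(mu) <- dimnames(sigma) <- list(as.character(0:41), colnames(desc))
    mu_l[[cl]] <- mu
    sigma_l[[cl]] <- sigma
    counts_l[[cl]] <- stats::setNames(cnt, as.character(0:41))
  }
  templates <- structure(list(
    descriptor_list = colnames(desc),
    bins = bins,
    params = params,
    mu = mu_l, sigma = sigma_l, counts = counts_l,
    selected = list(),
    excluded = excluded), class = "aap_templates")
  for (cl in active)
    templates$selected[[cl]] <- select_top_descriptors(templates, cl, params$N)
  templates
}

# rowsum over a factor with fixed levels, keeping empty groups as 0 rows
rowsum_by <- function(m, grp) {
  out <- matrix(0, nlevels(grp), ncol(m))
  got <- rowsum(m, grp)
  out[match(rownames(got), levels(grp)), ] <- got
  out
}

#' @export
print.aap_templates <- function(x, ...) {
  cat(sprintf("template set: %d cell lines x 42 bins, %d descriptors (top-%d selected), mode '%s'\n",
              length(x$mu), length(x$descriptor_list), x$params$N, x$params$G))
  if (length(x$excluded))
    cat("excluded cell lines:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Score a query against one template profile
#'
#' Per selected descriptor with a usable value (query present, template
#' statistic defined), a contribution is computed from the standardized
#' distance `z = (v - mu) / sigma`: mode `"a"` scores the hard indicator of
#' `mu - sigma <= v <= mu + sigma`, mode `"b"` the Gaussian kernel
#' `exp(-z^2/2)`, and mode `"c"` a twice-as-wide Gaussian `exp(-z^2/8)`.
#' The template score is the mean contribution over usable descriptors.
#'
#' @param query_vec named numeric query vector.
#' @param mu,sigma named per-descriptor template statistics.
#' @param selected descriptor names entering the score.
#' @param G smoothing mode `"a"`, `"b"` or `"c"`.
#' @return score in \[0, 1\], or `NA` if no descriptor is usable.
#' @export
template_match_score <- function(query_vec, mu, sigma,
                                 selected = names(mu),
                                 G = c("a", "b", "c")) {
  G <- match.arg(G)
  v <- query_vec[selected]
  m <- mu[selected]
  s <- sigma[selected]
  usable <- !is.na(v) & !is.na(m) & !is.na(s)
  if (!any(usable)) return(NA_real_)
  z <- (v[usable] - m[usable]) / s[usable]
  contrib <- switch(G,
    a = as.numeric(abs(z) <= 1),
    b = exp(-z^2 / 2),
    c = exp(-z^2 / 8))
  mean(contrib)
}

#' Assign pGI50 values from the best-matching template per cell line
#'
#' For each cell line, the query is scored against every non-empty template
#' (member count at least `params$min_members`) over that cell line's
#' selected descriptors, and receives the representative pGI50 of the
#' highest-scoring bin.  Score ties are broken toward the better-supported
#' template (larger member count), then the lower bin index.  Cell lines
#' whose templates are all empty or unusable yield `NA` with a warning.
#'
#' @param query_vec named numeric vector over the template descriptor set.
#' @param templates an `aap_templates` from [build_templates()].
#' @param params optional [cl_params()] overriding the smoothing mode /
#'   minimum membership used at build time.
#' @return data.frame with one row per cell line: `cell_line`, `gi50_cl`,
#'   `bin`, `score`.
#' @export
cl_predict <- function(query_vec, templates, params = templates$params) {
  stopifnot(inherits(templates, "aap_templates"))
  q <- align_query(query_vec, templates$descriptor_list)
  names(q) <- templates$descriptor_list
  cls <- names(templates$mu)
  bins <- templates$bins
  res <- data.frame(cell_line = cls, gi50_cl = NA_real_,
                    bin = NA_integer_, score = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cls)) {
    cl <- cls[i]
    sel <- templates$selected[[cl]]
    mu <- templates$mu[[cl]][, sel, drop = FALSE]
    sigma <- templates$sigma[[cl]][, sel, drop = FALSE]
    cnt <- templates$counts[[cl]]
    Q <- matrix(q[sel], 42L, length(sel), byrow = TRUE)
    Z <- (Q - mu) / sigma
    contrib <- switch(params$G,
      a = (abs(Z) <= 1) * 1,
      b = exp(-Z^2 / 2),
      c = exp(-Z^2 / 8))
    usable <- rowSums(!is.na(contrib))
    score <- rowMeans(contrib, na.rm = TRUE)
    eligible <- cnt >= params$min_members & usable > 0L
    if (!any(eligible)) {
      warning("no usable template for cell line '", cl, "'", call. = FALSE)
      next
    }
    cand <- which(eligible)
    ord <- order(-score[cand], -cnt[cand], cand)
    win <- cand[ord[1L]]
    res$gi50_cl[i] <- bins$assigned[win]
    res$bin[i] <- bins$index[win]
    res$score[i] <- score[win]
  }
  res
}

# ---- audit export / serialization helpers ----

#' Export template statistics as a long table
#'
#' One row per (cell line, bin, descriptor) with a defined statistic:
#' columns `cell_line`, `bin_index`, `lower`, `upper`, `member_count`,
#' `descriptor`, `mu`, `sigma`.
#'
#' @param templates an `aap_templates`.
#' @return a data.table.
#' @export
template_table <- function(templates) {
  stopifnot(inherits(templates, "aap_templates"))
  bins <- templates$bins
  pieces <- lapply(names(templates$mu), function(cl) {
    mu <- templates$mu[[cl]]
    sigma <- templates$sigma[[cl]]
    def <- which(!is.na(mu), arr.ind = TRUE)
    if (!nrow(def)) return(NULL)
    data.table::data.table(
      cell_line = cl,
      bin_index = def[, 1L] - 1L,
      lower = bins$lower[def[, 1L]],
      upper = bins$upper[def[, 1L]],
      member_count = templates$counts[[cl]][def[, 1L]],
      descriptor = colnames(mu)[def[, 2L]],
      mu = mu[def],
      sigma = sigma[def])
  })
  data.table::rbindlist(pieces)
}

# rebuild an aap_templates from the serialized tables
templates_from_tables <- function(descriptor_list, tmpl_df, cnt_df, sel_df,
                                  params) {
  cls <- unique(cnt_df$cell_line)
  mu_l <- sigma_l <- counts_l <- sel_l <- list()
  for (cl in cls) {
    mu <- matrix(NA_real_, 42L, length(descriptor_list),
                 dimnames = list(as.character(0:41), descriptor_list))
    sigma <- mu
    sub <- tmpl_df[tmpl_df$cell_line == cl, ]
    if (nrow(sub)) {
      ij <- cbind(sub$bin_index + 1L, match(sub$descriptor, descriptor_list))
      mu[ij] <- sub$mu
      sigma[ij] <- sub$sigma
    }
    csub <- cnt_df[cnt_df$cell_line == cl, ]
    counts <- stats::setNames(integer(42L), as.character(0:41))
    counts[as.character(csub$bin_index)] <- as.integer(csub$member_count)
    mu_l[[cl]] <- mu
    sigma_l[[cl]] <- sigma
    counts_l[[cl]] <- counts
    ssub <- sel_df[sel_df$cell_line == cl, ]
    sel_l[[cl]] <- ssub$descriptor[order(as.integer(ssub$rank))]
  }
  structure(list(descriptor_list = descriptor_list, bins = activity_bins(),
                 params = params, mu = mu_l, sigma = sigma_l,
                 counts = counts_l, selected = sel_l,
                 excluded = character()), class = "aap_templates")
}
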