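#' Model parameters for the template module
#'
#' @param N number of descriptors retained per cell line (ranked by
#'   within-template dispersion, see [select_top_descriptors()]).
#' @param Z maximum percentage of exactly-zero values tolerated per
#'   descriptor column before it is dropped (see [zero_filter()]).
#' @param G smoothing mode for template matching: `"a"` hard indicator on
#'   the mean +/- sd window, `"b"` Gaussian kernel `exp(-z^2/2)`, `"c"`
#'   wider Gaussian `exp(-z^2/8)`.
#' @param min_members templates with fewer member compounds are treated as
#'   empty.
#' @return a `cl_params` list.
#' @export
cl_params <- function(N = 240L, Z = 50, G = c("a", "b", "c"),
                      min_members = 1L) {
  G <- match.arg(as.character(G), c("a", "b", "c"))
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be a positive integer", call. = FALSE)
  if (!is.numeric(Z) || Z < 0 || Z > 100)
    stop("Z must be a percentage in [0, 100]", call. = FALSE)
  Z <- as.double(Z)
  min_members <- max(1L, as.integer(min_members))
  structure(list(N = N, Z = Z, G = G, min_members = min_members),
            class = "cl_params")
}

#' Drop descriptor columns dominated by zeros
#'
#' Removes every descriptor whose fraction of exactly-zero values, among its
#' non-missing entries, exceeds `Z` percent.  Column order of survivors is
#' preserved; the filter is idempotent.
#'
#' @param m a [descriptor_matrix()].
#' @param Z percentage in \[0, 100\].
#' @return the filtered descriptor matrix.
#' @export
zero_filter <- function(m, Z) {
  if (!is.numeric(Z) || Z < 0 || Z > 100)
    stop("Z must be a percentage in [0, 100]", call. = FALSE)
  n_obs <- colSums(!is.na(m))
  n_zero <- colSums(m == 0, na.rm = TRUE)
  frac <- ifelse(n_obs > 0, n_zero / n_obs, 0)
  keep <- frac * 100 <= Z
  if (!any(keep))
    stop("zero filter removed every descriptor; increase Z (got Z = ", Z, ")",
         call. = FALSE)
  m[, keep, drop = FALSE]
}

# rank descriptors for one cell line by mean within-template relative
# dispersion sigma / (|mu| + eps) over non-empty templates, ascending;
# ties broken lexicographically.  mu/sigma are 42 x D template statistics.
rank_descriptors <- function(mu, sigma, counts, min_members = 1L) {
  live <- counts >= min_members
  eps <- 1e-9
  disp <- sigma[live, , drop = FALSE] / (abs(mu[live, , drop = FALSE]) + eps)
  score <- colMeans(disp, na.rm = TRUE)           # NaN when never defined
  score[is.nan(score)] <- Inf
  colnames(mu)[order(score, colnames(mu))]
}

#' Rank and select the most template-discriminative descriptors
#'
#' Per cell line, descriptors are ranked by the mean (over non-empty
#' templates) of the within-template relative dispersion
#' `sigma / (|mu| + 1e-9)`, ascending: descriptors whose values are tight
#' inside activity bins make the mean +/- sd profile match discriminative.
#' Ties are broken by descriptor name.  `N` is clamped to the number of
#' available descriptors.
#'
#' @param templates an `aap_templates` set from [build_templates()].
#' @param cell_line cell-line id.
#' @param N number of descriptors to retain.
#' @return ordered character vector of descriptor names, length
#'   `min(N, available)`.
#' @export
select_top_descriptors <- function(templates, cell_line, N) {
  stopifnot(inherits(templates, "aap_templates"))
  if (!cell_line %in% names(templates$mu))
    stop("no templates for cell line '", cell_line, "'", call. = FALSE)
  ranked <- rank_descriptors(templates$mu[[cell_line]],
                             templates$sigma[[cell_line]],
                             templates$counts[[cell_line]],
                             templates$params$min_members)
  utils::head(ranked, max(1L, as.integer(N)))
}
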