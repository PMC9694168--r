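# small in-code fixtures and independent oracles shared across test files

# descriptor matrix with explicit values
dm <- function(values, ids = NULL, descs = NULL) {
  m <- as.matrix(values)
  if (is.null(ids)) ids <- sprintf("c%02d", seq_len(nrow(m)))
  if (is.null(descs)) descs <- sprintf("d%02d", seq_len(ncol(m)))
  dimnames(m) <- list(ids, descs)
  descriptor_matrix(m)
}

# activity matrix over toy cell lines, panels auto-assigned pairwise
am <- function(values, ids = NULL, lines = NULL, panels = NULL) {
  m <- as.matrix(values)
  if (is.null(ids)) ids <- sprintf("c%02d", seq_len(nrow(m)))
  if (is.null(lines)) lines <- sprintf("L%02d", seq_len(ncol(m)))
  if (is.null(panels))
    panels <- setNames(sprintf("P%d", (seq_along(lines) + 1) %/% 2), lines)
  dimnames(m) <- list(ids, lines)
  activity_matrix(m, panels)
}

# a random descriptor+activity training pair with activities spanning all
# three bin regions
random_training <- function(n = 30, d = 8, n_lines = 4, missing_rate = 0.2,
                            seed = 1) {
  set.seed(seed)
  desc <- dm(matrix(runif(n * d, 1, 10), n, d))
  a <- matrix(runif(n * n_lines, 3.2, 8.8), n, n_lines)
  a[runif(n * n_lines) < missing_rate] <- NA
  list(desc = desc, act = am(a))
}

# ---- independent oracles (kept deliberately naive) ----

# tolerance-count similarity, position by position
bf_similarity <- function(q, r) {
  n <- 0L; hits <- 0L
  for (i in seq_along(q)) {
    if (is.na(q[i]) || is.na(r[i])) next
    n <- n + 1L
    if (abs(q[i] - r[i]) <= 0.05 * abs(r[i])) hits <- hits + 1L
  }
  stopifnot(n > 0L)
  hits / n
}

# bin lookup by scanning the published edges
bf_assign_bin <- function(v) {
  bins <- activity_bins()
  for (i in seq_len(nrow(bins))) {
    lo <- bins$lower[i]; hi <- bins$upper[i]
    inside <- if (bins$index[i] == 40) v >= lo & v <= hi
              else if (bins$index[i] == 41) v > 8
              else v >= lo & v < hi
    if (inside) return(bins$index[i])
  }
  stop("no bin found")
}

# mode-a template score by explicit counting
bf_score_a <- function(q, mu, sigma, selected) {
  inside <- 0L; usable <- 0L
  for (d in selected) {
    if (is.na(q[d]) || is.na(mu[d])) next
    usable <- usable + 1L
    if (q[d] >= mu[d] - sigma[d] && q[d] <= mu[d] + sigma[d])
      inside <- inside + 1L
  }
  if (usable == 0L) return(NA_real_)
  inside / usable
}
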