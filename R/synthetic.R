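#' Specification for a synthetic descriptor/activity benchmark
#'
#' Describes a population in which compounds falling in the same pGI50
#' activity bin share a latent descriptor profile — exactly the statistical
#' structure the template module assumes.  Latent bin centers are placed in
#' descriptor space with a guaranteed minimum pairwise distance;
#' compound descriptors are drawn around their bin's center with
#' independent per-descriptor noise; activities are drawn inside the bin's
#' pGI50 range.  A fraction of compounds are cloned with small
#' multiplicative descriptor jitter to emulate near-duplicate structures,
#' and activity entries are knocked out at a fixed missing rate.
#'
#' @param n_compounds number of base compounds (before cloning).
#' @param n_descriptors descriptor-space dimension.
#' @param cell_lines named character vector: cell-line id -> subpanel.
#' @param bin_occupancy probability over bins 0..41 (names = bin indices);
#'   default: uniform over bins 5, 13, 21, 29, 37 plus the two edge bins.
#' @param within_sigma descriptor noise s.d. around a bin center.
#' @param between_separation minimum Euclidean distance between adjacent
#'   bin centers.
#' @param duplicate_fraction share of base compounds cloned with jitter.
#' @param jitter relative descriptor jitter of a clone (default 0.01, i.e.
#'   at most 1%, well inside the 5% similarity tolerance).
#' @param missing_rate fraction of activity entries knocked out.
#' @param seed integer seed; the whole benchmark is a deterministic
#'   function of the spec.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_compounds = 120L,
                           n_descriptors = 40L,
                           cell_lines = c(LINE_A1 = "alpha", LINE_A2 = "alpha",
                                          LINE_B1 = "beta",  LINE_B2 = "beta",
                                          LINE_C1 = "gamma", LINE_C2 = "gamma"),
                           bin_occupancy = NULL,
                           within_sigma = 0.4,
                           between_separation = 4,
                           duplicate_fraction = 0,
                           jitter = 0.01,
                           missing_rate = 0.1,
                           seed = 1L) {
  if (is.null(bin_occupancy)) {
    bins <- c(0L, 5L, 13L, 21L, 29L, 37L, 41L)
    bin_occupancy <- stats::setNames(rep(1 / length(bins), length(bins)),
                                     as.character(bins))
  }
  if (abs(sum(bin_occupancy) - 1) > 1e-8)
    stop("bin_occupancy must sum to 1", call. = FALSE)
  bi <- as.integer(names(bin_occupancy))
  if (anyNA(bi) || any(bi < 0L | bi > 41L))
    stop("bin_occupancy names must be bin indices 0..41", call. = FALSE)
  if (within_sigma <= 0) stop("within_sigma must be > 0", call. = FALSE)
  if (duplicate_fraction < 0 || duplicate_fraction > 1 ||
      missing_rate < 0 || missing_rate > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (between_separation <= 0)
    stop("between_separation must be > 0", call. = FALSE)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 cell_lines = cell_lines,
                 bin_occupancy = bin_occupancy,
                 within_sigma = within_sigma,
                 between_separation = between_separation,
                 duplicate_fraction = duplicate_fraction,
                 jitter = jitter,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# latent bin centers: a shared random baseline plus, per bin, a random
# direction scaled to between_separation.  Random directions in moderate
# dimension are nearly orthogonal, so pairwise center distances concentrate
# near separation * sqrt(2); any center closer than the promised minimum to
# an earlier one is redrawn.  Coordinate magnitudes stay near the baseline
# for every bin, so the relative similarity window behaves uniformly.
synthetic_centers <- function(spec) {
  D <- spec$n_descriptors
  s <- spec$between_separation
  baseline <- stats::rnorm(D, mean = 5, sd = 1)
  bins <- sort(as.integer(names(spec$bin_occupancy)))
  centers <- matrix(NA_real_, length(bins), D,
                    dimnames = list(as.character(bins),
                                    sprintf("D%03d", seq_len(D))))
  for (i in seq_along(bins)) {
    for (try in seq_len(200L)) {
      u <- stats::rnorm(D)
      cand <- baseline + s * u / sqrt(sum(u^2))
      if (i == 1L) break
      gaps <- sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                              matrix(cand, i - 1L, D, byrow = TRUE))^2))
      if (all(gaps >= s)) break
      if (try == 200L)
        stop("cannot place ", length(bins), " bin centers at separation ",
             s, " in ", D, " descriptor dimensions; reduce the separation ",
             "or add descriptors", call. = FALSE)
    }
    centers[i, ] <- cand
  }
  centers
}

# draw one pGI50 inside a bin; edge bins use uniform 3..4 / 8..9
draw_activity_in_bin <- function(bin_idx) {
  bins <- activity_bins()
  lo <- bins$lower[bin_idx + 1L]
  hi <- bins$upper[bin_idx + 1L]
  lo <- ifelse(is.infinite(lo), 3, lo)
  hi <- ifelse(is.infinite(hi), 9, hi)
  stats::runif(length(bin_idx), lo, hi)
}

#' Generate a synthetic training set with planted bin structure
#'
#' @param spec a [synthetic_spec()].
#' @return list with `desc` ([descriptor_matrix()]), `act`
#'   ([activity_matrix()]), `truth` (data.frame `compound_id`, `bin`,
#'   `parent_id`; `parent_id` is `NA` for base compounds and the source id
#'   for clones), and `centers` (latent bin-center matrix).
#' @export
generate_training <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_descriptors < 1L)
    stop("need at least one descriptor", call. = FALSE)
  set.seed(spec$seed)
  centers <- synthetic_centers(spec)
  D <- spec$n_descriptors
  n <- spec$n_compounds
  bins_avail <- as.integer(rownames(centers))
  bin_of <- bins_avail[sample.int(length(bins_avail), n, replace = TRUE,
                                  prob = spec$bin_occupancy[rownames(centers)])]
  ids <- sprintf("SYN%04d", seq_len(n))
  desc <- centers[as.character(bin_of), , drop = FALSE] +
    matrix(stats::rnorm(n * D, 0, spec$within_sigma), n, D)
  rownames(desc) <- ids
  cls <- names(spec$cell_lines)
  act <- matrix(NA_real_, n, length(cls), dimnames = list(ids, cls))
  for (j in seq_along(cls))
    act[, j] <- draw_activity_in_bin(bin_of)
  if (spec$missing_rate > 0) {
    knock <- matrix(stats::runif(n * length(cls)) < spec$missing_rate,
                    n, length(cls))
    # keep at least one measured activity per compound so no row is useless
    for (i in which(rowSums(!knock) == 0L)) knock[i, sample(length(cls), 1L)] <- FALSE
    act[knock] <- NA_real_
  }
  parent <- rep(NA_character_, n)
  if (spec$duplicate_fraction > 0) {
    n_dup <- round(n * spec$duplicate_fraction)
    if (n_dup > 0L) {
      src <- sample(n, n_dup, replace = FALSE)
      jit <- matrix(stats::runif(n_dup * D, -spec$jitter, spec$jitter),
                    n_dup, D)
      dup_desc <- desc[src, , drop = FALSE] * (1 + jit)
      dup_ids <- sprintf("DUP%04d", seq_len(n_dup))
      rownames(dup_desc) <- dup_ids
      desc <- rbind(desc, dup_desc)
      act <- rbind(act, act[src, , drop = FALSE])   # clones share the full row
      rownames(act) <- c(ids, dup_ids)
      bin_of <- c(bin_of, bin_of[src])
      parent <- c(parent, ids[src])
      ids <- c(ids, dup_ids)
    }
  }
  list(desc = descriptor_matrix(desc),
       act = activity_matrix(act, spec$cell_lines),
       truth = data.frame(compound_id = ids, bin = bin_of,
                          parent_id = parent, stringsAsFactors = FALSE),
       centers = centers)
}

#' Generate fresh query compounds from the planted templates
#'
#' Draws `k` new descriptor vectors (never copies of training rows) from
#' the latent bin centers of a generated training set, with the spec's
#' within-bin noise, and returns their true bin labels for recovery
#' scoring.
#'
#' @param spec the [synthetic_spec()] used for training.
#' @param training output of [generate_training()] (supplies the centers).
#' @param k number of queries (> 0).
#' @param seed seed for the query draw (default: spec seed + 1).
#' @return list with `desc` ([descriptor_matrix()]) and `truth`
#'   (data.frame `query_id`, `bin`).
#' @export
generate_queries <- function(spec, training, k, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- as.integer(k)
  if (is.na(k) || k <= 0L) stop("k must be a positive count", call. = FALSE)
  centers <- training$centers
  set.seed(seed)
  bins_avail <- as.integer(rownames(centers))
  bin_of <- bins_avail[sample.int(length(bins_avail), k, replace = TRUE,
                                  prob = spec$bin_occupancy[rownames(centers)])]
  D <- ncol(centers)
  desc <- centers[as.character(bin_of), , drop = FALSE] +
    matrix(stats::rnorm(k * D, 0, spec$within_sigma), k, D)
  rownames(desc) <- sprintf("QRY%04d", seq_len(k))
  list(desc = descriptor_matrix(desc),
       truth = data.frame(query_id = rownames(desc), bin = bin_of,
                          stringsAsFactors = FALSE))
}

#' Write a synthetic benchmark to disk in the standard formats
#'
#' Emits `descriptors.csv` (wide, compound rows), `activity.csv` (long
#' layout) — the files consumed by the model-building front end.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return the training list from [generate_training()], invisibly.
#' @export
write_synthetic <- function(spec, dir) {
  tr <- generate_training(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_num_table(matrix_to_df(tr$desc, "compound_id"),
                  file.path(dir, "descriptors.csv"))
  a <- act_values(tr$act)
  panels <- panel_of(tr$act)
  long <- data.frame(
    compound_id = rep(rownames(a), ncol(a)),
    cell_line = rep(colnames(a), each = nrow(a)),
    panel = rep(unname(panels[colnames(a)]), each = nrow(a)),
    pGI50 = as.vector(a), stringsAsFactors = FALSE)
  long <- long[!is.na(long$pGI50), ]
  write_num_table(long, file.path(dir, "activity.csv"))
  write_num_table(tr$truth, file.path(dir, "truth.csv"))
  invisible(tr)
}
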