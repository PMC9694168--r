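#' Descriptor-tolerance similarity score
#'
#' Counts the descriptors of a query that fall within +/- 5% of the
#' corresponding reference (training-compound) value, divided by the number
#' of descriptors usable in the comparison:
#' `S = #\{i : |q_i - r_i| <= 0.05 |r_i|\} / #\{i : both present\}`.
#' Positions where either side is missing enter neither the numerator nor
#' the denominator.  The tolerance window is relative to the reference, so
#' the score is deliberately asymmetric; a reference value of exactly 0
#' degenerates to the window `{0}` and matches only a query value of 0.
#'
#' @param query_vec,ref_vec numeric vectors in the same descriptor order
#'   (`NA` = missing).
#' @return similarity S in \[0, 1\].
#' @export
similarity_score <- function(query_vec, ref_vec) {
  if (length(query_vec) != length(ref_vec))
    stop("query and reference vectors differ in length", call. = FALSE)
  usable <- !is.na(query_vec) & !is.na(ref_vec)
  n <- sum(usable)
  if (n == 0L)
    stop("no descriptor position usable in both vectors", call. = FALSE)
  hits <- abs(query_vec[usable] - ref_vec[usable]) <=
    0.05 * abs(ref_vec[usable])
  sum(hits) / n
}

#' Transfer activities from the most similar training compound
#'
#' Scores the query against every training compound with
#' [similarity_score()] and copies the experimental pGI50 row of the best
#' match verbatim; cell lines where the best match was not tested remain
#' missing.  Ties on S prefer the training compound with more non-missing
#' activity entries, then the lexicographically smaller id, so results are
#' deterministic.
#'
#' @param query_vec named numeric vector over the training descriptor set.
#' @param training_desc training [descriptor_matrix()].
#' @param training_act training [activity_matrix()], row-aligned with
#'   `training_desc`.
#' @return list with `query_id` (if the vector carries one as an attribute),
#'   `best_match_id`, `S`, and `gi50_fp` (named vector over cell lines).
#' @export
fp_predict <- function(query_vec, training_desc, training_act) {
  if (nrow(training_desc) == 0L)
    stop("empty training set", call. = FALSE)
  if (!identical(rownames(training_desc), rownames(training_act)))
    stop("training descriptor and activity matrices are not row-aligned",
         call. = FALSE)
  q <- align_query(query_vec, colnames(training_desc))
  Q <- matrix(q, nrow(training_desc), ncol(training_desc), byrow = TRUE)
  usable <- !is.na(Q) & !is.na(training_desc)
  hits <- usable & (abs(Q - training_desc) <= 0.05 * abs(training_desc))
  n_usable <- rowSums(usable)
  S <- ifelse(n_usable > 0L, rowSums(hits) / n_usable, NA_real_)
  if (all(is.na(S)))
    stop("query shares no usable descriptor with any training compound",
         call. = FALSE)
  n_act <- rowSums(!is.na(training_act))
  ids <- rownames(training_desc)
  ord <- order(-S, -n_act, ids, na.last = TRUE)
  best <- ord[1L]
  list(best_match_id = ids[best],
       S = unname(S[best]),
       gi50_fp = act_values(training_act)[best, ])
}

# reorder a named query vector onto the model descriptor set; unnamed
# vectors must already match in length and order
align_query <- function(query_vec, descriptor_list) {
  if (!is.null(names(query_vec))) {
    miss <- setdiff(descriptor_list, names(query_vec))
    if (length(miss))
      stop("query lacks model descriptor(s): ",
           paste(utils::head(miss, 5L), collapse = ", "),
           if (length(miss) > 5L) ", ..." else "", call. = FALSE)
    query_vec <- query_vec[descriptor_list]
  } else if (length(query_vec) != length(descriptor_list)) {
    stop("unnamed query vector of length ", length(query_vec),
         " does not match the ", length(descriptor_list),
         "-descriptor model", call. = FALSE)
  }
  as.numeric(query_vec)
}
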