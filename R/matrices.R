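#' Construct a descriptor matrix
#'
#' A descriptor matrix is a plain numeric matrix with compound ids as row
#' names and descriptor names as column names.  `NA` encodes a missing
#' (uncomputable) value; `NaN` and infinities are coerced to `NA` on
#' construction so that every stored value is either finite or missing.
#'
#' @param values numeric matrix (or object coercible to one) with row and
#'   column names.
#' @return a validated numeric matrix.
#' @examples
#' m <- descriptor_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("c1", "c2"), c("mw", "logp"))))
#' @export
descriptor_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 1L)
    stop("descriptor matrix needs at least one column", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("descriptor matrix needs row (compound) and column (descriptor) names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate compound ids in descriptor matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate descriptor names in descriptor matrix", call. = FALSE)
  values[!is.finite(values)] <- NA_real_
  values
}

#' Construct an activity matrix
#'
#' Holds experimental pGI50 (-log10 GI50 in molar) values, compounds in rows
#' and cell lines in columns, with `NA` for untested pairs.  Each cell line
#' carries a subpanel (tumor-type) label used for panel-level error
#' aggregation.
#'
#' @param values numeric matrix, compounds x cell lines, dimnames required.
#' @param panel named character vector mapping every cell-line id (column
#'   name) to its subpanel name.
#' @return a matrix of class `aap_activity` with a `panel` attribute.
#' @export
activity_matrix <- function(values, panel) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("activity matrix needs row (compound) and column (cell line) names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate compound ids in activity matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell-line ids in activity matrix", call. = FALSE)
  values[!is.finite(values)] <- NA_real_
  panel <- unlist(panel)
  missing_panel <- setdiff(colnames(values), names(panel))
  if (length(missing_panel))
    stop("no panel assignment for cell line(s): ",
         paste(missing_panel, collapse = ", "), call. = FALSE)
  attr(values, "panel") <- panel[colnames(values)]
  class(values) <- c("aap_activity", class(values))
  values
}

#' Subpanel assignment of an activity matrix
#' @param act an `aap_activity` matrix.
#' @return named character vector, cell line -> subpanel.
#' @export
panel_of <- function(act) attr(act, "panel")

#' @export
`[.aap_activity` <- function(x, i, j, ..., drop = FALSE) {
  panel <- attr(x, "panel")
  y <- unclass(x)[i, j, drop = drop]
  if (is.matrix(y)) {
    attr(y, "panel") <- panel[colnames(y)]
    class(y) <- c("aap_activity", class(y))
  }
  y
}

#' @export
print.aap_activity <- function(x, ...) {
  cat(sprintf("pGI50 activity matrix: %d compounds x %d cell lines (%d panels), %d missing\n",
              nrow(x), ncol(x), length(unique(attr(x, "panel"))),
              sum(is.na(x))))
  print(utils::head(unclass(x), 6L))
  invisible(x)
}

# strip class/attributes for plain numeric work
act_values <- function(act) {
  a <- unclass(act)
  attr(a, "panel") <- NULL
  a
}
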