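#' Read chemical structures from SDF or SMILES files
#'
#' SDF files (V2000, one molecule block per record) are parsed with
#' \pkg{ChemmineR}; record ids are taken from the SDF data field named by
#' `id_property`, falling back to the molfile title line when the field is
#' absent.  SMILES files hold one record per line: the SMILES string followed
#' by whitespace and the compound id.
#'
#' Ids are opaque strings (an "NSC 000123" stays exactly as written) and must
#' be unique within a file.
#'
#' @param path input file.
#' @param format `"sdf"` or `"smiles"`.
#' @param id_property SDF data field holding the compound id (default
#'   `"NSC"`).
#' @return list of structure records, each a list with elements `id`,
#'   `structure` (molblock text or SMILES string), `name` and `format`.
#' @export
read_structures <- function(path, format = c("sdf", "smiles"),
                            id_property = "NSC") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  recs <- switch(format,
    sdf = read_structures_sdf(path, id_property),
    smiles = read_structures_smiles(path))
  ids <- vapply(recs, `[[`, "", "id")
  if (any(!nzchar(ids))) {
    bad <- which(!nzchar(ids))
    stop("record ", bad[1L], " has an empty id", call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate structure id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  recs
}

read_structures_sdf <- function(path, id_property) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF files requires the ChemmineR package", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) return(list())
  str <- ChemmineR::read.SDFstr(path)
  sdfset <- tryCatch(methods::as(str, "SDFset"),
    error = function(e) stop("unparsable SDF record in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  blocks <- ChemmineR::datablock(sdfset)
  titles <- ChemmineR::sdfid(sdfset)
  out <- vector("list", length(sdfset))
  for (k in seq_along(sdfset)) {
    db <- blocks[[k]]
    id <- if (length(db) && id_property %in% names(db)) {
      trimws(db[[id_property]])
    } else {
      trimws(titles[k])
    }
    if (!nzchar(id))
      stop("SDF record ", k, " has neither a '", id_property,
           "' field nor a title line id", call. = FALSE)
    # keep the original record text rather than regenerating it
    molblock <- paste(str[[k]], collapse = "\n")
    out[[k]] <- list(id = id, structure = molblock,
                     name = trimws(titles[k]), format = "sdf")
  }
  out
}

read_structures_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    toks <- strsplit(trimws(lines[k]), "[[:space:]]+")[[1L]]
    if (length(toks) < 2L)
      stop("SMILES record ", k, " lacks an id column", call. = FALSE)
    out[[k]] <- list(id = toks[2L], structure = toks[1L],
                     name = if (length(toks) > 2L) paste(toks[-(1:2)], collapse = " ") else "",
                     format = "smiles")
  }
  out
}

#' Read a pGI50 activity table
#'
#' The canonical layout is long: a delimited file (comma or tab, header
#' required) with columns `compound_id`, `cell_line`, `panel`, `pGI50`.
#' The wide layout is a convenience importer: compounds in rows, cell lines
#' in columns, with a side file mapping cell lines to panels (columns
#' `cell_line`, `panel`).  Empty fields and `"NA"` both read as missing.
#' Values are stored exactly as given; no unit or scale transformation is
#' applied.
#'
#' @param path main table file.
#' @param layout `"long"` or `"wide"`.
#' @param panel_file side file with cell-line/panel columns (wide layout
#'   only).
#' @return an [activity_matrix()].
#' @export
read_activity_table <- function(path, layout = c("long", "wide"),
                                panel_file = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (layout == "long") read_activity_long(path) else
    read_activity_wide(path, panel_file)
}

read_activity_long <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = 1:3),
                          na.strings = c("", "NA"), data.table = TRUE)
  need <- c("compound_id", "cell_line", "panel", "pGI50")
  if (!all(need %in% names(dt)))
    stop("long activity table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  raw <- dt[["pGI50"]]
  if (!is.numeric(raw)) {
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop("non-numeric pGI50 at data row ", bad[1L], ": '", raw[bad[1L]], "'",
           call. = FALSE)
    raw <- num
  }
  key <- paste(dt$compound_id, dt$cell_line, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate (compound, cell line) pair at data row ", d, ": ",
         dt$compound_id[d], " / ", dt$cell_line[d], call. = FALSE)
  }
  if (anyNA(dt$panel))
    stop("missing panel at data row ", which(is.na(dt$panel))[1L],
         call. = FALSE)
  cl_panel <- unique(dt[, c("cell_line", "panel")])
  if (anyDuplicated(cl_panel$cell_line))
    stop("cell line assigned to more than one panel: ",
         cl_panel$cell_line[duplicated(cl_panel$cell_line)][1L],
         call. = FALSE)
  rows <- unique(dt$compound_id)
  cols <- unique(dt$cell_line)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(dt$compound_id, rows), match(dt$cell_line, cols))] <- raw
  activity_matrix(m, stats::setNames(cl_panel$panel, cl_panel$cell_line))
}

read_activity_wide <- function(path, panel_file) {
  if (is.null(panel_file))
    stop("wide layout requires a panel_file (columns cell_line, panel)",
         call. = FALSE)
  dt <- data.table::fread(path, na.strings = c("", "NA"), data.table = FALSE,
                          colClasses = list(character = 1L))
  ids <- dt[[1L]]
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  pf <- data.table::fread(panel_file, data.table = FALSE,
                          colClasses = "character")
  if (!all(c("cell_line", "panel") %in% names(pf)))
    stop("panel_file must have columns cell_line, panel", call. = FALSE)
  unknown <- setdiff(colnames(m), pf$cell_line)
  if (length(unknown))
    stop("cell line(s) without panel assignment: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  activity_matrix(m, stats::setNames(pf$panel, pf$cell_line))
}

#' Read or write a precomputed descriptor matrix
#'
#' Wide delimited text: first column `compound_id`, one column per
#' descriptor, header required.  Lets precomputed matrices bypass the
#' descriptor backend entirely.
#'
#' @param path file to read or write.
#' @return [read_descriptor_table()] returns a [descriptor_matrix()].
#' @export
read_descriptor_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, na.strings = c("", "NA"),
                          colClasses = list(character = 1L))
  names(dt)[1L] <- "compound_id"
  descriptor_matrix(df_to_matrix(dt, "compound_id"))
}

#' @rdname read_descriptor_table
#' @param m a [descriptor_matrix()] to write.
#' @export
write_descriptor_table <- function(m, path) {
  write_num_table(matrix_to_df(m, "compound_id"), path)
  invisible(path)
}

#' Split an activity matrix into training and test sets by membership
#'
#' @param act an [activity_matrix()].
#' @param training_ids compound ids forming the training set; must all be
#'   present in `act`.
#' @return list with elements `train` and `test`, both activity matrices
#'   over the same cell lines; rows partition the input.
#' @export
split_by_membership <- function(act, training_ids) {
  unknown <- setdiff(training_ids, rownames(act))
  if (length(unknown))
    stop("unknown compound id(s) in training_ids: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  tr <- rownames(act) %in% training_ids
  list(train = act[tr, , drop = FALSE],
       test  = act[!tr, , drop = FALSE])
}

# ---- model serialization: a directory of delimited text plus a manifest ----

MODEL_FORMAT_VERSION <- "aapred-model-1"

# numeric columns go out as %.17g so doubles round-trip bitwise
write_num_table <- function(df, path) {
  df <- data.table::as.data.table(df)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      v <- df[[nm]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- ""
      data.table::set(df, j = nm, value = s)
    }
  }
  data.table::fwrite(df, path, sep = ",", na = "", quote = TRUE)
}

matrix_to_df <- function(m, id_col) {
  df <- data.table::as.data.table(m, keep.rownames = id_col)
  df
}

df_to_matrix <- function(df, id_col) {
  ids <- df[[id_col]]
  m <- as.matrix(df[, setdiff(names(df), id_col), with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Save / load a trained model
#'
#' A model is persisted as a documented directory of delimited text files
#' plus a JSON manifest: portable, diffable and independent of R's binary
#' serialization.  Numeric values are written with round-trip precision so
#' `load_model(save_model(m))` reproduces template statistics bitwise.
#'
#' @param model an `aap_model` as returned by [build_model()].
#' @param path directory to create (overwritten if it exists).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "aap_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format_version = MODEL_FORMAT_VERSION,
    backend_id = model$backend_id,
    descriptor_list = model$descriptor_list,
    params = model$params[c("N", "Z", "G", "min_members")],
    excluded_cell_lines = model$excluded)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_num_table(matrix_to_df(model$train_desc, "compound_id"),
                  file.path(path, "training_descriptors.csv"))
  write_num_table(matrix_to_df(act_values(model$train_act), "compound_id"),
                  file.path(path, "training_activity.csv"))
  pn <- panel_of(model$train_act)
  write_num_table(data.table::data.table(cell_line = names(pn), panel = unname(pn)),
                  file.path(path, "panels.csv"))
  write_num_table(template_table(model$templates),
                  file.path(path, "templates.csv"))
  sel <- model$templates$selected
  sel_df <- data.table::data.table(
    cell_line = rep(names(sel), lengths(sel)),
    rank = unlist(lapply(sel, seq_along), use.names = FALSE),
    descriptor = unlist(sel, use.names = FALSE))
  write_num_table(sel_df, file.path(path, "selected_descriptors.csv"))
  cnt <- model$templates$counts
  cnt_df <- data.table::data.table(
    cell_line = rep(names(cnt), each = 42L),
    bin_index = rep(0:41, length(cnt)),
    member_count = unlist(cnt, use.names = FALSE))
  write_num_table(cnt_df, file.path(path, "member_counts.csv"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path))
    stop("not a model directory (no manifest.json): ", path, call. = FALSE)
  manifest <- tryCatch(jsonlite::read_json(mf_path, simplifyVector = TRUE),
    error = function(e) stop("corrupted model manifest: ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(manifest$format_version, MODEL_FORMAT_VERSION))
    stop("model format version mismatch: expected '", MODEL_FORMAT_VERSION,
         "', found '", manifest$format_version, "'", call. = FALSE)
  desc <- descriptor_matrix(df_to_matrix(
    data.table::fread(file.path(path, "training_descriptors.csv"),
                      na.strings = c("", "NA"),
                      colClasses = list(character = 1L)), "compound_id"))
  pn <- data.table::fread(file.path(path, "panels.csv"), data.table = FALSE,
                          colClasses = "character")
  act <- activity_matrix(df_to_matrix(
    data.table::fread(file.path(path, "training_activity.csv"),
                      na.strings = c("", "NA"),
                      colClasses = list(character = 1L)), "compound_id"),
    stats::setNames(pn$panel, pn$cell_line))
  params <- do.call(cl_params, manifest$params)
  tmpl_df <- data.table::fread(file.path(path, "templates.csv"),
                               na.strings = c("", "NA"),
                               colClasses = list(character = c(1L, 6L)))
  cnt_df <- data.table::fread(file.path(path, "member_counts.csv"),
                              colClasses = list(character = 1L))
  sel_df <- data.table::fread(file.path(path, "selected_descriptors.csv"),
                              data.table = FALSE, colClasses = "character")
  templates <- templates_from_tables(manifest$descriptor_list, tmpl_df,
                                     cnt_df, sel_df, params)
  structure(list(
    backend_id = manifest$backend_id,
    descriptor_list = manifest$descriptor_list,
    train_desc = desc,
    train_act = act,
    templates = templates,
    params = params,
    excluded = as.character(manifest$excluded_cell_lines)),
    class = "aap_model")
}
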