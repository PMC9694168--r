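# registry of descriptor backends, keyed by backend_id
.backends <- new.env(parent = emptyenv())

#' Define a descriptor backend
#'
#' A backend maps one structure record to one real-valued descriptor vector
#' of fixed length and order.  Backends must be deterministic: the same
#' structure always yields the same vector.  Individual descriptors that the
#' backend cannot compute are returned as `NA`.
#'
#' @param backend_id short unique identifier.
#' @param descriptor_names ordered character vector of descriptor names.
#' @param compute function(record) returning a numeric vector of length
#'   `length(descriptor_names)` (names optional).
#' @return an object of class `aap_backend`.
#' @export
new_descriptor_backend <- function(backend_id, descriptor_names, compute) {
  stopifnot(is.character(backend_id), length(backend_id) == 1L,
            is.character(descriptor_names), length(descriptor_names) >= 1L,
            is.function(compute))
  structure(list(backend_id = backend_id,
                 descriptor_names = descriptor_names,
                 compute = compute,
                 cache = new.env(parent = emptyenv())),
            class = "aap_backend")
}

#' Register a backend under its id
#' @param backend an `aap_backend`.
#' @export
register_backend <- function(backend) {
  stopifnot(inherits(backend, "aap_backend"))
  assign(backend$backend_id, backend, envir = .backends)
  invisible(backend)
}

#' Look up a registered backend
#' @param backend_id identifier used at registration.
#' @export
descriptor_backend <- function(backend_id) {
  if (!exists(backend_id, envir = .backends, inherits = FALSE))
    stop("unknown descriptor backend '", backend_id, "'; registered: ",
         paste(ls(.backends), collapse = ", "), call. = FALSE)
  get(backend_id, envir = .backends, inherits = FALSE)
}

#' @rdname descriptor_backend
#' @export
list_backends <- function() ls(.backends)

#' Compute a descriptor matrix for a batch of structures
#'
#' One row per structure, one column per backend descriptor.  A failure for
#' a single structure yields an all-`NA` row and a warning, never an abort.
#' Results are cached inside the backend by structure payload, so
#' resubmitting a structure is a lookup.
#'
#' @param structures list of records from [read_structures()].
#' @param backend an `aap_backend` or a registered backend id.
#' @return a [descriptor_matrix()].
#' @export
compute_descriptors <- function(structures, backend) {
  if (is.character(backend)) backend <- descriptor_backend(backend)
  stopifnot(inherits(backend, "aap_backend"))
  nms <- backend$descriptor_names
  ids <- vapply(structures, `[[`, "", "id")
  m <- matrix(NA_real_, length(structures), length(nms),
              dimnames = list(ids, nms))
  for (k in seq_along(structures)) {
    rec <- structures[[k]]
    key <- paste0(rec$format, "\r", rec$structure)
    if (exists(key, envir = backend$cache, inherits = FALSE)) {
      m[k, ] <- get(key, envir = backend$cache, inherits = FALSE)
      next
    }
    v <- tryCatch({
      out <- backend$compute(rec)
      stopifnot(length(out) == length(nms))
      as.numeric(out)
    }, error = function(e) {
      warning("descriptor computation failed for '", rec$id, "': ",
              conditionMessage(e), call. = FALSE)
      rep(NA_real_, length(nms))
    })
    v[!is.finite(v)] <- NA_real_
    assign(key, v, envir = backend$cache)
    m[k, ] <- v
  }
  descriptor_matrix(m)
}

# ---- shipped default: 2D physicochemical backend over ChemmineR ----

chemmine2d_elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
chemmine2d_props <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD")

chemmine2d_names <- c(chemmine2d_props,
                      paste0("n", chemmine2d_elements),
                      "n_atoms", "n_rings", "n_arom_rings")

chemmine2d_compute <- function(rec) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("the 'chemmine2d' backend requires ChemmineR")
  sdfset <- if (identical(rec$format, "smiles")) {
    ChemmineR::smiles2sdf(rec$structure)
  } else {
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf), add = TRUE)
    writeLines(c(rec$structure, "$$$$"), tf)
    ChemmineR::read.SDFset(tf)
  }
  props <- suppressWarnings(ChemmineR::propOB(sdfset))
  pvals <- vapply(chemmine2d_props, function(p)
    if (p %in% names(props)) as.numeric(props[[p]][1L]) else NA_real_,
    0)
  counts <- ChemmineR::atomcountMA(sdfset, addH = FALSE)
  cvals <- vapply(chemmine2d_elements, function(el)
    if (el %in% colnames(counts)) as.numeric(counts[1L, el]) else 0,
    0)
  ring <- tryCatch(ChemmineR::rings(sdfset[[1L]], upper = 12,
                                    type = "count", arom = TRUE),
                   error = function(e) c(RINGS = NA_real_, AROMATIC = NA_real_))
  c(pvals, cvals,
    n_atoms = sum(cvals),
    n_rings = as.numeric(ring[["RINGS"]]),
    n_arom_rings = as.numeric(ring[["AROMATIC"]]))
}

register_default_backends <- function() {
  register_backend(new_descriptor_backend(
    "chemmine2d", chemmine2d_names, chemmine2d_compute))
}

.onLoad <- function(libname, pkgname) {
  register_default_backends()
}
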