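# Mosaic data containers: batches with partially overlapping modality sets,
# bridge connectivity, and readers/writers for the standard on-disk formats.

.BUILTIN_MODALITIES <- c("RNA", "ATAC", "Protein", "HistoneMark")
.MODALITY_ALIASES <- c(
  rna = "RNA", atac = "ATAC", protein = "Protein", adt = "Protein",
  histonemark = "HistoneMark", histone = "HistoneMark"
)

#' Canonicalize a modality name
#'
#' Built-in modality names (RNA, ATAC, Protein, HistoneMark) are matched
#' case-insensitively; `ADT` is an alias for `Protein` (the two terms are used
#' interchangeably for the antibody-derived-tag readout of CITE-seq/ASAP-seq).
#' Unknown names are kept verbatim, so user-defined modalities are allowed.
#'
#' @param x character vector of modality names.
#' @return character vector of canonical names.
#' @export
canonical_modality <- function(x) {
  stopifnot(is.character(x))
  key <- tolower(x)
  hit <- key %in% names(.MODALITY_ALIASES)
  x[hit] <- unname(.MODALITY_ALIASES[key[hit]])
  x
}

.check_matrix <- function(m, what) {
  if (!(is.matrix(m) || inherits(m, "Matrix"))) {
    stop(what, ": expected a numeric matrix", call. = FALSE)
  }
  vals <- if (inherits(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(vals) && !all(is.finite(vals))) {
    stop(what, ": matrix contains non-finite or non-numeric entries", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a batch record
#'
#' One sequencing batch with the matrices of the modalities it measures. All
#' matrices must have the same cells (identical rownames) in the same order;
#' rows are canonicalized by sorting on the cell identifier so that downstream
#' indices never depend on on-disk row order. Within a multimodal batch, rows
#' sharing a cell identifier are the same physical cell (paired assay).
#'
#' @param batch_id unique batch identifier.
#' @param matrices named list, modality name -> cells x features matrix with
#'   unique rownames (cell identifiers).
#' @return a `batch_record` list with elements `batch_id`, `matrices`,
#'   `measured_set`, `cell_ids`.
#' @export
batch_record <- function(batch_id, matrices) {
  stopifnot(is.character(batch_id), length(batch_id) == 1L, nzchar(batch_id))
  if (!is.list(matrices) || length(matrices) == 0L || is.null(names(matrices))) {
    stop("batch '", batch_id, "': matrices must be a non-empty named list", call. = FALSE)
  }
  names(matrices) <- canonical_modality(names(matrices))
  if (anyDuplicated(names(matrices))) {
    stop("batch '", batch_id, "': duplicated modality names after aliasing", call. = FALSE)
  }
  ids <- NULL
  for (mod in names(matrices)) {
    m <- matrices[[mod]]
    .check_matrix(m, sprintf("batch '%s', modality '%s'", batch_id, mod))
    rn <- rownames(m)
    if (is.null(rn) || anyDuplicated(rn)) {
      stop("batch '", batch_id, "', modality '", mod,
           "': rows must carry unique cell identifiers", call. = FALSE)
    }
    if (is.null(ids)) {
      ids <- rn
    } else if (!setequal(ids, rn) || length(ids) != length(rn)) {
      stop("batch '", batch_id, "': cell identifiers of modality '", mod,
           "' do not match the other modalities of this batch", call. = FALSE)
    }
  }
  ord <- sort(ids)
  matrices <- lapply(matrices, function(m) m[ord, , drop = FALSE])
  structure(
    list(batch_id = batch_id, matrices = matrices,
         measured_set = names(matrices), cell_ids = ord),
    class = "batch_record"
  )
}

#' Construct a mosaic dataset
#'
#' The full mosaic: an ordered list of batches, each measuring a subset of the
#' dataset's modalities. `(batch_id, cell_id)` is globally unique; cell-type
#' labels, when given, are used for evaluation only.
#'
#' @param batches list of [batch_record()] objects.
#' @param modalities optional ordered character vector of modality names;
#'   defaults to the union over batches in order of first appearance.
#' @param cell_types optional data.frame with columns `batch_id`, `cell_id`,
#'   `cell_type` covering any subset of cells.
#' @return a `mosaic_dataset`.
#' @export
mosaic_dataset <- function(batches, modalities = NULL, cell_types = NULL) {
  if (length(batches) == 0L) stop("no batches", call. = FALSE)
  stopifnot(all(vapply(batches, inherits, logical(1), "batch_record")))
  ids <- vapply(batches, `[[`, character(1), "batch_id")
  if (anyDuplicated(ids)) stop("duplicated batch ids", call. = FALSE)
  names(batches) <- ids
  seen <- unique(unlist(lapply(batches, `[[`, "measured_set")))
  if (is.null(modalities)) {
    modalities <- seen
  } else {
    modalities <- canonical_modality(modalities)
    if (!all(seen %in% modalities)) {
      stop("batches measure modalities not listed in `modalities`: ",
           paste(setdiff(seen, modalities), collapse = ", "), call. = FALSE)
    }
  }
  meta <- data.frame(
    batch_id = rep(ids, vapply(batches, function(b) length(b$cell_ids), integer(1))),
    cell_id = unlist(lapply(batches, `[[`, "cell_ids"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  meta$cell_type <- NA_character_
  if (!is.null(cell_types)) {
    stopifnot(all(c("batch_id", "cell_id", "cell_type") %in% names(cell_types)))
    key <- paste(meta$batch_id, meta$cell_id, sep = "\r")
    ck <- paste(cell_types$batch_id, cell_types$cell_id, sep = "\r")
    idx <- match(key, ck)
    meta$cell_type[!is.na(idx)] <- as.character(cell_types$cell_type[idx[!is.na(idx)]])
  }
  structure(
    list(batches = batches, modalities = modalities, cell_meta = meta),
    class = "mosaic_dataset"
  )
}

#' @exportS3Method base::print
print.mosaic_dataset <- function(x, ...) {
  cat("mosaic_dataset:", length(x$batches), "batches,",
      nrow(x$cell_meta), "cells,", length(x$modalities), "modalities\n")
  for (b in x$batches) {
    cat(sprintf("  %s: %d cells [%s]\n", b$batch_id, length(b$cell_ids),
                paste(b$measured_set, collapse = "+")))
  }
  invisible(x)
}

#' Cells measuring a modality
#'
#' @param ds a `mosaic_dataset`.
#' @param modality modality name.
#' @return data.frame with columns `batch_id`, `cell_id` in canonical order.
#' @export
cells_measuring <- function(ds, modality) {
  modality <- canonical_modality(modality)
  keep <- vapply(ds$batches, function(b) modality %in% b$measured_set, logical(1))
  bs <- ds$batches[keep]
  data.frame(
    batch_id = rep(names(bs), vapply(bs, function(b) length(b$cell_ids), integer(1))),
    cell_id = unlist(lapply(bs, `[[`, "cell_ids"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# ---- bridge graph -----------------------------------------------------------

#' Build the modality bridge graph
#'
#' Modalities are nodes; every batch measuring >= 2 modalities contributes one
#' edge per unordered modality pair it measures. Alignment is only possible
#' when all modalities fall in a single connected component of this graph.
#'
#' @param ds a `mosaic_dataset`.
#' @return a `bridge_graph` with elements `nodes`, `edges` (data.frame
#'   `from`, `to`, `batch_id`), `components` (list of node sets) and
#'   `is_connected`.
#' @export
build_bridge_graph <- function(ds) {
  stopifnot(inherits(ds, "mosaic_dataset"))
  nodes <- ds$modalities
  edges <- list()
  for (b in ds$batches) {
    s <- b$measured_set
    if (length(s) >= 2L) {
      pr <- utils::combn(sort(s), 2L)
      edges[[length(edges) + 1L]] <- data.frame(
        from = pr[1L, ], to = pr[2L, ], batch_id = b$batch_id,
        stringsAsFactors = FALSE
      )
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), batch_id = character(),
               stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  structure(
    list(nodes = nodes, edges = edges, components = unname(comps),
         is_connected = comp$no <= 1L),
    class = "bridge_graph"
  )
}

#' Assert that all modalities are bridged
#'
#' @param g a `bridge_graph` (or a `mosaic_dataset`, converted on the fly).
#' @return invisibly `TRUE` when connected; otherwise an error listing the
#'   disconnected components so the missing bridge is visible.
#' @export
require_connected <- function(g) {
  if (inherits(g, "mosaic_dataset")) g <- build_bridge_graph(g)
  stopifnot(inherits(g, "bridge_graph"))
  if (length(g$nodes) == 0L) stop("no batches", call. = FALSE)
  if (!g$is_connected) {
    desc <- vapply(g$components, function(s) paste0("{", paste(s, collapse = ","), "}"),
                   character(1))
    stop("modalities are not connected by any bridge batch; components: ",
         paste(desc, collapse = " "), call. = FALSE)
  }
  invisible(TRUE)
}

# ---- readers / writers ------------------------------------------------------

.read_matrix_file <- function(spec, what) {
  fmt <- tolower(spec$format %||% "")
  if (fmt == "mtx") {
    m <- as.matrix(Matrix::readMM(spec$path))
    rn <- readLines(spec$barcodes)
    cn <- if (!is.null(spec$features)) readLines(spec$features) else
      paste0("f", seq_len(ncol(m)))
    if (length(rn) != nrow(m)) {
      stop(what, ": barcodes file length does not match matrix rows", call. = FALSE)
    }
    dimnames(m) <- list(rn, cn)
    m
  } else if (fmt %in% c("csv", "tsv", "table")) {
    dt <- data.table::fread(spec$path, header = TRUE)
    rn <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop(what, ": non-numeric entries in table", call. = FALSE)
    rownames(m) <- rn
    m
  } else if (fmt == "h5ad") {
    read_h5ad_matrix(spec$path, layer = spec$layer)
  } else {
    stop(what, ": unknown format '", spec$format, "'", call. = FALSE)
  }
}

#' Load a mosaic dataset from standard files
#'
#' @param layout nested list: `layout$batches[[batch_id]][[modality]]` is a
#'   list describing one matrix file with fields `format` (`"mtx"`, `"csv"`,
#'   `"tsv"`, or `"h5ad"`), `path`, and for MTX additionally `barcodes` and
#'   optional `features` (line-per-entry text files). An optional
#'   `layout$cell_types` names a CSV with columns `batch_id,cell_id,cell_type`.
#' @return validated [mosaic_dataset()]; within each batch, rows of all
#'   modalities are re-ordered to one shared cell order (sorted identifiers).
#' @export
load_mosaic <- function(layout) {
  stopifnot(is.list(layout), is.list(layout$batches), length(layout$batches) > 0L)
  batches <- lapply(names(layout$batches), function(bid) {
    specs <- layout$batches[[bid]]
    mats <- lapply(names(specs), function(mod) {
      .read_matrix_file(specs[[mod]], sprintf("batch '%s', modality '%s'", bid, mod))
    })
    names(mats) <- names(specs)
    batch_record(bid, mats)
  })
  ct <- NULL
  if (!is.null(layout$cell_types)) {
    ct <- as.data.frame(data.table::fread(layout$cell_types, header = TRUE))
  }
  mosaic_dataset(batches, cell_types = ct)
}

#' Write a mosaic dataset to a directory
#'
#' One subdirectory per batch holding, per modality, an MTX matrix plus
#' barcode/feature label files, and a top-level `cell_types.csv` when labels
#' are present. [load_mosaic()] on the returned layout reproduces the dataset.
#'
#' @param ds a `mosaic_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, a `layout` list suitable for [load_mosaic()].
#' @export
write_mosaic <- function(ds, dir) {
  stopifnot(inherits(ds, "mosaic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layout <- list(batches = list())
  for (b in ds$batches) {
    bdir <- file.path(dir, b$batch_id)
    dir.create(bdir, showWarnings = FALSE)
    specs <- list()
    for (mod in b$measured_set) {
      m <- b$matrices[[mod]]
      base <- file.path(bdir, mod)
      Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                              "generalMatrix"), "TsparseMatrix"),
                      paste0(base, ".mtx"))
      writeLines(rownames(m), paste0(base, ".barcodes.txt"))
      writeLines(colnames(m) %||% paste0("f", seq_len(ncol(m))),
                 paste0(base, ".features.txt"))
      specs[[mod]] <- list(format = "mtx", path = paste0(base, ".mtx"),
                           barcodes = paste0(base, ".barcodes.txt"),
                           features = paste0(base, ".features.txt"))
    }
    layout$batches[[b$batch_id]] <- specs
  }
  if (any(!is.na(ds$cell_meta$cell_type))) {
    ctp <- file.path(dir, "cell_types.csv")
    data.table::fwrite(ds$cell_meta, ctp)
    layout$cell_types <- ctp
  }
  invisible(layout)
}

#' Load a mosaic dataset from a [write_mosaic()] directory
#'
#' Reconstructs the layout from the directory convention (one subdirectory
#' per batch; `<modality>.mtx` with `.barcodes.txt`/`.features.txt` label
#' files; optional top-level `cell_types.csv`) and calls [load_mosaic()].
#'
#' @param dir directory previously populated by [write_mosaic()].
#' @return a `mosaic_dataset`.
#' @export
read_mosaic_dir <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: '", dir, "'", call. = FALSE)
  bdirs <- list.dirs(dir, recursive = FALSE)
  if (length(bdirs) == 0L) {
    stop("no batch subdirectories under '", dir, "'", call. = FALSE)
  }
  layout <- list(batches = list())
  for (bdir in bdirs) {
    paths <- list.files(bdir, pattern = "\\.mtx$", full.names = TRUE)
    if (length(paths) == 0L) next
    specs <- list()
    for (p in paths) {
      mod <- sub("\\.mtx$", "", basename(p))
      base <- sub("\\.mtx$", "", p)
      specs[[mod]] <- list(format = "mtx", path = p,
                           barcodes = paste0(base, ".barcodes.txt"),
                           features = paste0(base, ".features.txt"))
    }
    layout$batches[[basename(bdir)]] <- specs
  }
  ctp <- file.path(dir, "cell_types.csv")
  if (file.exists(ctp)) layout$cell_types <- ctp
  load_mosaic(layout)
}

#' Write an embedding table
#'
#' Delimited table with `batch_id`, `cell_id` columns followed by the `d`
#' numeric embedding columns, written at full double precision so a read-back
#' reproduces the values.
#'
#' @param emb cells x d numeric matrix.
#' @param ids data.frame with columns `batch_id`, `cell_id`, one row per
#'   embedding row.
#' @param path output file; `.tsv` extension selects tab separation.
#' @export
write_embeddings <- function(emb, ids, path) {
  emb <- as.matrix(emb)
  stopifnot(is.data.frame(ids), all(c("batch_id", "cell_id") %in% names(ids)))
  if (nrow(emb) != nrow(ids)) {
    stop("embedding has ", nrow(emb), " rows but ids has ", nrow(ids), call. = FALSE)
  }
  d <- ncol(emb)
  cols <- colnames(emb) %||% sprintf("dim%d", seq_len(d))
  dt <- data.table::as.data.table(
    c(list(batch_id = ids$batch_id, cell_id = ids$cell_id),
      stats::setNames(lapply(seq_len(d), function(j) emb[, j]), cols))
  )
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Read an embedding table written by [write_embeddings()]
#'
#' @param path file path.
#' @return list with `ids` (data.frame `batch_id`, `cell_id`) and `values`
#'   (numeric matrix).
#' @export
read_embeddings <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  ids <- data.frame(batch_id = as.character(dt$batch_id),
                    cell_id = as.character(dt$cell_id),
                    stringsAsFactors = FALSE)
  vals <- as.matrix(dt[, -(1:2), drop = FALSE])
  list(ids = ids, values = vals)
}

# ---- minimal h5ad-dialect support -------------------------------------------

#' Read a cells x features matrix from an h5ad-dialect HDF5 file
#'
#' Supports dense `X`, CSR/CSC-encoded sparse `X`, and named entries under
#' `layers/`. Row names are taken from `obs/_index` (or `obs/index`), column
#' names from `var/_index`. Requires the rhdf5 package.
#'
#' @param path HDF5 file.
#' @param layer optional layer name; default the main `X` matrix.
#' @return dense numeric matrix with dimnames.
#' @export
read_h5ad_matrix <- function(path, layer = NULL) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("reading h5ad files requires the rhdf5 package", call. = FALSE)
  }
  node <- if (is.null(layer)) "X" else paste0("layers/", layer)
  h5 <- rhdf5::h5ls(path)
  read_obj <- function(name) rhdf5::h5read(path, name)
  grp_children <- h5$name[h5$group == paste0("/", node)]
  if (length(grp_children) && all(c("data", "indices", "indptr") %in% grp_children)) {
    data <- as.numeric(read_obj(paste0(node, "/data")))
    indices <- as.integer(read_obj(paste0(node, "/indices")))
    indptr <- as.integer(read_obj(paste0(node, "/indptr")))
    attrs <- rhdf5::h5readAttributes(path, node)
    shape <- as.integer(attrs$shape)
    enc <- attrs$`encoding-type` %||% "csr_matrix"
    if (grepl("csr", enc)) {
      m <- new("dgRMatrix", x = data, j = indices, p = indptr,
               Dim = shape)
      m <- as.matrix(m)
    } else {
      m <- as.matrix(Matrix::sparseMatrix(i = indices + 1L, p = indptr,
                                          x = data, dims = shape))
    }
  } else {
    m <- read_obj(node)
    # HDF5 stores row-major; h5read returns dims reversed relative to anndata
    m <- t(as.matrix(m))
  }
  idx <- function(grp) {
    for (cand in c("_index", "index")) {
      nm <- paste0(grp, "/", cand)
      ok <- any(h5$group == paste0("/", grp) & h5$name == cand)
      if (ok) return(as.character(read_obj(nm)))
    }
    NULL
  }
  rn <- idx("obs"); cn <- idx("var")
  if (!is.null(rn) && length(rn) == nrow(m)) rownames(m) <- rn
  if (!is.null(cn) && length(cn) == ncol(m)) colnames(m) <- cn
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
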