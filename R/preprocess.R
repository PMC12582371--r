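# Per-modality dimensionality reduction and within-modality horizontal batch
# correction. The reduced, corrected matrices are what the encoders consume.

#' Construct a modality input
#'
#' @param modality modality name.
#' @param rows data.frame with `batch_id`, `cell_id` (one per row of `values`).
#' @param values cells x p numeric matrix.
#' @param provenance free-form list recording how the matrix was produced.
#' @return a `modality_input`.
#' @export
modality_input <- function(modality, rows, values, provenance = list()) {
  values <- as.matrix(values)
  stopifnot(is.data.frame(rows), nrow(rows) == nrow(values),
            all(c("batch_id", "cell_id") %in% names(rows)))
  if (!all(is.finite(values))) stop("modality input contains non-finite values", call. = FALSE)
  structure(list(modality = canonical_modality(modality), rows = rows,
                 values = values, provenance = provenance),
            class = "modality_input")
}

.stack_modality <- function(ds, modality) {
  rows <- cells_measuring(ds, modality)
  mats <- lapply(unique(rows$batch_id), function(bid) ds$batches[[bid]]$matrices[[modality]])
  X <- do.call(rbind, mats)
  list(rows = rows, X = as.matrix(X))
}

#' Reduce one modality to a low-dimensional representation
#'
#' Computed jointly over all cells measuring the modality, across batches.
#' `pca`: per-cell library-size normalization to the median total, `log1p`,
#' feature standardization, then the top `p` principal components. For ATAC
#' `tfidf_lsi` is conventional: TF-IDF weighting followed by the top `p` left
#' singular vectors scaled by their singular values, optionally dropping the
#' first component (which typically tracks sequencing depth). `passthrough`
#' returns the matrix unchanged, for inputs that are already reduced.
#'
#' @param ds a `mosaic_dataset`.
#' @param modality modality name.
#' @param method one of `"pca"`, `"tfidf_lsi"`, `"passthrough"`.
#' @param p target dimension (ignored by `passthrough`).
#' @param drop_first for `tfidf_lsi`, drop the first component (default TRUE).
#' @param seed integer seed (reduction is deterministic; kept for provenance
#'   and future randomized solvers).
#' @return a [modality_input()].
#' @export
reduce_modality <- function(ds, modality,
                            method = c("pca", "tfidf_lsi", "passthrough"),
                            p = 100L, drop_first = TRUE, seed = 0L) {
  method <- match.arg(method)
  modality <- canonical_modality(modality)
  st <- .stack_modality(ds, modality)
  X <- st$X
  if (nrow(X) == 0L) stop("modality '", modality, "' is measured in no batch", call. = FALSE)
  if (method == "passthrough") {
    return(modality_input(modality, st$rows, X,
                          list(reduction = "passthrough", seed = seed)))
  }
  p <- as.integer(p)
  if (p > min(dim(X))) {
    stop("p = ", p, " exceeds the rank bound min(cells, features) = ",
         min(dim(X)), call. = FALSE)
  }
  zero_rows <- rowSums(abs(X)) == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows), " all-zero rows in modality '", modality,
            "'; kept as zero vectors")
  }
  if (method == "pca") {
    if (all(X >= 0)) {
      # count-like input: per-cell library-size scaling to the median total,
      # then log1p; continuous (signed) input goes straight to standardization
      lib <- rowSums(X)
      lib[lib == 0] <- 1
      Xn <- log1p(X / lib * stats::median(rowSums(X)))
    } else {
      Xn <- X
    }
    mu <- colMeans(Xn)
    sdv <- apply(Xn, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(Xn, 2L, mu), 2L, sdv, "/")
    sv <- svd(Xs, nu = p, nv = 0)
    red <- sv$u %*% diag(sv$d[seq_len(p)], p, p)
  } else { # tfidf_lsi
    tf <- X / pmax(rowSums(X), 1)
    idf <- log1p(nrow(X) / pmax(colSums(X > 0), 1))
    Xt <- sweep(tf, 2L, idf, "*")
    p_eff <- min(p + as.integer(drop_first), min(dim(Xt)))
    sv <- svd(Xt, nu = p_eff, nv = 0)
    red <- sv$u %*% diag(sv$d[seq_len(p_eff)], p_eff, p_eff)
    if (drop_first && ncol(red) > 1L) red <- red[, -1L, drop = FALSE]
  }
  colnames(red) <- sprintf("%s%d", toupper(substr(method, 1, 1)), seq_len(ncol(red)))
  modality_input(modality, st$rows, red,
                 list(reduction = method, p = p, drop_first = drop_first, seed = seed))
}

#' Correct additive batch effects within one modality
#'
#' `harmony` delegates to the external Harmony implementation through a
#' narrow adapter (matrix + labels in, matrix out) and errors when the package
#' is not installed. `center` subtracts each batch's mean and adds back the
#' global mean — it exactly removes purely additive per-batch shifts and keeps
#' the full pipeline testable without external dependencies. `none` is the
#' identity.
#'
#' @param mi a [modality_input()].
#' @param method one of `"harmony"`, `"center"`, `"none"`.
#' @param seed integer seed (passed to Harmony).
#' @return a corrected [modality_input()] of identical dimension.
#' @export
correct_batches <- function(mi, method = c("none", "center", "harmony"), seed = 0L) {
  method <- match.arg(method)
  stopifnot(inherits(mi, "modality_input"))
  labels <- mi$rows$batch_id
  if (method == "none") {
    mi$provenance$correction <- "none"
    return(mi)
  }
  if (length(unique(labels)) < 2L) {
    if (method == "harmony") warning("single batch: harmony skipped, input returned unchanged")
    mi$provenance$correction <- paste0(method, " (single batch, identity)")
    return(mi)
  }
  if (method == "center") {
    g <- colMeans(mi$values)
    V <- mi$values
    for (b in unique(labels)) {
      idx <- labels == b
      V[idx, ] <- sweep(V[idx, , drop = FALSE], 2L,
                        colMeans(V[idx, , drop = FALSE]) - g)
    }
    mi$values <- V
    mi$provenance$correction <- "center"
    return(mi)
  }
  # harmony adapter
  if (!requireNamespace("harmony", quietly = TRUE)) {
    stop("the harmony package is not installed; use correction method ",
         "'center' or 'none'", call. = FALSE)
  }
  V <- harmony::RunHarmony(mi$values, meta_data = data.frame(batch = labels),
                           vars_use = "batch", verbose = FALSE)
  mi$values <- as.matrix(V)
  mi$provenance$correction <- "harmony"
  mi
}

#' Prepare encoder inputs for every modality
#'
#' Convenience wrapper running [reduce_modality()] then [correct_batches()]
#' per modality. Defaults: PCA for RNA and Protein, TF-IDF/LSI for ATAC,
#' PCA for anything else.
#'
#' @param ds a `mosaic_dataset`.
#' @param p reduced dimension (single value or named per-modality vector).
#' @param correction correction method passed to [correct_batches()].
#' @param methods optional named character vector overriding the per-modality
#'   reduction method.
#' @param seed integer seed.
#' @return named list of [modality_input()] objects.
#' @export
prepare_inputs <- function(ds, p = 100L, correction = "none", methods = NULL, seed = 0L) {
  out <- list()
  for (mod in ds$modalities) {
    meth <- if (!is.null(methods) && mod %in% names(methods)) methods[[mod]]
            else if (mod == "ATAC") "tfidf_lsi" else "pca"
    pm <- if (length(p) > 1L && mod %in% names(p)) p[[mod]] else p[[1L]]
    st <- .stack_modality(ds, mod)
    pm <- min(as.integer(pm), min(dim(st$X)) - (meth == "tfidf_lsi"))
    mi <- reduce_modality(ds, mod, method = meth, p = pm, seed = seed)
    out[[mod]] <- correct_batches(mi, method = correction, seed = seed)
  }
  out
}
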