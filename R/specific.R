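# Modality-specific representations: independent per-modality encoders
# trained with the separation loss, cross-modality kNN imputation of
# missing-modality embeddings in the aligned space, and equal-weight
# consensus.

#' Imputation configuration
#'
#' @param k number of nearest neighbors averaged per imputation (default 2).
#' @param metric similarity used for cross-modality matching in the shared
#'   space: `"cosine"` (consistent with the training objective) or
#'   `"euclidean"`.
#' @return an `imputation_config`.
#' @export
imputation_config <- function(k = 2L, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(k >= 1L)
  structure(list(k = as.integer(k), metric = metric), class = "imputation_config")
}

#' Train modality-specific encoders
#'
#' Each modality's encoder is trained independently on mini-batches drawn
#' uniformly without replacement (per epoch) from all cells measuring that
#' modality, with [specificity_loss()] — the objective only separates cells,
#' so the learned space preserves within-modality variation. Training one
#' modality never reads another modality's data.
#'
#' @param inputs named list of [modality_input()] objects.
#' @param enc_specs optional named list of [encoder_spec()].
#' @param train_cfg a [train_config()]; defaults for this stage are
#'   lr 1.75e-4, batch 512, 10 epochs (see [train_config()]).
#' @param loss_cfg a [loss_config()]; only `tau` is used.
#' @return list with `encoders` (named list) and `trace` (data.frame with
#'   `modality`, `step`, `epoch`, `loss`).
#' @export
train_specific <- function(inputs, enc_specs = NULL,
                           train_cfg = train_config(lr = 1.75e-4, epochs = 10L),
                           loss_cfg = loss_config()) {
  enc_specs <- .default_enc_specs(inputs, enc_specs)
  encoders <- list()
  traces <- list()
  for (mod in names(inputs)) {
    X <- inputs[[mod]]$values
    if (nrow(X) < 2L) stop("modality '", mod, "' has fewer than 2 cells", call. = FALSE)
    set.seed(train_cfg$seed + match(mod, names(inputs)))
    enc <- mlp_init(enc_specs[[mod]])
    state <- adam_init(enc)
    steps_per_epoch <- max(1L, ceiling(nrow(X) / train_cfg$batch_size))
    step <- 0L
    for (ep in seq_len(train_cfg$epochs)) {
      perm <- sample.int(nrow(X))
      for (s in seq_len(steps_per_epoch)) {
        step <- step + 1L
        lo <- (s - 1L) * train_cfg$batch_size + 1L
        hi <- min(s * train_cfg$batch_size, nrow(X))
        sel <- perm[lo:hi]
        if (length(sel) < 2L) next
        fw <- mlp_forward(enc, X[sel, , drop = FALSE], training = TRUE)
        lg <- specificity_grad(fw$output, loss_cfg, norm_eps = 1e-8)
        if (!is.finite(lg$loss)) {
          stop("non-finite specificity loss for '", mod, "' at step ", step,
               call. = FALSE)
        }
        grads <- mlp_backward(enc, fw$cache, lg$grad)
        upd <- adam_step(enc, grads, state, train_cfg$lr, step)
        enc <- upd$encoder; state <- upd$state
        traces[[length(traces) + 1L]] <-
          data.frame(modality = mod, step = step, epoch = ep, loss = lg$loss)
      }
    }
    encoders[[mod]] <- enc
  }
  trace <- if (length(traces)) do.call(rbind, traces) else
    data.frame(modality = character(), step = integer(), epoch = integer(),
               loss = numeric())
  list(encoders = encoders, trace = trace)
}

#' Encode all cells into their modality-specific spaces
#'
#' @param encoders named list of trained encoders from [train_specific()].
#' @param inputs named list of [modality_input()].
#' @return named list of `specific_embedding` objects (`modality`, `rows`,
#'   `values`, `imputed` logical flag per row — all `FALSE` here).
#' @export
encode_specific <- function(encoders, inputs) {
  shared <- encode_shared(encoders, inputs)
  lapply(shared, function(se) {
    se$imputed <- rep(FALSE, nrow(se$values))
    class(se) <- "specific_embedding"
    se
  })
}

# deterministic kNN of each query row among candidate rows in the shared
# space; ties broken by (similarity desc, candidate index asc)
.match_knn <- function(query, candidates, k, metric) {
  if (metric == "cosine") {
    sim <- cosine_similarity_matrix(query, candidates)
  } else {
    q2 <- rowSums(query^2); c2 <- rowSums(candidates^2)
    sim <- -(outer(q2, c2, "+") - 2 * tcrossprod(query, candidates))
  }
  ord <- apply(sim, 1L, function(s) order(-s, seq_along(s))[seq_len(k)])
  if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
}

.impute_by_matching <- function(shared, ds, cfg, value_source) {
  # value_source(modality) -> list(rows, values) of per-cell payload to average
  out <- list()
  all_ids <- ds$cell_meta[, c("batch_id", "cell_id")]
  for (mj in ds$modalities) {
    src <- value_source(mj)
    cand_shared <- shared[[mj]]
    if (is.null(cand_shared) || nrow(cand_shared$values) == 0L) {
      stop("modality '", mj, "' is measured by no cell; nothing to impute from",
           call. = FALSE)
    }
    n_cand <- nrow(cand_shared$values)
    k <- cfg$k
    if (k > n_cand) {
      warning("k = ", cfg$k, " exceeds the ", n_cand, " candidate cells for '",
              mj, "'; clamped")
      k <- n_cand
    }
    d_out <- ncol(src$values)
    vals <- matrix(NA_real_, nrow(all_ids), d_out)
    imput <- rep(NA, nrow(all_ids))
    # measured rows pass through
    midx <- match(paste(src$rows$batch_id, src$rows$cell_id, sep = "\r"),
                  paste(all_ids$batch_id, all_ids$cell_id, sep = "\r"))
    vals[midx, ] <- src$values
    imput[midx] <- FALSE
    # candidate payload aligned to candidate shared rows
    pay_idx <- match(paste(cand_shared$rows$batch_id, cand_shared$rows$cell_id, sep = "\r"),
                     paste(src$rows$batch_id, src$rows$cell_id, sep = "\r"))
    payload <- src$values[pay_idx, , drop = FALSE]
    for (b in ds$batches) {
      if (mj %in% b$measured_set) next
      rows_out <- which(all_ids$batch_id == b$batch_id)
      acc <- matrix(0, length(rows_out), d_out)
      for (mt in b$measured_set) {
        se <- shared[[mt]]
        qidx <- which(se$rows$batch_id == b$batch_id)
        qidx <- qidx[match(b$cell_ids, se$rows$cell_id[qidx])]
        nn <- .match_knn(se$values[qidx, , drop = FALSE], cand_shared$values,
                         k, cfg$metric)
        imp <- matrix(0, length(rows_out), d_out)
        for (col in seq_len(k)) imp <- imp + payload[nn[, col], , drop = FALSE]
        acc <- acc + imp / k
      }
      vals[rows_out, ] <- acc / length(b$measured_set)
      imput[rows_out] <- TRUE
    }
    out[[mj]] <- structure(
      list(modality = mj, rows = all_ids, values = vals, imputed = imput),
      class = "specific_embedding")
  }
  out
}

#' Impute missing-modality specific embeddings
#'
#' For each batch and each modality it does not measure: every cell's shared
#' embedding in each measured modality is matched to its `k` nearest neighbors
#' among the shared embeddings of all cells that do measure the missing
#' modality; those neighbors' specific embeddings are averaged, and the
#' per-source-modality imputations are then averaged with equal weight.
#' Measured rows are never overwritten.
#'
#' @param shared named list of shared embeddings ([encode_shared()]).
#' @param specific named list of specific embeddings ([encode_specific()]).
#' @param ds the `mosaic_dataset`.
#' @param cfg an [imputation_config()].
#' @return named list of completed `specific_embedding` objects covering all
#'   cells, with per-row `imputed` flags.
#' @export
impute_missing_embeddings <- function(shared, specific, ds, cfg = imputation_config()) {
  .impute_by_matching(shared, ds, cfg, function(mj) {
    sp <- specific[[mj]]
    if (is.null(sp)) stop("no specific embedding for '", mj, "'", call. = FALSE)
    keep <- !sp$imputed
    list(rows = sp$rows[keep, , drop = FALSE],
         values = sp$values[keep, , drop = FALSE])
  })
}

#' Impute missing-modality raw feature profiles
#'
#' Identical matching logic to [impute_missing_embeddings()], but the neighbor
#' average is taken over raw feature rows of the target modality, yielding a
#' cells x D imputed profile matrix. Imputed profiles of a non-negative input
#' are non-negative (convex combination).
#'
#' @inheritParams impute_missing_embeddings
#' @param target modality whose raw features are imputed.
#' @return a `specific_embedding`-shaped object whose `values` are feature
#'   profiles (measured rows pass through, missing rows imputed).
#' @export
impute_missing_features <- function(shared, ds, cfg = imputation_config(), target) {
  target <- canonical_modality(target)
  res <- .impute_by_matching(shared, ds, cfg, function(mj) {
    st <- .stack_modality(ds, mj)
    list(rows = st$rows, values = st$X)
  })
  res[[target]]
}

#' Equal-weight consensus over completed specific embeddings
#'
#' Per-cell unweighted mean over all modalities (measured plus imputed).
#'
#' @param specific named list of completed `specific_embedding` objects; every
#'   modality must cover every cell.
#' @param ds the `mosaic_dataset`.
#' @return list with `ids` and `values` (cells x d consensus matrix).
#' @export
consensus_specific <- function(specific, ds) {
  ids <- ds$cell_meta[, c("batch_id", "cell_id")]
  key <- paste(ids$batch_id, ids$cell_id, sep = "\r")
  acc <- NULL
  for (mod in ds$modalities) {
    sp <- specific[[mod]]
    if (is.null(sp) || anyNA(sp$imputed) || nrow(sp$values) != nrow(ids)) {
      stop("specific embedding for '", mod, "' does not cover all cells; ",
           "run impute_missing_embeddings() first", call. = FALSE)
    }
    idx <- match(key, paste(sp$rows$batch_id, sp$rows$cell_id, sep = "\r"))
    if (anyNA(idx)) stop("specific embedding for '", mod, "' misses cells", call. = FALSE)
    V <- sp$values[idx, , drop = FALSE]
    acc <- if (is.null(acc)) V else acc + V
  }
  list(ids = ids, values = acc / length(ds$modalities))
}
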