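# Alignment training: per-modality encoders trained jointly on bridge
# mini-batches with the intra-negative contrastive loss, shared-space encoding
# of all cells, and weighted-average consensus.

.bridge_batches <- function(ds) {
  keep <- vapply(ds$batches, function(b) length(b$measured_set) >= 2L, logical(1))
  ds$batches[keep]
}

#' Sample a bridge mini-batch
#'
#' Picks one bridge batch with probability proportional to its cell count,
#' then samples `n` of its cells without replacement (all cells when the batch
#' is smaller than `n`). Returns the selected rows for each of that batch's
#' measured modalities, aligned cell-for-cell.
#'
#' @param ds a `mosaic_dataset`.
#' @param inputs named list of [modality_input()] objects.
#' @param n mini-batch size.
#' @return list with `batch_id`, `cell_ids`, and `blocks` (named list of
#'   per-modality input row blocks).
#' @export
sample_bridge_minibatch <- function(ds, inputs, n) {
  bb <- .bridge_batches(ds)
  if (length(bb) == 0L) stop("no bridge batch in the dataset", call. = FALSE)
  sizes <- vapply(bb, function(b) length(b$cell_ids), integer(1))
  pick <- if (length(bb) == 1L) 1L else sample.int(length(bb), 1L, prob = sizes)
  b <- bb[[pick]]
  take <- min(n, length(b$cell_ids))
  sel <- sort(sample.int(length(b$cell_ids), take))
  cells <- b$cell_ids[sel]
  blocks <- lapply(b$measured_set, function(mod) {
    mi <- inputs[[mod]]
    idx <- which(mi$rows$batch_id == b$batch_id)
    idx <- idx[match(cells, mi$rows$cell_id[idx])]
    mi$values[idx, , drop = FALSE]
  })
  names(blocks) <- b$measured_set
  list(batch_id = b$batch_id, cell_ids = cells, blocks = blocks)
}

#' Train modality-alignment encoders
#'
#' Jointly trains one encoder per modality on bridge mini-batches with
#' [align_contrastive_loss()] (or plain InfoNCE when
#' `loss_cfg$include_intra_negatives` is `FALSE`). One epoch is
#' `ceil(total bridge cells / batch_size)` gradient steps. Fully deterministic
#' given `train_cfg$seed`.
#'
#' @param inputs named list of [modality_input()] objects (one per modality).
#' @param ds the `mosaic_dataset` the inputs came from.
#' @param enc_specs optional named list of [encoder_spec()]; defaults are
#'   derived from each modality's input dimension.
#' @param train_cfg a [train_config()] (defaults: lr 2e-4, batch 512,
#'   100 epochs).
#' @param loss_cfg a [loss_config()].
#' @return list with `encoders` (named list) and `trace` (data.frame with
#'   `step`, `epoch`, `batch_id`, `loss`).
#' @export
train_align <- function(inputs, ds, enc_specs = NULL,
                        train_cfg = train_config(), loss_cfg = loss_config()) {
  require_connected(build_bridge_graph(ds))
  enc_specs <- .default_enc_specs(inputs, enc_specs)
  set.seed(train_cfg$seed)
  encoders <- lapply(enc_specs, mlp_init)
  states <- lapply(encoders, adam_init)
  n_bridge <- sum(vapply(.bridge_batches(ds), function(b) length(b$cell_ids), integer(1)))
  steps_per_epoch <- max(1L, ceiling(n_bridge / train_cfg$batch_size))
  trace <- list()
  t_adam <- stats::setNames(rep(0L, length(encoders)), names(encoders))
  step <- 0L
  for (ep in seq_len(train_cfg$epochs)) {
    for (s in seq_len(steps_per_epoch)) {
      step <- step + 1L
      mb <- sample_bridge_minibatch(ds, inputs, train_cfg$batch_size)
      mods <- names(mb$blocks)
      fw <- lapply(mods, function(mod)
        mlp_forward(encoders[[mod]], mb$blocks[[mod]], training = TRUE))
      names(fw) <- mods
      zs <- lapply(fw, `[[`, "output")
      lg <- align_contrastive_grad(zs, loss_cfg, norm_eps = 1e-8)
      if (!is.finite(lg$loss)) {
        stop("non-finite alignment loss at step ", step, call. = FALSE)
      }
      for (mod in mods) {
        grads <- mlp_backward(encoders[[mod]], fw[[mod]]$cache, lg$grads[[mod]])
        t_adam[mod] <- t_adam[mod] + 1L
        upd <- adam_step(encoders[[mod]], grads, states[[mod]],
                         train_cfg$lr, t_adam[mod])
        encoders[[mod]] <- upd$encoder
        states[[mod]] <- upd$state
      }
      trace[[step]] <- data.frame(step = step, epoch = ep,
                                  batch_id = mb$batch_id, loss = lg$loss)
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), epoch = integer(),
               batch_id = character(), loss = numeric())
  list(encoders = encoders, trace = trace)
}

.default_enc_specs <- function(inputs, enc_specs) {
  out <- enc_specs %||% list()
  for (mod in names(inputs)) {
    if (is.null(out[[mod]])) {
      out[[mod]] <- encoder_spec(mod, input_dim = ncol(inputs[[mod]]$values))
    } else if (out[[mod]]$input_dim != ncol(inputs[[mod]]$values)) {
      stop("encoder spec for '", mod, "' expects input dim ",
           out[[mod]]$input_dim, " but input has ", ncol(inputs[[mod]]$values),
           call. = FALSE)
    }
  }
  out[names(inputs)]
}

#' Encode all cells into the shared space
#'
#' Applies each modality's encoder (dropout disabled) to every cell measuring
#' that modality, across all batches.
#'
#' @param encoders named list of trained encoders (from [train_align()]).
#' @param inputs named list of [modality_input()].
#' @return named list of `shared_embedding` objects (`modality`, `rows`,
#'   `values`).
#' @export
encode_shared <- function(encoders, inputs) {
  out <- list()
  for (mod in names(inputs)) {
    mi <- inputs[[mod]]
    enc <- encoders[[mod]]
    if (is.null(enc)) stop("no encoder for modality '", mod, "'", call. = FALSE)
    if (enc$spec$input_dim != ncol(mi$values)) {
      stop("input dim ", ncol(mi$values), " does not match encoder spec (",
           enc$spec$input_dim, ") for '", mod, "'", call. = FALSE)
    }
    out[[mod]] <- structure(
      list(modality = mod, rows = mi$rows,
           values = mlp_forward(enc, mi$values, training = FALSE)),
      class = "shared_embedding")
  }
  out
}

#' Consensus over measured modalities (alignment output)
#'
#' Per-cell weighted average of the shared embeddings over the cell's
#' measured modalities only; weights are renormalized within each batch's
#' measured set, so single-modality batches pass their one embedding through.
#' The default `weights = "auto"` assigns weight 1 to RNA in multimodal
#' batches measuring RNA, else weight 1 to Protein, else equal weights.
#'
#' @param shared named list of shared embeddings from [encode_shared()].
#' @param ds the `mosaic_dataset`.
#' @param weights `"auto"` or a named numeric vector of per-modality weights
#'   in `[0, 1]`.
#' @return list with `ids` (data.frame `batch_id`, `cell_id`) and `values`
#'   (cells x d consensus matrix) covering all cells.
#' @export
consensus_align <- function(shared, ds, weights = "auto") {
  d <- ncol(shared[[1L]]$values)
  ids <- ds$cell_meta[, c("batch_id", "cell_id")]
  out <- matrix(0, nrow(ids), d)
  for (b in ds$batches) {
    meas <- b$measured_set
    w <- .restrict_weights(weights, meas)
    rows_out <- which(ids$batch_id == b$batch_id)
    for (mod in meas) {
      if (w[[mod]] == 0) next
      se <- shared[[mod]]
      idx <- which(se$rows$batch_id == b$batch_id)
      idx <- idx[match(b$cell_ids, se$rows$cell_id[idx])]
      out[rows_out, ] <- out[rows_out, ] + w[[mod]] * se$values[idx, , drop = FALSE]
    }
  }
  list(ids = ids, values = out)
}

.restrict_weights <- function(weights, measured) {
  if (identical(weights, "auto")) {
    w <- stats::setNames(rep(0, length(measured)), measured)
    if (length(measured) == 1L) {
      w[1L] <- 1
    } else if ("RNA" %in% measured) {
      w["RNA"] <- 1
    } else if ("Protein" %in% measured) {
      w["Protein"] <- 1
    } else {
      w[] <- 1 / length(measured)
    }
    return(w)
  }
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            all(weights >= 0), all(weights <= 1))
  w <- weights[measured]
  w[is.na(w)] <- 0
  names(w) <- measured
  tot <- sum(w)
  if (tot <= 0) stop("weights restricted to measured modalities {",
                     paste(measured, collapse = ","), "} sum to zero", call. = FALSE)
  w / tot
}

#' Modality gap of bridge cells
#'
#' Euclidean distance between the per-modality centroids of L2-normalized
#' bridge-cell embeddings. Smaller values mean the modalities occupy the same
#' region of the shared space. With more than two modalities the mean over
#' all unordered centroid pairs is reported.
#'
#' @param shared named list of shared embeddings.
#' @param ds the `mosaic_dataset`.
#' @return scalar gap.
#' @export
modality_gap <- function(shared, ds) {
  cents <- list()
  for (b in .bridge_batches(ds)) {
    for (mod in b$measured_set) {
      se <- shared[[mod]]
      idx <- which(se$rows$batch_id == b$batch_id)
      V <- se$values[idx, , drop = FALSE]
      V <- V / sqrt(rowSums(V^2))
      cents[[mod]] <- rbind(cents[[mod]], V)
    }
  }
  mods <- names(cents)
  if (length(mods) < 2L) stop("modality gap needs >= 2 bridged modalities", call. = FALSE)
  cent <- lapply(cents, colMeans)
  pairs <- utils::combn(mods, 2L)
  mean(apply(pairs, 2L, function(pr) sqrt(sum((cent[[pr[1]]] - cent[[pr[2]]])^2))))
}
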