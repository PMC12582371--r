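# Contrastive objectives for modality alignment and modality-specific
# training, with analytic gradients (gradients are consumed by the trainers
# and validated against finite differences in the test suite).
#
# All similarities are cosine; losses are therefore invariant to positive
# rescaling of any embedding matrix. Log-sum-exp terms use max-subtraction:
# at the default temperature 0.1 raw exponents reach 10, and mini-batch sums
# must stay finite in double precision.

#' Loss configuration
#'
#' @param tau temperature of the softmax over similarities; the default 0.1 is
#'   the value used throughout training.
#' @param include_intra_negatives if `TRUE` (default), similarities to other
#'   cells of the anchor's own modality enter the denominator as negatives —
#'   this is what closes the modality gap. With `FALSE` the objective reduces
#'   to plain InfoNCE.
#' @return a `loss_config` list.
#' @export
loss_config <- function(tau = 0.1, include_intra_negatives = TRUE) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0)
  structure(list(tau = tau, include_intra_negatives = isTRUE(include_intra_negatives)),
            class = "loss_config")
}

.row_normalize <- function(A, what = "embeddings", eps = 0) {
  nrm <- sqrt(rowSums(A * A))
  if (eps > 0) {
    nrm <- nrm + eps
  } else if (any(nrm == 0)) {
    stop(what, ": zero-norm rows are not allowed", call. = FALSE)
  }
  list(hat = A / nrm, norm = nrm)
}

#' Cosine similarity matrix
#'
#' Entry `(i, l)` is the cosine of the angle between row `i` of `A` and row
#' `l` of `B`; values lie in `[-1, 1]`.
#'
#' @param A n x d numeric matrix without zero-norm rows.
#' @param B m x d numeric matrix without zero-norm rows.
#' @return n x m matrix of cosine similarities.
#' @export
cosine_similarity_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B))
  a <- .row_normalize(A, "A")$hat
  b <- .row_normalize(B, "B")$hat
  tcrossprod(a, b)
}

.check_minibatch <- function(zs) {
  stopifnot(is.list(zs), length(zs) >= 2L)
  zs <- lapply(zs, as.matrix)
  n <- nrow(zs[[1L]]); d <- ncol(zs[[1L]])
  for (z in zs) {
    if (nrow(z) != n || ncol(z) != d) {
      stop("all modalities of a mini-batch must share the same n and d", call. = FALSE)
    }
  }
  zs
}

# Core: loss and (optionally) gradients of the generalized alignment
# objective. For each anchor (cell i, modality j) the positives are the same
# cell's embeddings in the other M-1 modalities; one denominator per anchor
# sums exp(sim/tau) over all cross-modality similarities to all n cells plus
# (when intra = TRUE) the n-1 intra-modality similarities to other cells.
#   l(i,j) = sum_{p != j} s_ii^{j,p}/tau - (M-1) * log D_ij
#   L = -(1/(M n)) sum_{i,j} l(i,j)          [bimodal case: -(1/(2n)) sum l(i)]
.align_loss_core <- function(zs, tau, intra, grad = FALSE, norm_eps = 0) {
  zs <- .check_minibatch(zs)
  M <- length(zs); n <- nrow(zs[[1L]])
  nz <- lapply(zs, .row_normalize, what = "mini-batch embeddings", eps = norm_eps)
  hats <- lapply(nz, `[[`, "hat")
  # similarity stacks per anchor modality j: n x (n * M) with blocks over v
  loss <- 0
  grads_hat <- if (grad) lapply(zs, function(z) matrix(0, n, ncol(z)))
  scale <- 1 / (M * n)
  for (j in seq_len(M)) {
    blocks <- vector("list", M)
    for (v in seq_len(M)) blocks[[v]] <- tcrossprod(hats[[j]], hats[[v]]) / tau
    # per-anchor-cell log-denominator over included entries
    mask_cols <- function(v) v != j || intra
    # assemble included entries into one n x K matrix
    inc <- which(vapply(seq_len(M), mask_cols, logical(1)))
    S <- do.call(cbind, blocks[inc])
    # exclude intra self-similarity (l = i) when intra is included
    if (intra) {
      pos_jj <- which(inc == j)
      off <- (pos_jj - 1L) * n
      S[cbind(seq_len(n), off + seq_len(n))] <- -Inf
    }
    mx <- apply(S, 1L, max)
    W <- exp(S - mx)
    denom <- rowSums(W)
    logD <- mx + log(denom)
    pos <- 0
    for (p in seq_len(M)) if (p != j) pos <- pos + diag(blocks[[p]])
    loss <- loss - scale * sum(pos - (M - 1) * logD)
    if (grad) {
      # dL/dS entries: numerator -scale/tau at (i,i) cross pairs;
      # denominator +scale*(M-1)*softmax/tau
      P <- (W / denom) * (scale * (M - 1) / tau)  # n x K, -Inf slots give 0
      for (bidx in seq_along(inc)) {
        v <- inc[bidx]
        G <- P[, (bidx - 1L) * n + seq_len(n), drop = FALSE]
        if (v != j) {
          G[cbind(seq_len(n), seq_len(n))] <-
            G[cbind(seq_len(n), seq_len(n))] - scale / tau
        }
        # S_block = hats[[j]] %*% t(hats[[v]]) (pre-division by tau handled above)
        grads_hat[[j]] <- grads_hat[[j]] + G %*% hats[[v]]
        grads_hat[[v]] <- grads_hat[[v]] + crossprod(G, hats[[j]])
      }
    }
  }
  out <- list(loss = loss)
  if (grad) {
    out$grads <- vector("list", M)
    for (j in seq_len(M)) {
      g <- grads_hat[[j]]; h <- hats[[j]]
      # backprop through row normalization: project out the radial component
      out$grads[[j]] <- (g - h * rowSums(g * h)) / nz[[j]]$norm
    }
    names(out$grads) <- names(zs)
  }
  out
}

#' InfoNCE alignment loss (bimodal)
#'
#' The symmetric two-modality InfoNCE objective: for each cell the positive is
#' its own embedding in the other modality and the negatives are the
#' cross-modality embeddings of the other `n - 1` cells. Intra-modality
#' relationships are ignored, which is what leaves a modality gap.
#'
#' @param zs list of exactly two n x d embedding matrices, row i of each being
#'   the same physical cell.
#' @param cfg a [loss_config()]; only `tau` is used.
#' @return scalar loss.
#' @export
infonce_loss <- function(zs, cfg = loss_config()) {
  if (length(zs) != 2L) stop("infonce_loss is defined for exactly 2 modalities", call. = FALSE)
  .align_loss_core(zs, cfg$tau, intra = FALSE)$loss
}

#' Alignment loss with intra-modality negatives
#'
#' Generalized contrastive alignment over `M >= 2` modalities. Anchored at
#' each (cell, modality), the same cell's other-modality embeddings are
#' positives; the denominator pools all cross-modality similarities to all
#' cells of the mini-batch together with the intra-modality similarities to
#' the other cells of the anchor's own modality (one shared denominator per
#' anchor). Averaged over all `M * n` anchors. With
#' `include_intra_negatives = FALSE` and `M = 2` this is exactly
#' [infonce_loss()].
#'
#' @param zs list of M n x d embedding matrices with aligned rows.
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
align_contrastive_loss <- function(zs, cfg = loss_config()) {
  .align_loss_core(zs, cfg$tau, intra = cfg$include_intra_negatives)$loss
}

#' Gradient of the alignment loss
#'
#' @inheritParams align_contrastive_loss
#' @param norm_eps epsilon added to row norms (training-time stabilization;
#'   the default 0 keeps the operation exact and rejects zero rows).
#' @return list with `loss` and `grads` (per-modality gradient matrices).
#' @export
align_contrastive_grad <- function(zs, cfg = loss_config(), norm_eps = 0) {
  .align_loss_core(zs, cfg$tau, intra = cfg$include_intra_negatives,
                   grad = TRUE, norm_eps = norm_eps)
}

#' Modality-specific separation loss
#'
#' Trains an encoder to spread cells apart within one modality: each cell is
#' its own positive (self-similarity fixed at exactly 1) and all other cells
#' in the mini-batch are negatives:
#' `L = -(1/n) sum_i log( e^{1/tau} / sum_l e^{sim(z_i, z_l)/tau} )`.
#'
#' @param z n x d embedding matrix without zero-norm rows.
#' @param cfg a [loss_config()]; only `tau` is used.
#' @return scalar loss.
#' @export
specificity_loss <- function(z, cfg = loss_config()) {
  .specificity_core(z, cfg$tau)$loss
}

#' Gradient of the modality-specific separation loss
#'
#' @inheritParams specificity_loss
#' @param norm_eps epsilon added to row norms inside training code paths.
#' @return list with `loss` and `grad`.
#' @export
specificity_grad <- function(z, cfg = loss_config(), norm_eps = 0) {
  .specificity_core(z, cfg$tau, grad = TRUE, norm_eps = norm_eps)
}

.specificity_core <- function(z, tau, grad = FALSE, norm_eps = 0) {
  z <- as.matrix(z)
  n <- nrow(z)
  nz <- .row_normalize(z, "embeddings", eps = norm_eps)
  h <- nz$hat
  S <- tcrossprod(h) / tau
  diag(S) <- 1 / tau  # self-similarity is exactly 1 by definition
  mx <- apply(S, 1L, max)
  W <- exp(S - mx)
  denom <- rowSums(W)
  loss <- -(1 / n) * sum(1 / tau - (mx + log(denom)))
  out <- list(loss = loss)
  if (grad) {
    P <- (W / denom) / (n * tau)
    diag(P) <- 0  # d sim(z_i, z_i) / d z_i = 0: cosine self-similarity is constant
    g <- P %*% h + crossprod(P, h)
    out$grad <- (g - h * rowSums(g * h)) / nz$norm
  }
  out
}
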