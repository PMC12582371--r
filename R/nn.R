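# Minimal fully connected encoder: linear layers with ELU activation and
# dropout after all but the last layer, trained with Adam. Written directly in
# matrix form; gradients flow from the analytic loss gradients in losses.R.

#' Encoder architecture specification
#'
#' Defaults mirror the reference architectures: three fully connected layers
#' with output dimensions 1024/512/256 for RNA and ATAC and 512/2048/256 for
#' protein, ELU activation and dropout (p = 0.2) after the first two layers
#' only, and a linear final layer.
#'
#' @param modality modality name (selects the default `layer_dims`).
#' @param input_dim input dimension (the reduced per-modality dimension).
#' @param layer_dims integer vector of layer output dimensions; the last entry
#'   is the latent dimension `d`.
#' @param dropout_p dropout probability applied after the hidden activations.
#' @return an `encoder_spec` list.
#' @export
encoder_spec <- function(modality, input_dim, layer_dims = NULL, dropout_p = 0.2) {
  modality <- canonical_modality(modality)
  if (is.null(layer_dims)) {
    layer_dims <- if (identical(modality, "Protein")) c(512L, 2048L, 256L)
                  else c(1024L, 512L, 256L)
  }
  stopifnot(input_dim >= 1L, length(layer_dims) >= 1L, all(layer_dims >= 1L),
            dropout_p >= 0, dropout_p < 1)
  structure(list(modality = modality, input_dim = as.integer(input_dim),
                 layer_dims = as.integer(layer_dims),
                 output_dim = as.integer(layer_dims[length(layer_dims)]),
                 dropout_p = dropout_p),
            class = "encoder_spec")
}

#' Training configuration
#'
#' @param lr Adam learning rate. Alignment training defaults to 2e-4;
#'   modality-specific training uses 1.75e-4 (see [train_specific()]).
#' @param batch_size mini-batch size (clamped to the available cells).
#' @param epochs training epochs; one epoch is `ceil(available cells /
#'   batch_size)` gradient steps.
#' @param seed integer seed controlling initialization, dropout and sampling.
#' @return a `train_config` list (optimizer is Adam with beta1 = 0.9,
#'   beta2 = 0.999, eps = 1e-8).
#' @export
train_config <- function(lr = 2e-4, batch_size = 512L, epochs = 100L, seed = 0L) {
  stopifnot(lr > 0, batch_size >= 1L, epochs >= 0L)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer = "adam"),
            class = "train_config")
}

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
mlp_init <- function(spec) {
  dims <- c(spec$input_dim, spec$layer_dims)
  layers <- vector("list", length(spec$layer_dims))
  for (k in seq_along(layers)) {
    fi <- dims[k]
    bound <- 1 / sqrt(fi)
    layers[[k]] <- list(
      W = matrix(stats::runif(fi * dims[k + 1L], -bound, bound), fi, dims[k + 1L]),
      b = stats::runif(dims[k + 1L], -bound, bound)
    )
  }
  structure(list(spec = spec, layers = layers), class = "mlp_encoder")
}

.elu <- function(x) ifelse(x > 0, x, expm1(x))
.elu_grad <- function(x, y) ifelse(x > 0, 1, y + 1)  # y = elu(x)

# forward pass; training = TRUE applies dropout and keeps caches for backward
mlp_forward <- function(enc, X, training = FALSE) {
  L <- length(enc$layers)
  p <- enc$spec$dropout_p
  a <- X
  cache <- if (training) vector("list", L)
  for (k in seq_len(L)) {
    ly <- enc$layers[[k]]
    z <- sweep(a %*% ly$W, 2L, ly$b, "+")
    if (k < L) {
      h <- .elu(z)
      if (training && p > 0) {
        mask <- matrix(stats::rbinom(length(h), 1L, 1 - p), nrow(h), ncol(h)) / (1 - p)
        out <- h * mask
      } else {
        mask <- NULL
        out <- h
      }
    } else {
      h <- z; mask <- NULL; out <- z
    }
    if (training) cache[[k]] <- list(input = a, z = z, h = h, mask = mask)
    a <- out
  }
  if (training) list(output = a, cache = cache) else a
}

# backward pass: returns gradients of the same shape as the layers
mlp_backward <- function(enc, cache, grad_out) {
  L <- length(enc$layers)
  grads <- vector("list", L)
  g <- grad_out
  for (k in rev(seq_len(L))) {
    cc <- cache[[k]]
    if (k < L) {
      if (!is.null(cc$mask)) g <- g * cc$mask
      g <- g * .elu_grad(cc$z, cc$h)
    }
    grads[[k]] <- list(W = crossprod(cc$input, g), b = colSums(g))
    if (k > 1L) g <- tcrossprod(g, enc$layers[[k]]$W)
  }
  grads
}

adam_init <- function(enc) {
  lapply(enc$layers, function(ly) list(
    mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
}

adam_step <- function(enc, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (k in seq_along(enc$layers)) {
    g <- grads[[k]]; s <- state[[k]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    enc$layers[[k]]$W <- enc$layers[[k]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    enc$layers[[k]]$b <- enc$layers[[k]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[k]] <- s
  }
  list(encoder = enc, state = state)
}
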