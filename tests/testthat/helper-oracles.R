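# Independent brute-force oracles: scalar loops and direct formula
# evaluations, deliberately kept free of the package's vectorized code paths.

cos_scalar <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))

# naive scalar-loop evaluation of the alignment objective (shared denominator
# per anchor), intra = FALSE gives plain InfoNCE for M = 2
oracle_align_loss <- function(zs, tau, intra = TRUE) {
  M <- length(zs); n <- nrow(zs[[1L]])
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(M)) {
      denom <- 0
      for (v in seq_len(M)) {
        for (l in seq_len(n)) {
          if (v != j) {
            denom <- denom + exp(cos_scalar(zs[[j]][i, ], zs[[v]][l, ]) / tau)
          } else if (intra && l != i) {
            denom <- denom + exp(cos_scalar(zs[[j]][i, ], zs[[j]][l, ]) / tau)
          }
        }
      }
      li <- 0
      for (p in seq_len(M)) {
        if (p != j) {
          li <- li + cos_scalar(zs[[j]][i, ], zs[[p]][i, ]) / tau - log(denom)
        }
      }
      total <- total + li
    }
  }
  -total / (M * n)
}

oracle_specificity_loss <- function(z, tau) {
  n <- nrow(z)
  total <- 0
  for (i in seq_len(n)) {
    denom <- 0
    for (l in seq_len(n)) {
      s <- if (l == i) 1 else cos_scalar(z[i, ], z[l, ])
      denom <- denom + exp(s / tau)
    }
    total <- total + log(exp(1 / tau) / denom)
  }
  -total / n
}

# all-pairs exact kNN with the package's documented tie-break:
# similarity descending, candidate index ascending
oracle_knn <- function(query, candidates, k, metric = "cosine") {
  res <- vapply(seq_len(nrow(query)), function(i) {
    s <- vapply(seq_len(nrow(candidates)), function(l) {
      if (metric == "cosine") cos_scalar(query[i, ], candidates[l, ])
      else -sum((query[i, ] - candidates[l, ])^2)
    }, numeric(1))
    order(-s, seq_along(s))[seq_len(k)]
  }, integer(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

# pair-counting ARI over all cell pairs
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# direct entropy-formula NMI (arithmetic-mean normalization)
oracle_nmi <- function(a, b) {
  n <- length(a)
  pa <- table(a) / n; pb <- table(b) / n
  ha <- -sum(pa * log(pa)); hb <- -sum(pb * log(pb))
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (x in names(pa)) {
    for (y in names(pb)) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0) mi <- mi + pxy * log(pxy / (pa[[x]] * pb[[y]]))
    }
  }
  mi / ((ha + hb) / 2)
}

oracle_foscttm <- function(za, zb) {
  n <- nrow(za)
  fr <- c()
  for (i in seq_len(n)) {
    dtrue <- sqrt(sum((za[i, ] - zb[i, ])^2))
    closer <- 0
    for (l in seq_len(n)) if (l != i && sqrt(sum((za[i, ] - zb[l, ])^2)) < dtrue)
      closer <- closer + 1
    fr <- c(fr, closer / (n - 1))
    closer <- 0
    for (l in seq_len(n)) if (l != i && sqrt(sum((za[l, ] - zb[i, ])^2)) < dtrue)
      closer <- closer + 1
    fr <- c(fr, closer / (n - 1))
  }
  1 - mean(fr)
}

oracle_matching_score <- function(za, zb, k) {
  n <- nrow(za)
  one_dir <- function(q, c_) {
    mass <- 0
    for (i in seq_len(n)) {
      d <- vapply(seq_len(n), function(l) sum((q[i, ] - c_[l, ])^2), numeric(1))
      nb <- order(d, seq_len(n))[seq_len(k)]
      mass <- mass + (i %in% nb) / k
    }
    mass / n
  }
  (one_dir(za, zb) + one_dir(zb, za)) / 2
}

# spreadsheet-style scalar aggregation of a score table
oracle_aggregate <- function(st, w) {
  mm <- function(x) if (max(x) == min(x)) rep(0.5, length(x))
                    else (x - min(x)) / (max(x) - min(x))
  sc <- lapply(st, mm)
  s_bio <- (sc$nmi + sc$ari) / 2
  s_batch <- (sc$ilisi_batch + sc$ilisi_mod) / 2
  if (!is.null(sc$foscttm)) {
    s_mod <- (sc$foscttm + sc$matching_score) / 2
    w[["bio"]] * s_bio + w[["batch"]] * s_batch + w[["modAlign"]] * s_mod
  } else {
    w[["bio"]] * s_bio + w[["batch"]] * s_batch
  }
}

# union-find connectivity oracle over a modality/bridge pattern
oracle_connected <- function(modalities, batch_sets) {
  parent <- seq_along(modalities)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (s in batch_sets) {
    if (length(s) >= 2L) {
      for (m in s[-1]) {
        a <- find(match(s[1], modalities))
        b <- find(match(m, modalities))
        parent[b] <- a
      }
    }
  }
  length(unique(vapply(seq_along(modalities), find, integer(1)))) == 1L
}
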