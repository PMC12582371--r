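# Integration-quality metrics: clustering agreement (NMI, ARI), neighborhood
# label mixing (graph iLISI at batch and modality level), cross-modal
# alignment (FOSCTTM with 1 = perfect, matching score), and the min-max-scaled
# weighted aggregation into bio-conservation / batch-correction /
# modality-alignment / overall scores.

.check_labels <- function(a, b) {
  if (length(a) == 0L || length(a) != length(b)) {
    stop("label vectors must be non-empty and of equal length", call. = FALSE)
  }
  list(a = as.character(a), b = as.character(b))
}

#' Normalized mutual information
#'
#' Arithmetic-mean normalization: `MI / ((H(a) + H(b)) / 2)`; 1 for identical
#' partitions. When either partition has a single cluster (zero entropy) the
#' score is 0 by convention.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return value in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  lb <- .check_labels(labels_a, labels_b)
  tab <- table(lb$a, lb$b)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  ha <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  hb <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  if (ha == 0 || hb == 0) return(0)
  p <- tab / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (pj[row(tab)[nz]] * pk[col(tab)[nz]])))
  max(0, min(1, mi / ((ha + hb) / 2)))
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected Rand index from the contingency table;
#' 1 for identical partitions, about 0 for random ones.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return value in `[-1, 1]`.
#' @export
ari <- function(labels_a, labels_b) {
  lb <- .check_labels(labels_a, labels_b)
  tab <- table(lb$a, lb$b)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  exp_idx <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)  # both partitions trivial
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# per-cell inverse Simpson's index of label proportions over a
# Gaussian-kernel-weighted nearest neighborhood (LISI)
.lisi_per_cell <- function(emb, labels, n_neighbors, perplexity) {
  n <- nrow(emb)
  labels <- as.integer(factor(labels))
  d2 <- as.matrix(stats::dist(emb))^2
  target <- log(perplexity)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- setdiff(order(d2[i, ]), i)[seq_len(n_neighbors)]
    dd <- d2[i, nb]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-beta * dd)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-beta * dd)
    p <- w / sum(w)
    lp <- vapply(split(p, labels[nb]), sum, numeric(1))
    out[i] <- 1 / sum(lp^2)
  }
  out
}

#' Graph iLISI mixing score
#'
#' For each cell, the inverse Simpson's index of label proportions over its
#' `n_neighbors` nearest embedding neighbors (Gaussian-kernel weights fitted
#' to a fixed perplexity of `n_neighbors / 3`), averaged over cells and
#' rescaled by `(mean - 1) / (B - 1)` with `B` label categories:
#' 0 = categories fully separated, 1 = perfectly mixed.
#'
#' @param emb cells x d embedding matrix.
#' @param labels batch or modality labels, >= 2 categories.
#' @param n_neighbors neighborhood size (default 90).
#' @return value in `[0, 1]`.
#' @export
graph_ilisi <- function(emb, labels, n_neighbors = 90L) {
  emb <- as.matrix(emb)
  labels <- as.character(labels)
  B <- length(unique(labels))
  if (B < 2L) stop("iLISI needs >= 2 label categories", call. = FALSE)
  if (n_neighbors >= nrow(emb)) {
    stop("n_neighbors must be smaller than the number of cells", call. = FALSE)
  }
  li <- .lisi_per_cell(emb, labels, n_neighbors, perplexity = n_neighbors / 3)
  max(0, min(1, (mean(li) - 1) / (B - 1)))
}

#' FOSCTTM alignment score (1 = perfect)
#'
#' Fraction of samples closer than the true match: for each cell, the fraction
#' of the other modality's `n - 1` remaining cells lying strictly closer
#' (Euclidean) than the cell's true match, averaged over cells and both
#' directions. Reported as `1 - mean fraction` so that 1 means perfect
#' alignment.
#'
#' @param za,zb n x d embedding matrices whose rows are true matches.
#' @return value in `[0, 1]`.
#' @export
foscttm <- function(za, zb) {
  za <- as.matrix(za); zb <- as.matrix(zb)
  n <- nrow(za)
  if (n < 2L || nrow(zb) != n) stop("paired embeddings with n >= 2 required", call. = FALSE)
  a2 <- rowSums(za^2); b2 <- rowSums(zb^2)
  D <- outer(a2, b2, "+") - 2 * tcrossprod(za, zb)  # squared cross distances
  f_ab <- vapply(seq_len(n), function(i) sum(D[i, -i] < D[i, i]) / (n - 1), numeric(1))
  f_ba <- vapply(seq_len(n), function(i) sum(D[-i, i] < D[i, i]) / (n - 1), numeric(1))
  1 - mean(c(f_ab, f_ba))
}

#' Cross-modal matching score
#'
#' Builds the k-nearest-neighbor indicator from one modality to the other,
#' row-normalizes it into a matching-probability matrix, and returns the mean
#' probability mass on the true match, averaged over both directions. With
#' `k = 1`, 1 means every cell's sole neighbor is its true match.
#'
#' @param za,zb n x d paired embedding matrices.
#' @param k neighborhood size (default 10, clamped to `n - 1`).
#' @return value in `[0, 1]`.
#' @export
matching_score <- function(za, zb, k = 10L) {
  za <- as.matrix(za); zb <- as.matrix(zb)
  n <- nrow(za)
  if (n < 2L || nrow(zb) != n) stop("paired embeddings with n >= 2 required", call. = FALSE)
  k <- min(as.integer(k), n - 1L)
  a2 <- rowSums(za^2); b2 <- rowSums(zb^2)
  D <- outer(a2, b2, "+") - 2 * tcrossprod(za, zb)
  mass <- function(Dm) {
    hit <- vapply(seq_len(n), function(i) {
      nb <- order(Dm[i, ], seq_len(n))[seq_len(k)]
      (i %in% nb) / k
    }, numeric(1))
    mean(hit)
  }
  (mass(D) + mass(t(D))) / 2
}

#' Shared-nearest-neighbor graph of an embedding
#'
#' Jaccard-weighted SNN graph over the `k` nearest Euclidean neighbors,
#' pruning weights below 1/15 (the common default).
#'
#' @param emb cells x d matrix.
#' @param k_neighbors kNN size.
#' @return an igraph graph with edge weights.
#' @export
snn_graph <- function(emb, k_neighbors = 15L) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  k <- min(k_neighbors, n - 1L)
  d2 <- as.matrix(stats::dist(emb))
  nn <- lapply(seq_len(n), function(i) setdiff(order(d2[i, ]), i)[seq_len(k)])
  edges <- list(); wts <- list()
  for (i in seq_len(n)) {
    for (j in nn[[i]]) {
      if (j > i || !(i %in% nn[[j]])) {
        shared <- length(intersect(nn[[i]], nn[[j]]))
        jac <- shared / (2 * k - shared)
        if (jac > 1 / 15) {
          edges[[length(edges) + 1L]] <- c(i, j)
          wts[[length(wts) + 1L]] <- jac
        }
      }
    }
  }
  if (length(edges) == 0L) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
  } else {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    igraph::E(g)$weight <- unlist(wts)
  }
  g
}

#' Cluster an embedding for label-based evaluation
#'
#' Default: SNN graph ([snn_graph()]) partitioned with Louvain at the given
#' resolution. A k-means fallback is available (`centers` required).
#'
#' @param emb cells x d matrix (or, for Louvain, a prebuilt [snn_graph()]).
#' @param method `"louvain"` or `"kmeans"`.
#' @param k_neighbors kNN size for the SNN graph.
#' @param resolution Louvain resolution.
#' @param centers number of centers for k-means.
#' @param seed integer seed (Louvain tie-shuffling, k-means starts).
#' @return integer cluster labels.
#' @export
cluster_embedding <- function(emb, method = c("louvain", "kmeans"),
                              k_neighbors = 15L, resolution = 1.0,
                              centers = NULL, seed = 0L) {
  method <- match.arg(method)
  set.seed(seed)
  if (method == "kmeans") {
    stopifnot(!is.null(centers))
    return(stats::kmeans(as.matrix(emb), centers = centers, nstart = 10L)$cluster)
  }
  g <- if (inherits(emb, "igraph")) emb else snn_graph(emb, k_neighbors)
  if (igraph::ecount(g) == 0L) return(rep(1L, igraph::vcount(g)))
  igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
}

#' Resolution-optimized Louvain clustering (scIB convention)
#'
#' Clusters the SNN graph at a grid of Louvain resolutions and keeps the
#' partition maximizing NMI against the reference labels — the procedure the
#' scIB benchmark uses before reporting NMI/ARI, which decouples the score
#' from an arbitrary fixed resolution.
#'
#' @param emb cells x d matrix.
#' @param labels reference labels (NA rows are ignored in the NMI selection).
#' @param resolutions resolution grid (default `seq(0.1, 2, by = 0.1)`).
#' @param k_neighbors kNN size for the SNN graph.
#' @param seed integer seed.
#' @return integer cluster labels of the best partition.
#' @export
cluster_optimal <- function(emb, labels, resolutions = seq(0.1, 2, by = 0.1),
                            k_neighbors = 15L, seed = 0L) {
  g <- snn_graph(emb, k_neighbors)
  keep <- !is.na(labels)
  best <- NULL; best_nmi <- -Inf
  for (res in resolutions) {
    cl <- cluster_embedding(g, resolution = res, seed = seed)
    v <- nmi(labels[keep], cl[keep])
    if (v > best_nmi) { best_nmi <- v; best <- cl }
  }
  best
}

#' Aggregate a method x metric score table
#'
#' Each metric column is min-max scaled to `[0, 1]` across methods (a constant
#' column scores 0.5 for every method — the scaling is otherwise undefined),
#' then averaged into `S_bio = (NMI + ARI)/2`,
#' `S_batch = (iLISI_batch + iLISI_mod)/2`,
#' `S_modAlign = (FOSCTTM + MS)/2`, and
#' `S_overall = w_bio S_bio + w_batch S_batch + w_modAlign S_modAlign`.
#' Default weights: `(0.6, 0.4)` without modality-alignment metrics,
#' `(0.4, 0.3, 0.3)` with them.
#'
#' @param st data.frame of raw metric values; rownames are method names and
#'   columns are named among `nmi`, `ari`, `ilisi_batch`, `ilisi_mod`,
#'   `foscttm`, `matching_score`.
#' @param weights optional named numeric vector / list with entries `bio`,
#'   `batch` and (when alignment metrics are present) `modAlign`; must sum
#'   to 1.
#' @return data.frame with per-method `S_bio`, `S_batch`, `S_modAlign` (NA
#'   when not computed) and `S_overall`.
#' @export
aggregate_scores <- function(st, weights = NULL) {
  st <- as.data.frame(st)
  stopifnot(nrow(st) >= 1L)
  if (!all(vapply(st, is.numeric, logical(1))) || !all(is.finite(as.matrix(st)))) {
    stop("score table must be finite numeric", call. = FALSE)
  }
  has_align <- all(c("foscttm", "matching_score") %in% names(st))
  need <- c("nmi", "ari", "ilisi_batch", "ilisi_mod")
  if (!all(need %in% names(st))) {
    stop("score table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- if (has_align) c(bio = 0.4, batch = 0.3, modAlign = 0.3)
               else c(bio = 0.6, batch = 0.4)
  }
  weights <- unlist(weights)
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1", call. = FALSE)
  if (!has_align && isTRUE(weights["modAlign"] > 0)) {
    stop("modAlign weight given but alignment metric columns are missing", call. = FALSE)
  }
  scaled <- as.data.frame(lapply(st, function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) rep(0.5, length(x)) else (x - rng[1]) / (rng[2] - rng[1])
  }))
  rownames(scaled) <- rownames(st)
  out <- data.frame(
    S_bio = (scaled$nmi + scaled$ari) / 2,
    S_batch = (scaled$ilisi_batch + scaled$ilisi_mod) / 2,
    S_modAlign = if (has_align) (scaled$foscttm + scaled$matching_score) / 2 else NA_real_,
    row.names = rownames(st)
  )
  out$S_overall <- weights[["bio"]] * out$S_bio + weights[["batch"]] * out$S_batch +
    (if (has_align) weights[["modAlign"]] * out$S_modAlign else 0)
  out
}
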