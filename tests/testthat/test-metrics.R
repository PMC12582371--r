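test_that("NMI matches the entropy-formula oracle and its conventions", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, rep(1, 6)), 0)          # zero-entropy partition
  expect_equal(nmi(a, c(9, 9, 8, 8, 7, 7)), 1) # label-name invariance
  set.seed(30)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(letters[1:3], n, replace = TRUE)
    expect_equal(nmi(x, y), oracle_nmi(x, y), tolerance = 1e-12)
  }
})

test_that("ARI matches the pair-counting oracle and known values", {
  a <- c(1, 1, 2, 2)
  expect_equal(ari(a, a), 1)
  expect_equal(ari(a, c("x", "x", "y", "y")), 1)
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(8:40, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    expect_equal(ari(x, y), oracle_ari(x, y), tolerance = 1e-12)
  }
  # random labels on many cells: close to 0
  set.seed(32)
  x <- sample(1:4, 2000, replace = TRUE); y <- sample(1:4, 2000, replace = TRUE)
  expect_lt(abs(ari(x, y)), 0.05)
  expect_error(ari(1:3, 1:4), "equal length")
})

test_that("FOSCTTM and matching score match oracles and their exact limits", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(5:25, 1); d <- sample(2:6, 1)
    za <- matrix(rnorm(n * d), n, d); zb <- matrix(rnorm(n * d), n, d)
    expect_equal(foscttm(za, zb), oracle_foscttm(za, zb), tolerance = 1e-12)
    k <- sample(1:4, 1)
    expect_equal(matching_score(za, zb, k), oracle_matching_score(za, zb, k),
                 tolerance = 1e-12)
  }
  # perfectly aligned embeddings score exactly 1
  z <- matrix(rnorm(20 * 3), 20, 3)
  expect_equal(foscttm(z, z), 1)
  expect_equal(matching_score(z, z, k = 1L), 1)
  # reversed pairing on orthogonal points: for each cell exactly one of the
  # nine non-matches (its own coordinate vector) is strictly closer than the
  # true match, all others tie, so the score is 1 - 1/9
  sep <- diag(10) * 100
  expect_equal(foscttm(sep, sep[10:1, ]), 8 / 9)
  expect_error(foscttm(z, z[1:5, ]), "paired")
})

test_that("graph iLISI reaches its separation and mixing limits", {
  set.seed(34)
  # two tight, far-apart blobs labeled by blob: no mixing
  blob <- function(center, n) sweep(matrix(rnorm(n * 2, sd = 0.05), n, 2), 2,
                                    center, "+")
  emb_sep <- rbind(blob(c(0, 0), 60), blob(c(100, 100), 60))
  lab <- rep(c("a", "b"), each = 60)
  expect_lte(graph_ilisi(emb_sep, lab, n_neighbors = 30L), 0.05)
  # 10 far-apart clusters of 12 colocated points, 6 of each label: every
  # neighborhood is 5-vs-6 at equal weight, giving iLISI = 121/61 - 1 exactly
  centers <- matrix(rnorm(10 * 2, sd = 100), 10, 2)
  emb_mix <- centers[rep(1:10, each = 12), ]
  lab_mix <- rep(rep(c("a", "b"), each = 6), times = 10)
  expect_equal(graph_ilisi(emb_mix, lab_mix, n_neighbors = 30L),
               121 / 61 - 1, tolerance = 1e-6)
  # three-category rescaling stays in [0, 1]
  lab3 <- rep(c("a", "b", "c"), each = 40)
  v <- graph_ilisi(emb_mix, lab3, n_neighbors = 30L)
  expect_gte(v, 0); expect_lte(v, 1)
  expect_error(graph_ilisi(emb_mix, rep("a", 120), n_neighbors = 30L), "categories")
  expect_error(graph_ilisi(emb_mix[1:10, ], lab_mix[1:10], n_neighbors = 90L),
               "smaller")
})

test_that("metrics are invariant to rigid motions of the embedding", {
  set.seed(35)
  n <- 40
  za <- matrix(rnorm(n * 3), n, 3); zb <- matrix(rnorm(n * 3), n, 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  shift <- c(5, -3, 2)
  rot <- function(z) sweep(z %*% R, 2, shift, "+")
  expect_equal(foscttm(rot(za), rot(zb)), foscttm(za, zb), tolerance = 1e-9)
  expect_equal(matching_score(rot(za), rot(zb), 5L), matching_score(za, zb, 5L),
               tolerance = 1e-9)
  lab <- rep(c("a", "b"), each = 20)
  expect_equal(graph_ilisi(rot(za), lab, 15L), graph_ilisi(za, lab, 15L),
               tolerance = 1e-6)
})

test_that("clustering recovers well-separated groups and the scan helps", {
  set.seed(36)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), 4, 2, byrow = TRUE)
  emb <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(50 * 2, sd = 0.5), 50, 2), 2, centers[k, ], "+")))
  truth <- rep(1:4, each = 50)
  cl <- cluster_embedding(emb, "louvain", k_neighbors = 15L, seed = 1L)
  expect_gte(ari(truth, cl), 0.95)
  cl_opt <- cluster_optimal(emb, truth, seed = 1L)
  expect_gte(ari(truth, cl_opt), 0.95)
  expect_gte(nmi(truth, cl_opt), nmi(truth, cl) - 1e-12)  # scan can only match or beat
  km <- cluster_embedding(emb, "kmeans", centers = 4L, seed = 1L)
  expect_gte(ari(truth, km), 0.95)
})

test_that("score aggregation matches the spreadsheet oracle", {
  st <- data.frame(nmi = c(0.8, 0.6, 0.9), ari = c(0.7, 0.5, 0.95),
                   ilisi_batch = c(0.4, 0.9, 0.6), ilisi_mod = c(0.5, 0.8, 0.7),
                   foscttm = c(0.9, 0.3, 0.99), matching_score = c(0.8, 0.2, 0.97),
                   row.names = c("m1", "m2", "m3"))
  w <- c(bio = 0.4, batch = 0.3, modAlign = 0.3)
  out <- aggregate_scores(st, w)
  expect_equal(out$S_overall, oracle_aggregate(st, as.list(w)), tolerance = 1e-12)
  # defaults equal the explicit full-weight call
  expect_equal(aggregate_scores(st)$S_overall, out$S_overall, tolerance = 1e-12)

  # without alignment columns, 0.6/0.4 weighting
  st2 <- st[, c("nmi", "ari", "ilisi_batch", "ilisi_mod")]
  out2 <- aggregate_scores(st2)
  expect_equal(out2$S_overall,
               oracle_aggregate(st2, list(bio = 0.6, batch = 0.4)),
               tolerance = 1e-12)
  expect_true(all(is.na(out2$S_modAlign)))

  # a constant column contributes 0.5 to every method
  st3 <- st2; st3$nmi <- 0.7
  out3 <- aggregate_scores(st3)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  expect_equal(out3$S_bio, (0.5 + mm(st3$ari)) / 2, tolerance = 1e-12)

  expect_error(aggregate_scores(st, c(bio = 0.5, batch = 0.3, modAlign = 0.3)),
               "sum to 1")
  expect_error(aggregate_scores(st2[, 1:3]), "columns")
})
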