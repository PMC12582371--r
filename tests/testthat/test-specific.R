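# helpers to build hand-specified shared/specific embeddings over a dataset
mk_emb <- function(ds, mod, values, class = "shared_embedding", imputed = NULL) {
  rows <- cells_measuring(ds, mod)
  stopifnot(nrow(rows) == nrow(values))
  x <- list(modality = mod, rows = rows, values = values)
  if (!is.null(imputed)) x$imputed <- imputed
  structure(x, class = class)
}

test_that("specific training is per-modality, progresses, and is seeded", {
  bd <- bench_data()
  r <- bench_specific(seed = 1L)
  tr <- r$fit$trace
  for (mod in c("RNA", "Protein")) {
    tm <- tr[tr$modality == mod, ]
    expect_lt(mean(tm$loss[tm$epoch == max(tm$epoch)]),
              mean(tm$loss[tm$epoch == 1]))
  }
  # independence: training with another modality's input removed leaves the
  # trained modality bit-identical (the decoupling contract)
  solo <- train_specific(bd$inputs["RNA"], NULL,
                         train_config(lr = 1.75e-4, batch_size = 128L,
                                      epochs = 2L, seed = 9L), loss_config())
  both <- train_specific(bd$inputs, NULL,
                         train_config(lr = 1.75e-4, batch_size = 128L,
                                      epochs = 2L, seed = 9L), loss_config())
  expect_equal(solo$encoders$RNA$layers, both$encoders$RNA$layers, tolerance = 1e-12)

  again <- train_specific(bd$inputs["RNA"], NULL,
                          train_config(lr = 1.75e-4, batch_size = 128L,
                                       epochs = 2L, seed = 9L), loss_config())
  expect_identical(solo$encoders$RNA$layers, again$encoders$RNA$layers)
})

test_that("kNN imputation reproduces exact-match and equidistant cases", {
  # bridge b1 (RNA+Protein, 3 cells), b2 RNA-only (2 cells missing Protein)
  ids1 <- c("c1", "c2", "c3"); ids2 <- c("r1", "r2")
  ds <- mosaic_dataset(list(
    batch_record("b1", list(RNA = matrix(rnorm(9), 3, 3, dimnames = list(ids1, NULL)),
                            ADT = matrix(rnorm(9), 3, 3, dimnames = list(ids1, NULL)))),
    batch_record("b2", list(RNA = matrix(rnorm(6), 2, 3, dimnames = list(ids2, NULL))))))
  # shared space: protein candidates sit at distinct directions
  sh_prot <- rbind(c(1, 0), c(0, 1), c(1, 1))
  sh_rna <- rbind(c(1, 0), c(0, 1), c(1, 1),   # bridge cells
                  c(1, 0.01), c(0, 1))          # query cells (b2)
  sp_prot <- rbind(c(10, 10), c(20, 20), c(30, 30))
  shared <- list(RNA = mk_emb(ds, "RNA", sh_rna),
                 Protein = mk_emb(ds, "Protein", sh_prot))
  specific <- list(
    RNA = mk_emb(ds, "RNA", matrix(0, 5, 2), "specific_embedding", rep(FALSE, 5)),
    Protein = mk_emb(ds, "Protein", sp_prot, "specific_embedding", rep(FALSE, 3)))
  # k = 1: nearest candidate's specific embedding is copied exactly
  done <- impute_missing_embeddings(shared, specific, ds, imputation_config(k = 1L))
  out <- done$Protein
  r1 <- which(out$rows$batch_id == "b2" & out$rows$cell_id == "r1")
  expect_equal(out$values[r1, ], c(10, 10))
  expect_true(out$imputed[r1])
  # measured rows pass through untouched, flagged FALSE
  b1r <- out$rows$batch_id == "b1"
  expect_equal(out$values[b1r, ], sp_prot, ignore_attr = TRUE)
  expect_false(any(out$imputed[b1r]))
  # k = 2: r2's shared embedding (0,1) has cosine 1 with candidate 2,
  # 1/sqrt(2) with candidate 3 and 0 with candidate 1 -> neighbors {2, 3}
  r2 <- which(out$rows$batch_id == "b2" & out$rows$cell_id == "r2")
  done2 <- impute_missing_embeddings(shared, specific, ds, imputation_config(k = 2L))
  expect_equal(done2$Protein$values[r2, ], (c(20, 20) + c(30, 30)) / 2)
  # exact tie: duplicated candidates 1 and 3 resolve by candidate index
  sh_prot_tie <- rbind(c(1, 0), c(0, 1), c(1, 0))
  shared_tie <- list(RNA = shared$RNA, Protein = mk_emb(ds, "Protein", sh_prot_tie))
  done3 <- impute_missing_embeddings(shared_tie, specific, ds,
                                     imputation_config(k = 1L))
  expect_equal(done3$Protein$values[r1, ], c(10, 10))  # index 1 beats index 3
})

test_that("imputation equals the brute-force oracle on random instances", {
  set.seed(20)
  for (rep in 1:20) {
    n_bridge <- sample(5:60, 1); n_solo <- sample(3:40, 1)
    d <- sample(c(2L, 4L, 16L), 1); k <- sample(1:4, 1)
    metric <- sample(c("cosine", "euclidean"), 1)
    ids1 <- sprintf("b%03d", seq_len(n_bridge))
    ids2 <- sprintf("s%03d", seq_len(n_solo))
    ds <- mosaic_dataset(list(
      batch_record("b1", list(
        RNA = matrix(rnorm(n_bridge * 3), n_bridge, 3, dimnames = list(ids1, NULL)),
        ADT = matrix(rnorm(n_bridge * 3), n_bridge, 3, dimnames = list(ids1, NULL)))),
      batch_record("b2", list(
        RNA = matrix(rnorm(n_solo * 3), n_solo, 3, dimnames = list(ids2, NULL))))))
    sh_rna <- matrix(rnorm((n_bridge + n_solo) * d), n_bridge + n_solo, d)
    sh_prot <- matrix(rnorm(n_bridge * d), n_bridge, d)
    sp_prot <- matrix(rnorm(n_bridge * 5), n_bridge, 5)
    shared <- list(RNA = mk_emb(ds, "RNA", sh_rna),
                   Protein = mk_emb(ds, "Protein", sh_prot))
    specific <- list(
      RNA = mk_emb(ds, "RNA", matrix(0, n_bridge + n_solo, 5),
                   "specific_embedding", rep(FALSE, n_bridge + n_solo)),
      Protein = mk_emb(ds, "Protein", sp_prot, "specific_embedding",
                       rep(FALSE, n_bridge)))
    done <- impute_missing_embeddings(shared, specific, ds,
                                      imputation_config(k, metric))
    out <- done$Protein
    # oracle: queries are b2 cells' RNA shared embeddings (b2 cells come
    # after b1 cells in the RNA stacking order)
    q <- sh_rna[n_bridge + seq_len(n_solo), , drop = FALSE]
    nn <- oracle_knn(q, sh_prot, k, metric)
    for (i in seq_len(n_solo)) {
      expected <- colMeans(sp_prot[nn[i, ], , drop = FALSE])
      row <- which(out$rows$batch_id == "b2")[i]
      expect_equal(out$values[row, ], expected, tolerance = 1e-10)
    }
  }
})

test_that("raw-feature imputation averages neighbor profiles and stays non-negative", {
  sim <- simulate_mosaic(mosaic_sim_spec(
    cells_per_batch = c(30L, 20L, 20L),
    modalities = list(RNA = list(D = 20L), Protein = list(D = 8L)),
    counts = TRUE, seed = 21L))
  ds <- sim$dataset
  set.seed(22)
  d <- 4L
  n_rna <- nrow(cells_measuring(ds, "RNA")); n_prot <- nrow(cells_measuring(ds, "Protein"))
  shared <- list(RNA = mk_emb(ds, "RNA", matrix(rnorm(n_rna * d), n_rna, d)),
                 Protein = mk_emb(ds, "Protein", matrix(rnorm(n_prot * d), n_prot, d)))
  imp <- impute_missing_features(shared, ds, imputation_config(k = 2L), "Protein")
  expect_true(all(imp$values >= 0))
  # measured profiles pass through
  b1 <- ds$batches$b1$matrices$Protein
  b1r <- imp$rows$batch_id == "b1"
  expect_equal(imp$values[b1r, ], b1, ignore_attr = TRUE)
  # oracle check on the imputed b2 rows
  q <- shared$RNA$values[shared$RNA$rows$batch_id == "b2", , drop = FALSE]
  cand <- shared$Protein$values
  nn <- oracle_knn(q, cand, 2L, "cosine")
  prot_stack <- rbind(ds$batches$b1$matrices$Protein, ds$batches$b3$matrices$Protein)
  i <- 1L
  for (row in which(imp$rows$batch_id == "b2")) {
    expect_equal(imp$values[row, ], colMeans(prot_stack[nn[i, ], , drop = FALSE]),
                 tolerance = 1e-10, ignore_attr = TRUE)
    i <- i + 1L
  }
})

test_that("k larger than the candidate pool clamps with a warning", {
  ds <- tiny_mosaic(n_bridge = 3L)
  sh_rna <- matrix(rnorm(8 * 2), 8, 2)
  sh_prot <- matrix(rnorm(8 * 2), 8, 2)
  shared <- list(RNA = mk_emb(ds, "RNA", sh_rna),
                 Protein = mk_emb(ds, "Protein", sh_prot))
  specific <- list(
    RNA = mk_emb(ds, "RNA", matrix(rnorm(16), 8, 2), "specific_embedding",
                 rep(FALSE, 8)),
    Protein = mk_emb(ds, "Protein", matrix(rnorm(16), 8, 2), "specific_embedding",
                     rep(FALSE, 8)))
  # both modalities have fewer than 50 candidates, so each emits a warning
  w <- capture_warnings(
    impute_missing_embeddings(shared, specific, ds, imputation_config(k = 50L)))
  expect_length(w, 2L)
  expect_true(all(grepl("clamped", w)))
})

test_that("equal-weight specific consensus matches a scalar-loop oracle", {
  ds <- tiny_mosaic()
  n <- nrow(ds$cell_meta)
  ids <- ds$cell_meta[, c("batch_id", "cell_id")]
  mk_full <- function(mult) {
    structure(list(modality = "x", rows = ids,
                   values = matrix(rnorm(n * 3), n, 3) * mult,
                   imputed = rep(FALSE, n)),
              class = "specific_embedding")
  }
  sp <- list(RNA = mk_full(1), Protein = mk_full(2))
  cons <- consensus_specific(sp, ds)
  for (i in c(1L, 5L, n)) {
    expect_equal(cons$values[i, ],
                 (sp$RNA$values[i, ] + sp$Protein$values[i, ]) / 2,
                 tolerance = 1e-12)
  }
  # all modalities identical -> consensus equals the common row
  sp2 <- list(RNA = sp$RNA, Protein = sp$RNA)
  expect_equal(consensus_specific(sp2, ds)$values, sp$RNA$values)
  # incomplete modality rejected
  bad <- sp; bad$Protein$imputed[1] <- NA
  expect_error(consensus_specific(bad, ds), "cover")
})
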