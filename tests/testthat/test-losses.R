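test_that("cosine similarity matches a scalar-loop oracle and rejects zero rows", {
  expect_equal(cosine_similarity_matrix(diag(2), diag(2)), diag(2))
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(12), 4, 3)
  S <- cosine_similarity_matrix(A, B)
  for (i in 1:4) for (l in 1:4) {
    expect_equal(S[i, l], cos_scalar(A[i, ], B[l, ]), tolerance = 1e-12)
  }
  # positive rescaling leaves the diagonal at 1
  expect_equal(diag(cosine_similarity_matrix(A, 3.7 * A)), rep(1, 4))
  A[2, ] <- 0
  expect_error(cosine_similarity_matrix(A, B), "zero-norm")
})

test_that("alignment and InfoNCE losses match the naive scalar-loop oracle", {
  set.seed(10)
  for (rep in 1:50) {
    M <- sample(2:3, 1); n <- sample(1:16, 1); d <- sample(2:8, 1)
    zs <- lapply(seq_len(M), function(j) matrix(rnorm(n * d), n, d))
    tau <- sample(c(0.1, 0.5, 1), 1)
    expect_equal(align_contrastive_loss(zs, loss_config(tau, TRUE)),
                 oracle_align_loss(zs, tau, TRUE), tolerance = 1e-10)
    expect_equal(align_contrastive_loss(zs, loss_config(tau, FALSE)),
                 oracle_align_loss(zs, tau, FALSE), tolerance = 1e-10)
    if (M == 2) {
      expect_equal(infonce_loss(zs, loss_config(tau)),
                   oracle_align_loss(zs, tau, FALSE), tolerance = 1e-10)
      expect_equal(align_contrastive_loss(zs, loss_config(tau, FALSE)),
                   infonce_loss(zs, loss_config(tau)), tolerance = 1e-10)
    }
  }
})

test_that("worked bimodal examples evaluate to their closed forms", {
  z <- rbind(c(1, 0), c(0, 1))
  # InfoNCE, tau = 1, identical orthonormal embeddings
  expect_equal(infonce_loss(list(z, z), loss_config(1)),
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-12)
  # with intra negatives the denominator gains one more unit-similarity term
  expect_equal(align_contrastive_loss(list(z, z), loss_config(1, TRUE)),
               -log(exp(1) / (exp(1) + 2)), tolerance = 1e-12)
  # specificity at n = 2, orthogonal rows
  expect_equal(specificity_loss(z, loss_config(1)),
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-12)
})

test_that("single-cell mini-batches reduce to their closed forms", {
  z1 <- matrix(c(0.3, -1.2, 0.5), 1)
  # M = 2, n = 1: no negatives remain, so the loss is 0 for any embeddings
  expect_equal(align_contrastive_loss(list(z1, z1 * 2), loss_config(0.1, TRUE)), 0,
               tolerance = 1e-12)
  z2 <- matrix(rnorm(3, sd = 2), 1)
  expect_equal(align_contrastive_loss(list(z1, z2), loss_config(0.1, TRUE)), 0,
               tolerance = 1e-12)
  # M = 3, n = 1, identical embeddings: each anchor still sees the two other
  # modalities in its shared denominator, giving 2/tau - 2 log(2 e^{1/tau})
  # = -2 log 2 per anchor, hence a total loss of 2 log 2 for any tau
  expect_equal(align_contrastive_loss(list(z1, z1, z1), loss_config(0.1, TRUE)),
               2 * log(2), tolerance = 1e-12)
  expect_equal(align_contrastive_loss(list(z1, z1, z1), loss_config(1, TRUE)),
               2 * log(2), tolerance = 1e-12)
  expect_identical(specificity_loss(z1, loss_config(0.1)), 0)
})

test_that("specificity loss matches its oracle and decreases toward orthogonality", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:12, 1); d <- sample(2:6, 1)
    z <- matrix(rnorm(n * d), n, d)
    expect_equal(specificity_loss(z, loss_config(0.1)),
                 oracle_specificity_loss(z, 0.1), tolerance = 1e-10)
  }
  # rotate the second of two rows from parallel to orthogonal: loss decreases
  angles <- seq(0.05, pi / 2, length.out = 20)
  losses <- vapply(angles, function(a) {
    specificity_loss(rbind(c(1, 0), c(cos(a), sin(a))), loss_config(1))
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("losses are invariant to scale and to joint permutation of cells", {
  set.seed(12)
  zs <- lapply(1:2, function(j) matrix(rnorm(6 * 4), 6, 4))
  cfg <- loss_config(0.1, TRUE)
  base <- align_contrastive_loss(zs, cfg)
  expect_equal(align_contrastive_loss(list(zs[[1]] * 17, zs[[2]] * 0.01), cfg),
               base, tolerance = 1e-12)
  perm <- sample(6)
  expect_equal(align_contrastive_loss(lapply(zs, function(z) z[perm, ]), cfg),
               base, tolerance = 1e-12)
  expect_equal(infonce_loss(lapply(zs, function(z) z[perm, ]), loss_config(0.1)),
               infonce_loss(zs, loss_config(0.1)), tolerance = 1e-12)
  z <- zs[[1]]
  expect_equal(specificity_loss(z[perm, ], cfg), specificity_loss(z, cfg),
               tolerance = 1e-12)
  expect_equal(specificity_loss(z * 5, cfg), specificity_loss(z, cfg),
               tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(13)
  h <- 1e-6
  n <- 4; d <- 3
  for (M in 2:3) {
    zs <- lapply(seq_len(M), function(j) matrix(rnorm(n * d), n, d))
    for (intra in c(TRUE, FALSE)) {
      cfg <- loss_config(0.1, intra)
      g <- align_contrastive_grad(zs, cfg)
      expect_equal(g$loss, align_contrastive_loss(zs, cfg))
      for (j in seq_len(M)) {
        for (idx in seq_len(n * d)) {
          zp <- zs; zp[[j]][idx] <- zp[[j]][idx] + h
          zm <- zs; zm[[j]][idx] <- zm[[j]][idx] - h
          fd <- (align_contrastive_loss(zp, cfg) -
                 align_contrastive_loss(zm, cfg)) / (2 * h)
          expect_equal(g$grads[[j]][idx], fd,
                       tolerance = 1e-4 * max(1, abs(fd)))
        }
      }
    }
  }
  z <- matrix(rnorm(n * d), n, d)
  cfg <- loss_config(0.1)
  gs <- specificity_grad(z, cfg)
  for (idx in seq_len(n * d)) {
    zp <- z; zp[idx] <- zp[idx] + h
    zm <- z; zm[idx] <- zm[idx] - h
    fd <- (specificity_loss(zp, cfg) - specificity_loss(zm, cfg)) / (2 * h)
    expect_equal(gs$grad[idx], fd, tolerance = 1e-4 * max(1, abs(fd)))
  }
})

test_that("shape mismatches and invalid temperatures are rejected", {
  expect_error(loss_config(tau = 0), "tau")
  expect_error(align_contrastive_loss(list(matrix(1, 2, 2), matrix(1, 3, 2))),
               "same n and d")
  expect_error(infonce_loss(list(matrix(1, 2, 2), matrix(1, 2, 2),
                                 matrix(1, 2, 2))), "2 modalities")
})
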