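# Fixtures built in code, plus a session-level cache so the expensive
# benchmark trainings are shared across test files.

# tiny hand-built mosaic: bridge RNA+Protein, one RNA-only, one Protein-only
tiny_mosaic <- function(n_bridge = 8L, seed = 42L) {
  set.seed(seed)
  mk <- function(ids, D, prefix) {
    m <- matrix(rnorm(length(ids) * D), length(ids), D,
                dimnames = list(ids, paste0(prefix, seq_len(D))))
    m
  }
  b1 <- batch_record("b1", list(
    RNA = mk(sprintf("c%02d", seq_len(n_bridge)), 6L, "g"),
    ADT = mk(sprintf("c%02d", seq_len(n_bridge)), 4L, "p")))
  b2 <- batch_record("b2", list(RNA = mk(sprintf("r%02d", 1:5), 6L, "g")))
  b3 <- batch_record("b3", list(Protein = mk(sprintf("p%02d", 1:5), 4L, "p")))
  mosaic_dataset(list(b1, b2, b3))
}

# session cache ---------------------------------------------------------------
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the benchmark mosaic and its encoder inputs (small-data preset: p = 20,
# additive-shift removal by centering)
bench_data <- function() {
  cached("bench_data", {
    em <- easy_mosaic()
    inputs <- prepare_inputs(em$dataset, p = 20L, correction = "center", seed = 11L)
    list(ds = em$dataset, truth = em$truth, inputs = inputs)
  })
}

bench_bridge_pair <- function(shared, ds) {
  bb <- ds$batches[["b1"]]
  pick <- function(mod) {
    se <- shared[[mod]]
    idx <- which(se$rows$batch_id == "b1")
    se$values[idx[match(bb$cell_ids, se$rows$cell_id[idx])], , drop = FALSE]
  }
  list(za = pick("RNA"), zb = pick("Protein"))
}

# one full alignment training on the benchmark (align epochs 30, batch 128)
bench_align <- function(seed, include_intra = TRUE, epochs = 30L) {
  key <- sprintf("align_s%d_i%d_e%d", seed, include_intra, epochs)
  cached(key, {
    bd <- bench_data()
    fit <- train_align(bd$inputs, bd$ds, NULL,
                       train_config(lr = 2e-4, batch_size = 128L,
                                    epochs = epochs, seed = seed),
                       loss_config(0.1, include_intra))
    shared <- encode_shared(fit$encoders, bd$inputs)
    list(fit = fit, shared = shared)
  })
}

bench_specific <- function(seed) {
  key <- sprintf("spec_s%d", seed)
  cached(key, {
    bd <- bench_data()
    fit <- train_specific(bd$inputs, NULL,
                          train_config(lr = 1.75e-4, batch_size = 128L,
                                       epochs = 10L, seed = seed),
                          loss_config(0.1))
    list(fit = fit, specific = encode_specific(fit$encoders, bd$inputs))
  })
}

# shared embeddings from untrained (initialization-only) encoders
bench_init_shared <- function(seed) {
  key <- sprintf("init_s%d", seed)
  cached(key, {
    bd <- bench_data()
    fit <- train_align(bd$inputs, bd$ds, NULL,
                       train_config(epochs = 0L, seed = seed), loss_config())
    encode_shared(fit$encoders, bd$inputs)
  })
}
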