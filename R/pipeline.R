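# Run configuration and pipeline orchestration:
# simulate -> preprocess -> align -> specific -> evaluate.

#' Default run configuration
#'
#' Nested list of all tunable parameters with their reference defaults:
#' temperature 0.1 with intra-modality negatives on; alignment training
#' lr 2e-4 / batch 512 / 100 epochs; modality-specific training lr 1.75e-4 /
#' batch 512 / 10 epochs; latent dimension 256; imputation k = 2 with cosine
#' matching; consensus weights `"auto"` (RNA-or-Protein one-hot for
#' multimodal batches).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 0L,
    loss = list(tau = 0.1, include_intra_negatives = TRUE),
    preprocess = list(p = 100L, correction = "none"),
    encoder = list(
      RNA = list(layer_dims = c(1024L, 512L, 256L), dropout_p = 0.2),
      ATAC = list(layer_dims = c(1024L, 512L, 256L), dropout_p = 0.2),
      Protein = list(layer_dims = c(512L, 2048L, 256L), dropout_p = 0.2)
    ),
    align = list(train = list(lr = 2e-4, batch_size = 512L, epochs = 100L)),
    specific = list(train = list(lr = 1.75e-4, batch_size = 512L, epochs = 10L)),
    impute = list(k = 2L, metric = "cosine"),
    consensus = list(weights = "auto"),
    evaluate = list(cluster = "louvain", resolution = "scan",
                    k_neighbors = 15L, ilisi_neighbors = 90L, ms_k = 10L)
  )
}

.merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop("unknown configuration key: '", full, "'", call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- .merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Merges user overrides onto [default_config()]; unknown keys are rejected
#' with their full dotted path.
#'
#' @param cfg named list of overrides, or a path to a YAML file.
#' @return validated configuration list.
#' @export
load_config <- function(cfg = list()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  stopifnot(is.list(cfg))
  out <- .merge_config(default_config(), cfg)
  stopifnot(out$loss$tau > 0, out$impute$k >= 1L)
  out
}

# stage seeds are derived from the one global seed so stages are individually
# re-runnable yet jointly reproducible; offsets are fixed constants
.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, preprocess = 211L, align = 307L,
            specific = 401L, evaluate = 503L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full mosaic integration pipeline
#'
#' Executes preprocess -> alignment training -> shared encoding -> consensus
#' -> modality-specific training -> imputation -> specific consensus, and
#' optionally evaluation against the dataset's cell-type labels. All
#' randomness derives from `cfg$seed`.
#'
#' @param ds a `mosaic_dataset` (e.g., from [simulate_mosaic()]).
#' @param cfg configuration from [load_config()].
#' @param out_dir optional directory; when given, embedding tables, traces
#'   and a run manifest (config hash + seed) are written there.
#' @param evaluate compute the metric table (needs cell-type labels).
#' @return list with `inputs`, `align` (encoders, trace, shared, consensus),
#'   `specific` (encoders, trace, completed, consensus), and optionally
#'   `metrics`.
#' @export
run_pipeline <- function(ds, cfg = load_config(), out_dir = NULL, evaluate = FALSE) {
  require_connected(build_bridge_graph(ds))
  t0 <- proc.time()[["elapsed"]]
  log_line <- function(...) message(sprintf("[%6.1fs] ", proc.time()[["elapsed"]] - t0), ...)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "preprocess"
  # on stage failure: abort naming the stage; partial outputs in out_dir are
  # retained next to a FAILED marker recording the stage and message
  on_fail <- function(e) {
    if (!is.null(out_dir)) {
      writeLines(paste0("stage: ", stage, "\nerror: ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    }
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({

  log_line("preprocess")
  inputs <- prepare_inputs(ds, p = cfg$preprocess$p,
                           correction = cfg$preprocess$correction,
                           seed = .stage_seed(cfg$seed, "preprocess"))
  enc_specs <- lapply(names(inputs), function(mod) {
    ec <- cfg$encoder[[mod]]
    encoder_spec(mod, input_dim = ncol(inputs[[mod]]$values),
                 layer_dims = ec$layer_dims, dropout_p = ec$dropout_p %||% 0.2)
  })
  names(enc_specs) <- names(inputs)

  stage <- "align"
  log_line("alignment training")
  at <- cfg$align$train
  align_fit <- train_align(
    inputs, ds, enc_specs,
    train_config(lr = at$lr, batch_size = at$batch_size, epochs = at$epochs,
                 seed = .stage_seed(cfg$seed, "align")),
    loss_config(cfg$loss$tau, cfg$loss$include_intra_negatives))
  shared <- encode_shared(align_fit$encoders, inputs)
  cons_align <- consensus_align(shared, ds, cfg$consensus$weights)

  stage <- "specific"
  log_line("modality-specific training")
  st <- cfg$specific$train
  spec_fit <- train_specific(
    inputs, enc_specs,
    train_config(lr = st$lr, batch_size = st$batch_size, epochs = st$epochs,
                 seed = .stage_seed(cfg$seed, "specific")),
    loss_config(cfg$loss$tau, TRUE))
  specific <- encode_specific(spec_fit$encoders, inputs)
  completed <- impute_missing_embeddings(
    shared, specific, ds, imputation_config(cfg$impute$k, cfg$impute$metric))
  cons_spec <- consensus_specific(completed, ds)

  res <- list(
    inputs = inputs,
    align = list(encoders = align_fit$encoders, trace = align_fit$trace,
                 shared = shared, consensus = cons_align),
    specific = list(encoders = spec_fit$encoders, trace = spec_fit$trace,
                    completed = completed, consensus = cons_spec)
  )

  if (evaluate) {
    stage <- "evaluate"
    log_line("evaluation")
    res$metrics <- evaluate_mosaic(ds, list(align = cons_align, spec = cons_spec),
                                   shared = shared, cfg = cfg)
  }
  stage <- "write"
  if (!is.null(out_dir)) {
    write_embeddings(cons_align$values, cons_align$ids,
                     file.path(out_dir, "consensus_align.csv"))
    write_embeddings(cons_spec$values, cons_spec$ids,
                     file.path(out_dir, "consensus_specific.csv"))
    for (mod in names(shared)) {
      write_embeddings(shared[[mod]]$values, shared[[mod]]$rows,
                       file.path(out_dir, sprintf("shared_%s.csv", mod)))
      sp <- res$specific$completed[[mod]]
      dt <- data.table::data.table(batch_id = sp$rows$batch_id,
                                   cell_id = sp$rows$cell_id,
                                   imputed = sp$imputed)
      data.table::fwrite(cbind(dt, data.table::as.data.table(sp$values)),
                         file.path(out_dir, sprintf("specific_%s.csv", mod)))
    }
    data.table::fwrite(align_fit$trace, file.path(out_dir, "align_trace.csv"))
    data.table::fwrite(spec_fit$trace, file.path(out_dir, "specific_trace.csv"))
    manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    if (!is.null(res$metrics)) {
      data.table::fwrite(cbind(method = rownames(res$metrics), res$metrics),
                         file.path(out_dir, "metrics.csv"))
    }
  }
  log_line("done")
  res

  }, error = on_fail)
}

#' Hash of a configuration (run provenance stamp)
#'
#' @param cfg configuration list.
#' @return md5 string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}

#' Evaluate consensus embeddings against ground-truth labels
#'
#' Clusters each method's consensus embedding (SNN Louvain by default),
#' scores it against the dataset's cell-type labels (NMI, ARI), measures
#' batch and modality-set mixing (graph iLISI), and — when shared embeddings
#' of bridge pairs are supplied — modality alignment (FOSCTTM, matching
#' score).
#'
#' @param ds a `mosaic_dataset` with cell-type labels.
#' @param consensus named list of consensus results (`ids` + `values`).
#' @param shared optional shared embeddings for alignment metrics (bridge
#'   cells of the first bridge batch, first two measured modalities).
#' @param cfg configuration list (evaluation block).
#' @return data.frame: methods x raw metrics.
#' @export
evaluate_mosaic <- function(ds, consensus, shared = NULL, cfg = load_config()) {
  meta <- ds$cell_meta
  if (all(is.na(meta$cell_type))) stop("dataset carries no cell-type labels", call. = FALSE)
  ev <- cfg$evaluate
  mod_label <- vapply(meta$batch_id, function(b)
    paste(sort(ds$batches[[b]]$measured_set), collapse = "+"), character(1))
  rows <- list()
  for (method in names(consensus)) {
    cs <- consensus[[method]]
    keep <- !is.na(meta$cell_type)
    cl <- if (identical(ev$resolution, "scan") && ev$cluster == "louvain") {
      cluster_optimal(cs$values, meta$cell_type, k_neighbors = ev$k_neighbors,
                      seed = .stage_seed(cfg$seed, "evaluate"))
    } else {
      cluster_embedding(cs$values, method = ev$cluster,
                        k_neighbors = ev$k_neighbors,
                        resolution = if (is.numeric(ev$resolution)) ev$resolution else 1.0,
                        centers = length(unique(stats::na.omit(meta$cell_type))),
                        seed = .stage_seed(cfg$seed, "evaluate"))
    }
    nn <- min(ev$ilisi_neighbors, nrow(cs$values) - 1L)
    row <- data.frame(
      nmi = nmi(meta$cell_type[keep], cl[keep]),
      ari = ari(meta$cell_type[keep], cl[keep]),
      ilisi_batch = graph_ilisi(cs$values, meta$batch_id, nn),
      ilisi_mod = if (length(unique(mod_label)) >= 2L)
        graph_ilisi(cs$values, mod_label, nn) else NA_real_
    )
    rows[[method]] <- row
  }
  out <- do.call(rbind, rows)
  if (!is.null(shared)) {
    bb <- .bridge_batches(ds)[[1L]]
    mods <- bb$measured_set[1:2]
    pick <- function(mod) {
      se <- shared[[mod]]
      idx <- which(se$rows$batch_id == bb$batch_id)
      se$values[idx[match(bb$cell_ids, se$rows$cell_id[idx])], , drop = FALSE]
    }
    za <- pick(mods[1]); zb <- pick(mods[2])
    out$foscttm <- foscttm(za, zb)
    out$matching_score <- matching_score(za, zb, k = ev$ms_k)
  }
  out
}
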