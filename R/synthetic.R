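# Synthetic mosaic generator with known ground truth: a shared low-dimensional
# cell-state space with discrete types, modality-specific linear feature maps
# plus Gaussian noise, additive per-batch shifts within each modality, and a
# mosaic missingness pattern with at least one bridge batch. It validates
# algorithms, not biology: no count distributions, no zero inflation.

#' Simulation specification for a mosaic dataset
#'
#' @param n_cell_types number of discrete cell types.
#' @param cells_per_batch integer vector, one entry per batch.
#' @param modalities named list: modality name -> list with `D` (feature
#'   count) and optional `loading_scale` (scale of the linear map, default 1).
#' @param missingness list of character vectors: the modalities each batch
#'   measures; must bridge all modalities unless `allow_disconnected`.
#' @param latent_dim dimension of the shared cell-state space.
#' @param noise_sd feature-level Gaussian noise s.d.
#' @param batch_effect_sd s.d. of the additive per-batch, per-feature shift
#'   within each modality (the purely horizontal batch effect).
#' @param centroid_sd s.d. of cell-type centroids in latent space (default 3:
#'   types are well separated relative to the unit latent jitter).
#' @param latent_jitter_sd within-type latent s.d. (default 1).
#' @param shared_type_proportion fraction of cell types shared across all
#'   batches; the remaining types are each restricted to one batch, emulating
#'   composition shifts between experiments.
#' @param bridge_downsample fraction of bridge-batch cells retained, emulating
#'   scarce bridge data.
#' @param counts if `TRUE`, features are passed through `exp` then Poisson
#'   sampling to give non-negative count-like matrices (for raw-feature
#'   imputation tests).
#' @param allow_disconnected keep a missingness pattern whose bridge graph is
#'   disconnected (for negative tests).
#' @param seed integer seed; generation is fully reproducible.
#' @return a `mosaic_sim_spec` list.
#' @export
mosaic_sim_spec <- function(n_cell_types = 4L,
                            cells_per_batch = c(300L, 200L, 200L),
                            modalities = list(RNA = list(D = 300L),
                                              Protein = list(D = 40L)),
                            missingness = list(c("RNA", "Protein"), "RNA", "Protein"),
                            latent_dim = 8L,
                            noise_sd = 0.3,
                            batch_effect_sd = 0.5,
                            centroid_sd = 3,
                            latent_jitter_sd = 1,
                            shared_type_proportion = 1.0,
                            bridge_downsample = 1.0,
                            counts = FALSE,
                            allow_disconnected = FALSE,
                            seed = 7L) {
  stopifnot(n_cell_types >= 1L, latent_dim >= 1L,
            length(cells_per_batch) == length(missingness),
            shared_type_proportion > 0, shared_type_proportion <= 1,
            bridge_downsample > 0, bridge_downsample <= 1,
            noise_sd >= 0, batch_effect_sd >= 0)
  structure(as.list(environment()), class = "mosaic_sim_spec")
}

#' Simulate a mosaic dataset with ground truth
#'
#' Per type, a latent centroid is drawn; per cell, latent state = centroid +
#' jitter; per modality, features = latent %*% loading + noise + per-batch
#' shift; missingness then deletes unmeasured matrices. The returned truth
#' carries cell types, the cross-modal pairing (bridge cells only), the
#' per-batch shift vectors and the latent states.
#'
#' @param spec a [mosaic_sim_spec()].
#' @return list with `dataset` (a `mosaic_dataset`) and `truth`.
#' @export
simulate_mosaic <- function(spec = mosaic_sim_spec()) {
  stopifnot(inherits(spec, "mosaic_sim_spec"))
  set.seed(spec$seed)
  mods <- canonical_modality(names(spec$modalities))
  names(spec$modalities) <- mods
  missing_sets <- lapply(spec$missingness, canonical_modality)
  n_batches <- length(spec$cells_per_batch)
  batch_ids <- sprintf("b%d", seq_len(n_batches))

  # shared vs batch-private cell types
  n_shared <- max(1L, round(spec$shared_type_proportion * spec$n_cell_types))
  shared_types <- seq_len(n_shared)
  private_types <- setdiff(seq_len(spec$n_cell_types), shared_types)
  private_owner <- if (length(private_types))
    stats::setNames(rep(seq_len(n_batches), length.out = length(private_types)),
                    private_types) else integer()

  centroids <- matrix(stats::rnorm(spec$n_cell_types * spec$latent_dim,
                                   sd = spec$centroid_sd),
                      spec$n_cell_types, spec$latent_dim)
  loadings <- lapply(mods, function(m) {
    sc <- spec$modalities[[m]]$loading_scale %||% 1
    matrix(stats::rnorm(spec$latent_dim * spec$modalities[[m]]$D,
                        sd = sc / sqrt(spec$latent_dim)),
           spec$latent_dim, spec$modalities[[m]]$D)
  })
  names(loadings) <- mods
  shifts <- list()

  batches <- list(); types_all <- list(); latents <- list()
  for (bi in seq_len(n_batches)) {
    nb <- spec$cells_per_batch[bi]
    meas <- missing_sets[[bi]]
    if (length(meas) >= 2L && spec$bridge_downsample < 1) {
      nb <- max(2L, round(nb * spec$bridge_downsample))
    }
    pool <- c(shared_types, as.integer(names(private_owner))[private_owner == bi])
    # near-balanced assignment: floor(nb/k) of each pooled type, remainder random
    base <- rep(pool, each = nb %/% length(pool))
    n_extra <- nb - length(base)
    extra <- pool[sample.int(length(pool), n_extra, replace = length(pool) < n_extra)]
    ty <- c(base, extra)[sample.int(nb)]
    lat <- centroids[ty, , drop = FALSE] +
      matrix(stats::rnorm(nb * spec$latent_dim, sd = spec$latent_jitter_sd),
             nb, spec$latent_dim)
    ids <- sprintf("%s_c%04d", batch_ids[bi], seq_len(nb))
    matrices <- list()
    for (m in meas) {
      D <- spec$modalities[[m]]$D
      shift <- stats::rnorm(D, sd = spec$batch_effect_sd)
      shifts[[paste(batch_ids[bi], m, sep = ":")]] <- shift
      X <- lat %*% loadings[[m]] +
        matrix(stats::rnorm(nb * D, sd = spec$noise_sd), nb, D)
      X <- sweep(X, 2L, shift, "+")
      if (isTRUE(spec$counts)) {
        lambda <- exp(pmin(X, 12))
        X <- matrix(stats::rpois(length(lambda), lambda), nb, D)
      }
      rownames(X) <- ids
      colnames(X) <- sprintf("%s_f%d", m, seq_len(D))
      matrices[[m]] <- X
    }
    batches[[bi]] <- batch_record(batch_ids[bi], matrices)
    rownames(lat) <- ids
    types_all[[bi]] <- data.frame(batch_id = batch_ids[bi], cell_id = ids,
                                  cell_type = sprintf("type%d", ty),
                                  stringsAsFactors = FALSE)
    latents[[bi]] <- lat
  }
  ct <- do.call(rbind, types_all)
  ds <- mosaic_dataset(batches, modalities = mods, cell_types = ct)
  g <- build_bridge_graph(ds)
  if (!g$is_connected && !spec$allow_disconnected) {
    stop("missingness pattern leaves the bridge graph disconnected", call. = FALSE)
  }
  bridge_ids <- unlist(lapply(.bridge_batches(ds), function(b)
    paste(b$batch_id, b$cell_ids, sep = "\r")), use.names = FALSE)
  truth <- list(
    cell_types = ct,
    pairing = data.frame(
      batch_id = sub("\r.*", "", bridge_ids),
      cell_id = sub(".*\r", "", bridge_ids),
      stringsAsFactors = FALSE),
    shifts = shifts,
    centroids = centroids,
    loadings = loadings,
    latent = do.call(rbind, latents)
  )
  list(dataset = ds, truth = truth)
}

#' Canonical small benchmark mosaic
#'
#' 700 cells, 4 cell types (latent dimension 8), three batches: one bridge
#' batch measuring RNA+Protein (300 cells) and one single-modality batch each
#' for RNA (200) and Protein (200); 300 RNA features, 40 protein features,
#' feature noise s.d. 0.3, additive batch shift s.d. 0.5, seed 7.
#'
#' @param seed seed override (default 7).
#' @return list with `dataset` and `truth` (see [simulate_mosaic()]).
#' @export
easy_mosaic <- function(seed = 7L) {
  simulate_mosaic(mosaic_sim_spec(seed = as.integer(seed)))
}
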