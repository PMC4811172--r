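#' Configuration of the multi-platform two-class simulator
#'
#' Defines a compendium-style design: `n_datasets` datasets (one platform
#' each) with `samples_per_class` MSC and non-MSC samples apiece, on a
#' log2 expression scale. A set of `n_informative` genes carries a class
#' effect of `effect_size` within-class standard deviations; every
#' dataset adds a per-gene batch offset with standard deviation
#' `dataset_shift_sd` (per-gene, not scalar, which is what makes
#' cross-platform integration non-trivial); per dataset a random
#' `platform_missing_fraction` of genes is unmeasured and zero-filled.
#' Optional `mixture_samples` interpolate the two class profiles at
#' lambda in `{0.25, 0.5, 0.75}` and are labelled `unknown`, emulating
#' partially differentiated cultures.
#'
#' The gene-level profiles (baseline expression and the identity of the
#' informative genes) are a deterministic function of `seed`, so
#' additional datasets or transition series simulated from the same
#' config are drawn from the same underlying biology.
#'
#' @param n_genes,n_informative Number of genes and of informative genes.
#' @param effect_size Class effect in units of `noise_sd`.
#' @param n_datasets Number of datasets/platforms.
#' @param samples_per_class Samples per class per dataset.
#' @param platform_missing_fraction Fraction of genes unmeasured per
#'   dataset, in `[0, 1)`.
#' @param dataset_shift_sd Standard deviation of the per-gene dataset
#'   offsets (log2 units).
#' @param noise_sd Within-class noise standard deviation (log2 units).
#' @param mixture_samples Number of interpolated `unknown` samples.
#' @param seed Master seed.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 1000L, n_informative = 15L,
                              effect_size = 1.5, n_datasets = 4L,
                              samples_per_class = 20L,
                              platform_missing_fraction = 0.1,
                              dataset_shift_sd = 1.0, noise_sd = 1.0,
                              mixture_samples = 0L, seed = 42L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_informative = as.integer(n_informative),
              effect_size = effect_size,
              n_datasets = as.integer(n_datasets),
              samples_per_class = as.integer(samples_per_class),
              platform_missing_fraction = platform_missing_fraction,
              dataset_shift_sd = dataset_shift_sd,
              noise_sd = noise_sd,
              mixture_samples = as.integer(mixture_samples),
              seed = as.integer(seed))
  if (cfg$n_informative > cfg$n_genes)
    stop("'n_informative' must not exceed 'n_genes'")
  if (cfg$platform_missing_fraction < 0 ||
      cfg$platform_missing_fraction >= 1)
    stop("'platform_missing_fraction' must be in [0, 1)")
  if (cfg$dataset_shift_sd < 0 || cfg$noise_sd < 0 ||
      cfg$effect_size < 0)
    stop("standard deviations and effect size must be >= 0")
  if (cfg$n_genes < 1 || cfg$n_datasets < 1 || cfg$samples_per_class < 1 ||
      cfg$mixture_samples < 0)
    stop("counts must be positive")
  class(cfg) <- "SimulationConfig"
  cfg
}

# gene-level profiles shared by every dataset simulated under one config:
# baseline log2 expression, informative gene set, and per-class mean
# profiles (the class effect raises MSC expression)
sim_profiles <- function(cfg) {
  withr::with_seed(cfg$seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    informative <- sort(sample(cfg$n_genes, cfg$n_informative))
    baseline <- stats::runif(cfg$n_genes, 4, 12)
    effect <- numeric(cfg$n_genes)
    effect[informative] <- cfg$effect_size * cfg$noise_sd
    list(genes = genes, informative = genes[informative],
         baseline = baseline, effect = effect)
  })
}

# one dataset: baseline + per-gene offset + class effect + noise, with a
# random platform_missing_fraction of genes zero-filled
sim_one_dataset <- function(cfg, prof, dataset_id, n_msc, n_non,
                            mixture_lambda = numeric(0)) {
  p <- cfg$n_genes
  offsets <- stats::rnorm(p, 0, cfg$dataset_shift_sd)
  n_mix <- length(mixture_lambda)
  n <- n_msc + n_non + n_mix
  labels <- c(rep("MSC", n_msc), rep("nonMSC", n_non),
              rep("unknown", n_mix))
  lambda <- c(rep(1, n_msc), rep(0, n_non), mixture_lambda)
  mean_mat <- outer(prof$baseline + offsets, rep(1, n)) +
    outer(prof$effect, lambda)
  values <- mean_mat + matrix(stats::rnorm(p * n, 0, cfg$noise_sd), p, n)
  values <- pmax(values, 0)
  n_miss <- floor(cfg$platform_missing_fraction * p)
  missing <- if (n_miss > 0) sample(p, n_miss) else integer(0)
  presence <- matrix(TRUE, p, n)
  if (length(missing)) {
    values[missing, ] <- 0
    presence[missing, ] <- FALSE
  }
  ids <- sprintf("%s_s%03d", dataset_id, seq_len(n))
  dimnames(values) <- dimnames(presence) <- list(prof$genes, ids)
  list(values = values, presence = presence,
       samples = data.frame(sample_id = ids, dataset_id = dataset_id,
                            platform = paste0("platform_", dataset_id),
                            class_label = labels,
                            stringsAsFactors = FALSE),
       missing = missing)
}

#' Simulate a multi-dataset, multi-platform two-class compendium
#'
#' Draws the datasets described by a [simulation_config()], merges them
#' gene-wise (union of measured genes, zero-fill for absences), and
#' returns the merged matrix, the sample table, and the ground-truth
#' informative gene list. Mixture samples, if requested, are spread over
#' the datasets round-robin with interpolation weights cycling through
#' 0.25, 0.5, 0.75. Informative genes are guaranteed to be measured in at
#' least one dataset. Bit-reproducible for a given config.
#'
#' @param cfg A [simulation_config()].
#' @return List with `expression` ([expression_matrix()]), `samples`
#'   (sample table) and `truth` (character vector of informative genes).
#' @export
simulate_multiplatform <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  prof <- sim_profiles(cfg)
  lam_pool <- rep_len(c(0.25, 0.5, 0.75), cfg$mixture_samples)
  mix_per_ds <- split(lam_pool,
                      rep_len(seq_len(cfg$n_datasets),
                              cfg$mixture_samples))
  withr::with_seed(cfg$seed + 1L, {
    dsets <- lapply(seq_len(cfg$n_datasets), function(d) {
      sim_one_dataset(cfg, prof, sprintf("d%d", d),
                      cfg$samples_per_class, cfg$samples_per_class,
                      mix_per_ds[[as.character(d)]] %||% numeric(0))
    })
    # an informative gene absent from every dataset would make the ground
    # truth unlearnable; restore it on one random dataset
    inf_idx <- match(prof$informative, prof$genes)
    for (g in inf_idx) {
      absent <- vapply(dsets, function(ds) g %in% ds$missing, logical(1))
      if (all(absent)) {
        d <- sample(cfg$n_datasets, 1)
        dsets[[d]]$missing <- setdiff(dsets[[d]]$missing, g)
        dsets[[d]]$presence[g, ] <- TRUE
        n <- ncol(dsets[[d]]$values)
        off <- stats::rnorm(1, 0, cfg$dataset_shift_sd)
        lam <- as.numeric(dsets[[d]]$samples$class_label == "MSC")
        dsets[[d]]$values[g, ] <-
          pmax(prof$baseline[g] + off + prof$effect[g] * lam +
                 stats::rnorm(n, 0, cfg$noise_sd), 0)
      }
    }
    samples <- do.call(rbind, lapply(dsets, `[[`, "samples"))
    matrices <- lapply(dsets, function(ds) {
      keep <- setdiff(seq_len(cfg$n_genes), ds$missing)
      expression_matrix(ds$values[keep, , drop = FALSE],
                        ds$presence[keep, , drop = FALSE])
    })
    list(expression = merge_datasets(matrices, samples),
         samples = samples, truth = prof$informative)
  })
}

#' Simulate one additional dataset from an existing design
#'
#' Draws a fresh dataset from the same gene-level profiles as
#' [simulate_multiplatform()] with the same config, but with its own
#' batch offsets, missing-gene mask and noise governed by `seed` — the
#' situation of scoring a newly published study against a trained
#' classifier.
#'
#' @param cfg The [simulation_config()] used for training.
#' @param seed Seed for this dataset's randomness.
#' @param dataset_id Identifier for the new dataset.
#' @return List with `expression` and `samples` (classes MSC / nonMSC).
#' @export
simulate_dataset <- function(cfg, seed, dataset_id = "d_new") {
  stopifnot(inherits(cfg, "SimulationConfig"))
  prof <- sim_profiles(cfg)
  withr::with_seed(as.integer(seed), {
    ds <- sim_one_dataset(cfg, prof, dataset_id,
                          cfg$samples_per_class, cfg$samples_per_class)
    keep <- setdiff(seq_len(cfg$n_genes), ds$missing)
    list(expression = expression_matrix(ds$values[keep, , drop = FALSE],
                                        ds$presence[keep, , drop = FALSE]),
         samples = ds$samples)
  })
}

#' Simulate a differentiation-style transition series
#'
#' Generates samples interpolating the two class mean profiles:
#' `lambda = 1` is the MSC endpoint, `lambda = 0` the non-MSC endpoint,
#' intermediate values emulate cells captured mid-differentiation. Each
#' sample is the interpolated class mean profile plus fresh within-class
#' noise (no batch offset and no missing genes: a transition series is a
#' single experimental series). All samples are labelled `unknown`
#' because their identity is what a classifier must decide.
#'
#' @param cfg The [simulation_config()] used for training.
#' @param timepoints Numeric vector of interpolation weights in `[0, 1]`,
#'   ordered as a series; one sample is generated per entry.
#' @param seed Seed for the series noise (default `cfg$seed + 2`).
#' @return List with `expression` ([expression_matrix()]) and `samples`.
#' @export
simulate_transition <- function(cfg, timepoints, seed = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (!length(timepoints)) stop("'timepoints' must be non-empty")
  if (any(timepoints < 0 | timepoints > 1))
    stop("'timepoints' must lie in [0, 1]")
  prof <- sim_profiles(cfg)
  seed <- as.integer(seed %||% (cfg$seed + 2L))
  p <- cfg$n_genes
  n <- length(timepoints)
  withr::with_seed(seed, {
    mean_mat <- outer(prof$baseline, rep(1, n)) +
      outer(prof$effect, timepoints)
    values <- pmax(mean_mat +
                     matrix(stats::rnorm(p * n, 0, cfg$noise_sd), p, n), 0)
    ids <- sprintf("t%03d_lam%03d", seq_len(n), round(100 * timepoints))
    dimnames(values) <- list(prof$genes, ids)
    list(expression = expression_matrix(values),
         samples = data.frame(sample_id = ids, dataset_id = "transition",
                              platform = "platform_transition",
                              class_label = "unknown",
                              stringsAsFactors = FALSE))
  })
}
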