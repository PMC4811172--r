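#' Pipeline configuration
#'
#' Bundles every tunable of the training pipeline with validation.
#' Defaults follow the reference protocol where it states a value
#' (`H = 4` components, `M = 200` subsamplings, 99% class coverage, 95%
#' confidence intervals); the remaining knobs are implementation defaults
#' documented in the methods vignette (subsample fraction 0.8, `keepX`
#' 20 genes per component before refinement, refinement alpha 0.05).
#'
#' @param H Number of sPLS-DA components.
#' @param M Number of subsamplings (stability selection and ensemble).
#' @param fraction Per-stratum subsampling fraction, in `(0, 1)`.
#' @param keepX Per-component sparsity before refinement (recycled to
#'   length `H`).
#' @param keepX_grid Optional candidate grid; when non-`NULL`,
#'   [tune_keepX()] chooses `keepX` by cross-validation before stability
#'   selection.
#' @param alpha_refine Significance threshold of the refinement t-test.
#' @param coverage Class coverage defining the decision thresholds.
#' @param ci_level Confidence level of per-sample score intervals.
#' @param decision_rule `"ci"` or `"pass_rate"`.
#' @param max_set_size Candidate cap per component during refinement.
#' @param prescreen Whether to drop genes measured in fewer than half the
#'   samples before normalization.
#' @param oob Whether the thresholds and the training report use each
#'   sample's out-of-bag submodels only (see [build_ensemble()]).
#' @param folds Cross-validation folds for `keepX` tuning.
#' @param seed Master seed for every stochastic stage.
#' @return A validated list of class `msc_run_config`.
#' @export
run_config <- function(H = 4L, M = 200L, fraction = 0.8, keepX = 20L,
                       keepX_grid = NULL, alpha_refine = 0.05,
                       coverage = 0.99, ci_level = 0.95,
                       decision_rule = c("ci", "pass_rate"),
                       max_set_size = 30L, prescreen = TRUE, folds = 5L,
                       oob = FALSE, seed = 1L) {
  decision_rule <- match.arg(decision_rule)
  cfg <- list(H = as.integer(H), M = as.integer(M), fraction = fraction,
              keepX = as.integer(keepX), keepX_grid = keepX_grid,
              alpha_refine = alpha_refine, coverage = coverage,
              ci_level = ci_level, decision_rule = decision_rule,
              max_set_size = as.integer(max_set_size),
              prescreen = isTRUE(prescreen), folds = as.integer(folds),
              oob = isTRUE(oob), seed = as.integer(seed))
  if (cfg$H < 1) stop("'H' must be >= 1")
  if (cfg$M < 2) stop("'M' must be at least 2")
  if (!is.numeric(cfg$fraction) || cfg$fraction <= 0 || cfg$fraction >= 1)
    stop("'fraction' must be in (0, 1)")
  if (any(cfg$keepX < 1)) stop("'keepX' must be >= 1")
  if (cfg$alpha_refine <= 0 || cfg$alpha_refine > 1)
    stop("'alpha_refine' must be in (0, 1]")
  if (cfg$coverage < 0.5 || cfg$coverage >= 1)
    stop("'coverage' must be in [0.5, 1)")
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1)
    stop("'ci_level' must be in (0, 1)")
  class(cfg) <- "msc_run_config"
  cfg
}

#' Train the full MSC classification pipeline
#'
#' Runs pre-screening, YuGene normalization, (optional) `keepX` tuning,
#' stability selection, nested-set refinement, ensemble fitting and
#' threshold learning, end to end. Only samples labelled `MSC` or
#' `nonMSC` are used for training. When `out_dir` is given, writes
#' `signature.tsv`, `ensemble.json`, `training_report.tsv` and
#' `manifest.json` (full config, seeds and output checksums, sufficient
#' to reproduce the artifacts exactly).
#'
#' @param expression An [expression_matrix()] of log2 values (merged
#'   across datasets, presence mask populated).
#' @param samples Sample table covering the matrix columns.
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list of class `msc_training` with `signature`,
#'   `ensemble`, `report`, `profile`, `keepX` and `config`.
#' @export
cmd_train <- function(expression, samples, config = run_config(),
                      out_dir = NULL) {
  stopifnot(inherits(expression, "ExpressionMatrix"),
            inherits(config, "msc_run_config"))
  samples <- validate_sample_table(samples)
  if (!all(colnames(expression$values) %in% samples$sample_id))
    stop("every expression column needs a sample table row")

  screened <- if (config$prescreen) prescreen_genes(expression)
              else expression
  normalized <- yugene_matrix(screened)

  train_ids <- samples$sample_id[samples$class_label %in%
                                   c("MSC", "nonMSC")]
  if (!length(train_ids)) stop("no labelled MSC/nonMSC training samples")
  train_samples <- samples[match(train_ids, samples$sample_id), ,
                           drop = FALSE]
  rownames(train_samples) <- NULL
  X <- t(normalized$values[, train_ids, drop = FALSE])

  keepX <- if (!is.null(config$keepX_grid)) {
    tune_keepX(X, train_samples$class_label, config$keepX_grid,
               folds = config$folds, H = config$H, seed = config$seed)
  } else {
    rep_len(config$keepX, config$H)
  }

  profile <- stability_selection(X, train_samples, H = config$H,
                                 keepX = keepX, M = config$M,
                                 fraction = config$fraction,
                                 seed = config$seed)
  signature <- refine_signature(profile, X, train_samples,
                                alpha_refine = config$alpha_refine,
                                max_set_size = config$max_set_size)
  ensemble <- build_ensemble(X, train_samples, signature, M = config$M,
                             fraction = config$fraction,
                             seed = config$seed + config$M,
                             coverage = config$coverage,
                             ci_level = config$ci_level,
                             oob = config$oob)
  ensemble$gene_universe <- rownames(normalized$values)

  result <- structure(list(signature = signature, ensemble = ensemble,
                           report = ensemble$train_report,
                           profile = profile, keepX = keepX,
                           config = config),
                      class = "msc_training")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sig_path <- file.path(out_dir, "signature.tsv")
    ens_path <- file.path(out_dir, "ensemble.json")
    rep_path <- file.path(out_dir, "training_report.tsv")
    write_signature(signature, sig_path)
    write_ensemble(ensemble, ens_path)
    write_report(ensemble$train_report, rep_path)
    manifest <- list(config = unclass(config)[!vapply(unclass(config),
                                                      is.null, logical(1))],
                     keepX = keepX,
                     n_training_samples = nrow(X),
                     n_genes_after_prescreen = ncol(X),
                     outputs = as.list(tools::md5sum(
                       c(sig_path, ens_path, rep_path))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}

#' Score new samples with a trained ensemble
#'
#' Applies the training normalization to new data — the matrix is
#' restricted (zero-filling absences) to the ensemble's stored training
#' gene universe so YuGene cumulative proportions use the same gene set
#' as training — then scores every sample with all submodels and applies
#' the three-way decision rule. Optionally writes the report TSV.
#'
#' @param ensemble An `msc_ensemble` (or a path to an `ensemble.json`).
#' @param expression An [expression_matrix()] of log2 values for the new
#'   samples.
#' @param out Optional output TSV path.
#' @param decision_rule `"ci"` (default) or `"pass_rate"`.
#' @param yugene Set to `FALSE` when `expression` is already in YuGene
#'   units.
#' @return An `msc_score_report` data frame.
#' @export
cmd_score <- function(ensemble, expression, out = NULL,
                      decision_rule = c("ci", "pass_rate"),
                      yugene = TRUE) {
  if (is.character(ensemble)) ensemble <- read_ensemble(ensemble)
  stopifnot(inherits(ensemble, "msc_ensemble"),
            inherits(expression, "ExpressionMatrix"))
  decision_rule <- match.arg(decision_rule)
  if (ncol(expression$values) == 0) stop("empty expression matrix")
  m <- expression
  if (!is.null(ensemble$gene_universe)) {
    # restrict to the training gene universe; genes outside it must not
    # contribute cumulative mass. Genes of the universe that are absent
    # here are dropped (zero mass either way) and flagged downstream,
    # where they are imputed at the training center.
    keep <- rownames(m$values) %in% ensemble$gene_universe &
      rowSums(m$presence) > 0
    if (!any(keep))
      stop("no gene of the training universe is present in the input")
    m <- expression_matrix(m$values[keep, , drop = FALSE],
                           m$presence[keep, , drop = FALSE])
  }
  if (yugene) m <- yugene_matrix(m)
  report <- score_samples(ensemble, t(m$values), decision_rule)
  if (!is.null(out)) write_report(report, out)
  message("calls: ", sum(report$call == "MSC"), " MSC, ",
          sum(report$call == "nonMSC"), " nonMSC, ",
          sum(report$call == "unknown"), " unknown")
  report
}
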