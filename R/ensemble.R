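#' Learn the three-way decision thresholds from training scores
#'
#' Given the per-sample mean ensemble scores of the labelled training set,
#' `t_high` is the `(1 - coverage)` quantile of the MSC scores (so a
#' `coverage` share of MSC lies above it) and `t_low` the `coverage`
#' quantile of the non-MSC scores (a `coverage` share of non-MSC lies
#' below it). The interval `(t_low, t_high)` is the uncertainty region: a
#' sample whose confidence interval touches it is called `unknown`. If the
#' two quantiles cross (`t_low > t_high`) there is no uncertainty region
#' and `empty_overlap` is flagged. Quantiles use linear interpolation
#' between order statistics (type 7) for bit-reproducibility.
#'
#' @param mean_scores Numeric vector of per-sample mean scores.
#' @param labels Matching class labels; both `MSC` and `nonMSC` must be
#'   present.
#' @param coverage Class coverage in `[0.5, 1)`; the reference protocol
#'   uses 0.99 (99% of each class falls on its own side).
#' @return List with `t_low`, `t_high`, `empty_overlap`.
#' @export
learn_thresholds <- function(mean_scores, labels, coverage = 0.99) {
  if (!is.numeric(coverage) || coverage < 0.5 || coverage >= 1)
    stop("'coverage' must be in [0.5, 1)")
  labels <- as.character(labels)
  if (length(mean_scores) != length(labels))
    stop("'mean_scores' and 'labels' lengths differ")
  msc <- mean_scores[labels == "MSC"]
  non <- mean_scores[labels == "nonMSC"]
  if (!length(msc) || !length(non)) stop("single class")
  t_high <- unname(stats::quantile(msc, 1 - coverage, type = 7))
  t_low <- unname(stats::quantile(non, coverage, type = 7))
  list(t_low = t_low, t_high = t_high, empty_overlap = t_low > t_high)
}

# per-sample x per-submodel score matrix on pre-aligned data
score_matrix <- function(submodels, X) {
  vapply(submodels, function(m) predict_score(m, X), numeric(nrow(X)))
}

# assemble a ScoreReport data frame from an n x M score matrix
make_report <- function(sample_ids, scores, thresholds, ci_level,
                        decision_rule = c("ci", "pass_rate")) {
  decision_rule <- match.arg(decision_rule)
  a <- (1 - ci_level) / 2
  ci <- t(apply(scores, 1, stats::quantile, probs = c(a, 1 - a), type = 7,
                na.rm = TRUE))
  mean_score <- rowMeans(scores, na.rm = TRUE)
  if (decision_rule == "ci") {
    call <- ifelse(ci[, 1] > thresholds$t_high, "MSC",
                   ifelse(ci[, 2] < thresholds$t_low, "nonMSC", "unknown"))
  } else {
    pr <- rowMeans(scores > thresholds$t_high, na.rm = TRUE)
    nr <- rowMeans(scores < thresholds$t_low, na.rm = TRUE)
    call <- ifelse(pr >= 0.95, "MSC", ifelse(nr >= 0.95, "nonMSC",
                                             "unknown"))
  }
  out <- data.frame(sample_id = sample_ids, mean_score = mean_score,
                    ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
                    call = call, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  class(out) <- c("msc_score_report", "data.frame")
  out
}

#' Build the subsampling ensemble behind the MSC score
#'
#' Restricts the training matrix to the signature genes, fits `M` sPLS-DA
#' submodels on stratified subsamples (each component's `keepX` equals the
#' number of signature genes assigned to it), scores every training sample
#' with all `M` submodels, and learns the decision thresholds from the
#' per-sample mean scores with [learn_thresholds()]. Training samples are
#' scored by all submodels, including those whose subsample contained
#' them, mirroring the reference protocol of recording one score per
#' subsampling; see [score_samples()] for out-of-sample use.
#'
#' @param X Samples x genes matrix in training (YuGene) units, rows
#'   aligned with `samples`.
#' @param samples Sample table with labels in `{MSC, nonMSC}`.
#' @param signature An `msc_signature` data frame; all its genes must be
#'   columns of `X`.
#' @param M Ensemble size (the reference protocol uses 200).
#' @param fraction Per-stratum subsampling fraction.
#' @param seed Master seed (submodel `m` uses `seed + m`).
#' @param coverage Class coverage for the thresholds.
#' @param ci_level Confidence level of the per-sample percentile interval.
#' @param oob When `TRUE`, the training report and the thresholds use only
#'   each sample's out-of-bag submodels (those whose subsample excluded
#'   it), giving an honest estimate of the score spread a sample from an
#'   unseen dataset would show; when `FALSE`, every sample is scored by
#'   all `M` submodels.
#' @return An object of class `msc_ensemble`.
#' @export
build_ensemble <- function(X, samples, signature, M = 200L, fraction = 0.8,
                           seed = 1L, coverage = 0.99, ci_level = 0.95,
                           oob = FALSE) {
  samples <- validate_sample_table(samples)
  check_aligned(X, samples)
  stopifnot(is.data.frame(signature))
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("'ci_level' must be in (0, 1)")
  miss <- setdiff(signature$gene, colnames(X))
  if (length(miss))
    stop("signature gene(s) absent from the training matrix: ",
         paste(miss, collapse = ", "))
  M <- as.integer(M)
  if (M < 2) stop("'M' must be at least 2")
  comps <- sort(unique(signature$component))
  keepx <- vapply(comps, function(h) sum(signature$component == h),
                  integer(1))
  Xs <- X[, signature$gene, drop = FALSE]
  submodels <- vector("list", M)
  inbag <- matrix(FALSE, nrow(Xs), M)
  for (m in seq_len(M)) {
    res <- fit_on_subsample(Xs, samples, length(comps), keepx,
                            fraction, seed + m)
    submodels[[m]] <- res$fit
    inbag[res$idx, m] <- TRUE
  }
  scores <- score_matrix(submodels, Xs)
  if (oob) {
    masked <- scores
    masked[inbag] <- NA_real_
    # a sample in-bag everywhere (tiny strata) falls back to all models
    allin <- rowSums(!inbag) == 0
    masked[allin, ] <- scores[allin, ]
    scores <- masked
  }
  thresholds <- learn_thresholds(rowMeans(scores, na.rm = TRUE),
                                 samples$class_label, coverage)
  clf <- structure(
    list(submodels = submodels, signature = signature,
         thresholds = thresholds, coverage = coverage,
         ci_level = ci_level, M = M, fraction = fraction, seed = seed,
         genes = signature$gene, gene_universe = NULL),
    class = "msc_ensemble")
  clf$train_report <- make_report(samples$sample_id, scores, thresholds,
                                  ci_level)
  clf
}

#' @export
print.msc_ensemble <- function(x, ...) {
  cat("MSC ensemble classifier: ", x$M, " submodels on ",
      length(x$genes), " signature genes; thresholds t_low = ",
      format(x$thresholds$t_low, digits = 4), ", t_high = ",
      format(x$thresholds$t_high, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Score samples with an ensemble and call MSC / non-MSC / unknown
#'
#' Every sample receives one score per submodel; its confidence interval
#' is the percentile interval of those `M` scores at the ensemble's
#' `ci_level`. Under the `ci` rule a sample is called `MSC` when the lower
#' CI bound lies strictly above `t_high`, `nonMSC` when the upper bound
#' lies strictly below `t_low`, and `unknown` otherwise. Under the
#' alternative `pass_rate` rule a sample is `MSC` when at least 95% of its
#' scores exceed `t_high` (symmetrically `nonMSC` below `t_low`). Genes
#' missing from `X_new` are zero-filled with a warning; input must be in
#' training (YuGene) units.
#'
#' @param clf An [build_ensemble()] classifier.
#' @param X_new Samples x genes matrix in YuGene units.
#' @param decision_rule `"ci"` (default) or `"pass_rate"`.
#' @return An `msc_score_report` data frame with columns `sample_id`,
#'   `mean_score`, `ci_low`, `ci_high`, `call`; the full n x M score
#'   matrix is attached as attribute `"scores"`.
#' @export
score_samples <- function(clf, X_new, decision_rule = c("ci", "pass_rate")) {
  stopifnot(inherits(clf, "msc_ensemble"))
  decision_rule <- match.arg(decision_rule)
  if (is.null(dim(X_new)))
    X_new <- matrix(X_new, nrow = 1, dimnames = list(NULL, names(X_new)))
  if (nrow(X_new) == 0) stop("empty input: no samples to score")
  if (is.null(colnames(X_new)) && ncol(X_new) == length(clf$genes))
    colnames(X_new) <- clf$genes
  present <- intersect(colnames(X_new), clf$genes)
  miss <- setdiff(clf$genes, present)
  if (2 * length(miss) > length(clf$genes))
    stop("insufficient gene coverage: ", length(miss), " of ",
         length(clf$genes), " signature genes missing")
  if (length(miss))
    warning(length(miss), " signature gene(s) missing from input, ",
            "imputed at the training center: ",
            paste(utils::head(miss, 5), collapse = ", "))
  A <- X_new[, present, drop = FALSE]
  ids <- rownames(X_new) %||% paste0("sample_", seq_len(nrow(X_new)))
  scores <- vapply(clf$submodels,
                   function(m) suppressWarnings(predict_score(m, A)),
                   numeric(nrow(A)))
  if (nrow(A) == 1) scores <- matrix(scores, nrow = 1)
  make_report(ids, scores, clf$thresholds, clf$ci_level, decision_rule)
}

#' Fraction of ensemble scores above the MSC threshold
#'
#' The alternative decision statistic: the fraction of a sample's `M`
#' scores strictly above `t_high`. A sample passes the rate rule when
#' `pass_rate >= 0.95`.
#'
#' @param scores Numeric vector of one sample's ensemble scores.
#' @param t_high Upper decision threshold.
#' @return Fraction in `[0, 1]`.
#' @export
pass_rate <- function(scores, t_high) {
  if (!length(scores)) stop("'scores' must be non-empty")
  mean(scores > t_high)
}

#' Write a score report as TSV
#'
#' Header `sample_id mean_score ci_low ci_high call`.
#'
#' @param report An `msc_score_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  utils::write.table(as.data.frame(report)[c("sample_id", "mean_score",
                                             "ci_low", "ci_high", "call")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
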