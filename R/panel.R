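#' Evaluate a fixed marker panel by subsampled PLS-DA
#'
#' Benchmarks a fixed gene panel (for example the minimal CD45/CD73/CD105
#' immunophenotype, or a 32-marker surface panel) the same way the
#' signature itself is scored: the matrix is restricted to the panel, and
#' over `M` stratified subsamplings a non-sparse PLS-DA
#' (`keepX` = panel size) is fitted and the held-out complement is
#' classified by the maximum predicted class indicator (MSC when the
#' predicted MSC indicator is >= 0.5). Error rates are pooled over all
#' held-out samples, so the overall error is exactly the sample-weighted
#' combination of the class-wise errors.
#'
#' @param X Samples x genes matrix, rows aligned with `samples`.
#' @param samples Sample table with labels in `{MSC, nonMSC}`.
#' @param panel Character vector of panel gene IDs (at least one must be
#'   present in `X`; absent ones are dropped with a warning).
#' @param n_components Number of PLS-DA components (default 2, the
#'   convention for fixed marker panels); must not exceed the panel size.
#' @param M Number of subsamplings.
#' @param fraction Per-stratum subsampling fraction.
#' @param seed Master seed.
#' @param name Panel label carried into the result.
#' @return A one-row `data.frame` with columns `panel`, `overall_error`,
#'   `msc_misclassified`, `nonmsc_misclassified` (percentages), `M`,
#'   `n_components`.
#' @export
evaluate_panel <- function(X, samples, panel, n_components = 2L, M = 200L,
                           fraction = 0.8, seed = 1L, name = "panel") {
  samples <- validate_sample_table(samples)
  check_aligned(X, samples)
  panel <- unique(as.character(panel))
  present <- intersect(panel, colnames(X))
  if (!length(present)) stop("no panel gene is present in the matrix")
  if (length(present) < length(panel))
    warning(length(panel) - length(present),
            " panel gene(s) absent from the matrix, dropped")
  n_components <- as.integer(n_components)
  if (n_components > length(present))
    stop("'n_components' (", n_components, ") exceeds the panel size (",
         length(present), ")")
  M <- as.integer(M)
  if (M < 1) stop("'M' must be >= 1")
  Xp <- X[, present, drop = FALSE]
  wrong <- c(MSC = 0, nonMSC = 0)
  total <- c(MSC = 0, nonMSC = 0)
  for (m in seq_len(M)) {
    res <- fit_on_subsample(Xp, samples, n_components,
                            length(present), fraction, seed + m)
    out <- setdiff(seq_len(nrow(Xp)), res$idx)
    if (!length(out)) next
    sc <- predict_score(res$fit, Xp[out, , drop = FALSE])
    call <- ifelse(sc >= 0.5, "MSC", "nonMSC")
    lab <- samples$class_label[out]
    for (cl in c("MSC", "nonMSC")) {
      total[cl] <- total[cl] + sum(lab == cl)
      wrong[cl] <- wrong[cl] + sum(lab == cl & call != cl)
    }
  }
  if (all(total == 0)) stop("no held-out samples: use fraction < 1")
  data.frame(panel = name,
             overall_error = 100 * sum(wrong) / sum(total),
             msc_misclassified = 100 * wrong[["MSC"]] /
               max(total[["MSC"]], 1),
             nonmsc_misclassified = 100 * wrong[["nonMSC"]] /
               max(total[["nonMSC"]], 1),
             M = M, n_components = n_components,
             stringsAsFactors = FALSE)
}

#' Per-gene differential expression between MSC and non-MSC
#'
#' Welch two-sample two-tailed t-test of one gene between the two classes;
#' the significance flag uses the conventional genome-wide threshold of
#' 1e-6. Welch's unequal-variance form is used because class sizes are
#' typically very unbalanced. A gene with zero variance in both classes is
#' degenerate and reported with p = 1.
#'
#' @param X Samples x genes matrix, rows aligned with `samples`.
#' @param samples Sample table.
#' @param gene Gene ID (must be a column of `X`).
#' @param threshold Significance threshold (default `1e-6`).
#' @return List with `p_value` and `significant`.
#' @export
marker_ttest <- function(X, samples, gene, threshold = 1e-6) {
  samples <- validate_sample_table(samples)
  check_aligned(X, samples)
  if (!gene %in% colnames(X)) stop("gene '", gene, "' not in the matrix")
  x <- X[, gene]
  msc <- x[samples$class_label == "MSC"]
  non <- x[samples$class_label == "nonMSC"]
  if (length(msc) < 2 || length(non) < 2)
    stop("each class needs at least 2 samples")
  p <- tryCatch(stats::t.test(msc, non)$p.value,
                error = function(e) 1)  # zero-variance degenerate case
  list(p_value = p, significant = p < threshold)
}

#' Read a panel file
#'
#' Plain text, one gene ID per line; blank lines and lines starting with
#' `#` are skipped.
#'
#' @param path File path.
#' @return Character vector of gene IDs.
#' @export
read_panel <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("no genes in panel file '", path, "'")
  unique(x)
}
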