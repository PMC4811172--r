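#' Stratified subsampling of a multi-dataset two-class design
#'
#' Draws `ceiling(fraction * n)` samples without replacement from every
#' (dataset, class) stratum, so no single data source or platform can
#' dominate a fit. Strata of size 1 are always retained (with a warning).
#' The result is reproducible given `seed` and always contains both
#' classes when both are present in the input.
#'
#' @param samples Sample table (see [validate_sample_table()]).
#' @param fraction Fraction to draw per stratum, in `(0, 1]`.
#' @param seed Integer seed.
#' @return Sorted integer vector of row indices into `samples`.
#' @export
subsample_indices <- function(samples, fraction, seed) {
  samples <- validate_sample_table(samples)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  if (length(unique(samples$class_label)) < 2)
    stop("both classes must be present")
  key <- paste(samples$dataset_id, samples$class_label, sep = "\r")
  strata <- split(seq_len(nrow(samples)), factor(key, levels = unique(key)))
  out <- withr::with_seed(seed, {
    unlist(lapply(strata, function(idx) {
      if (length(idx) == 1) {
        warning("stratum of size 1 is always retained")
        return(idx)
      }
      sample(idx, ceiling(fraction * length(idx)))
    }), use.names = FALSE)
  })
  sort(out)
}

#' Selection-frequency estimation over repeated subsamplings
#'
#' Fits [fit_splsda()] on `M` stratified subsamples and records, per gene
#' and per component, the fraction of fits in which the gene received a
#' nonzero loading. A gene's frequency measures the stability of its
#' selection: genes whose inclusion depends on one dominant dataset or
#' platform score low. All `M` fitted models and their subsample index
#' sets are retained for the refinement and ensemble stages.
#'
#' @param X Samples x genes matrix (rows aligned with `samples`).
#' @param samples Sample table with labels in `{MSC, nonMSC}`.
#' @param H Number of components.
#' @param keepX Per-component sparsity (recycled to length `H`).
#' @param M Number of subsamplings (>= 2; the reference protocol uses 200).
#' @param fraction Per-stratum subsampling fraction.
#' @param seed Master seed; iteration `m` uses `seed + m`, and a failed
#'   fit is redrawn with a derived seed up to 10 times.
#' @return An object of class `StabilityProfile`: list with `frequency`
#'   (genes x components matrix in `[0, 1]`), `M`, `fraction`, `seed`,
#'   `keepX`, `H`, `models`, `subsamples`.
#' @export
stability_selection <- function(X, samples, H = 4L, keepX = 20L, M = 200L,
                                fraction = 0.8, seed = 1L) {
  samples <- validate_sample_table(samples)
  check_aligned(X, samples)
  M <- as.integer(M)
  if (M < 2) stop("'M' must be at least 2")
  H <- as.integer(H)
  keepX <- rep_len(as.integer(keepX), H)
  genes <- colnames(X)
  counts <- matrix(0L, ncol(X), H, dimnames = list(genes, NULL))
  models <- vector("list", M)
  subsamples <- vector("list", M)
  for (m in seq_len(M)) {
    res <- fit_on_subsample(X, samples, H, keepX, fraction, seed + m)
    models[[m]] <- res$fit
    subsamples[[m]] <- res$idx
    for (h in seq_len(H))
      counts[, h] <- counts[, h] + (res$fit$components[[h]]$loading != 0)
  }
  structure(list(frequency = counts / M, M = M, fraction = fraction,
                 seed = seed, keepX = keepX, H = H, models = models,
                 subsamples = subsamples),
            class = "StabilityProfile")
}

#' @export
print.StabilityProfile <- function(x, ...) {
  cat("StabilityProfile: ", nrow(x$frequency), " genes x ", x$H,
      " components over ", x$M, " subsamplings (fraction ", x$fraction,
      ")\n", sep = "")
  invisible(x)
}

# out-of-bag balanced error of an sPLS-DA refit restricted to a candidate
# signature (gene/component assignment), one value per retained
# subsampling. The refit uses as many components as the candidate
# populates, with per-component keepX equal to the assigned gene counts.
set_errors <- function(X, samples, profile, sig) {
  comps <- sort(unique(sig$component))
  keepx <- vapply(comps, function(h) sum(sig$component == h), integer(1))
  genes <- sig$gene
  vapply(seq_len(profile$M), function(m) {
    idx <- profile$subsamples[[m]]
    out <- setdiff(seq_len(nrow(X)), idx)
    if (!length(out)) return(NA_real_)
    fit <- tryCatch(
      fit_splsda(X[idx, genes, drop = FALSE],
                 make_dummy(samples$class_label[idx]),
                 H = length(comps), keepX = keepx),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    balanced_error(predict_score(fit, X[out, genes, drop = FALSE]),
                   samples$class_label[out])
  }, numeric(1))
}

# one-tailed paired t-test p-value that `new` errors are lower than `prev`
paired_improvement_p <- function(prev, new) {
  ok <- is.finite(prev) & is.finite(new)
  d <- prev[ok] - new[ok]
  if (length(d) < 3) return(1)
  if (stats::sd(d) == 0) return(if (mean(d) > 0) 0 else 1)
  stats::t.test(prev[ok], new[ok], paired = TRUE,
                alternative = "greater")$p.value
}

#' Nested-set refinement of a stability profile into a compact signature
#'
#' Candidate genes are ordered per component by decreasing selection
#' frequency (ties by gene ID) and grown as nested cross-component sets
#' \eqn{S_1 \subset S_2 \subset \dots}: component 1's candidates first,
#' then component 2's appended, and so on, each set carrying its
#' gene-to-component assignment. Each set's classification error is the
#' out-of-bag balanced error of a multi-component refit restricted to the
#' set, evaluated on every retained subsampling's held-out complement.
#' Every nested set is assessed against the last accepted set with a
#' one-tailed paired t-test (alternative: the larger set has lower error)
#' and accepted when the improvement is significant at `alpha_refine`;
#' the signature is the accepted set after which no further extension
#' improves significantly. Two consequences: a single uninformative gene
#' (for instance one with unlucky batch offsets) cannot truncate the
#' signature while the error is still falling, and a whole component
#' whose genes never improve the cumulative accuracy — one tracking batch
#' structure rather than class structure — contributes no genes at all.
#' `alpha_refine = 1` retains every candidate. Genes are unique across
#' the signature (a gene claimed by an earlier component is withheld from
#' later ones). Each signature gene is annotated with the Pearson
#' correlation between its expression and its component's score in a
#' final full-data fit restricted to the signature, and with its loading
#' sign there.
#'
#' @param profile A [stability_selection()] result.
#' @param X,samples The same matrix and sample table the profile was
#'   computed on.
#' @param alpha_refine Significance threshold for continuing growth
#'   (default 0.05).
#' @param max_set_size Cap on candidates examined per component (default
#'   30).
#' @return An object of classes `msc_signature`/`data.frame` with columns
#'   `gene`, `component`, `frequency`, `correlation`, `sign`.
#' @export
refine_signature <- function(profile, X, samples, alpha_refine = 0.05,
                             max_set_size = 30L) {
  stopifnot(inherits(profile, "StabilityProfile"))
  samples <- validate_sample_table(samples)
  check_aligned(X, samples)
  if (!is.numeric(alpha_refine) || alpha_refine <= 0 || alpha_refine > 1)
    stop("'alpha_refine' must be in (0, 1]")
  freq <- profile$frequency
  selected <- NULL
  err_sel <- NULL
  for (h in seq_len(profile$H)) {
    f <- freq[, h]
    cand <- rownames(freq)[f > 0 &
                             !(rownames(freq) %in% selected$gene)]
    if (!length(cand)) next
    cand <- cand[radix_order(-f[cand], cand)]
    if (length(cand) > max_set_size) cand <- cand[seq_len(max_set_size)]
    first_component <- is.null(selected)
    if (first_component && length(cand) < 2)
      warning("component ", h,
              ": fewer than 2 candidate genes; all retained")
    base <- selected
    for (k in seq_along(cand)) {
      trial <- rbind(base,
                     data.frame(gene = cand[seq_len(k)], component = h,
                                frequency = unname(f[cand[seq_len(k)]])))
      if (first_component && k == 1) {
        # the seed set: the single most stable gene is the baseline every
        # later set must improve on
        selected <- trial
        err_sel <- set_errors(X, samples, profile, trial)
        next
      }
      err_k <- set_errors(X, samples, profile, trial)
      if (paired_improvement_p(err_sel, err_k) <= alpha_refine) {
        selected <- trial
        err_sel <- err_k
      }
    }
  }
  if (is.null(selected))
    stop("empty signature: no gene was ever selected")
  sig <- selected
  rownames(sig) <- NULL

  comps <- sort(unique(sig$component))
  keepx <- vapply(comps, function(h) sum(sig$component == h), integer(1))
  fit <- fit_splsda(X[, sig$gene, drop = FALSE],
                    make_dummy(samples$class_label),
                    H = length(comps), keepX = keepx)
  corr <- numeric(nrow(sig))
  sgn <- numeric(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    cm <- fit$components[[match(sig$component[i], comps)]]
    corr[i] <- component_correlation(X[, sig$gene[i]], cm$score)
    l <- cm$loading[[sig$gene[i]]]
    sgn[i] <- if (l != 0) sign(l) else sign(corr[i])
  }
  sig$correlation <- corr
  sig$sign <- sgn
  class(sig) <- c("msc_signature", "data.frame")
  attr(sig, "alpha_refine") <- alpha_refine
  sig
}

#' Correlation of a gene with a component score
#'
#' Plain Pearson correlation, the per-gene annotation reported alongside a
#' signature. A zero-variance input is degenerate: the correlation is
#' reported as 0 with attribute `degenerate = TRUE`.
#'
#' @param gene_values,component_score Numeric vectors of equal length
#'   >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
component_correlation <- function(gene_values, component_score) {
  if (length(gene_values) != length(component_score) ||
      length(gene_values) < 3)
    stop("inputs must have equal length >= 3")
  if (stats::sd(gene_values) == 0 || stats::sd(component_score) == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(gene_values, component_score)
}

#' Read and write signature files
#'
#' A signature is serialized as TSV with header
#' `gene component frequency correlation sign`; the file is both the
#' output of [refine_signature()] and the input of scoring-only mode.
#'
#' @param sig An `msc_signature` data frame.
#' @param path File path.
#' @return `read_signature()` returns an `msc_signature` data frame.
#' @export
write_signature <- function(sig, path) {
  stopifnot(is.data.frame(sig))
  utils::write.table(as.data.frame(sig)[c("gene", "component", "frequency",
                                          "correlation", "sign")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "component", "frequency", "correlation", "sign")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("signature file lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup)) stop("duplicated signature gene: '", dup[1], "'")
  class(df) <- c("msc_signature", "data.frame")
  df
}
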