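# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# locale-independent ordering/sorting (C collation via radix)
radix_sort <- function(x) sort(x, method = "radix")
radix_order <- function(...) order(..., method = "radix")

# balanced classification error of indicator-regression scores:
# call MSC when the predicted MSC indicator is >= 0.5, then average the
# per-class error rates so the 125-vs-510 style imbalance cannot dominate
balanced_error <- function(scores, labels) {
  call <- ifelse(scores >= 0.5, "MSC", "nonMSC")
  cls <- unique(labels)
  mean(vapply(cls, function(cl) mean(call[labels == cl] != cl), numeric(1)))
}

# fit an sPLS-DA on a stratified subsample, redrawing with a derived seed
# on failure (up to max_retry times)
fit_on_subsample <- function(X, samples, H, keepX, fraction, seed,
                             max_retry = 10L) {
  last <- NULL
  for (r in 0:max_retry) {
    s <- seed + r * 1000003
    idx <- subsample_indices(samples, fraction, s)
    fit <- tryCatch(
      fit_splsda(X[idx, , drop = FALSE],
                 make_dummy(samples$class_label[idx]),
                 H = H, keepX = keepX),
      error = identity)
    if (!inherits(fit, "error")) return(list(fit = fit, idx = idx))
    last <- fit
  }
  stop("model fit failed after ", max_retry, " subsampling redraws: ",
       conditionMessage(last))
}

check_aligned <- function(X, samples) {
  if (nrow(X) != nrow(samples))
    stop("expression matrix has ", nrow(X), " rows but the sample table has ",
         nrow(samples))
  if (!is.null(rownames(X)) && !identical(rownames(X), samples$sample_id))
    stop("expression row names do not match the sample table order")
  invisible(TRUE)
}
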