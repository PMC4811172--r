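#' YuGene cumulative-proportion transform of one sample
#'
#' Rescales a vector of log2 expression values to `[0, 1)` using the
#' cumulative proportion of total expression: with the values sorted in
#' decreasing order as \eqn{x_{(1)} \ge \dots \ge x_{(p)}} and total
#' \eqn{S = \sum_j x_j}, the gene at rank \eqn{k} receives
#' \eqn{1 - \sum_{j \le k} x_{(j)} / S}, mapped back to the original gene
#' order. The transform is a pure function of the single sample, so adding
#' or removing other samples (or whole datasets) never changes its output —
#' the property that makes it suitable for incremental cross-platform
#' integration.
#'
#' Conventions: negative inputs (possible after some background
#' corrections) are shifted by the sample minimum so the smallest value is
#' 0 before transforming; ties are broken by a stable sort on (value
#' decreasing, gene ID ascending — positional index when `x` is unnamed),
#' each tied gene keeping its own cumulative rank; an all-zero sample maps
#' to all zeros.
#'
#' @param x Finite numeric vector of length >= 1, optionally named by gene
#'   ID.
#' @return Numeric vector in `[0, 1)`, same length and order as `x`. The
#'   minimum-expression gene(s) map to 0.
#' @examples
#' yugene_transform(c(4, 3, 2, 1)) # 0.6 0.3 0.1 0.0
#' @export
yugene_transform <- function(x) {
  if (!is.numeric(x) || length(x) < 1) stop("'x' must be a numeric vector")
  if (any(!is.finite(x))) stop("non-finite values in input")
  nm <- names(x)
  x <- unname(x)
  if (min(x) < 0) x <- x - min(x)
  out <- numeric(length(x))
  s <- sum(x)
  if (s > 0) {
    key <- if (is.null(nm)) seq_along(x) else nm
    ord <- radix_order(-x, key)
    out[ord] <- 1 - cumsum(x[ord]) / s
    # the tail of the cumulative sum equals S exactly in exact arithmetic;
    # clamp the floating-point residue so zero-mass genes map to exact 0
    out[x == 0] <- 0
    out[ord[length(ord)]] <- 0
    out <- pmax(out, 0)
  }
  names(out) <- nm
  out
}

#' YuGene transform of every sample of an expression matrix
#'
#' Applies [yugene_transform()] column-wise (per sample). The presence mask
#' is carried through unchanged and zero-filled cells remain exactly 0:
#' absent genes carry zero cumulative mass, and any shift needed for
#' negative measured values is applied to measured cells only.
#'
#' @param m An [expression_matrix()] of log2 expression values.
#' @return An [expression_matrix()] in YuGene units.
#' @export
yugene_matrix <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  vals <- m$values
  ids <- rownames(vals)
  out <- vals
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    pres <- m$presence[, j]
    if (any(pres) && min(x[pres]) < 0)
      x[pres] <- x[pres] - min(x[pres])
    names(x) <- ids
    out[, j] <- yugene_transform(x)
  }
  expression_matrix(out, m$presence)
}
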