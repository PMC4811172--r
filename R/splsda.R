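#' Indicator (dummy) response matrix for two-class discriminant analysis
#'
#' Encodes class labels as an n x 2 indicator matrix with fixed column
#' order `(MSC, nonMSC)`, the response used by [fit_splsda()].
#'
#' @param labels Character vector (or factor) with values in
#'   `{"MSC", "nonMSC"}`.
#' @return Numeric n x 2 matrix of 0/1 indicators; each row sums to 1.
#'   Warns if only a single class is present.
#' @export
make_dummy <- function(labels) {
  labels <- as.character(labels)
  if (!length(labels)) stop("empty labels")
  bad <- setdiff(unique(labels), c("MSC", "nonMSC"))
  if (length(bad))
    stop("unknown class label(s): ", paste(sQuote(bad), collapse = ", "))
  if (length(unique(labels)) == 1) warning("single class")
  cbind(MSC = as.numeric(labels == "MSC"),
        nonMSC = as.numeric(labels == "nonMSC"))
}

#' Sparse selection of a loading vector by soft thresholding
#'
#' The lasso-style sparsity operator of sPLS-DA: shrinks a candidate
#' loading vector `v` towards zero by \eqn{\lambda} = the
#' `(keepX + 1)`-th largest absolute entry (\eqn{\lambda = 0} when
#' `keepX = length(v)`), i.e. returns
#' \eqn{\mathrm{sign}(v_j)(|v_j| - \lambda)_+} renormalized to unit
#' Euclidean norm. With distinct magnitudes exactly `keepX` entries stay
#' nonzero. When ties make the shrinkage degenerate (all entries would
#' vanish), the top `keepX` entries by (magnitude, then index) are kept
#' unshrunk and renormalized instead.
#'
#' @param v Finite numeric vector.
#' @param keepX Number of entries allowed to stay nonzero, in
#'   `[1, length(v)]`.
#' @return Unit-norm numeric vector with at most `keepX` nonzeros.
#' @export
soft_threshold_select <- function(v, keepX) {
  p <- length(v)
  if (!is.numeric(v) || any(!is.finite(v))) stop("'v' must be finite numeric")
  keepX <- as.integer(keepX)
  if (length(keepX) != 1 || is.na(keepX) || keepX < 1 || keepX > p)
    stop("'keepX' must be a single integer in [1, ", p, "]")
  a <- abs(v)
  lambda <- if (keepX == p) 0 else sort(a, decreasing = TRUE)[keepX + 1]
  w <- sign(v) * pmax(a - lambda, 0)
  if (all(w == 0)) {
    # tied magnitudes at the cutoff: deterministic top-keepX fallback
    keep <- order(-a, seq_len(p))[seq_len(keepX)]
    w[keep] <- v[keep]
  }
  w / sqrt(sum(w^2))
}

# dominant left singular vector of the p x 2 cross-covariance, by power
# iteration on the 2 x 2 Gram matrix with a fixed all-ones start so the
# result is deterministic
dominant_left_sv <- function(M, tol = 1e-12, max_iter = 1000L) {
  A <- crossprod(M)
  v <- rep(1, ncol(M))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(max_iter)) {
    v2 <- drop(A %*% v)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) stop("no class signal")
    v2 <- v2 / nv
    done <- sum((v2 - v)^2) < tol^2
    v <- v2
    if (done) break
  }
  u <- drop(M %*% v)
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("no class signal")
  u / nu
}

#' Fit a sparse PLS discriminant analysis model
#'
#' Columns of `X` are centered and scaled to unit variance once, before the
#' first component (zero-variance genes get scale 1 and are barred from the
#' loadings); the indicator response is centered. For each component
#' \eqn{h}: the cross-covariance \eqn{M_h = X_h^\top Y_h} is formed on the
#' current deflated matrices, its dominant left singular vector is
#' sparsified with [soft_threshold_select()] at `keepX[h]`, the score is
#' \eqn{t_h = X_h u_h}, and both matrices are deflated by regression on
#' \eqn{t_h}. Per-component regression coefficients of the response on the
#' score are stored for prediction. Loading signs are oriented so the MSC
#' class mean score is positive on every component (component orientation
#' is otherwise arbitrary).
#'
#' @param X Numeric samples x genes matrix (n >= 3), gene names as column
#'   names.
#' @param Y An indicator matrix from [make_dummy()], or the labels
#'   themselves; both classes must be present.
#' @param H Number of components (default 4).
#' @param keepX Integer vector (recycled to length `H`) of per-component
#'   sparsity levels; `NULL` means no sparsity (`keepX = ncol(X)`).
#' @return An object of class `FittedSPLSDA` with elements `components`
#'   (each holding `loading`, `score`, `x_proj`, `response_coefs`,
#'   `keepX`), `center`, `scale`, `y_means`, `genes`, `class_order`.
#' @export
fit_splsda <- function(X, Y, H = 4L, keepX = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3) stop("at least 3 samples are required")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  if (!is.matrix(Y)) Y <- make_dummy(Y)
  if (nrow(Y) != n) stop("'Y' must have one row per sample")
  if (any(colSums(Y) == 0)) stop("both classes must be present")
  H <- as.integer(H)
  if (H < 1) stop("'H' must be >= 1")
  if (is.null(keepX)) keepX <- p
  keepX <- rep_len(as.integer(keepX), H)
  if (any(keepX < 1 | keepX > p))
    stop("'keepX' must be in [1, ", p, "]")

  center <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  zerovar <- sds < 1e-12
  scl <- ifelse(zerovar, 1, sds)
  Xh <- sweep(sweep(X, 2, center), 2, scl, "/")
  y_means <- colMeans(Y)
  Yh <- sweep(Y, 2, y_means)
  msc <- Y[, 1] == 1

  comps <- vector("list", H)
  for (h in seq_len(H)) {
    M <- crossprod(Xh, Yh)
    if (max(abs(M)) < 1e-12) stop("no class signal on component ", h)
    u <- dominant_left_sv(M)
    if (any(zerovar)) {
      u[zerovar] <- 0
      nu <- sqrt(sum(u^2))
      if (nu == 0) stop("no class signal on component ", h)
      u <- u / nu
    }
    u <- soft_threshold_select(u, keepX[h])
    t_h <- drop(Xh %*% u)
    ss <- sum(t_h^2)
    if (ss < 1e-24) stop("degenerate score on component ", h)
    if (mean(t_h[msc]) < mean(t_h[!msc])) {
      u <- -u
      t_h <- -t_h
    }
    p_h <- drop(crossprod(Xh, t_h)) / ss
    c_h <- drop(crossprod(Yh, t_h)) / ss
    names(c_h) <- colnames(Y)
    Xh <- Xh - tcrossprod(t_h, p_h)
    Yh <- Yh - tcrossprod(t_h, c_h)
    names(u) <- names(p_h) <- colnames(X)
    comps[[h]] <- list(loading = u, score = t_h, x_proj = p_h,
                       response_coefs = c_h, keepX = keepX[h])
  }
  structure(list(components = comps, center = center, scale = scl,
                 y_means = y_means, genes = colnames(X),
                 class_order = colnames(Y), n = n),
            class = "FittedSPLSDA")
}

#' @export
print.FittedSPLSDA <- function(x, ...) {
  cat("sPLS-DA fit: ", length(x$genes), " genes, ", x$n, " samples, ",
      length(x$components), " component(s); keepX = ",
      paste(vapply(x$components, `[[`, integer(1), "keepX"),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# zero-fill columns of x_new so they align with the model gene order;
# errors when more than half the model genes are absent
align_genes <- function(x_new, genes) {
  if (is.null(dim(x_new)))
    x_new <- matrix(x_new, nrow = 1, dimnames = list(NULL, names(x_new)))
  if (is.null(colnames(x_new))) {
    if (ncol(x_new) != length(genes))
      stop("unnamed input must have exactly ", length(genes), " gene columns")
    colnames(x_new) <- genes
  }
  miss <- setdiff(genes, colnames(x_new))
  if (2 * length(miss) > length(genes))
    stop("insufficient gene coverage: ", length(miss), " of ",
         length(genes), " model genes missing")
  out <- matrix(0, nrow(x_new), length(genes),
                dimnames = list(rownames(x_new), genes))
  common <- intersect(genes, colnames(x_new))
  out[, common] <- x_new[, common, drop = FALSE]
  if (length(miss))
    warning(length(miss), " model gene(s) missing from input: ",
            paste(utils::head(miss, 5), collapse = ", "))
  attr(out, "missing_genes") <- miss
  out
}

#' Predict the MSC score of new samples
#'
#' Applies the stored centering and scaling, projects the new data through
#' the model's deflation sequence, and returns the predicted MSC-indicator
#' value (class-mean offset plus the sum of score-times-coefficient
#' contributions over the components), clipped to `[0, 1]`. High scores are
#' MSC-like. Genes absent from `x_new` are flagged with a warning and
#' imputed at the stored training center, so after centering they
#' contribute exactly zero to every component score (an unmeasured gene
#' carries no evidence either way); an error is raised when more than half
#' the model genes are missing.
#'
#' @param model A [fit_splsda()] fit.
#' @param x_new Numeric samples x genes matrix (or a single named vector),
#'   in the same units as the training data.
#' @param n_components Number of leading components to use (default: all).
#' @return Numeric vector of scores in `[0, 1]`, one per row of `x_new`.
#' @export
predict_score <- function(model, x_new, n_components = NULL) {
  stopifnot(inherits(model, "FittedSPLSDA"))
  H <- length(model$components)
  nc <- as.integer(n_components %||% H)
  if (nc < 1 || nc > H) stop("'n_components' must be in [1, ", H, "]")
  A <- align_genes(x_new, model$genes)
  miss <- attr(A, "missing_genes")
  if (length(miss))
    A[, miss] <- rep(model$center[miss], each = nrow(A))
  Xs <- sweep(sweep(A, 2, model$center), 2, model$scale, "/")
  pred <- rep(model$y_means[["MSC"]], nrow(A))
  for (h in seq_len(nc)) {
    cm <- model$components[[h]]
    t_h <- drop(Xs %*% cm$loading)
    pred <- pred + t_h * cm$response_coefs[["MSC"]]
    Xs <- Xs - tcrossprod(t_h, cm$x_proj)
  }
  pmin(pmax(unname(pred), 0), 1)
}

# stratified folds; redraws until every fold holds both classes
stratified_folds <- function(labels, k, max_redraw = 20L) {
  for (r in seq_len(max_redraw)) {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(labels[fold == f])) == 2, logical(1)))
    if (ok) return(fold)
  }
  stop("could not draw stratified folds with both classes in every fold")
}

#' Choose per-component sparsity by cross-validation
#'
#' Sequentially per component, selects the `grid` value minimizing the
#' k-fold cross-validated balanced classification error (mean of the two
#' class-wise error rates, MSC called when the predicted indicator is
#' >= 0.5); earlier components keep their chosen values while later ones
#' are tuned. Ties favour the smallest `keepX`.
#'
#' @param X Samples x genes matrix.
#' @param labels Class labels (`MSC` / `nonMSC`).
#' @param grid Candidate `keepX` values.
#' @param folds Number of stratified folds (>= 2).
#' @param H Number of components to tune.
#' @param seed Seed for the fold assignment.
#' @return Integer vector of length `H`.
#' @export
tune_keepX <- function(X, labels, grid, folds = 5L, H = 1L, seed = 1L) {
  grid <- sort(unique(as.integer(grid)))
  if (!length(grid)) stop("'grid' must be non-empty")
  folds <- as.integer(folds)
  if (folds < 2) stop("'folds' must be >= 2")
  labels <- as.character(labels)
  fold <- withr::with_seed(seed, stratified_folds(labels, folds))
  chosen <- integer(0)
  for (h in seq_len(H)) {
    cv_err <- vapply(grid, function(g) {
      if (g > ncol(X)) return(NA_real_)
      errs <- vapply(seq_len(folds), function(f) {
        tr <- fold != f
        fit <- tryCatch(
          fit_splsda(X[tr, , drop = FALSE], make_dummy(labels[tr]),
                     H = h, keepX = c(chosen, g)),
          error = function(e) NULL)
        if (is.null(fit)) return(0.5)
        balanced_error(predict_score(fit, X[!tr, , drop = FALSE]),
                       labels[!tr])
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    if (all(is.na(cv_err))) stop("no grid value fits the data")
    chosen <- c(chosen, grid[which.min(cv_err)])
  }
  chosen
}
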