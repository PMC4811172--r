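# JSON serialization of a fitted ensemble: metadata plus dense arrays for
# centers, scales, loadings and coefficients. Written at full double
# precision so a round trip is bit-exact.

ENSEMBLE_FORMAT_VERSION <- 1L

serialize_splsda <- function(fit) {
  list(genes = fit$genes,
       center = unname(fit$center),
       scale = unname(fit$scale),
       y_means = unname(fit$y_means),
       class_order = fit$class_order,
       n = fit$n,
       components = lapply(fit$components, function(cm)
         list(loading = unname(cm$loading),
              x_proj = unname(cm$x_proj),
              response_coefs = unname(cm$response_coefs),
              keepX = cm$keepX)))
}

deserialize_splsda <- function(obj) {
  genes <- as.character(obj$genes)
  cls <- as.character(obj$class_order)
  comps <- lapply(obj$components, function(cm) {
    loading <- as.numeric(cm$loading)
    x_proj <- as.numeric(cm$x_proj)
    rc <- as.numeric(cm$response_coefs)
    names(loading) <- names(x_proj) <- genes
    names(rc) <- cls
    list(loading = loading, score = NULL, x_proj = x_proj,
         response_coefs = rc, keepX = as.integer(cm$keepX))
  })
  center <- as.numeric(obj$center)
  scl <- as.numeric(obj$scale)
  ym <- as.numeric(obj$y_means)
  names(center) <- names(scl) <- genes
  names(ym) <- cls
  structure(list(components = comps, center = center, scale = scl,
                 y_means = ym, genes = genes, class_order = cls,
                 n = as.integer(obj$n)),
            class = "FittedSPLSDA")
}

#' Serialize an ensemble classifier to JSON
#'
#' Stores format version, thresholds, signature, the training gene
#' universe and all submodels (centering, scaling, loadings, projection
#' vectors and response coefficients) at full double precision; training
#' score vectors are not stored since prediction does not need them.
#' [read_ensemble()] refuses files with a different format version.
#'
#' @param clf An `msc_ensemble`.
#' @param path Output path.
#' @return `read_ensemble()` returns the restored `msc_ensemble`.
#' @export
write_ensemble <- function(clf, path) {
  stopifnot(inherits(clf, "msc_ensemble"))
  obj <- list(
    format_version = ENSEMBLE_FORMAT_VERSION,
    package = "msclassify",
    M = clf$M,
    fraction = clf$fraction,
    seed = clf$seed,
    coverage = clf$coverage,
    ci_level = clf$ci_level,
    thresholds = clf$thresholds,
    signature = as.list(as.data.frame(clf$signature)[
      c("gene", "component", "frequency", "correlation", "sign")]),
    gene_universe = clf$gene_universe,
    submodels = lapply(clf$submodels, serialize_splsda))
  # digits = I(17): doubles must survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(as.integer(obj$format_version), ENSEMBLE_FORMAT_VERSION))
    stop("unsupported ensemble file version: ", obj$format_version)
  sig <- data.frame(gene = as.character(obj$signature$gene),
                    component = as.integer(obj$signature$component),
                    frequency = as.numeric(obj$signature$frequency),
                    correlation = as.numeric(obj$signature$correlation),
                    sign = as.numeric(obj$signature$sign),
                    stringsAsFactors = FALSE)
  class(sig) <- c("msc_signature", "data.frame")
  clf <- structure(
    list(submodels = lapply(obj$submodels, deserialize_splsda),
         signature = sig,
         thresholds = list(t_low = as.numeric(obj$thresholds$t_low),
                           t_high = as.numeric(obj$thresholds$t_high),
                           empty_overlap =
                             isTRUE(obj$thresholds$empty_overlap)),
         coverage = as.numeric(obj$coverage),
         ci_level = as.numeric(obj$ci_level),
         M = as.integer(obj$M),
         fraction = as.numeric(obj$fraction),
         seed = as.integer(obj$seed),
         genes = sig$gene,
         gene_universe = if (is.null(obj$gene_universe)) NULL
                         else as.character(obj$gene_universe)),
    class = "msc_ensemble")
  clf
}
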