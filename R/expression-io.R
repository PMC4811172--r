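#' Expression matrix with a presence mask
#'
#' Container for a genes-by-samples matrix of non-negative expression values
#' (log2 intensity or YuGene units) together with a logical presence mask of
#' the same shape. A `FALSE` entry in the mask records that the gene was not
#' measured on that sample's platform and that the stored value is a
#' zero-fill, not a measurement. Zero-filled cells are always exactly 0.
#'
#' @param values Numeric matrix with unique gene IDs as row names and unique
#'   sample IDs as column names. All values must be finite.
#' @param presence Logical matrix of the same dimensions, or `NULL` for
#'   all-`TRUE` (every value measured).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `presence`.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
#' dim(m$values)
#' @export
expression_matrix <- function(values, presence = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("'values' must have gene row names and sample column names")
  if (is.null(dimnames(values)))
    dimnames(values) <- list(character(0), character(0))
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicated gene ID: '", dup[1], "'")
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop("duplicated sample ID: '", dup[1], "'")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (is.null(presence)) {
    presence <- matrix(TRUE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  } else {
    if (!is.matrix(presence) || !is.logical(presence) ||
        !identical(dim(presence), dim(values)))
      stop("'presence' must be a logical matrix of the same shape as 'values'")
    dimnames(presence) <- dimnames(values)
    if (any(values[!presence] != 0))
      stop("zero-filled (absent) cells must have value exactly 0")
  }
  structure(list(values = values, presence = presence),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", sum(!x$presence), " zero-filled cells)\n", sep = "")
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' Expects one header row of sample IDs, one leading column of gene (or
#' probe) IDs, and numeric cells. Rejects duplicated IDs, ragged rows and
#' non-numeric cells with an error naming the offender. The returned
#' presence mask is all-`TRUE`; zero-fills are introduced later by
#' [merge_datasets()].
#'
#' @param path Path to a TSV file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("no data rows in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2) stop("header of '", path, "' has no sample columns")
  sample_ids <- header[-1]
  body <- fields[-1]
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  bad <- which(lengths(body) != length(header))
  if (length(bad))
    stop("malformed row for gene '", gene_ids[bad[1]], "' (line ",
         bad[1] + 1L, "): expected ", length(header), " fields, found ",
         lengths(body)[bad[1]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicated gene ID: '", dup[1], "'")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicated sample ID: '", dup[1], "'")
  cells <- vapply(body, function(f) f[-1], character(length(sample_ids)))
  cells <- matrix(cells, nrow = length(sample_ids))  # samples x genes
  values <- suppressWarnings(array(as.numeric(cells), dim(cells)))
  if (anyNA(values)) {
    ij <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("non-numeric value '", cells[ij[1], ij[2]], "' for gene '",
         gene_ids[ij[2]], "', sample '", sample_ids[ij[1]], "'")
  }
  expression_matrix(matrix(t(values), nrow = length(gene_ids),
                           dimnames = list(gene_ids, sample_ids)))
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; the presence mask is not serialized
#' (zero-filled cells are written as 0).
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(m$values)), collapse = "\t"), con)
  body <- apply(m$values, 1, function(v)
    paste(format(v, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = "\t"))
  writeLines(paste(rownames(m$values), body, sep = "\t"), con)
  invisible(path)
}

#' Read or validate a sample annotation table
#'
#' The table must have columns `sample_id`, `dataset_id`, `platform` and
#' `class_label`; class labels are restricted to `MSC`, `nonMSC` and
#' `unknown`; sample IDs must be unique and each dataset must map to a
#' single platform.
#'
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame` with the four columns above.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param df A data frame to validate in place of reading a file.
#' @export
validate_sample_table <- function(df) {
  need <- c("sample_id", "dataset_id", "platform", "class_label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  bad <- setdiff(unique(df$class_label), c("MSC", "nonMSC", "unknown"))
  if (length(bad))
    stop("unknown class label(s): ", paste(sQuote(bad), collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicated sample ID: '", dup[1], "'")
  plat <- unique(df[c("dataset_id", "platform")])
  dup <- plat$dataset_id[duplicated(plat$dataset_id)]
  if (length(dup))
    stop("dataset '", dup[1], "' is annotated with more than one platform")
  rownames(df) <- NULL
  df
}

#' Read a probe-to-gene mapping table
#'
#' Two tab-separated columns `probe_id` and `gene_id`; many probes may map
#' to one gene but each probe appears at most once.
#'
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame` with columns `probe_id` and `gene_id`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  validate_probe_map(df)
}

validate_probe_map <- function(map) {
  need <- c("probe_id", "gene_id")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("probe map lacks column(s): ", paste(miss, collapse = ", "))
  map <- as.data.frame(map)[need]
  dup <- map$probe_id[duplicated(map$probe_id)]
  if (length(dup)) stop("duplicated probe ID: '", dup[1], "'")
  map
}

#' Collapse probe-level rows to gene level
#'
#' For every gene with several mapped probes, the probe with the highest
#' mean expression across the dataset's samples is retained; ties are
#' broken by the lexicographically first probe ID so the collapse is
#' deterministic. Unmapped probes are dropped. Intended for a matrix
#' holding the samples of a single dataset, since the choice of probe is
#' made per dataset.
#'
#' @param probe_matrix An [expression_matrix()] with probe IDs as rows.
#' @param map Probe-to-gene mapping (`probe_id`, `gene_id` columns).
#' @return A gene-level [expression_matrix()] with genes sorted
#'   lexicographically.
#' @export
collapse_probes <- function(probe_matrix, map) {
  stopifnot(inherits(probe_matrix, "ExpressionMatrix"))
  map <- validate_probe_map(map)
  common <- intersect(rownames(probe_matrix$values), map$probe_id)
  if (!length(common))
    stop("no probe in the mapping table is present in the matrix")
  map <- map[map$probe_id %in% common, , drop = FALSE]
  means <- rowMeans(probe_matrix$values)[map$probe_id]
  ord <- radix_order(map$gene_id, -means, map$probe_id)
  map <- map[ord, , drop = FALSE]
  chosen <- map[!duplicated(map$gene_id), , drop = FALSE]
  values <- probe_matrix$values[chosen$probe_id, , drop = FALSE]
  presence <- probe_matrix$presence[chosen$probe_id, , drop = FALSE]
  rownames(values) <- rownames(presence) <- chosen$gene_id
  expression_matrix(values, presence)
}

#' Merge gene-level matrices from several datasets
#'
#' The merged gene set is the union across datasets. Where a dataset has no
#' probe for a gene, its samples receive the value 0 with `presence =
#' FALSE`. Genes are sorted lexicographically; columns follow the sample
#' table order.
#'
#' @param matrices List of gene-level [expression_matrix()] objects with
#'   disjoint sample IDs.
#' @param samples Sample table covering exactly the samples of `matrices`.
#' @return A merged [expression_matrix()].
#' @export
merge_datasets <- function(matrices, samples) {
  samples <- validate_sample_table(samples)
  if (!length(matrices) || !all(vapply(matrices, inherits, logical(1),
                                       "ExpressionMatrix")))
    stop("'matrices' must be a non-empty list of ExpressionMatrix objects")
  all_samples <- unlist(lapply(matrices, function(m) colnames(m$values)))
  dup <- all_samples[duplicated(all_samples)]
  if (length(dup))
    stop("sample ID '", dup[1], "' appears in more than one matrix")
  miss <- setdiff(samples$sample_id, all_samples)
  if (length(miss))
    stop("sample(s) present in the sample table but in no matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  extra <- setdiff(all_samples, samples$sample_id)
  if (length(extra))
    stop("sample(s) present in a matrix but not in the sample table: ",
         paste(utils::head(extra, 5), collapse = ", "))
  genes <- radix_sort(unique(unlist(lapply(matrices,
                                           function(m) rownames(m$values)))))
  values <- matrix(0, length(genes), nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  presence <- matrix(FALSE, length(genes), nrow(samples),
                     dimnames = dimnames(values))
  for (m in matrices) {
    g <- rownames(m$values)
    s <- colnames(m$values)
    values[g, s] <- m$values
    presence[g, s] <- m$presence
  }
  expression_matrix(values, presence)
}

#' Pre-screen genes by platform coverage
#'
#' Retains genes measured (presence mask `TRUE`) in at least half of the
#' samples, i.e. in `>= ceiling(n / 2)` of `n` samples; with odd `n` the
#' majority convention rounds up. "Present" means measured on that
#' sample's platform, not above any expression threshold, because
#' zero-filling is the only absence mechanism in the merge step.
#'
#' @param m A merged [expression_matrix()].
#' @return The matrix restricted to retained genes, order preserved. Warns
#'   if no gene survives.
#' @export
prescreen_genes <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  n <- ncol(m$values)
  keep <- rowSums(m$presence) >= ceiling(n / 2)
  if (!any(keep)) warning("no genes pass the presence pre-screen")
  expression_matrix(m$values[keep, , drop = FALSE],
                    m$presence[keep, , drop = FALSE])
}
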