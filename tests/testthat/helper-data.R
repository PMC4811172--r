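# small in-code fixtures shared across test files

tiny_matrix <- function(values, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_samples <- function(ids, dataset, class) {
  data.frame(sample_id = ids, dataset_id = dataset,
             platform = paste0("pf_", dataset), class_label = class,
             stringsAsFactors = FALSE)
}

# two-dataset, two-class design with k informative genes at a given
# effect; returns a samples x genes matrix plus sample table, bypassing
# the full generator for tests that need direct control
toy_design <- function(p = 40, k = 3, n_per = 8, effect = 3, seed = 1,
                       n_datasets = 2) {
  withr::with_seed(seed, {
    n <- n_per * 2 * n_datasets
    labels <- rep(rep(c("MSC", "nonMSC"), each = n_per), n_datasets)
    dataset <- rep(sprintf("d%d", seq_len(n_datasets)), each = 2 * n_per)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%03d", seq_len(n)),
                                sprintf("g%03d", seq_len(p))))
    X[labels == "MSC", seq_len(k)] <- X[labels == "MSC", seq_len(k)] + effect
    list(X = X,
         samples = tiny_samples(rownames(X), dataset, labels),
         informative = colnames(X)[seq_len(k)])
  })
}
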