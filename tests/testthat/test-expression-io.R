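test_that("expression TSV round-trips and preserves order", {
  m <- tiny_matrix(matrix(c(1.5, 2, 3, 4.25, 5, 6), 3, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  m2 <- read_expression(path)
  expect_identical(dim(m2$values), c(3L, 2L))
  expect_equal(m2$values, m$values)
  expect_true(all(m2$presence))
})

test_that("malformed expression files fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), path)
  expect_error(read_expression(path), "duplicated gene ID: 'g1'")
  writeLines(c("gene_id\ts1\ts1", "g1\t1\t2"), path)
  expect_error(read_expression(path), "duplicated sample ID: 's1'")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\tfoo"), path)
  expect_error(read_expression(path), "non-numeric value 'foo'.*g1.*s2")
  writeLines(c("gene_id\ts1\ts2", "g1\t1"), path)
  expect_error(read_expression(path), "malformed row for gene 'g1'")
  writeLines("gene_id\ts1", path)
  expect_error(read_expression(path), "no data rows")
})

test_that("expression_matrix enforces its invariants", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(expression_matrix(matrix(1:4, 2, 2)), "row names")
  bad <- v; bad[1, 1] <- Inf
  expect_error(expression_matrix(bad), "finite")
  pres <- matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2)
  expect_error(expression_matrix(v + 0, pres), "exactly 0")
  v2 <- v; v2[1, 1] <- 0
  m <- expression_matrix(v2 + 0, pres)
  expect_false(m$presence[1, 1])
})

test_that("sample tables are validated", {
  s <- tiny_samples(c("a", "b"), "d1", c("MSC", "nonMSC"))
  expect_silent(validate_sample_table(s))
  s2 <- s; s2$class_label[1] <- "stem"
  expect_error(validate_sample_table(s2), "unknown class label")
  s3 <- s; s3$sample_id[2] <- "a"
  expect_error(validate_sample_table(s3), "duplicated sample ID")
  s4 <- rbind(s, tiny_samples("c", "d1", "MSC"))
  s4$platform[3] <- "other"
  expect_error(validate_sample_table(s4), "more than one platform")
})

test_that("collapse_probes keeps the highest-mean probe per gene", {
  m <- tiny_matrix(matrix(c(4, 6, 1, 6, 8, 1), 3, 2),
                   genes = c("p1", "p2", "p3"))
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_id = c("G", "G", "H"))
  out <- collapse_probes(m, map)
  # p2 has mean 7 vs p1's 5
  expect_equal(out$values["G", ], m$values["p2", ])
  expect_equal(rownames(out$values), c("G", "H"))
})

test_that("collapse_probes breaks mean ties by the first probe ID", {
  # brute-force oracle: both probes tie at mean 5; documented tie-break is
  # the lexicographically smallest probe ID
  m <- tiny_matrix(matrix(c(4, 6, 6, 4), 2, 2), genes = c("pB", "pA"))
  map <- data.frame(probe_id = c("pA", "pB"), gene_id = c("G", "G"))
  out <- collapse_probes(m, map)
  expect_equal(unname(out$values["G", ]), unname(m$values["pA", ]))
})

test_that("collapse_probes retains a maximal-mean row for every gene", {
  withr::with_seed(5, {
    m <- tiny_matrix(matrix(runif(60, 1, 10), 20, 3),
                     genes = sprintf("p%02d", 1:20))
    map <- data.frame(probe_id = sprintf("p%02d", 1:20),
                      gene_id = sprintf("G%d", rep(1:5, each = 4)))
    out <- collapse_probes(m, map)
    means <- rowMeans(m$values)
    for (g in rownames(out$values)) {
      competitors <- map$probe_id[map$gene_id == g]
      expect_gte(mean(out$values[g, ]), max(means[competitors]) - 1e-12)
    }
  })
})

test_that("collapse_probes rejects maps with no matching probe", {
  m <- tiny_matrix(matrix(1:4, 2, 2), genes = c("p1", "p2"))
  map <- data.frame(probe_id = "px", gene_id = "G")
  expect_error(collapse_probes(m, map), "no probe")
})

test_that("merge_datasets zero-fills platform-absent genes", {
  a <- tiny_matrix(matrix(c(1, 2, 3, 4), 2, 2), genes = c("g1", "g2"),
                   samples = c("a1", "a2"))
  b <- tiny_matrix(matrix(c(5, 6, 7, 8), 2, 2), genes = c("g2", "g3"),
                   samples = c("b1", "b2"))
  samp <- tiny_samples(c("a1", "a2", "b1", "b2"),
                       rep(c("dA", "dB"), each = 2),
                       c("MSC", "MSC", "nonMSC", "nonMSC"))
  merged <- merge_datasets(list(a, b), samp)
  expect_identical(rownames(merged$values), c("g1", "g2", "g3"))
  expect_identical(colnames(merged$values), samp$sample_id)
  expect_equal(unname(merged$values["g3", c("a1", "a2")]), c(0, 0))
  expect_false(any(merged$presence["g3", c("a1", "a2")]))
  expect_true(all(merged$presence["g2", ]))

  # identical gene sets: no zero-filling anywhere
  b2 <- tiny_matrix(matrix(c(5, 6, 7, 8), 2, 2), genes = c("g1", "g2"),
                    samples = c("b1", "b2"))
  m2 <- merge_datasets(list(a, b2), samp)
  expect_true(all(m2$presence))

  # single dataset in, identity out
  m3 <- merge_datasets(list(a), samp[1:2, ])
  expect_equal(m3$values, a$values)
  expect_true(all(m3$presence))
})

test_that("merge_datasets rejects unmatched samples", {
  a <- tiny_matrix(matrix(1:4, 2, 2), samples = c("a1", "a2"))
  samp <- tiny_samples(c("a1", "a2", "ghost"), "dA",
                       c("MSC", "MSC", "nonMSC"))
  expect_error(merge_datasets(list(a), samp), "in no matrix")
  expect_error(merge_datasets(list(a), samp[1, , drop = FALSE]),
               "not in the sample table")
})

test_that("prescreen_genes keeps genes measured in at least half the samples", {
  v <- matrix(1, 3, 6, dimnames = list(c("g1", "g2", "g3"),
                                       sprintf("s%d", 1:6)))
  pres <- rbind(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),   # 3 of 6: keep
                c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),  # 2 of 6: drop
                rep(TRUE, 6))
  v[!pres] <- 0
  m <- prescreen_genes(expression_matrix(v, pres))
  expect_identical(rownames(m$values), c("g1", "g3"))
})

test_that("prescreen threshold uses the ceiling for odd sample counts", {
  # brute-force check of the ceiling(n/2) convention at n = 5
  n <- 5
  for (k in 0:n) {
    pres <- matrix(c(rep(TRUE, k), rep(FALSE, n - k)), 1, n,
                   dimnames = list("g1", sprintf("s%d", 1:n)))
    v <- matrix(as.numeric(pres), 1, n, dimnames = dimnames(pres))
    kept <- nrow(suppressWarnings(
      prescreen_genes(expression_matrix(v, pres)))$values)
    expect_identical(kept == 1L, k >= ceiling(n / 2))
  }
})

test_that("merge then prescreen is idempotent and keeps zero-fills absent", {
  withr::with_seed(11, {
    a <- tiny_matrix(matrix(runif(12, 1, 5), 4, 3),
                     genes = c("g1", "g2", "g3", "g4"),
                     samples = c("a1", "a2", "a3"))
    b <- tiny_matrix(matrix(runif(6, 1, 5), 2, 3),
                     genes = c("g1", "g2"), samples = c("b1", "b2", "b3"))
    samp <- tiny_samples(c(colnames(a$values), colnames(b$values)),
                         rep(c("dA", "dB"), each = 3),
                         rep(c("MSC", "nonMSC"), each = 3))
    once <- prescreen_genes(merge_datasets(list(a, b), samp))
    twice <- prescreen_genes(once)
    expect_identical(once, twice)
    # zero-filled cells stay absent through yugene too
    yg <- yugene_matrix(once)
    expect_identical(yg$presence, once$presence)
    expect_true(all(yg$values[!yg$presence] == 0))
  })
})
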