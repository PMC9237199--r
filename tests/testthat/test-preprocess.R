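# build the 6-cell hand-computed fixture: totals (1e3 x5, 1e9), detected
# gene counts (600,600,600,600,499,600). log10 totals are (3,3,3,3,3,9):
# mean 4, sd sqrt(6) ~ 2.449, band [4 - 2*2.449, 4 + 2*2.449] = [-0.899, 8.899]
# -> cell 6 (1e9) is an outlier; cell 5 fails the 500-gene floor.
six_cell_fixture <- function() {
  n_genes <- 700
  mk_cell <- function(detected, total) {
    x <- integer(n_genes)
    x[seq_len(detected - 1L)] <- 1L
    x[detected] <- as.integer(total - (detected - 1L))
    x
  }
  counts <- cbind(mk_cell(600, 1e3), mk_cell(600, 1e3), mk_cell(600, 1e3),
                  mk_cell(600, 1e3), mk_cell(499, 1e3), mk_cell(600, 1e9))
  count_matrix(counts, sprintf("g%03d", seq_len(n_genes)),
               sprintf("c%d", 1:6))
}

test_that("hand-computed 6-cell fixture: cell 5 fails gene floor, cell 6 is a UMI outlier", {
  res <- filter_cells(six_cell_fixture())
  expect_equal(res$matrix$cell_ids, c("c1", "c2", "c3", "c4"))
  expect_equal(res$report$removed_ids$low_gene_cell, "c5")
  expect_equal(res$report$removed_ids$umi_outlier_cell, "c6")
  expect_equal(unname(res$report$removals),
               c(1L, 1L), ignore_attr = TRUE)
  expect_equal(res$report$cells_in - sum(res$report$removals),
               res$report$cells_out)
})

test_that("boundary cases: exactly 500 detected genes kept; identical cells never removed", {
  n_genes <- 600
  mk <- function(detected) { x <- integer(n_genes); x[seq_len(detected)] <- 2L; x }
  m <- count_matrix(cbind(mk(500), mk(500), mk(499)),
                    sprintf("g%03d", 1:n_genes), c("a", "b", "c"))
  res <- filter_cells(m)
  expect_equal(res$matrix$cell_ids, c("a", "b"))   # 500 inclusive, 499 out
  ident <- count_matrix(matrix(2L, 600, 5), sprintf("g%03d", 1:600),
                        sprintf("c%d", 1:5))
  expect_equal(filter_cells(ident)$matrix$cell_ids, ident$cell_ids)
  tiny <- count_matrix(matrix(1L, 3, 2), c("g1", "g2", "g3"), c("a", "b"))
  expect_error(filter_cells(tiny), "empty result")
})

test_that("gene prevalence boundary is inclusive and mito genes always go", {
  # 12 cells; gene in 9 cells removed, in 10 kept; flagged mito removed even
  # when prevalent
  counts <- rbind(c(rep(1L, 9), rep(0L, 3)),
                  c(rep(1L, 10), rep(0L, 2)),
                  rep(1L, 12),
                  rep(5L, 12))
  m <- count_matrix(counts, c("g9", "g10", "gAll", "mt-01"),
                    sprintf("c%02d", 1:12))
  ga <- data.frame(gene_id = m$gene_ids,
                   is_mitochondrial = m$gene_ids == "mt-01",
                   is_housekeeping = FALSE, is_tf = FALSE,
                   is_ligand = FALSE, is_receptor = FALSE)
  res <- filter_genes(m, ga)
  expect_equal(res$matrix$gene_ids, c("g10", "gAll"))
  expect_equal(res$report$removed_ids$mito_gene, "mt-01")
  expect_equal(res$report$removed_ids$low_cell_gene, "g9")
  # prefix fallback without an annotation
  res2 <- filter_genes(m, NULL)
  expect_equal(res2$matrix$gene_ids, c("g10", "gAll"))
})

test_that("surviving sets equal a brute-force two-pass filter on random fixtures", {
  for (seed in c(31, 32)) {
    set.seed(seed)
    counts <- matrix(rnbinom(300 * 60, mu = 2, size = 0.5), 300, 60)
    counts[, 1] <- c(rep(60L, 299), 1e7L)   # force a UMI outlier
    m <- count_matrix(counts, sprintf("g%03d", 1:300), sprintf("c%02d", 1:60))
    is_mito <- seq_len(300) <= 5
    ga <- data.frame(gene_id = m$gene_ids, is_mitochondrial = is_mito,
                     is_housekeeping = FALSE, is_tf = FALSE,
                     is_ligand = FALSE, is_receptor = FALSE)
    oracle <- naive_two_pass_filter(counts, is_mito, min_genes = 50,
                                    umi_sd = 2, min_cells = 10)
    fc <- filter_cells(m, min_genes = 50)
    fg <- filter_genes(fc$matrix, ga, min_cells = 10)
    expect_identical(fc$matrix$cell_ids, m$cell_ids[oracle$cells])
    expect_identical(fg$matrix$gene_ids, m$gene_ids[oracle$genes])
  }
})

test_that("filter order (cells then genes) is part of the contract", {
  # gene detected in exactly 10 cells, one of which the cell filter removes:
  # prevalence counted after cell filtering -> gene out
  n_genes <- 600
  base <- matrix(0L, n_genes, 12)
  base[1:550, ] <- 1L                      # all cells detect 550 genes
  base[551, 1:10] <- 1L                    # focal gene in 10 cells
  base[552, 1] <- 10^9L                    # cell 1 is a UMI outlier
  m <- count_matrix(base, sprintf("g%03d", 1:n_genes), sprintf("c%02d", 1:12))
  fc <- filter_cells(m, min_genes = 500)
  expect_false("c01" %in% fc$matrix$cell_ids)
  fg <- filter_genes(fc$matrix, NULL, min_cells = 10)
  expect_false("g551" %in% fg$matrix$gene_ids)
})

test_that("normalization closed forms and per-cell invariant", {
  m <- count_matrix(matrix(c(10L, 0L), 2, 1), c("g1", "g2"), "c1")
  nm <- normalize_counts(m)
  expect_equal(nm$values["g1", "c1"], log(10001))
  expect_equal(nm$values["g2", "c1"], 0)
  r <- random_counts(40, 30, seed = 5)
  nm2 <- normalize_counts(r)
  sums <- colSums(expm1(nm2$values))
  expect_true(all(abs(sums - 10000) < 1e-6))
  # strictly monotone per cell, zero-preserving
  v <- as.matrix(r$values)
  for (j in c(1, 17)) {
    ord <- order(v[, j])
    expect_true(all(diff(nm2$values[ord, j]) >= 0))
    expect_true(all((v[, j] == 0) == (nm2$values[, j] == 0)))
  }
  z <- count_matrix(matrix(c(1L, 0L), 1, 2), "g1", c("a", "b"))
  expect_error(normalize_counts(z), "filter_cells first")
})

test_that("RLE diagnostic: closed forms and null-simulation medians near 0", {
  # 3 housekeeping genes, 5 cells; one entry doubled relative to the median
  v <- matrix(log1p(matrix(100, 3, 5)), 3, 5,
              dimnames = list(c("h1", "h2", "h3"), sprintf("c%d", 1:5)))
  v["h1", "c2"] <- log1p(200)
  nm <- normalized_matrix(v)
  # a gene at its across-cell median has RLE 0; the doubled entry has +1
  expr <- expm1(v)
  expect_equal(log2(expr["h1", "c1"] / median(expr["h1", ])), 0)
  expect_equal(log2(expr["h1", "c2"] / median(expr["h1", ])), 1)
  res <- rle_diagnostic(nm, c("h1", "h2", "h3"),
                        grouping = setNames(rep(c("s1", "s2"), c(2, 3)),
                                            colnames(v)))
  expect_equal(sort(res$sample), c("s1", "s2"))
  expect_true(all(is.finite(res$median_rle)))
  expect_error(rle_diagnostic(nm, c("absent1", "absent2")),
               "no housekeeping genes")
  # batch-free synthetic data: per-sample median RLE within +/- 0.1 of 0
  sim <- simulate_time_course(sim_config(seed = 8))
  nm2 <- normalize_counts(sim$counts)
  hk <- sim$genes$gene_id[sim$genes$is_housekeeping]
  grp <- setNames(sub("^cell_(t\\d+)_.*$", "\\1", sim$cells$cell_id),
                  sim$cells$cell_id)
  res2 <- rle_diagnostic(nm2, hk, grouping = grp)
  expect_true(all(abs(res2$median_rle) <= 0.1))
})

test_that("default synthetic world passes QC near-unscathed at the scaled floor", {
  sim <- simulate_time_course(sim_config(seed = 2))
  pp <- preprocess(sim$counts, gene_annotation = sim$genes,
                   min_genes = SYNTH_MIN_GENES)
  expect_equal(pp$gene_report$removed_ids$mito_gene,
               sim$genes$gene_id[sim$genes$is_mitochondrial])
  expect_length(pp$gene_report$removed_ids$low_cell_gene, 0)
  expect_lt(1 - pp$cell_report$cells_out / pp$cell_report$cells_in, 0.05)
})
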