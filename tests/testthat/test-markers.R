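test_that("exact rank-sum p-values match enumeration and the reference", {
  # disjoint triples: U = 0, two-sided tail 2/20
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical multisets are maximally null
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3)), 1)
  # all splits of n <= 8 distinct values against stats::wilcox.test (exact)
  for (n in 4:8) {
    vals <- seq_len(n) * 1.37
    for (na in 1:(n - 1)) {
      splits <- utils::combn(n, na, simplify = FALSE)
      for (sp in splits) {
        p_pkg <- rank_sum_test(vals[sp], vals[-sp])
        p_ref <- stats::wilcox.test(vals[sp], vals[-sp],
                                    exact = TRUE)$p.value
        expect_equal(p_pkg, p_ref, tolerance = 1e-12)
      }
    }
  }
})

test_that("normal-approximation path matches the reference within 1e-8", {
  set.seed(91)
  for (rep in 1:5) {
    a <- rnorm(40); b <- rnorm(40, 0.3)
    p_pkg <- rank_sum_test(a, b)
    p_ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-8)
  }
  # tied data take the tie-corrected approximation
  a <- c(1, 1, 2, 2, 3); b <- c(2, 3, 3, 4, 4)
  expect_equal(rank_sum_test(a, b),
               suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                   correct = TRUE))$p.value,
               tolerance = 1e-12)
  expect_error(rank_sum_test(numeric(0), 1), "empty group")
})

test_that("BH q-values match the brute-force oracle on random p-vectors", {
  set.seed(101)
  for (rep in 1:100) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), naive_bh(p), tolerance = 1e-12)
  }
  p <- runif(30)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("find_markers: strong marker passes, undetected gene is excluded, identical groups yield nothing", {
  n <- 20
  on <- log1p(10)
  v <- rbind(c(rep(on, n), rep(0, n)),              # perfect A marker
             c(rep(on, 2), rep(0, n - 2), rep(on, 2), rep(0, n - 2)),
             rep(c(on, 0), n))                      # 10% detection both sides
  nm <- normalized_matrix(v, c("gA", "gLow", "gHalf"),
                          sprintf("c%02d", 1:(2 * n)))
  groups <- rep(c("A", "B"), each = n)
  mk <- find_markers(nm, groups, mode = "pairwise")
  row_gA <- mk[mk$gene == "gA", ]
  expect_true(row_gA$tested)
  expect_true(row_gA$passed_filters)
  expect_lt(row_gA$q_value, 0.05)
  expect_equal(row_gA$pct_in, 1)
  row_low <- mk[mk$gene == "gLow", ]                # 10% in both groups
  expect_false(row_low$tested)
  expect_true(is.na(row_low$p_value))
  # identical groups: no gene passes
  v2 <- matrix(rep(c(on, 0, on, on), each = 2 * n), 4, 2 * n, byrow = TRUE)
  nm2 <- normalized_matrix(v2, paste0("g", 1:4), sprintf("c%02d", 1:(2 * n)))
  mk2 <- find_markers(nm2, groups, mode = "pairwise")
  expect_false(any(mk2$passed_filters))
})

test_that("find_markers is invariant to cell order and antisymmetric in group labels", {
  set.seed(111)
  nm <- random_nm(30, 40, seed = 112)
  groups <- setNames(rep(c("A", "B"), each = 20), nm$cell_ids)
  mk <- find_markers(nm, groups, mode = "pairwise")
  perm <- sample(40)
  nm_p <- normalized_matrix(nm$values[, perm], nm$gene_ids,
                            nm$cell_ids[perm])
  mk_p <- find_markers(nm_p, groups[nm_p$cell_ids], mode = "pairwise")
  expect_equal(mk_p$p_value, mk$p_value)
  expect_equal(mk_p$log_fc, mk$log_fc)
  # swapping labels flips log_fc sign, keeps p
  swapped <- setNames(ifelse(groups == "A", "B", "A"), names(groups))
  mk_s <- find_markers(nm, swapped, mode = "pairwise")
  expect_equal(mk_s$p_value, mk$p_value)
  expect_equal(mk_s$log_fc, -mk$log_fc)
})

test_that("block comparisons additionally require |logFC| >= 0.58", {
  n <- 30
  base <- log1p(5)
  small_shift <- log(expm1(base) * 1.5 + 1)  # de-logged FC 1.5 -> lnFC ~ 0.4
  v <- rbind(c(rep(small_shift, n), rep(base, n)),
             c(rep(log1p(40), n), rep(base, n)))
  nm <- normalized_matrix(v, c("gSmall", "gBig"), sprintf("c%02d", 1:(2 * n)))
  groups <- rep(c("A", "B"), each = n)
  mk <- find_markers(nm, groups, mode = "pairwise", block = TRUE)
  expect_false(mk[mk$gene == "gSmall", "passed_filters"])
  expect_true(mk[mk$gene == "gBig", "passed_filters"])
  expect_lt(mk[mk$gene == "gSmall", "q_value"], 0.05)  # fails only the block FC
})

test_that("degenerate partitions are refused", {
  nm <- random_nm(5, 10, seed = 113)
  expect_error(find_markers(nm, rep("A", 10)), "degenerate")
  expect_error(find_markers(nm, c(rep("A", 8), "B", "B")), "degenerate")
})

test_that("select_stage_tfs recovers program TFs and stays empty on null input", {
  hits <- 0L
  for (seed in 1:20) {
    sim <- simulate_time_course(sim_config(seed = seed))
    nm <- normalize_counts(sim$counts)
    nt <- split_by_time(nm, sim$cells)
    tfs <- sim$genes$gene_id[sim$genes$is_tf]
    sel <- select_stage_tfs(nt[[1]], nt[[length(nt)]], tfs = tfs)
    a_tfs <- grep("^gA", tfs, value = TRUE)
    b_tfs <- grep("^gB", tfs, value = TRUE)
    hits <- hits + (setequal(sel$first, a_tfs) && setequal(sel$last, b_tfs))
    expect_length(intersect(sel$first, sel$last), 0)
  }
  expect_gte(hits, 18L)
  # identically distributed TF lands in neither set; identical cells -> empty
  v <- matrix(log1p(3), 2, 8, dimnames = list(c("tf1", "tf2"), NULL))
  nmA <- normalized_matrix(v, c("tf1", "tf2"), sprintf("a%d", 1:8))
  nmB <- normalized_matrix(v, c("tf1", "tf2"), sprintf("b%d", 1:8))
  sel0 <- select_stage_tfs(nmA, nmB)
  expect_length(sel0$first, 0)
  expect_length(sel0$last, 0)
})

test_that("type-I error calibration on null splits", {
  frac <- numeric(20)
  for (seed in 1:20) {
    set.seed(seed + 200)
    v <- matrix(log1p(rnbinom(60 * 80, mu = 5, size = 2)), 60, 80)
    nm <- normalized_matrix(v, sprintf("g%02d", 1:60), sprintf("c%02d", 1:80))
    groups <- sample(rep(c("A", "B"), each = 40))
    mk <- find_markers(nm, groups, mode = "pairwise")
    frac[seed] <- sum(mk$q_value < 0.05, na.rm = TRUE) / nrow(mk)
  }
  expect_lte(mean(frac), 0.05)
})
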