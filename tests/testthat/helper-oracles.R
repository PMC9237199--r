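# Independent oracles, kept deliberately naive and separate from the
# package's own code paths.

# double-loop Pearson over columns of a plain matrix
naive_cor_columns <- function(v) {
  n <- ncol(v)
  R <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- v[, i]; xj <- v[, j]
    R[i, j] <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
  }
  R
}

# mean over unordered distinct pairs via explicit loops
naive_pair_mean <- function(R, absolute = TRUE) {
  n <- nrow(R); acc <- 0; k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    acc <- acc + if (absolute) abs(R[i, j]) else R[i, j]
    k <- k + 1L
  }
  acc / k
}

# I_C on one time point's matrix by the naive route
naive_ic <- function(v) {
  num <- naive_pair_mean(naive_cor_columns(t(v)), absolute = TRUE)
  den <- naive_pair_mean(naive_cor_columns(v), absolute = TRUE)
  num / den
}

# brute-force BH step-up from the definition
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- prev
  }
  q
}

# two-pass gene/cell filter as a brute-force reference
naive_two_pass_filter <- function(counts, is_mito, min_genes, umi_sd,
                                  min_cells) {
  detected <- apply(counts, 2L, function(x) sum(x > 0))
  lt <- log10(colSums(counts))
  keep_cells <- detected >= min_genes &
    lt >= mean(lt) - umi_sd * stats::sd(lt) &
    lt <= mean(lt) + umi_sd * stats::sd(lt)
  sub <- counts[, keep_cells, drop = FALSE]
  prevalence <- apply(sub, 1L, function(x) sum(x > 0))
  keep_genes <- prevalence >= min_cells & !is_mito
  list(cells = keep_cells, genes = keep_genes)
}

# small dense random count fixture
random_counts <- function(n_genes, n_cells, seed, mu = 5, size = 2) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = size),
              n_genes, n_cells)
  count_matrix(m, sprintf("g%03d", seq_len(n_genes)),
               sprintf("c%03d", seq_len(n_cells)))
}

# random strictly positive normalized-style matrix
random_nm <- function(n_genes, n_cells, seed) {
  set.seed(seed)
  v <- matrix(abs(rnorm(n_genes * n_cells, 2, 1)), n_genes, n_cells)
  normalized_matrix(v, sprintf("g%03d", seq_len(n_genes)),
                    sprintf("c%03d", seq_len(n_cells)))
}

# per-seed QC floor for the ~200-gene synthetic world (see vignette)
SYNTH_MIN_GENES <- 98
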