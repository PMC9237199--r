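#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-value by enumeration of all rank assignments when
#' n_a + n_b <= 12 and the pooled sample has no ties; otherwise the normal
#' approximation with midrank tie correction and continuity correction.
#'
#' @param a,b numeric expression vectors, both non-empty.
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("empty group")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2   # Mann-Whitney U for a
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && na + nb <= 12L) {
    # exact: U distribution by enumeration of C(n, na) rank assignments
    combs <- utils::combn(na + nb, na)
    us <- colSums(combs) - na * (na + 1) / 2
    mu <- na * nb / 2
    p <- if (u > mu) 2 * mean(us >= u) else 2 * mean(us <= u)
    return(min(1, p))
  }
  mu <- na * nb / 2
  tie_tab <- table(pooled)
  n <- na + nb
  sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p numeric vector of p-values.
#' @return q-values in the input order; monotone step-up, q >= p.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / (m:1)))
  q[order(o)]
}

# natural-log fold change on the de-logged mean scale
log_fc_delog <- function(xa, xb) {
  log(mean(expm1(xa)) + 1) - log(mean(expm1(xb)) + 1)
}

#' Wilcoxon marker detection with detection-fraction and fold-change filters
#'
#' For each contrast, genes are pre-filtered to those detected (value > 0) in
#' at least \code{min_pct} of either group AND with absolute natural-log fold
#' change (on the de-logged mean scale, pseudocount 1) of at least
#' \code{logfc_threshold}; the rank-sum test runs on survivors and BH
#' q-values are computed over the genes actually tested within the contrast.
#' \code{passed_filters} is q < \code{q_threshold}, additionally requiring
#' |log_fc| >= \code{block_logfc} when \code{block = TRUE} (block
#' comparisons such as one stage versus all others combined).
#'
#' @param nm a \code{NormalizedMatrix}.
#' @param groups character/factor of group labels, one per cell (a named
#'   vector is matched to cell ids).
#' @param mode \code{"one_vs_rest"} (each group against all other cells) or
#'   \code{"pairwise"} (every unordered group pair).
#' @param min_pct detection-fraction floor (default 0.2).
#' @param logfc_threshold pre-filter log fold change (default 0.2).
#' @param q_threshold BH significance level (default 0.05).
#' @param block_logfc block-comparison fold-change filter (default 0.58).
#' @param block apply the block fold-change filter to passed_filters.
#' @return a \code{MarkerTable} data.frame: contrast, gene, p_value, q_value,
#'   log_fc, pct_in, pct_out, direction, tested, passed_filters.
#' @export
find_markers <- function(nm, groups, mode = c("one_vs_rest", "pairwise"),
                         min_pct = 0.2, logfc_threshold = 0.2,
                         q_threshold = 0.05, block_logfc = 0.58,
                         block = FALSE) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  mode <- match.arg(mode)
  if (!is.null(names(groups))) groups <- groups[nm$cell_ids]
  groups <- as.character(groups)
  if (length(groups) != length(nm$cell_ids))
    stop("groups must label every cell")
  lv <- sort(unique(groups))   # contrast orientation independent of cell order
  if (length(lv) < 2L) stop("degenerate partition: need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes < 3L))
    stop("degenerate partition: group smaller than 3 cells (",
         names(sizes)[which(sizes < 3L)[1L]], ")")
  contrasts <- if (mode == "one_vs_rest") {
    lapply(lv, function(g) list(name = paste0(g, "_vs_rest"),
                                a = groups == g, b = groups != g))
  } else {
    cmb <- utils::combn(lv, 2L, simplify = FALSE)
    lapply(cmb, function(pr) list(name = paste0(pr[1L], "_vs_", pr[2L]),
                                  a = groups == pr[1L], b = groups == pr[2L]))
  }
  v <- nm$values
  out <- lapply(contrasts, function(ct) {
    va <- v[, ct$a, drop = FALSE]; vb <- v[, ct$b, drop = FALSE]
    pct_in <- rowMeans(va > 0); pct_out <- rowMeans(vb > 0)
    lfc <- vapply(seq_len(nrow(v)),
                  function(i) log_fc_delog(va[i, ], vb[i, ]), numeric(1))
    tested <- (pct_in >= min_pct | pct_out >= min_pct) &
      abs(lfc) >= logfc_threshold
    p <- rep(NA_real_, nrow(v))
    p[tested] <- vapply(which(tested),
                        function(i) rank_sum_test(va[i, ], vb[i, ]),
                        numeric(1))
    q <- rep(NA_real_, nrow(v))
    q[tested] <- bh_adjust(p[tested])
    passed <- tested & !is.na(q) & q < q_threshold
    if (block) passed <- passed & abs(lfc) >= block_logfc
    data.frame(contrast = ct$name, gene = nm$gene_ids,
               p_value = p, q_value = q, log_fc = lfc,
               pct_in = pct_in, pct_out = pct_out,
               direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
               tested = tested, passed_filters = passed,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("MarkerTable", "data.frame")
  attr(res, "params") <- list(min_pct = min_pct,
                              logfc_threshold = logfc_threshold,
                              q_threshold = q_threshold,
                              block_logfc = block_logfc, block = block,
                              logfc_scale = "natural log of de-logged means + 1")
  res
}

#' Stage-specific transcription-factor selection
#'
#' Rank-sum test per TF between the first-stage and last-stage matrices;
#' TFs with p < \code{p_threshold} are assigned to the stage with the higher
#' mean expression. The two sets are disjoint by construction.
#'
#' @param nm_first,nm_last \code{NormalizedMatrix} objects restricted to (or
#'   containing) the TF genes, for the two terminal stages.
#' @param tfs character vector of TF gene ids; default = all shared genes.
#' @param p_threshold selection p-value (default 0.05).
#' @return list with \code{first} and \code{last} character vectors of TF ids
#'   and a \code{table} of per-TF p-values and means.
#' @export
select_stage_tfs <- function(nm_first, nm_last, tfs = NULL,
                             p_threshold = 0.05) {
  shared <- intersect(nm_first$gene_ids, nm_last$gene_ids)
  if (is.null(tfs)) tfs <- shared
  tfs <- intersect(tfs, shared)
  if (length(tfs) == 0L) stop("no TFs flagged/present in both matrices")
  va <- nm_first$values[tfs, , drop = FALSE]
  vb <- nm_last$values[tfs, , drop = FALSE]
  p <- vapply(seq_along(tfs),
              function(i) rank_sum_test(va[i, ], vb[i, ]), numeric(1))
  ma <- rowMeans(va); mb <- rowMeans(vb)
  sel <- p < p_threshold & ma != mb
  tab <- data.frame(gene = tfs, p_value = p, mean_first = ma, mean_last = mb,
                    stage = ifelse(!sel, "none",
                                   ifelse(ma > mb, "first", "last")),
                    stringsAsFactors = FALSE)
  list(first = tab$gene[tab$stage == "first"],
       last = tab$gene[tab$stage == "last"],
       table = tab)
}
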