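#' TF-pair product scores across a time course
#'
#' For every cross pair (one first-stage TF, one last-stage TF) and every
#' cell, the TF value is the product of the two genes' normalized expression
#' values (natural-log scale, the matrix the rest of the pipeline uses). Per
#' time point and pair: the mean TF value over cells, the fraction of cells
#' expressing both members (value > 0) and the fraction expressing exactly
#' one. The product is low at stable states (one program off) and elevated at
#' a transition where both programs are partially active.
#'
#' @param nm_by_time named list of \code{NormalizedMatrix} in time order.
#' @param p1_tfs,p28_tfs non-empty character vectors of first-stage and
#'   last-stage TF gene ids; every id must be present in every matrix.
#' @return object of class \code{TFPairScores}: \code{pair_summary}
#'   data.frame (time_point, p1_tf, p28_tf, mean_tf_value,
#'   coexpression_fraction, exclusive_fraction) and \code{pooled} named list
#'   of per-time pooled cell-level TF values.
#' @export
tf_pair_products <- function(nm_by_time, p1_tfs, p28_tfs) {
  if (length(p1_tfs) == 0L || length(p28_tfs) == 0L)
    stop("both TF sets must be non-empty")
  if (is.null(names(nm_by_time)))
    names(nm_by_time) <- sprintf("t%d", seq_along(nm_by_time) - 1L)
  for (nm in nm_by_time) {
    miss <- setdiff(c(p1_tfs, p28_tfs), nm$gene_ids)
    if (length(miss)) stop("TF absent from matrix: ", miss[1L])
  }
  pooled <- list()
  rows <- lapply(names(nm_by_time), function(t) {
    v <- nm_by_time[[t]]$values
    grid <- expand.grid(p1_tf = p1_tfs, p28_tf = p28_tfs,
                        stringsAsFactors = FALSE)
    vals <- lapply(seq_len(nrow(grid)), function(k) {
      x <- v[grid$p1_tf[k], ]; y <- v[grid$p28_tf[k], ]
      x * y
    })
    pooled[[t]] <<- unlist(vals, use.names = FALSE)
    grid$time_point <- t
    grid$mean_tf_value <- vapply(vals, mean, numeric(1))
    both <- vapply(seq_len(nrow(grid)), function(k) {
      x <- v[grid$p1_tf[k], ] > 0; y <- v[grid$p28_tf[k], ] > 0
      c(mean(x & y), mean(xor(x, y)))
    }, numeric(2))
    grid$coexpression_fraction <- both[1L, ]
    grid$exclusive_fraction <- both[2L, ]
    grid[, c("time_point", "p1_tf", "p28_tf", "mean_tf_value",
             "coexpression_fraction", "exclusive_fraction")]
  })
  out <- list(pair_summary = do.call(rbind, rows), pooled = pooled)
  class(out) <- "TFPairScores"
  out
}

#' Per-time-point bifurcation summary of TF-pair scores
#'
#' Pools cell-level TF values over all pairs at each time point and reports
#' mean, median and upper decile, together with the average co-expression
#' and exclusive-expression fractions across pairs.
#'
#' @param scores a \code{TFPairScores} object.
#' @return data.frame with one row per time point.
#' @export
bifurcation_summary <- function(scores) {
  stopifnot(inherits(scores, "TFPairScores"))
  ps <- scores$pair_summary
  tps <- unique(ps$time_point)
  out <- lapply(tps, function(t) {
    vals <- scores$pooled[[t]]
    sub <- ps[ps$time_point == t, ]
    data.frame(time_point = t,
               mean_tf_value = mean(vals),
               median_tf_value = stats::median(vals),
               upper_decile_tf_value = stats::quantile(vals, 0.9, names = FALSE),
               coexpression_fraction = mean(sub$coexpression_fraction),
               exclusive_fraction = mean(sub$exclusive_fraction),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
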