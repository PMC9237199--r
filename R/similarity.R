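#' Jaccard similarity of two gene sets
#'
#' |intersection| / |union|; duplicates are ignored (sets). Undefined when
#' both sets are empty.
#'
#' @param a,b character vectors.
#' @return similarity in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("jaccard undefined: both sets empty")
  length(intersect(a, b)) / u
}

#' Cross-similarity matrix of signature-gene sets with best matches
#'
#' Full Jaccard matrix between two collections of cluster signature sets;
#' per-row best matches are reported with ties listed, never broken silently.
#'
#' @param setsA,setsB named lists of character vectors (cluster id -> genes);
#'   each collection non-empty.
#' @return list with \code{matrix} (rows = A clusters, columns = B clusters)
#'   and \code{best_match} data.frame (cluster_a, best_b =
#'   comma-joined argmax set, similarity, tie flag).
#' @export
similarity_matrix <- function(setsA, setsB) {
  if (length(setsA) == 0L || length(setsB) == 0L)
    stop("need >= 1 signature set on each side")
  if (is.null(names(setsA))) names(setsA) <- sprintf("A%d", seq_along(setsA))
  if (is.null(names(setsB))) names(setsB) <- sprintf("B%d", seq_along(setsB))
  M <- matrix(NA_real_, length(setsA), length(setsB),
              dimnames = list(names(setsA), names(setsB)))
  for (i in seq_along(setsA)) for (j in seq_along(setsB)) {
    M[i, j] <- tryCatch(jaccard(setsA[[i]], setsB[[j]]),
                        error = function(e)
                          stop("empty signature sets for clusters '",
                               names(setsA)[i], "' and '", names(setsB)[j],
                               "'"))
  }
  best <- do.call(rbind, lapply(seq_len(nrow(M)), function(i) {
    mx <- max(M[i, ])
    hits <- colnames(M)[M[i, ] == mx]
    data.frame(cluster_a = rownames(M)[i],
               best_b = paste(hits, collapse = ","),
               similarity = mx, tie = length(hits) > 1L,
               stringsAsFactors = FALSE)
  }))
  list(matrix = M, best_match = best)
}

#' Extract signature sets from a MarkerTable
#'
#' Markers with \code{passed_filters} per contrast, capped at the top
#' \code{top_n} by q-value (ties by p-value then gene id for determinism).
#' Identity genes are positive markers, so only up-regulated ones are kept
#' by default.
#'
#' @param markers a \code{MarkerTable} from \code{\link{find_markers}}.
#' @param top_n cap per cluster (default 100).
#' @param positive_only keep only direction "up" markers (default TRUE).
#' @return named list of gene-id vectors, one per contrast.
#' @export
signature_sets <- function(markers, top_n = 100, positive_only = TRUE) {
  stopifnot(inherits(markers, "MarkerTable"))
  keep <- markers[markers$passed_filters, , drop = FALSE]
  if (positive_only) keep <- keep[keep$direction == "up", , drop = FALSE]
  sp <- split(keep, keep$contrast)
  lapply(sp, function(d) {
    d <- d[order(d$q_value, d$p_value, d$gene), , drop = FALSE]
    utils::head(d$gene, top_n)
  })
}
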