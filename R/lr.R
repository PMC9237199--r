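#' Ligand-receptor interaction significance by cluster-label permutation
#'
#' For every ligand-receptor pair and every ordered (sender, receiver)
#' cluster combination, the observed statistic is the mean of the ligand's
#' average expression in the sender cluster and the receptor's average
#' expression in the receiver cluster (natural-log normalized values). The
#' null is built from \code{n_perm} random permutations of the cluster
#' labels, shared across all combinations; p = fraction of permuted
#' statistics >= observed. A combination is undefined (p set to 1, flagged)
#' when the ligand is detected in fewer than \code{detection_floor} of the
#' sender cluster or the receptor in fewer than that of the receiver.
#'
#' @param nm a \code{NormalizedMatrix}.
#' @param clusters cluster label per cell (named vectors matched to cell
#'   ids); >= 2 clusters.
#' @param pairs data.frame with \code{ligand} and \code{receptor} columns.
#' @param n_perm number of permutations (default 1000, must be >= 1).
#' @param seed RNG seed; results are deterministic given it.
#' @param detection_floor in-cluster detection fraction floor (default 0.1).
#' @param include_self include sender == receiver combinations (default TRUE).
#' @return data.frame: ligand, receptor, sender, receiver, interaction_mean,
#'   detected, p_value.
#' @export
lr_significance <- function(nm, clusters, pairs, n_perm = 1000, seed = 1L,
                            detection_floor = 0.1, include_self = TRUE) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(names(clusters))) clusters <- clusters[nm$cell_ids]
  clusters <- as.character(clusters)
  if (length(clusters) != length(nm$cell_ids))
    stop("clusters must label every cell")
  lv <- sort(unique(clusters))
  if (length(lv) < 2L) stop("need >= 2 clusters")
  genes <- unique(c(pairs$ligand, pairs$receptor))
  miss <- setdiff(genes, nm$gene_ids)
  if (length(miss)) stop("pair references missing gene: ", miss[1L])
  v <- nm$values[genes, , drop = FALSE]
  cl <- factor(clusters, levels = lv)
  grp_mean <- function(m, f) {
    # genes x clusters matrix of within-cluster means
    t(rowsum(t(m), f) / as.vector(table(f)))
  }
  obs_mean <- grp_mean(v, cl)
  det <- grp_mean((v > 0) * 1, cl)
  combos <- expand.grid(sender = lv, receiver = lv,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!include_self) combos <- combos[combos$sender != combos$receiver, ]
  grid <- merge(pairs[, c("ligand", "receptor")], combos, by = NULL)
  li <- match(grid$ligand, genes); ri <- match(grid$receptor, genes)
  si <- match(grid$sender, lv);    vi <- match(grid$receiver, lv)
  obs <- (obs_mean[cbind(li, si)] + obs_mean[cbind(ri, vi)]) / 2
  detected <- det[cbind(li, si)] >= detection_floor &
    det[cbind(ri, vi)] >= detection_floor
  set.seed(seed)
  ge <- integer(length(obs))
  for (b in seq_len(n_perm)) {
    pm <- grp_mean(v, sample(cl))
    stat <- (pm[cbind(li, si)] + pm[cbind(ri, vi)]) / 2
    ge <- ge + (stat >= obs)
  }
  p <- ge / n_perm
  p[!detected] <- 1
  data.frame(ligand = grid$ligand, receptor = grid$receptor,
             sender = grid$sender, receiver = grid$receiver,
             interaction_mean = obs, detected = detected, p_value = p,
             stringsAsFactors = FALSE)
}

#' Rank ligand-receptor pairs by mean expression and select the top list
#'
#' Per pair, counts the significant (p < \code{p_threshold}) cluster
#' combinations and averages their interaction means; pairs with no
#' significant combination are excluded; ranking is descending by that mean
#' and the top \code{top_n} are retained.
#'
#' @param table output of \code{\link{lr_significance}} for one condition.
#' @param top_n list size (default 20).
#' @param p_threshold significance cut (default 0.05).
#' @return data.frame: ligand, receptor, n_significant_cell_pairs,
#'   pair_mean_expression, rank.
#' @export
rank_and_select <- function(table, top_n = 20, p_threshold = 0.05) {
  sig <- table[table$p_value < p_threshold & table$detected, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(ligand = character(0), receptor = character(0),
                      n_significant_cell_pairs = integer(0),
                      pair_mean_expression = numeric(0), rank = integer(0)))
  key <- paste(sig$ligand, sig$receptor, sep = "\r")
  agg <- lapply(split(sig, key), function(d)
    data.frame(ligand = d$ligand[1L], receptor = d$receptor[1L],
               n_significant_cell_pairs = nrow(d),
               pair_mean_expression = mean(d$interaction_mean),
               stringsAsFactors = FALSE))
  res <- do.call(rbind, agg)
  res <- res[order(-res$pair_mean_expression, res$ligand, res$receptor), ,
             drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  utils::head(res, top_n)
}

#' Classify between-condition deltas of ligand-receptor pair expression
#'
#' For the union of both conditions' selected pairs, delta = condition B's
#' pair mean expression minus condition A's; a pair present in only one
#' condition's table contributes 0 for the missing side and is flagged.
#' delta > +threshold is "increased", delta < -threshold "decreased",
#' otherwise "unchanged".
#'
#' @param tableA,tableB outputs of \code{\link{rank_and_select}} for the two
#'   conditions.
#' @param threshold classification half-width (default 0.4).
#' @param conditions the two condition labels (must differ).
#' @return data.frame: ligand, receptor, mean_a, mean_b, delta, delta_class,
#'   missing_in.
#' @export
classify_delta <- function(tableA, tableB, threshold = 0.4,
                           conditions = c("A", "B")) {
  if (conditions[1L] == conditions[2L])
    stop("condition labels are identical")
  keyA <- paste(tableA$ligand, tableA$receptor, sep = "\r")
  keyB <- paste(tableB$ligand, tableB$receptor, sep = "\r")
  keys <- union(keyA, keyB)
  split_key <- function(k) do.call(rbind, strsplit(k, "\r", fixed = TRUE))
  ids <- split_key(keys)
  ma <- tableA$pair_mean_expression[match(keys, keyA)]
  mb <- tableB$pair_mean_expression[match(keys, keyB)]
  missing_in <- ifelse(is.na(ma), conditions[1L],
                       ifelse(is.na(mb), conditions[2L], ""))
  ma[is.na(ma)] <- 0; mb[is.na(mb)] <- 0
  delta <- mb - ma
  cls <- ifelse(delta > threshold, "increased",
                ifelse(delta < -threshold, "decreased", "unchanged"))
  out <- data.frame(ligand = ids[, 1L], receptor = ids[, 2L],
                    mean_a = ma, mean_b = mb, delta = delta,
                    delta_class = cls, missing_in = missing_in,
                    stringsAsFactors = FALSE)
  out[order(out$ligand, out$receptor), , drop = FALSE]
}

#' Full ligand-receptor delta procedure between two conditions
#'
#' Runs \code{\link{lr_significance}} and \code{\link{rank_and_select}} per
#' condition on a shared normalized matrix, then
#' \code{\link{classify_delta}}.
#'
#' @param nm a \code{NormalizedMatrix} holding both conditions' cells.
#' @param cells a CellAnnotation (cluster + condition columns).
#' @param pairs ligand-receptor pair data.frame.
#' @param conditions the two condition labels, in (A, B) order; default = the
#'   first two labels present.
#' @param n_perm,seed,detection_floor,p_threshold,top_n,threshold knobs as in
#'   the component operations.
#' @return list with per-condition significance tables, ranked tables, and
#'   the delta classification.
#' @export
lr_delta <- function(nm, cells, pairs, conditions = NULL, n_perm = 1000,
                     seed = 1L, detection_floor = 0.1, p_threshold = 0.05,
                     top_n = 20, threshold = 0.4) {
  ann <- check_annotated(nm, cells)
  if (is.null(conditions)) conditions <- unique(ann$condition)[1:2]
  if (anyNA(conditions) || length(conditions) != 2L ||
      conditions[1L] == conditions[2L])
    stop("need two distinct condition labels")
  per_cond <- lapply(seq_len(2L), function(i) {
    sel <- ann$condition == conditions[i]
    nmc <- subset_normalized(nm, cells = which(sel))
    sig <- lr_significance(nmc, stats::setNames(ann$cluster[sel],
                                                ann$cell_id[sel]),
                           pairs, n_perm = n_perm, seed = seed + i,
                           detection_floor = detection_floor)
    list(significance = sig,
         ranked = rank_and_select(sig, top_n = top_n,
                                  p_threshold = p_threshold))
  })
  names(per_cond) <- conditions
  delta <- classify_delta(per_cond[[1L]]$ranked, per_cond[[2L]]$ranked,
                          threshold = threshold, conditions = conditions)
  list(per_condition = per_cond, delta = delta, conditions = conditions)
}
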