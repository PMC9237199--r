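#' Default simulation configuration
#'
#' The stated world for every recovery test: a 5-time-point UMI course with
#' two antagonistic gene programs (60 genes each, first 10 of each flagged as
#' transcription factors), 40 housekeeping genes, the 37 mitochondrial genes,
#' 200 cells per time point, and a broadened latent-state distribution at the
#' transition time point (index 2). Negative-binomial counts (size 2) with
#' log-normal library-size variation (sigma 0.3) and per-cell-per-gene
#' log-normal expression noise (sd 0.3).
#'
#' @param ... overrides for any field.
#' @return a \code{SimulationConfig} list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_time_points = 5L,
    transition_index = 2L,      # 0-based, as a position among time points
    cells_per_time = 200L,
    n_program_A_genes = 60L,
    n_program_B_genes = 60L,
    n_housekeeping = 40L,
    n_mito = 37L,
    n_tf_per_program = 10L,
    base_mean = 50,
    dispersion = 2,
    libsize_lognorm_sigma = 0.3,
    stable_beta = 30,
    transition_beta = 0.8,
    noise_sd = 0.3,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field: ", unknown[1L])
  cfg[names(over)] <- over
  validate_sim_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_time_points < 3) stop("n_time_points must be >= 3")
  if (cfg$transition_index < 0 || cfg$transition_index > cfg$n_time_points - 1)
    stop("transition_index must lie in [0, n_time_points-1]")
  if (cfg$transition_beta >= cfg$stable_beta)
    stop("transition_beta must be < stable_beta")
  pos <- c("cells_per_time", "n_program_A_genes", "n_program_B_genes",
           "base_mean", "dispersion", "stable_beta", "transition_beta")
  for (f in pos) if (cfg[[f]] <= 0) stop(f, " must be positive")
  nonneg <- c("n_housekeeping", "n_mito", "libsize_lognorm_sigma", "noise_sd")
  for (f in nonneg) if (cfg[[f]] < 0) stop(f, " must be non-negative")
  if (cfg$n_tf_per_program > min(cfg$n_program_A_genes, cfg$n_program_B_genes))
    stop("n_tf_per_program exceeds program size")
  invisible(cfg)
}

# latent-state means across time: 0.05 ... 0.5 at t* ... 0.95
latent_means <- function(n_time, t_star) {
  m <- numeric(n_time)
  if (t_star > 0)
    m[seq_len(t_star + 1L)] <- seq(0.05, 0.5, length.out = t_star + 1L)
  else m[1L] <- 0.5
  if (t_star < n_time - 1L)
    m[(t_star + 1L):n_time] <- seq(0.5, 0.95,
                                   length.out = n_time - t_star)
  m
}

# NB sampler with Poisson limit at dispersion = Inf
rcounts <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate a two-attractor single-cell UMI time course
#'
#' Each cell draws a latent state s in [0,1] from a Beta distribution whose
#' mean moves monotonically from 0.05 (first time point) through 0.5 (the
#' transition time point, where the Beta is broad and symmetric with
#' concentration \code{transition_beta}) to 0.95 (last time point). Program-A
#' genes have mean \code{base_mean*(1-s)}, program-B genes
#' \code{base_mean*s}, housekeeping genes \code{base_mean}, mitochondrial
#' genes \code{0.05*base_mean}; each mean is multiplied by an independent
#' log-normal noise factor (sd \code{noise_sd}) and the cell's library factor
#' (log-normal, sigma \code{libsize_lognorm_sigma}), then counts are drawn
#' NB(mean, size = \code{dispersion}). Deterministic given \code{seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{counts} (\code{CountMatrix}), \code{cells}
#'   (CellAnnotation), \code{genes} (GeneAnnotation) and \code{truth}
#'   (latent states, program membership, transition index).
#' @export
simulate_time_course <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  nt <- config$n_time_points
  t_star <- config$transition_index
  nA <- config$n_program_A_genes; nB <- config$n_program_B_genes
  nH <- config$n_housekeeping;    nM <- config$n_mito
  nc <- config$cells_per_time
  gene_ids <- c(sprintf("gA%03d", seq_len(nA)), sprintf("gB%03d", seq_len(nB)),
                if (nH) sprintf("hk%03d", seq_len(nH)),
                if (nM) sprintf("mt-%02d", seq_len(nM)))
  program <- c(rep("A", nA), rep("B", nB),
               rep("housekeeping", nH), rep("mito", nM))
  is_tf <- program %in% c("A", "B") &
    c(seq_len(nA) <= config$n_tf_per_program,
      seq_len(nB) <= config$n_tf_per_program,
      logical(nH + nM))
  mns <- latent_means(nt, t_star)
  time_labels <- sprintf("t%d", seq_len(nt) - 1L)

  n_genes <- length(gene_ids)
  n_cells <- nt * nc
  counts <- matrix(0L, n_genes, n_cells)
  s_all <- numeric(n_cells)
  cell_ids <- character(n_cells)
  time_of_cell <- character(n_cells)
  # per-gene baseline multiplier of base_mean as a function of s
  for (t in seq_len(nt)) {
    idx <- (t - 1L) * nc + seq_len(nc)
    if (t - 1L == t_star) {
      a <- config$transition_beta; b <- config$transition_beta
    } else {
      a <- mns[t] * config$stable_beta
      b <- (1 - mns[t]) * config$stable_beta
    }
    s <- stats::rbeta(nc, a, b)
    s_all[idx] <- s
    cell_ids[idx] <- sprintf("cell_%s_%03d", time_labels[t], seq_len(nc))
    time_of_cell[idx] <- time_labels[t]
    L <- stats::rlnorm(nc, 0, config$libsize_lognorm_sigma)
    base <- rbind(
      matrix(rep(1 - s, each = nA), nA, nc),
      matrix(rep(s, each = nB), nB, nc),
      matrix(1, nH, nc),
      matrix(0.05, nM, nc)
    ) * config$base_mean
    eps <- matrix(stats::rlnorm(n_genes * nc, 0, config$noise_sd), n_genes, nc)
    mu <- base * eps * rep(L, each = n_genes)
    counts[, idx] <- rcounts(length(mu), mu, config$dispersion)
  }
  cm <- count_matrix(counts, gene_ids, cell_ids)
  cells <- as_cell_annotation(data.frame(
    cell_id = cell_ids, time_point = time_of_cell,
    cluster = "CM", condition = "none",
    stringsAsFactors = FALSE), time_levels = time_labels)
  genes <- data.frame(
    gene_id = gene_ids,
    is_mitochondrial = program == "mito",
    is_housekeeping = program == "housekeeping",
    is_tf = is_tf,
    is_ligand = FALSE, is_receptor = FALSE,
    stringsAsFactors = FALSE)
  class(genes) <- c("GeneAnnotation", "data.frame")
  truth <- list(latent_state = stats::setNames(s_all, cell_ids),
                program = stats::setNames(program, gene_ids),
                is_tf = stats::setNames(is_tf, gene_ids),
                transition_index = t_star,
                time_levels = time_labels)
  list(counts = cm, cells = cells, genes = genes, truth = truth)
}

#' Simulate a two-condition, two-cluster dataset with planted ligand shifts
#'
#' Fixture for the ligand-receptor delta procedure: a sender cluster ("CM")
#' and a receiver cluster ("NCM") under two condition labels. Each
#' ligand-receptor pair i has its ligand expressed only in the sender cluster
#' and its receptor only in the receiver cluster (mean \code{lr_base_mean} in
#' the home cluster, zero elsewhere), on top of \code{n_background} uniformly
#' expressed genes.
#' In condition B the ligand mean of pair i is multiplied by \code{folds[i]};
#' with all folds 1 the two conditions are samples from one distribution.
#'
#' @param n_cells_per_cluster cells per cluster per condition (default 250,
#'   i.e. 500 cells per condition over the two clusters).
#' @param n_pairs number of ligand-receptor pairs.
#' @param folds numeric vector (length \code{n_pairs}) of condition-B ligand
#'   fold changes.
#' @param lr_base_mean expected ligand/receptor counts in their home cluster.
#' @param n_background uniformly expressed background genes.
#' @param base_mean background gene mean.
#' @param dispersion NB size parameter.
#' @param libsize_lognorm_sigma library-size log-sd.
#' @param conditions two condition labels.
#' @param seed RNG seed.
#' @return list with \code{counts}, \code{cells}, \code{genes}, and
#'   \code{pairs} (the ligand-receptor pair table).
#' @export
simulate_condition_pair <- function(n_cells_per_cluster = 250L,
                                    n_pairs = 5L,
                                    folds = rep(1, n_pairs),
                                    lr_base_mean = 20,
                                    n_background = 40L,
                                    base_mean = 20,
                                    dispersion = 2,
                                    libsize_lognorm_sigma = 0.3,
                                    conditions = c("condA", "condB"),
                                    seed = 1L) {
  if (length(folds) != n_pairs) stop("folds must have length n_pairs")
  if (length(conditions) != 2L || conditions[1L] == conditions[2L])
    stop("two distinct condition labels required")
  set.seed(seed)
  lig_ids <- sprintf("lig%02d", seq_len(n_pairs))
  rec_ids <- sprintf("rec%02d", seq_len(n_pairs))
  bg_ids <- sprintf("bg%03d", seq_len(n_background))
  gene_ids <- c(lig_ids, rec_ids, bg_ids)
  ng <- length(gene_ids)
  clusters <- c("CM", "NCM")
  per_cond <- 2L * n_cells_per_cluster
  n_cells <- 2L * per_cond
  counts <- matrix(0L, ng, n_cells)
  cell_ids <- character(n_cells)
  cl_lab <- character(n_cells); cond_lab <- character(n_cells)
  col <- 0L
  for (cond in seq_len(2L)) {
    for (cl in seq_len(2L)) {
      idx <- col + seq_len(n_cells_per_cluster)
      col <- col + n_cells_per_cluster
      cell_ids[idx] <- sprintf("cell_%s_%s_%03d", conditions[cond],
                               clusters[cl], seq_len(n_cells_per_cluster))
      cl_lab[idx] <- clusters[cl]
      cond_lab[idx] <- conditions[cond]
      lig_mu <- rep(lr_base_mean * (cl == 1L), n_pairs)
      if (cond == 2L) lig_mu <- lig_mu * folds
      rec_mu <- rep(lr_base_mean * (cl == 2L), n_pairs)
      mu_gene <- c(lig_mu, rec_mu, rep(base_mean, n_background))
      L <- stats::rlnorm(n_cells_per_cluster, 0, libsize_lognorm_sigma)
      mu <- outer(mu_gene, L)
      counts[, idx] <- rcounts(length(mu), mu, dispersion)
    }
  }
  cm <- count_matrix(counts, gene_ids, cell_ids)
  cells <- as_cell_annotation(data.frame(
    cell_id = cell_ids, time_point = "t0", cluster = cl_lab,
    condition = cond_lab, stringsAsFactors = FALSE), time_levels = "t0")
  genes <- data.frame(
    gene_id = gene_ids,
    is_mitochondrial = FALSE, is_housekeeping = grepl("^bg", gene_ids),
    is_tf = FALSE,
    is_ligand = gene_ids %in% lig_ids,
    is_receptor = gene_ids %in% rec_ids,
    stringsAsFactors = FALSE)
  class(genes) <- c("GeneAnnotation", "data.frame")
  pairs <- data.frame(ligand = lig_ids, receptor = rec_ids,
                      fold = folds, stringsAsFactors = FALSE)
  list(counts = cm, cells = cells, genes = genes, pairs = pairs)
}
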