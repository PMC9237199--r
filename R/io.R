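#' Read a UMI count matrix
#'
#' Two on-disk layouts are supported: MatrixMarket coordinate format with
#' companion identifier files (\code{genes.tsv}, \code{barcodes.tsv}, one id
#' per line, in the same directory or given explicitly), and dense TSV with
#' gene ids in the first column and a header row of cell ids. The in-memory
#' orientation is always genes x cells; set \code{transpose = TRUE} when the
#' file stores cells as rows.
#'
#' @param path file (MTX or TSV) to read.
#' @param format \code{"mtx"} or \code{"dense_tsv"}; inferred from the file
#'   extension by default.
#' @param genes_path,cells_path identifier files for the MTX layout; default
#'   \code{genes.tsv} / \code{barcodes.tsv} next to \code{path}.
#' @param transpose set TRUE if the on-disk matrix is cells x genes.
#' @return a \code{\link{count_matrix}}.
#' @export
read_count_matrix <- function(path, format = c("auto", "mtx", "dense_tsv"),
                              genes_path = NULL, cells_path = NULL,
                              transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense_tsv"
  if (format == "mtx") {
    if (is.null(genes_path)) genes_path <- file.path(dirname(path), "genes.tsv")
    if (is.null(cells_path)) cells_path <- file.path(dirname(path), "barcodes.tsv")
    for (p in c(genes_path, cells_path))
      if (!file.exists(p)) stop("missing identifier file: ", p)
    v <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MTX header in ", path,
                                           ": ", conditionMessage(e)))
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = NA,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("malformed dense TSV (need id column + data): ", path)
    genes <- as.character(tab[[1L]])
    v <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(v)) stop("non-numeric entry in ", path)
    cells <- colnames(tab)[-1L]
  }
  if (transpose) {
    v <- Matrix::t(v)
    tmp <- genes; genes <- cells; cells <- tmp
  }
  count_matrix(v, genes, cells)
}

#' Write a count matrix
#'
#' @param m a \code{CountMatrix}.
#' @param path output file; \code{.mtx} writes MatrixMarket plus
#'   \code{genes.tsv}/\code{barcodes.tsv} beside it, anything else a dense TSV.
#' @param format as in \code{\link{read_count_matrix}}.
#' @return invisibly, \code{path}.
#' @export
write_count_matrix <- function(m, path, format = c("auto", "mtx", "dense_tsv")) {
  stopifnot(inherits(m, "CountMatrix"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense_tsv"
  if (format == "mtx") {
    v <- methods::as(methods::as(m$values, "CsparseMatrix"), "generalMatrix")
    v <- methods::as(v, "dMatrix")
    dimnames(v) <- NULL
    Matrix::writeMM(v, path)
    writeLines(m$gene_ids, file.path(dirname(path), "genes.tsv"))
    writeLines(m$cell_ids, file.path(dirname(path), "barcodes.tsv"))
  } else {
    tab <- data.frame(gene_id = m$gene_ids,
                      as.matrix(m$values), check.names = FALSE)
    colnames(tab) <- c("gene_id", m$cell_ids)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a cell annotation table
#'
#' TSV with header; requires columns \code{cell_id}, \code{time_point},
#' \code{cluster}, \code{condition}. \code{time_point} becomes an ordered
#' factor whose level order must be supplied (or is taken from first
#' appearance, with a message) because sampling-time labels such as P1 < P4 <
#' P14 do not sort lexically. Unknown columns are preserved as character.
#'
#' @param path TSV file.
#' @param time_levels explicit total order of time-point labels.
#' @return data.frame of class \code{c("CellAnnotation","data.frame")}.
#' @export
read_cell_annotation <- function(path, time_levels = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  req <- c("cell_id", "time_point", "cluster", "condition")
  miss <- setdiff(req, colnames(tab))
  if (length(miss)) stop("missing required column: ", miss[1L])
  if (anyDuplicated(tab$cell_id))
    stop("cell_id not unique: ", tab$cell_id[duplicated(tab$cell_id)][1L])
  as_cell_annotation(tab, time_levels)
}

#' Coerce a data.frame to a CellAnnotation
#' @param tab data.frame with the required columns.
#' @param time_levels explicit time-point order; default = first appearance.
#' @export
as_cell_annotation <- function(tab, time_levels = NULL) {
  if (is.null(time_levels)) time_levels <- unique(tab$time_point)
  unknown <- setdiff(unique(tab$time_point), time_levels)
  if (length(unknown)) stop("time_point not in declared levels: ", unknown[1L])
  tab$time_point <- factor(tab$time_point, levels = time_levels, ordered = TRUE)
  class(tab) <- c("CellAnnotation", "data.frame")
  tab
}

#' Read a gene annotation table
#'
#' TSV with header; requires \code{gene_id} plus boolean flag columns
#' \code{is_mitochondrial}, \code{is_housekeeping}, \code{is_tf},
#' \code{is_ligand}, \code{is_receptor} (TRUE/FALSE or 0/1).
#'
#' @param path TSV file.
#' @return data.frame of class \code{c("GeneAnnotation","data.frame")}.
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("gene_id", "is_mitochondrial", "is_housekeeping", "is_tf",
           "is_ligand", "is_receptor")
  miss <- setdiff(req, colnames(tab))
  if (length(miss)) stop("missing required column: ", miss[1L])
  if (anyDuplicated(tab$gene_id))
    stop("gene_id not unique: ", tab$gene_id[duplicated(tab$gene_id)][1L])
  for (col in req[-1L]) tab[[col]] <- as.logical(tab[[col]])
  class(tab) <- c("GeneAnnotation", "data.frame")
  tab
}

#' Write an annotation table as TSV
#' @param ann a data.frame (cell or gene annotation).
#' @param path output file.
#' @export
write_annotation <- function(ann, path) {
  out <- as.data.frame(ann)
  if ("time_point" %in% colnames(out))
    out$time_point <- as.character(out$time_point)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ligand-receptor pair list
#'
#' TSV with header; requires columns \code{ligand} and \code{receptor}.
#' @param path TSV file.
#' @return data.frame with ligand/receptor character columns.
#' @export
read_lr_pairs <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("ligand", "receptor"), colnames(tab))
  if (length(miss)) stop("missing required column: ", miss[1L])
  tab
}
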