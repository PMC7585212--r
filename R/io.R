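#' Read a count matrix
#'
#' Reads MatrixMarket (10x layout: genes x cells on disk with companion
#' genes/barcodes files, transposed on load to the internal cells x genes
#' orientation) or dense CSV/TSV (cells in rows, genes in columns, header =
#' gene ids).  Counts must be nonnegative integers.
#'
#' @param path path to the \code{.mtx} or delimited file.
#' @param format one of \code{"mtx"}, \code{"csv"}, \code{"tsv"}; guessed
#'   from the extension by default.
#' @param genes,barcodes companion files for MTX input (defaults:
#'   \code{genes.tsv} / \code{barcodes.tsv} next to the matrix; optional).
#' @param transpose for MTX: whether the on-disk matrix is genes x cells
#'   (default TRUE, the 10x convention).
#' @return dense integer matrix, cells x genes, with dimnames when known.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        genes = NULL, barcodes = NULL, transpose = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("count file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format == "mtx") {
    M <- as.matrix(Matrix::readMM(path))
    if (transpose) M <- t(M)
    gpath <- if (!is.null(genes)) genes else
      file.path(dirname(path), "genes.tsv")
    bpath <- if (!is.null(barcodes)) barcodes else
      file.path(dirname(path), "barcodes.tsv")
    if (file.exists(gpath)) {
      g <- utils::read.delim(gpath, header = FALSE)[[1L]]
      if (length(g) != ncol(M))
        stop("gene file has ", length(g), " entries for ", ncol(M), " genes")
      colnames(M) <- as.character(g)
    }
    if (file.exists(bpath)) {
      b <- utils::read.delim(bpath, header = FALSE)[[1L]]
      if (length(b) != nrow(M))
        stop("barcode file has ", length(b), " entries for ", nrow(M), " cells")
      rownames(M) <- as.character(b)
    }
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE)
    M <- as.matrix(df)
    if (!is.numeric(M)) stop("non-numeric entries in count file")
  }
  if (any(M < 0)) stop("negative entries in count matrix")
  storage.mode(M) <- "double"
  M
}

#' Read per-cell cluster labels
#'
#' One label per line (or first column of a delimited file), in the same
#' cell order as the count matrix.  Labels are mapped to stable integer
#' codes (sorted label order) with the codebook attached.
#'
#' @param path label file.
#' @param n_cells optional expected length; mismatch is an error.
#' @return integer vector of codes with attributes \code{labels} (original
#'   strings) and \code{codebook} (named code map).
#' @export
read_labels <- function(path, n_cells = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE,
                           colClasses = "character")[[1L]]
  if (!is.null(n_cells) && length(raw) != n_cells)
    stop("label file has ", length(raw), " entries but the matrix has ",
         n_cells, " cells")
  lev <- sort(unique(raw))
  codes <- match(raw, lev)
  attr(codes, "labels") <- raw
  attr(codes, "codebook") <- stats::setNames(seq_along(lev), lev)
  codes
}

#' Write marker files for a fit
#'
#' Writes one TSV per cluster (cluster, gene, coefficient, rank within the
#' cluster), a union TSV, and a JSON manifest recording s and the package
#' version.  Output ordering is deterministic, so reruns are byte-identical.
#'
#' @param fit a \code{"rankcorr"} fit.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_markers <- function(fit, out_dir) {
  stopifnot(inherits(fit, "rankcorr"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in names(fit$per_cluster)) {
    z <- fit$per_cluster[[k]]
    tab <- data.frame(cluster = k, gene = z$gene_ids,
                      coefficient = z$coefficients,
                      rank = seq_along(z$gene_ids))
    p <- file.path(out_dir, paste0("markers_cluster_", k, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  pu <- file.path(out_dir, "markers_union.tsv")
  utils::write.table(data.frame(gene = fit$union), pu, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pm <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(s = fit$s,
                            n_clusters = length(fit$classes),
                            n_markers_union = length(fit$union),
                            package_version =
                              as.character(utils::packageVersion("rankcorr"))),
                       pm, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pu, pm))
}

#' Read marker files back into per-cluster lists
#'
#' Inverse of \code{\link{write_markers}} for round-trip checks.
#'
#' @param out_dir directory written by \code{\link{write_markers}}.
#' @return list with \code{per_cluster} (named list of data.frames),
#'   \code{union} (character vector) and \code{manifest}.
#' @export
read_markers <- function(out_dir) {
  files <- sort(list.files(out_dir, pattern = "^markers_cluster_.*\\.tsv$",
                           full.names = TRUE))
  per <- lapply(files, utils::read.delim, colClasses = c(
    cluster = "character", gene = "character", coefficient = "numeric",
    rank = "integer"))
  names(per) <- sub("^markers_cluster_(.*)\\.tsv$", "\\1", basename(files))
  union <- utils::read.delim(file.path(out_dir, "markers_union.tsv"),
                             colClasses = "character")$gene
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  list(per_cluster = per, union = union, manifest = manifest)
}

#' Write a simulated dataset to disk
#'
#' Counts as MatrixMarket (genes x cells, the 10x on-disk convention) with
#' genes/barcodes TSVs, group labels as one label per line (the
#' \code{\link{read_labels}} format), DE ground truth as TSV, and the
#' configuration as JSON.
#'
#' @param sim a \code{"synthetic_dataset"}.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "synthetic_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(out_dir, "matrix.mtx")
  Matrix::writeMM(Matrix::Matrix(t(sim$counts), sparse = TRUE), mtx)
  writeLines(colnames(sim$counts), file.path(out_dir, "genes.tsv"))
  writeLines(rownames(sim$counts), file.path(out_dir, "barcodes.tsv"))
  writeLines(as.character(sim$group), file.path(out_dir, "labels.tsv"))
  utils::write.table(data.frame(gene = colnames(sim$counts),
                                de_flag = sim$de_flag,
                                de_factor = sim$de_factor),
                     file.path(out_dir, "de_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(out_dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                                 "labels.tsv", "de_truth.tsv", "config.json")))
}
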