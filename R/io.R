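#' Read a MatrixMarket count bundle
#'
#' Loads `matrix.mtx` with its `barcodes.tsv` (cell ids) and `genes.tsv`
#' (gene ids) sidecars, as written by droplet pipelines or by
#' [write_sim_dataset()].  Orientation (genes-as-rows versus
#' cells-as-rows) is autodetected from the sidecar lengths; use
#' `orientation` when the matrix is square.
#'
#' @param dir directory holding the three files, or `NULL` when the
#'   individual paths are given.
#' @param mtx,barcodes,genes individual file paths (override `dir`).
#' @param orientation `"auto"`, `"genes_rows"`, or `"cells_rows"`.
#' @param batch optional path to a batch-label TSV (see
#'   [read_batch_labels()]).
#' @return a `count_matrix` (cells as rows).
#' @export
read_counts_mtx <- function(dir = NULL, mtx = file.path(dir, "matrix.mtx"),
                            barcodes = file.path(dir, "barcodes.tsv"),
                            genes = file.path(dir, "genes.tsv"),
                            orientation = c("auto", "genes_rows", "cells_rows"),
                            batch = NULL) {
  orientation <- match.arg(orientation)
  for (f in c(mtx, barcodes, genes)) {
    check_that(file.exists(f), "file not found: ", f)
  }
  m <- Matrix::readMM(mtx)
  cell_ids <- readLines(barcodes)
  # sidecars may carry extra annotation columns; the id is the first field
  gene_ids <- vapply(strsplit(readLines(genes), "\t"), `[[`, "", 1L)
  if (orientation == "auto") {
    orientation <- if (nrow(m) == length(gene_ids) &&
                       ncol(m) == length(cell_ids)) "genes_rows"
      else if (nrow(m) == length(cell_ids) &&
               ncol(m) == length(gene_ids)) "cells_rows"
      else stop("matrix is ", nrow(m), " x ", ncol(m), " but sidecars have ",
                length(cell_ids), " barcodes and ", length(gene_ids),
                " genes", call. = FALSE)
  }
  if (orientation == "genes_rows") m <- Matrix::t(m)
  cm <- count_matrix(as.matrix(m), cell_ids, gene_ids)
  if (!is.null(batch)) {
    cm$batch_labels <- read_batch_labels(batch, cell_ids)
  }
  cm
}

#' Read a dense delimited count matrix
#'
#' Expects a header row of gene identifiers and a first column of cell
#' identifiers; the delimiter is inferred from the file extension
#' (`.csv` versus `.tsv`/`.txt`) unless given.
#'
#' @param path file path.
#' @param sep field delimiter; inferred when `NULL`.
#' @param batch optional path to a batch-label TSV.
#' @return a `count_matrix`.
#' @export
read_counts_csv <- function(path, sep = NULL, batch = NULL) {
  check_that(file.exists(path), "file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  cell_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  cm <- count_matrix(m, cell_ids, colnames(df)[-1L])
  if (!is.null(batch)) cm$batch_labels <- read_batch_labels(batch, cell_ids)
  cm
}

#' Read per-cell batch labels
#'
#' Two-column TSV (`cell_id`, `batch`), with or without a header.  Labels
#' are matched to `cell_ids` by identifier, so file order need not match
#' matrix order; every cell must be present exactly once.
#'
#' @param path TSV path.
#' @param cell_ids cell identifiers of the target matrix.
#' @return character vector of batch labels aligned with `cell_ids`.
#' @export
read_batch_labels <- function(path, cell_ids) {
  check_that(file.exists(path), "file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) > 0 && identical(tolower(df[1, 1]), "cell_id")) {
    df <- df[-1L, , drop = FALSE]
  }
  check_that(ncol(df) >= 2, "batch file must have two columns: cell_id, batch")
  idx <- match(cell_ids, df[[1L]])
  if (anyNA(idx)) {
    stop("batch labels missing for cell(s): ",
         paste(utils::head(cell_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  as.character(df[[2L]][idx])
}

#' Write a processed expression matrix as TSV
#'
#' @param x an `expr_matrix`.
#' @param path output TSV (first column `cell_id`, then one column per
#'   retained gene).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  check_that(inherits(x, "expr_matrix"), "`x` must be an expr_matrix")
  df <- data.frame(cell_id = rownames(x$values), x$values,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Write a gene mask as a single-column TSV
#'
#' @param mask named logical vector over genes.
#' @param path output path; one selected gene id per line.
#' @return `path`, invisibly.
#' @export
write_gene_mask <- function(mask, path) {
  writeLines(names(mask)[mask], path)
  invisible(path)
}
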