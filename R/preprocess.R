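#' Construct a validated cells-by-genes count matrix
#'
#' The package's raw-data container: non-negative integer UMI counts with
#' unique cell and gene identifiers and optional per-cell batch labels.
#'
#' @param counts numeric matrix (base or `Matrix` sparse), cells as rows.
#' @param cell_ids,gene_ids unique identifier vectors matching the matrix
#'   dimensions; taken from `dimnames(counts)` when omitted.
#' @param batch_labels optional per-cell batch factor/character vector.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts), batch_labels = NULL) {
  dense <- as.matrix(counts)
  check_that(all(dense >= 0), "counts must be non-negative")
  check_that(max(abs(dense - round(dense))) < 1e-8,
             "counts must be integers (UMI counts)")
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%04d", seq_len(nrow(dense)))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%03d", seq_len(ncol(dense)))
  check_that(length(cell_ids) == nrow(dense),
             "cell_ids length (", length(cell_ids),
             ") != number of rows (", nrow(dense), ")")
  check_that(length(gene_ids) == ncol(dense),
             "gene_ids length (", length(gene_ids),
             ") != number of columns (", ncol(dense), ")")
  check_that(!anyDuplicated(cell_ids), "cell_ids must be unique")
  check_that(!anyDuplicated(gene_ids), "gene_ids must be unique")
  if (!is.null(batch_labels)) {
    check_that(length(batch_labels) == nrow(dense),
               "batch_labels length (", length(batch_labels),
               ") != number of cells (", nrow(dense), ")")
    batch_labels <- as.character(batch_labels)
  }
  dimnames(dense) <- list(cell_ids, gene_ids)
  structure(list(counts = dense, cell_ids = cell_ids, gene_ids = gene_ids,
                 batch_labels = batch_labels),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$batch_labels)) ""
              else sprintf(", %d batches", length(unique(x$batch_labels)))))
  invisible(x)
}

#' Drop cells with too few total counts
#'
#' Load-time quality filter: removes cells whose total UMI count is below
#' `min_counts` (default 1, i.e. only empty cells).  Downstream
#' normalization requires every cell total to be positive and refuses to
#' run otherwise, so this filter is the supported way to handle empty
#' barcodes.
#'
#' @param x a `count_matrix`.
#' @param min_counts minimum total UMI count a cell must have to be kept.
#' @return a filtered `count_matrix`; a message reports removals.
#' @export
filter_cells <- function(x, min_counts = 1) {
  check_that(inherits(x, "count_matrix"), "`x` must be a count_matrix")
  totals <- rowSums(x$counts)
  keep <- totals >= min_counts
  if (!all(keep)) {
    message(sum(!keep), " cell(s) below ", min_counts,
            " total counts removed: ",
            paste(utils::head(x$cell_ids[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ..." else "")
  }
  count_matrix(x$counts[keep, , drop = FALSE],
               x$cell_ids[keep], x$gene_ids,
               if (is.null(x$batch_labels)) NULL else x$batch_labels[keep])
}

new_expr_matrix <- function(values, gene_mask, steps, batch_labels = NULL) {
  structure(list(values = values, gene_mask = gene_mask, steps = steps,
                 batch_labels = batch_labels),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d cells x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), paste(x$steps, collapse = " -> ")))
  invisible(x)
}

#' Library-size normalization and log transform
#'
#' Divides each cell's counts by its total UMI count, multiplies by
#' `scale` (10,000 by default, counts-per-ten-thousand), and applies the
#' natural log with a pseudo-count of one: entry `(i, g)` becomes
#' `ln(1 + counts[i, g] / total_i * scale)`.  No gene standardization is
#' performed here.
#'
#' @param x a `count_matrix` with every cell total positive (see
#'   [filter_cells()]).
#' @param scale library-size scale factor.
#' @return an `expr_matrix` carrying the full gene set and the batch
#'   labels of `x`.
#' @examples
#' cm <- count_matrix(matrix(c(1, 0, 2, 3), 2, 2))
#' normalize_cells(cm)$values
#' @export
normalize_cells <- function(x, scale = 1e4) {
  check_that(inherits(x, "count_matrix"), "`x` must be a count_matrix")
  check_that(scale > 0, "`scale` must be positive")
  totals <- rowSums(x$counts)
  if (any(totals <= 0)) {
    bad <- x$cell_ids[totals <= 0]
    stop("cell(s) with zero total counts: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "",
         " — run filter_cells() first", call. = FALSE)
  }
  vals <- log1p(x$counts / totals * scale)
  mask <- stats::setNames(rep(TRUE, ncol(vals)), x$gene_ids)
  new_expr_matrix(vals, mask, sprintf("normalize(scale=%g)+log1p", scale),
                  x$batch_labels)
}

#' Select highly variable genes by binned dispersion
#'
#' Operates on the cell-normalized, log-transformed (not yet standardized)
#' matrix.  Statistics follow the classic dispersion filter: the log
#' transform is undone, per-gene mean and dispersion (variance / mean)
#' are computed on the normalized linear scale, genes are binned by mean
#' expression (log scale) into `n_bins` equal-width bins, log-dispersions
#' are z-scored within each bin, and the `n_top` genes with the highest
#' normalized dispersion are selected.  Genes with zero variance are
#' never selected while any positive-dispersion gene remains; bins
#' holding a single gene (or with zero dispersion spread) get z-score 0.
#'
#' @param x an `expr_matrix` straight from [normalize_cells()].
#' @param n_top number of genes to keep (must not exceed gene count).
#' @param n_bins number of mean-expression bins.
#' @return a named logical gene mask over the genes of `x`.
#' @export
select_hvg <- function(x, n_top, n_bins = 20) {
  check_that(inherits(x, "expr_matrix"), "`x` must be an expr_matrix")
  p <- ncol(x$values)
  check_that(n_top >= 1 && n_top <= p,
             "`n_top` must be between 1 and the number of genes (", p, ")")
  linear <- expm1(x$values)
  mu <- colMeans(linear)
  v <- apply(linear, 2, stats::var)
  disp <- ifelse(mu > 0 & v > 0, v / mu, 0)
  log_disp <- ifelse(disp > 0, log(disp), -Inf)
  bins <- cut(log1p(mu), breaks = n_bins, include.lowest = TRUE)
  z <- numeric(p)
  for (b in levels(bins)) {
    idx <- which(bins == b)
    pos <- idx[is.finite(log_disp[idx])]
    if (length(pos) == 0L) next
    s <- stats::sd(log_disp[pos])
    if (length(pos) < 2L || !is.finite(s) || s == 0) {
      # a lone (or spread-less) gene in its expression stratum is itself
      # the evidence of high dispersion: keep its raw log-dispersion
      z[pos] <- log_disp[pos]
    } else {
      z[pos] <- (log_disp[pos] - mean(log_disp[pos])) / s
    }
  }
  z[v == 0] <- -Inf   # flat genes carry no signal
  sel <- order(z, seq_len(p), decreasing = c(TRUE, FALSE), method = "radix")
  mask <- stats::setNames(logical(p), colnames(x$values))
  mask[sel[seq_len(n_top)]] <- TRUE
  mask
}

#' Z-score genes, optionally within batches
#'
#' Standardizes every gene to mean 0 and standard deviation 1 across
#' cells — across all cells when `batch_labels` is `NULL`, otherwise
#' across the cells of each batch separately (so each gene has mean 0 and
#' sd 1 *within every batch*, which removes additive and scale batch
#' differences at the gene level).  Genes with zero variance in scope are
#' set to zero rather than NaN.
#'
#' @param x an `expr_matrix` (already cell-normalized and logged).
#' @param batch_labels optional per-cell batch labels; defaults to the
#'   labels carried by `x` (pass `NULL` explicitly for pooled scaling).
#' @return an `expr_matrix` with standardized values.
#' @export
standardize_genes <- function(x, batch_labels) {
  check_that(inherits(x, "expr_matrix"), "`x` must be an expr_matrix")
  if (missing(batch_labels)) batch_labels <- x$batch_labels
  vals <- x$values
  if (is.null(batch_labels)) {
    vals <- scale_zero_safe(vals)
    step <- "standardize(pooled)"
  } else {
    check_that(length(batch_labels) == nrow(vals),
               "batch_labels length (", length(batch_labels),
               ") != number of cells (", nrow(vals), ")")
    for (b in unique(batch_labels)) {
      rows <- which(batch_labels == b)
      vals[rows, ] <- scale_zero_safe(vals[rows, , drop = FALSE])
    }
    step <- "standardize(per-batch)"
  }
  new_expr_matrix(vals, x$gene_mask, c(x$steps, step), batch_labels)
}

# column z-scoring with a zero-variance guard
scale_zero_safe <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  out <- sweep(m, 2, mu, "-")
  pos <- s > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2, s[pos], "/")
  out[, !pos] <- 0
  out
}

#' Full preprocessing pipeline
#'
#' Cell filter, library-size normalization with log transform, highly
#' variable gene selection, then gene standardization — in that fixed
#' order (selection uses the normalized but unstandardized scale).
#'
#' @param x a `count_matrix`.
#' @param n_top number of highly variable genes to keep; `NULL` keeps all.
#' @param scale library-size scale factor for [normalize_cells()].
#' @param n_bins dispersion bins for [select_hvg()].
#' @param min_counts cell filter threshold for [filter_cells()].
#' @param per_batch if `TRUE` (default) and batch labels are present,
#'   standardization is performed within each batch; gene selection always
#'   uses pooled statistics.
#' @return an `expr_matrix` restricted to the selected genes, with
#'   `gene_mask` recording the selection over the original gene set.
#' @export
preprocess_counts <- function(x, n_top = NULL, scale = 1e4, n_bins = 20,
                              min_counts = 1, per_batch = TRUE) {
  x <- filter_cells(x, min_counts)
  norm <- normalize_cells(x, scale)
  if (is.null(n_top)) {
    mask <- stats::setNames(rep(TRUE, ncol(norm$values)), x$gene_ids)
  } else {
    mask <- select_hvg(norm, n_top, n_bins)
  }
  sub <- new_expr_matrix(norm$values[, mask, drop = FALSE], mask,
                         c(norm$steps, sprintf("hvg(n=%d)", sum(mask))),
                         norm$batch_labels)
  standardize_genes(sub, if (per_batch) sub$batch_labels else NULL)
}
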