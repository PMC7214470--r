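#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same cells,
#' computed from the contingency table `n[j, j']` with row margins `a_j`
#' and column margins `b_j'`:
#' `ARI = (S - E) / (0.5 * (Sa + Sb) - E)` where
#' `S = sum choose(n[j, j'], 2)`, `Sa = sum choose(a_j, 2)`,
#' `Sb = sum choose(b_j', 2)` and `E = Sa * Sb / choose(n, 2)`.
#' Symmetric in its arguments and invariant to label renaming; 1 means
#' identical partitions, 0 is the chance level.
#'
#' @param labels_a,labels_b equal-length label vectors (any type usable
#'   as a factor), `n >= 2`.
#' @return a scalar in [-1, 1].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))          # -0.5
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  check_that(length(labels_a) == length(labels_b),
             "label vectors differ in length (", length(labels_a), " vs ",
             length(labels_b), ")")
  n <- length(labels_a)
  check_that(n >= 2, "need at least 2 observations")
  tab <- table(labels_a, labels_b)
  s <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1)   # both partitions trivial and identical
  (s - expected) / denom
}

#' Batch-mixing KL divergence
#'
#' Measures how well cells from different batches are mixed in an
#' embedding.  Per repeat, `n_regions` cells are sampled uniformly
#' without replacement; around each, the `k_neighbors` nearest cells
#' (Euclidean distance, ties broken by cell index, the query cell itself
#' excluded by default) define a region, and the regional KL divergence
#' `sum_b p_b log(p_b / q_b)` compares the region's batch proportions
#' `p_b` with the global proportions `q_b` (`0 log 0 = 0`).  The repeat's
#' value is the mean over its regions; all `repeats` values are returned.
#' 0 means perfect mixing; the upper bound for fully separated equal
#' batches is `log(B)`.
#'
#' @param z embedding or corrected-expression matrix (cells x d).
#' @param batch_labels per-cell batch labels, at least 2 batches, each
#'   with at least one cell.
#' @param n_regions sampled region centres per repeat.
#' @param k_neighbors neighbourhood size; default `5 * number of batches`.
#' @param repeats number of independent repeats.
#' @param seed RNG seed for region sampling.
#' @param include_self count the query cell as part of its own region.
#' @return an object of class `metric_report`: `kl` (one value per
#'   repeat), `median`, `iqr`, and the sampling parameters.
#' @export
batch_mixing_kl <- function(z, batch_labels, n_regions = 100,
                            k_neighbors = NULL, repeats = 200, seed = 1L,
                            include_self = FALSE) {
  z <- as.matrix(z)
  n <- nrow(z)
  check_that(length(batch_labels) == n,
             "batch_labels length (", length(batch_labels),
             ") != number of cells (", n, ")")
  # keep caller-declared factor levels so empty batches are caught
  batch <- if (is.factor(batch_labels)) batch_labels else factor(batch_labels)
  counts <- table(batch)
  check_that(nlevels(batch) >= 2, "need at least 2 batches")
  if (any(counts == 0)) {
    stop("batch(es) with zero cells: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  b_levels <- nlevels(batch)
  if (is.null(k_neighbors)) k_neighbors <- 5L * b_levels
  check_that(k_neighbors >= 1 && k_neighbors < n,
             "`k_neighbors` must be in [1, n)")
  check_that(n_regions >= 1 && n_regions <= n,
             "`n_regions` must be in [1, n]")
  q_global <- as.numeric(counts) / n
  batch_int <- as.integer(batch)

  kl_vals <- with_seed(derive_seed(seed, "batch-kl"), {
    vapply(seq_len(repeats), function(r) {
      centers <- sample.int(n, n_regions)
      d2 <- sq_dist(z[centers, , drop = FALSE], z)
      mean(vapply(seq_len(n_regions), function(i) {
        row <- d2[i, ]
        ord <- order(row, seq_len(n))
        if (!include_self) ord <- ord[ord != centers[i]]
        nb <- batch_int[ord[seq_len(k_neighbors)]]
        p_b <- tabulate(nb, nbins = b_levels) / k_neighbors
        pos <- p_b > 0
        sum(p_b[pos] * log(p_b[pos] / q_global[pos]))
      }, numeric(1)))
    }, numeric(1))
  })
  structure(list(kl = kl_vals,
                 median = stats::median(kl_vals),
                 iqr = stats::IQR(kl_vals),
                 params = list(n_regions = n_regions,
                               k_neighbors = k_neighbors,
                               repeats = repeats, seed = seed,
                               include_self = include_self,
                               n_batches = b_levels)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("batch-mixing KL: median %.4f (IQR %.4f) over %d ",
                     "repeats of %d regions, k = %d\n"),
              x$median, x$iqr, x$params$repeats, x$params$n_regions,
              x$params$k_neighbors))
  invisible(x)
}

#' Per-cluster batch-mixing KL divergence
#'
#' Runs [batch_mixing_kl()] separately on the cells of each cluster,
#' which distinguishes technical mixing from biology that is confounded
#' with batch: a cluster whose batches remain separated while the others
#' mix carries a batch-specific biological signal.
#'
#' @param z embedding matrix.
#' @param batch_labels per-cell batch labels.
#' @param cluster_labels per-cell cluster labels.
#' @param n_regions,k_neighbors,repeats,seed as in [batch_mixing_kl()];
#'   `n_regions` is capped at each cluster's size.
#' @return named numeric vector of median KL per cluster (NA for
#'   clusters containing a single batch).
#' @export
per_cluster_batch_kl <- function(z, batch_labels, cluster_labels,
                                 n_regions = 100, k_neighbors = NULL,
                                 repeats = 50, seed = 1L) {
  z <- as.matrix(z)
  check_that(length(cluster_labels) == nrow(z),
             "cluster_labels length != number of cells")
  cl <- sort(unique(cluster_labels))
  out <- vapply(cl, function(c) {
    idx <- which(cluster_labels == c)
    b <- batch_labels[idx]
    if (length(unique(b)) < 2 || length(idx) <= max(2, k_neighbors %||% 10)) {
      return(NA_real_)
    }
    rep <- batch_mixing_kl(z[idx, , drop = FALSE], b,
                           n_regions = min(n_regions, length(idx)),
                           k_neighbors = k_neighbors, repeats = repeats,
                           seed = seed)
    rep$median
  }, numeric(1))
  names(out) <- as.character(cl)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
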