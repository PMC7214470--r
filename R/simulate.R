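#' Simulation configuration for UMI-like count data
#'
#' Builds the parameter set for [simulate_counts()].  Counts are drawn from
#' a negative-binomial model in which the expected count of gene `g` in
#' cell `i` (member of cluster `c` and batch `b`) factorizes as
#' `lib_i * m[c, g] * f[b, g]`: a log-normal library-size factor, a
#' cluster-specific mean profile, and a gene-wise multiplicative batch
#' factor.  Cluster identity is encoded by disjoint blocks of marker genes
#' whose means are raised `fold_change`-fold in their cluster; batch
#' distortion strength is controlled by a single knob, `sigma_batch`, the
#' standard deviation of the log batch factors.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes.
#' @param k_clusters number of planted clusters.
#' @param proportions cluster mixing proportions (length `k_clusters`,
#'   sums to 1). Default: equal.
#' @param n_batches number of batches.
#' @param batch_proportions batch proportions (length `n_batches`, sums
#'   to 1). Default: equal.
#' @param n_markers number of marker genes per cluster (disjoint blocks).
#' @param fold_change fold increase of marker-gene means in their cluster.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline gene means.
#' @param sigma_batch standard deviation of log-normal gene-wise batch
#'   factors; 0 means exchangeable batches.
#' @param lib_meanlog,lib_sdlog log-normal parameters of cell library-size
#'   factors.
#' @param theta negative-binomial dispersion (`size` in [stats::rnbinom()]);
#'   variance is `mu + mu^2 / theta`.
#' @param shift optional confounded-condition shift: a list with elements
#'   `cluster`, `batch`, `n_genes`, `fold`; cells of that cluster in that
#'   batch get their own extra block of `n_genes` genes raised `fold`-fold,
#'   emulating a biological condition completely confounded with a batch.
#' @param seed master seed for the generator.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [scenario_config()] for ready-made difficulty presets.
#' @export
sim_config <- function(n_cells = 900L, n_genes = 200L, k_clusters = 3L,
                       proportions = NULL, n_batches = 2L,
                       batch_proportions = NULL,
                       n_markers = 10L, fold_change = 6,
                       baseline_meanlog = log(0.5), baseline_sdlog = 1,
                       sigma_batch = 0.15,
                       lib_meanlog = 0, lib_sdlog = 0.3,
                       theta = 10, shift = NULL, seed = 1L) {
  if (is.null(proportions)) proportions <- rep(1 / k_clusters, k_clusters)
  if (is.null(batch_proportions)) {
    batch_proportions <- rep(1 / n_batches, n_batches)
  }
  check_that(length(proportions) == k_clusters &&
               abs(sum(proportions) - 1) < 1e-8 && all(proportions > 0),
             "`proportions` must be ", k_clusters,
             " positive values summing to 1")
  check_that(length(batch_proportions) == n_batches &&
               abs(sum(batch_proportions) - 1) < 1e-8 &&
               all(batch_proportions > 0),
             "`batch_proportions` must be ", n_batches,
             " positive values summing to 1")
  check_that(sigma_batch >= 0, "`sigma_batch` must be >= 0")
  check_that(theta > 0, "`theta` must be > 0")
  check_that(k_clusters >= 1 && n_batches >= 1, "need >= 1 cluster and batch")
  n_shift <- if (is.null(shift)) 0L else shift$n_genes
  check_that(k_clusters * n_markers + n_shift <= n_genes,
             "not enough genes for the requested marker/shift blocks")
  if (!is.null(shift)) {
    check_that(all(c("cluster", "batch", "n_genes", "fold") %in% names(shift)),
               "`shift` needs elements cluster, batch, n_genes, fold")
    check_that(shift$cluster <= k_clusters && shift$batch <= n_batches,
               "`shift` refers to a cluster or batch that does not exist")
  }
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    k_clusters = as.integer(k_clusters), proportions = proportions,
    n_batches = as.integer(n_batches), batch_proportions = batch_proportions,
    n_markers = as.integer(n_markers), fold_change = fold_change,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    sigma_batch = sigma_batch,
    lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
    theta = theta, shift = shift, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Difficulty presets for the simulator
#'
#' Three fixed scenarios exercising the clustering pipeline:
#' \describe{
#'   \item{easy}{cluster separation far larger than batch distortion
#'     (900 cells, 200 genes, 3 clusters, 2 batches, `sigma_batch = 0.05`).}
#'   \item{confounded}{one cluster carries a condition-specific expression
#'     shift in one batch only, so for those cells the biological condition
#'     is completely confounded with the batch; all other clusters differ
#'     across batches only by small technical factors.}
#'   \item{hard}{`sigma_batch` comparable to cluster separation — the
#'     regime where technical variation rivals biological variation and
#'     batch-agnostic clustering is expected to degrade.}
#' }
#' Presets are pure functions of their arguments: repeated calls return
#' identical configurations.
#'
#' @param level one of `"easy"`, `"confounded"`, `"hard"`.
#' @param seed master seed stored in the returned config.
#' @return a `sim_config`.
#' @export
scenario_config <- function(level = c("easy", "confounded", "hard"),
                            seed = 1L) {
  level <- match.arg(level)
  switch(level,
    easy = sim_config(n_cells = 900L, n_genes = 200L, k_clusters = 3L,
                      n_batches = 2L, n_markers = 10L, fold_change = 6,
                      sigma_batch = 0.15, seed = seed),
    confounded = sim_config(n_cells = 800L, n_genes = 200L, k_clusters = 4L,
                            n_batches = 2L, n_markers = 10L, fold_change = 6,
                            sigma_batch = 0.15,
                            shift = list(cluster = 1L, batch = 2L,
                                         n_genes = 10L, fold = 6),
                            seed = seed),
    hard = sim_config(n_cells = 900L, n_genes = 200L, k_clusters = 3L,
                      n_batches = 2L, n_markers = 10L, fold_change = 6,
                      sigma_batch = 1, seed = seed)
  )
}

#' Simulate a UMI count matrix with planted clusters and batches
#'
#' Draws a `cells x genes` negative-binomial count matrix under the model
#' described in [sim_config()], together with the ground truth that
#' produced it.  The same configuration (including its seed) always yields
#' a bit-identical dataset.
#'
#' @param cfg a `sim_config`.
#' @return an object of class `sim_dataset`: a list with `counts`
#'   (integer matrix, cells x genes, dimnames set), `cell_ids`, `gene_ids`,
#'   `true_labels` (integer cluster per cell), `batch_labels` (character
#'   per cell), and `truth` (cluster profiles `m`, batch factors `f`,
#'   library sizes `lib`, expected means `mu`, marker indices, config).
#' @examples
#' d <- simulate_counts(sim_config(n_cells = 50, n_genes = 30, seed = 7))
#' dim(d$counts)
#' table(d$true_labels, d$batch_labels)
#' @export
simulate_counts <- function(cfg) {
  check_that(inherits(cfg, "sim_config"), "`cfg` must come from sim_config()")
  n <- cfg$n_cells; g <- cfg$n_genes
  K <- cfg$k_clusters; B <- cfg$n_batches
  with_seed(derive_seed(cfg$seed, "simulate"), {
    baseline <- stats::rlnorm(g, cfg$baseline_meanlog, cfg$baseline_sdlog)
    # cluster profiles: baseline times fold change on each cluster's block
    markers <- lapply(seq_len(K), function(c) {
      if (cfg$n_markers == 0L) integer(0)
      else seq.int((c - 1L) * cfg$n_markers + 1L, c * cfg$n_markers)
    })
    m <- matrix(rep(baseline, each = K), nrow = K, ncol = g)
    for (c in seq_len(K)) m[c, markers[[c]]] <- m[c, markers[[c]]] * cfg$fold_change
    f <- matrix(stats::rlnorm(B * g, 0, cfg$sigma_batch), nrow = B, ncol = g)
    clusters <- sample.int(K, n, replace = TRUE, prob = cfg$proportions)
    batches <- sample.int(B, n, replace = TRUE, prob = cfg$batch_proportions)
    lib <- stats::rlnorm(n, cfg$lib_meanlog, cfg$lib_sdlog)
    mu <- lib * m[clusters, , drop = FALSE] * f[batches, , drop = FALSE]
    shift_genes <- integer(0)
    if (!is.null(cfg$shift)) {
      s <- cfg$shift
      shift_genes <- seq.int(K * cfg$n_markers + 1L,
                             K * cfg$n_markers + s$n_genes)
      hit <- clusters == s$cluster & batches == s$batch
      mu[hit, shift_genes] <- mu[hit, shift_genes] * s$fold
    }
    counts <- matrix(stats::rnbinom(n * g, mu = mu, size = cfg$theta),
                     nrow = n, ncol = g)
    cell_ids <- sprintf("cell_%04d", seq_len(n))
    gene_ids <- sprintf("gene_%03d", seq_len(g))
    dimnames(counts) <- list(cell_ids, gene_ids)
    dimnames(mu) <- dimnames(counts)
    structure(list(
      counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
      true_labels = clusters,
      batch_labels = paste0("batch", batches),
      truth = list(m = m, f = f, lib = lib, mu = mu,
                   markers = markers, shift_genes = shift_genes,
                   config = cfg)
    ), class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(paste0("sim_dataset: %d cells x %d genes, %d clusters, ",
                     "%d batches (sigma_batch = %g, theta = %g)\n"),
              cfg$n_cells, cfg$n_genes, cfg$k_clusters, cfg$n_batches,
              cfg$sigma_batch, cfg$theta))
  invisible(x)
}

#' Write a simulated dataset as an MTX bundle
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket), `barcodes.tsv`,
#' `genes.tsv`, `batches.tsv` (cell_id, batch) and `truth.tsv`
#' (cell_id, cluster), so the dataset round-trips through
#' [read_counts_mtx()] and [read_batch_labels()].
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  check_that(inherits(dataset, "sim_dataset"), "`dataset` must be a sim_dataset")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # genes-as-rows orientation, the droplet-pipeline convention
  mm <- Matrix::Matrix(t(dataset$counts), sparse = TRUE)
  Matrix::writeMM(mm, file.path(dir, "matrix.mtx"))
  writeLines(dataset$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(dataset$gene_ids, file.path(dir, "genes.tsv"))
  write_tsv(data.frame(cell_id = dataset$cell_ids,
                       batch = dataset$batch_labels),
            file.path(dir, "batches.tsv"))
  write_tsv(data.frame(cell_id = dataset$cell_ids,
                       cluster = dataset$true_labels),
            file.path(dir, "truth.tsv"))
  invisible(dir)
}
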