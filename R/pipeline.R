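# End-to-end runners behind the command-line interface.  Each runner is
# an ordinary exported function so the CLI stays a thin argument-parsing
# shim; everything is reproducible from the metadata JSON it writes.

run_config_defaults <- function() {
  list(
    seed = 1L,
    # preprocessing
    n_top = NULL, scale = 1e4, n_bins = 20, min_counts = 1, per_batch = TRUE,
    # clustering
    alpha = 1, tol = 0.005, louvain_resolution = 1, n_neighbors = NULL,
    max_epochs = 300, update_interval = 300, plateau_rel = 1e-4,
    patience = 3, lr = 0.01, momentum = 0.9,
    batch_size = 256, layer_dims = NULL, epochs_per_layer = 300,
    finetune_epochs = 300, kernel = "student_t",
    # simulation
    scenario = "easy", n_cells = NULL, n_genes = NULL, k_clusters = NULL,
    n_batches = NULL, sigma_batch = NULL, fold_change = NULL, theta = NULL,
    # evaluation
    n_regions = 100, k_neighbors = NULL, repeats = 200,
    verbose = FALSE
  )
}

#' Assemble a run configuration
#'
#' Merges, in increasing precedence: package defaults, an optional YAML
#' config file, and direct overrides.  Unknown keys are rejected so that
#' typos cannot silently fall back to defaults.
#'
#' @param path optional YAML file of key-value settings.
#' @param ... direct overrides (e.g. `seed = 7, n_top = 100`).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- run_config_defaults()
  layer <- function(cfg, new, origin) {
    unknown <- setdiff(names(new), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    utils::modifyList(cfg, new)
  }
  if (!is.null(path)) {
    check_that(file.exists(path), "config file not found: ", path)
    cfg <- layer(cfg, yaml::read_yaml(path), path)
  }
  structure(layer(cfg, list(...), "arguments"), class = "run_config")
}

as_dec_config <- function(cfg) {
  dec_config(alpha = cfg$alpha, tol = cfg$tol,
             louvain_resolution = cfg$louvain_resolution,
             n_neighbors = cfg$n_neighbors, max_epochs = cfg$max_epochs,
             update_interval = cfg$update_interval,
             plateau_rel = cfg$plateau_rel, patience = cfg$patience,
             lr = cfg$lr,
             momentum = cfg$momentum, batch_size = cfg$batch_size,
             layer_dims = cfg$layer_dims,
             epochs_per_layer = cfg$epochs_per_layer,
             finetune_epochs = cfg$finetune_epochs, kernel = cfg$kernel,
             seed = cfg$seed)
}

say <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

#' Simulate a dataset and write it to disk
#'
#' @param out_dir output directory for the MTX bundle and label files.
#' @param cfg a [run_config()]; the `scenario` key picks a
#'   [scenario_config()] preset whose fields individual keys
#'   (`n_cells`, `sigma_batch`, ...) may override.
#' @return the `sim_dataset`, invisibly.
#' @export
run_simulate <- function(out_dir, cfg = run_config()) {
  sim <- scenario_config(cfg$scenario, seed = cfg$seed)
  for (key in c("n_cells", "n_genes", "k_clusters", "n_batches",
                "sigma_batch", "fold_change", "theta")) {
    if (!is.null(cfg[[key]])) sim[[key]] <- cfg[[key]]
  }
  d <- simulate_counts(sim)
  write_sim_dataset(d, out_dir)
  write_metadata(file.path(out_dir, "metadata.json"), cfg,
                 list(command = "simulate", n_cells = sim$n_cells,
                      n_genes = sim$n_genes))
  say(cfg, "wrote ", sim$n_cells, " cells x ", sim$n_genes, " genes to ",
      out_dir)
  invisible(d)
}

#' Cluster a count matrix end to end
#'
#' Reads counts (MTX bundle directory or dense CSV/TSV), preprocesses,
#' fits deep embedded clustering, and writes four files to `out_dir`:
#' `assignments.tsv` (cell_id, cluster, max_probability),
#' `probabilities.tsv`, `embedding.tsv`, and `metadata.json`.
#'
#' @param input directory with `matrix.mtx`/`barcodes.tsv`/`genes.tsv`,
#'   or a dense count CSV/TSV file.
#' @param out_dir output directory (created if missing).
#' @param cfg a [run_config()].
#' @param batch optional batch-label TSV; when absent the run is
#'   batch-agnostic.
#' @return the `dec_fit`, invisibly.
#' @export
run_cluster <- function(input, out_dir, cfg = run_config(), batch = NULL) {
  cm <- if (dir.exists(input)) read_counts_mtx(input, batch = batch)
        else read_counts_csv(input, batch = batch)
  say(cfg, "loaded ", nrow(cm$counts), " cells x ", ncol(cm$counts), " genes")
  xp <- preprocess_counts(cm, n_top = cfg$n_top, scale = cfg$scale,
                          n_bins = cfg$n_bins, min_counts = cfg$min_counts,
                          per_batch = cfg$per_batch)
  fit <- dec_fit(xp, as_dec_config(cfg))
  say(cfg, "K = ", fit$k, ", ", fit$epochs_run, " epochs, tol trace: ",
      paste(signif(fit$tol_trace, 3), collapse = " "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ids <- rownames(xp$values)
  write_tsv(data.frame(cell_id = ids, cluster = fit$labels,
                       max_probability = fit$max_prob),
            file.path(out_dir, "assignments.tsv"))
  prob <- as.data.frame(fit$probabilities)
  names(prob) <- paste0("cluster_", seq_len(ncol(prob)))
  write_tsv(cbind(data.frame(cell_id = ids), prob),
            file.path(out_dir, "probabilities.tsv"))
  emb <- as.data.frame(fit$embedding)
  names(emb) <- paste0("dim_", seq_len(ncol(emb)))
  write_tsv(cbind(data.frame(cell_id = ids), emb),
            file.path(out_dir, "embedding.tsv"))
  write_metadata(file.path(out_dir, "metadata.json"), cfg,
                 list(command = "cluster", input = input,
                      k = fit$k, epochs_run = fit$epochs_run,
                      converged = fit$converged,
                      tol_trace = fit$tol_trace))
  invisible(fit)
}

#' Evaluate clustering and batch mixing from files
#'
#' Computes the adjusted Rand index when predicted and reference label
#' files are given, and the batch-mixing KL divergence when an embedding
#' and batch labels are given; writes `kl_repeats.tsv` (one KL value per
#' repeat) and `evaluation.json` to `out_dir`.
#'
#' @param out_dir output directory.
#' @param cfg a [run_config()] (`n_regions`, `k_neighbors`, `repeats`,
#'   `seed`).
#' @param labels,reference TSVs with columns cell_id, cluster; cell ids
#'   must align (matched by id; the first mismatch is reported).
#' @param embedding embedding TSV (cell_id then coordinates).
#' @param batch batch-label TSV.
#' @return list with `ari` and the `metric_report`, invisibly.
#' @export
run_evaluate <- function(out_dir, cfg = run_config(), labels = NULL,
                         reference = NULL, embedding = NULL, batch = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ari <- NULL
  report <- NULL
  if (!is.null(labels) && !is.null(reference)) {
    a <- utils::read.table(labels, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    b <- utils::read.table(reference, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    idx <- match(a[[1L]], b[[1L]])
    if (anyNA(idx)) {
      first <- a[[1L]][which(is.na(idx))[1L]]
      stop("cell id not found in reference labels: ", first, call. = FALSE)
    }
    ari <- adjusted_rand_index(a[[2L]], b[[2L]][idx])
  }
  if (!is.null(embedding) && !is.null(batch)) {
    emb <- utils::read.table(embedding, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    ids <- emb[[1L]]
    z <- as.matrix(emb[, -1L, drop = FALSE])
    bl <- read_batch_labels(batch, ids)
    report <- batch_mixing_kl(z, bl, n_regions = min(cfg$n_regions, nrow(z)),
                              k_neighbors = cfg$k_neighbors,
                              repeats = cfg$repeats, seed = cfg$seed)
    write_tsv(data.frame(repeat_index = seq_along(report$kl),
                         kl = report$kl),
              file.path(out_dir, "kl_repeats.tsv"))
  }
  summary <- list(ari = ari,
                  kl_median = if (is.null(report)) NULL else report$median,
                  kl_iqr = if (is.null(report)) NULL else report$iqr,
                  params = if (is.null(report)) NULL else report$params)
  jsonlite::write_json(Filter(Negate(is.null), summary),
                       file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(ari = ari, report = report))
}

write_metadata <- function(path, cfg, extra) {
  payload <- c(extra, list(
    config = Filter(Negate(is.null), unclass(cfg)),
    package_version = as.character(utils::packageVersion("scdec")),
    r_version = R.version.string
  ))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
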