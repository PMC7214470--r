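# Iterative deep embedded clustering: Louvain initialization, Student-t
# soft assignment, self-training target distribution, and joint SGD over
# encoder weights and centroids under a KL divergence loss.

#' Configuration for deep embedded clustering
#'
#' @param alpha degrees of freedom of the Student-t kernel (default 1).
#' @param tol stopping threshold: training halts at the first target
#'   update where the fraction of cells changing hard assignment is
#'   strictly below `tol` (default 0.005).
#' @param louvain_resolution resolution of the Louvain initialization.
#' @param n_neighbors neighbours for the initialization kNN graph;
#'   `NULL` picks 15 (10 when fewer than 100 cells).
#' @param max_epochs cap on total clustering epochs.
#' @param update_interval epoch cap per self-training iteration: within an
#'   iteration the target distribution P is held fixed and SGD runs until
#'   the KL loss stops decreasing (relative improvement below
#'   `plateau_rel` for `patience` consecutive epochs) or `update_interval`
#'   epochs have elapsed; then P is refreshed and the stopping rule
#'   checked.
#' @param plateau_rel,patience plateau detection for the within-iteration
#'   loss curve.
#' @param lr,momentum,batch_size stochastic-gradient-descent settings for
#'   the clustering phase.
#' @param layer_dims autoencoder widths from input to bottleneck; `NULL`
#'   selects `c(p, 64, 32)` up to 1e5 cells and `c(p, 128, 64, 32)` above.
#' @param epochs_per_layer,finetune_epochs autoencoder training caps.
#' @param kernel similarity kernel; only `"student_t"` is implemented
#'   (`"gaussian"` is reserved).
#' @param seed master seed; fans out to weight initialization, minibatch
#'   shuffling and graph clustering.
#' @return a `dec_config` list.
#' @export
dec_config <- function(alpha = 1, tol = 0.005, louvain_resolution = 1,
                       n_neighbors = NULL, max_epochs = 300,
                       update_interval = 300, plateau_rel = 1e-4,
                       patience = 3, lr = 0.01, momentum = 0.9,
                       batch_size = 256, layer_dims = NULL,
                       epochs_per_layer = 300, finetune_epochs = 300,
                       kernel = c("student_t", "gaussian"), seed = 1L) {
  kernel <- match.arg(kernel)
  check_that(alpha > 0, "`alpha` must be > 0")
  check_that(tol > 0 && tol < 1, "`tol` must be in (0, 1)")
  check_that(update_interval >= 1, "`update_interval` must be >= 1")
  if (kernel == "gaussian") {
    stop("the Gaussian kernel is reserved but not implemented; ",
         "use kernel = \"student_t\"", call. = FALSE)
  }
  structure(list(alpha = alpha, tol = tol,
                 louvain_resolution = louvain_resolution,
                 n_neighbors = n_neighbors, max_epochs = max_epochs,
                 update_interval = update_interval,
                 plateau_rel = plateau_rel, patience = patience, lr = lr,
                 momentum = momentum, batch_size = batch_size,
                 layer_dims = layer_dims,
                 epochs_per_layer = epochs_per_layer,
                 finetune_epochs = finetune_epochs,
                 kernel = kernel, seed = as.integer(seed)),
            class = "dec_config")
}

# k nearest neighbours by squared Euclidean distance, ties broken by
# cell index, self excluded
knn_indices <- function(z, k) {
  n <- nrow(z)
  check_that(n >= k + 1, "need at least k + 1 points for a kNN graph")
  rs <- rowSums(z^2)
  gram <- z %*% t(z)
  d2 <- outer(rs, rs, "+") - 2 * gram
  diag(d2) <- Inf
  t(apply(d2, 1L, function(row) order(row, seq_len(n))[seq_len(k)]))
}

#' Initialize clusters with Louvain community detection
#'
#' Builds a k-nearest-neighbour graph on the embedding (Euclidean
#' distances, undirected union of neighbourhoods) and runs Louvain
#' modularity optimization.  The number of communities gives the number
#' of clusters K, and each centroid is the arithmetic mean of its
#' community's embedded points.
#'
#' @param z embedding matrix (cells x d).
#' @param resolution Louvain resolution parameter.
#' @param n_neighbors neighbours per cell for the graph.
#' @param seed RNG seed for the community search.
#' @return a list with `k`, `centroids` (K x d) and integer `labels`
#'   (1-based, renumbered by first appearance).
#' @export
init_louvain <- function(z, resolution = 1, n_neighbors = 15, seed = 1L) {
  z <- as.matrix(z)
  nn <- knn_indices(z, n_neighbors)
  edges <- cbind(rep(seq_len(nrow(z)), each = ncol(nn)), as.vector(t(nn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  memb <- with_seed(derive_seed(seed, "louvain"), {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  labels <- as.integer(factor(memb, levels = unique(memb)))
  k <- max(labels)
  if (k < 2L) {
    stop("Louvain found a single community; increase `louvain_resolution` ",
         "(soft assignment needs at least 2 clusters)", call. = FALSE)
  }
  centroids <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(z[labels == j, , drop = FALSE])
  }))
  list(k = k, centroids = centroids, labels = labels)
}

#' Student-t soft cluster assignment
#'
#' The similarity between embedded point `z_i` and centroid `mu_j` is the
#' Student-t kernel `(1 + ||z_i - mu_j||^2 / alpha)^(-1)`; soft
#' assignments are the row-normalized kernels, so each row of Q is a
#' probability distribution over the K clusters.
#'
#' @param z embedding matrix (n x d).
#' @param centroids centroid matrix (K x d, K >= 2).
#' @param alpha Student-t degrees of freedom (> 0).
#' @return the n x K soft-assignment matrix Q (rows sum to 1).
#' @export
soft_assign <- function(z, centroids, alpha = 1) {
  check_that(alpha > 0, "`alpha` must be > 0")
  z <- as.matrix(z); centroids <- as.matrix(centroids)
  check_that(nrow(centroids) >= 2, "need at least 2 centroids")
  check_that(ncol(z) == ncol(centroids),
             "z and centroids must share the embedding dimension")
  kern <- 1 / (1 + sq_dist(z, centroids) / alpha)
  kern / rowSums(kern)
}

# pairwise squared Euclidean distances between rows of a and rows of b
sq_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  pmax(d2, 0)
}

#' Self-training target distribution
#'
#' Sharpens the soft assignments: `p_ij` is proportional to
#' `q_ij^2 / f_j` with `f_j = sum_i q_ij` the soft cluster frequency,
#' renormalized per cell.  Squaring emphasizes high-confidence
#' assignments; dividing by the frequency prevents large clusters from
#' absorbing everything.
#'
#' @param q soft-assignment matrix (rows sum to 1).
#' @return the target matrix P (same shape, rows sum to 1).
#' @export
target_distribution <- function(q) {
  q <- as.matrix(q)
  f <- colSums(q)
  if (any(f < 1e-12)) {
    stop("cluster(s) ", paste(which(f < 1e-12), collapse = ", "),
         " have vanished (soft frequency ~ 0); clustering cannot continue",
         call. = FALSE)
  }
  w <- sweep(q^2, 2, f, "/")
  w / rowSums(w)
}

#' KL divergence between target and soft assignments
#'
#' `L = sum_ij p_ij log(p_ij / q_ij)`, with the convention
#' `0 * log(0 / q) = 0`.  Zero `q_ij` where `p_ij > 0` signals a
#' degenerate assignment and raises an error.
#'
#' @param p,q matching row-stochastic matrices.
#' @return a non-negative scalar.
#' @export
kl_loss <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  check_that(all(dim(p) == dim(q)), "P and Q must have the same shape")
  pos <- p > 0
  if (any(q[pos] == 0)) {
    stop("q is 0 where p > 0: degenerate assignment", call. = FALSE)
  }
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Closed-form gradients of the clustering loss for one cell
#'
#' For one embedded point with its rows of P and Q, returns the gradient
#' of the KL loss with respect to the embedding (`dz`, length d) and to
#' every centroid (`dmu`, K x d):
#' `dz = (alpha+1)/alpha * sum_j (1 + ||z - mu_j||^2/alpha)^(-1)
#'        (p_j - q_j)(z - mu_j)` and `dmu_j` its negation per cluster.
#' At the default `alpha = 1` these coincide with the exact derivatives
#' of [kl_loss()] composed with [soft_assign()] (P held fixed), which is
#' how they are verified; the training path uses the same formulas in
#' vectorized form.
#'
#' @param z_i embedding of one cell (length d).
#' @param centroids K x d centroid matrix.
#' @param p_row,q_row the cell's rows of P and Q (length K).
#' @param alpha Student-t degrees of freedom.
#' @return list with `dz` (length d) and `dmu` (K x d).
#' @export
clustering_gradients <- function(z_i, centroids, p_row, q_row, alpha = 1) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  check_that(length(z_i) == ncol(centroids),
             "z_i and centroids must share the embedding dimension")
  check_that(length(p_row) == k && length(q_row) == k,
             "p_row and q_row must have one entry per centroid")
  diff <- sweep(-centroids, 2, z_i, "+")      # rows: z_i - mu_j
  kern <- 1 / (1 + rowSums(diff^2) / alpha)
  coef <- (alpha + 1) / alpha * kern * (p_row - q_row)
  dmu <- -coef * diff
  list(dz = colSums(coef * diff), dmu = dmu)
}

# vectorized gradients for a minibatch; loss scaled as mean per cell
grad_batch <- function(z, centroids, p, q, alpha) {
  kern <- 1 / (1 + sq_dist(z, centroids) / alpha)
  g <- (alpha + 1) / alpha * kern * (p - q) / nrow(z)
  dz <- rowSums(g) * z - g %*% centroids
  dmu <- colSums(g) * centroids - t(g) %*% z
  list(dz = dz, dmu = dmu)
}

#' Fraction of cells changing hard assignment
#'
#' @param y_curr,y_prev equal-length label vectors from consecutive
#'   target updates.
#' @return the fraction of positions where the labels differ, in [0, 1].
#' @export
change_fraction <- function(y_curr, y_prev) {
  check_that(length(y_curr) == length(y_prev),
             "label vectors differ in length (", length(y_curr), " vs ",
             length(y_prev), ")")
  mean(y_curr != y_prev)
}

#' Has the stopping rule fired?
#'
#' The iterative procedure stops at the first target update where the
#' change fraction is strictly below `tol`; a change fraction exactly
#' equal to `tol` keeps training.
#'
#' @param y_curr,y_prev hard labels at consecutive target updates.
#' @param tol stopping threshold (default 0.005).
#' @return `TRUE` when training should halt.
#' @export
tol_reached <- function(y_curr, y_prev, tol = 0.005) {
  change_fraction(y_curr, y_prev) < tol
}

hard_labels <- function(q) max.col(q, ties.method = "first")

#' Fit deep embedded clustering
#'
#' The full procedure: layer-wise pretraining and fine-tuning of the
#' stacked autoencoder, Louvain initialization of the cluster centres on
#' the bottleneck embedding, then iterative self-training — soft
#' assignment with a Student-t kernel, target-distribution refresh every
#' `update_interval` epochs, and joint SGD over encoder weights and
#' centroids on the KL divergence loss — until fewer than `tol` of the
#' cells change hard assignment between consecutive target updates (or
#' `max_epochs` is hit).
#'
#' @param x an `expr_matrix` from [preprocess_counts()], or an already
#'   standardized numeric matrix (cells x features).
#' @param cfg a [dec_config()].
#' @param model optional pre-trained `autoencoder` to reuse (skips
#'   pretraining and fine-tuning).
#' @return an object of class `dec_fit`: `labels` (1-based hard
#'   assignments, ties to the lowest cluster index), `probabilities`
#'   (n x K soft assignments), `max_prob` (per-cell assignment
#'   confidence), `centroids`, `k`, `embedding`, `embedding_init` and
#'   `labels_init` (state after initialization, before self-training),
#'   `encoder`, `epochs_run`, `tol_trace`, `loss_trace`, `converged`,
#'   and the `config` used.
#' @examples
#' \donttest{
#' d <- simulate_counts(scenario_config("easy", seed = 3))
#' cm <- count_matrix(d$counts, batch_labels = d$batch_labels)
#' xp <- preprocess_counts(cm, n_top = 100)
#' fit <- dec_fit(xp, dec_config(seed = 3, epochs_per_layer = 40,
#'                               finetune_epochs = 60))
#' adjusted_rand_index(fit$labels, d$true_labels)
#' }
#' @export
dec_fit <- function(x, cfg = dec_config(), model = NULL) {
  check_that(inherits(cfg, "dec_config"), "`cfg` must come from dec_config()")
  xm <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  n <- nrow(xm); p <- ncol(xm)
  layer_dims <- cfg$layer_dims
  if (is.null(layer_dims)) {
    hidden <- if (n <= 1e5) c(64, 32) else c(128, 64, 32)
    hidden <- hidden[hidden < p]
    # tiny feature spaces still get a bottleneck below the input width
    if (length(hidden) == 0L) hidden <- max(2L, p %/% 2L)
    layer_dims <- c(p, hidden)
  }
  if (is.null(model)) {
    model <- pretrain_layerwise(xm, layer_dims,
                                epochs_per_layer = cfg$epochs_per_layer,
                                lr = cfg$lr, momentum = cfg$momentum,
                                batch_size = cfg$batch_size, seed = cfg$seed)
    model <- finetune(model, xm, epochs = cfg$finetune_epochs, lr = cfg$lr,
                      momentum = cfg$momentum, batch_size = cfg$batch_size,
                      seed = cfg$seed)
  }
  enc <- encoder(model)
  z <- encode(enc, xm)
  n_neighbors <- cfg$n_neighbors
  if (is.null(n_neighbors)) n_neighbors <- if (n < 100) 10L else 15L
  init <- init_louvain(z, cfg$louvain_resolution, n_neighbors, cfg$seed)
  mu <- init$centroids
  q <- soft_assign(z, mu, cfg$alpha)
  y_prev <- hard_labels(q)
  p_target <- target_distribution(q)
  z_init <- z
  labels_init <- y_prev

  layers <- enc$layers
  vel <- zero_velocity(layers)
  vel_mu <- array(0, dim(mu))
  tol_trace <- numeric(0)
  loss_trace <- numeric(0)
  converged <- FALSE
  epochs_run <- 0L

  # Each self-training iteration holds P fixed and runs SGD until the KL
  # loss plateaus (or the per-iteration epoch cap is hit); P is then
  # refreshed and the tol rule compares hard labels across consecutive
  # refreshes.
  with_seed(derive_seed(cfg$seed, "cluster-sgd"), {
    full_loss <- function() {
      enc$layers <<- layers
      kl_loss(p_target, soft_assign(encode(enc, xm), mu, cfg$alpha))
    }
    while (epochs_run < cfg$max_epochs) {
      prev_loss <- full_loss()
      stale <- 0L
      iter_epochs <- 0L
      while (iter_epochs < cfg$update_interval &&
             epochs_run < cfg$max_epochs) {
        perm <- sample.int(n)
        for (start in seq(1L, n, by = cfg$batch_size)) {
          idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
          outs <- mlp_forward(layers, xm[idx, , drop = FALSE])
          zb <- outs[[length(outs)]]
          qb <- soft_assign(zb, mu, cfg$alpha)
          gr <- grad_batch(zb, mu, p_target[idx, , drop = FALSE], qb,
                           cfg$alpha)
          grads <- mlp_backward(layers, outs, gr$dz)
          st <- sgd_step(layers, grads, vel, cfg$lr, cfg$momentum)
          layers <- st$layers; vel <- st$vel
          vel_mu <- cfg$momentum * vel_mu - cfg$lr * gr$dmu
          mu <- mu + vel_mu
        }
        if (!all(is.finite(mu)) ||
            !all(vapply(layers, function(l) all(is.finite(l$W)),
                        logical(1)))) {
          stop("clustering diverged (non-finite parameters) at epoch ",
               epochs_run + 1L, call. = FALSE)
        }
        epochs_run <- epochs_run + 1L
        iter_epochs <- iter_epochs + 1L
        loss <- full_loss()
        loss_trace <- c(loss_trace, loss)
        rel <- (prev_loss - loss) / max(abs(prev_loss), 1e-12)
        stale <- if (rel < cfg$plateau_rel) stale + 1L else 0L
        prev_loss <- loss
        if (stale >= cfg$patience) break
      }
      # iteration over: refresh target, evaluate the stopping rule
      enc$layers <- layers
      z <- encode(enc, xm)
      q <- soft_assign(z, mu, cfg$alpha)
      y_curr <- hard_labels(q)
      cf <- change_fraction(y_curr, y_prev)
      tol_trace <- c(tol_trace, cf)
      if (tol_reached(y_curr, y_prev, cfg$tol)) {
        converged <- TRUE
        break
      }
      p_target <- target_distribution(q)
      y_prev <- y_curr
    }
  })

  enc$layers <- layers
  z <- encode(enc, xm)
  q <- soft_assign(z, mu, cfg$alpha)
  labels <- hard_labels(q)
  rownames(z) <- rownames(xm)
  rownames(q) <- rownames(xm)
  structure(list(
    labels = labels, probabilities = q,
    max_prob = apply(q, 1L, max),
    centroids = mu, k = init$k,
    embedding = z, embedding_init = z_init, labels_init = labels_init,
    encoder = enc, epochs_run = epochs_run,
    tol_trace = tol_trace, loss_trace = loss_trace,
    converged = converged, config = cfg
  ), class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf(paste0("dec_fit: %d cells, K = %d, %d epochs (%s), ",
                     "final change fraction %.4g\n"),
              length(x$labels), x$k, x$epochs_run,
              if (x$converged) "converged" else "epoch cap reached",
              if (length(x$tol_trace)) x$tol_trace[length(x$tol_trace)]
              else NA_real_))
  invisible(x)
}
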