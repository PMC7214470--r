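test_that("soft assignment follows the Student-t kernel", {
  # equidistant point splits evenly
  mu <- rbind(c(-1, 0), c(1, 0))
  expect_equal(soft_assign(rbind(c(0, 5)), mu)[1, ], c(0.5, 0.5))
  # distances 0 and 1 give kernels (1, 1/2) -> (2/3, 1/3)
  expect_equal(soft_assign(rbind(c(0, 0)), rbind(c(0, 0), c(0, 1)))[1, ],
               c(2 / 3, 1 / 3))
  expect_error(soft_assign(rbind(c(0, 0)), mu, alpha = 0), "alpha")
  expect_error(soft_assign(matrix(0, 1, 2), matrix(0, 1, 2)), "2 centroids")

  set.seed(2)
  for (i in 1:50) {
    z <- matrix(rnorm(10 * 3), 10, 3)
    mu <- matrix(rnorm(4 * 3), 4, 3)
    q <- soft_assign(z, mu)
    expect_equal(q, soft_assign_oracle(z, mu), tolerance = 1e-12)
    expect_equal(rowSums(q), rep(1, 10), tolerance = 1e-12)
  }
})

test_that("the target distribution sharpens and fixes its fixed points", {
  # identical rows: P reduces to Q
  q <- matrix(rep(c(0.2, 0.3, 0.5), each = 4), 4, 3)
  expect_equal(target_distribution(q), q, tolerance = 1e-12)
  # one-hot Q is a fixed point
  oh <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(target_distribution(oh), oh)
  # hand-computed 3x2 instance (scalar oracle)
  q3 <- rbind(c(.9, .1), c(.6, .4), c(.2, .8))
  expect_equal(target_distribution(q3), target_oracle(q3), tolerance = 1e-12)
  f <- colSums(q3)
  p11 <- (.81 / f[1]) / (.81 / f[1] + .01 / f[2])
  expect_equal(target_distribution(q3)[1, 1], p11)
  # vanished cluster is an error
  expect_error(target_distribution(cbind(c(1, 1), 0)), "vanished")

  set.seed(3)
  for (i in 1:50) {
    q <- random_simplex(8, 3)
    p <- target_distribution(q)
    expect_equal(p, target_oracle(q), tolerance = 1e-12)
    expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-12)
  }
})

test_that("the KL loss matches its definition and is non-negative", {
  q <- random_simplex(5, 4)
  expect_equal(kl_loss(q, q), 0)
  expect_equal(kl_loss(rbind(c(1, 0)), rbind(c(0.5, 0.5))), log(2))
  expect_error(kl_loss(rbind(c(1, 0)), rbind(c(0, 1))), "degenerate")
  expect_error(kl_loss(q, q[, 1:2]), "shape")
  set.seed(4)
  for (i in 1:100) {
    p <- random_simplex(6, 3)
    q <- random_simplex(6, 3)
    l <- kl_loss(p, q)
    expect_gte(l, 0)
    expect_equal(l, kl_oracle(p, q), tolerance = 1e-10)
  }
})

test_that("closed-form clustering gradients agree with finite differences", {
  # symmetric midpoint with P = Q has zero gradients
  mu <- rbind(c(-2, 0, 0), c(2, 0, 0))
  zi <- c(0, 0, 0)
  q <- soft_assign(rbind(zi), mu)[1, ]
  g <- clustering_gradients(zi, mu, q, q)
  expect_equal(g$dz, rep(0, 3))
  expect_equal(g$dmu, matrix(0, 2, 3))

  set.seed(5)
  for (i in 1:20) {
    d <- sample(2:3, 1); k <- sample(2:4, 1)
    mu <- matrix(rnorm(k * d), k, d)
    zi <- rnorm(d)
    p_row <- as.vector(random_simplex(1, k))
    q_row <- soft_assign(rbind(zi), mu)[1, ]
    g <- clustering_gradients(zi, mu, p_row, q_row)
    gz_num <- numeric_grad(function(z) {
      kl_loss(rbind(p_row), soft_assign(rbind(z), mu))
    }, zi)
    expect_equal(g$dz, gz_num, tolerance = 1e-5)
    gmu_num <- matrix(numeric_grad(function(m) {
      kl_loss(rbind(p_row), soft_assign(rbind(zi), matrix(m, k, d)))
    }, as.vector(mu)), k, d)
    expect_equal(g$dmu, gmu_num, tolerance = 1e-5)
  }
})

test_that("minibatch gradients equal the per-cell closed form", {
  set.seed(6)
  z <- matrix(rnorm(12 * 3), 12, 3)
  mu <- matrix(rnorm(3 * 3), 3, 3)
  q <- soft_assign(z, mu)
  p <- target_distribution(q)
  g <- scdec:::grad_batch(z, mu, p, q, alpha = 1)
  dz <- matrix(0, 12, 3)
  dmu <- matrix(0, 3, 3)
  for (i in 1:12) {
    gi <- clustering_gradients(z[i, ], mu, p[i, ], q[i, ])
    dz[i, ] <- gi$dz / 12
    dmu <- dmu + gi$dmu / 12
  }
  expect_equal(g$dz, dz, tolerance = 1e-12)
  expect_equal(g$dmu, dmu, tolerance = 1e-12)
})

test_that("change fraction and the strict stopping rule behave as defined", {
  expect_equal(change_fraction(1:5, 1:5), 0)
  expect_equal(change_fraction(1:4, 5:8), 1)
  y <- rep(1, 1000)
  y2 <- y; y2[1:5] <- 2
  expect_equal(change_fraction(y2, y), 0.005)
  # exactly tol does NOT halt; strictly below does
  expect_false(tol_reached(y2, y, tol = 0.005))
  y3 <- y; y3[1:4] <- 2
  expect_true(tol_reached(y3, y, tol = 0.005))
  expect_error(change_fraction(1:3, 1:4), "length")
})

test_that("Louvain initialization recovers well-separated blobs", {
  set.seed(7)
  centers <- rbind(c(0, 0), c(20, 0))
  blobs <- make_blobs(100, centers, sd = 1)
  # modularity at resolution 1 subdivides diffuse 100-point clouds (the
  # usual Louvain behaviour on kNN graphs); coarse structure needs a
  # lower resolution
  init <- init_louvain(blobs$z, resolution = 0.2, n_neighbors = 15, seed = 1)
  expect_equal(init$k, 2)
  expect_equal(adjusted_rand_index(init$labels, blobs$labels), 1)
  # centroids sit within 0.5 sd of the generating blob means
  for (j in 1:2) {
    truth <- centers[which.min(colSums((t(centers) - init$centroids[j, ])^2)), ]
    expect_lt(sqrt(sum((init$centroids[j, ] - truth)^2)), 0.5)
  }
  # centroid identity: mean of members
  for (j in 1:init$k) {
    expect_equal(init$centroids[j, ],
                 colMeans(blobs$z[init$labels == j, , drop = FALSE]))
  }
})

test_that("Louvain finds the modularity-optimal split of two tight cliques", {
  # two tight groups of five, far apart: the 4-NN graph is two 5-cliques
  # joined by no edge; check the returned 2-partition attains the maximum
  # modularity over all 2-partitions by exhaustive enumeration
  set.seed(8)
  z <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 30, 0.1), 5))
  nn <- scdec:::knn_indices(z, 4)
  edges <- cbind(rep(1:10, each = 4), as.vector(t(nn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  init <- init_louvain(z, resolution = 1, n_neighbors = 4, seed = 1)
  expect_equal(init$k, 2)
  best <- -Inf
  for (code in 1:(2^9)) {  # fix vertex 1 in group 1, enumerate the rest
    memb <- c(1L, as.integer(intToBits(code))[1:9] + 1L)
    best <- max(best, igraph::modularity(g, memb))
  }
  expect_equal(igraph::modularity(g, init$labels), best, tolerance = 1e-12)
})

test_that("permuting centroid order permutes assignment columns identically", {
  set.seed(9)
  z <- matrix(rnorm(20 * 2), 20, 2)
  mu <- matrix(rnorm(4 * 2), 4, 2)
  perm <- c(3, 1, 4, 2)
  expect_equal(soft_assign(z, mu[perm, ]), soft_assign(z, mu)[, perm])
})

test_that("the full fit returns a coherent cluster state on small data", {
  d <- simulate_counts(sim_config(n_cells = 200, n_genes = 60, k_clusters = 2,
                                  n_batches = 2, seed = 10))
  xp <- preprocess_counts(count_matrix(d$counts), n_top = 40)
  cfg <- dec_config(seed = 10, epochs_per_layer = 30, finetune_epochs = 30,
                    max_epochs = 30, update_interval = 10)
  fit <- dec_fit(xp, cfg)
  expect_s3_class(fit, "dec_fit")
  expect_equal(unname(rowSums(fit$probabilities)), rep(1, 200),
               tolerance = 1e-8)
  expect_true(all(fit$labels %in% seq_len(ncol(fit$probabilities))))
  expect_equal(fit$max_prob, apply(fit$probabilities, 1, max))
  expect_equal(dim(fit$embedding), c(200, 32))
  expect_true(all(abs(fit$embedding) < 1))
  expect_gte(length(fit$tol_trace), 1)
  # reusing the trained model reproduces the clustering deterministically
  fit2 <- dec_fit(xp, cfg)
  expect_identical(fit$labels, fit2$labels)
  expect_identical(fit$probabilities, fit2$probabilities)
  # the Gaussian kernel remains reserved
  expect_error(dec_config(kernel = "gaussian"), "not implemented")
})
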