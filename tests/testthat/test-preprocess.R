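test_that("cell normalization matches the counts-per-10k log formula", {
  cm <- count_matrix(rbind(c(1, 0), c(2, 3)),
                     cell_ids = c("a", "b"), gene_ids = c("g1", "g2"))
  x <- normalize_cells(cm)
  # cell with counts (1, 0): total 1 -> (ln(1 + 10000), 0)
  expect_equal(x$values["a", ], c(g1 = log(10001), g2 = 0))
  expect_equal(x$values["b", "g1"], log1p(2 / 5 * 1e4))

  # a gene that is zero everywhere stays exactly zero
  cm0 <- count_matrix(cbind(c(3, 1, 4), 0))
  expect_true(all(normalize_cells(cm0)$values[, 2] == 0))

  # random Poisson matrix vs element-by-element loop oracle
  set.seed(21)
  m <- matrix(rpois(20 * 30, 2), 20, 30)
  m[rowSums(m) == 0, 1] <- 1
  x <- normalize_cells(count_matrix(m))$values
  oracle <- m * 0
  for (i in 1:20) {
    tot <- sum(m[i, ])
    for (g in 1:30) oracle[i, g] <- log(1 + m[i, g] / tot * 1e4)
  }
  expect_equal(unname(x), oracle, tolerance = 1e-12)
})

test_that("zero-total cells are rejected by name and removed by the filter", {
  cm <- count_matrix(rbind(c(1, 2), c(0, 0)), cell_ids = c("good", "empty"))
  expect_error(normalize_cells(cm), "empty")
  expect_message(f <- filter_cells(cm), "empty")
  expect_identical(f$cell_ids, "good")
})

test_that("gene standardization gives mean 0 / sd 1 with zero-variance guard", {
  set.seed(4)
  cm <- count_matrix(matrix(rpois(50 * 10, 5), 50, 10))
  x <- standardize_genes(normalize_cells(cm), batch_labels = NULL)
  expect_true(all(abs(colMeans(x$values)) < 1e-8))
  expect_true(all(abs(apply(x$values, 2, sd) - 1) < 1e-6))

  # constant gene -> all-zero column, never NaN
  cm2 <- count_matrix(cbind(matrix(rpois(40, 5), 20, 2), 1))
  x2 <- standardize_genes(normalize_cells(cm2), batch_labels = NULL)
  expect_false(anyNA(x2$values))
  # standardizing twice equals standardizing once
  again <- scale_like <- standardize_genes(x2, batch_labels = NULL)
  expect_equal(standardize_genes(again, batch_labels = NULL)$values,
               again$values, tolerance = 1e-10)
})

test_that("per-batch standardization centres genes within each batch", {
  set.seed(9)
  counts <- matrix(rpois(60 * 8, 6), 60, 8)
  batch <- rep(c("b1", "b2"), each = 30)
  x <- standardize_genes(normalize_cells(count_matrix(counts)), batch)
  for (b in c("b1", "b2")) {
    sub <- x$values[batch == b, ]
    # loop-oracle per-batch means
    for (g in seq_len(ncol(sub))) expect_lt(abs(mean(sub[, g])), 1e-8)
  }
  expect_error(standardize_genes(normalize_cells(count_matrix(counts)),
                                 batch_labels = c("b1", "b2")),
               "batch_labels length")
})

test_that("normalization is invariant to library-size rescaling of a cell", {
  set.seed(13)
  for (rep in 1:5) {
    m <- matrix(rpois(15 * 12, 3) + 1, 15, 12)
    scaled <- m
    i <- sample(15, 1)
    scaled[i, ] <- scaled[i, ] * sample(c(2, 5, 13), 1)
    a <- normalize_cells(count_matrix(m))$values
    b <- normalize_cells(count_matrix(scaled))$values
    expect_equal(a[i, ], b[i, ], tolerance = 1e-12)
  }
})

test_that("highly variable gene selection finds planted markers", {
  # 10 planted genes whose means differ 8-fold between two cell groups
  # (around the same average as the 190 flat genes, so the signal is
  # dispersion, not abundance), among 190 flat genes
  set.seed(17)
  cl <- rep(1:2, each = 150)
  means <- matrix(2, 300, 200)
  means[cl == 1, 1:10] <- 4 / 9
  means[cl == 2, 1:10] <- 32 / 9
  counts <- matrix(rnbinom(300 * 200, mu = means, size = 10), 300, 200)
  x <- normalize_cells(count_matrix(counts))
  mask <- select_hvg(x, n_top = 20)
  expect_true(all(mask[1:10]))

  # zero-variance genes are never selected while informative genes remain
  cm <- count_matrix(cbind(matrix(rpois(200, 4), 20, 10), 0))
  xx <- normalize_cells(cm)
  expect_false(select_hvg(xx, n_top = 10)[11])
  # identity case and over-asking
  expect_true(all(select_hvg(xx, n_top = 11)))
  expect_error(select_hvg(xx, n_top = 12), "n_top")
})

test_that("gene selection depends only on column statistics", {
  set.seed(31)
  m <- matrix(rpois(40 * 25, 4), 40, 25)
  x <- normalize_cells(count_matrix(m))
  perm <- sample(40)
  xp <- normalize_cells(count_matrix(m[perm, ]))
  expect_identical(unname(select_hvg(x, 8)), unname(select_hvg(xp, 8)))
})

test_that("the full preprocessing pipeline composes the steps in order", {
  d <- simulate_counts(sim_config(n_cells = 120, n_genes = 80, seed = 2))
  cm <- count_matrix(d$counts, batch_labels = d$batch_labels)
  xp <- preprocess_counts(cm, n_top = 30)
  expect_equal(dim(xp$values), c(120, 30))
  expect_equal(sum(xp$gene_mask), 30)
  expect_identical(colnames(xp$values), names(xp$gene_mask)[xp$gene_mask])
  # per-batch standardization applied by default when labels are present
  for (b in unique(d$batch_labels)) {
    expect_lt(max(abs(colMeans(xp$values[d$batch_labels == b, ]))), 1e-8)
  }
})
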