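# Independent oracles used to cross-check the vectorized implementations.
# All of these are deliberately written as plain scalar loops.

# pair-counting adjusted Rand index: O(n^2) over all cell pairs
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == expected) return(1)
  (n11 - expected) / (max_idx - expected)
}

# Student-t soft assignment by explicit double loop
soft_assign_oracle <- function(z, mu, alpha = 1) {
  n <- nrow(z); k <- nrow(mu)
  q <- matrix(0, n, k)
  for (i in seq_len(n)) {
    kern <- numeric(k)
    for (j in seq_len(k)) {
      kern[j] <- (1 + sum((z[i, ] - mu[j, ])^2) / alpha)^(-1)
    }
    q[i, ] <- kern / sum(kern)
  }
  q
}

# self-training target by explicit loop
target_oracle <- function(q) {
  n <- nrow(q); k <- ncol(q)
  f <- numeric(k)
  for (j in seq_len(k)) f[j] <- sum(q[, j])
  p <- matrix(0, n, k)
  for (i in seq_len(n)) {
    w <- numeric(k)
    for (j in seq_len(k)) w[j] <- q[i, j]^2 / f[j]
    p[i, ] <- w / sum(w)
  }
  p
}

# KL divergence by explicit loop
kl_oracle <- function(p, q) {
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / q[i, j])
    }
  }
  s
}

# central finite differences of f at x (vector input, scalar output)
numeric_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# a random row-stochastic matrix
random_simplex <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}

# two well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per, centers, sd = 1) {
  z <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
    sweep(matrix(stats::rnorm(n_per * ncol(centers), 0, sd), n_per),
          2, centers[j, ], "+")
  }))
  list(z = z, labels = rep(seq_len(nrow(centers)), each = n_per))
}
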