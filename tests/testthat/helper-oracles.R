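# Layered Gaussian range fixture: one bump of `n_per` points per layer mean.
gauss_layers <- function(means, sd = 0.5, n_per = 100, seed = 1L) {
  withr::with_seed(seed, {
    unlist(lapply(means, function(m) stats::rnorm(n_per, m, sd)))
  })
}

# Brute-force scalar evaluations of the fuzzy clustering formulas, written
# as plain double loops so they share no code path with the package.
brute_centers <- function(x, U, q) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  V <- matrix(0, nrow(U), ncol(X))
  for (i in seq_len(nrow(U))) {
    num <- rep(0, ncol(X))
    den <- 0
    for (j in seq_len(ncol(U))) {
      num <- num + U[i, j]^q * X[j, ]
      den <- den + U[i, j]^q
    }
    V[i, ] <- num / den
  }
  V
}

brute_memberships <- function(x, V, q) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  U <- matrix(0, nrow(V), nrow(X))
  for (i in seq_len(nrow(V))) {
    for (j in seq_len(nrow(X))) {
      s <- 0
      for (p in seq_len(nrow(V))) {
        s <- s + (sum((X[j, ] - V[i, ])^2) / sum((X[j, ] - V[p, ])^2))^(1 / (q - 1))
      }
      U[i, j] <- 1 / s
    }
  }
  U
}

brute_objective <- function(x, V, U, q) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  J <- 0
  for (i in seq_len(nrow(U))) {
    for (j in seq_len(ncol(U))) {
      J <- J + U[i, j]^q * sum((X[j, ] - V[i, ])^2)
    }
  }
  J
}

brute_entropy <- function(U) {
  v <- 0
  for (j in seq_len(ncol(U))) {
    for (i in seq_len(nrow(U))) {
      if (U[i, j] > 0) v <- v - U[i, j] * log(U[i, j])
    }
  }
  v / ncol(U)
}

brute_nearest <- function(x, centers) {
  lab <- integer(length(x))
  for (j in seq_along(x)) {
    d <- abs(x[j] - centers)
    lab[j] <- which(d == min(d))[1]
  }
  lab
}

# Globally optimal k-means by exhaustive assignment enumeration (tiny n only).
brute_kmeans_best <- function(x, c) {
  n <- length(x)
  stopifnot(c^n <= 3^9 + 1)
  grid <- as.matrix(expand.grid(rep(list(seq_len(c)), n)))
  best <- Inf
  best_centers <- NULL
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    if (length(unique(lab)) < c) next
    ss <- 0
    centers <- numeric(c)
    for (i in seq_len(c)) {
      xi <- x[lab == i]
      centers[i] <- mean(xi)
      ss <- ss + sum((xi - centers[i])^2)
    }
    if (ss < best) {
      best <- ss
      best_centers <- sort(centers)
    }
  }
  list(ss = best, centers = best_centers)
}

# Random valid fuzzy partition (columns normalised to sum 1).
random_partition <- function(c, n, seed) {
  withr::with_seed(seed, {
    R <- matrix(stats::runif(c * n), nrow = c)
    sweep(R, 2, colSums(R), "/")
  })
}
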