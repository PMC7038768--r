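#' Fuzzy c-means machinery
#'
#' The clustering core alternates two closed-form updates derived from the
#' weighted within-cluster squared-distance objective
#' \deqn{J(U, V) = \sum_{i=1}^{c} \sum_{j=1}^{n} (u_{ij})^q \|X_j - V_i\|^2,}
#' where `U` is the fuzzy partition, `V` the cluster centers and `q > 1` the
#' fuzziness (weight) exponent. Minimising `J` subject to unit column sums of
#' `U` yields the membership and center expressions implemented by
#' [update_memberships()] and [update_centers()].
#'
#' @name fcm
NULL

# squared Euclidean distances, c x n; exact zeros preserved for the
# coincident-sample convention
squared_distances <- function(X, V) {
  c <- nrow(V)
  n <- nrow(X)
  d2 <- matrix(0, nrow = c, ncol = n)
  tX <- t(X)
  for (i in seq_len(c)) {
    d2[i, ] <- colSums((tX - V[i, ])^2)
  }
  d2
}

#' Update cluster centers from a fuzzy partition
#'
#' Each center is the membership-weighted mean of all samples,
#' \eqn{V_i = \sum_j (u_{ij})^q X_j / \sum_j (u_{ij})^q}. With a crisp
#' partition this reduces to the per-cluster arithmetic mean.
#'
#' @param samples A [sample_set()] (or coercible numeric vector/matrix).
#' @param partition A `c x n` [fuzzy_partition()].
#' @param q Weight exponent, `> 1`. Default 2, the standard choice.
#' @return A `c x d` matrix of cluster centers.
#' @export
update_centers <- function(samples, partition, q = 2) {
  X <- as_matrix(sample_set(samples))
  U <- fuzzy_partition(partition)
  stopifnot(q > 1)
  if (ncol(U) != nrow(X)) {
    stop("partition has ", ncol(U), " columns but there are ", nrow(X),
      " samples",
      call. = FALSE
    )
  }
  W <- unclass(U)^q
  denom <- rowSums(W)
  if (any(denom == 0)) {
    bad <- which(denom == 0)[1]
    stop(sprintf(
      "degenerate cluster %d: all membership weights are zero", bad
    ), call. = FALSE)
  }
  (W %*% X) / denom
}

#' Update membership degrees from cluster centers
#'
#' Memberships follow the inverse-squared-distance rule
#' \eqn{u_{ij} = 1 / \sum_p (\|X_j - V_i\|^2 / \|X_j - V_p\|^2)^{1/(q-1)}}.
#' When a sample coincides exactly with one or more centers the formula is
#' singular; by continuity the sample then takes membership 1 split uniformly
#' over the coincident centers and 0 elsewhere.
#'
#' @inheritParams update_centers
#' @param centers `c x d` matrix of cluster centers, `c >= 2`.
#' @return A [fuzzy_partition()].
#' @export
update_memberships <- function(samples, centers, q = 2) {
  X <- as_matrix(sample_set(samples))
  V <- center_set(centers, nrow(X))
  stopifnot(q > 1)
  if (nrow(V) < 2) {
    stop("membership update needs at least 2 cluster centers", call. = FALSE)
  }
  if (ncol(V) != ncol(X)) {
    stop("centers and samples disagree on dimension d", call. = FALSE)
  }
  d2 <- squared_distances(X, V)
  P <- d2^(-1 / (q - 1))
  U <- sweep(P, 2, colSums(P), "/")
  # coincident samples (exact zero distance) and numerically exploded columns
  singular <- colSums(d2 == 0) > 0 | colSums(!is.finite(P)) > 0
  if (any(singular)) {
    for (j in which(singular)) {
      hit <- d2[, j] == min(d2[, j])
      U[, j] <- hit / sum(hit)
    }
  }
  fuzzy_partition(U)
}

#' Fuzzy clustering objective
#'
#' @inheritParams update_centers
#' @param centers `c x d` matrix of cluster centers.
#' @return The scalar objective `J(U, V)` (cm^2 for range scans), `>= 0`.
#' @export
fcm_objective <- function(samples, centers, partition, q = 2) {
  X <- as_matrix(sample_set(samples))
  V <- center_set(centers, nrow(X))
  U <- unclass(fuzzy_partition(partition))
  sum(U^q * squared_distances(X, V))
}

#' Run fuzzy c-means to convergence
#'
#' Alternates the center update and the membership update, starting from an
#' initial partition, until the largest membership change between successive
#' iterations drops to `epsilon` or the iteration cap is hit. The objective
#' is non-increasing along the iterates (each half-step is an exact
#' coordinate minimisation of `J`).
#'
#' @inheritParams update_centers
#' @param partition Initial `c x n` fuzzy partition; see [initial_partition()].
#' @param epsilon Convergence tolerance on `max |u_ij^(k+1) - u_ij^(k)|`.
#' @param max_iter Iteration cap. If hit before convergence the state is
#'   returned with `converged = FALSE` and a warning, not an error.
#' @return An object of class `"fcm_state"`: a list with elements
#'   `partition`, `centers`, `objective`, `objective_trace`, `iteration`,
#'   `converged` and `delta` (the final membership change).
#' @export
fcm_converge <- function(samples, partition, q = 2, epsilon = 1e-4,
                         max_iter = 300) {
  X <- sample_set(samples)
  U <- fuzzy_partition(partition)
  stopifnot(epsilon > 0, max_iter >= 1)
  trace <- numeric(0)
  V <- NULL
  delta <- Inf
  converged <- FALSE
  k <- 0L
  while (k < max_iter) {
    k <- k + 1L
    V <- update_centers(X, U, q)
    U_new <- update_memberships(X, V, q)
    delta <- max(abs(unclass(U_new) - unclass(U)))
    trace[k] <- fcm_objective(X, V, U_new, q)
    U <- U_new
    if (delta <= epsilon) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "fuzzy c-means did not converge in %d iterations (last delta %.3g)",
      max_iter, delta
    ), call. = FALSE)
  }
  structure(
    list(
      partition = U, centers = V, objective = trace[k],
      objective_trace = trace, iteration = k, converged = converged,
      delta = delta
    ),
    class = "fcm_state"
  )
}

#' @export
print.fcm_state <- function(x, ...) {
  cat(sprintf(
    "<fcm_state> c = %d, iterations = %d, converged = %s\n  objective = %.6g\n",
    nrow(x$centers), x$iteration, x$converged, x$objective
  ))
  invisible(x)
}

#' Initial partition for fuzzy c-means
#'
#' The default deterministic initialisation places `c` provisional centers at
#' evenly spaced quantiles of the data (probabilities `(2i - 1) / (2c)`) and
#' assigns each sample crisply to its nearest one; on layered 1-D range data
#' this lands one center per occupied echo level whenever the levels carry
#' comparable mass. Duplicate quantile centers (which arise when the data take
#' fewer than `c` distinct values) are collapsed, and provisional clusters
#' left empty by the crisp assignment are dropped, so the returned partition
#' may have fewer than `c` rows. A seeded random initialisation is available
#' for sensitivity checks.
#'
#' @inheritParams update_centers
#' @param c Number of clusters requested.
#' @param method `"quantile"` (deterministic, default) or `"random"` (each
#'   sample gets a random membership column, normalised to sum 1).
#' @param seed Integer seed, used by the random method only.
#' @return A [fuzzy_partition()] with at most `c` rows.
#' @export
initial_partition <- function(samples, c, method = c("quantile", "random"),
                              seed = NULL) {
  X <- sample_set(samples)
  method <- match.arg(method)
  n <- nrow(X)
  stopifnot(c >= 2, c <= n)
  if (method == "random") {
    R <- withr::with_seed(
      if (is.null(seed)) 1L else seed,
      matrix(stats::runif(c * n), nrow = c)
    )
    return(fuzzy_partition(sweep(R, 2, colSums(R), "/")))
  }
  V <- quantile_centers(X, c)
  labels <- hard_assign(X, V)
  keep <- tabulate(labels, nrow(V)) > 0
  if (!all(keep)) {
    labels <- hard_assign(X, V[keep, , drop = FALSE])
  }
  crisp_partition(labels, sum(keep))
}

# c centers at evenly spaced per-dimension quantiles, duplicates collapsed
quantile_centers <- function(X, c) {
  X <- as_matrix(X)
  probs <- (2 * seq_len(c) - 1) / (2 * c)
  V <- apply(X, 2, stats::quantile, probs = probs, names = FALSE, type = 7)
  V <- matrix(V, ncol = ncol(X))
  unique(V)
}
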