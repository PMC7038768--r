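#' Configuration for fuzzy ISODATA clustering
#'
#' Bundles the tunable parameters of the split/merge driver. The defaults are
#' the settings that work well on layered corn range scans: start from
#' `c_init = 3` clusters (canopy, lower leaves, ground), converge the fuzzy
#' memberships to `epsilon = 1e-4`, and adjust the cluster count with a
#' minimum cluster size `theta_n = 20` samples, a split standard-deviation
#' threshold `theta_S = 5` cm and a minimum inter-center distance
#' `theta_c = 2` cm.
#'
#' @param c_init Initial number of clusters (>= 2).
#' @param epsilon Fuzzy c-means convergence tolerance on membership change.
#' @param q Weight exponent of the fuzzy objective (> 1).
#' @param theta_n Minimum samples per cluster; a cluster only splits when it
#'   holds more than `2 * (theta_n + 1)` samples. Larger values suit faster
#'   sensor speeds, where scans carry fewer points per plant.
#' @param theta_S Split threshold on the within-cluster standard deviation, cm.
#' @param theta_c Merge threshold on the distance between two centers, cm.
#' @param max_outer Cap on split/merge rounds of the outer loop. `1` gives
#'   single-pass behaviour (one split/merge adjustment, no re-clustering).
#' @param max_inner Iteration cap of each inner fuzzy c-means run.
#' @param init Initialisation method, `"quantile"` or `"random"`; see
#'   [initial_partition()].
#' @param seed Integer seed (used by the random initialisation only).
#' @return A list of class `"isodata_config"`.
#' @export
isodata_config <- function(c_init = 3, epsilon = 1e-4, q = 2, theta_n = 20,
                           theta_S = 5, theta_c = 2, max_outer = 10,
                           max_inner = 300, init = "quantile", seed = NULL) {
  stopifnot(
    c_init >= 2, epsilon > 0, q > 1, theta_n >= 1, theta_S > 0, theta_c > 0,
    max_outer >= 1, max_inner >= 1
  )
  structure(
    list(
      c_init = as.integer(c_init), epsilon = epsilon, q = q,
      theta_n = as.integer(theta_n), theta_S = theta_S, theta_c = theta_c,
      max_outer = as.integer(max_outer), max_inner = as.integer(max_inner),
      init = match.arg(init, c("quantile", "random")), seed = seed
    ),
    class = "isodata_config"
  )
}

#' Nearest-center hard assignment
#'
#' Labels each sample with the index of its nearest center. Distance ties are
#' broken in favour of the lowest cluster index; the driver keeps centers
#' sorted ascending, so ties go to the shallower (closer-to-sensor) cluster.
#'
#' @inheritParams update_centers
#' @param centers `c x d` matrix (or numeric vector for `d = 1`) of centers.
#' @return Integer vector of cluster labels, one per sample.
#' @export
hard_assign <- function(samples, centers) {
  X <- as_matrix(sample_set(samples))
  V <- center_set(centers, Inf)
  d2 <- squared_distances(X, V)
  max.col(-t(d2), ties.method = "first")
}

#' Per-cluster dispersion statistics
#'
#' For each cluster `i` with `n_i` members, computes the mean distance from
#' its members to its center, `Dbar_i = (1/n_i) sum ||X - V_i||`, and the
#' population standard deviation `sigma_i = sqrt((1/n_i) sum ||X - V_i||^2)`,
#' together with the global mean distance
#' `Dbar = (1/n) sum_i n_i Dbar_i`. These are the quantities the split rule
#' inspects.
#'
#' @inheritParams update_centers
#' @param centers `c x d` matrix of cluster centers.
#' @param labels Integer hard labels, as from [hard_assign()].
#' @return A list of class `"cluster_stats"`: `table` (data frame with
#'   columns `cluster`, `n`, `center`, `mean_dist`, `sd`, `split_dim`),
#'   `centers`, `global_mean_dist` and `n`.
#' @export
cluster_stats <- function(samples, centers, labels) {
  X <- as_matrix(sample_set(samples))
  V <- center_set(centers, nrow(X))
  c <- nrow(V)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(X), all(labels >= 1), all(labels <= c))
  counts <- tabulate(labels, c)
  if (any(counts == 0)) {
    stop("cluster ", which(counts == 0)[1], " is empty", call. = FALSE)
  }
  mean_dist <- sd_i <- numeric(c)
  split_dim <- integer(c)
  for (i in seq_len(c)) {
    M <- X[labels == i, , drop = FALSE]
    d2 <- colSums((t(M) - V[i, ])^2)
    mean_dist[i] <- mean(sqrt(d2))
    sd_i[i] <- sqrt(mean(d2))
    # axis used if this cluster splits: the coordinate with the largest
    # within-cluster variance (trivially 1 for range scans)
    vars <- colMeans(sweep(M, 2, V[i, ])^2)
    split_dim[i] <- which.max(vars)
  }
  tab <- data.frame(
    cluster = seq_len(c), n = counts,
    center = if (ncol(V) == 1) as.numeric(V) else I(asplit(V, 1)),
    mean_dist = mean_dist, sd = sd_i, split_dim = split_dim
  )
  structure(
    list(
      table = tab, centers = V,
      global_mean_dist = sum(counts * mean_dist) / nrow(X), n = nrow(X)
    ),
    class = "cluster_stats"
  )
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf(
    "<cluster_stats> %d clusters, %d samples, global mean distance %.3f cm\n",
    nrow(x$table), x$n, x$global_mean_dist
  ))
  print(x$table[, c("cluster", "n", "center", "mean_dist", "sd")],
    row.names = FALSE
  )
  invisible(x)
}

#' Propose cluster splits
#'
#' A cluster `i` splits if, simultaneously, its standard deviation exceeds
#' `theta_S`, its mean member-to-center distance exceeds the global mean
#' distance, and it holds more than `2 * (theta_n + 1)` samples (all strict
#' inequalities). The split replaces its center by the pair
#' `V_i - 0.5 * sigma_i` and `V_i + 0.5 * sigma_i`, displaced along the axis
#' of maximum within-cluster variance (the only axis, for range scans).
#'
#' @param stats A [cluster_stats()] object.
#' @param config An [isodata_config()].
#' @return A list of split events, each a list with `cluster`, `sigma` and
#'   `new_centers` (2 x d matrix); empty if nothing qualifies.
#' @export
try_split <- function(stats, config = isodata_config()) {
  tab <- stats$table
  qualify <- tab$sd > config$theta_S &
    tab$mean_dist > stats$global_mean_dist &
    tab$n > 2 * (config$theta_n + 1)
  lapply(which(qualify), function(i) {
    lo <- hi <- stats$centers[i, ]
    a <- tab$split_dim[i]
    lo[a] <- lo[a] - 0.5 * tab$sd[i]
    hi[a] <- hi[a] + 0.5 * tab$sd[i]
    list(
      type = "split", cluster = i, sigma = tab$sd[i],
      new_centers = rbind(lo, hi, deparse.level = 0)
    )
  })
}

#' Propose cluster merges
#'
#' Any pair of centers closer than `theta_c` (strictly) merges into the
#' count-weighted mean `V_k = (n_i V_i + n_j V_j) / (n_i + n_j)`. Candidate
#' pairs are processed in ascending distance order and each cluster takes
#' part in at most one merge per round.
#'
#' @param centers `c x d` matrix of cluster centers, `c >= 2`.
#' @param counts Integer vector of per-cluster sample counts.
#' @param config An [isodata_config()].
#' @return A list of merge events, each a list with `clusters` (pair of
#'   indices), `distance` and `new_center`; empty if no pair is close enough.
#' @export
try_merge <- function(centers, counts, config = isodata_config()) {
  V <- center_set(centers, Inf)
  c <- nrow(V)
  stopifnot(c >= 2, length(counts) == c)
  D <- as.matrix(stats::dist(V))
  pairs <- which(upper.tri(D) & D < config$theta_c, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    return(list())
  }
  pairs <- pairs[order(D[pairs]), , drop = FALSE]
  used <- logical(c)
  events <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]
    j <- pairs[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    ni <- counts[i]
    nj <- counts[j]
    events[[length(events) + 1]] <- list(
      type = "merge", clusters = c(i, j), distance = D[i, j],
      new_center = (ni * V[i, ] + nj * V[j, ]) / (ni + nj)
    )
  }
  events
}

#' Fuzzy ISODATA clustering of a range scan
#'
#' The full driver: each outer round converges fuzzy c-means from a crisp
#' assignment to the current centers, hard-assigns every sample to its
#' nearest center, computes cluster statistics, and then adjusts the cluster
#' set — splitting over-dispersed clusters and merging centers that have
#' drifted together. Rounds repeat until one produces no split and no merge
#' (a split or merge invalidates the converged partition, so the memberships
#' are re-fitted), or until `max_outer` rounds have run. Clusters emptied by
#' hard reassignment are deleted and logged. The result is deterministic
#' given the configuration (and seed, if random initialisation is used).
#'
#' @inheritParams update_centers
#' @param config An [isodata_config()].
#' @param init_centers Optional matrix (or numeric vector) of starting
#'   centers, overriding the configured initialisation; useful to resume from
#'   a previous model or to probe fixed points.
#' @return An object of class `"canopy_model"`: a list with sorted `centers`,
#'   hard `labels`, the fuzzy `partition`, cluster `stats`, an `entropy`
#'   report ([fuzzy_entropy()]), the ordered split/merge/delete `events` log,
#'   `rounds`, `iterations` (inner iterations of the final fit), `converged`,
#'   `config` and `n`.
#' @examples
#' scan <- simulate_scan(scan_scenario("4-leaf", seed = 7))
#' model <- run_fuzzy_isodata(scan$distance_cm)
#' cluster_centers(model)
#' @export
run_fuzzy_isodata <- function(samples, config = isodata_config(),
                              init_centers = NULL) {
  X <- sample_set(samples)
  n <- nrow(X)
  if (n <= config$c_init) {
    stop("need more than c_init = ", config$c_init, " samples, got ", n,
      call. = FALSE
    )
  }
  events <- list()
  log_event <- function(e, round) {
    e$round <- round
    events[[length(events) + 1]] <<- e
  }

  if (is.null(init_centers)) {
    U <- initial_partition(X, config$c_init, config$init, config$seed)
    centers <- update_centers(X, U, config$q)
  } else {
    centers <- center_set(init_centers, n)
  }
  centers <- sort_centers(centers)

  round <- 0
  state <- NULL
  labels <- NULL
  stats <- NULL
  repeat {
    round <- round + 1
    labels0 <- hard_assign(X, centers)
    keep <- tabulate(labels0, nrow(centers)) > 0
    if (!all(keep)) {
      for (i in which(!keep)) {
        log_event(list(type = "delete", cluster = i, reason = "empty"), round)
      }
      centers <- centers[keep, , drop = FALSE]
      labels0 <- hard_assign(X, centers)
    }
    if (nrow(centers) < 2) {
      stop("clustering degenerated to a single cluster", call. = FALSE)
    }
    state <- fcm_converge(
      X, crisp_partition(labels0, nrow(centers)),
      q = config$q, epsilon = config$epsilon, max_iter = config$max_inner
    )
    ord <- order(state$centers[, 1])
    centers <- state$centers[ord, , drop = FALSE]
    U <- fuzzy_partition(unclass(state$partition)[ord, , drop = FALSE])
    labels <- hard_assign(X, centers)
    keep <- tabulate(labels, nrow(centers)) > 0
    if (!all(keep)) {
      for (i in which(!keep)) {
        log_event(list(type = "delete", cluster = i, reason = "empty"), round)
      }
      centers <- centers[keep, , drop = FALSE]
      next
    }
    stats <- cluster_stats(X, centers, labels)

    splits <- try_split(stats, config)
    new_centers <- centers
    if (length(splits) > 0) {
      drop_idx <- vapply(splits, `[[`, integer(1), "cluster")
      new_centers <- rbind(
        centers[-drop_idx, , drop = FALSE],
        do.call(rbind, lapply(splits, `[[`, "new_centers"))
      )
      new_centers <- sort_centers(new_centers)
    }
    counts <- tabulate(hard_assign(X, new_centers), nrow(new_centers))
    merges <- if (nrow(new_centers) >= 2 && all(counts > 0)) {
      try_merge(new_centers, counts, config)
    } else {
      list()
    }
    if (length(splits) == 0 && length(merges) == 0) {
      break
    }
    if (round >= config$max_outer) {
      warning("outer loop cap reached with split/merge still pending; ",
        "returning the last converged model",
        call. = FALSE
      )
      break
    }
    for (e in splits) log_event(e, round)
    if (length(merges) > 0) {
      drop_idx <- unlist(lapply(merges, `[[`, "clusters"))
      new_centers <- rbind(
        new_centers[-drop_idx, , drop = FALSE],
        do.call(rbind, lapply(merges, function(e) rbind(e$new_center)))
      )
      for (e in merges) log_event(e, round)
    }
    centers <- sort_centers(new_centers)
  }

  structure(
    list(
      centers = centers, labels = labels, partition = U, stats = stats,
      entropy = fuzzy_entropy(U), events = events, rounds = round,
      iterations = state$iteration, converged = state$converged,
      config = config, n = n
    ),
    class = "canopy_model"
  )
}

sort_centers <- function(V) {
  V[order(V[, 1]), , drop = FALSE]
}

#' Cluster centers of a fitted model
#'
#' @param model A `"canopy_model"` from [run_fuzzy_isodata()].
#' @return For 1-D scans, a sorted numeric vector of centers (cm); otherwise
#'   the sorted center matrix.
#' @export
cluster_centers <- function(model) {
  stopifnot(inherits(model, "canopy_model"))
  if (ncol(model$centers) == 1) as.numeric(model$centers) else model$centers
}

#' @export
print.canopy_model <- function(x, ...) {
  cat(sprintf(
    "<canopy_model> %d clusters from %d samples (%d outer round%s)\n",
    nrow(x$centers), x$n, x$rounds, if (x$rounds == 1) "" else "s"
  ))
  cat(
    "  centers (cm):",
    paste(sprintf("%.2f", cluster_centers(x)), collapse = ", "), "\n"
  )
  cat(sprintf(
    "  sizes: %s | v_PE = %.4f\n",
    paste(x$stats$table$n, collapse = ", "), x$entropy$v_pe
  ))
  if (length(x$events) > 0) {
    cat("  events:", paste(
      vapply(x$events, function(e) {
        sprintf("%s@r%d", e$type, e$round)
      }, character(1)),
      collapse = ", "
    ), "\n")
  }
  invisible(x)
}
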