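#' Baseline canopy estimators
#'
#' Three simple references against which the fuzzy ISODATA pipeline is
#' compared: k-means clustering (canopy = smallest final center), the grand
#' mean, and the sample median of the scan. Mean and median cannot exclude
#' lower-leaf and ground echoes, so on mixed scans they land between the
#' canopy and the ground; k-means separates the levels but needs the cluster
#' count supplied and is sensitive to its random initialisation.
#'
#' @name baselines
NULL

#' k-means baseline
#'
#' Lloyd's algorithm via [stats::kmeans()], initialised with `c` samples
#' drawn at random under `seed`. The seed is exposed deliberately: rerunning
#' with different seeds demonstrates the initialisation sensitivity that the
#' self-adjusting fuzzy pipeline avoids. An initialisation that empties a
#' cluster is retried with fresh draws.
#'
#' @inheritParams update_centers
#' @param c Number of clusters.
#' @param seed Integer seed for the initial center draw.
#' @param retries Re-draws allowed when an initialisation empties a cluster.
#' @return A list of class `"baseline_report"` with `method`, `canopy`
#'   (smallest center, cm) and sorted `centers`.
#' @export
kmeans_estimate <- function(samples, c, seed = 1L, retries = 5L) {
  X <- as_matrix(sample_set(samples))
  n <- nrow(X)
  if (n < c) {
    stop("k-means needs at least as many samples as clusters", call. = FALSE)
  }
  fit <- withr::with_seed(seed, {
    for (attempt in seq_len(retries + 1L)) {
      init <- X[sample.int(n, c), , drop = FALSE]
      res <- tryCatch(
        stats::kmeans(X, centers = init, iter.max = 100, algorithm = "Lloyd"),
        error = function(e) e,
        warning = function(w) {
          suppressWarnings(
            stats::kmeans(X, centers = init, iter.max = 100, algorithm = "Lloyd")
          )
        }
      )
      if (!inherits(res, "error")) break
    }
    res
  })
  if (inherits(fit, "error")) {
    stop("k-means failed after ", retries, " reseeds: ",
      conditionMessage(fit),
      call. = FALSE
    )
  }
  centers <- unname(sort(fit$centers[, 1]))
  baseline_report("k-means", centers[1], centers)
}

#' Mean baseline
#'
#' @inheritParams update_centers
#' @return A `"baseline_report"` whose canopy estimate is the arithmetic
#'   mean of all range readings.
#' @export
mean_estimate <- function(samples) {
  X <- as_matrix(sample_set(samples))
  baseline_report("mean", mean(X[, 1]))
}

#' Median baseline
#'
#' @inheritParams update_centers
#' @return A `"baseline_report"` whose canopy estimate is the sample median
#'   (mean of the middle two readings for even `n`).
#' @export
median_estimate <- function(samples) {
  X <- as_matrix(sample_set(samples))
  baseline_report("median", stats::median(X[, 1]))
}

baseline_report <- function(method, canopy, centers = NULL) {
  stopifnot(is.finite(canopy), canopy > 0)
  structure(
    list(method = method, canopy = canopy, centers = centers),
    class = "baseline_report"
  )
}

#' @export
print.baseline_report <- function(x, ...) {
  cat(sprintf("<baseline_report> %s: canopy %.2f cm\n", x$method, x$canopy))
  if (!is.null(x$centers)) {
    cat("  centers:", paste(sprintf("%.2f", x$centers), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare all estimators on one scan
#'
#' Runs fuzzy ISODATA, k-means (with the cluster count the fuzzy model
#' settled on), mean and median on the same range data and tabulates the
#' canopy estimates, with absolute errors when the true canopy distance is
#' known.
#'
#' @inheritParams run_fuzzy_isodata
#' @param truth_canopy Optional true sensor-to-canopy distance, cm.
#' @param seed Seed for the k-means initialisation.
#' @return A data frame with columns `method`, `canopy_cm` and (if truth is
#'   supplied) `abs_error_cm`.
#' @export
compare_estimators <- function(samples, config = isodata_config(),
                               truth_canopy = NULL, seed = 1L) {
  X <- sample_set(samples)
  model <- run_fuzzy_isodata(X, config)
  ests <- c(
    "fuzzy-isodata" = cluster_centers(model)[1],
    "k-means" = kmeans_estimate(X, nrow(model$centers), seed = seed)$canopy,
    "mean" = mean_estimate(X)$canopy,
    "median" = median_estimate(X)$canopy
  )
  out <- data.frame(
    method = names(ests), canopy_cm = unname(ests),
    stringsAsFactors = FALSE
  )
  if (!is.null(truth_canopy)) {
    out$abs_error_cm <- abs(out$canopy_cm - truth_canopy)
  }
  out
}
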