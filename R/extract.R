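#' Extract canopy and ground distances from a clustered scan
#'
#' The canopy is the cluster closest to the sensor and the ground the cluster
#' farthest from it, so the canopy distance is the smallest cluster center
#' and the ground distance the largest — but only if the largest center is
#' plausible as ground. Once the canopy closes over (large plants), the
#' sound no longer reaches the soil and the farthest cluster is just another
#' leaf layer; the plausibility check compares the largest center against the
#' known sensor mounting height (`nominal_ground`) and rejects it when it is
#' off by more than `ground_tol`. A rejected ground does not affect the
#' canopy estimate. Canopy height is the difference
#' `ground_distance - canopy_distance`, available only when the ground was
#' detected.
#'
#' @param model A `"canopy_model"` from [run_fuzzy_isodata()], or a numeric
#'   vector of cluster centers (cm) for direct use.
#' @param nominal_ground Known sensor-to-soil mounting distance, cm
#'   (default 81, a boom-bench mounting height of 0.81 m).
#' @param ground_tol Absolute tolerance around `nominal_ground` within which
#'   the farthest cluster is accepted as ground, cm (default 5).
#' @return A list of class `"canopy_result"`: `canopy_distance`,
#'   `ground_distance` (`NA` if not detected), `ground_detected`,
#'   `canopy_height` (`NA` if no ground), `nominal_ground`, `ground_tol`,
#'   `cluster_centers` (sorted ascending) and `v_pe` (entropy of the model's
#'   partition, `NA` when raw centers were supplied).
#' @examples
#' extract_canopy_ground(c(63.25, 80.17), nominal_ground = 81)
#' @export
extract_canopy_ground <- function(model, nominal_ground = 81, ground_tol = 5) {
  stopifnot(nominal_ground > 0, ground_tol >= 0)
  if (inherits(model, "canopy_model")) {
    centers <- cluster_centers(model)
    v_pe <- model$entropy$v_pe
  } else {
    centers <- as.numeric(model)
    v_pe <- NA_real_
  }
  if (!is.numeric(centers) || length(centers) < 2) {
    stop("need at least 2 cluster centers to separate the canopy from ",
      "anything else",
      call. = FALSE
    )
  }
  centers <- sort(centers)
  canopy <- centers[1]
  farthest <- centers[length(centers)]
  detected <- abs(farthest - nominal_ground) <= ground_tol
  structure(
    list(
      canopy_distance = canopy,
      ground_distance = if (detected) farthest else NA_real_,
      ground_detected = detected,
      canopy_height = if (detected) farthest - canopy else NA_real_,
      nominal_ground = nominal_ground, ground_tol = ground_tol,
      cluster_centers = centers, v_pe = v_pe
    ),
    class = "canopy_result"
  )
}

#' @export
print.canopy_result <- function(x, ...) {
  cat(sprintf("<canopy_result> canopy at %.2f cm\n", x$canopy_distance))
  if (x$ground_detected) {
    cat(sprintf(
      "  ground at %.2f cm -> canopy height %.2f cm\n",
      x$ground_distance, x$canopy_height
    ))
  } else {
    cat(sprintf(
      "  ground not detected (farthest center %.2f cm vs nominal %.2f +/- %.1f)\n",
      x$cluster_centers[length(x$cluster_centers)],
      x$nominal_ground, x$ground_tol
    ))
  }
  cat(
    "  centers (cm):",
    paste(sprintf("%.2f", x$cluster_centers), collapse = ", "), "\n"
  )
  invisible(x)
}
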