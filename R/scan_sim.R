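#' Plant echo profile
#'
#' Describes the echo structure a single plant presents to a downward-looking
#' ultrasonic sensor: the canopy (top leaf layer) distance, zero or more
#' lower leaf layers, the fraction of the plant footprint each layer returns,
#' and whether sound still reaches the soil between or through the leaves.
#' The canopy occupies the middle of the footprint and deeper layers sit
#' progressively toward its edges, which is where lower leaves peek out from
#' under the top ones.
#'
#' @param canopy_distance Sensor-to-canopy distance, cm.
#' @param lower_leaf_distances Sensor-to-lower-leaf distances, cm (0-3
#'   layers), each deeper than the canopy.
#' @param layer_widths Fractions of the footprint returning each layer
#'   (canopy first); normalised internally. Default: equal fractions.
#' @param footprint_frac Fraction of the plant spacing covered by the plant
#'   (the rest shows ground, when visible).
#' @param ground_visible Does any sound reach the soil around this plant?
#' @param stage Optional growth-stage label carried along for bookkeeping.
#' @return A list of class `"plant_profile"`.
#' @seealso [stage_preset()] for ready-made corn growth-stage profiles.
#' @export
plant_profile <- function(canopy_distance, lower_leaf_distances = numeric(0),
                          layer_widths = NULL, footprint_frac = 0.5,
                          ground_visible = TRUE, stage = NA_character_) {
  stopifnot(
    canopy_distance > 0,
    length(lower_leaf_distances) <= 3,
    all(lower_leaf_distances > canopy_distance),
    footprint_frac > 0, footprint_frac <= 1
  )
  if (is.unsorted(lower_leaf_distances)) {
    stop("lower leaf layers must be ordered shallow to deep", call. = FALSE)
  }
  k <- 1 + length(lower_leaf_distances)
  if (is.null(layer_widths)) layer_widths <- rep(1 / k, k)
  stopifnot(length(layer_widths) == k, all(layer_widths > 0))
  structure(
    list(
      canopy_distance = canopy_distance,
      lower_leaf_distances = lower_leaf_distances,
      layer_widths = layer_widths / sum(layer_widths),
      footprint_frac = footprint_frac,
      ground_visible = isTRUE(ground_visible),
      stage = stage
    ),
    class = "plant_profile"
  )
}

#' Corn growth-stage presets
#'
#' Ready-made [plant_profile()]s for corn from the 3-leaf to the 6-leaf
#' stage. The presets mirror how the echo structure develops as the plant
#' grows: a 3-leaf plant shows only canopy and ground; each following stage
#' adds one lower leaf layer and widens the footprint; by the 6-leaf stage
#' the canopy has closed over and the soil is no longer visible, so a scan
#' contains four leaf levels and no ground echo. Cluster counts recovered
#' from noiseless scans of the four presets are therefore 2, 3, 4 and 4.
#'
#' The 3- and 4-leaf layer distances are typical bench values for potted
#' corn under a sensor mounted 81 cm above the soil. For the 4-level presets
#' the adjacent layers are spaced 11-12 cm apart: the presets idealise each
#' leaf level as a single discrete distance, and with the default split
#' threshold (`theta_S = 5` cm) a two-level cluster is only recognisably
#' over-dispersed when its levels are at least two thresholds apart. Real
#' canopies present a continuous spread around each level instead; see the
#' package vignette.
#'
#' @param stage One of `"3-leaf"`, `"4-leaf"`, `"5-leaf"`, `"6-leaf"`.
#' @return A [plant_profile()].
#' @examples
#' stage_preset("4-leaf")
#' @export
stage_preset <- function(stage = c("3-leaf", "4-leaf", "5-leaf", "6-leaf")) {
  stage <- match.arg(stage)
  switch(stage,
    "3-leaf" = plant_profile(63.25,
      footprint_frac = 0.40, stage = stage
    ),
    "4-leaf" = plant_profile(59.81, 65.53,
      layer_widths = c(0.6, 0.4), footprint_frac = 0.55, stage = stage
    ),
    "5-leaf" = plant_profile(44.26, c(56.2, 68.1),
      layer_widths = c(0.5, 0.3, 0.2), footprint_frac = 0.70, stage = stage
    ),
    "6-leaf" = plant_profile(39.71, c(50.7, 61.7, 72.7),
      layer_widths = rep(0.25, 4), footprint_frac = 1.0,
      ground_visible = FALSE, stage = stage
    )
  )
}

#' Scan scenario
#'
#' Bench geometry and sensing parameters for a simulated scan: plants placed
#' at a regular spacing under a rail, a sensor moving over them at a given
#' speed, and the known mounting height above the soil. The sample rate
#' default (45 Hz) is set so that a five-plant scan at 6 km/h yields about
#' 40 range readings, the point count reported for fast passes of boom-
#' mounted ultrasonic sensors; sample count scales inversely with speed.
#'
#' @param plants A stage name (recycled to `n_plants` identical plants), a
#'   single [plant_profile()], or a list of profiles (its length overrides
#'   `n_plants`).
#' @param n_plants Number of plants under the rail.
#' @param plant_spacing Plant interval along the rail, m.
#' @param nominal_ground Sensor-to-soil mounting distance, cm.
#' @param speed Sensor travel speed, km/h, in `(0, 10]`.
#' @param sample_rate Ranging rate, Hz.
#' @param noise_sd Gaussian measurement noise, cm. Noise values are drawn on
#'   a fixed spatial lattice (pitch = the sample spacing at 0.5 km/h), so
#'   scans that share a seed also share noise at shared positions across
#'   speeds — a common-random-numbers design that makes speed comparisons
#'   paired rather than independent.
#' @param dropout_prob Probability that a sample's first echo is lost to an
#'   inclined leaf, in `[0, 1)`.
#' @param dropout_policy What the sensor reports for a lost echo:
#'   `"deeper"` (default) substitutes the next deeper visible surface,
#'   emulating a missed first echo; `"max-range"` reports the sensor ceiling.
#' @param max_range Sensor ceiling used by the `"max-range"` policy, cm.
#' @param seed Integer seed; scans are deterministic given the scenario.
#' @return A list of class `"scan_scenario"`.
#' @export
scan_scenario <- function(plants = "4-leaf", n_plants = 5, plant_spacing = 0.3,
                          nominal_ground = 81, speed = 1, sample_rate = 45,
                          noise_sd = 0.5, dropout_prob = 0.05,
                          dropout_policy = c("deeper", "max-range"),
                          max_range = 1100, seed = 1L) {
  if (is.character(plants)) {
    plants <- replicate(n_plants, stage_preset(plants), simplify = FALSE)
  } else if (inherits(plants, "plant_profile")) {
    plants <- replicate(n_plants, plants, simplify = FALSE)
  }
  stopifnot(
    is.list(plants), length(plants) >= 1,
    all(vapply(plants, inherits, logical(1), "plant_profile")),
    plant_spacing > 0, nominal_ground > 0,
    speed > 0, speed <= 10, sample_rate > 0,
    noise_sd >= 0, dropout_prob >= 0, dropout_prob < 1
  )
  for (p in plants) {
    if (any(c(p$canopy_distance, p$lower_leaf_distances) >= nominal_ground)) {
      stop("all plant layers must be closer than the nominal ground (",
        nominal_ground, " cm)",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      plants = plants, n_plants = length(plants),
      plant_spacing = plant_spacing, nominal_ground = nominal_ground,
      speed = speed, sample_rate = sample_rate, noise_sd = noise_sd,
      dropout_prob = dropout_prob,
      dropout_policy = match.arg(dropout_policy),
      max_range = max_range, seed = as.integer(seed)
    ),
    class = "scan_scenario"
  )
}

#' @export
print.scan_scenario <- function(x, ...) {
  stages <- unique(vapply(x$plants, `[[`, character(1), "stage"))
  cat(sprintf(
    "<scan_scenario> %d plant(s) [%s] @ %.2f m, %.1f km/h, %.0f Hz\n",
    x$n_plants, paste(stages, collapse = ","), x$plant_spacing, x$speed,
    x$sample_rate
  ))
  cat(sprintf(
    "  ground %.1f cm | noise sd %.2f cm | dropout %.2f (%s) | seed %d\n",
    x$nominal_ground, x$noise_sd, x$dropout_prob, x$dropout_policy, x$seed
  ))
  invisible(x)
}

# layer under a rail position: list(distance, label, profile index)
# label codes: 0 canopy, k = 1..3 lower leaf k, -1 ground
layer_at <- function(scenario, pos) {
  sp <- scenario$plant_spacing
  j <- pmin(pmax(floor(pos / sp) + 1, 1), scenario$n_plants)
  plant <- scenario$plants[[j]]
  center <- (j - 0.5) * sp
  off <- abs(pos - center) / (plant$footprint_frac * sp / 2)
  if (off <= 1) {
    cum <- cumsum(plant$layer_widths)
    k <- which(off <= cum + 1e-12)[1]
    if (k == 1) {
      list(distance = plant$canopy_distance, code = 0L, plant = j)
    } else {
      list(distance = plant$lower_leaf_distances[k - 1], code = k - 1L, plant = j)
    }
  } else if (plant$ground_visible) {
    list(distance = scenario$nominal_ground, code = -1L, plant = j)
  } else {
    # closed canopy: the gap region is covered by the deepest leaf layer
    k <- length(plant$layer_widths)
    d <- if (k == 1) plant$canopy_distance else plant$lower_leaf_distances[k - 1]
    list(distance = d, code = k - 1L, plant = j)
  }
}

# next deeper visible surface under a position, or NULL if none
deeper_surface <- function(scenario, info) {
  plant <- scenario$plants[[info$plant]]
  n_leaf <- length(plant$lower_leaf_distances)
  code <- info$code
  if (code >= 0 && code < n_leaf) {
    list(distance = plant$lower_leaf_distances[code + 1], code = code + 1L)
  } else if (code >= 0 && plant$ground_visible) {
    list(distance = scenario$nominal_ground, code = -1L)
  } else {
    NULL
  }
}

code_label <- function(code) {
  ifelse(code == 0L, "canopy", ifelse(code == -1L, "ground",
    paste0("leaf-", code)
  ))
}

#' Simulate an ultrasonic range scan
#'
#' Sweeps the sensor along the rail at the scenario speed, sampling the
#' surface directly underneath at the scenario rate: the sample count is
#' `floor(track_length / (speed * sample_interval))`, so faster passes
#' acquire proportionally fewer points. Each reading is the underlying layer
#' distance plus Gaussian noise; with probability `dropout_prob` the first
#' echo is lost and replaced according to the dropout policy, and the sample
#' is labelled `"dropout"`. Deterministic given the scenario seed.
#'
#' @param scenario A [scan_scenario()].
#' @return A data frame of class `"labeled_scan"` with columns `position_m`,
#'   `distance_cm` and `label` (`"canopy"`, `"leaf-1"`..., `"ground"`,
#'   `"dropout"`), and attributes `truth` (list with `canopy_cm`,
#'   `ground_cm` — `NA` when no soil is visible — and `layers_cm`) and
#'   `scenario`.
#' @examples
#' scan <- simulate_scan(scan_scenario("3-leaf", noise_sd = 0, dropout_prob = 0))
#' table(scan$label)
#' @export
simulate_scan <- function(scenario) {
  stopifnot(inherits(scenario, "scan_scenario"))
  track <- scenario$n_plants * scenario$plant_spacing
  step <- (scenario$speed / 3.6) / scenario$sample_rate
  n <- floor(track / step)
  if (n < 1) {
    stop("scenario yields zero samples: speed too high for the track",
      call. = FALSE
    )
  }
  pos <- (seq_len(n) - 1) * step
  # speed-independent noise lattice (common random numbers across speeds)
  pitch <- min(step, (0.5 / 3.6) / scenario$sample_rate)
  idx <- as.integer(round(pos / pitch)) + 1L
  nlat <- max(floor(track / pitch) + 1L, max(idx))
  fields <- withr::with_seed(scenario$seed, list(
    noise = stats::rnorm(nlat, 0, scenario$noise_sd),
    drop = stats::runif(nlat)
  ))

  info <- lapply(pos, layer_at, scenario = scenario)
  base <- vapply(info, `[[`, numeric(1), "distance")
  code <- vapply(info, `[[`, integer(1), "code")
  label <- code_label(code)

  lost <- fields$drop[idx] < scenario$dropout_prob
  for (s in which(lost)) {
    if (scenario$dropout_policy == "max-range") {
      base[s] <- scenario$max_range
      label[s] <- "dropout"
    } else {
      deeper <- deeper_surface(scenario, info[[s]])
      if (!is.null(deeper)) {
        base[s] <- deeper$distance
        label[s] <- "dropout"
      }
    }
  }
  dist_cm <- base + fields$noise[idx]

  layers <- sort(unique(unlist(lapply(scenario$plants, function(p) {
    c(p$canopy_distance, p$lower_leaf_distances)
  }))))
  truth <- list(
    canopy_cm = min(vapply(
      scenario$plants, `[[`, numeric(1), "canopy_distance"
    )),
    ground_cm = if (any(code == -1L)) scenario$nominal_ground else NA_real_,
    layers_cm = layers
  )
  out <- data.frame(
    position_m = pos, distance_cm = dist_cm, label = label,
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- truth
  attr(out, "scenario") <- scenario
  class(out) <- c("labeled_scan", class(out))
  out
}

#' Ground truth of a simulated scan
#'
#' @param scan A `"labeled_scan"` from [simulate_scan()].
#' @return The truth list (`canopy_cm`, `ground_cm`, `layers_cm`).
#' @export
scan_truth <- function(scan) {
  t <- attr(scan, "truth")
  if (is.null(t)) {
    stop("scan carries no ground truth (not a simulated scan?)", call. = FALSE)
  }
  t
}

#' Canopy estimation error across sensor speeds
#'
#' Re-simulates the base scenario at each speed, runs the full fuzzy ISODATA
#' pipeline, and averages the absolute canopy-distance error over seeded
#' replicates. Replicate `r` uses seed `base seed + r` at every speed, so the
#' per-speed errors are positively correlated (paired by noise field) and
#' speed contrasts are sharper than with independent draws. Fewer samples
#' are available at higher speeds, so the error grows with speed.
#'
#' @param scenario_base A [scan_scenario()]; its `speed` is overridden.
#' @param speeds Speeds to sweep, km/h.
#' @param replicates Seeded replicates per speed.
#' @param config An [isodata_config()] for the pipeline.
#' @param ground_tol Ground plausibility tolerance passed to
#'   [extract_canopy_ground()].
#' @return A data frame with one row per speed: `speed_kmh`, `n_samples`,
#'   `mean_abs_error_cm`, `sd_abs_error_cm`, `replicates`.
#' @export
speed_sweep <- function(scenario_base, speeds = c(0.5, 1, 2, 4, 6),
                        replicates = 20, config = isodata_config(),
                        ground_tol = 5) {
  stopifnot(inherits(scenario_base, "scan_scenario"), replicates >= 1)
  rows <- lapply(speeds, function(v) {
    errs <- ns <- numeric(replicates)
    for (r in seq_len(replicates)) {
      scen <- scenario_base
      scen$speed <- v
      scen$seed <- scenario_base$seed + r
      scan <- simulate_scan(scen)
      model <- run_fuzzy_isodata(scan$distance_cm, config)
      res <- extract_canopy_ground(model, scen$nominal_ground, ground_tol)
      errs[r] <- abs(res$canopy_distance - scan_truth(scan)$canopy_cm)
      ns[r] <- nrow(scan)
    }
    data.frame(
      speed_kmh = v, n_samples = mean(ns),
      mean_abs_error_cm = mean(errs), sd_abs_error_cm = stats::sd(errs),
      replicates = replicates
    )
  })
  do.call(rbind, rows)
}
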