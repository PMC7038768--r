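#' Range-scan sample set
#'
#' Validating constructor for the sample container used throughout the
#' package: an `n x d` numeric matrix of `n` samples with `d` characteristic
#' indicators each. For ultrasonic range scans `d = 1` and the values are
#' sensor-to-surface distances in centimetres.
#'
#' @param values Numeric vector (taken as a single indicator, `d = 1`) or an
#'   `n x d` numeric matrix.
#' @param max_range Maximum admissible range reading in cm. Range data must be
#'   strictly positive and no larger than this; defaults to 1100 cm (an 11 m
#'   sensing ceiling, typical of agricultural ultrasonic transducers). Set to
#'   `Inf` to validate generic (non-range) data.
#'
#' @return A numeric matrix of class `"sample_set"` with attribute
#'   `max_range`.
#' @examples
#' x <- sample_set(c(63.1, 63.4, 80.8, 81.2))
#' nrow(x)
#' @export
sample_set <- function(values, max_range = 1100) {
  if (inherits(values, "sample_set")) {
    return(values)
  }
  x <- if (is.matrix(values)) values else matrix(as.numeric(values), ncol = 1)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) {
    stop("a sample set needs at least 2 samples, got ", nrow(x), call. = FALSE)
  }
  if (ncol(x) < 1) {
    stop("a sample set needs at least 1 indicator column", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("all sample values must be finite", call. = FALSE)
  }
  if (is.finite(max_range) && (any(x <= 0) || any(x > max_range))) {
    stop("range samples must lie in (0, ", max_range, "] cm", call. = FALSE)
  }
  structure(x, class = c("sample_set", class(x)), max_range = max_range)
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples x %d indicator(s)\n", nrow(x), ncol(x)))
  rng <- range(x)
  cat(sprintf("  values in [%.2f, %.2f]\n", rng[1], rng[2]))
  invisible(x)
}

# strip class/attrs so matrix arithmetic stays plain
as_matrix <- function(x) {
  if (inherits(x, "sample_set")) {
    attributes(x) <- list(dim = dim(x))
  }
  x
}

#' Fuzzy partition matrix
#'
#' Validates a `c x n` matrix `U` of membership degrees `u_ij` of sample `j`
#' in cluster `i`. A valid fuzzy partition has all entries in `[0, 1]`, every
#' column summing to 1 (each sample distributes its full unit of membership
#' over the clusters), and every row sum strictly inside `(0, n)` (no cluster
#' is empty, none owns everything).
#'
#' @param U Numeric `c x n` matrix of membership degrees.
#' @param tol Tolerance on the column-sum constraint.
#' @return `U` with class `"fuzzy_partition"`.
#' @export
fuzzy_partition <- function(U, tol = 1e-9) {
  if (inherits(U, "fuzzy_partition")) {
    return(U)
  }
  U <- as.matrix(U)
  storage.mode(U) <- "double"
  n <- ncol(U)
  if (any(U < 0) || any(U > 1)) {
    stop("membership degrees must lie in [0, 1]", call. = FALSE)
  }
  cs <- colSums(U)
  if (any(abs(cs - 1) > tol)) {
    bad <- which.max(abs(cs - 1))
    stop(sprintf(
      "membership columns must sum to 1 (column %d sums to %.12f)", bad, cs[bad]
    ), call. = FALSE)
  }
  rs <- rowSums(U)
  if (any(rs <= 0) || any(rs >= n)) {
    stop("every cluster row sum must lie strictly in (0, n)", call. = FALSE)
  }
  structure(U, class = c("fuzzy_partition", class(U)))
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy_partition> %d clusters x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

# crisp c x n partition from integer labels; errors if any cluster is empty
crisp_partition <- function(labels, c) {
  n <- length(labels)
  U <- matrix(0, nrow = c, ncol = n)
  U[cbind(labels, seq_len(n))] <- 1
  fuzzy_partition(U)
}

# validate a center matrix against a sample set
center_set <- function(centers, n = Inf) {
  V <- if (is.matrix(centers)) centers else matrix(as.numeric(centers), ncol = 1)
  storage.mode(V) <- "double"
  if (nrow(V) < 1 || !all(is.finite(V))) {
    stop("cluster centers must be a non-empty finite matrix", call. = FALSE)
  }
  if (nrow(V) > n) {
    stop("cannot have more cluster centers than samples", call. = FALSE)
  }
  V
}
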