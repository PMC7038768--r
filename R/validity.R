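#' Partition entropy of a fuzzy clustering
#'
#' The average fuzzy entropy
#' \deqn{v_{PE}(U) = -\frac{1}{n} \sum_{j=1}^{n} \sum_{i=1}^{c}
#'       u_{ij} \ln(u_{ij}),}
#' with \eqn{u \ln u \equiv 0} at \eqn{u = 0} by continuity. It ranges from 0
#' for a crisp partition to \eqn{\ln(c)} for the uniform (maximally uncertain)
#' partition; smaller values indicate a more decisive clustering and hence a
#' better separation of the echo levels.
#'
#' @param partition A `c x n` [fuzzy_partition()].
#' @return A list of class `"entropy_report"` with elements `v_pe`, `c` and
#'   `normalized` (`v_pe / log(c)`).
#' @examples
#' fuzzy_entropy(matrix(c(1, 0, 0, 1), nrow = 2))$v_pe # crisp: 0
#' @export
fuzzy_entropy <- function(partition) {
  U <- unclass(fuzzy_partition(partition))
  H <- U * log(U)
  H[U == 0] <- 0
  v <- -sum(H) / ncol(U)
  structure(
    list(v_pe = v, c = nrow(U), normalized = v / log(nrow(U))),
    class = "entropy_report"
  )
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf(
    "<entropy_report> v_PE = %.4f (c = %d, normalized %.4f of ln c)\n",
    x$v_pe, x$c, x$normalized
  ))
  invisible(x)
}
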