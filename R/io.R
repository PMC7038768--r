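# classed conditions so the CLI can map failures to exit codes
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = "canopyclust_input_error"))
}

#' Read a range scan from CSV
#'
#' Expects a header with at least a `distance_cm` column (or `distance_m`
#' when `unit = "m"`; values are converted to cm on read). A `position_m`
#' column and a `label` column are carried through when present and ignored
#' by clustering. Malformed input — empty file, missing column, non-numeric
#' cell — raises an input error naming the offending line.
#'
#' @param path CSV file path.
#' @param unit Distance unit in the file, `"cm"` (default) or `"m"`.
#' @return A data frame with columns `position_m` (may be `NA`),
#'   `distance_cm`, and `label` if present.
#' @export
read_scan_csv <- function(path, unit = c("cm", "m")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) {
    stop_input("scan file not found: ", path)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop_input("cannot parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(df) == 0 || ncol(df) == 0) {
    stop_input(path, ": no data rows")
  }
  dcol <- if (unit == "cm") "distance_cm" else "distance_m"
  if (!dcol %in% names(df)) {
    stop_input(path, ": missing required column '", dcol, "'")
  }
  d <- suppressWarnings(as.numeric(df[[dcol]]))
  bad <- which(!is.finite(d))
  if (length(bad) > 0) {
    stop_input(sprintf(
      "%s: line %d: non-numeric distance '%s'",
      path, bad[1] + 1L, df[[dcol]][bad[1]]
    ))
  }
  if (unit == "m") d <- d * 100
  out <- data.frame(
    position_m = if ("position_m" %in% names(df)) {
      suppressWarnings(as.numeric(df$position_m))
    } else {
      NA_real_
    },
    distance_cm = d,
    stringsAsFactors = FALSE
  )
  if ("label" %in% names(df)) out$label <- df$label
  out
}

#' Write a scan to CSV
#'
#' Emits `position_m,distance_cm[,label]`, the interchange format the
#' clustering command reads back.
#'
#' @param scan A data frame with `position_m` and `distance_cm` (a
#'   `"labeled_scan"` keeps its `label` column).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  cols <- intersect(c("position_m", "distance_cm", "label"), names(scan))
  utils::write.csv(as.data.frame(scan)[, cols], path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
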