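#' Write a plate table to CSV
#'
#' Long-format, comma-separated, dot decimal, one header row; provenance
#' metadata (package version and, when given, seed) is written as `#`
#' comment lines that [load_plate()] skips.
#'
#' @param plate Plate tibble (see [generate_plate()]).
#' @param path Output file path.
#' @param seed Optional seed recorded in the header metadata.
#' @export
write_plate <- function(plate, path, seed = NULL) {
  check_plate_columns(plate)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# phenazox plate table v%s",
                     as.character(utils::packageVersion("phenazox"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  write.csv(as.data.frame(plate), con, row.names = FALSE)
  invisible(path)
}

#' Load and validate a plate table
#'
#' Reads a long-format plate CSV, checks the required columns, and
#' validates every well: strictly increasing times (a duplicated time point
#' is an error naming the well), non-negative fluorescence, at least two
#' time points. The number of wells and any dropped rows are reported.
#'
#' @param path Path to a CSV written by [write_plate()] or of the same
#'   shape.
#' @return A validated plate tibble.
#' @export
load_plate <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  check_plate_columns(df)
  n0 <- nrow(df)
  df <- df[is.finite(df$time_h) & is.finite(df$fluorescence), , drop = FALSE]
  dropped <- n0 - nrow(df)
  for (w in unique(df$well)) {
    tw <- df$time_h[df$well == w]
    if (anyDuplicated(tw)) {
      stop("well '", w, "': duplicated time point(s)", call. = FALSE)
    }
    if (is.unsorted(tw, strictly = TRUE)) {
      stop("well '", w, "': time not strictly increasing", call. = FALSE)
    }
    if (length(tw) < 2L) stop("well '", w, "': fewer than 2 time points", call. = FALSE)
    fl <- df$fluorescence[df$well == w]
    if (any(fl < 0)) stop("well '", w, "': negative fluorescence", call. = FALSE)
  }
  message(length(unique(df$well)), " well(s) loaded, ", dropped, " row(s) dropped")
  tibble::as_tibble(df)
}

#' Write an electron-transport-chain trajectory as long-format CSV
#'
#' Columns `time_h`, `variable`, `value`.
#'
#' @param traj An `etc_trajectory` from [simulate_etc()].
#' @param path Output path.
#' @export
write_trajectory <- function(traj, path) {
  long <- tidyr::pivot_longer(tibble::as_tibble(traj), -"time_h",
                              names_to = "variable", values_to = "value")
  write.csv(as.data.frame(long), path, row.names = FALSE)
  invisible(path)
}
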