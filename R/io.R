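#' Read a space-delimited measurement file
#'
#' Parses the measurement dialect used for the aggregated fluorescence
#' series: whitespace-separated numeric columns `(t, Rab5, Rab7)`, lines
#' beginning with `#` ignored. The time axis can be shifted by a constant on
#' read; the published aggregated series uses a shift of 828.56 s to align
#' measurement time with the simulation window of earlier studies (its raw
#' time axis places the conversion switch at 0 s).
#'
#' @param path File to read.
#' @param time_shift Constant added to the time column (s); default 0.
#' @param col_order Mapping of the first three columns; a permutation of
#'   `c("t", "Rab5", "Rab7")`.
#' @param persistence Persistence window (s) for switch detection.
#' @param t_s Optional externally supplied switch time (after shifting).
#' @return A `rab_dataset`.
#' @export
read_measurements <- function(path, time_shift = 0,
                              col_order = c("t", "Rab5", "Rab7"),
                              persistence = 5, t_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(setequal(col_order, c("t", "Rab5", "Rab7")))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("no data lines in ", path, call. = FALSE)

  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- keep[which(nf < 3L)[1]]
    stop("line ", bad, ": expected at least 3 whitespace-separated columns, found ",
         nf[which(nf < 3L)[1]], call. = FALSE)
  }
  cols <- lapply(1:3, function(j) {
    vals <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", j)))
    if (anyNA(vals)) {
      bad <- keep[which(is.na(vals))[1]]
      stop("line ", bad, ": non-numeric value in column ", j, call. = FALSE)
    }
    vals
  })
  names(cols) <- col_order
  t <- cols$t + time_shift
  if (any(diff(t) <= 0)) {
    bad <- keep[which(diff(t) <= 0)[1] + 1L]
    stop("line ", bad, ": time points must be strictly increasing",
         call. = FALSE)
  }
  rab_dataset(t, cols$Rab5, cols$Rab7, t_s = t_s, persistence = persistence)
}

#' Write a dataset in the space-delimited measurement dialect
#'
#' @param dataset A `rab_dataset` (or data frame with `t`, `Rab5`, `Rab7`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(dataset, path) {
  lines <- c("# t Rab5 Rab7",
             sprintf("%.12g %.12g %.12g",
                     dataset$t, dataset$Rab5, dataset$Rab7))
  writeLines(lines, path)
  invisible(path)
}

#' Export a trajectory as CSV
#'
#' Columns `t, r5, R5, r7, R7, Rab5_hat, Rab7_hat`, 6 significant digits.
#'
#' @param traj A `rab_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- tibble::as_tibble(traj)
  out[] <- lapply(out, signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
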