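# Plain-text recording and table I/O. A recording is one CSV per run (time x
# channel-by-wavelength intensity matrix) with `#`-prefixed header metadata
# and an events sidecar `<stem>_events.csv`; all numerics are written at full
# 64-bit precision so round trips are loss-free.

#' Documented column order of the block-response table
#' @export
block_table_schema <- c("subject_id", "task_id", "run_index", "channel_id",
                        "block_index", "condition", "mean_hbo", "mean_hbr")

events_path <- function(path) sub("\\.csv$", "", path) |>
  paste0("_events.csv")

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a recording to the delimited on-disk format
#'
#' @param rec `nirs_run`.
#' @param path output CSV path; an events sidecar `<stem>_events.csv` is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  dims <- dim(rec$intensity)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# fcoinirs_recording v1",
    sprintf("# subject_id: %s", rec$subject_id),
    sprintf("# task_id: %s", rec$task_id),
    sprintf("# run_index: %d", rec$run_index),
    sprintf("# sampling_rate_hz: %s", fmt_full(rec$fs)),
    sprintf("# wavelengths_nm: %s",
            paste(rec$montage$wavelengths_nm, collapse = ",")),
    sprintf("# n_channels: %d", dims[2])
  ), con)
  cols <- as.vector(outer(seq_len(dims[2]), seq_len(dims[3]),
                          function(ch, w) sprintf("ch%d_wl%d", ch, w)))
  M <- matrix(rec$intensity, dims[1], dims[2] * dims[3])
  writeLines(paste(c("sample", cols), collapse = ","), con)
  body <- cbind(seq_len(dims[1]),
                matrix(fmt_full(M), dims[1]))
  writeLines(apply(body, 1, paste, collapse = ","), con)
  ev <- rec$events
  ev$onset_s <- fmt_full(ev$onset_s)
  ev$duration_s <- fmt_full(ev$duration_s)
  write.csv(ev, events_path(path), row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_header <- function(lines) {
  kv <- sub("^# *", "", lines[-1])
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  setNames(as.list(vals), keys)
}

#' Load a recording from the delimited on-disk format
#'
#' Validates wavelength and channel metadata against the supplied montage and
#' checks that every event block falls inside the recording span.
#'
#' @param path CSV written by [write_recording()].
#' @param montage `nirs_montage` the file must be consistent with.
#' @return a validated `nirs_run`.
#' @export
load_recording <- function(path, montage) {
  if (!file.exists(path)) stop_fcoi(sprintf("no such file: %s", path),
                                    "fcoi_io_error")
  lines <- readLines(path, n = 20)
  hdr_n <- sum(startsWith(lines, "#"))
  if (hdr_n < 6 || !grepl("fcoinirs_recording", lines[1])) {
    stop_fcoi("not an fcoinirs recording file", "fcoi_format_error")
  }
  hdr <- parse_header(lines[seq_len(hdr_n)])
  wl <- as.numeric(strsplit(hdr$wavelengths_nm, ",")[[1]])
  if (length(wl) != length(montage$wavelengths_nm) ||
      any(wl != montage$wavelengths_nm)) {
    stop_fcoi("file wavelengths do not match the montage",
              "fcoi_format_error")
  }
  n_ch <- as.integer(hdr$n_channels)
  if (n_ch != montage$n_channels) {
    stop_fcoi("file channel count does not match the montage",
              "fcoi_format_error")
  }
  body <- read.csv(path, comment.char = "#", check.names = FALSE)
  n_wl <- length(wl)
  M <- as.matrix(body[, -1, drop = FALSE])
  if (ncol(M) != n_ch * n_wl) {
    stop_fcoi("intensity column count inconsistent with header",
              "fcoi_format_error")
  }
  intensity <- array(M, dim = c(nrow(M), n_ch, n_wl))
  ev <- read.csv(events_path(path), stringsAsFactors = FALSE)
  new_run(hdr$subject_id, hdr$task_id, as.integer(hdr$run_index),
          intensity, ev, montage)
}

#' Write a result table as delimited text
#'
#' Columns are written in their stored order with a header row; numeric
#' values keep full 64-bit precision so write/read round trips are
#' loss-free. Empty tables are an error, never an empty file.
#'
#' @param table non-empty data frame (block responses, fCOI summaries,
#'   model fits, ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  if (is.null(table) || nrow(table) == 0) {
    stop_fcoi("refusing to write an empty table", "fcoi_validation_error")
  }
  out <- table
  for (cc in names(out)) {
    if (is.double(out[[cc]])) out[[cc]] <- fmt_full(out[[cc]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop_fcoi(sprintf("no such file: %s", path),
                                    "fcoi_io_error")
  read.csv(path, stringsAsFactors = FALSE)
}
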