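#' Read and write trace and trial tables
#'
#' Delimited-text I/O for the pipeline's two table formats. Trace files
#' carry columns `time_s`, `angle_deg`, `stream` (plus `trace_id` when
#' several traces share a file); trial tables carry `trial`, `gaze_mode`,
#' `target_presentation`, `background`, `gain`, `comparison_deg`,
#' `response` (plus `subject` for multi-subject tables). Both round-trip
#' exactly; malformed rows raise an error naming the offending line.
#'
#' @param x A [sampled_trace()], or a named list of them (written with a
#'   `trace_id` column).
#' @param file Path to a CSV file.
#' @return `read_traces()` returns a `sampled_trace` or a named list of
#'   them; `read_trials()` returns a data frame; the writers return the
#'   file path invisibly.
#' @name trace-io
NULL

#' @rdname trace-io
#' @export
write_traces <- function(x, file) {
  if (is_sampled_trace(x)) {
    df <- as.data.frame(x)
  } else {
    stopifnot(is.list(x), all(vapply(x, is_sampled_trace, logical(1))))
    ids <- names(x)
    if (is.null(ids)) ids <- as.character(seq_along(x))
    df <- do.call(rbind, lapply(seq_along(x), function(i)
      cbind(trace_id = ids[i], as.data.frame(x[[i]]))))
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname trace-io
#' @export
read_traces <- function(file) {
  df <- read_checked(file, required = c("time_s", "angle_deg", "stream"),
                     numeric_cols = c("time_s", "angle_deg"))
  if (!all(df$stream %in% c("head", "gaze")))
    stop("'stream' must be 'head' or 'gaze' in ", file)
  build <- function(d) sampled_trace(d$time_s, d$angle_deg, d$stream[1])
  if ("trace_id" %in% names(df)) {
    lapply(split(df, factor(df$trace_id, unique(df$trace_id))), build)
  } else {
    build(df)
  }
}

#' @rdname trace-io
#' @param trials Trial table data frame.
#' @export
write_trials <- function(trials, file) {
  req <- c("trial", "gaze_mode", "target_presentation", "background",
           "gain", "comparison_deg", "response")
  missing <- setdiff(req, names(trials))
  if (length(missing))
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  utils::write.csv(trials, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname trace-io
#' @export
read_trials <- function(file) {
  df <- read_checked(
    file,
    required = c("trial", "gaze_mode", "target_presentation",
                 "background", "gain", "comparison_deg", "response"),
    numeric_cols = c("trial", "gain", "comparison_deg"))
  bad <- which(!df$response %in% c("left", "right"))
  if (length(bad))
    stop(sprintf("%s line %d: response must be 'left' or 'right'",
                 file, bad[1] + 1L))
  df
}

# shared reader: header check, per-column numeric validation with line
# numbers (line 1 is the header)
read_checked <- function(file, required, numeric_cols) {
  if (!file.exists(file)) stop("file not found: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing header column(s): %s", file,
                 paste(missing, collapse = ", ")))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "")))
    bad <- c(bad, which(df[[col]] %in% c("NA", "") & FALSE))
    if (length(bad))
      stop(sprintf("%s line %d: non-numeric value '%s' in column '%s'",
                   file, bad[1] + 1L, df[[col]][bad[1]], col))
    df[[col]] <- v
  }
  df
}
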