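#' Sampled angular trace
#'
#' Container for a timestamped angular position stream: head yaw or
#' horizontal gaze position, in degrees. This is the raw input to all
#' event detection.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param angles Numeric vector of angular positions in degrees, same
#'   length as `times`.
#' @param stream Character scalar, `"head"` or `"gaze"`.
#' @param nominal_rate Nominal sample rate in Hz. Defaults to the
#'   reciprocal median inter-sample interval.
#'
#' @return An object of class `sampled_trace`: a list with elements
#'   `times`, `angles`, `stream`, `nominal_rate`.
#' @examples
#' tr <- sampled_trace(seq(0, 1, by = 1/120), rep(0, 121), "gaze")
#' tr
#' @export
sampled_trace <- function(times, angles, stream = c("head", "gaze"),
                          nominal_rate = NULL) {
  stream <- match.arg(stream)
  times <- as.numeric(times)
  angles <- as.numeric(angles)
  if (length(times) != length(angles))
    stop("'times' and 'angles' must have the same length")
  if (length(times) < 2L)
    stop("a trace needs at least 2 samples")
  if (anyNA(times) || anyNA(angles))
    stop("trace contains missing values")
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (is.null(nominal_rate))
    nominal_rate <- 1 / stats::median(diff(times))
  structure(
    list(times = times, angles = angles, stream = stream,
         nominal_rate = nominal_rate),
    class = "sampled_trace"
  )
}

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf(
    "<sampled_trace> %s stream: %d samples, %.3f-%.3f s, ~%.1f Hz\n",
    x$stream, length(x$times), x$times[1], x$times[length(x$times)],
    x$nominal_rate))
  cat(sprintf("  angle range: [%.2f, %.2f] deg\n",
              min(x$angles), max(x$angles)))
  invisible(x)
}

#' @export
length.sampled_trace <- function(x) length(x$times)

#' @export
as.data.frame.sampled_trace <- function(x, ...) {
  data.frame(time_s = x$times, angle_deg = x$angles, stream = x$stream)
}

is_sampled_trace <- function(x) inherits(x, "sampled_trace")

assert_trace <- function(trace) {
  if (!is_sampled_trace(trace))
    stop("expected a 'sampled_trace' object")
  invisible(trace)
}
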