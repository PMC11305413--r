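#' Aggregate 2AFC trials into a response table
#'
#' Counts "right" responses per comparison position, the input format for
#' [fit_psychometric()].
#'
#' @param trials Data frame with columns `comparison_deg` and `response`
#'   (`"left"`/`"right"`). Sessions are pooled: all rows contribute.
#' @return A `response_table` data frame with columns `position`,
#'   `n_right`, `n_total`, sorted by position.
#' @export
tabulate_responses <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("comparison_deg", "response") %in% names(trials)))
  if (!all(trials$response %in% c("left", "right")))
    stop("responses must be 'left' or 'right'")
  pos <- sort(unique(trials$comparison_deg))
  tab <- data.frame(
    position = pos,
    n_right = vapply(pos, function(p)
      sum(trials$response[trials$comparison_deg == p] == "right"),
      numeric(1)),
    n_total = vapply(pos, function(p)
      sum(trials$comparison_deg == p), numeric(1)))
  response_table(tab$position, tab$n_right, tab$n_total)
}

#' Construct a response table from counts
#'
#' @param positions Comparison positions in degrees.
#' @param n_right Count of "right" responses at each position.
#' @param n_total Trials at each position.
#' @return A `response_table` data frame sorted by position.
#' @export
response_table <- function(positions, n_right, n_total) {
  stopifnot(length(positions) == length(n_right),
            length(positions) == length(n_total))
  if (any(n_right < 0) || any(n_right > n_total))
    stop("need 0 <= n_right <= n_total")
  o <- order(positions)
  structure(data.frame(position = positions[o], n_right = n_right[o],
                       n_total = n_total[o]),
            class = c("response_table", "data.frame"))
}

# JND <-> sigma of the cumulative Gaussian.
# "sd": JND = sigma (the 50% -> 84.1% half-width).
# "p75": JND = qnorm(0.75) * sigma (the 50% -> 75% half-width).
jnd_factor <- function(convention = c("sd", "p75")) {
  switch(match.arg(convention), sd = 1, p75 = stats::qnorm(0.75))
}

#' @rdname compute_jnd
#' @param jnd A JND in degrees.
#' @export
jnd_to_sigma <- function(jnd, convention = c("sd", "p75")) {
  jnd / jnd_factor(convention)
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of P(right; x) = Phi((x - mu) / sigma) to
#' binomial response counts. The point of horizontal alignment (PHA) is
#' the 50% point mu — the accuracy of the localization judgement; the
#' just-noticeable difference (JND) is derived from sigma — its precision.
#' The negative log-likelihood is minimized by quasi-Newton (BFGS) search
#' over (mu, log sigma) from `n_starts` seeded multistarts; ties are
#' broken by highest log-likelihood, then smallest sigma. Relative
#' convergence tolerance on the log-likelihood is 1e-8.
#'
#' All-left or all-right response tables are flagged `converged = FALSE`
#' and report no PHA.
#'
#' @param table A `response_table` (see [response_table()],
#'   [tabulate_responses()]); needs at least 2 positions with trials.
#' @param jnd_convention JND convention, see [compute_jnd()].
#' @param stimulus_range Half-range of the comparison positions used for
#'   the inclusion flag, degrees.
#' @param n_starts Number of multistarts.
#' @param start_seed Seed for the multistart jitter.
#' @return Object of class `psychometric_fit`: `pha`, `sigma`, `jnd`
#'   (deg), `log_likelihood` (nats), `converged`, `included`, plus the
#'   data and convention. Supports `print`, `coef`, `logLik`, `predict`
#'   and `plot`.
#' @examples
#' sched <- generate_trial_schedule(trial_schedule_spec(seed = 2))
#' resp <- simulate_responses(sched, observer_spec(pha = 0.2, jnd = 0.8),
#'                            seed = 3)
#' fit_psychometric(tabulate_responses(resp))
#' @export
fit_psychometric <- function(table, jnd_convention = c("sd", "p75"),
                             stimulus_range = 1.37, n_starts = 5L,
                             start_seed = 1L) {
  stopifnot(inherits(table, "response_table"))
  jnd_convention <- match.arg(jnd_convention)
  tab <- table[table$n_total > 0, , drop = FALSE]
  if (nrow(tab) < 2) stop("need at least 2 positions with trials")

  k <- tab$n_right
  n <- tab$n_total
  x <- tab$position
  degenerate <- sum(k) == 0 || sum(k) == sum(n)

  nll <- function(par) {
    p <- stats::pnorm((x - par[1]) / exp(par[2]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log1p(-p))
  }

  if (degenerate) {
    fit <- list(pha = NA_real_, sigma = NA_real_, jnd = NA_real_,
                log_likelihood = NA_real_, converged = FALSE)
  } else {
    # moment starts: empirical 50% crossing and proportion-based spread
    p_emp <- (k + 0.5) / (n + 1)
    mu0 <- stats::weighted.mean(x, w = n * p_emp * (1 - p_emp))
    sd0 <- max(diff(range(x)) / 4, 0.1)
    starts <- with_seed(start_seed, cbind(
      mu = mu0 + c(0, stats::runif(n_starts - 1, -1, 1) * diff(range(x)) / 2),
      logsigma = log(sd0) + c(0, stats::runif(n_starts - 1, -1, 1))))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- tryCatch(
        stats::optim(starts[s, ], nll, method = "BFGS",
                     control = list(reltol = 1e-8, maxit = 500)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value - 1e-12 ||
          (abs(o$value - best$value) <= 1e-12 &&
             exp(o$par[2]) < exp(best$par[2])))
        best <- o
    }
    if (is.null(best)) {
      fit <- list(pha = NA_real_, sigma = NA_real_, jnd = NA_real_,
                  log_likelihood = NA_real_, converged = FALSE)
    } else {
      sigma <- exp(best$par[2])
      fit <- list(pha = unname(best$par[1]), sigma = unname(sigma),
                  jnd = unname(sigma * jnd_factor(jnd_convention)),
                  log_likelihood = -best$value,
                  converged = best$convergence == 0)
    }
  }
  fit$jnd_convention <- jnd_convention
  fit$data <- tab
  fit$included <- isTRUE(fit$converged) && !is.na(fit$pha) &&
    abs(fit$pha) <= stimulus_range
  class(fit) <- "psychometric_fit"
  fit
}

#' Just-noticeable difference of a fitted psychometric function
#'
#' Converts the fitted cumulative-Gaussian spread into a JND under a
#' stated convention: `"sd"` (default) takes JND = sigma, the distance
#' from the 50% to the 84.1% point; `"p75"` takes JND = 0.6745 sigma, the
#' distance to the 75% point. The constant lives here so switching
#' convention is a one-argument change, in the generator and the fit
#' alike.
#'
#' @param fit A converged `psychometric_fit`.
#' @param convention `"sd"` or `"p75"`.
#' @return JND in degrees.
#' @export
compute_jnd <- function(fit, convention = c("sd", "p75")) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge; JND undefined")
  fit$sigma * jnd_factor(match.arg(convention))
}

#' Participant-inclusion check for a psychometric fit
#'
#' A participant (fit) is included when the fit converged and the PHA lies
#' within the presented stimulus range, i.e. the observer could perceive
#' the point of alignment within the tested positions.
#'
#' @param fit A `psychometric_fit`.
#' @param stimulus_range Half-range of the comparison positions, degrees.
#' @return Logical flag.
#' @export
check_inclusion <- function(fit, stimulus_range = 1.37) {
  stopifnot(inherits(fit, "psychometric_fit"))
  isTRUE(fit$converged) && !is.na(fit$pha) &&
    abs(fit$pha) <= stimulus_range
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf(
      "<psychometric_fit> PHA = %.3f deg, JND = %.3f deg (sigma %.3f, %s convention)\n",
      x$pha, x$jnd, x$sigma, x$jnd_convention))
    cat(sprintf("  logLik %.3f; %sincluded (|PHA| %s stimulus range)\n",
                x$log_likelihood, if (x$included) "" else "not ",
                if (x$included) "within" else "outside"))
  } else {
    cat("<psychometric_fit> not converged; no PHA reported\n")
  }
  invisible(x)
}

#' @export
coef.psychometric_fit <- function(object, ...) {
  c(pha = object$pha, sigma = object$sigma)
}

#' @export
logLik.psychometric_fit <- function(object, ...) {
  structure(object$log_likelihood, df = 2, class = "logLik")
}

#' @export
predict.psychometric_fit <- function(object, positions = NULL, ...) {
  if (!isTRUE(object$converged)) stop("cannot predict from unconverged fit")
  if (is.null(positions)) positions <- object$data$position
  stats::pnorm((positions - object$pha) / object$sigma)
}

#' @export
plot.psychometric_fit <- function(x, ...) {
  graphics::plot(x$data$position, x$data$n_right / x$data$n_total,
                 ylim = c(0, 1), xlab = "comparison position (deg)",
                 ylab = "P(right)", main = "Psychometric function", ...)
  if (isTRUE(x$converged)) {
    xs <- seq(min(x$data$position), max(x$data$position), length.out = 200)
    graphics::lines(xs, predict(x, xs), col = "red3", lwd = 2)
    graphics::abline(v = x$pha, lty = 2)
  }
  invisible(x)
}
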