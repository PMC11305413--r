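#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject factorial ANOVA on a fully crossed, balanced table (one
#' value per subject x cell). For every main effect and interaction the F
#' ratio is the effect mean square over its subject-by-effect interaction
#' mean square (the classical univariate within-subject decomposition,
#' computed through [stats::aov()] error strata). Sphericity is handled by
#' the Greenhouse-Geisser epsilon, estimated from the covariance matrix of
#' the effect's orthonormalized within-subject difference scores and
#' applied to both degrees of freedom whenever the effect has more than
#' one numerator df; 2-level factors have epsilon = 1 and need no
#' correction. Partial eta-squared is SS_effect / (SS_effect + SS_error).
#' Observed power is computed from the noncentral F distribution with
#' noncentrality lambda = F x df_num at the alpha = 0.05 critical value
#' (the convention of mainstream GUI statistics packages; approximate).
#'
#' @param data Data frame in long format.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param factors Character vector of within-subject factor columns
#'   (2 or 3 levels each, typically).
#' @param alpha Significance level used for the observed-power
#'   computation.
#' @return Object of class `rm_anova`: a data frame with one row per
#'   effect and columns `effect`, `df_num`, `df_den` (GG-scaled when
#'   applied), `F`, `p`, `gg_epsilon`, `eta_sq_partial`, `power`,
#'   `degenerate`.
#' @examples
#' d <- expand.grid(subject = factor(1:6), mode = c("a", "b"))
#' d$y <- rnorm(nrow(d)) + (d$mode == "b") * 0.5
#' rm_anova(d, dv = "y", subject = "subject", factors = "mode")
#' @export
rm_anova <- function(data, dv, subject, factors, alpha = 0.05) {
  stopifnot(is.data.frame(data),
            all(c(dv, subject, factors) %in% names(data)))
  d <- data.frame(
    .y = data[[dv]],
    .subj = factor(data[[subject]]),
    lapply(data[factors], factor),
    check.names = FALSE)
  n_subj <- nlevels(d$.subj)
  if (n_subj < 2) stop("need at least 2 subjects")
  cells <- interaction(d[factors], drop = FALSE)
  counts <- table(d$.subj, cells)
  if (any(counts != 1))
    stop("table must be balanced and complete: one value per subject x cell")

  rhs <- paste(factors, collapse = " * ")
  form <- stats::as.formula(
    sprintf(".y ~ %s + Error(.subj/(%s))", rhs, rhs))
  fit <- stats::aov(form, data = d)
  s <- summary(fit)
  tot_ss <- sum((d$.y - mean(d$.y))^2)

  rows <- list()
  for (stratum in names(s)) {
    tab <- s[[stratum]][[1]]
    terms <- trimws(rownames(tab))
    eff_i <- which(terms != "Residuals")
    res_i <- which(terms == "Residuals")
    if (!length(eff_i) || !length(res_i)) next
    ss_err <- tab[res_i, "Sum Sq"]
    df_err <- tab[res_i, "Df"]
    for (i in eff_i) {
      eff <- terms[i]
      ss_eff <- tab[i, "Sum Sq"]
      df_eff <- tab[i, "Df"]
      degen <- ss_err <= 1e-12 * max(tot_ss, 1e-300)
      Fval <- if (degen) {
        if (ss_eff <= 1e-12 * max(tot_ss, 1e-300)) 0 else Inf
      } else (ss_eff / df_eff) / (ss_err / df_err)
      eps <- gg_epsilon(d, eff)
      df1 <- df_eff * eps
      df2 <- df_err * eps
      p <- if (degen) { if (is.infinite(Fval)) 0 else 1 } else
        stats::pf(Fval, df1, df2, lower.tail = FALSE)
      eta <- if (ss_eff + ss_err <= 1e-300) 0 else ss_eff / (ss_eff + ss_err)
      pow <- if (degen) { if (is.infinite(Fval)) 1 else alpha } else
        observed_power_f(Fval, df1, df2, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = eff, df_num = df1, df_den = df2, F = Fval, p = p,
        gg_epsilon = eps, eta_sq_partial = eta, power = pow,
        degenerate = degen)
    }
  }
  out <- do.call(rbind, rows)
  # present effects in model order
  ord <- attr(stats::terms(stats::as.formula(paste("~", rhs))),
              "term.labels")
  out <- out[match(ord, out$effect), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

# Greenhouse-Geisser epsilon for one effect, from the covariance of the
# orthonormalized within-subject difference scores. The contrast matrix is
# a Kronecker product over the design's factors: orthonormal between-level
# contrasts for factors in the effect, the normalized unit vector
# (averaging) for the rest. Equals 1 exactly for 1-df effects.
gg_epsilon <- function(d, effect) {
  facs <- names(d)[!names(d) %in% c(".y", ".subj")]
  in_eff <- facs %in% strsplit(effect, ":", fixed = TRUE)[[1]]
  mats <- lapply(seq_along(facs), function(i) {
    k <- nlevels(d[[facs[i]]])
    if (in_eff[i]) t(orthonormal_contrasts(k)) else matrix(1 / k, 1, k)
  })
  M <- Reduce(kronecker, mats)
  if (nrow(M) == 1) return(1)
  # subject x cell matrix, cell order matching the Kronecker product
  # (last factor varying fastest)
  key_d <- do.call(paste, c(d[facs], list(sep = "\r")))
  grid <- expand.grid(lapply(rev(facs), function(f) levels(d[[f]])),
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(facs)), drop = FALSE]
  key_cells <- do.call(paste, c(grid, list(sep = "\r")))
  subj <- levels(d$.subj)
  Y <- matrix(NA_real_, length(subj), length(key_cells))
  for (j in seq_along(key_cells)) {
    sel <- key_d == key_cells[j]
    Y[match(d$.subj[sel], subj), j] <- d$.y[sel]
  }
  S <- stats::cov(Y %*% t(M))
  q <- nrow(M)
  tr <- sum(diag(S))
  denom <- q * sum(S^2)
  if (denom <= 1e-300) return(1)
  min(max(tr^2 / denom, 1 / q), 1)
}

# orthonormal contrasts: an orthonormal basis of the space orthogonal to
# the unit vector in R^k
orthonormal_contrasts <- function(k) {
  qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))[, -1, drop = FALSE]
}

observed_power_f <- function(F, df1, df2, alpha = 0.05) {
  lambda <- F * df1
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' @export
print.rm_anova <- function(x, digits = 3, ...) {
  cat("Repeated-measures ANOVA (Greenhouse-Geisser corrected where needed)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %-30s F(%.4g, %.4g) = %.*f, p = %.4g, eta_p^2 = %.*f, power = %.*f%s\n",
      x$effect[i], x$df_num[i], x$df_den[i], digits, x$F[i], x$p[i],
      digits, x$eta_sq_partial[i], digits, x$power[i],
      if (x$gg_epsilon[i] < 1) sprintf(" [GG eps = %.3f]", x$gg_epsilon[i])
      else ""))
  }
  invisible(x)
}

#' Paired (or unpaired) t-test with Bonferroni correction
#'
#' Two-tailed t-test whose p-value is multiplied by the number of
#' comparisons in the post hoc family (`correction_m`) and capped at 1.
#' Zero-variance input is flagged degenerate instead of erroring: equal
#' samples give t = 0, p = 1.
#'
#' @param a,b Numeric vectors of equal length (paired) or arbitrary
#'   lengths (unpaired).
#' @param correction_m Bonferroni family size (>= 1).
#' @param paired Paired test (default) or unpaired.
#' @return Object of class `effect_result` with `statistic` (t), `df`,
#'   `p` (corrected), `p_uncorrected`, `effect_size` (Cohen's d on the
#'   differences for paired tests) and `degenerate`.
#' @export
paired_t <- function(a, b, correction_m = 1, paired = TRUE) {
  stopifnot(correction_m >= 1)
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    if (length(a) < 2) stop("need at least 2 pairs")
    d <- a - b
    if (stats::sd(d) == 0) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
      return(effect_result("paired t", t, length(d) - 1,
                           min(p * correction_m, 1), p,
                           effect_size = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    es <- mean(d) / stats::sd(d)
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      eq <- mean(a) == mean(b)
      return(effect_result("unpaired t", if (eq) 0 else Inf,
                           length(a) + length(b) - 2,
                           if (eq) 1 else 0, if (eq) 1 else 0,
                           effect_size = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    es <- (mean(a) - mean(b)) / sp
  }
  effect_result(if (paired) "paired t" else "unpaired t",
                unname(tt$statistic), unname(tt$parameter),
                min(tt$p.value * correction_m, 1), tt$p.value,
                effect_size = es, degenerate = FALSE)
}

#' Per-subject regression of PHA on visual velocity gain
#'
#' Fits, for every subject, an ordinary least-squares line through the
#' (gain, PHA) pairs — one PHA per visual velocity gain level. A nonzero
#' mean slope across subjects indicates that the artificial background
#' motion shifted the localization judgement.
#'
#' @param pha_by_gain Data frame with columns `subject`, `gain`, `pha`
#'   (one row per subject x gain; exactly 3 gain levels per subject).
#' @return Object of class `gain_slopes`: data frame with `subject`,
#'   `slope` (deg per unit gain) and `intercept` (deg).
#' @export
fit_gain_slopes <- function(pha_by_gain) {
  stopifnot(is.data.frame(pha_by_gain),
            all(c("subject", "gain", "pha") %in% names(pha_by_gain)))
  out <- lapply(split(pha_by_gain, pha_by_gain$subject), function(di) {
    if (nrow(di) != 3 || length(unique(di$gain)) != 3)
      stop("each subject needs exactly 3 (gain, PHA) pairs")
    co <- stats::coef(stats::lm(pha ~ gain, data = di))
    data.frame(subject = di$subject[1], slope = unname(co[2]),
               intercept = unname(co[1]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("gain_slopes", "data.frame")
  out
}

#' One-sample t-test of gain slopes against zero
#'
#' Tests whether the per-subject gain slopes deviate from zero. The
#' default is one-tailed (positive direction): higher visual velocity
#' gains pushing the PHA further in the gain direction. A two-tailed
#' variant is available by flag.
#'
#' @param slopes A `gain_slopes` object (see [fit_gain_slopes()]) or a
#'   numeric vector of slopes.
#' @param tails `"one"` (default, positive alternative) or `"two"`.
#' @return Object of class `effect_result` with `statistic` (t), `df`,
#'   `p`, `effect_size` (Cohen's d) and `degenerate`.
#' @export
slopes_vs_zero <- function(slopes, tails = c("one", "two")) {
  tails <- match.arg(tails)
  v <- if (is.data.frame(slopes)) slopes$slope else as.numeric(slopes)
  if (length(v) < 2) stop("need at least 2 slopes")
  n <- length(v)
  if (stats::sd(v) == 0) {
    t <- if (mean(v) == 0) 0 else sign(mean(v)) * Inf
    p <- if (mean(v) == 0) 1 else if (t > 0 || tails == "two") 0 else 1
    return(effect_result("slopes vs 0", t, n - 1, p, p,
                         effect_size = NA_real_, degenerate = TRUE))
  }
  t <- mean(v) / (stats::sd(v) / sqrt(n))
  p <- if (tails == "one") stats::pt(t, n - 1, lower.tail = FALSE)
       else 2 * stats::pt(-abs(t), n - 1)
  effect_result("slopes vs 0", t, n - 1, p, p,
                effect_size = mean(v) / stats::sd(v), degenerate = FALSE)
}

effect_result <- function(name, statistic, df, p, p_uncorrected = p,
                          effect_size = NA_real_, degenerate = FALSE) {
  structure(list(name = name, statistic = statistic, df = df, p = p,
                 p_uncorrected = p_uncorrected, effect_size = effect_size,
                 degenerate = degenerate),
            class = "effect_result")
}

#' @export
print.effect_result <- function(x, ...) {
  cat(sprintf("<effect_result> %s: t(%g) = %.3f, p = %.4g%s\n",
              x$name, x$df, x$statistic, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
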