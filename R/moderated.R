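# Empirical-Bayes variance moderation: per-protein sample variances are
# shrunk toward a scaled inverse-chi-square prior (d0, s0^2) whose
# hyperparameters are estimated by moment matching on log variances.

# Newton inversion of the trigamma function; scalar input.
trigamma_inverse <- function(x) {
  stopifnot(is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(100)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-12 * y) break
  }
  y
}

#' Fit the variance prior by moment matching on log variances
#'
#' Under the hierarchical model s_g^2 | sigma_g^2 ~ sigma_g^2 chi^2_d / d
#' with sigma_g^2 ~ s0^2 d0 / chi^2_d0, the statistic
#' e_g = ln s_g^2 - psi(d/2) + ln(d/2) has mean ln sigma^2-related
#' moments that identify (d0, s0^2): the excess of var(e) over the
#' sampling term psi'(d/2) equals psi'(d0/2), solved by Newton
#' iteration on the trigamma inverse, and
#' s0^2 = exp(mean(e) + psi(d0/2) - ln(d0/2)).
#'
#' Zero or non-finite variances are excluded from fitting (they are
#' still moderated downstream). If the observed dispersion does not
#' exceed the sampling term, the prior is degenerate: d0 = Inf with
#' s0^2 = exp(mean(e)).
#'
#' @param variances Per-protein sample variances (log2-units squared).
#' @param df Residual degrees of freedom of each variance (scalar or
#'   vector recycled to match).
#' @return A `variance_prior` list with elements `d0`, `s0sq` and
#'   `n_used`.
#' @export
fit_variance_prior <- function(variances, df) {
  df <- rep_len(as.numeric(df), length(variances))
  ok <- is.finite(variances) & variances > 0 & is.finite(df) & df > 0
  if (sum(ok) < 2L)
    stop("need at least two positive finite variances to fit the prior")
  v <- variances[ok]
  d <- df[ok]
  e <- log(v) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  excess <- stats::var(e) - mean(trigamma(d / 2))
  if (excess <= 0) {
    d0 <- Inf
    s0sq <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0sq = s0sq, n_used = sum(ok)),
            class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat("variance prior: d0 = ", format(x$d0), ", s0^2 = ",
      format(x$s0sq), " (fit on ", x$n_used, " variances)\n", sep = "")
  invisible(x)
}

#' Moderated one-sample t-test
#'
#' Shrinks each sample variance toward the prior,
#' s2_post = (d0 s0^2 + d s_g^2) / (d0 + d), and tests the mean against
#' zero on d0 + d degrees of freedom. With d0 = 0 this is the ordinary
#' one-sample t-test; with d0 = Inf the variance is fully shrunk to
#' s0^2 and the p-value comes from the normal distribution.
#'
#' @param mean Per-protein means (vectorized).
#' @param s2 Per-protein sample variances, same length.
#' @param n Number of observations behind each mean (scalar or vector);
#'   for an unpaired contrast pass the effective n = 1/(1/n1 + 1/n2)
#'   and override `df`.
#' @param prior A `variance_prior` (or a list with `d0` and `s0sq`).
#' @param df Residual degrees of freedom of `s2`; defaults to `n - 1`.
#' @return List with vectors `t`, `df_total` and `p` (two-sided).
#' @export
moderated_t <- function(mean, s2, n, prior, df = n - 1) {
  stopifnot(length(s2) == length(mean))
  n <- rep_len(as.numeric(n), length(mean))
  df <- rep_len(as.numeric(df), length(mean))
  if (any(n <= 0)) stop("`n` must be positive")
  if (any(df < 1)) stop("need at least two observations (df >= 1)")
  if (any(s2 < 0, na.rm = TRUE)) stop("negative variance")
  d0 <- prior$d0
  s0sq <- prior$s0sq
  if (is.infinite(d0)) {
    s2post <- rep_len(s0sq, length(mean))
    df_total <- rep_len(Inf, length(mean))
  } else {
    s2post <- (d0 * s0sq + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  if (any(s2post <= 0, na.rm = TRUE))
    stop("posterior variance is zero; cannot form a t-statistic")
  tstat <- mean / sqrt(s2post / n)
  p <- ifelse(is.finite(df_total),
              2 * stats::pt(-abs(tstat), df_total),
              2 * stats::pnorm(-abs(tstat)))
  list(t = tstat, df_total = df_total, p = p)
}

#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()]: Benjamini-Hochberg step-up
#' (`"fdr"`) or Bonferroni. Output order matches input order.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @param method `"fdr"` or `"bonferroni"`.
#' @return Adjusted values, same length and order.
#' @export
adjust_p <- function(p_values, method = c("fdr", "bonferroni")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = method)
}
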