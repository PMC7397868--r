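# Comparative RIC: mutant-vs-WT shift coefficients. The RIC/WCE ratio
# of each genotype gets an expectation and variance by Taylor
# propagation of the errors of the mean RIC and mean WCE signals; the
# shift (mutant - WT) is recentred over crosslinked proteins, turned
# into n = 3 pseudo-replicates with exact sample moments, and tested
# with the moderated t.

#' Second-order Taylor propagation of uncertainty through a ratio
#'
#' For jointly Gaussian (x, y) with means, variances and covariance as
#' given, approximates E\[f\] = f(mu) + tr(H Sigma)/2 and
#' Var\[f\] = g' Sigma g + tr((H Sigma)^2)/2, with g and H the gradient
#' and Hessian of f at the mean. `scale = "log2_difference"` uses
#' f = x - y, whose Hessian vanishes, so the result is exact:
#' E = mu_x - mu_y, Var = var_x + var_y - 2 cov.
#' `scale = "linear_ratio"` uses f = x / y on linear-scale inputs.
#' All arguments are vectorized.
#'
#' @param mu_x,mu_y Means of the two signals.
#' @param var_x,var_y Squared standard errors of those means.
#' @param cov Covariance of the two means (default 0).
#' @param scale `"log2_difference"` or `"linear_ratio"`.
#' @return List with vectors `expected` and `variance`.
#' @export
taylor_propagate <- function(mu_x, mu_y, var_x, var_y, cov = 0,
                             scale = c("log2_difference", "linear_ratio")) {
  scale <- match.arg(scale)
  k <- max(length(mu_x), length(mu_y), length(var_x), length(var_y),
           length(cov))
  mu_x <- rep_len(mu_x, k); mu_y <- rep_len(mu_y, k)
  var_x <- rep_len(var_x, k); var_y <- rep_len(var_y, k)
  cov <- rep_len(cov, k)
  if (any(var_x < 0) || any(var_y < 0)) stop("variances must be >= 0")
  if (any(abs(cov) > sqrt(var_x * var_y) + 1e-12))
    stop("|cov| may not exceed sqrt(var_x * var_y)")
  if (scale == "log2_difference") {
    return(list(expected = mu_x - mu_y,
                variance = var_x + var_y - 2 * cov))
  }
  if (any(mu_y == 0)) stop("mu_y must be nonzero for a linear ratio")
  # f = x/y: g = (1/y, -x/y^2); H = [[0, -1/y^2], [-1/y^2, 2x/y^3]]
  ex <- mu_x / mu_y - cov / mu_y^2 + mu_x * var_y / mu_y^3
  grad_term <- var_x / mu_y^2 - 2 * mu_x * cov / mu_y^3 +
    mu_x^2 * var_y / mu_y^4
  a11 <- -cov / mu_y^2
  a12 <- -var_y / mu_y^2
  a21 <- -var_x / mu_y^2 + 2 * mu_x * cov / mu_y^3
  a22 <- -cov / mu_y^2 + 2 * mu_x * var_y / mu_y^3
  hess_term <- 0.5 * (a11^2 + 2 * a12 * a21 + a22^2)
  list(expected = ex, variance = grad_term + hess_term)
}

#' Draw values with exact empirical mean and SD
#'
#' Returns `n` values whose sample mean is exactly `mean` and whose
#' sample SD (n - 1 denominator) is exactly `sd`: standard normals are
#' centered, rescaled and shifted. A degenerate draw (all equal) is
#' re-drawn. With `sd = 0` all values equal `mean`.
#'
#' @param n Number of values (>= 2).
#' @param mean Target sample mean.
#' @param sd Target sample SD (>= 0).
#' @param seed Optional seed set before drawing.
#' @return Numeric vector of length `n`.
#' @export
empirical_mvn <- function(n, mean = 0, sd = 1, seed = NULL) {
  stopifnot(n >= 2, sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(rep(mean, n))
  repeat {
    z <- stats::rnorm(n)
    s <- stats::sd(z)
    if (s > 0) break
  }
  mean + sd * (z - base::mean(z)) / s
}

# Row-wise version: one draw of n values per protein with exact
# per-row sample moments.
empirical_mvn_matrix <- function(n, means, sds) {
  m <- length(means)
  stopifnot(length(sds) == m, n >= 2)
  z <- matrix(stats::rnorm(m * n), m, n)
  z <- z - rowMeans(z)
  rs <- sqrt(rowSums(z^2) / (n - 1))
  while (any(rs == 0)) {
    bad <- which(rs == 0)
    z[bad, ] <- stats::rnorm(length(bad) * n)
    z[bad, ] <- z[bad, , drop = FALSE] - rowMeans(z[bad, , drop = FALSE])
    rs[bad] <- sqrt(rowSums(z[bad, , drop = FALSE]^2) / (n - 1))
  }
  out <- z / rs * sds + means
  out[sds == 0, ] <- means[sds == 0]
  out
}

#' Rescale raw shift coefficients by a global constant
#'
#' Subtracts the mean raw shift over the crosslinked-protein mask from
#' every shift (a constant multiplicative factor in linear space),
#' which minimizes the global variance of mutant vs WT ratios across
#' crosslinked proteins. Idempotent; the corrected shifts average to
#' zero over the mask.
#'
#' @param raw_shifts Per-protein raw shifts (log2).
#' @param crosslinked_mask Logical; which proteins enter the centering.
#' @return List with `constant` (the additive log2 correction) and
#'   `shifts` (corrected values for all proteins).
#' @export
rescale_shifts <- function(raw_shifts, crosslinked_mask) {
  stopifnot(length(raw_shifts) == length(crosslinked_mask))
  if (!any(crosslinked_mask)) stop("no crosslinked proteins in mask")
  constant <- -mean(raw_shifts[crosslinked_mask])
  list(constant = constant, shifts = raw_shifts + constant)
}

# Per-protein moments of the RIC/WCE ratio for one genotype's table.
ratio_moments <- function(table, config) {
  ric <- samples_for(table, fraction = "RIC")
  wce <- samples_for(table, fraction = "WCE")
  if (!length(ric) || !length(wce))
    stop("table lacks RIC or WCE samples")
  fc <- mean_log2_fc(table, ric, wce, paired = TRUE)
  R <- table$values[, ric, drop = FALSE]
  kb <- pair_key(table$meta, wce)
  ka <- pair_key(table$meta, ric)
  W <- table$values[, wce, drop = FALSE][, match(ka, kb), drop = FALSE]
  n <- ncol(R)
  if (config$propagation == "linear_ratio") {
    R <- 2^R
    W <- 2^W
  }
  mu_x <- rowMeans(R)
  mu_y <- rowMeans(W)
  var_x <- row_vars(R) / n
  var_y <- row_vars(W) / n
  cv <- if (config$cov_mode == "paired") {
    rowSums((R - mu_x) * (W - mu_y)) / (n - 1) / n
  } else 0
  pr <- taylor_propagate(mu_x, mu_y, var_x, var_y, cv, config$propagation)
  if (config$propagation == "linear_ratio") {
    # map ratio moments to the log2 scale by the delta method
    if (any(pr$expected <= 0))
      stop("nonpositive expected linear ratio; cannot take log2")
    pr$variance <- pr$variance / (pr$expected * log(2))^2
    pr$expected <- log2(pr$expected)
  }
  list(expected = pr$expected, variance = pr$variance,
       n_ric = n, ric = ric)
}

# Align two tables on the union of proteins; absent rows are filled at
# the imputation value and flagged imputed.
align_union <- function(table, prots, fill) {
  cur <- rownames(table$values)
  add <- setdiff(prots, cur)
  if (length(add)) {
    pad_v <- matrix(fill, length(add), ncol(table$values),
                    dimnames = list(add, colnames(table$values)))
    pad_i <- matrix(TRUE, length(add), ncol(table$values),
                    dimnames = list(add, colnames(table$values)))
    table$values <- rbind(table$values, pad_v)[prots, , drop = FALSE]
    table$imputed <- rbind(table$imputed, pad_i)[prots, , drop = FALSE]
  } else {
    table$values <- table$values[prots, , drop = FALSE]
    table$imputed <- table$imputed[prots, , drop = FALSE]
  }
  table
}

#' Mutant-vs-WT comparative RIC: shift coefficients
#'
#' Per protein: (1) RIC/WCE ratio moments for WT and mutant from
#' replicate data, (2) Taylor propagation of each, (3) raw shift =
#' mutant - WT with SE = sqrt of the summed variances, (4) global
#' rescaling over crosslinked proteins (detected pre-imputation in the
#' RIC of both genotypes), (5) pseudo-replicates with exact sample
#' moments, (6) variance-prior fit and moderated t across proteins,
#' (7) BH adjustment.
#'
#' Because the pseudo-replicates have exact sample moments, the
#' statistics do not depend on `seed`. Both tables are expected to be
#' imputed and median-normalized; proteins absent from one table are
#' filled at `config$impute_value` and flagged imputed.
#'
#' @param wt,mut [intensity_table()] objects with RIC and WCE samples
#'   for the wild-type and mutant genotype.
#' @param config A [ric_config()].
#' @param seed Seed for the pseudo-replicate draw.
#' @return Data frame with `protein_id`, `shift` (corrected), `se_shift`,
#'   `t_mod`, `df_total`, `p`, `q_fdr`, `detected_in_mutant`,
#'   `rescale_constant_applied`. The fitted prior is attached as
#'   attribute `"prior"`.
#' @export
compare_ric <- function(wt, mut, config = ric_config(), seed = config$seed) {
  stopifnot(inherits(wt, "intensity_table"), inherits(mut, "intensity_table"))
  prots <- union(rownames(wt$values), rownames(mut$values))
  wt <- align_union(wt, prots, config$impute_value)
  mut <- align_union(mut, prots, config$impute_value)
  if (any(is.na(wt$values)) || any(is.na(mut$values)))
    stop("tables still have missing cells; run impute_background() first")
  mo_wt <- ratio_moments(wt, config)
  mo_mut <- ratio_moments(mut, config)
  raw <- mo_mut$expected - mo_wt$expected
  se <- sqrt(mo_wt$variance + mo_mut$variance)
  det_wt <- rowSums(detected_matrix(wt)[, mo_wt$ric, drop = FALSE]) >=
    config$min_detected
  det_mut <- rowSums(detected_matrix(mut)[, mo_mut$ric, drop = FALSE]) >=
    config$min_detected
  crosslinked <- det_wt & det_mut
  rs <- rescale_shifts(raw, crosslinked)
  sd_scale <- if (config$pseudo_sd_scale == "sqrt_n")
    sqrt(config$n_pseudo) else 1
  set.seed(seed)
  reps <- empirical_mvn_matrix(config$n_pseudo, rs$shifts, se * sd_scale)
  s2 <- row_vars(reps)
  mns <- rowMeans(reps)
  prior <- tryCatch(fit_variance_prior(s2, config$n_pseudo - 1L),
                    error = function(e) NULL)
  if (is.null(prior)) {
    tv <- rep(NA_real_, length(prots))
    mt <- list(t = tv, df_total = tv, p = tv)
  } else {
    mt <- moderated_t(mns, s2, config$n_pseudo, prior,
                      df = config$n_pseudo - 1L)
  }
  out <- data.frame(
    protein_id = prots,
    shift = rs$shifts,
    se_shift = se,
    t_mod = mt$t,
    df_total = mt$df_total,
    p = mt$p,
    q_fdr = adjust_p(mt$p, "fdr"),
    detected_in_mutant = det_mut,
    rescale_constant_applied = rs$constant,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "prior") <- prior
  out
}
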