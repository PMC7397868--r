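# Fluorescence anisotropy and four-parameter logistic (4PL) binding
# curves: y = ymin + (ymax - ymin) / (1 + (x / Kd)^(-n)), an increasing
# sigmoid in protein concentration x with midpoint at x = Kd.

#' Fluorescence anisotropy from polarized intensities
#'
#' Standard definition r = (I_par - G I_perp) / (I_par + 2 G I_perp),
#' bounded in (-0.5, 1].
#'
#' @param parallel,perpendicular Emission intensities measured parallel
#'   and perpendicular to the excitation plane (vectorized).
#' @param g_factor Instrument G factor (default 1).
#' @return Anisotropy values (dimensionless).
#' @export
anisotropy <- function(parallel, perpendicular, g_factor = 1) {
  total <- parallel + 2 * g_factor * perpendicular
  if (any(total <= 0))
    stop("total intensity I_par + 2 G I_perp must be positive")
  (parallel - g_factor * perpendicular) / total
}

#' Average replicate anisotropy readings
#'
#' Each titration point is usually the mean of several technical
#' readings; this helper collapses a points x readings matrix to one
#' value per point.
#'
#' @param readings Numeric matrix, one row per titration point.
#' @return Vector of per-point means.
#' @export
average_readings <- function(readings) {
  rowMeans(as.matrix(readings))
}

four_pl <- function(x, ymin, ymax, kd, n) {
  ymin + (ymax - ymin) / (1 + (x / kd)^(-n))
}

#' Fit a four-parameter logistic binding curve
#'
#' Unweighted nonlinear least squares of the 4PL to a titration,
#' estimating the anisotropy floor and ceiling, the dissociation
#' constant Kd (nM) and the Hill slope n. Kd and n are kept positive
#' by fitting on the log scale (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]). Initial values: ymin = min(y),
#' ymax = max(y), Kd from log-linear interpolation of the y midpoint,
#' n = 1; on failure up to three jittered re-initializations are
#' attempted.
#'
#' @param concentration Protein concentrations (nM), strictly positive,
#'   spanning at least one order of magnitude, >= 5 points.
#' @param anisotropy Measured anisotropy at each concentration.
#' @return Object of class `four_pl_fit`: list with `ymin`, `ymax`,
#'   `kd`, `n`, `rss`, `se` (named parameter standard errors from the
#'   Jacobian at the optimum), `fitted`, `residuals`.
#' @export
fit_4pl <- function(concentration, anisotropy) {
  x <- as.numeric(concentration)
  y <- as.numeric(anisotropy)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 5L) stop("need at least 5 titration points")
  if (any(x <= 0)) stop("concentrations must be positive")
  if (max(x) / min(x) < 10)
    stop("concentrations must span at least one order of magnitude")
  if (diff(range(y)) < 1e-12)
    stop("degenerate flat curve: anisotropy has no dynamic range")
  ord <- order(x)
  xo <- x[ord]; yo <- y[ord]
  ymin0 <- min(y); ymax0 <- max(y)
  ymid <- (ymin0 + ymax0) / 2
  # log-linear interpolation of the concentration at the y midpoint
  kd0 <- tryCatch(
    2^stats::approx(yo, log2(xo), xout = ymid, ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(kd0)) kd0 <- exp(mean(log(x)))
  dat <- data.frame(x = x, y = y)
  tries <- list(c(0, 0))
  for (i in 1:3) tries[[i + 1]] <- stats::rnorm(2, 0, 0.4)
  fit <- NULL
  for (jit in tries) {
    start <- list(ymin = ymin0, ymax = ymax0,
                  lkd = log(kd0) + jit[1], ln = 0 + jit[2])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ ymin + (ymax - ymin) / (1 + (x / exp(lkd))^(-exp(ln))),
        data = dat, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("4PL fit did not converge after 3 jittered restarts ",
         "(ymin0 = ", signif(ymin0, 4), ", ymax0 = ", signif(ymax0, 4),
         ", kd0 = ", signif(kd0, 4), ")")
  cf <- stats::coef(fit)
  kd <- exp(cf[["lkd"]])
  hill <- exp(cf[["ln"]])
  vc <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 4, 4, dimnames = list(names(cf), names(cf))))
  se <- c(ymin = sqrt(vc["ymin", "ymin"]),
          ymax = sqrt(vc["ymax", "ymax"]),
          kd = kd * sqrt(vc["lkd", "lkd"]),     # delta method
          n = hill * sqrt(vc["ln", "ln"]))
  fitted <- four_pl(x, cf[["ymin"]], cf[["ymax"]], kd, hill)
  structure(list(ymin = cf[["ymin"]], ymax = cf[["ymax"]],
                 kd = kd, n = hill,
                 rss = sum((y - fitted)^2), se = se,
                 fitted = fitted, residuals = y - fitted),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat("4PL fit: Kd = ", format(x$kd, digits = 4), " nM (SE ",
      format(x$se[["kd"]], digits = 3), "), Hill n = ",
      format(x$n, digits = 3), ", ymin = ", format(x$ymin, digits = 3),
      ", ymax = ", format(x$ymax, digits = 3), ", RSS = ",
      format(x$rss, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted 4PL curve
#'
#' @param fit A `four_pl_fit` (or any list with `ymin`, `ymax`, `kd`,
#'   `n`).
#' @param x Concentrations (nM), strictly positive.
#' @return Predicted anisotropy; monotone increasing in `x` for n > 0
#'   and ymax > ymin, with y -> ymin as x -> 0 and y -> ymax as
#'   x -> Inf.
#' @export
predict_4pl <- function(fit, x) {
  if (any(x <= 0)) stop("concentrations must be positive")
  four_pl(x, fit$ymin, fit$ymax, fit$kd, fit$n)
}
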