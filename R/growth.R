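#' Convert calendar days to thermal time (growing degree days)
#'
#' Plant age in growing degree days accumulates daily mean temperature above
#' a base temperature `t_base` below which no growth is assumed:
#' \eqn{t(i) = \sum_{j \le i} \max(T_j - T_b, 0)}, cumulative from the first
#' day of the temperature series.
#'
#' @param days Integer day-of-year indices at which ages are requested.
#' @param temp_days Day-of-year indices of the temperature series
#'   (contiguous coverage of the trial span).
#' @param temps Daily mean air temperatures (degrees C), same length as
#'   `temp_days`.
#' @param t_base Base temperature in degrees C (default 5).
#' @return Ages in GDD at each requested day.
#' @examples
#' gdd_transform(3, 1:3, c(10, 3, 7))  # 5 + 0 + 2 = 7
#' @export
gdd_transform <- function(days, temp_days, temps, t_base = 5) {
  stopifnot(length(temp_days) == length(temps))
  if (any(diff(temp_days) != 1L))
    stop("temperature series must cover contiguous days")
  if (any(!(days %in% temp_days)))
    stop("temperature series does not cover all requested days")
  cum <- cumsum(pmax(temps - t_base, 0))
  cum[match(days, temp_days)]
}

#' Invert cumulative GDD back to day of year
#'
#' Maps thermal ages back to (fractional) day of year by inverting the
#' cumulative degree-day sum, interpolating linearly within days.
#'
#' @inheritParams gdd_transform
#' @param gdd Thermal ages to invert.
#' @return Fractional day-of-year values.
#' @export
gdd_to_doy <- function(gdd, temp_days, temps, t_base = 5) {
  cum <- cumsum(pmax(temps - t_base, 0))
  if (any(gdd < 0) || any(gdd > cum[length(cum)]))
    stop("thermal age outside the temperature-series span")
  stats::approx(x = c(0, cum), y = c(temp_days[1] - 1, temp_days),
                xout = gdd, ties = "ordered")$y
}

#' Beta-sigmoid height curve
#'
#' Determinate growth curve
#' \deqn{h(t) = h_0 + (h_{max}-h_0)\left(1 + \frac{t_e - t}{t_e - t_m}\right)
#'   \left(\frac{t}{t_e}\right)^{t_e/(t_e-t_m)}, \quad t < t_e}
#' with \eqn{h(t) = h_{max}} for \eqn{t \ge t_e}. `tm` is the age of maximal
#' growth and `te` the age at the end of growth, both in GDD.
#'
#' @param t Thermal ages (GDD, >= 0).
#' @param h0,hmax Initial and final heights (cm), `0 <= h0 < hmax`.
#' @param tm,te Inflection and end-of-growth ages (GDD), `0 < tm < te`.
#' @return Heights in cm.
#' @export
beta_sigmoid_height <- function(t, h0, hmax, tm, te) {
  stopifnot(h0 >= 0, hmax > h0, tm > 0, te > tm)
  if (any(t < 0)) stop("negative thermal age")
  q <- te / (te - tm)
  h <- h0 + (hmax - h0) * (1 + (te - t) / (te - tm)) * (t / te)^q
  h[t >= te] <- hmax
  h
}

#' Analytic growth rate of the beta-sigmoid curve
#'
#' @inheritParams beta_sigmoid_height
#' @return dh/dt in cm per GDD (0 for `t >= te`).
#' @export
beta_sigmoid_rate <- function(t, h0, hmax, tm, te) {
  q <- te / (te - tm)
  a <- 1 + (te - t) / (te - tm)
  b <- (t / te)^q
  r <- (hmax - h0) * (-b / (te - tm) + a * q * b / t)
  r[t >= te] <- 0
  r[t == 0] <- 0
  r
}

#' Fit the beta-sigmoid growth curve to a height time series
#'
#' Bounded nonlinear least squares on (h0, hmax, tm, te) using
#' `nls(algorithm = "port")`, with starting values h0 = min height,
#' hmax = max height, tm = age of the largest observed increment and
#' te = 1.1 x last observed age. On failure, a Levenberg-Marquardt refit
#' (minpack.lm) is attempted when available; otherwise the result is flagged
#' unconverged with parameters absent.
#'
#' @param ages Thermal ages (GDD) of the measurements.
#' @param heights Measured heights (cm), same length.
#' @return Object of class `growth_curve` with elements `par` (named vector
#'   h0, hmax, tm, te or NULL), `converged`, `rss`, `data`.
#' @export
growth_curve <- function(ages, heights) {
  stopifnot(length(ages) == length(heights), length(ages) >= 5)
  o <- order(ages)
  ages <- ages[o]; heights <- heights[o]
  # fit on (h0, dh, tm, dte) with hmax = h0 + dh, te = tm + dte so the
  # constraints h0 < hmax, tm < te are box bounds
  curve_re <- function(t, h0, dh, tm, dte) {
    te <- tm + dte
    q <- te / dte
    h <- h0 + dh * (1 + (te - t) / dte) * (t / te)^q
    h[t >= te] <- h0 + dh
    h
  }
  tm0 <- ages[min(which.max(diff(heights)) + 1L, length(ages))]
  start <- list(h0 = max(min(heights), 0),
                dh = max(max(heights) - min(heights), 1e-3),
                tm = max(tm0, 1e-3),
                dte = max(1.1 * max(ages) - tm0, 1e-3))
  lower <- c(h0 = 0, dh = 1e-6, tm = 1e-6, dte = 1e-6)
  upper <- c(h0 = max(heights) + 1, dh = 3 * max(heights) + 1,
             tm = 3 * max(ages), te = 3 * max(ages))
  df <- data.frame(t = ages, h = heights)
  fit <- tryCatch(
    stats::nls(h ~ curve_re(t, h0, dh, tm, dte), data = df,
               start = start, lower = lower, upper = upper,
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) && requireNamespace("minpack.lm", quietly = TRUE)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(h ~ curve_re(t, h0, dh, tm, dte),
                        data = df, start = start,
                        lower = lower, upper = upper),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    out <- list(par = NULL, converged = FALSE, rss = NA_real_, data = df)
  } else {
    cf <- stats::coef(fit)
    par <- c(h0 = unname(cf["h0"]), hmax = unname(cf["h0"] + cf["dh"]),
             tm = unname(cf["tm"]), te = unname(cf["tm"] + cf["dte"]))
    # a fit pegged at the degenerate bounds is reported as unconverged
    ok <- cf["dh"] > 1e-5 && cf["dte"] > 1e-5
    out <- list(par = par, converged = isTRUE(unname(ok)),
                rss = sum(stats::residuals(fit)^2), data = df)
  }
  class(out) <- "growth_curve"
  out
}

#' @export
print.growth_curve <- function(x, ...) {
  if (!x$converged) {
    cat("Beta-sigmoid growth curve: fit did not converge\n")
  } else {
    cat("Beta-sigmoid growth curve fit\n")
    print(round(x$par, 3))
    cat(sprintf("  RSS: %.4g on %d points\n", x$rss, nrow(x$data)))
  }
  invisible(x)
}

#' @export
coef.growth_curve <- function(object, ...) object$par

#' @export
predict.growth_curve <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from an unconverged fit")
  t <- if (is.null(newdata)) object$data$t else newdata$t
  p <- object$par
  beta_sigmoid_height(t, p["h0"], p["hmax"], p["tm"], p["te"])
}

#' @export
residuals.growth_curve <- function(object, ...) {
  object$data$h - predict(object)
}

#' Shoot-growth summary phenotypes from a fitted curve
#'
#' Derives the time of maximal shoot growth and end of shoot growth in days
#' after sowing (DAS), and the maximum growth rate in cm/GDD, from fitted
#' beta-sigmoid parameters. Thermal ages are converted back to day of year by
#' inverting the cumulative degree-day sum ([gdd_to_doy()]) and then to DAS.
#'
#' @param fit A converged [growth_curve()] object.
#' @inheritParams gdd_transform
#' @param sowing_doy Day of year of sowing; DAS = DOY - sowing DOY, with
#'   days rolling over the year boundary when the trial spans new year.
#' @return Named vector: `time_max_growth_das`, `max_growth_rate`,
#'   `end_growth_das`.
#' @export
growth_summary <- function(fit, temp_days, temps, t_base = 5,
                           sowing_doy = temp_days[1]) {
  stopifnot(inherits(fit, "growth_curve"))
  if (!fit$converged) stop("unconverged growth fit")
  p <- fit$par
  doy <- gdd_to_doy(c(p["tm"], p["te"]), temp_days, temps, t_base)
  das <- doy - sowing_doy
  das[das < 0] <- das[das < 0] + 365
  rate <- beta_sigmoid_rate(p["tm"], p["h0"], p["hmax"], p["tm"], p["te"])
  c(time_max_growth_das = unname(das[1]),
    max_growth_rate = unname(rate),
    end_growth_das = unname(das[2]))
}
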