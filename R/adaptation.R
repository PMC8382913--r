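# Phenotypic rate-of-adaptation statistics: the half-change rate alpha, the
# per-capita forward-difference rate r_e, the reciprocal-AUC rate r_auc,
# dose-increment significance tests, inverted-U classification, and the
# periodogram used to identify non-biological plate-reader oscillations.

#' Rate of adaptation from the half-change time
#'
#' For a phenotype timeseries \eqn{r(t)} spanning a treatment of duration
#' \eqn{T}, the total change is \eqn{\Delta r = r(T) - r(0)} and the adaptive
#' time \eqn{t_a} is the first time at which \eqn{r(t_a) = r(0) + \Delta r/2}.
#' The rate of adaptation is \eqn{\alpha = (\Delta r/2)/t_a}. Endpoint levels
#' are short-window means (default 3 points) to damp noise; the crossing is
#' linearly interpolated between samples. When \eqn{\Delta r < 0} the crossing
#' is sought downward and \eqn{\alpha} is negative (loss of the phenotype).
#'
#' @param times numeric vector of times (hours), increasing, length >= 3.
#' @param values phenotype values (OD, or GFP-per-OD).
#' @param endpoint_window number of points averaged to estimate \eqn{r(0)}
#'   and \eqn{r(T)}.
#' @param tol \eqn{|\Delta r|} below \code{tol * max(1, |r(T)|)} is treated
#'   as no change: \eqn{\alpha = 0}, \eqn{t_a} undefined.
#' @return list with \code{alpha} (per hour), \code{t_a} (hours, NA when
#'   undefined), \code{delta_r}, \code{r0}, \code{rT}.
#' @export
roa_alpha <- function(times, values, endpoint_window = 3L, tol = 1e-10) {
  stopifnot(length(times) >= 3L, length(times) == length(values),
            !is.unsorted(times), all(is.finite(values)))
  w <- min(endpoint_window, length(values))
  r0 <- mean(values[seq_len(w)])
  rT <- mean(values[seq(length(values) - w + 1L, length(values))])
  dr <- rT - r0
  if (abs(dr) < tol * max(1, abs(rT)))
    return(list(alpha = 0, t_a = NA_real_, delta_r = dr, r0 = r0, rT = rT))
  level <- r0 + dr / 2
  above <- if (dr > 0) values >= level else values <= level
  i <- which(above)[1L]
  if (is.na(i))
    stop("roa_alpha: level r(0) + delta_r/2 never crossed (non-monotone series?)")
  if (i == 1L) {
    t_a <- times[1L]
  } else {
    # linear interpolation between the bracketing samples
    f <- (level - values[i - 1L]) / (values[i] - values[i - 1L])
    t_a <- times[i - 1L] + f * (times[i] - times[i - 1L])
  }
  if (t_a <= 0) t_a <- times[which(times > 0)[1L]]  # degenerate immediate crossing
  list(alpha = (dr / 2) / t_a, t_a = t_a, delta_r = dr, r0 = r0, rT = rT)
}

#' Maximal per-capita growth rate of a fitted model
#'
#' Evaluates the forward-difference per-capita growth rate
#' \deqn{r_e = \max_{0 \le t \le 24h} \frac{1}{B(t)} \frac{B(t+\Delta t) - B(t)}{\Delta t}}
#' on the fitted growth model (fitting first filters high-frequency noise,
#' which a per-capita derivative would otherwise amplify). The default
#' \eqn{\Delta t} of 20 min matches the plate-reader sampling interval.
#'
#' @param fit a \code{\link{growth_fit}} for one 24-h season.
#' @param dt forward-difference step in hours (default 1/3 = 20 min).
#' @param window length of the evaluation window in hours.
#' @return \code{r_e} in per hour.
#' @export
roa_growth_rate <- function(fit, dt = 1 / 3, window = 24) {
  stopifnot(inherits(fit, "growth_fit"), dt > 0, window > dt)
  t <- seq(0, window - dt, by = dt)
  B <- predict(fit, t)
  B_next <- predict(fit, t + dt)
  if (any(B <= 0))
    stop("roa_growth_rate: fitted density non-positive on the window; per-capita rate undefined")
  max((B_next - B) / (B * dt))
}

#' Reciprocal area-under-the-curve growth rate
#'
#' \deqn{r_{auc} = B(24h) / \int_0^{24h} B(t)\,dt} (units 1/h), computed with
#' the trapezoidal rule on a blank-corrected trace. Scale-invariant: doubling
#' the trace leaves \code{r_auc} unchanged.
#'
#' @param curve a blank-corrected \code{\link{growth_curve}} covering 24 h,
#'   or a list with \code{times} and \code{od}.
#' @param window integration window in hours.
#' @return \code{r_auc} in per hour.
#' @export
roa_auc <- function(curve, window = 24) {
  t <- curve$times; y <- curve$od
  keep <- t <= window + 1e-9
  t <- t[keep]; y <- y[keep]
  stopifnot(length(t) >= 2L)
  auc <- sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (auc <= 0) stop("roa_auc: non-positive area under the curve")
  y[length(y)] / auc
}

#' Significance of density changes across dose increments
#'
#' For each adjacent dose pair in a dose-response, computes per-replicate
#' density differences (higher dose minus lower dose) and a two-sided
#' one-sample t-test against zero. No multiplicity correction is applied by
#' default (each increment is reported at raw P < 0.05);
#' Benjamini-Hochberg adjustment is available.
#'
#' @param dr a \code{\link{dose_response}}.
#' @param dr2 optional second \code{dose_response} at a later read time; when
#'   supplied both are analysed and stacked with a \code{season} column.
#' @param alpha significance level.
#' @param p_adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame with columns \code{season}, \code{dose_lo},
#'   \code{dose_hi}, \code{mean_delta}, \code{se}, \code{p_value},
#'   \code{direction} (\code{"increase"}/\code{"decrease"}/\code{"none"}),
#'   \code{significant}.
#' @export
dose_increment_change <- function(dr, dr2 = NULL, alpha = 0.05,
                                  p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  one <- function(d) {
    nd <- length(d$doses)
    rows <- lapply(seq_len(nd - 1L), function(j) {
      delta <- d$densities[, j + 1L] - d$densities[, j]
      if (stats::sd(delta) < 1e-15) {
        p <- NA_real_
      } else {
        p <- stats::t.test(delta, mu = 0)$p.value
      }
      m <- mean(delta)
      data.frame(season = d$season, dose_lo = d$doses[j],
                 dose_hi = d$doses[j + 1L], mean_delta = m,
                 se = stats::sd(delta) / sqrt(length(delta)), p_value = p,
                 direction = if (abs(m) < 1e-15) "none"
                             else if (m > 0) "increase" else "decrease")
    })
    do.call(rbind, rows)
  }
  out <- one(dr)
  if (!is.null(dr2)) {
    stopifnot(identical(dr$doses, dr2$doses),
              nrow(dr$densities) == nrow(dr2$densities))
    out <- rbind(out, one(dr2))
  }
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Classify the dose-dependence of a rate-of-adaptation profile
#'
#' Smooths replicate-mean ROA values across dose (optional cubic smoothing
#' spline), counts interior local maxima and classifies the profile:
#' \code{inverted_u} (a single interior local maximum which is the global
#' maximum), \code{monotone_down} ("L"), \code{monotone_up}, \code{flat}, or
#' \code{complex} (an "M" or worse). When per-replicate values are supplied,
#' each dose's ROA is also tested against the zero-dose ROA (two-sided
#' t-test).
#'
#' @param doses numeric vector (>= 4 doses).
#' @param roa either a numeric vector of mean ROA per dose or a matrix
#'   (replicates x doses).
#' @param smooth \code{"none"} or \code{"spline"}.
#' @param flat_tol relative spread below which the profile is \code{flat}.
#' @return list with \code{classification}, \code{argmax_dose},
#'   \code{mean_roa}, \code{smoothed}, and (matrix input) \code{p_vs_zero}.
#' @export
inverted_u_summary <- function(doses, roa, smooth = c("none", "spline"),
                               flat_tol = 1e-8) {
  smooth <- match.arg(smooth)
  stopifnot(length(doses) >= 4L, !is.unsorted(doses))
  p_vs_zero <- NULL
  if (is.matrix(roa)) {
    stopifnot(ncol(roa) == length(doses))
    mean_roa <- colMeans(roa)
    if (doses[1L] == 0 && nrow(roa) > 1L) {
      p_vs_zero <- vapply(seq_along(doses), function(j) {
        if (j == 1L) return(NA_real_)
        tryCatch(stats::t.test(roa[, j], roa[, 1L])$p.value,
                 error = function(e) NA_real_)
      }, numeric(1))
    }
  } else {
    stopifnot(length(roa) == length(doses))
    mean_roa <- roa
  }
  sm <- mean_roa
  if (smooth == "spline" && length(doses) >= 5L) {
    sp <- stats::smooth.spline(doses, mean_roa,
                               df = min(length(doses) - 1, 5))
    sm <- stats::predict(sp, doses)$y
  }
  rng <- diff(range(sm))
  scale <- max(abs(sm), 1e-12)
  if (rng < flat_tol * scale) {
    cls <- "flat"; argmax <- doses[1L]
  } else {
    d1 <- diff(sm)
    n_max <- 0L
    for (j in 2:(length(sm) - 1L)) {
      if (sm[j] >= sm[j - 1L] && sm[j] >= sm[j + 1L] &&
          (sm[j] > sm[j - 1L] || sm[j] > sm[j + 1L])) n_max <- n_max + 1L
    }
    argmax <- doses[which.max(sm)]
    if (all(d1 <= 0)) cls <- "monotone_down"
    else if (all(d1 >= 0)) cls <- "monotone_up"
    else if (n_max == 1L && argmax != doses[1L] &&
             argmax != doses[length(doses)]) cls <- "inverted_u"
    else cls <- "complex"
  }
  list(classification = cls, argmax_dose = argmax, mean_roa = mean_roa,
       smoothed = sm, p_vs_zero = p_vs_zero)
}

#' Power spectrum of a phenotype timeseries
#'
#' Discrete-Fourier-transform periodogram used to identify periodic
#' components in plate-reader traces, e.g. the ~0.75-h electro-mechanical
#' oscillation of the reading device and the ~10-h regulatory component seen
#' in fluorescence data. Non-uniform series are resampled onto a uniform grid
#' by linear interpolation. By default the series is detrended by subtracting
#' its best AICc growth-model fit before transforming (\code{detrend =
#' "none"} reproduces the raw-variant spectrum up to the zero-frequency
#' term).
#'
#' @param times sampling times in hours (length >= 16).
#' @param values series values.
#' @param detrend \code{"model"} (subtract the fitted growth model) or
#'   \code{"none"} (subtract the mean only).
#' @param n_peaks how many dominant interior wavelengths to report.
#' @return list with \code{spectrum} (data.frame: wavelength_h, frequency,
#'   power) and \code{dominant} (wavelengths of the top peaks, decreasing
#'   power).
#' @export
oscillation_periodogram <- function(times, values,
                                    detrend = c("model", "none"),
                                    n_peaks = 2L) {
  detrend <- match.arg(detrend)
  stopifnot(length(times) >= 16L, length(times) == length(values))
  dt <- stats::median(diff(times))
  grid <- seq(min(times), max(times), by = dt)
  y <- stats::approx(times, values, xout = grid)$y
  if (detrend == "model") {
    cv <- growth_curve(grid, y)
    fit <- tryCatch(suppressWarnings(fit_growth_models(cv)),
                    error = function(e) NULL)
    y <- if (is.null(fit)) y - mean(y) else y - predict(fit, grid)
  } else {
    y <- y - mean(y)
  }
  n <- length(y)
  sp <- Mod(stats::fft(y))^2 / n
  k <- seq_len(floor(n / 2))          # positive-frequency bins
  freq <- k / (n * dt)                 # cycles per hour
  spec <- data.frame(wavelength_h = 1 / freq, frequency = freq,
                     power = sp[k + 1L])
  # dominant components = interior local maxima of the spectrum, ranked by
  # power (adjacent leakage bins of one component count once)
  pow <- spec$power
  floor_pow <- 1e-10 * max(pow, .Machine$double.eps)
  is_peak <- vapply(seq_along(pow), function(i) {
    left <- if (i == 1L) -Inf else pow[i - 1L]
    right <- if (i == length(pow)) -Inf else pow[i + 1L]
    pow[i] > floor_pow && pow[i] >= left && pow[i] >= right
  }, logical(1))
  peaks <- spec[is_peak, , drop = FALSE]
  peaks <- peaks[order(peaks$power, decreasing = TRUE), , drop = FALSE]
  list(spectrum = spec, dominant = utils::head(peaks$wavelength_h, n_peaks))
}
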