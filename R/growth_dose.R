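# Growth-curve model fitting, blank correction, Hill dose-responses,
# MIC (IC99) and the effective antibiotic dose (EAD).

#' A single well-season growth curve
#'
#' @param times numeric vector of times in hours, strictly increasing
#'   (nominally 20-min spacing).
#' @param od numeric vector of OD600 readings, same length as \code{times}.
#' @param gfp optional numeric vector of GFP fluorescence readings.
#' @param well_id well label (e.g. \code{"A1"}).
#' @param season season (day) index, 1-based.
#' @param dose antibiotic dose in ug/ml.
#' @return An object of class \code{growth_curve}.
#' @export
growth_curve <- function(times, od, gfp = NULL, well_id = "", season = 1L,
                         dose = NA_real_) {
  stopifnot(is.numeric(times), is.numeric(od), length(times) == length(od),
            all(is.finite(times)), all(is.finite(od)))
  if (is.unsorted(times, strictly = TRUE))
    stop("growth_curve: times must be strictly increasing")
  if (!is.null(gfp)) stopifnot(length(gfp) == length(od))
  structure(list(times = times, od = od, gfp = gfp, well_id = well_id,
                 season = as.integer(season), dose = dose),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("growth curve: well %s, season %d, dose %g ug/ml, %d points (%g-%g h)\n",
              x$well_id, x$season, x$dose, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

# Gaussian least-squares AICc with k = model parameters + 1 (residual
# variance). Returns Inf when the sample is too small for the correction.
.aicc <- function(rss, n, k_model) {
  k <- k_model + 1L
  if (n - k - 1L <= 0L) return(Inf)
  n * log(max(rss, .Machine$double.xmin) / n) + 2 * k +
    2 * k * (k + 1) / (n - k - 1)
}

.fit_linear <- function(t, y) {
  fit <- stats::lm(y ~ t)
  co <- stats::coef(fit)
  list(model = "linear", B0 = unname(co[1L]), r = unname(co[2L]),
       a = NA_real_, K = NA_real_, rss = sum(stats::resid(fit)^2), k = 2L)
}

.fit_exponential <- function(t, y) {
  # B(t) = B0 + a exp(r t); starts from a log-linear fit of the span
  span <- max(y) - min(y)
  y0 <- pmax(y - min(y) + 0.05 * max(span, 1e-8), .Machine$double.eps)
  lf <- stats::lm(log(y0) ~ t)
  r0 <- unname(stats::coef(lf)[2L])
  if (!is.finite(r0) || abs(r0) < 1e-8) r0 <- 0.1
  starts <- list(c(B0 = min(y), a = max(span, 1e-4), r = r0),
                 c(B0 = min(y), a = max(span, 1e-4), r = r0 / 4),
                 c(B0 = min(y) * 0.5, a = max(span, 1e-4) * 0.1, r = r0 * 2))
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ B0 + a * exp(r * t),
                        start = as.list(st),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      return(list(model = "exponential", B0 = unname(co["B0"]),
                  r = unname(co["r"]), a = unname(co["a"]), K = NA_real_,
                  rss = sum(stats::resid(fit)^2), k = 3L))
    }
  }
  NULL
}

.fit_logistic <- function(t, y) {
  # B(t) = B0 + K/(1 + a exp(-r t)); reparameterised as the four-parameter
  # logistic for stats::SSfpl self-starting, then mapped back.
  fit <- tryCatch(stats::nls(y ~ SSfpl(t, lo, hi, xmid, scal)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    st <- list(B0 = min(y), K = max(max(y) - min(y), 1e-4), a = 50,
               r = 4 / max(diff(range(t)), 1e-8))
    fit2 <- tryCatch(
      minpack.lm::nlsLM(y ~ B0 + K / (1 + a * exp(-r * t)), start = st,
                        lower = c(-Inf, 1e-12, 1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit2)) return(NULL)
    co <- stats::coef(fit2)
    return(list(model = "logistic", B0 = unname(co["B0"]), r = unname(co["r"]),
                a = unname(co["a"]), K = unname(co["K"]),
                rss = sum(stats::resid(fit2)^2), k = 4L))
  }
  co <- stats::coef(fit)
  scal <- unname(co["scal"])
  if (!is.finite(scal) || scal <= 0) return(NULL)  # decreasing: not a growth fit
  r <- 1 / scal
  list(model = "logistic", B0 = unname(co["lo"]), r = r,
       a = exp(unname(co["xmid"]) / scal),
       K = unname(co["hi"] - co["lo"]),
       rss = sum(stats::resid(fit)^2), k = 4L)
}

#' Fit candidate growth models to a curve and select by AICc
#'
#' Fits the three blank-inclusive growth models
#' \deqn{B(t) = B_0 + r t, \quad B_0 + a e^{r t}, \quad B_0 + K/(1 + a e^{-r t})}
#' (lag-phase linear, exponential-phase, and resource/antibiotic-limited
#' logistic growth) by least squares and selects the model with minimal
#' corrected AIC, \eqn{AICc = n\ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)} with
#' \eqn{k} counting model parameters plus one variance parameter. Ties are
#' broken toward fewer parameters. For the logistic model
#' \eqn{B(0) = B_0 + K/(1+a)}, so \eqn{a} is inversely related to inoculum
#' density.
#'
#' @param curve a \code{\link{growth_curve}} with at least 6 observations.
#' @return An object of class \code{growth_fit} with fields \code{model},
#'   \code{B0}, \code{r}, \code{a}, \code{K}, \code{rss}, \code{aicc},
#'   \code{n_obs} and \code{aicc_all} (per-candidate AICc).
#' @export
fit_growth_models <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  t <- curve$times; y <- curve$od
  n <- length(y)
  if (n < 6L) stop("fit_growth_models: need at least 6 observations")
  cands <- list(.fit_linear(t, y))
  fe <- .fit_exponential(t, y)
  if (is.null(fe)) warning("fit_growth_models: exponential model did not converge")
  else cands <- c(cands, list(fe))
  fl <- .fit_logistic(t, y)
  if (is.null(fl)) warning("fit_growth_models: logistic model did not converge")
  else cands <- c(cands, list(fl))
  if (length(cands) == 0L) stop("fit_growth_models: no model converged")
  aiccs <- vapply(cands, function(cc) .aicc(cc$rss, n, cc$k), numeric(1))
  ks <- vapply(cands, `[[`, integer(1), "k")
  ord <- order(ks)  # candidates by parsimony; first strict minimum wins ties
  best <- ord[which.min(aiccs[ord])]
  out <- cands[[best]]
  names(aiccs) <- vapply(cands, `[[`, character(1), "model")
  structure(list(model = out$model, B0 = out$B0, r = out$r, a = out$a,
                 K = out$K, rss = out$rss, aicc = aiccs[[best]], n_obs = n,
                 aicc_all = aiccs),
            class = "growth_fit")
}

#' Construct a growth-model fit directly from parameters
#'
#' Useful for evaluating rate statistics on analytically specified models.
#'
#' @param model \code{"linear"}, \code{"exponential"} or \code{"logistic"}.
#' @param B0 blank (baseline OD).
#' @param r growth rate per hour.
#' @param a inoculum coefficient (exponential/logistic).
#' @param K carrying capacity (logistic).
#' @return An object of class \code{growth_fit}.
#' @export
growth_fit <- function(model = c("linear", "exponential", "logistic"),
                       B0 = 0, r = 0, a = NA_real_, K = NA_real_) {
  model <- match.arg(model)
  structure(list(model = model, B0 = B0, r = r, a = a, K = K,
                 rss = NA_real_, aicc = NA_real_, n_obs = NA_integer_,
                 aicc_all = NULL),
            class = "growth_fit")
}

#' Evaluate a fitted growth model
#'
#' @param object a \code{growth_fit}.
#' @param times numeric vector of times (hours).
#' @param ... unused.
#' @return numeric vector \eqn{B(t)}.
#' @export
predict.growth_fit <- function(object, times, ...) {
  switch(object$model,
         linear = object$B0 + object$r * times,
         exponential = object$B0 + object$a * exp(object$r * times),
         logistic = object$B0 + object$K / (1 + object$a * exp(-object$r * times)))
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth fit: %s model, B0 = %.4g, r = %.4g /h", x$model, x$B0, x$r))
  if (x$model == "logistic") cat(sprintf(", K = %.4g, a = %.4g", x$K, x$a))
  if (x$model == "exponential") cat(sprintf(", a = %.4g", x$a))
  if (is.finite(x$aicc)) cat(sprintf(" (AICc %.2f, n = %d)", x$aicc, x$n_obs))
  cat("\n")
  invisible(x)
}

#' Blank-correct a growth curve using its fitted blank
#'
#' Subtracts the fitted blank \eqn{B_0} from the OD trace (and an optional
#' GFP blank from the fluorescence trace). Negative corrected values are
#' retained, not clipped, so downstream statistics see unbiased noise.
#'
#' @param curve a \code{\link{growth_curve}}.
#' @param fit the \code{growth_fit} obtained for this curve; fitted on the
#'   fly when omitted.
#' @param gfp_blank optional fluorescence blank to subtract.
#' @return the corrected \code{growth_curve} (attribute \code{"blank"} records
#'   the subtracted \eqn{B_0}).
#' @export
blank_correct <- function(curve, fit = NULL, gfp_blank = NULL) {
  stopifnot(inherits(curve, "growth_curve"))
  if (is.null(fit)) fit <- fit_growth_models(curve)
  out <- curve
  out$od <- curve$od - fit$B0
  if (!is.null(gfp_blank) && !is.null(curve$gfp))
    out$gfp <- curve$gfp - gfp_blank
  attr(out, "blank") <- fit$B0
  out
}

#' Dose-response data at a fixed read time
#'
#' @param doses numeric vector of doses (ug/ml), non-negative and sorted.
#' @param densities matrix of densities (rows = replicates, columns = doses)
#'   at the read time (24 h by convention).
#' @param strain strain label.
#' @param season season index.
#' @return An object of class \code{dose_response}.
#' @export
dose_response <- function(doses, densities, strain = "", season = 1L) {
  densities <- as.matrix(densities)
  stopifnot(all(doses >= 0), !is.unsorted(doses),
            ncol(densities) == length(doses), all(is.finite(densities)))
  if (length(unique(doses)) < 3L)
    stop("dose_response: need at least 3 distinct doses")
  structure(list(doses = doses, densities = densities, strain = strain,
                 season = as.integer(season)),
            class = "dose_response")
}

.hill_value <- function(dose, b_max, k_half, n_hill, b_floor) {
  b_floor + (b_max - b_floor) / (1 + (dose / k_half)^n_hill)
}

#' Fit a Hill function to dose-response data
#'
#' Fits the decreasing Hill curve
#' \deqn{B(A) = b_{floor} + (b_{max} - b_{floor}) / (1 + (A/k_{1/2})^{n})}
#' to replicate-mean densities by nonlinear least squares, then locates the
#' MIC (IC99) and a bootstrap confidence interval for it by resampling
#' replicates.
#'
#' @param dr a \code{\link{dose_response}} with >= 3 doses.
#' @param fit_floor estimate the high-dose asymptote \code{b_floor}
#'   (default \code{FALSE}: fixed at 0, detection-limit plateaus can be
#'   turned on when present in the data).
#' @param bootstrap_n bootstrap resamples for the MIC confidence interval
#'   (0 disables the bootstrap).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class \code{hill_fit} with fields \code{b_max},
#'   \code{k_half}, \code{n_hill}, \code{b_floor}, \code{param_cov},
#'   \code{mic}, \code{mic_attained}, \code{mic_ci}, \code{rss}.
#' @export
fit_hill <- function(dr, fit_floor = FALSE, bootstrap_n = 1000L, seed = 1L) {
  stopifnot(inherits(dr, "dose_response"))
  doses <- dr$doses
  means <- colMeans(dr$densities)
  if (all(diff(means) >= 0) && means[length(means)] > means[1L] + 1e-12)
    stop("fit_hill: dose-response is monotone increasing; Hill model assumes inhibition")
  if (stats::sd(means) < 1e-12 * max(abs(means), 1))
    stop("fit_hill: no dose signal (constant densities); Hill exponent unidentifiable")
  core <- .fit_hill_means(doses, means, fit_floor, seed)
  if (is.null(core)) stop("fit_hill: Hill fit did not converge")
  zd <- if (doses[1L] == 0) means[1L] else core$b_max
  mic <- mic_ic99(core, zero_dose_density = zd)
  mic_ci <- c(NA_real_, NA_real_)
  k_half_ci <- c(NA_real_, NA_real_)
  if (bootstrap_n > 0L && nrow(dr$densities) > 1L) {
    set.seed(seed)
    n_rep <- nrow(dr$densities)
    boots <- vapply(seq_len(bootstrap_n), function(i) {
      idx <- sample.int(n_rep, n_rep, replace = TRUE)
      m <- colMeans(dr$densities[idx, , drop = FALSE])
      cb <- tryCatch(.fit_hill_means(doses, m, fit_floor, seed + i),
                     error = function(e) NULL)
      if (is.null(cb)) return(c(NA_real_, NA_real_))
      zdb <- if (doses[1L] == 0) m[1L] else cb$b_max
      c(mic_ic99(cb, zero_dose_density = zdb)$dose, cb$k_half)
    }, numeric(2))
    mics <- boots[1L, ][is.finite(boots[1L, ])]
    khs <- boots[2L, ][is.finite(boots[2L, ])]
    if (length(mics) >= 10L)
      mic_ci <- unname(stats::quantile(mics, c(0.025, 0.975)))
    if (length(khs) >= 10L)
      k_half_ci <- unname(stats::quantile(khs, c(0.025, 0.975)))
  }
  structure(c(core, list(mic = mic$dose, mic_attained = mic$attained,
                         mic_ci = mic_ci, k_half_ci = k_half_ci)),
            class = "hill_fit")
}

# Core Hill fit on replicate means; returns plain list or NULL. Multi-start
# is deterministic (fixed jitter factors) so it has no RNG side effects
# inside the bootstrap loop.
.fit_hill_means <- function(doses, means, fit_floor, seed = NULL) {
  b_max0 <- max(means)
  half <- b_max0 / 2
  k0 <- doses[which.min(abs(means - half))]
  if (k0 <= 0) k0 <- max(stats::median(doses[doses > 0]), 1e-3)
  jitters <- list(c(1, 1, 1), c(0.7, 1.5, 0.6), c(1.3, 0.6, 1.6),
                  c(1, 2.5, 0.4))
  starts <- lapply(jitters, function(j)
    c(b_max = b_max0 * j[1L], k_half = k0 * j[2L], n_hill = 2 * j[3L]))
  for (st in starts) {
    fit <- tryCatch({
      if (fit_floor) {
        minpack.lm::nlsLM(
          means ~ b_floor + (b_max - b_floor) / (1 + (doses / k_half)^n_hill),
          start = c(as.list(st), list(b_floor = min(means))),
          lower = c(1e-12, 1e-9, 1e-9, 0),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        minpack.lm::nlsLM(
          means ~ b_max / (1 + (doses / k_half)^n_hill),
          start = as.list(st), lower = c(1e-12, 1e-9, 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
      return(list(b_max = unname(co["b_max"]), k_half = unname(co["k_half"]),
                  n_hill = unname(co["n_hill"]),
                  b_floor = if (fit_floor) unname(co["b_floor"]) else 0,
                  param_cov = vc, rss = sum(stats::resid(fit)^2)))
    }
  }
  NULL
}

#' Evaluate a fitted Hill dose-response
#'
#' @param object a \code{hill_fit} (or the plain parameter list).
#' @param dose numeric vector of doses.
#' @param ... unused.
#' @return predicted densities.
#' @export
predict.hill_fit <- function(object, dose, ...) {
  .hill_value(dose, object$b_max, object$k_half, object$n_hill, object$b_floor)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: b_max = %.4g, k_half = %.4g ug/ml, n = %.3g, floor = %.4g\n",
              x$b_max, x$k_half, x$n_hill, x$b_floor))
  if (x$mic_attained) {
    cat(sprintf("MIC (IC99) = %.4g ug/ml", x$mic))
    if (all(is.finite(x$mic_ci)))
      cat(sprintf(" [95%% CI %.4g-%.4g]", x$mic_ci[1L], x$mic_ci[2L]))
    cat("\n")
  } else cat("MIC (IC99): not attained (floor above 1% of control)\n")
  invisible(x)
}

#' MIC as the 99% inhibitory concentration (IC99)
#'
#' The MIC is defined as the dose \eqn{E} at which the 24-h density equals 1%
#' of the drug-free density, \eqn{B(24h, E) = B(24h, 0)/100}. Solved
#' analytically from the Hill inverse; when the fitted floor lies above the 1%
#' target the MIC is flagged as not attained.
#'
#' @param fit a \code{hill_fit} (or list with \code{b_max}, \code{k_half},
#'   \code{n_hill}, \code{b_floor}).
#' @param zero_dose_density observed drug-free density (> 0); defaults to the
#'   fitted zero-dose density \code{b_max}.
#' @return list with \code{dose} (NA when not attained) and \code{attained}.
#' @export
mic_ic99 <- function(fit, zero_dose_density = fit$b_max) {
  stopifnot(zero_dose_density > 0)
  target <- zero_dose_density / 100
  if (fit$b_floor >= target || target >= fit$b_max)
    return(list(dose = NA_real_, attained = FALSE))
  ratio <- (fit$b_max - fit$b_floor) / (target - fit$b_floor) - 1
  if (ratio <= 0) return(list(dose = NA_real_, attained = FALSE))
  list(dose = fit$k_half * ratio^(1 / fit$n_hill), attained = TRUE)
}

#' Effective antibiotic dose (EAD)
#'
#' The EAD translates the density reached by a drug-adapted population into
#' the ancestral-dose scale: it is the dose that, applied to the ancestral
#' strain, would have limited growth to the same density \eqn{B^*}. It is
#' obtained by inverting the ancestral Hill dose-response,
#' \eqn{A_{EAD} = B^{-1}(B^*)}. If the treated strain grows to the drug-free
#' ancestral density or beyond, the EAD is zero; densities at or below the
#' fitted floor are beyond the fitted range and return \code{NA}. Larger
#' \eqn{B^*} yields smaller EAD.
#'
#' @param ancestral the ancestral strain's \code{hill_fit}.
#' @param b_star density (or vector of densities) reached by the treated
#'   population.
#' @return numeric vector of EAD doses; \code{NA} flags densities beyond the
#'   fitted range.
#' @export
ead <- function(ancestral, b_star) {
  stopifnot(all(is.finite(b_star)))
  b0 <- predict.hill_fit(ancestral, 0)
  out <- numeric(length(b_star))
  for (i in seq_along(b_star)) {
    b <- b_star[i]
    if (b >= b0) { out[i] <- 0; next }
    if (b <= ancestral$b_floor) { out[i] <- NA_real_; next }
    ratio <- (ancestral$b_max - ancestral$b_floor) / (b - ancestral$b_floor) - 1
    out[i] <- ancestral$k_half * ratio^(1 / ancestral$n_hill)
  }
  out
}
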