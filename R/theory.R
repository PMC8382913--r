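# Two-strain selection models for dose-dependent resistance evolution.
#
# A drug-susceptible strain S mutates at rate mu into a resistant strain R
# that experiences a reduced effective dose (scaling lambda < 1) at a fitness
# cost (multiplier ell < 1). The dose-dependence of the selection coefficient
# s(A) produces the "inverted-U": an interior dose at which resistance is
# enriched fastest (the dosing "hotspot").

#' Dose-dependent per-capita growth response
#'
#' Constructs the growth-response function \eqn{g(A)} mapping antibiotic dose
#' to the per-capita growth rate of the susceptible strain, normalised so that
#' \eqn{g(0) = 1} and strictly decreasing in dose.
#'
#' Two standard forms are supported:
#' \describe{
#'   \item{exponential}{\eqn{g(A) = e^{-pA}}, with efficacy parameter
#'     \code{p > 0} (per unit dose). Yields a closed-form hotspot dose.}
#'   \item{hill}{\eqn{g(A) = 1/((A/k_{1/2})^{n} + 1)}, the Hill inhibition
#'     curve with half-inhibitory dose \code{k_half} and exponent
#'     \code{n_hill}. The defaults \code{k_half = 1}, \code{n_hill = 7}
#'     give the steep sigmoidal response used for illustrating the
#'     mutant selection window.}
#' }
#'
#' @param form character, \code{"exponential"} or \code{"hill"}.
#' @param p decay rate per unit dose (exponential form only).
#' @param k_half half-inhibitory dose (hill form only).
#' @param n_hill Hill exponent (hill form only).
#' @return An object of class \code{growth_response}.
#' @examples
#' g <- growth_response("hill", k_half = 1, n_hill = 7)
#' predict(g, c(0, 1, 2))  # 1, 0.5, ~0.0078
#' @export
growth_response <- function(form = c("exponential", "hill"),
                            p = 1, k_half = 1, n_hill = 7) {
  form <- match.arg(form)
  if (form == "exponential") {
    stopifnot(is.finite(p), p > 0)
  } else {
    stopifnot(is.finite(k_half), k_half > 0, is.finite(n_hill), n_hill > 0)
  }
  structure(list(form = form, p = p, k_half = k_half, n_hill = n_hill),
            class = "growth_response")
}

#' Evaluate a growth response at given doses
#'
#' @param object a \code{\link{growth_response}}.
#' @param dose numeric vector of doses (>= 0).
#' @param ... unused.
#' @return numeric vector \eqn{g(A)}.
#' @export
predict.growth_response <- function(object, dose, ...) {
  stopifnot(is.numeric(dose), all(dose >= 0))
  switch(object$form,
         exponential = exp(-object$p * dose),
         hill = 1 / ((dose / object$k_half)^object$n_hill + 1))
}

#' @export
print.growth_response <- function(x, ...) {
  if (x$form == "exponential") {
    cat(sprintf("growth response: g(A) = exp(-%g A)\n", x$p))
  } else {
    cat(sprintf("growth response: g(A) = 1 / ((A/%g)^%g + 1)\n",
                x$k_half, x$n_hill))
  }
  invisible(x)
}

#' Parameters of the two-strain selection model
#'
#' Bundles the parameters of the exponential-growth competition model
#' \deqn{dS/dt = (g(A) - d)S - \mu S, \quad dR/dt = (\ell g(\lambda A) - d)R + \mu S}
#' where \code{mu} is the mutation rate from susceptible to resistant,
#' \code{d} a natural death rate, \code{lam} the dose scaling experienced by
#' the resistant strain (0 < lam < 1) and \code{ell} its fitness-cost
#' multiplier (0 < ell < 1).
#'
#' @param mu mutation rate per unit time (>= 0).
#' @param d natural death rate per unit time (>= 0).
#' @param ell fitness-cost multiplier in (0, 1).
#' @param lam dose-scaling factor in (0, 1).
#' @param g a \code{\link{growth_response}}.
#' @return An object of class \code{theory_params}.
#' @export
theory_params <- function(mu, d, ell, lam, g) {
  stopifnot(inherits(g, "growth_response"))
  vals <- c(mu = mu, d = d, ell = ell, lam = lam)
  if (!all(is.finite(vals)))
    stop("theory_params: all parameters must be finite")
  if (mu < 0 || d < 0) stop("theory_params: mu and d must be >= 0")
  if (ell <= 0 || ell >= 1 || lam <= 0 || lam >= 1)
    stop("theory_params: need 0 < ell < 1 and 0 < lam < 1")
  structure(list(mu = mu, d = d, ell = ell, lam = lam, g = g),
            class = "theory_params")
}

#' Net growth rates of the susceptible and resistant strains
#'
#' Computes \eqn{\theta_1 = g(A) - d - \mu} (susceptible) and
#' \eqn{\theta_2 = \ell g(\lambda A) - d} (resistant) at dose \code{A}.
#'
#' @param params a \code{\link{theory_params}}.
#' @param A dose (vectorised).
#' @return list with components \code{theta1} and \code{theta2}.
#' @export
theta_pair <- function(params, A) {
  stopifnot(inherits(params, "theory_params"))
  list(theta1 = predict(params$g, A) - params$d - params$mu,
       theta2 = params$ell * predict(params$g, params$lam * A) - params$d)
}

# Relative threshold below which theta1 ~ theta2 is treated as degenerate and
# the l'Hopital limit R(t) = mu t exp(theta1 t) is used.
.theta_degenerate_tol <- 1e-10

#' Exact solution of the exponential two-strain model
#'
#' Returns the closed-form solution \eqn{S(t) = e^{\theta_1 t}} and
#' \eqn{R(t) = \mu/(\theta_1-\theta_2)\,(e^{\theta_1 t} - e^{\theta_2 t})}
#' for the initially clonal population \eqn{S(0)=1, R(0)=0}. When
#' \eqn{\theta_1 \approx \theta_2} the removable singularity is replaced by
#' its limit \eqn{R(t) = \mu t e^{\theta_1 t}}.
#'
#' @param params a \code{\link{theory_params}}.
#' @param A dose (scalar).
#' @param times numeric vector of times >= 0.
#' @return data.frame with columns \code{time}, \code{S}, \code{R}.
#' @export
exact_solution <- function(params, A, times) {
  stopifnot(inherits(params, "theory_params"), length(A) == 1L,
            is.numeric(times), all(times >= 0))
  th <- theta_pair(params, A)
  if (!all(is.finite(c(th$theta1, th$theta2))))
    stop("exact_solution: non-finite net growth rates")
  S <- exp(th$theta1 * times)
  dth <- th$theta1 - th$theta2
  if (abs(dth) < .theta_degenerate_tol * max(1, abs(th$theta1))) {
    R <- params$mu * times * exp(th$theta1 * times)
  } else {
    R <- params$mu / dth * (exp(th$theta1 * times) - exp(th$theta2 * times))
  }
  data.frame(time = times, S = S, R = R)
}

#' Frequency of the susceptible strain over time
#'
#' Closed form
#' \eqn{\rho(t) = 1/(1 + \mu(1 - e^{(\theta_2-\theta_1)t})/(\theta_1-\theta_2))},
#' the frequency \eqn{S/(S+R)} under \code{\link{exact_solution}}. It depends
#' on the death rate \code{d} only through \eqn{\theta_1 - \theta_2}, which is
#' independent of \code{d}: dose-dependent selection is independent of the
#' susceptible strain's MIC.
#'
#' @inheritParams exact_solution
#' @param t numeric vector of times >= 0.
#' @return numeric vector of frequencies in (0, 1].
#' @export
resistant_frequency <- function(params, A, t) {
  stopifnot(inherits(params, "theory_params"), length(A) == 1L, all(t >= 0))
  th <- theta_pair(params, A)
  dth <- th$theta1 - th$theta2
  if (abs(dth) < .theta_degenerate_tol * max(1, abs(th$theta1))) {
    # limit of the closed form as theta1 -> theta2: rho = 1/(1 + mu t)
    return(1 / (1 + params$mu * t))
  }
  1 / (1 + params$mu * (1 - exp(-dth * t)) / dth)
}

#' Selection coefficient for resistance at a given dose
#'
#' \eqn{s(A) = \theta_2 - \theta_1 = \ell g(\lambda A) - g(A) + \mu}. A
#' positive value means the resistant strain is enriched; its maximiser over
#' dose is the adaptation "hotspot".
#'
#' @param params a \code{\link{theory_params}}.
#' @param A dose (vectorised).
#' @return numeric vector \eqn{s(A)}.
#' @export
selection_coefficient <- function(params, A) {
  stopifnot(inherits(params, "theory_params"), all(A >= 0))
  params$ell * predict(params$g, params$lam * A) - predict(params$g, A) +
    params$mu
}

#' Dose of fastest resistance evolution (hotspot)
#'
#' Maximises the selection coefficient \eqn{s(A)} over dose. For the
#' exponential growth response the maximiser has the closed form
#' \deqn{A_{hot} = \frac{1}{p(1-\lambda)} \ln\frac{1}{\ell\lambda},}
#' which is positive because \eqn{0 < \ell, \lambda < 1}. For the Hill
#' response the maximiser is found numerically on a log-spaced grid over
#' \code{[1e-4, A_max]} followed by golden-section refinement to relative
#' tolerance \code{1e-8}; the maximum may also sit at \eqn{A = 0} or at the
#' bracket edge, which is reported rather than silently truncated.
#'
#' @param params a \code{\link{theory_params}}.
#' @param A_max upper end of the search bracket; default \code{100 * k_half}
#'   (hill) or \code{100 / p} (exponential).
#' @param force_numeric maximise numerically even for the exponential form
#'   (used for cross-checks).
#' @return list with \code{A_hot}, \code{s_max}, \code{method}
#'   (\code{"closed_form"} or \code{"numeric"}) and \code{location}
#'   (\code{"interior"}, \code{"zero"} or \code{"edge"}); an edge location
#'   carries a warning.
#' @export
hotspot_dose <- function(params, A_max = NULL, force_numeric = FALSE) {
  stopifnot(inherits(params, "theory_params"))
  g <- params$g
  if (is.null(A_max))
    A_max <- if (g$form == "hill") 100 * g$k_half else 100 / g$p
  if (g$form == "exponential" && !force_numeric) {
    A_hot <- 1 / (g$p * (1 - params$lam)) * log(1 / (params$ell * params$lam))
    return(list(A_hot = A_hot, s_max = selection_coefficient(params, A_hot),
                method = "closed_form", location = "interior"))
  }
  grid <- c(0, exp(seq(log(1e-4), log(A_max), length.out = 400L)))
  s_grid <- selection_coefficient(params, grid)
  i <- which.max(s_grid)
  if (i == 1L)
    return(list(A_hot = 0, s_max = s_grid[1L], method = "numeric",
                location = "zero"))
  if (i == length(grid)) {
    warning("hotspot_dose: maximiser at the bracket edge; increase A_max")
    return(list(A_hot = grid[i], s_max = s_grid[i], method = "numeric",
                location = "edge"))
  }
  opt <- stats::optimize(function(a) selection_coefficient(params, a),
                         lower = grid[i - 1L], upper = grid[i + 1L],
                         maximum = TRUE, tol = 1e-8 * max(1, grid[i]))
  list(A_hot = opt$maximum, s_max = opt$objective, method = "numeric",
       location = "interior")
}

#' Mutant-selection-window boundaries
#'
#' Computes the three characteristic doses of the model: the MSC (mutant
#' selection concentration), the smallest dose with a positive selection
#' coefficient; the susceptible strain's MIC, where \eqn{g(A) = d}; and the
#' MPC (mutant prevention concentration, the resistant strain's MIC), where
#' \eqn{\ell g(\lambda A) = d}. The MSW hypothesis places selection for
#' resistance between MIC and MPC; the selection-coefficient model places its
#' onset at the (typically lower) MSC.
#'
#' @param params a \code{\link{theory_params}}; a root for MIC/MPC requires
#'   \code{0 < d < 1} since \eqn{g(0) = 1}.
#' @param A_max upper end of the root bracket (default as in
#'   \code{\link{hotspot_dose}}).
#' @return list with components \code{msc}, \code{mic_s}, \code{mpc} (each
#'   \code{NA} with the corresponding \code{*_attained = FALSE} flag when the
#'   defining equation has no root in the bracket).
#' @export
msw_boundaries <- function(params, A_max = NULL) {
  stopifnot(inherits(params, "theory_params"))
  g <- params$g
  if (is.null(A_max))
    A_max <- if (g$form == "hill") 100 * g$k_half else 100 / g$p
  root <- function(f) {
    lo <- f(0); hi <- f(A_max)
    if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) return(NA_real_)
    stats::uniroot(f, c(0, A_max), tol = 1e-8)$root
  }
  mic_s <- root(function(a) predict(g, a) - params$d)
  mpc <- root(function(a) params$ell * predict(g, params$lam * a) - params$d)
  s0 <- selection_coefficient(params, 0)
  msc <- if (s0 > 0) 0 else root(function(a) selection_coefficient(params, a))
  list(msc = msc, msc_attained = !is.na(msc),
       mic_s = mic_s, mic_attained = !is.na(mic_s),
       mpc = mpc, mpc_attained = !is.na(mpc))
}

#' Logistic competition between susceptible and resistant strains
#'
#' Integrates the resource-limited competition model with unit carrying
#' capacity
#' \deqn{dS/dt = S(1 - A - (S+R)) - \mu S, \quad dR/dt = R(1 - (S+R)) + \mu S,}
#' where the antibiotic dose \code{A} is in units of the susceptible strain's
#' MIC and resistance carries no cost. Unlike the exponential model this
#' produces saturating density trajectories whose dose-responses are monotone
#' for short treatments but non-monotone for longer ones.
#'
#' @param A dose in model units (1 = susceptible MIC).
#' @param mu mutation rate per unit time.
#' @param S0,R0 initial densities (>= 0).
#' @param t_end final time (> 0).
#' @param dt_out output sampling interval.
#' @param rtol,atol solver tolerances (adaptive \code{deSolve::lsoda}).
#' @return data.frame with columns \code{time}, \code{S}, \code{R}; negative
#'   round-off is clipped at 0.
#' @export
simulate_competition <- function(A, mu, S0, R0, t_end, dt_out = t_end / 200,
                                 rtol = 1e-8, atol = 1e-9) {
  stopifnot(S0 >= 0, R0 >= 0, t_end > 0, mu >= 0)
  times <- seq(0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  deriv <- function(t, y, parms) {
    N <- y[1L] + y[2L]
    list(c(y[1L] * (1 - A - N) - mu * y[1L],
           y[2L] * (1 - N) + mu * y[1L]))
  }
  sol <- deSolve::lsoda(c(S = S0, R = R0), times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop(sprintf("simulate_competition: solver failed at t = %g",
                 sol[nrow(sol), 1L]))
  out <- as.data.frame(sol)
  out$S <- pmax(out$S, 0)
  out$R <- pmax(out$R, 0)
  out
}

#' Dynamic dose-responses and their time differences
#'
#' Runs \code{\link{simulate_competition}} on a dose grid, records the total
#' density \eqn{N(A, t) = S + R} at the requested snapshot times, and computes
#' the forward time-difference \eqn{(N(A, t_{k+1}) - N(A, t_k))/\Delta t} per
#' dose. The dose at which the time-difference is maximal is the empirical
#' analogue of the adaptation hotspot; it moves to higher doses with longer
#' treatment duration.
#'
#' @param A_grid numeric vector of doses.
#' @param mu mutation rate.
#' @param S0,R0 initial densities.
#' @param t_snapshots increasing vector (length >= 2) of snapshot times.
#' @return list with \code{density} (data.frame: dose, time, N),
#'   \code{differences} (data.frame: dose, t_from, t_to, dN_dt) and
#'   \code{argmax} (data.frame: t_from, t_to, dose_argmax).
#' @export
dose_response_time_difference <- function(A_grid, mu, S0, R0, t_snapshots) {
  stopifnot(length(t_snapshots) >= 2L, !is.unsorted(t_snapshots))
  dens <- do.call(rbind, lapply(A_grid, function(a) {
    sim <- simulate_competition(a, mu, S0, R0,
                                t_end = max(t_snapshots),
                                dt_out = max(t_snapshots) / 400)
    N <- vapply(t_snapshots, function(tt) {
      i <- which.min(abs(sim$time - tt))
      sim$S[i] + sim$R[i]
    }, numeric(1))
    data.frame(dose = a, time = t_snapshots, N = N)
  }))
  diffs <- do.call(rbind, lapply(seq_len(length(t_snapshots) - 1L), function(k) {
    t1 <- t_snapshots[k]; t2 <- t_snapshots[k + 1L]
    n1 <- dens$N[dens$time == t1]
    n2 <- dens$N[dens$time == t2]
    data.frame(dose = A_grid, t_from = t1, t_to = t2,
               dN_dt = (n2 - n1) / (t2 - t1))
  }))
  argmax <- do.call(rbind, lapply(split(diffs, list(diffs$t_from, diffs$t_to),
                                        drop = TRUE), function(d) {
    data.frame(t_from = d$t_from[1L], t_to = d$t_to[1L],
               dose_argmax = d$dose[which.max(d$dN_dt)])
  }))
  rownames(argmax) <- NULL
  list(density = dens, differences = diffs, argmax = argmax)
}
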