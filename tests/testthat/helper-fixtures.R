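# Shared fixture builders for the test suite.

# A standard exponential-response parameter set.
exp_params <- function(mu = 0.01, d = 0.1, ell = 0.9, lam = 0.5, p = 1) {
  theory_params(mu = mu, d = d, ell = ell, lam = lam,
                g = growth_response("exponential", p = p))
}

hill_params <- function(mu = 0.001, d = 0.5, ell = 0.9, lam = 0.5,
                        k_half = 1, n_hill = 7) {
  theory_params(mu = mu, d = d, ell = ell, lam = lam,
                g = growth_response("hill", k_half = k_half, n_hill = n_hill))
}

# Independent ODE oracle for the exponential two-strain model.
integrate_two_strain <- function(params, A, times) {
  g <- params$g
  deriv <- function(t, y, p) {
    list(c((predict(g, A) - params$d) * y[1L] - params$mu * y[1L],
           (params$ell * predict(g, params$lam * A) - params$d) * y[2L] +
             params$mu * y[1L]))
  }
  sol <- deSolve::lsoda(c(S = 1, R = 0), times, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-14)
  as.data.frame(sol)
}

# Noiseless growth traces at 20-min spacing over 24 h.
trace_times <- seq(0, 24, by = 1 / 3)

make_logistic_trace <- function(B0 = 0.05, K = 1, a = 99, r = 0.5,
                                times = trace_times) {
  B0 + K / (1 + a * exp(-r * times))
}

# Hill dose-response replicate matrix (rows = replicates).
make_hill_dr <- function(doses = seq(0, 50, by = 5), b_max = 1, k_half = 20,
                         n_hill = 4, n_rep = 4, noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- b_max / (1 + (doses / k_half)^n_hill)
  dens <- matrix(rep(mu, each = n_rep), nrow = n_rep)
  if (noise_cv > 0)
    dens <- dens * (1 + matrix(stats::rnorm(length(dens), 0, noise_cv),
                               nrow = n_rep))
  dose_response(doses, dens)
}

# A noise-free serial-transfer configuration (deterministic signal only).
quiet_noise <- list(blank_mean = 0, blank_sd = 0, cv = 0, osc_amp = 0,
                    osc_wavelengths_h = c(10, 0.75))
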