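# Two-strain selection models: exact solution, selection coefficient,
# hotspot dose, MSW boundaries, logistic competition.

test_that("exact solution matches the trivial no-mutation case", {
  pp <- exp_params(mu = 0)
  sol <- exact_solution(pp, A = 1, times = c(0, 1, 5))
  th <- theta_pair(pp, 1)
  expect_equal(sol$R, c(0, 0, 0))
  expect_equal(sol$S, exp(th$theta1 * c(0, 1, 5)))
})

test_that("exact solution agrees with adaptive ODE integration", {
  set.seed(11)
  for (i in 1:10) {
    pp <- theory_params(mu = runif(1, 0, 0.05), d = runif(1, 0, 0.5),
                        ell = runif(1, 0.5, 0.99), lam = runif(1, 0.2, 0.9),
                        g = growth_response("exponential", p = runif(1, 0.5, 2)))
    A <- runif(1, 0, 3)
    times <- seq(0, 10, by = 0.5)
    ana <- exact_solution(pp, A, times)
    num <- integrate_two_strain(pp, A, times)
    expect_lt(max(abs(ana$S - num$S) / pmax(abs(num$S), 1e-12)), 1e-6)
    expect_lt(max(abs(ana$R - num$R) / pmax(abs(num$R), 1e-12)), 1e-6)
  }
})

test_that("degenerate theta1 == theta2 uses the analytic limit", {
  # pick the dose where theta1 = theta2 (exists for mu > 0 small)
  pp <- exp_params(mu = 0.01)
  f <- function(A) {
    th <- theta_pair(pp, A)
    th$theta1 - th$theta2
  }
  A_star <- uniroot(f, c(0.1, 10), tol = 1e-14)$root
  th <- theta_pair(pp, A_star)
  sol <- exact_solution(pp, A_star, times = c(1, 2, 5))
  expect_equal(sol$R, pp$mu * c(1, 2, 5) * exp(th$theta1 * c(1, 2, 5)),
               tolerance = 1e-6)
})

test_that("resistant frequency: initial clonality, long-time limit, closed form", {
  # parameters engineered so theta1 = 0.5, theta2 = 0.3, mu = 0.1
  g <- growth_response("exponential", p = 1)
  A <- -log(0.8)                       # g(A) = 0.8
  ell <- 0.5 / exp(-0.5 * A)           # ell g(A/2) = 0.5
  pp <- theory_params(mu = 0.1, d = 0.2, ell = ell, lam = 0.5, g = g)
  th <- theta_pair(pp, A)
  expect_equal(th$theta1, 0.5, tolerance = 1e-12)
  expect_equal(th$theta2, 0.3, tolerance = 1e-12)
  expect_equal(resistant_frequency(pp, A, 0), 1)
  expect_equal(resistant_frequency(pp, A, 1000), 1 / (1 + 0.1 / 0.2),
               tolerance = 1e-9)
  # closed form equals S/(S+R) from the exact solution
  ts <- c(0.5, 1, 3, 7)
  sol <- exact_solution(pp, A, ts)
  expect_equal(resistant_frequency(pp, A, ts), sol$S / (sol$S + sol$R),
               tolerance = 1e-10)
})

test_that("resistant frequency is invariant under the death rate", {
  set.seed(21)
  g <- growth_response("exponential", p = 1.3)
  ts <- seq(0, 20, by = 2)
  base <- theory_params(0.02, 0.1, 0.8, 0.4, g)
  ref <- resistant_frequency(base, 1.5, ts)
  for (d in runif(8, 0, 2)) {
    pp <- theory_params(0.02, d, 0.8, 0.4, g)
    expect_equal(resistant_frequency(pp, 1.5, ts), ref, tolerance = 1e-12)
  }
})

test_that("selection coefficient forced values and hotspot geometry", {
  g <- growth_response("exponential", p = 1)
  pp <- theory_params(0.01, 0.1, 0.999999, 0.999999, g)
  # ell = lam = 1 limit: s(A) -> mu for every A (approached from below 1)
  expect_equal(selection_coefficient(pp, c(0, 1, 7)), rep(0.01, 3),
               tolerance = 1e-4)
  pp2 <- exp_params(mu = 0.02)
  expect_equal(selection_coefficient(pp2, 0), pp2$ell - 1 + pp2$mu)
  # interior hotspot beats both endpoints
  pp3 <- exp_params(mu = 0, ell = 0.9, lam = 0.5, p = 1)
  hot <- hotspot_dose(pp3)
  expect_gt(selection_coefficient(pp3, hot$A_hot),
            selection_coefficient(pp3, 0))
  expect_gt(selection_coefficient(pp3, hot$A_hot),
            selection_coefficient(pp3, 10))
})

test_that("hotspot dose: closed form, scaling in p, maximality", {
  pp <- exp_params()
  hot <- hotspot_dose(pp)
  expect_equal(hot$A_hot, 2 * log(1 / 0.45), tolerance = 1e-12)
  expect_equal(hot$method, "closed_form")
  # grid + refinement maximiser agrees with the closed form
  num <- hotspot_dose(pp, force_numeric = TRUE)
  expect_lt(abs(num$A_hot - hot$A_hot), 1e-6)
  # doubling antibiotic efficacy halves the hotspot dose
  pp2 <- exp_params(p = 2)
  expect_equal(hotspot_dose(pp2)$A_hot, hot$A_hot / 2, tolerance = 1e-12)
  # second derivative negative at an interior maximiser
  h <- 1e-4
  s <- function(a) selection_coefficient(pp, a)
  d2 <- (s(hot$A_hot + h) - 2 * s(hot$A_hot) + s(hot$A_hot - h)) / h^2
  expect_lt(d2, 0)
  # hill response: interior numeric maximiser
  hh <- hotspot_dose(hill_params())
  expect_equal(hh$method, "numeric")
  expect_equal(hh$location, "interior")
  expect_gt(hh$A_hot, 0)
})

test_that("MSW boundaries solve their defining equations", {
  pp <- exp_params(d = exp(-2))
  b <- msw_boundaries(pp)
  expect_equal(b$mic_s, 2, tolerance = 1e-7)
  bh <- msw_boundaries(hill_params(d = 0.5))
  expect_equal(bh$mic_s, 1, tolerance = 1e-7)
  # MPC exceeds the susceptible MIC exactly when the mutant still grows at
  # that dose (benefit of the dose scaling outweighs the fitness cost):
  # ell * g(lam * mic_s) > d. A strong cost with a weak benefit reverses it.
  set.seed(31)
  for (i in 1:20) {
    pp <- theory_params(0.001, runif(1, 0.05, 0.8), runif(1, 0.5, 0.95),
                        runif(1, 0.3, 0.9),
                        growth_response("exponential", p = runif(1, 0.5, 2)))
    b <- msw_boundaries(pp)
    expect_true(b$mic_attained)
    grows_at_mic <- pp$ell * predict(pp$g, pp$lam * b$mic_s) > pp$d
    if (grows_at_mic) {
      expect_true(b$mpc_attained)
      expect_gt(b$mpc, b$mic_s)
    } else if (b$mpc_attained) {
      expect_lte(b$mpc, b$mic_s)
    }
  }
  # canonical resistant regime: moderate cost, strong dose scaling
  bc <- msw_boundaries(exp_params(mu = 0.001, d = 0.2, ell = 0.9, lam = 0.5))
  expect_gt(bc$mpc, bc$mic_s)
  # no root when d >= 1: flagged, not fabricated
  b2 <- msw_boundaries(theory_params(0.001, 1.5, 0.9, 0.5,
                                     growth_response("exponential", p = 1)))
  expect_false(b2$mic_attained)
})

test_that("logistic competition: logistic limit, resistant takeover, positivity", {
  sim <- simulate_competition(A = 0, mu = 0, S0 = 0.01, R0 = 0, t_end = 25)
  expect_equal(tail(sim$S, 1), 1, tolerance = 1e-4)
  expect_true(all(sim$R == 0))
  # analytic logistic law
  t_mid <- sim$time[sim$time > 0]
  expect_equal(sim$S[sim$time %in% t_mid],
               0.01 * exp(t_mid) / (1 + 0.01 * (exp(t_mid) - 1)),
               tolerance = 1e-5)
  sim2 <- simulate_competition(A = 0.5, mu = 0, S0 = 0.01, R0 = 0.001,
                               t_end = 60)
  expect_equal(tail(sim2$R, 1), 1, tolerance = 1e-3)
  expect_lt(tail(sim2$S, 1), 1e-3)
  expect_true(all(sim2$S >= 0) && all(sim2$R >= 0))
})

test_that("dose-response time differences: no-resistance and hotspot drift", {
  A_grid <- seq(0, 1.5, by = 0.25)
  # mu = 0, R0 = 0 during the growth phase: nothing adapts and growth is
  # fastest without drug, so the change is maximal at zero dose (once the
  # zero-dose culture saturates the remaining-growth window shifts the
  # argmax even without resistance, so snapshots stay pre-saturation)
  dr0 <- dose_response_time_difference(A_grid, mu = 0, S0 = 0.01, R0 = 0,
                                       t_snapshots = c(1, 2, 3))
  expect_true(all(dr0$argmax$dose_argmax == 0))
  # doses above all MICs with mu = 0: densities only decay
  dr_hi <- dose_response_time_difference(c(1.1, 1.3, 1.5), mu = 0, S0 = 0.01,
                                         R0 = 0, t_snapshots = c(3, 10))
  expect_true(all(dr_hi$differences$dN_dt <= 1e-12))
  # resistant sweeps push the argmax dose up with treatment duration
  dr <- dose_response_time_difference(A_grid, mu = 1e-6, S0 = 0.01, R0 = 0,
                                      t_snapshots = c(3, 6, 12, 24))
  am <- dr$argmax$dose_argmax
  expect_true(all(diff(am) >= 0))
  expect_gt(am[length(am)], am[1L])
})

test_that("parameter validation rejects invalid inputs", {
  g <- growth_response("exponential", p = 1)
  expect_error(theory_params(0.01, 0.1, 1.2, 0.5, g))
  expect_error(theory_params(0.01, 0.1, 0.9, 0, g))
  expect_error(theory_params(-0.01, 0.1, 0.9, 0.5, g))
  expect_error(theory_params(NaN, 0.1, 0.9, 0.5, g))
  expect_error(growth_response("exponential", p = -1))
})
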