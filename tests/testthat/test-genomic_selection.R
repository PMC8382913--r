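# Coverage-based relative copies, amplification selection proxies, SNP
# selection fits and the parallelism coefficient.

toy_track <- function(depth, dose = 20, time = 0, id = "s") {
  st <- seq(0, 99000, by = 1000)
  coverage_track("chr", st, st + 1000, depth, sample_id = id, dose = dose,
                 time = time)
}
toy_feature <- list(chrom = "chr", start = 40000, end = 50000, name = "amp")

test_that("relative copies: uniform null, whole-genome-mean bias, median", {
  anc <- toy_track(rep(200, 100), dose = 0)
  expect_equal(relative_copies(toy_track(rep(200, 100)), toy_feature,
                               anc)$rel_copies, 1)
  # 10% of genome at depth 600: genome mean 240, so mean-normalised 2.5
  dep <- rep(200, 100); dep[41:50] <- 600
  expect_equal(relative_copies(toy_track(dep), toy_feature, anc)$rel_copies,
               2.5)
  # the median denominator ignores the amplified tail: 600/200 = 3
  expect_equal(relative_copies(toy_track(dep), toy_feature, anc,
                               stat = "median")$rel_copies, 3)
  expect_equal(relative_copies(toy_track(dep), toy_feature, anc,
                               stat = "mode")$rel_copies, 3)
})

test_that("relative copies are invariant to global depth rescaling", {
  anc <- toy_track(rep(200, 100), dose = 0)
  dep <- rep(200, 100); dep[41:50] <- 450
  r1 <- relative_copies(toy_track(dep), toy_feature, anc)$rel_copies
  r2 <- relative_copies(toy_track(dep * 7), toy_feature, anc)$rel_copies
  expect_equal(r1, r2, tolerance = 1e-12)
  # errors: feature outside genome, zero coverage
  expect_error(relative_copies(toy_track(dep),
                               list(chrom = "chr", start = 2e6, end = 3e6),
                               anc), "overlaps no window")
  expect_error(relative_copies(toy_track(rep(0, 100)), toy_feature, anc))
})

test_that("amplification fit recovers parameters and the selection proxy", {
  t <- c(0, 2, 4)
  Ff <- function(t, p1, p2) p1 * (1 + t) / (1 + p2 * (1 + t))
  fit <- fit_amplification(list(times = t, rel_copies = Ff(t, 1.8, 0.6)))
  expect_equal(fit$p1, 1.8, tolerance = 1.8 * 0.005)
  expect_equal(fit$p2, 0.6, tolerance = 0.6 * 0.005)
  # closed-form maximum derivative at the earliest time
  expect_equal(fit$s_proxy, 1.8 / (1 + 0.6)^2, tolerance = 1e-6)
  # derivative arithmetic: p1 = 2, p2 = 1 at t = 0 gives 0.5
  fit2 <- fit_amplification(list(times = t, rel_copies = Ff(t, 2, 1)))
  expect_equal(fit2$s_proxy, 0.5, tolerance = 1e-6)
  # analytic derivative against finite differences of the fitted curve
  h <- 1e-6
  fd <- (Ff(h, fit$p1, fit$p2) - Ff(0, fit$p1, fit$p2)) / h
  expect_equal(fit$s_proxy, fd, tolerance = 1e-4)
})

test_that("flat relative-copy tracks yield a near-zero selection proxy", {
  t <- c(0, 2, 4)
  for (level in c(0.5, 1, 2)) {
    fit <- fit_amplification(list(times = t, rel_copies = rep(level, 3)))
    expect_lt(fit$s_proxy, 0.01)
  }
  # seeded noiseless recovery property over random parameters
  set.seed(8)
  for (i in 1:10) {
    p1 <- runif(1, 0.5, 3); p2 <- runif(1, 0.1, 2)
    y <- p1 * (1 + t) / (1 + p2 * (1 + t))
    fit <- fit_amplification(list(times = t, rel_copies = y))
    expect_lt(abs(fit$p1 - p1) / p1, 0.005)
    expect_lt(abs(fit$p2 - p2) / p2, 0.005)
  }
})

test_that("quadratic dose hotspot: vertex, boundary decline, recovery", {
  expect_equal(gene_dose_hotspot(c(10, 20, 30), c(1, 2, 1))$E_max, 20)
  # monotone decline: boundary maximum at zero dose (no inverted-U)
  dec <- gene_dose_hotspot(seq(0, 40, 10), c(5, 4, 3, 2, 1))
  expect_equal(dec$E_max, 0)
  expect_equal(dec$location, "boundary")
  # flat: no signal
  expect_equal(gene_dose_hotspot(seq(0, 40, 10), rep(1, 5))$location, "flat")
  # noisy recovery of a true peak at 22 ug/ml within one 5 ug/ml grid step
  set.seed(99)
  doses <- seq(0, 40, by = 5)
  s_true <- 2 - 0.004 * (doses - 22)^2
  hits <- 0L; n_runs <- 100L
  for (i in seq_len(n_runs)) {
    s_obs <- s_true * (1 + rnorm(length(doses), 0, 0.10))
    h <- gene_dose_hotspot(doses, s_obs)
    if (abs(h$E_max - 22) <= 5) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.9)
})

test_that("SNP logistic fit: worked example, constants, noisy recovery", {
  fit <- fit_snp_selection(c(0, 3, 6), c(0.05, 0.5139, 0.9531))
  expect_equal(fit$p, 19, tolerance = 19 * 0.05)
  expect_equal(fit$s, 1, tolerance = 0.05)
  cfit <- fit_snp_selection(c(0, 2, 4), rep(0.3, 3))
  expect_equal(cfit$s, 0, tolerance = 1e-6)
  nofit <- fit_snp_selection(c(0, 2, 4), rep(0, 3))
  expect_false(nofit$converged)
  # binomial-noise recovery, scaled down (full size in the acceptance suite)
  snps <- synth_snp_trajectories(100, s = 0.8, p0 = 19, depth = 1000,
                                 times = c(0, 2, 4), seed = 5)
  s_hat <- vapply(split(snps, snps$locus),
                  function(d) fit_snp_selection(d$time, d$freq)$s, numeric(1))
  expect_lt(abs(median(s_hat, na.rm = TRUE) - 0.8) / 0.8, 0.1)
})

test_that("SNP frequency filter keeps only trajectories reaching 5%", {
  tab <- data.frame(position = rep(1:3, each = 3), time = rep(c(0, 2, 4), 3),
                    freq = c(0.01, 0.02, 0.03, 0.01, 0.06, 0.2, 0, 0, 0.049))
  out <- filter_snp_trajectories(tab)
  expect_equal(unique(out$position), 2L)
})

test_that("parallelism: closed-form projection and normalisation", {
  pr <- parallelism(rbind(u = rep(0.5, 7),
                          spike = c(1, 0, 0, 0, 0, 0, 0)))
  expect_equal(pr$P[pr$gene == "u"], 0)
  expect_equal(pr$lambda_star[pr$gene == "u"], 0.5)
  expect_equal(pr$P[pr$gene == "spike"], sqrt(6 / 7), tolerance = 1e-12)
  expect_equal(pr$lambda_star[pr$gene == "spike"], 1 / 7)
  # the maximising gene has coefficient exactly 1
  expect_equal(pr$p_coeff[pr$gene == "spike"], 1)
  expect_true(pr$parallel_flag[pr$gene == "spike"])
  # closed-form lambda* equals the numeric minimiser
  set.seed(17)
  for (i in 1:20) {
    f <- runif(7)
    num <- optimize(function(l) sqrt(sum((f - l)^2)), c(0, 2), tol = 1e-12)
    pr1 <- parallelism(matrix(f, nrow = 1))
    expect_lt(abs(pr1$lambda_star - num$minimum), 1e-6)
    expect_lt(abs(pr1$P - num$objective), 1e-8)
  }
  # degenerate cases
  expect_equal(nrow(parallelism(matrix(numeric(0), 0, 7))), 0L)
  allu <- parallelism(rbind(a = rep(0.2, 7), b = rep(0.4, 7)))
  expect_true(all(is.na(allu$p_coeff)))
})
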