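# Synthetic-data generator: serial-transfer plate-reader experiments with a
# copy-number-structured resistant class, longitudinal coverage tracks with
# amplifying regions, and SNP frequency trajectories — all with known ground
# truth, so estimator-recovery and end-to-end properties can be tested.

#' Configuration of a synthetic serial-transfer experiment
#'
#' Defaults mirror the standard treatment design: a linear erythromycin-style
#' gradient 0, 5, ..., 50 ug/ml, seven 24-h seasons with one transfer per
#' day, eight replicate wells per dose, readings every 20 min.
#'
#' Within a season densities follow the unit-carrying-capacity competition
#' model with a copy-number ladder: the susceptible strain S (one copy of the
#' resistance operon) mutates at rate \code{mu} into a 2-copy class, which
#' amplifies further into a 3-copy class; a cell with \eqn{c} copies
#' experiences the dose divided by \eqn{c}. Between seasons densities are
#' multiplied by \code{dilution} and the dose is reset.
#'
#' @param doses dose grid in ug/ml.
#' @param n_seasons number of 24-h seasons.
#' @param n_reps replicate wells per dose (max 8, plate rows A-H).
#' @param season_h season length in hours.
#' @param dt_h sampling interval in hours (default 1/3 = 20 min).
#' @param dilution fraction of the culture carried between seasons.
#' @param mu per-step amplification (mutation) rate in scaled time units.
#' @param mic_scale dose (ug/ml) corresponding to one model dose unit, i.e.
#'   the nominal ancestral MIC.
#' @param rate_h per-capita growth-rate scale in 1/h (sets how fast the
#'   logistic season unfolds in clock time).
#' @param inoculum initial susceptible density of season 1 (0 gives a
#'   cell-free control plate: blank + oscillation + noise only).
#' @param noise list: \code{blank_mean}, \code{blank_sd} (per-well OD blank),
#'   \code{cv} (multiplicative noise on the signal), \code{osc_amp} and
#'   \code{osc_wavelengths_h} (additive instrument oscillations; the 0.75-h
#'   component emulates the electro-mechanical plate-reader artefact, the
#'   10-h component the slow regulatory one).
#' @param gfp_model list: \code{per_copy} expression per operon copy and
#'   \code{repression} multiplier per extra copy (amplified repressors reduce
#'   expression per additional operon), or \code{NULL} for no fluorescence
#'   channel.
#' @param seed RNG seed.
#' @return An object of class \code{serial_transfer_config}.
#' @export
serial_transfer_config <- function(doses = seq(0, 50, by = 5),
                                   n_seasons = 7L, n_reps = 8L,
                                   season_h = 24, dt_h = 1 / 3,
                                   dilution = 0.01, mu = 1e-4,
                                   mic_scale = 30, rate_h = 0.5,
                                   inoculum = 0.01,
                                   noise = list(blank_mean = 0.05,
                                                blank_sd = 0.005,
                                                cv = 0.05,
                                                osc_amp = 0.01,
                                                osc_wavelengths_h = c(10, 0.75)),
                                   gfp_model = list(per_copy = 1000,
                                                    repression = 0.7),
                                   seed = 1L) {
  stopifnot(dilution > 0, dilution <= 1, mu >= 0, mic_scale > 0, rate_h > 0,
            n_reps >= 1L, n_reps <= 8L, inoculum >= 0)
  if (abs(season_h / dt_h - round(season_h / dt_h)) > 1e-9)
    stop("serial_transfer_config: dt_h must divide season_h")
  structure(list(doses = doses, n_seasons = as.integer(n_seasons),
                 n_reps = as.integer(n_reps), season_h = season_h,
                 dt_h = dt_h, dilution = dilution, mu = mu,
                 mic_scale = mic_scale, rate_h = rate_h, inoculum = inoculum,
                 noise = noise, gfp_model = gfp_model,
                 seed = as.integer(seed)),
            class = "serial_transfer_config")
}

# Deterministic within-season dynamics for one dose (model units a =
# dose/mic_scale). State: S (1 copy), R2, R3 (2 and 3 copies). Returns the
# deterministic class densities sampled at the within-season grid.
.season_dynamics <- function(a, y0, cfg) {
  times <- seq(0, cfg$season_h, by = cfg$dt_h)
  deriv <- function(t, y, parms) {
    N <- sum(y)
    gS <- 1 - a - N
    g2 <- 1 - a / 2 - N
    g3 <- 1 - a / 3 - N
    list(cfg$rate_h * c(
      y[1L] * gS - cfg$mu * y[1L],
      y[2L] * g2 + cfg$mu * y[1L] - cfg$mu * y[2L],
      y[3L] * g3 + cfg$mu * y[2L]))
  }
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-12)
  out <- unname(as.matrix(as.data.frame(sol)[, 2:4]))
  out[out < 0] <- 0
  out
}

# Deterministic multi-season trajectory for one dose: list with the
# concatenated time grid (hours from treatment start), per-class density
# matrix, and season-end summaries.
.dose_trajectory <- function(dose, cfg) {
  a <- dose / cfg$mic_scale
  y <- c(S = cfg$inoculum, R2 = 0, R3 = 0)
  nt <- round(cfg$season_h / cfg$dt_h)
  all_t <- numeric(0); all_y <- NULL
  season_end <- matrix(0, cfg$n_seasons, 3L,
                       dimnames = list(NULL, c("S", "R2", "R3")))
  for (s in seq_len(cfg$n_seasons)) {
    ys <- if (cfg$inoculum == 0) {
      matrix(0, nt + 1L, 3L)
    } else {
      .season_dynamics(a, y, cfg)
    }
    t_season <- seq(0, cfg$season_h, by = cfg$dt_h) + (s - 1L) * cfg$season_h
    keep <- if (s == 1L) seq_len(nt + 1L) else seq_len(nt) + 1L
    all_t <- c(all_t, t_season[keep])
    all_y <- rbind(all_y, ys[keep, , drop = FALSE])
    season_end[s, ] <- ys[nt + 1L, ]
    y <- ys[nt + 1L, ] * cfg$dilution
    names(y) <- c("S", "R2", "R3")
  }
  list(times = all_t, classes = all_y, season_end = season_end)
}

#' Simulate a serial-transfer plate-reader experiment
#'
#' Generates the full plate dataset for the configured dose gradient: an
#' OD600 trace (and optionally a GFP trace) per replicate well over all
#' seasons, a plate-layout table, and the generating ground truth. Replicate
#' wells share the deterministic dose trajectory and differ only in their
#' blank, multiplicative noise and the shared instrument oscillation:
#' \deqn{OD(t) = B_0 + N(t)(1 + \epsilon_t) + a_{osc} \sum_i \sin(2\pi t/\lambda_i).}
#' GFP is proportional to \eqn{\sum_c N_c \, c \, \beta^{c-1}} (copies times
#' per-copy expression times repression per extra copy).
#'
#' The ground truth records, per dose, the noiseless class densities at each
#' season end, the resistant fraction, the rate of adaptation computed on the
#' noiseless season-end density series, and the fastest-adapting dose (the
#' argmax of that noiseless rate).
#'
#' @param cfg a \code{\link{serial_transfer_config}}.
#' @return list with \code{plate} (data.frame: time_h, well, od600, gfp),
#'   \code{layout} (data.frame: well, strain, dose_ug_ml, replicate) and
#'   \code{ground_truth}.
#' @export
simulate_serial_transfer <- function(cfg) {
  stopifnot(inherits(cfg, "serial_transfer_config"))
  set.seed(cfg$seed)
  trajs <- lapply(cfg$doses, .dose_trajectory, cfg = cfg)
  t_grid <- trajs[[1L]]$times
  osc <- 0
  if (!is.null(cfg$noise$osc_amp) && cfg$noise$osc_amp > 0)
    osc <- cfg$noise$osc_amp *
      Reduce(`+`, lapply(cfg$noise$osc_wavelengths_h,
                         function(w) sin(2 * pi * t_grid / w)))
  gfp_weights <- NULL
  if (!is.null(cfg$gfp_model))
    gfp_weights <- cfg$gfp_model$per_copy * (1:3) *
      cfg$gfp_model$repression^(0:2)

  plate <- vector("list", length(cfg$doses) * cfg$n_reps)
  layout <- vector("list", length(plate))
  idx <- 0L
  for (j in seq_along(cfg$doses)) {
    N <- rowSums(trajs[[j]]$classes)
    gfp_signal <- if (is.null(gfp_weights)) NULL
                  else as.numeric(trajs[[j]]$classes %*% gfp_weights)
    for (rep_i in seq_len(cfg$n_reps)) {
      idx <- idx + 1L
      well <- paste0(LETTERS[rep_i], j)
      B0 <- stats::rnorm(1, cfg$noise$blank_mean, cfg$noise$blank_sd)
      eps <- stats::rnorm(length(t_grid), 0, cfg$noise$cv)
      od <- B0 + N * (1 + eps) + osc
      gfp <- NULL
      if (!is.null(gfp_signal)) {
        gB0 <- stats::rnorm(1, 10 * cfg$noise$blank_mean, cfg$noise$blank_sd)
        geps <- stats::rnorm(length(t_grid), 0, cfg$noise$cv)
        gfp <- gB0 + gfp_signal * (1 + geps) +
          100 * if (length(osc) > 1L) osc else 0
      }
      plate[[idx]] <- data.frame(time_h = t_grid, well = well, od600 = od,
                                 gfp = if (is.null(gfp)) NA_real_ else gfp)
      layout[[idx]] <- data.frame(well = well, strain = "synthetic",
                                  dose_ug_ml = cfg$doses[j],
                                  replicate = rep_i)
    }
  }

  season_t <- seq_len(cfg$n_seasons) * cfg$season_h
  per_dose <- lapply(seq_along(cfg$doses), function(j) {
    se <- trajs[[j]]$season_end
    N_end <- rowSums(se)
    data.frame(dose = cfg$doses[j], season = seq_len(cfg$n_seasons),
               time_h = season_t, S = se[, 1L], R2 = se[, 2L], R3 = se[, 3L],
               N = N_end,
               R_fraction = ifelse(N_end > 0, (se[, 2L] + se[, 3L]) / N_end, 0))
  })
  alpha_true <- vapply(per_dose, function(d) {
    if (nrow(d) < 3L) return(NA_real_)  # ROA needs >= 3 seasons
    roa_alpha(d$time_h, d$N)$alpha
  }, numeric(1))
  ground_truth <- list(
    season_end = do.call(rbind, per_dose),
    alpha_true = data.frame(dose = cfg$doses, alpha = alpha_true),
    fastest_dose = if (all(is.na(alpha_true))) NA_real_
                   else cfg$doses[which.max(alpha_true)],
    config = cfg)
  list(plate = do.call(rbind, plate), layout = do.call(rbind, layout),
       ground_truth = ground_truth)
}

#' Synthetic longitudinal coverage tracks with amplifying features
#'
#' Draws per-window depths negative-binomially with mean
#' \code{depth_mean * copies}, where \code{copies} is 1 genome-wide except
#' over the given features, which follow the supplied true copy-number
#' trajectories. An ancestral track (copies = 1 everywhere) is generated
#' alongside.
#'
#' @param genome_length genome length in bp.
#' @param window window size in bp (tiling, 0-based half-open).
#' @param features data.frame with columns \code{name}, \code{start},
#'   \code{end} (non-overlapping).
#' @param copies matrix of true copy numbers, rows = features, columns =
#'   times.
#' @param times sampling times in days.
#' @param depth_mean mean per-base depth for unamplified regions.
#' @param dispersion negative-binomial size parameter.
#' @param dose dose label attached to the tracks.
#' @param seed RNG seed.
#' @return list with \code{tracks} (one \code{\link{coverage_track}} per
#'   time), \code{ancestral}, and \code{truth} (the copies matrix).
#' @export
synth_coverage <- function(genome_length = 1e5, window = 1000, features,
                           copies, times = c(0, 2, 4), depth_mean = 200,
                           dispersion = 50, dose = NA_real_, seed = 1L) {
  stopifnot(depth_mean > 0, nrow(features) == nrow(copies),
            ncol(copies) == length(times),
            all(features$start >= 0), all(features$end <= genome_length))
  o <- order(features$start)
  if (nrow(features) > 1L &&
      any(features$start[o][-1L] < features$end[o][-nrow(features)]))
    stop("synth_coverage: features must not overlap")
  set.seed(seed)
  starts <- seq(0, genome_length - window, by = window)
  ends <- starts + window
  mids <- (starts + ends) / 2
  window_copies <- function(col) {
    cp <- rep(1, length(starts))
    for (f in seq_len(nrow(features))) {
      hit <- mids >= features$start[f] & mids < features$end[f]
      cp[hit] <- copies[f, col]
    }
    cp
  }
  draw <- function(cp, id, tt) {
    depth <- stats::rnbinom(length(starts), size = dispersion,
                            mu = depth_mean * cp)
    coverage_track("chr", starts, ends, depth, sample_id = id,
                   dose = dose, time = tt)
  }
  ancestral <- draw(rep(1, length(starts)), "ancestral", 0)
  tracks <- lapply(seq_along(times), function(k)
    draw(window_copies(k), paste0("t", times[k]), times[k]))
  list(tracks = tracks, ancestral = ancestral, truth = copies)
}

#' Synthetic SNP frequency trajectories under logistic selection
#'
#' True frequencies follow \eqn{f(t) = 1/(1 + p_0 e^{-s t})}; observed
#' frequencies are binomial draws at the stated read depth. Loci whose
#' observed frequency never reaches 0.05 are still emitted — the analysis
#' filter is expected to remove them.
#'
#' @param n_loci number of loci.
#' @param s true selection coefficient(s) per day, recycled over loci.
#' @param p0 initial-odds parameter (f(0) = 1/(1+p0)).
#' @param depth read depth (>= 20, the caller threshold for usable calls).
#' @param times sampling times in days.
#' @param dose dose label.
#' @param seed RNG seed.
#' @return data.frame with columns \code{locus}, \code{position},
#'   \code{gene}, \code{dose}, \code{time}, \code{freq}, \code{depth},
#'   \code{true_s}.
#' @export
synth_snp_trajectories <- function(n_loci, s, p0 = 19, depth = 200,
                                   times = c(0, 2, 4), dose = NA_real_,
                                   seed = 1L) {
  stopifnot(depth >= 20, n_loci >= 1)
  set.seed(seed)
  s <- rep_len(s, n_loci)
  rows <- lapply(seq_len(n_loci), function(i) {
    f_true <- 1 / (1 + p0 * exp(-s[i] * times))
    obs <- stats::rbinom(length(times), depth, f_true) / depth
    data.frame(locus = i, position = i * 1000L, gene = paste0("gene", i),
               dose = dose, time = times, freq = obs, depth = depth,
               true_s = s[i])
  })
  do.call(rbind, rows)
}
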