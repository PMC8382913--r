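# Selection proxies from longitudinal sequencing data: coverage-based
# relative copy numbers, saturating amplification fits and their maximum
# derivative ("selection proxy"), per-gene dose hotspots from quadratic
# regression, logistic SNP selection fits, and the between-treatment
# parallelism coefficient.

#' Windowed coverage track for one sequenced sample
#'
#' @param chrom chromosome name (recycled).
#' @param start,end window coordinates, 0-based half-open, tiling without
#'   overlap.
#' @param depth mean per-base depth per window (>= 0).
#' @param sample_id sample label.
#' @param dose antibiotic dose (ug/ml).
#' @param time sampling time in days (0 = first sequenced sample).
#' @return An object of class \code{coverage_track}.
#' @export
coverage_track <- function(chrom, start, end, depth, sample_id = "",
                           dose = NA_real_, time = NA_real_) {
  n <- length(depth)
  chrom <- rep_len(as.character(chrom), n)
  stopifnot(length(start) == n, length(end) == n, all(end > start),
            all(depth >= 0), all(is.finite(depth)))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    o <- order(start[i])
    s <- start[i][o]; e <- end[i][o]
    if (any(s[-1] < e[-length(e)]))
      stop("coverage_track: overlapping windows on ", ch)
  }
  structure(list(chrom = chrom, start = start, end = end, depth = depth,
                 sample_id = sample_id, dose = dose, time = time),
            class = "coverage_track")
}

# Summary statistic of per-base depth, weighted by window width.
.depth_stat <- function(depth, width, stat) {
  switch(stat,
         mean = sum(depth * width) / sum(width),
         median = {
           o <- order(depth)
           cw <- cumsum(width[o]) / sum(width)
           depth[o][which(cw >= 0.5)[1L]]
         },
         mode = {
           key <- round(depth, 6)
           tot <- tapply(width, key, sum)
           as.numeric(names(tot)[which.max(tot)])
         })
}

.feature_windows <- function(track, feature) {
  ov <- track$chrom == feature$chrom &
    track$end > feature$start & track$start < feature$end
  if (!any(ov)) stop("relative_copies: feature overlaps no window in sample '",
                     track$sample_id, "'")
  w <- pmin(track$end[ov], feature$end) - pmax(track$start[ov], feature$start)
  list(depth = track$depth[ov], width = w)
}

#' Relative copy number of a genomic feature over time
#'
#' For each sample, the feature's depth statistic is divided by the
#' genome-wide statistic of the same track ("relative coverage"), then by the
#' identical ratio in the ancestral sample, so the ancestral baseline is 1 by
#' construction. Values above 1 indicate gene amplification, below 1
#' deletion. The normalisation statistic is configurable (mean, median or
#' mode of per-base depth); note that with the default whole-genome mean a
#' large amplified region inflates the denominator, which is why swapping in
#' the median changes the numbers (but not, in practice, the conclusions).
#'
#' @param tracks list of \code{\link{coverage_track}}s for one treatment,
#'   ordered by time.
#' @param feature list with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open) and optionally \code{name}.
#' @param ancestral the ancestral (pre-treatment) \code{coverage_track}.
#' @param stat \code{"mean"} (default), \code{"median"} or \code{"mode"}.
#' @return An object of class \code{relative_copies}: list with
#'   \code{feature}, \code{dose}, \code{times}, \code{rel_copies}.
#' @export
relative_copies <- function(tracks, feature, ancestral,
                            stat = c("mean", "median", "mode")) {
  stat <- match.arg(stat)
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  ratio <- function(track) {
    gw <- .depth_stat(track$depth, track$end - track$start, stat)
    if (gw <= 0) stop("relative_copies: non-positive genome-wide depth")
    fw <- .feature_windows(track, feature)
    .depth_stat(fw$depth, fw$width, stat) / gw
  }
  anc <- ratio(ancestral)
  if (anc <= 0) stop("relative_copies: ancestral feature ratio is zero")
  rel <- vapply(tracks, ratio, numeric(1)) / anc
  structure(list(feature = feature,
                 dose = tracks[[1L]]$dose,
                 times = vapply(tracks, `[[`, numeric(1), "time"),
                 rel_copies = rel),
            class = "relative_copies")
}

#' Fit the saturating amplification model and its selection proxy
#'
#' Fits \deqn{F(t) = \frac{p_1 (1+t)}{1 + p_2 (1+t)}} (time \eqn{t} in days,
#' \eqn{p_1, p_2 \ge 0}) to relative copy numbers by least squares, then
#' evaluates the maximum derivative of the fitted curve over the observed
#' span,
#' \deqn{F'(t) = \frac{p_1}{(1 + p_2(1+t))^2},}
#' which for \eqn{p_2 > 0} is attained at the earliest observed time. This
#' maximum derivative is the "selection proxy" for the amplification: the
#' fastest rate at which copies per genome were gained.
#'
#' @param rc a \code{\link{relative_copies}} object, or any list with
#'   \code{times} (days) and \code{rel_copies} of length >= 3.
#' @return An object of class \code{amplification_fit}: \code{p1}, \code{p2},
#'   \code{s_proxy} (per day; \code{NA} when the fit failed), \code{rss},
#'   \code{converged}.
#' @export
fit_amplification <- function(rc) {
  t <- rc$times; y <- rc$rel_copies
  stopifnot(length(t) >= 3L, length(t) == length(y))
  if (!all(is.finite(y)))
    return(structure(list(p1 = NA_real_, p2 = NA_real_, s_proxy = NA_real_,
                          rss = NA_real_, converged = FALSE),
                     class = "amplification_fit"))
  # p1 enters linearly: for fixed p2 the least-squares p1 has a closed form,
  # so the fit reduces to a 1-D minimisation over p2 >= 0 (log scale). This
  # remains well-behaved in the constant-F limit p2 -> infinity.
  p1_given <- function(p2) {
    x <- (1 + t) / (1 + p2 * (1 + t))
    max(sum(x * y) / sum(x * x), 0)
  }
  rss_p2 <- function(p2) {
    x <- (1 + t) / (1 + p2 * (1 + t))
    sum((y - p1_given(p2) * x)^2)
  }
  lu <- seq(-20, 20, length.out = 200L)
  r_grid <- vapply(lu, function(u) rss_p2(exp(u)), numeric(1))
  r_zero <- rss_p2(0)
  i <- which.min(r_grid)
  if (r_zero <= r_grid[i]) {
    p2 <- 0
  } else {
    lo <- lu[max(i - 1L, 1L)]; hi <- lu[min(i + 1L, length(lu))]
    p2 <- exp(stats::optimize(function(u) rss_p2(exp(u)), c(lo, hi),
                              tol = 1e-12)$minimum)
  }
  p1 <- p1_given(p2)
  # F'(t) = p1/(1 + p2(1+t))^2 decreases in t for p2 > 0: the maximum over
  # the observed span is attained at the earliest time
  s_proxy <- max(p1 / (1 + p2 * (1 + t))^2)
  structure(list(p1 = p1, p2 = p2, s_proxy = s_proxy, rss = rss_p2(p2),
                 converged = TRUE),
            class = "amplification_fit")
}

#' @export
print.amplification_fit <- function(x, ...) {
  if (!x$converged) cat("amplification fit: did not converge\n")
  else cat(sprintf("amplification fit: p1 = %.4g, p2 = %.4g, selection proxy = %.4g /day\n",
                   x$p1, x$p2, x$s_proxy))
  invisible(x)
}

#' Dose at which selection for a gene's amplification is maximal
#'
#' Given selection proxies \eqn{s(E)} at doses \eqn{E} on a grid, fits an
#' ordinary least-squares quadratic \eqn{s(E) = aE^2 + bE + c} and predicts
#' the dose of maximal selection: the interior vertex \eqn{-b/2a} (clamped to
#' the dose range) when the parabola opens downward, otherwise the boundary
#' dose with the larger predicted value. A gene is retained for genome-wide
#' summaries when its predicted maximum exceeds \code{sd_mult} times the
#' residual standard deviation of the quadratic fit.
#'
#' @param doses dose grid (>= 4 doses with available proxies).
#' @param s_values selection proxies at those doses.
#' @param sd_mult screening multiplier (default 3).
#' @return list with \code{E_max}, \code{s_max_pred},
#'   \code{log10_s_max}, \code{keep}, \code{location}
#'   (\code{"interior"}, \code{"boundary"} or \code{"flat"}).
#' @export
gene_dose_hotspot <- function(doses, s_values, sd_mult = 3) {
  ok <- is.finite(s_values)
  doses <- doses[ok]; s_values <- s_values[ok]
  stopifnot(length(doses) >= 3L)
  if (diff(range(s_values)) < 1e-12 * max(abs(s_values), 1))
    return(list(E_max = NA_real_, s_max_pred = s_values[1L],
                log10_s_max = log10(max(s_values[1L], .Machine$double.xmin)),
                keep = FALSE, location = "flat"))
  fit <- stats::lm(s_values ~ doses + I(doses^2))
  co <- stats::coef(fit)
  a <- co[[3L]]; b <- co[[2L]]
  pred <- function(E) co[[1L]] + b * E + a * E^2
  if (is.finite(a) && a < 0) {
    E_max <- min(max(-b / (2 * a), min(doses)), max(doses))
    location <- if (E_max > min(doses) && E_max < max(doses)) "interior"
                else "boundary"
  } else {
    ends <- range(doses)
    E_max <- ends[which.max(pred(ends))]
    location <- "boundary"
  }
  s_max_pred <- pred(E_max)
  resid_sd <- sqrt(sum(stats::resid(fit)^2) /
                     max(stats::df.residual(fit), 1L))
  list(E_max = E_max, s_max_pred = s_max_pred,
       log10_s_max = log10(max(s_max_pred, .Machine$double.xmin)),
       keep = is.finite(s_max_pred) && s_max_pred > sd_mult * resid_sd,
       location = location)
}

#' Logistic selection fit for a SNP frequency trajectory
#'
#' Fits \deqn{f(t) = \frac{1}{1 + p e^{-s t}}} to longitudinal SNP
#' frequencies by nonlinear least squares (\eqn{p > 0}; \eqn{s} free in sign,
#' negative for declining variants). The fitted \eqn{s} (per day) is
#' reported as the numerical proxy for the strength of selection on the SNP.
#' Starting values: \eqn{p = (1-f_0)/\max(f_0, 10^{-3})} and \eqn{s} from the
#' slope of a log-odds regression.
#'
#' @param times sampling times in days (>= 3).
#' @param freq observed frequencies in [0, 1].
#' @return An object of class \code{snp_selection_fit}: \code{p}, \code{s},
#'   \code{rss}, \code{converged} (\code{FALSE} with \code{NA} estimates for
#'   an all-zero trajectory or non-convergence).
#' @export
fit_snp_selection <- function(times, freq) {
  stopifnot(length(times) >= 3L, length(times) == length(freq),
            all(freq >= 0), all(freq <= 1))
  no_fit <- structure(list(p = NA_real_, s = NA_real_, rss = NA_real_,
                           converged = FALSE),
                      class = "snp_selection_fit")
  if (all(freq == 0)) return(no_fit)
  f0 <- freq[1L]
  p0 <- (1 - f0) / max(f0, 1e-3)
  fc <- pmin(pmax(freq, 1e-4), 1 - 1e-4)
  s0 <- unname(stats::coef(stats::lm(stats::qlogis(fc) ~ times))[2L])
  if (!is.finite(s0)) s0 <- 0
  for (st in list(list(p = max(p0, 1e-6), s = s0),
                  list(p = max(p0, 1e-6), s = 0),
                  list(p = 1, s = s0))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(freq ~ 1 / (1 + p * exp(-s * times)), start = st,
                        lower = c(1e-9, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      return(structure(list(p = unname(co["p"]), s = unname(co["s"]),
                            rss = sum(stats::resid(fit)^2), converged = TRUE),
                       class = "snp_selection_fit"))
    }
  }
  no_fit
}

#' @export
print.snp_selection_fit <- function(x, ...) {
  if (!x$converged) cat("SNP selection fit: no fit\n")
  else cat(sprintf("SNP selection fit: s = %.4g /day, p = %.4g\n", x$s, x$p))
  invisible(x)
}

#' Filter SNP trajectories by the common-frequency threshold
#'
#' Retains only loci whose frequency reaches at least \code{min_freq} at some
#' timepoint (default 0.05, the threshold for a "sufficiently common" SNP).
#'
#' @param snps data.frame with at least columns \code{position} (or
#'   \code{locus}), \code{time}, \code{freq}.
#' @param min_freq frequency threshold.
#' @param id_col column identifying a trajectory.
#' @return the filtered data.frame.
#' @export
filter_snp_trajectories <- function(snps, min_freq = 0.05,
                                    id_col = intersect(c("position", "locus"),
                                                       names(snps))[1L]) {
  stopifnot(!is.na(id_col), "freq" %in% names(snps))
  keep_ids <- unique(snps[[id_col]][ave(snps$freq, snps[[id_col]],
                                        FUN = max) >= min_freq])
  snps[snps[[id_col]] %in% keep_ids, , drop = FALSE]
}

#' Between-treatment parallelism coefficient
#'
#' For each gene \eqn{g} with SNP-frequency vector
#' \eqn{f = (f_1, \ldots, f_N)} across the \eqn{N} assayed dosages, the
#' statistic \deqn{P(g) = \min_{\lambda > 0} \lVert f - \lambda (1,\ldots,1)
#' \rVert_2} is the Euclidean distance of \eqn{f} from the uniform ray,
#' solved in closed form by projecting onto the ray
#' (\eqn{\lambda^* = \max(\bar f, 0)}). The coefficient is normalised by the
#' largest distance in the gene set, \eqn{p(g) = P(g)/P^*}, and
#' \eqn{p(g) > 0.7} is flagged. Note the apparent tension in this definition:
#' \eqn{P} measures distance \emph{from} the uniform ray, so a large
#' coefficient marks across-dose variability in SNP frequency, yet the
#' threshold is conventionally used to highlight "parallel" evolution. It is
#' implemented here exactly as defined, without inversion.
#'
#' @param freqs matrix of frequencies (rows = genes, columns = doses), or a
#'   named list of equal-length vectors.
#' @param threshold flagging threshold on \eqn{p(g)}.
#' @return data.frame with columns \code{gene}, \code{lambda_star}, \code{P},
#'   \code{p_coeff}, \code{parallel_flag}; zero rows for an empty gene set.
#'   When every vector is uniform (\eqn{P^* = 0}) the coefficient is
#'   \code{NA}.
#' @export
parallelism <- function(freqs, threshold = 0.7) {
  if (is.list(freqs) && !is.data.frame(freqs) && !is.matrix(freqs))
    freqs <- do.call(rbind, freqs)
  freqs <- as.matrix(freqs)
  if (nrow(freqs) == 0L)
    return(data.frame(gene = character(), lambda_star = numeric(),
                      P = numeric(), p_coeff = numeric(),
                      parallel_flag = logical()))
  genes <- rownames(freqs)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(freqs)))
  lambda_star <- pmax(rowMeans(freqs), 0)
  P <- sqrt(rowSums((freqs - lambda_star)^2))
  P_star <- max(P)
  p_coeff <- if (P_star > 0) P / P_star else rep(NA_real_, length(P))
  data.frame(gene = genes, lambda_star = lambda_star, P = P,
             p_coeff = p_coeff,
             parallel_flag = !is.na(p_coeff) & p_coeff > threshold,
             row.names = NULL)
}
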