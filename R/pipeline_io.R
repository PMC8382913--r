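# Readers/writers for plate-reader tables, coverage tracks, feature
# intervals and SNP tables, plus the end-to-end orchestration that strings
# the analysis together: dose-responses -> MIC/EAD -> rates of adaptation ->
# amplification selection proxies -> SNP selection and parallelism.

.read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' Read a plate-reader table and layout into growth curves
#'
#' The plate table is long-format (columns \code{time_h}, \code{well},
#' \code{od600}, optional \code{gfp}); the layout maps wells to strain, dose
#' and replicate. Traces are split into one \code{\link{growth_curve}} per
#' well and 24-h season, with season-local times (a reading at exactly a
#' season boundary closes the earlier season).
#'
#' @param plate plate table (data.frame) or path to a TSV/CSV file.
#' @param layout layout table (columns \code{well}, \code{strain},
#'   \code{dose_ug_ml}, \code{replicate}) or path.
#' @param season_h season length in hours.
#' @return list of \code{growth_curve} objects; attributes \code{layout} and
#'   \code{season_h}.
#' @export
read_plate <- function(plate, layout, season_h = 24) {
  if (is.character(plate)) plate <- .read_table_auto(plate)
  if (is.character(layout)) layout <- .read_table_auto(layout)
  need <- c("time_h", "well", "od600")
  if (!all(need %in% names(plate)))
    stop("read_plate: plate table must have columns ",
         paste(need, collapse = ", "))
  if (!all(c("well", "dose_ug_ml", "replicate") %in% names(layout)))
    stop("read_plate: layout must have columns well, dose_ug_ml, replicate")
  unknown <- setdiff(unique(plate$well), layout$well)
  if (length(unknown) > 0L)
    stop("read_plate: well(s) not in layout: ", paste(unknown, collapse = ", "))
  plate$season <- pmax(ceiling(plate$time_h / season_h), 1L)
  has_gfp <- "gfp" %in% names(plate) && !all(is.na(plate$gfp))
  curves <- list()
  for (w in unique(plate$well)) {
    lay <- layout[layout$well == w, , drop = FALSE][1L, ]
    pw <- plate[plate$well == w, , drop = FALSE]
    for (s in sort(unique(pw$season))) {
      ps <- pw[pw$season == s, , drop = FALSE]
      ps <- ps[order(ps$time_h), , drop = FALSE]
      if (anyDuplicated(ps$time_h))
        stop("read_plate: non-monotone/duplicated times in well ", w,
             " season ", s)
      curves[[length(curves) + 1L]] <- growth_curve(
        times = ps$time_h - (s - 1L) * season_h, od = ps$od600,
        gfp = if (has_gfp) ps$gfp else NULL,
        well_id = w, season = s, dose = lay$dose_ug_ml)
    }
  }
  attr(curves, "layout") <- layout
  attr(curves, "season_h") <- season_h
  curves
}

#' Write plate and layout tables as TSV
#'
#' @param plate,layout data.frames as produced by
#'   \code{\link{simulate_serial_transfer}}.
#' @param plate_path,layout_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_plate <- function(plate, layout, plate_path, layout_path) {
  utils::write.table(plate, plate_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(layout, layout_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(plate_path, layout_path))
}

#' Read a bedGraph coverage file into a coverage track
#'
#' Coordinates are normalised to 0-based half-open internally.
#'
#' @param path bedGraph (or 4-column chrom/start/end/depth TSV) file.
#' @param sample_id,dose,time metadata attached to the track.
#' @return a \code{\link{coverage_track}}.
#' @export
read_coverage <- function(path, sample_id = basename(path),
                          dose = NA_real_, time = NA_real_) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- as.data.frame(gr)
  coverage_track(chrom = as.character(df$seqnames),
                 start = df$start - 1L,  # back to 0-based half-open
                 end = df$end, depth = df$score,
                 sample_id = sample_id, dose = dose, time = time)
}

#' Read a BED file of feature intervals
#'
#' @param path BED file (0-based half-open).
#' @param strict validate that intervals are plausible 0-based half-open:
#'   records with \code{start >= end} (the signature of 1-based inclusive
#'   coordinates for short features) are rejected.
#' @return data.frame with columns \code{name}, \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @export
read_features <- function(path, strict = TRUE) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (strict && any(raw[[2L]] >= raw[[3L]]))
    stop("read_features: start >= end; input looks 1-based inclusive, ",
         "expected 0-based half-open BED")
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  data.frame(name = if ("name" %in% names(df)) df$name
                    else paste0("feature", seq_len(nrow(df))),
             chrom = as.character(df$seqnames),
             start = df$start - 1L, end = df$end,
             stringsAsFactors = FALSE)
}

#' Read a SNP frequency table
#'
#' @param path TSV with columns \code{chrom}, \code{position}, \code{gene},
#'   \code{dose}, \code{time}, \code{freq}, \code{depth}.
#' @return validated data.frame.
#' @export
read_snps <- function(path) {
  df <- .read_table_auto(path)
  need <- c("position", "gene", "dose", "time", "freq", "depth")
  if (!all(need %in% names(df)))
    stop("read_snps: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$freq < 0 | df$freq > 1))
    stop("read_snps: frequencies outside [0, 1]")
  df
}

#' Extract SNP allele frequencies from a VCF
#'
#' Frequencies are taken from the per-sample \code{AD} field
#' (alt / (ref + alt)) when present, otherwise from \code{AF}.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @return data.frame with columns \code{chrom}, \code{position},
#'   \code{sample}, \code{freq}.
#' @export
read_snps_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fmt <- if (nrow(vcf@gt) > 0L) colnames(vcf@gt)[-1L] else character()
  out <- NULL
  ad <- tryCatch(vcfR::extract.gt(vcf, "AD"), error = function(e) NULL)
  if (!is.null(ad)) {
    for (smp in colnames(ad)) {
      parts <- strsplit(ad[, smp], ",", fixed = TRUE)
      freq <- vapply(parts, function(p) {
        v <- suppressWarnings(as.numeric(p))
        if (length(v) < 2L || any(is.na(v)) || sum(v) == 0) return(NA_real_)
        sum(v[-1L]) / sum(v)
      }, numeric(1))
      out <- rbind(out, data.frame(chrom = fix[, "CHROM"],
                                   position = as.integer(fix[, "POS"]),
                                   sample = smp, freq = freq,
                                   stringsAsFactors = FALSE))
    }
  } else {
    af <- tryCatch(vcfR::extract.gt(vcf, "AF", as.numeric = TRUE),
                   error = function(e) NULL)
    if (is.null(af)) stop("read_snps_vcf: neither AD nor AF fields found")
    for (smp in colnames(af))
      out <- rbind(out, data.frame(chrom = fix[, "CHROM"],
                                   position = as.integer(fix[, "POS"]),
                                   sample = smp, freq = af[, smp],
                                   stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Length of a genomic interval in kb
#'
#' Convenience for reporting amplified-region sizes the way genome figures
#' quote them (end minus start of a 0-based half-open interval, divided by
#' 1000).
#'
#' @param start,end interval coordinates in bp (0-based half-open), or a
#'   single feature row with \code{start}/\code{end}.
#' @return length in kb.
#' @export
interval_length_kb <- function(start, end = NULL) {
  if (is.null(end)) { end <- start$end; start <- start$start }
  (end - start) / 1000
}

#' End-to-end analysis of a serial-transfer experiment
#'
#' Runs the full phenotype pipeline on plate data: per-well blank estimation
#' from the season-1 AICc model fit, a season-1 Hill dose-response with MIC
#' (IC99), per-season EAD against the season-1 (ancestral) dose-response,
#' per-well rates of adaptation on blank-corrected season-end densities, and
#' the dose-profile classification of the ROA. When coverage tracks and/or
#' SNP tables are supplied, amplification selection proxies with per-gene
#' dose hotspots, SNP selection fits and the parallelism table are added.
#'
#' @param plate,layout plate-reader table and layout (data.frames or paths).
#' @param season_h season length in hours.
#' @param roa_metric \code{"alpha"} (ROA of season-end density) or
#'   \code{"rauc"} (ROA of the per-season reciprocal-AUC growth rate).
#' @param coverage optional named list, one element per dose: list with
#'   \code{tracks} (list of \code{coverage_track} over time) and
#'   \code{ancestral}.
#' @param features optional data.frame of feature intervals (\code{name},
#'   \code{chrom}, \code{start}, \code{end}) for amplification analysis.
#' @param snps optional SNP table (columns as in \code{\link{read_snps}}).
#' @param norm_stat coverage normalisation statistic.
#' @param out_dir optional directory: tidy TSV tables and a JSON summary are
#'   written there.
#' @return list with elements \code{hill}, \code{mic}, \code{ead},
#'   \code{roa}, \code{inverted_u}, and (when inputs given)
#'   \code{amplification}, \code{hotspots}, \code{snp_selection},
#'   \code{parallelism}, plus \code{summary} (JSON-ready).
#' @export
run_full_analysis <- function(plate, layout, season_h = 24,
                              roa_metric = c("alpha", "rauc"),
                              coverage = NULL, features = NULL, snps = NULL,
                              norm_stat = "mean", out_dir = NULL) {
  roa_metric <- match.arg(roa_metric)
  curves <- read_plate(plate, layout, season_h = season_h)
  lay <- attr(curves, "layout")
  wells <- unique(vapply(curves, `[[`, character(1), "well_id"))
  seasons <- sort(unique(vapply(curves, `[[`, integer(1), "season")))
  n_seasons <- length(seasons)

  # per-well blank from the season-1 model fit, then season-end densities
  per_well <- lapply(wells, function(w) {
    cw <- Filter(function(cv) cv$well_id == w, curves)
    s1 <- Filter(function(cv) cv$season == 1L, cw)[[1L]]
    fit1 <- tryCatch(suppressWarnings(fit_growth_models(s1)),
                     error = function(e) NULL)
    B0 <- if (is.null(fit1)) min(s1$od) else fit1$B0
    end_od <- vapply(seasons, function(s) {
      cs <- Filter(function(cv) cv$season == s, cw)[[1L]]
      cs$od[length(cs$od)] - B0
    }, numeric(1))
    rauc <- vapply(seasons, function(s) {
      cs <- Filter(function(cv) cv$season == s, cw)[[1L]]
      tryCatch(roa_auc(list(times = cs$times, od = cs$od - B0)),
               error = function(e) NA_real_)
    }, numeric(1))
    list(well = w, dose = cw[[1L]]$dose, B0 = B0, end_od = end_od,
         rauc = rauc)
  })
  doses <- sort(unique(lay$dose_ug_ml))
  well_dose <- vapply(per_well, `[[`, numeric(1), "dose")

  # season-1 dose-response (24-h read), Hill fit, MIC; replicate x dose
  dens_mat <- sapply(doses, function(d) {
    vapply(which(well_dose == d), function(i) per_well[[i]]$end_od[1L],
           numeric(1))
  })
  if (is.null(dim(dens_mat))) dens_mat <- matrix(dens_mat, nrow = 1L)
  dr1 <- dose_response(doses, dens_mat, season = 1L)
  hill <- tryCatch(fit_hill(dr1, bootstrap_n = 200L), error = function(e) NULL)

  # EAD of each well-season against the ancestral (season 1) dose-response
  ead_tab <- NULL
  if (!is.null(hill)) {
    ead_tab <- do.call(rbind, lapply(per_well, function(pw) {
      data.frame(well = pw$well, dose = pw$dose, season = seasons,
                 ead = ead(hill, pw$end_od))
    }))
  }

  # rate of adaptation per well
  season_t <- seasons * season_h
  roa_tab <- do.call(rbind, lapply(per_well, function(pw) {
    series <- if (roa_metric == "alpha") pw$end_od else pw$rauc
    a <- tryCatch(roa_alpha(season_t, series)$alpha, error = function(e) NA_real_)
    data.frame(well = pw$well, dose = pw$dose, metric = roa_metric, value = a)
  }))
  roa_mat <- do.call(cbind, lapply(doses, function(d) {
    roa_tab$value[roa_tab$dose == d]
  }))
  colnames(roa_mat) <- doses
  iu <- tryCatch(inverted_u_summary(doses, roa_mat), error = function(e)
    list(classification = "undetermined", argmax_dose = NA_real_,
         mean_roa = colMeans(roa_mat), smoothed = NULL, p_vs_zero = NULL))
  if (anyNA(iu$mean_roa)) {
    iu$classification <- "undetermined"
    iu$argmax_dose <- NA_real_
  }

  out <- list(hill = hill,
              mic = if (is.null(hill)) NA_real_ else hill$mic,
              ead = ead_tab, roa = roa_tab, inverted_u = iu)

  if (!is.null(coverage) && !is.null(features)) {
    amp <- do.call(rbind, lapply(names(coverage), function(dn) {
      cv <- coverage[[dn]]
      do.call(rbind, lapply(seq_len(nrow(features)), function(f) {
        rc <- relative_copies(cv$tracks, as.list(features[f, ]),
                              cv$ancestral, stat = norm_stat)
        fit <- fit_amplification(rc)
        data.frame(gene = features$name[f], dose = as.numeric(dn),
                   p1 = fit$p1, p2 = fit$p2, s_proxy = fit$s_proxy)
      }))
    }))
    hot <- do.call(rbind, lapply(split(amp, amp$gene), function(g) {
      if (sum(is.finite(g$s_proxy)) < 4L) return(NULL)
      h <- gene_dose_hotspot(g$dose, g$s_proxy)
      data.frame(gene = g$gene[1L], E_max = h$E_max,
                 s_max_pred = h$s_max_pred, keep = h$keep,
                 location = h$location)
    }))
    out$amplification <- amp
    out$hotspots <- hot
  }

  if (!is.null(snps)) {
    snps_f <- if (nrow(snps) > 0L) filter_snp_trajectories(snps) else snps
    if (nrow(snps_f) > 0L) {
      sel <- do.call(rbind, lapply(split(snps_f,
                                         list(snps_f$position, snps_f$dose),
                                         drop = TRUE), function(tr) {
        tr <- tr[order(tr$time), ]
        fit <- fit_snp_selection(tr$time, tr$freq)
        data.frame(position = tr$position[1L], gene = tr$gene[1L],
                   dose = tr$dose[1L], p = fit$p, s = fit$s,
                   converged = fit$converged)
      }))
      rownames(sel) <- NULL
      t_last <- max(snps_f$time)
      fm <- tapply(snps_f$freq[snps_f$time == t_last],
                   list(snps_f$gene[snps_f$time == t_last],
                        snps_f$dose[snps_f$time == t_last]), mean)
      fm[is.na(fm)] <- 0
      out$snp_selection <- sel
      out$parallelism <- parallelism(fm)
    } else {
      out$snp_selection <- NULL
      out$parallelism <- parallelism(matrix(numeric(0), nrow = 0, ncol = 0))
    }
  }

  out$summary <- list(
    mic_ic99 = out$mic,
    roa_metric = roa_metric,
    roa_classification = iu$classification,
    roa_argmax_dose = iu$argmax_dose,
    n_wells = length(wells), n_seasons = n_seasons)
  if (!is.null(out$hotspots))
    out$summary$hotspots <- stats::setNames(as.list(out$hotspots$E_max),
                                            out$hotspots$gene)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(roa_tab, file.path(out_dir, "roa.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(ead_tab))
      utils::write.table(ead_tab, file.path(out_dir, "ead.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(out$amplification))
      utils::write.table(out$amplification,
                         file.path(out_dir, "amplification.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(out$parallelism) && nrow(out$parallelism) > 0L)
      utils::write.table(out$parallelism,
                         file.path(out_dir, "parallelism.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
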