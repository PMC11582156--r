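#' Configuration of the reliability experiments
#'
#' @param snr_levels SNR levels of the sweep (default 25, 50, 75, 100,
#'   150, 200 — every level reported for the bone phantoms).
#' @param power_subsets Character subset selectors ("3SP", "2SP").
#' @param init_modes Initialization modes ("ground_truth", "fixed").
#' @param n_realizations Noise realizations per condition (default 1,
#'   matching single-realization phantom figures; statistical checks use
#'   more).
#' @param report_threshold_snr Minimum SNR at which exchange rates are
#'   reported (default 75; below it unstable fits dominate).
#' @param voxels_per_chip Side length of the centered square block of
#'   voxels fitted per chip (NULL = all voxels).  Sub-sampling keeps sweep
#'   runtimes at desk scale without changing per-chip statistics.
#' @param seed Root RNG seed; per-condition seeds are derived from it.
#' @return An object of class \code{experiment_config}.
#' @export
experiment_config <- function(snr_levels = c(25, 50, 75, 100, 150, 200),
                              power_subsets = c("3SP", "2SP"),
                              init_modes = c("ground_truth", "fixed"),
                              n_realizations = 1,
                              report_threshold_snr = 75,
                              voxels_per_chip = NULL,
                              seed = 1L) {
  if (any(diff(snr_levels) <= 0) || any(snr_levels <= 0))
    stop("snr_levels must be positive and ascending")
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  structure(list(snr_levels = snr_levels, power_subsets = power_subsets,
                 init_modes = init_modes,
                 n_realizations = as.integer(n_realizations),
                 report_threshold_snr = report_threshold_snr,
                 voxels_per_chip = voxels_per_chip,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# deterministic per-stage seed derived from a root seed and labels
derive_seed <- function(root, ...) {
  h <- as.integer(root) %% 1000003L
  for (s in c(...)) {
    for (ch in utf8ToInt(as.character(s)))
      h <- (h * 31L + ch) %% 1000003L
  }
  h + 1L
}

# centered k x k block of voxel indices within each chip
chip_voxel_block <- function(images, k = NULL) {
  chip <- images$truth_maps$chip
  ids <- sort(unique(as.integer(chip)))
  out <- NULL
  for (ci in ids) {
    idx <- which(chip == ci, arr.ind = TRUE)
    if (!is.null(k)) {
      rs <- sort(unique(idx[, 1])); cs <- sort(unique(idx[, 2]))
      mid <- function(v, k) {
        lo <- floor((length(v) - k) / 2) + 1
        v[lo:(lo + k - 1)]
      }
      idx <- as.matrix(expand.grid(row = mid(rs, k), col = mid(cs, k)))
    }
    out <- rbind(out, idx)
  }
  out
}

#' ROI statistics of fitted parameter maps, per chip
#'
#' Mean and SD over retained voxels of each chip, for each fitted
#' parameter; unstable voxels (see [flag_unstable()]) are dropped when
#' \code{apply_exclusion = TRUE}.
#'
#' @param maps A \code{parameter_maps} object.
#' @param chip_mask Integer matrix labeling chips (default: the truth
#'   chip map carried by \code{maps}).
#' @param apply_exclusion Drop unstable voxels before averaging.
#' @return data.frame: chip, parameter, mean, sd, n_voxels, n_excluded.
#' @export
roi_stats <- function(maps, chip_mask = NULL, apply_exclusion = TRUE) {
  stopifnot(inherits(maps, "parameter_maps"))
  if (is.null(chip_mask)) chip_mask <- maps$truth_maps$chip
  if (is.null(chip_mask) || !any(!is.na(chip_mask)))
    stop("chip mask is empty")
  excl <- maps$exclusion_mask
  params <- c("m0a", "mmf", "k_ab", "k_ba", "t1_obs", "t2a")
  rows <- list()
  for (ci in sort(unique(stats::na.omit(as.integer(chip_mask))))) {
    in_chip <- !is.na(chip_mask) & chip_mask == ci
    for (pn in params) {
      vals <- maps$maps[[pn]][in_chip]
      fitted <- !is.na(vals)
      drop <- if (apply_exclusion) excl[in_chip] & fitted else
        rep(FALSE, sum(in_chip))
      keep <- fitted & !drop
      if (!any(keep))
        stop(sprintf("all voxels of chip %d excluded for %s", ci, pn))
      rows[[length(rows) + 1L]] <- data.frame(
        chip = ci, parameter = pn,
        mean = mean(vals[keep]), sd = stats::sd(vals[keep]),
        n_voxels = sum(keep), n_excluded = sum(drop))
    }
  }
  do.call(rbind, rows)
}

#' Error metrics of fitted maps against ground truth, per chip
#'
#' @inheritParams roi_stats
#' @return data.frame: chip, parameter, truth, bias, rmse, rel_bias,
#'   rel_rmse, n_voxels, n_excluded.
#' @export
error_metrics <- function(maps, apply_exclusion = TRUE) {
  stopifnot(inherits(maps, "parameter_maps"))
  tm <- maps$truth_maps
  if (is.null(tm)) stop("error metrics require truth maps")
  excl <- maps$exclusion_mask
  params <- c("mmf", "k_ab", "k_ba", "t1_obs", "t2a")
  rows <- list()
  for (ci in sort(unique(stats::na.omit(as.integer(tm$chip))))) {
    in_chip <- !is.na(tm$chip) & tm$chip == ci
    for (pn in params) {
      vals <- maps$maps[[pn]][in_chip]
      truth <- tm[[pn]][in_chip]
      keep <- !is.na(vals)
      if (apply_exclusion) keep <- keep & !excl[in_chip]
      if (!any(keep)) next
      err <- vals[keep] - truth[keep]
      tv <- truth[keep][1]
      rows[[length(rows) + 1L]] <- data.frame(
        chip = ci, parameter = pn, truth = tv,
        bias = mean(err), rmse = sqrt(mean(err^2)),
        rel_bias = mean(err) / tv, rel_rmse = sqrt(mean(err^2)) / tv,
        n_voxels = sum(keep),
        n_excluded = sum(!keep & !is.na(vals)))
    }
  }
  do.call(rbind, rows)
}

#' SNR sweep over data-point and initial-point conditions
#'
#' For each (SNR, power subset, init mode, realization): add calibrated
#' Rician noise to the noiseless phantom, fit every selected voxel, and
#' tabulate per-chip ROI statistics and ground-truth error metrics.
#' Exchange-rate rows below \code{report_threshold_snr} are flagged
#' \code{reported = FALSE} (unstable fits dominate there), mirroring the
#' reporting convention for bone phantoms.
#'
#' @param cfg An [experiment_config()].
#' @param spec A [phantom_spec()] (default 20-chip bone grid).
#' @param keep_maps Also return the fitted \code{parameter_maps} objects.
#' @return List: \code{stats} (long data.frame), \code{errors}, and
#'   optionally \code{maps}.
#' @export
run_snr_sweep <- function(cfg = experiment_config(), spec = phantom_spec(),
                          keep_maps = FALSE) {
  base <- generate_phantom(spec)
  voxels <- chip_voxel_block(base, cfg$voxels_per_chip)
  stats_rows <- list(); err_rows <- list(); all_maps <- list()
  for (snr in cfg$snr_levels) for (ps in cfg$power_subsets)
    for (im in cfg$init_modes) for (rz in seq_len(cfg$n_realizations)) {
      sd_seed <- derive_seed(cfg$seed, "snr_sweep", snr, ps, im, rz)
      noisy <- add_rician_noise(base, snr, seed = sd_seed)
      maps <- fit_image(noisy, fit_config(init_mode = im), powers = ps,
                        voxels = voxels)
      st <- roi_stats(maps)
      er <- error_metrics(maps)
      cond <- data.frame(snr = snr, powers = ps, init = im,
                         realization = rz, seed = sd_seed)
      st <- cbind(cond[rep(1, nrow(st)), ], st)
      er <- cbind(cond[rep(1, nrow(er)), ], er)
      st$reported <- !(st$parameter %in% c("k_ab", "k_ba") &
                         snr < cfg$report_threshold_snr)
      stats_rows[[length(stats_rows) + 1L]] <- st
      err_rows[[length(err_rows) + 1L]] <- er
      if (keep_maps)
        all_maps[[sprintf("snr%g_%s_%s_r%d", snr, ps, im, rz)]] <- maps
    }
  out <- list(stats = do.call(rbind, stats_rows),
              errors = do.call(rbind, err_rows))
  rownames(out$stats) <- rownames(out$errors) <- NULL
  if (keep_maps) out$maps <- all_maps
  out
}

# spatially estimated SNR: mean reference signal over the per-chip SD of
# the reference volume (signal is constant within a chip, so within-chip
# SD estimates the residual noise level) — usable after denoising, where
# the injected sigma no longer applies
snr_spatial <- function(images) {
  ref <- reference_condition(images$protocol)
  vol <- images$signal[, , ref["power"], ref["offset"]]
  chip <- images$truth_maps$chip
  sds <- tapply(as.numeric(vol), as.integer(chip), stats::sd)
  mean(vol) / mean(sds)
}

#' Denoising comparison at a fixed SNR
#'
#' Three arms — raw, tMPPCA, Gaussian filter — built from the same noisy
#' phantom and fitted identically (3 powers, ground-truth init), with
#' per-arm ROI statistics, error metrics, and spatially estimated SNR.
#'
#' @param cfg An [experiment_config()] (its seed and voxel block apply).
#' @param snr Reference SNR of the noisy input (default 50).
#' @param spec A [phantom_spec()].
#' @param realization Realization index folded into the noise seed.
#' @return List with per-arm \code{stats}, \code{errors},
#'   \code{measured_snr}, and the fitted maps.
#' @export
run_denoise_comparison <- function(cfg = experiment_config(), snr = 50,
                                   spec = phantom_spec(),
                                   realization = 1) {
  base <- generate_phantom(spec)
  voxels <- chip_voxel_block(base, cfg$voxels_per_chip)
  noisy <- add_rician_noise(
    base, snr, seed = derive_seed(cfg$seed, "denoise", snr, realization))
  arms <- list(raw = noisy,
               tmppca = tmppca(noisy)$denoised,
               gaussian = gaussian_baseline(noisy)$denoised)
  res <- list()
  for (an in names(arms)) {
    maps <- fit_image(arms[[an]], fit_config(init_mode = "ground_truth"),
                      powers = "3SP", voxels = voxels)
    st <- roi_stats(maps); st$arm <- an
    er <- error_metrics(maps); er$arm <- an
    res[[an]] <- list(stats = st, errors = er, maps = maps,
                      measured_snr = snr_spatial(arms[[an]]))
  }
  list(arms = res,
       stats = do.call(rbind, lapply(res, `[[`, "stats")),
       errors = do.call(rbind, lapply(res, `[[`, "errors")),
       measured_snr = vapply(res, `[[`, numeric(1), "measured_snr"),
       input_snr = snr)
}

#' Write experiment tables and map panels to disk
#'
#' @param tables Named list of data.frames (written as CSV).
#' @param maps Optional named list of \code{parameter_maps}; each is
#'   written as a per-parameter PNG panel (fitted beside ground truth)
#'   when ggplot2 is available, and always as per-parameter CSV matrices.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_report <- function(tables, maps = NULL, outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    f <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    paths <- c(paths, f)
  }
  for (nm in names(maps)) {
    m <- maps[[nm]]
    for (pn in c("mmf", "k_ab", "k_ba")) {
      f <- file.path(outdir, sprintf("%s_%s.csv", nm, pn))
      utils::write.csv(m$maps[[pn]], f, row.names = FALSE)
      paths <- c(paths, f)
    }
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      df <- NULL
      for (pn in c("mmf", "k_ab")) {
        fit_m <- m$maps[[pn]]; tru_m <- m$truth_maps[[pn]]
        grid <- expand.grid(y = seq_len(nrow(fit_m)),
                            x = seq_len(ncol(fit_m)))
        df <- rbind(df,
          data.frame(grid, value = as.numeric(fit_m), parameter = pn,
                     panel = "fitted"),
          data.frame(grid, value = as.numeric(tru_m), parameter = pn,
                     panel = "ground truth"))
      }
      gp <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                             fill = .data$value)) +
        ggplot2::geom_raster() +
        ggplot2::facet_grid(parameter ~ panel, scales = "free") +
        ggplot2::scale_y_reverse() +
        ggplot2::labs(title = nm, fill = NULL)
      f <- file.path(outdir, paste0(nm, "_maps.png"))
      ggplot2::ggsave(f, gp, width = 7, height = 6, dpi = 120)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}
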