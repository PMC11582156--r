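#' Configuration of the voxel-wise qMT fit
#'
#' Five parameters are free when T1obs is fitted — m0a, mmf, k_ab, t1_obs,
#' t2a — with r1b fixed to 1 s^-1 and t2b to 15 us (t2b overridable); when
#' \code{t1obs_mode = "fixed"} (the ex vivo convention, default 250 ms)
#' only four are free.  Bounds are deliberately wide so that the
#' instability of exchange-rate fits at low SNR is reproduced rather than
#' suppressed.
#'
#' @param init_mode "ground_truth" (truth maps supply per-voxel starts),
#'   "fixed" (the midpoint start below) or "custom".
#' @param fixed_init Named list of starting values for mmf, k_ab, t1_obs,
#'   t2a (defaults: 0.50, 25 s^-1, 240 ms, 0.8 ms).  m0a always starts at
#'   the voxel's reference-condition signal.
#' @param t1obs_mode "fit" or "fixed".
#' @param t1obs_fixed Fixed T1obs in seconds when \code{t1obs_mode="fixed"}.
#' @param t2b,r1b Fixed model constants.
#' @param bounds Named list of \code{c(lo, hi)} per free parameter; the
#'   m0a upper bound is expressed as a multiple of the voxel reference
#'   signal (\code{m0a_ref_mult}).
#' @param m0a_ref_mult Upper bound on m0a as multiple of reference signal.
#' @param maxiter,ftol Optimizer controls (bounded Levenberg-Marquardt).
#' @return An object of class \code{fit_config}.
#' @export
fit_config <- function(init_mode = c("ground_truth", "fixed", "custom"),
                       fixed_init = list(mmf = 0.50, k_ab = 25,
                                         t1_obs = 0.240, t2a = 0.8e-3),
                       t1obs_mode = c("fit", "fixed"),
                       t1obs_fixed = 0.250,
                       t2b = 15e-6, r1b = 1,
                       bounds = list(mmf = c(0.01, 0.99),
                                     k_ab = c(0.1, 5e3),
                                     t1_obs = c(0.05, 2),
                                     t2a = c(0.1e-3, 5e-3)),
                       m0a_ref_mult = 10,
                       maxiter = 60, ftol = 1e-10) {
  init_mode <- match.arg(init_mode)
  t1obs_mode <- match.arg(t1obs_mode)
  for (b in bounds) if (!(b[1] < b[2])) stop("bounds must satisfy lo < hi")
  structure(list(init_mode = init_mode, fixed_init = fixed_init,
                 t1obs_mode = t1obs_mode, t1obs_fixed = t1obs_fixed,
                 t2b = t2b, r1b = r1b, bounds = bounds,
                 m0a_ref_mult = m0a_ref_mult,
                 maxiter = maxiter, ftol = ftol),
            class = "fit_config")
}

# restrict a protocol to a subset of powers ("all", "2SP", or indices);
# 2SP drops the middle power of three (the 800 deg dataset)
subset_protocol <- function(protocol, powers = "all") {
  if (identical(powers, "all") || identical(powers, "3SP")) {
    idx <- seq_along(protocol$powers_deg)
  } else if (identical(powers, "2SP")) {
    ord <- order(protocol$powers_deg)
    idx <- ord[c(1, length(ord))]
  } else {
    idx <- as.integer(powers)
  }
  proto <- protocol
  proto$powers_deg <- protocol$powers_deg[idx]
  list(protocol = proto, idx = idx)
}

#' Fit the two-pool model to one voxel's qMT spectrum
#'
#' Bounded Levenberg-Marquardt (trust-region style) least squares on the
#' magnitude signal, with the forward model of [simulate_spectrum()].
#'
#' @param spectrum Matrix \code{[n_powers x n_offsets]} of measured
#'   magnitudes (a.u.).
#' @param protocol The [mt_protocol()] matching the spectrum grid.
#' @param config A [fit_config()].
#' @param init Named list with mmf, k_ab, t1_obs, t2a starting values
#'   (m0a optional; defaults to the voxel's reference-condition signal).
#' @return An object of class \code{fit_result}: \code{estimates} (m0a,
#'   mmf, k_ab, k_ba, t1_obs, t2a), \code{residual_norm},
#'   \code{converged}, \code{n_iter}, \code{at_bound} flags.
#' @export
fit_voxel <- function(spectrum, protocol, config = fit_config(),
                      init = config$fixed_init) {
  spectrum <- as.matrix(spectrum)
  if (!all(is.finite(spectrum))) stop("spectrum contains non-finite values")
  if (nrow(spectrum) != length(protocol$powers_deg) ||
      ncol(spectrum) != length(protocol$offsets_hz))
    stop("spectrum dimensions do not match the protocol grid")
  ref <- reference_condition(protocol)
  ref_sig <- spectrum[ref["power"], ref["offset"]]
  if (is.null(init$m0a)) {
    # the voxel's reference-condition signal sets the initial m0a scale:
    # map it through the forward model's unit-m0a baseline at the initial
    # parameters so m0a starts on the right order of magnitude
    ref_proto <- protocol
    ref_proto$powers_deg <- protocol$powers_deg[ref["power"]]
    ref_proto$offsets_hz <- protocol$offsets_hz[ref["offset"]]
    t1_init <- if (config$t1obs_mode == "fit") init$t1_obs else
      config$t1obs_fixed
    base1 <- try(qmt_spectrum_raw(init$mmf, init$k_ab, t1_init, init$t2a,
                                  config$t2b, config$r1b, 1,
                                  ref_proto)[1, 1], silent = TRUE)
    if (inherits(base1, "try-error") || !is.finite(base1) || base1 <= 0) {
      # physically inconsistent start (derived R1a <= 0): fall back to the
      # readout scale sin(FA) as the unit-m0a baseline
      base1 <- sin(protocol$timing$excitation_fa_deg * pi / 180)
    }
    init$m0a <- max(ref_sig, .Machine$double.eps) / base1
  }

  fit_t1 <- config$t1obs_mode == "fit"
  par_names <- c("m0a", "mmf", "k_ab", if (fit_t1) "t1_obs", "t2a")
  lower <- c(0, config$bounds$mmf[1], config$bounds$k_ab[1],
             if (fit_t1) config$bounds$t1_obs[1], config$bounds$t2a[1])
  upper <- c(config$m0a_ref_mult * max(ref_sig, .Machine$double.eps),
             config$bounds$mmf[2], config$bounds$k_ab[2],
             if (fit_t1) config$bounds$t1_obs[2], config$bounds$t2a[2])
  start <- c(init$m0a, init$mmf, init$k_ab,
             if (fit_t1) init$t1_obs, init$t2a)
  names(start) <- names(lower) <- names(upper) <- par_names
  start <- pmin(pmax(start, lower), upper)

  y <- as.numeric(spectrum)
  t1_fixed <- config$t1obs_fixed
  resid_fn <- function(par) {
    t1 <- if (fit_t1) par[["t1_obs"]] else t1_fixed
    mdl <- try(qmt_spectrum_raw(par[["mmf"]], par[["k_ab"]], t1,
                                par[["t2a"]], config$t2b, config$r1b,
                                par[["m0a"]], protocol),
               silent = TRUE)
    if (inherits(mdl, "try-error")) return(rep(1e6, length(y)))
    as.numeric(mdl) - y
  }
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = config$maxiter, ftol = config$ftol, ptol = 1e-10))),
    silent = TRUE)

  if (inherits(fit, "try-error")) {
    est <- stats::setNames(rep(NA_real_, length(start)), par_names)
    return(structure(list(
      estimates = c(est, k_ba = NA_real_,
                    if (!fit_t1) c(t1_obs = t1_fixed)),
      residual_norm = NA_real_, converged = FALSE, n_iter = 0L,
      at_bound = stats::setNames(rep(FALSE, length(start)), par_names),
      message = as.character(fit)), class = "fit_result"))
  }
  par <- fit$par
  tol <- 1e-8
  at_bound <- (par - lower) <= tol * pmax(abs(lower), 1) |
              (upper - par) <= tol * pmax(abs(upper), 1)
  est <- c(m0a = par[["m0a"]], mmf = par[["mmf"]], k_ab = par[["k_ab"]],
           k_ba = par[["k_ab"]] * (1 - par[["mmf"]]) / par[["mmf"]],
           t1_obs = if (fit_t1) par[["t1_obs"]] else t1_fixed,
           t2a = par[["t2a"]])
  structure(list(estimates = est,
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 converged = fit$info %in% 1:4,
                 n_iter = fit$niter,
                 at_bound = at_bound,
                 message = fit$message),
            class = "fit_result")
}

#' Fit every voxel of a phantom or measured image set
#'
#' @param images A \code{phantom_image_set} (from [generate_phantom()] /
#'   [add_rician_noise()] or [read_stack()]).
#' @param config A [fit_config()].
#' @param powers "all"/"3SP" for the full power set, "2SP" to drop the
#'   middle of three powers, or explicit power indices.
#' @param voxels Optional integer matrix \code{[n x 2]} of (row, col)
#'   indices to fit (default: all voxels); unfitted voxels carry NA.
#' @return An object of class \code{parameter_maps}: per-parameter 2-D
#'   maps (m0a, mmf, k_ab, k_ba, t1_obs, t2a, residual_norm, converged),
#'   \code{exclusion_mask} from [flag_unstable()], and provenance.
#' @export
fit_image <- function(images, config = fit_config(), powers = "all",
                      voxels = NULL) {
  stopifnot(inherits(images, "phantom_image_set"))
  sub <- subset_protocol(images$protocol, powers)
  dims <- dim(images$signal)
  if (config$init_mode == "ground_truth" && is.null(images$truth_maps))
    stop("init_mode='ground_truth' requires truth maps")
  if (is.null(voxels)) {
    voxels <- as.matrix(expand.grid(row = seq_len(dims[1]),
                                    col = seq_len(dims[2])))
  }
  map_names <- c("m0a", "mmf", "k_ab", "k_ba", "t1_obs", "t2a",
                 "residual_norm")
  maps <- stats::setNames(
    replicate(length(map_names), matrix(NA_real_, dims[1], dims[2]),
              simplify = FALSE), map_names)
  maps$converged <- matrix(NA, dims[1], dims[2])
  for (v in seq_len(nrow(voxels))) {
    r <- voxels[v, 1]; cl <- voxels[v, 2]
    spec <- images$signal[r, cl, sub$idx, , drop = FALSE]
    spec <- matrix(spec, nrow = length(sub$idx))
    init <- switch(config$init_mode,
      ground_truth = list(mmf = images$truth_maps$mmf[r, cl],
                          k_ab = images$truth_maps$k_ab[r, cl],
                          t1_obs = images$truth_maps$t1_obs[r, cl],
                          t2a = images$truth_maps$t2a[r, cl]),
      config$fixed_init)
    fr <- fit_voxel(spec, sub$protocol, config, init)
    for (nm in c("m0a", "mmf", "k_ab", "k_ba", "t1_obs", "t2a"))
      maps[[nm]][r, cl] <- fr$estimates[[nm]]
    maps$residual_norm[r, cl] <- fr$residual_norm
    maps$converged[r, cl] <- fr$converged
  }
  out <- structure(list(maps = maps,
                        exclusion_mask = NULL,
                        truth_maps = images$truth_maps,
                        config = config, powers = powers,
                        protocol = sub$protocol,
                        noise_sigma = images$noise_sigma,
                        seed = images$seed),
                   class = "parameter_maps")
  out$exclusion_mask <- flag_unstable(out)
  out
}

#' Flag voxels with unstable exchange-rate fits
#'
#' Low-SNR exchange-rate fits can run away to unrealistically large values;
#' voxels with k_ab > 10^3 s^-1 or k_ba > 5 x 10^3 s^-1 are excluded from
#' ROI statistics.
#'
#' @param maps A \code{parameter_maps} object.
#' @param threshold_kab,threshold_kba Exclusion thresholds, s^-1.
#' @return Logical matrix, TRUE where a voxel is excluded.
#' @export
flag_unstable <- function(maps, threshold_kab = 1e3, threshold_kba = 5e3) {
  stopifnot(inherits(maps, "parameter_maps"))
  kab <- maps$maps$k_ab
  kba <- maps$maps$k_ba
  mask <- (!is.na(kab) & kab > threshold_kab) |
          (!is.na(kba) & kba > threshold_kba)
  mask[is.na(kab) & is.na(kba)] <- FALSE
  mask
}
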