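#' MT saturation pulse description
#'
#' The preparation pulse is characterized by its total equivalent
#' on-resonance rotation (the "saturation power", in degrees), its offset
#' from water resonance, its duration, and its amplitude envelope.  For the
#' rectangular-pulse (RP) steady-state model only the root-mean-square Rabi
#' frequency over the pulse matters; the envelope enters through the ratio
#' of its mean-square to squared-mean amplitude (see [omega1_rms()]).
#'
#' @param flip_angle_deg Total equivalent flip angle, degrees (>= 0).
#' @param offset_hz Offset frequency Delta from water, Hz (> 0).
#' @param duration_s Pulse duration, seconds.
#' @param shape Envelope: "rect", "fermi" (default) or "gaussian".
#' @return An object of class \code{saturation_pulse}.
#' @export
saturation_pulse <- function(flip_angle_deg, offset_hz, duration_s = 8e-3,
                             shape = c("fermi", "rect", "gaussian")) {
  shape <- match.arg(shape)
  if (flip_angle_deg < 0) stop("flip_angle_deg must be >= 0")
  if (offset_hz <= 0) stop("offset_hz must be > 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  structure(list(flip_angle_deg = flip_angle_deg, offset_hz = offset_hz,
                 duration_s = duration_s, shape = shape),
            class = "saturation_pulse")
}

#' Readout timing of one MT cycle
#'
#' Each MT preparation pulse is followed by a train of low-flip-angle
#' ultrashort-TE excitations (spokes); the remaining time up to the full
#' cycle TR is free recovery.  Defaults are the bone protocol values
#' (TR 86 ms, 13 spokes, 5 ms inter-spoke spacing, 10 degree excitations).
#'
#' @param tr_s Full MT-cycle repetition time, seconds.
#' @param n_spokes Excitations per MT preparation (>= 1).
#' @param inter_spoke_tr_s Spacing between readout excitations, seconds.
#' @param excitation_fa_deg Readout flip angle, degrees.
#' @return An object of class \code{sequence_timing}.
#' @export
sequence_timing <- function(tr_s = 0.086, n_spokes = 13,
                            inter_spoke_tr_s = 0.005,
                            excitation_fa_deg = 10) {
  if (n_spokes < 1) stop("n_spokes must be >= 1")
  if (tr_s <= 0 || inter_spoke_tr_s <= 0) stop("timing must be > 0")
  structure(list(tr_s = tr_s, n_spokes = as.integer(n_spokes),
                 inter_spoke_tr_s = inter_spoke_tr_s,
                 excitation_fa_deg = excitation_fa_deg),
            class = "sequence_timing")
}

#' Measurement protocol: the (power x offset) grid plus timing
#'
#' @param powers_deg Saturation flip angles, degrees
#'   (default 400, 800, 1200).
#' @param offsets_hz Offset frequencies, Hz (default 2, 5, 10, 20, 50 kHz).
#' @param timing A [sequence_timing()] object.
#' @param pulse_duration_s MT pulse duration, seconds (default 8 ms).
#' @param pulse_shape MT pulse envelope (default "fermi").
#' @param lineshape Bound-pool absorption lineshape: "gaussian" (default),
#'   "lorentzian" or "super_lorentzian".
#' @return An object of class \code{mt_protocol}.
#' @export
mt_protocol <- function(powers_deg = c(400, 800, 1200),
                        offsets_hz = c(2, 5, 10, 20, 50) * 1e3,
                        timing = sequence_timing(),
                        pulse_duration_s = 8e-3,
                        pulse_shape = "fermi",
                        lineshape = "gaussian") {
  if (length(powers_deg) < 1 || length(offsets_hz) < 1)
    stop("powers_deg and offsets_hz must be nonempty")
  if (any(powers_deg < 0)) stop("powers must be >= 0")
  if (any(offsets_hz <= 0)) stop("offsets must be > 0")
  sat_time <- pulse_duration_s +
    (timing$n_spokes - 1) * timing$inter_spoke_tr_s
  if (timing$tr_s <= sat_time)
    stop("tr_s must exceed pulse duration + spoke train length")
  structure(list(powers_deg = powers_deg, offsets_hz = offsets_hz,
                 timing = timing, pulse_duration_s = pulse_duration_s,
                 pulse_shape = pulse_shape, lineshape = lineshape),
            class = "mt_protocol")
}

#' @export
print.mt_protocol <- function(x, ...) {
  cat(sprintf(
    "mt_protocol: %d powers (%s deg) x %d offsets (%s kHz), %s pulse %.1f ms, %s lineshape\n",
    length(x$powers_deg), paste(x$powers_deg, collapse = "/"),
    length(x$offsets_hz), paste(x$offsets_hz / 1e3, collapse = "/"),
    x$pulse_shape, 1e3 * x$pulse_duration_s, x$lineshape))
  invisible(x)
}

# Envelope moments (mean and mean-square of the normalized amplitude) used
# to convert a total flip angle into the rms Rabi frequency of the
# equivalent rectangular pulse.  Gaussian: truncated at +-3 sigma.  Fermi:
# plateau with 10%-of-duration transition bands.
shape_moments <- function(shape) {
  switch(shape,
    rect = c(mean = 1, meansq = 1),
    gaussian = {
      u <- seq(-3, 3, length.out = 4001)
      e <- exp(-u^2 / 2)
      c(mean = mean(e), meansq = mean(e^2))
    },
    fermi = {
      u <- seq(0, 1, length.out = 4001)
      a <- 0.02                       # transition width / duration
      t0 <- 0.38                      # half-width of the plateau
      e <- 1 / (1 + exp((abs(u - 0.5) - t0) / a))
      c(mean = mean(e), meansq = mean(e^2))
    },
    stop(sprintf("unknown pulse shape '%s'", shape)))
}

#' Root-mean-square Rabi frequency of the equivalent rectangular pulse
#'
#' For a shaped pulse with envelope e(t) and total flip angle theta,
#' \eqn{\omega_{1,rms} = (\theta/\tau)\sqrt{\overline{e^2}}/\overline{e}},
#' so that the equivalent rectangular pulse deposits the same average
#' saturation power \eqn{\omega_{1,rms}^2 = (1/\tau)\int \omega_1(t)^2 dt}.
#'
#' @param flip_angle_deg Total flip angle, degrees.
#' @param duration_s Pulse duration, seconds.
#' @param shape Envelope name.
#' @return Rabi frequency in rad/s.
#' @export
omega1_rms <- function(flip_angle_deg, duration_s, shape = "fermi") {
  mom <- shape_moments(shape)
  theta <- flip_angle_deg * pi / 180
  (theta / duration_s) * sqrt(mom[["meansq"]]) / mom[["mean"]]
}
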