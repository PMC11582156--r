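#' Saturation rates of the two pools under one MT pulse
#'
#' Rectangular-pulse approximation: the shaped pulse is replaced by a
#' rectangle of equal average power, and each pool is saturated at
#' W = pi * omega1rms^2 * g(Delta), with the bound-pool lineshape evaluated
#' at t2b and the free pool's Lorentzian at t2a (direct saturation).
#'
#' @param pulse A [saturation_pulse()] object.
#' @param p A [tissue_params()] object.
#' @param kind Bound-pool lineshape kind (default "gaussian").
#' @return Named numeric \code{c(w_b =, w_a =)} in s^-1.
#' @export
saturation_rates <- function(pulse, p, kind = "gaussian") {
  w1 <- omega1_rms(pulse$flip_angle_deg, pulse$duration_s, pulse$shape)
  gb <- absorption_lineshape(pulse$offset_hz, p$t2b, kind)
  ga <- absorption_lineshape(pulse$offset_hz, p$t2a, "lorentzian")
  c(w_b = pi * w1^2 * gb, w_a = pi * w1^2 * ga)
}

# Grid of saturation rates for a full protocol: returns two
# n_powers x n_offsets matrices (list wa, wb), flattened column-major on
# request by the callers.
saturation_rate_grid <- function(protocol, t2a, t2b) {
  w1 <- vapply(protocol$powers_deg, omega1_rms, numeric(1),
               duration_s = protocol$pulse_duration_s,
               shape = protocol$pulse_shape)
  gb <- absorption_lineshape(protocol$offsets_hz, t2b, protocol$lineshape)
  ga <- absorption_lineshape(protocol$offsets_hz, t2a, "lorentzian")
  list(wb = pi * outer(w1^2, gb), wa = pi * outer(w1^2, ga))
}

# Core spectrum evaluation from raw parameter values (no validation);
# shared by simulate_spectrum and the fitting residual.
qmt_spectrum_raw <- function(mmf, k_ab, t1_obs, t2a, t2b, r1b, m0a,
                             protocol, first_spoke_only = FALSE) {
  p <- list(mmf = mmf, k_ab = k_ab, t1_obs = t1_obs, t2a = t2a,
            t2b = t2b, r1b = r1b, m0a = m0a)
  class(p) <- "tissue_params"
  r1a <- derive_r1a(p)
  kba <- k_ab * (1 - mmf) / mmf
  m0b <- m0a * mmf / (1 - mmf)
  w <- saturation_rate_grid(protocol, t2a, t2b)
  tm <- protocol$timing
  t_rec <- tm$tr_s - protocol$pulse_duration_s -
    (tm$n_spokes - 1) * tm$inter_spoke_tr_s
  fa <- tm$excitation_fa_deg * pi / 180
  sig <- qmt_spectrum_cpp(r1a, r1b, k_ab, kba, m0a, m0b,
                          as.numeric(w$wa), as.numeric(w$wb),
                          protocol$pulse_duration_s, tm$n_spokes,
                          tm$inter_spoke_tr_s, t_rec,
                          cos(fa), sin(fa), first_spoke_only)
  matrix(sig, nrow = length(protocol$powers_deg))
}

#' Steady-state MT-weighted signal for one measurement condition
#'
#' Periodic steady state of the two-pool longitudinal magnetization over
#' one MT cycle: (i) the saturation segment with RP-model rates (W_a, W_b)
#' added to relaxation and exchange, (ii) the spoke train, each excitation
#' instantaneously scaling the free-pool term by cos(FA), (iii) free
#' recovery filling the TR.  Segments are exact affine flows (closed-form
#' 2x2 matrix exponentials); the steady state solves
#' M_ss = P_cycle M_ss + c_cycle.  The reported signal is sin(FA) times the
#' mean free-pool longitudinal magnetization immediately before each spoke
#' (center-out radial readouts share the k-space center), or the
#' first-spoke value if \code{first_spoke_only = TRUE}.
#'
#' @param p A [tissue_params()] object.
#' @param pulse A [saturation_pulse()] object.
#' @param timing A [sequence_timing()] object.
#' @param kind Bound-pool lineshape kind.
#' @param first_spoke_only Readout convention switch.
#' @return Signal amplitude, arbitrary units (> 0).
#' @export
simulate_signal <- function(p, pulse, timing = sequence_timing(),
                            kind = "gaussian", first_spoke_only = FALSE) {
  proto <- mt_protocol(powers_deg = pulse$flip_angle_deg,
                       offsets_hz = pulse$offset_hz,
                       timing = timing,
                       pulse_duration_s = pulse$duration_s,
                       pulse_shape = pulse$shape,
                       lineshape = kind)
  qmt_spectrum_raw(p$mmf, p$k_ab, p$t1_obs, p$t2a, p$t2b, p$r1b, p$m0a,
                   proto, first_spoke_only)[1, 1]
}

#' Full qMT spectrum over a (power x offset) grid
#'
#' @param p A [tissue_params()] object.
#' @param protocol An [mt_protocol()] object.
#' @param first_spoke_only Readout convention switch.
#' @return Matrix \code{[n_powers x n_offsets]} of signals, a.u.  The entry
#'   for the lowest power at the largest offset is the SNR reference
#'   condition.
#' @export
simulate_spectrum <- function(p, protocol = mt_protocol(),
                              first_spoke_only = FALSE) {
  stopifnot(inherits(p, "tissue_params"), inherits(protocol, "mt_protocol"))
  qmt_spectrum_raw(p$mmf, p$k_ab, p$t1_obs, p$t2a, p$t2b, p$r1b, p$m0a,
                   protocol, first_spoke_only)
}
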