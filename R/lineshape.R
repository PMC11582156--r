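#' Absorption lineshape of a spin pool
#'
#' Spectral density g(Delta) (units: seconds) governing the saturation rate
#' W = pi * omega1rms^2 * g(Delta) of a pool with transverse relaxation time
#' \code{t2}.  The macromolecular pool of collagen-dominated tissue is
#' modeled with a Gaussian lineshape by default; the free water pool is
#' always Lorentzian.  The super-Lorentzian (orientationally averaged rigid
#' dipolar lineshape) diverges on resonance, so evaluation below a cutoff
#' offset raises an error unless extrapolation is requested.
#'
#' Forms: Gaussian \eqn{G(\Delta)=\frac{T_2}{\sqrt{2\pi}}
#' e^{-(2\pi\Delta T_2)^2/2}}; Lorentzian \eqn{g(\Delta)=\frac{T_2/\pi}
#' {1+(2\pi\Delta T_2)^2}}; super-Lorentzian
#' \eqn{g(\Delta)=\int_0^1 \sqrt{\frac{2}{\pi}}\frac{T_2}{|3u^2-1|}
#' \exp\!\big(-2(\frac{2\pi\Delta T_2}{3u^2-1})^2\big)\,du}.
#'
#' @param offset_hz Offset frequency (or vector), Hz.
#' @param t2 Transverse relaxation time of the pool, seconds.
#' @param kind "gaussian", "lorentzian" or "super_lorentzian".
#' @param sl_cutoff_hz Offset below which the super-Lorentzian is not
#'   evaluated (default 1 kHz).
#' @param sl_extrapolate If TRUE, offsets below the cutoff return the
#'   cutoff value instead of an error.
#' @return Spectral density in seconds, same length as \code{offset_hz}.
#' @export
absorption_lineshape <- function(offset_hz, t2,
                                 kind = c("gaussian", "lorentzian",
                                          "super_lorentzian"),
                                 sl_cutoff_hz = 1e3,
                                 sl_extrapolate = FALSE) {
  kind <- match.arg(kind)
  if (t2 <= 0) stop("t2 must be > 0")
  d <- abs(offset_hz)
  switch(kind,
    gaussian = (t2 / sqrt(2 * pi)) * exp(-(2 * pi * d * t2)^2 / 2),
    lorentzian = (t2 / pi) / (1 + (2 * pi * d * t2)^2),
    super_lorentzian = {
      low <- d < sl_cutoff_hz
      if (any(low) && !sl_extrapolate)
        stop(sprintf(
          "super-Lorentzian requested at |offset| < %g Hz; set sl_extrapolate = TRUE to clamp",
          sl_cutoff_hz))
      d[low] <- sl_cutoff_hz
      vapply(d, function(di) {
        stats::integrate(function(u) {
          s <- 3 * u^2 - 1
          sqrt(2 / pi) * (t2 / abs(s)) * exp(-2 * (2 * pi * di * t2 / s)^2)
        }, 0, 1, rel.tol = 1e-8, stop.on.error = FALSE)$value
      }, numeric(1))
    })
}
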