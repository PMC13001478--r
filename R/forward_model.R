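# Forward model shared by the simulator and the reconvolution fitter.
#
# Decays repeat with the laser period, so all convolutions are circular over
# the acquisition window and exponential tails wrap around. On a discrete
# periodic axis the wrapped exponential, normalised to unit sum, reduces to
# exp(-t/tau) / sum(exp(-t/tau)): the wrap-around factor 1/(1 - exp(-T/tau))
# cancels under normalisation.

#' Circular convolution over the repetition window
#'
#' @param x Numeric vector (decay shape).
#' @param h Numeric vector of the same length (IRF weights).
#' @return Numeric vector, the circular convolution of `x` and `h`.
#' @keywords internal
convolve_circular <- function(x, h) {
  n <- length(x)
  stopifnot(length(h) == n)
  Re(stats::fft(stats::fft(x) * stats::fft(h), inverse = TRUE)) / n
}

# Unit-sum periodic mono-exponential decay shape on bin centres t.
decay_shape <- function(tau, t) {
  s <- exp(-(t - t[1]) / tau)
  s / sum(s)
}

# Derivative of decay_shape with respect to tau.
decay_shape_dtau <- function(tau, t) {
  s <- decay_shape(tau, t)
  tc <- t - t[1]
  s * (tc - sum(s * tc)) / tau^2
}

#' Expected biexponential TCSPC histogram
#'
#' Expected photon counts per bin for a biexponential emitter observed through
#' an instrument response: amplitude-scaled unit-sum component decays,
#' circularly convolved with the IRF, plus a flat background. Because each
#' component curve is normalised to unit area before scaling, the component
#' amplitudes are the expected photon counts contributed by each component.
#'
#' @param tau1,tau2 Short and long lifetime components, picoseconds.
#' @param a1,a2 Expected photons in the short / long component.
#' @param c_bg Flat background, expected photons per bin.
#' @param irf A [make_irf()] object.
#' @return Numeric vector of expected counts per bin.
#' @export
decay_model_expected <- function(tau1, tau2, a1, a2, c_bg, irf) {
  stopifnot(inherits(irf, "flim_irf"), tau1 > 0, tau2 > 0,
            a1 >= 0, a2 >= 0, c_bg >= 0)
  t <- irf$time_ps
  g1 <- convolve_circular(decay_shape(tau1, t), irf$weights)
  g2 <- convolve_circular(decay_shape(tau2, t), irf$weights)
  a1 * g1 + a2 * g2 + c_bg
}
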