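#' Channel-center times of a TCSPC histogram
#'
#' Time axis convention used throughout the package: channel k covers
#' `[(k-1), k] * channel_width` and is evaluated at its center
#' `t_k = (k - 1/2) * channel_width`.
#'
#' @param n_channels number of time channels (default 256).
#' @param channel_width channel width in ps.
#' @return numeric vector of channel-center times (ps).
#' @export
channel_times <- function(n_channels, channel_width) {
  (seq_len(n_channels) - 0.5) * channel_width
}

#' Gaussian instrument response function
#'
#' Discrete IRF kernel: a Gaussian of given full width at half maximum,
#' sampled at channel centers and normalized to unit sum.
#'
#' @param n_channels number of time channels.
#' @param channel_width channel width in ps.
#' @param fwhm full width at half maximum in ps (default 150).
#' @param peak_channel channel index of the IRF peak (default 10).
#' @return an `irf` object: list with `kernel` (unit-sum weights) and
#'   `peak_channel`.
#' @export
gaussian_irf <- function(n_channels = 256, channel_width = 12500 / 256,
                         fwhm = 150, peak_channel = 10) {
  stopifnot(fwhm > 0, peak_channel >= 1, peak_channel <= n_channels)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  t <- channel_times(n_channels, channel_width)
  mu <- t[peak_channel]
  k <- exp(-0.5 * ((t - mu) / sigma)^2)
  new_irf(k / sum(k), peak_channel)
}

#' Delta (ideal) instrument response function
#'
#' @inheritParams gaussian_irf
#' @return an `irf` object with all weight in one channel.
#' @export
delta_irf <- function(n_channels = 256, peak_channel = 1) {
  k <- numeric(n_channels)
  k[peak_channel] <- 1
  new_irf(k, peak_channel)
}

new_irf <- function(kernel, peak_channel) {
  stopifnot(all(kernel >= 0), abs(sum(kernel) - 1) < 1e-9)
  structure(list(kernel = kernel, peak_channel = peak_channel),
            class = "irf")
}

#' Amplitude-weighted mean lifetime
#'
#' `tau_m = (a1*tau1 + a2*tau2) / (a1 + a2)`; the characteristic signature
#' of a bi-exponential decay. Always lies between `tau1` and `tau2`.
#'
#' @param a1,a2 non-negative component amplitudes.
#' @param tau1,tau2 component lifetimes in ps.
#' @return mean lifetime in ps.
#' @export
mean_lifetime <- function(a1, tau1, a2, tau2) {
  if (any(a1 + a2 <= 0)) {
    stop("mean lifetime undefined: a1 + a2 must be > 0")
  }
  (a1 * tau1 + a2 * tau2) / (a1 + a2)
}

#' Amplitude ratio and asymmetry
#'
#' @param a1,a2 component amplitudes, `a2 > 0`.
#' @return list with `ratio = a1/a2` and `asym = (a1 - a2)/(a1 + a2)`.
#' @export
amplitude_ratios <- function(a1, a2) {
  if (any(a2 == 0)) stop("amplitude ratio undefined: a2 must be non-zero")
  if (any(a1 + a2 <= 0)) stop("asymmetry undefined: a1 + a2 must be > 0")
  list(ratio = a1 / a2, asym = (a1 - a2) / (a1 + a2))
}

#' Unit-amplitude decay basis convolved with the IRF
#'
#' Discrete causal convolution of `exp(-t/tau)` (sampled at channel
#' centers) with the IRF kernel, truncated to the acquisition window.
#'
#' @param tau lifetime in ps, > 0.
#' @param irf an `irf` object.
#' @param n_channels,channel_width histogram geometry.
#' @param wrap if `TRUE`, add one wrapped laser period for long tails.
#' @return numeric vector of length `n_channels`.
#' @keywords internal
decay_basis <- function(tau, irf, n_channels, channel_width, wrap = FALSE) {
  stopifnot(tau > 0)
  e <- exp(-channel_times(n_channels, channel_width) / tau)
  m <- conv_causal(irf$kernel, e)
  if (wrap) {
    # one extra period folded back: tail photons from the previous pulse
    period_decay <- exp(-n_channels * channel_width / tau)
    m <- m + conv_causal(irf$kernel, e * period_decay)
  }
  m
}

# causal discrete convolution, truncated to length(x); FFT round-off can
# leave ~1e-17-scale negatives where the true tail is zero — clamp them
conv_causal <- function(kernel, x) {
  n <- length(x)
  pmax(stats::convolve(kernel, rev(x), type = "open")[seq_len(n)], 0)
}

#' Expected bi-exponential decay curve
#'
#' Model counts per channel for `a1*exp(-t/tau1) + a2*exp(-t/tau2)`
#' convolved with the instrument response.
#'
#' @param a1,a2 amplitudes (expected counts at t = 0 per channel).
#' @param tau1,tau2 lifetimes in ps, > 0.
#' @param irf an `irf` object.
#' @param n_channels,channel_width histogram geometry.
#' @param wrap include one wrapped laser period (default `FALSE`).
#' @return expected counts per channel, non-negative.
#' @export
model_decay <- function(a1, tau1, a2, tau2, irf,
                        n_channels = length(irf$kernel),
                        channel_width = 12500 / 256, wrap = FALSE) {
  if (tau1 <= 0 || tau2 <= 0) stop("lifetimes must be positive")
  if (a1 < 0 || a2 < 0) stop("amplitudes must be non-negative")
  a1 * decay_basis(tau1, irf, n_channels, channel_width, wrap) +
    a2 * decay_basis(tau2, irf, n_channels, channel_width, wrap)
}
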