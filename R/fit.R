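#' Fitting configuration
#'
#' @param binning spatial binning value `b`: each pixel's histogram is
#'   summed over its `(2b+1) x (2b+1)` neighborhood (b = 3 aggregates the
#'   48 neighbors plus the center). Default 3.
#' @param intensity_threshold photons/mW below which a pixel is masked.
#'   200 is the in vivo working point, 800 for in vitro / ex vivo.
#' @param tau_bounds lifetime search interval in ps.
#' @param weight_scheme `"poisson"` (default: iteratively reweighted with
#'   model-based weights `1/max(model, 1)`, equivalent to the Poisson
#'   maximum-likelihood fit and unbiased at typical photon budgets) or
#'   `"neyman"` (fixed weights `1/max(counts, 1)`; biased low at low
#'   counts, kept for comparison with software using that convention).
#' @param shift fixed temporal shift between decay and IRF, in channels.
#' @param max_iterations,tolerance Levenberg-Marquardt controls.
#' @param chi2_max reduced chi-square above which a fit is flagged invalid.
#' @param starts matrix of multi-start `(tau1, tau2)` initial values (ps).
#' @return a `fit_config` list.
#' @export
fit_config <- function(binning = 3,
                       intensity_threshold = 200,
                       tau_bounds = c(1, 10000),
                       weight_scheme = c("poisson", "neyman"),
                       shift = 0,
                       max_iterations = 50,
                       tolerance = 1e-8,
                       chi2_max = 5,
                       starts = cbind(tau1 = c(200, 200, 500, 500),
                                      tau2 = c(1500, 2500, 1500, 2500))) {
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(binning >= 0, intensity_threshold > 0,
            length(tau_bounds) == 2, tau_bounds[1] > 0,
            tau_bounds[2] > tau_bounds[1])
  structure(list(binning = as.integer(binning),
                 intensity_threshold = intensity_threshold,
                 tau_bounds = tau_bounds, weight_scheme = weight_scheme,
                 shift = shift, max_iterations = max_iterations,
                 tolerance = tolerance, chi2_max = chi2_max,
                 starts = starts),
            class = "fit_config")
}

#' Spatially bin a decay cube
#'
#' Every pixel's histogram becomes the sum over its `(2b+1) x (2b+1)`
#' square neighborhood; at image borders the kernel is truncated to
#' in-bounds pixels (no padding).
#'
#' @param cube a `decay_cube` (see [make_cube()]).
#' @param b binning value (b = 0 is the identity).
#' @return a `decay_cube` with binned counts.
#' @export
bin_decays <- function(cube, b) {
  stopifnot(inherits(cube, "decay_cube"), b >= 0)
  b <- as.integer(b)
  if (b == 0L) return(cube)
  counts <- cube$counts
  d <- dim(counts)
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    out[, , k] <- box_sum(counts[, , k], b)
  }
  cube$counts <- out
  cube$binning <- b
  cube
}

# truncated box-filter sum via a summed-area table
box_sum <- function(m, b) {
  nr <- nrow(m); nc <- ncol(m)
  sat <- apply(apply(m, 2, cumsum), 1, cumsum) # sat[j, i] after transpose
  sat <- t(sat)                                # sat[i, j] = sum m[1:i, 1:j]
  sat <- rbind(0, cbind(0, sat))               # 1-padded for i0/j0 = 0
  i1 <- pmax(seq_len(nr) - b, 1); i2 <- pmin(seq_len(nr) + b, nr)
  j1 <- pmax(seq_len(nc) - b, 1); j2 <- pmin(seq_len(nc) + b, nc)
  sat[i2 + 1, j2 + 1, drop = FALSE] - sat[i1, j2 + 1, drop = FALSE] -
    sat[i2 + 1, j1, drop = FALSE] + sat[i1, j1, drop = FALSE]
}

# weighted linear solve for the amplitudes given the two basis curves;
# negative solutions collapse to the better single-component fit
project_amplitudes <- function(B, counts, w) {
  BW <- B * w
  a <- tryCatch(solve(crossprod(BW, B), crossprod(BW, counts)),
                error = function(e) matrix(c(0, 0), 2))
  a <- as.numeric(a)
  if (any(a < 0)) {
    a1 <- max(sum(w * B[, 1] * counts) / sum(w * B[, 1]^2), 0)
    a2 <- max(sum(w * B[, 2] * counts) / sum(w * B[, 2]^2), 0)
    r1 <- sum(w * (counts - a1 * B[, 1])^2)
    r2 <- sum(w * (counts - a2 * B[, 2])^2)
    a <- if (r1 <= r2) c(a1, 0) else c(0, a2)
  }
  a
}

#' Fit one pixel's decay histogram
#'
#' Weighted least-squares bi-exponential regression against the
#' IRF-convolved model. Amplitudes are profiled out by a weighted linear
#' solve (variable projection); the two lifetimes are refined by
#' Levenberg-Marquardt from a 4-point multi-start grid, and the start with
#' the lowest weighted residual wins. Pixels whose total counts per mW
#' fall below the intensity threshold are masked (`valid = FALSE`), not
#' fitted.
#'
#' @param counts integer photon counts per time channel.
#' @param irf an `irf` object of matching length.
#' @param config a [fit_config()].
#' @param power excitation power in mW.
#' @param channel_width channel width in ps.
#' @return list with `a1, a2, tau1, tau2, tau_m, ratio, asym, chi2,`
#'   `intensity` (counts/mW) and `valid`; canonical ordering `tau1 <= tau2`.
#' @export
fit_pixel <- function(counts, irf, config = fit_config(), power = 1,
                      channel_width = 12500 / 256) {
  n <- length(counts)
  stopifnot(n == length(irf$kernel))
  intensity <- sum(counts) / power
  blank <- list(a1 = NA_real_, a2 = NA_real_, tau1 = NA_real_,
                tau2 = NA_real_, tau_m = NA_real_, ratio = NA_real_,
                asym = NA_real_, chi2 = NA_real_, intensity = intensity,
                valid = FALSE)
  if (intensity < config$intensity_threshold) return(blank)

  w <- 1 / pmax(counts, 1) # starting weights under either scheme
  lb <- log(config$tau_bounds)
  run_lm <- function(p0, w) {
    resid_fn <- function(p) {
      B <- cbind(decay_basis(exp(p[1]), irf, n, channel_width),
                 decay_basis(exp(p[2]), irf, n, channel_width))
      a <- project_amplitudes(B, counts, w)
      sqrt(w) * (counts - B %*% a)
    }
    tryCatch(
      minpack.lm::nls.lm(p0, lower = c(lb[1], lb[1]),
                         upper = c(lb[2], lb[2]), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$max_iterations,
                           ftol = config$tolerance)),
      error = function(e) NULL)
  }
  best <- NULL
  for (s in seq_len(nrow(config$starts))) {
    p0 <- log(pmin(pmax(config$starts[s, ], config$tau_bounds[1]),
                   config$tau_bounds[2]))
    fitted <- run_lm(p0, w)
    if (!is.null(fitted) &&
        (is.null(best) || fitted$deviance < best$deviance)) best <- fitted
  }
  if (is.null(best)) return(blank)
  taus <- exp(best$par)
  B <- cbind(decay_basis(taus[1], irf, n, channel_width),
             decay_basis(taus[2], irf, n, channel_width))
  a <- project_amplitudes(B, counts, w)

  if (config$weight_scheme == "poisson") {
    # iteratively reweighted least squares with model-based weights;
    # converges to the Poisson maximum-likelihood estimate
    for (iter in 1:5) {
      w_new <- 1 / pmax(as.numeric(B %*% a), 1)
      if (max(abs(w_new - w) / w) < 1e-4) break
      w <- w_new
      refit <- run_lm(log(taus), w)
      if (is.null(refit)) break
      taus <- exp(refit$par)
      B <- cbind(decay_basis(taus[1], irf, n, channel_width),
                 decay_basis(taus[2], irf, n, channel_width))
      a <- project_amplitudes(B, counts, w)
    }
  }
  if (sum(a) <= 0) return(blank)
  # a component carrying < 1% of the modelled photons is unidentifiable
  # (e.g. a sub-channel-width lifetime soaking up a noise spike with an
  # arbitrarily large raw amplitude): collapse to the mono-exponential
  # representation tau1 = tau2, a1 = a2
  contrib <- a * colSums(B)
  if (min(contrib) < 0.01 * sum(contrib)) {
    keep <- which.max(contrib)
    taus <- rep(taus[keep], 2)
    Bk <- B[, keep]
    alpha <- max(sum(w * Bk * counts) / sum(w * Bk^2), 0)
    a <- rep(alpha / 2, 2)
    B <- cbind(Bk, Bk)
  }
  if (taus[1] > taus[2]) { taus <- rev(taus); a <- rev(a); B <- B[, 2:1] }
  taus <- unname(taus)
  chi2 <- sum(w * (counts - B %*% a)^2) / max(n - 4, 1)
  if (sum(a) <= 0) return(blank)
  ra <- if (a[2] > 0) amplitude_ratios(a[1], a[2]) else
    list(ratio = Inf, asym = 1)
  list(a1 = a[1], a2 = a[2], tau1 = taus[1], tau2 = taus[2],
       tau_m = mean_lifetime(a[1], taus[1], a[2], taus[2]),
       ratio = ra$ratio, asym = ra$asym, chi2 = chi2,
       intensity = intensity,
       valid = is.finite(chi2) && chi2 <= config$chi2_max)
}

#' Fit every pixel of a decay cube
#'
#' Applies spatial binning, computes the per-mW intensity map from the
#' binned counts, and runs [fit_pixel()] on every pixel above the
#' intensity threshold.
#'
#' @param cube a `decay_cube`.
#' @param irf an `irf`; defaults to the IRF stored in the cube.
#' @param config a [fit_config()].
#' @param roi optional logical matrix: fit only these pixels (the
#'   intensity map still covers the whole frame).
#' @return a `fit_maps` list of matrices (`a1, a2, tau1, tau2, tau_m,`
#'   `ratio, asym, chi2, intensity`), a logical `valid` mask, plus the
#'   configuration and cube metadata.
#' @export
fit_image <- function(cube, irf = cube$irf, config = fit_config(),
                      roi = NULL) {
  stopifnot(inherits(cube, "decay_cube"))
  if (is.null(cube$power) || cube$power <= 0) {
    stop("cube metadata error: excitation power must be > 0")
  }
  binned <- bin_decays(cube, config$binning)
  d <- dim(binned$counts)
  fields <- c("a1", "a2", "tau1", "tau2", "tau_m", "ratio", "asym", "chi2",
              "intensity")
  maps <- lapply(fields, function(f) matrix(NA_real_, d[1], d[2]))
  names(maps) <- fields
  valid <- matrix(FALSE, d[1], d[2])
  totals <- apply(binned$counts, c(1, 2), sum)
  maps$intensity <- totals / cube$power
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (!is.null(roi) && !roi[i, j]) next
      if (maps$intensity[i, j] < config$intensity_threshold) next
      fp <- fit_pixel(binned$counts[i, j, ], irf, config, cube$power,
                      cube$channel_width)
      for (f in setdiff(fields, "intensity")) maps[[f]][i, j] <- fp[[f]]
      valid[i, j] <- fp$valid
    }
  }
  structure(list(maps = maps, valid = valid, config = config,
                 pixel_pitch = cube$pixel_pitch, power = cube$power,
                 channel_width = cube$channel_width),
            class = "fit_maps")
}
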