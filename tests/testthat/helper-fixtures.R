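# shared fixtures: TCSPC geometry and small synthetic inputs
DW <- 12500 / 256 # channel width, ps (80 MHz laser, 256 channels)

delta1 <- delta_irf(256, 1)
girf <- gaussian_irf(256, DW)

# noiseless bi-exponential histogram at the given photon budget
biexp_hist <- function(a1, tau1, a2, tau2, photons, irf = girf) {
  m <- model_decay(a1, tau1, a2, tau2, irf, 256, DW)
  m / sum(m) * photons
}

# uniform mono-exponential cube: every pixel the same noiseless decay
uniform_cube <- function(n = 8, tau = 1200, photons = 2000, power = 1,
                         irf = girf) {
  shape <- model_decay(1, tau, 0, tau, irf, 256, DW)
  shape <- shape / sum(shape) * photons
  counts <- array(rep(shape, each = n * n), c(n, n, 256))
  make_cube(counts, DW, power, irf, pixel_pitch = 0.3)
}

# pure-R exhaustive split-search oracle (independent of the C++ path)
oracle_best_split <- function(X, y) {
  best <- NULL
  n <- nrow(X)
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (t in (v[-length(v)] + v[-1]) / 2) {
      left <- X[, j] <= t
      g <- (sum(left) * gini(y[left]) + sum(!left) * gini(y[!left])) / n
      if (is.null(best) || g < best$score - 1e-12) {
        best <- list(feature = j, threshold = t, score = g)
      }
    }
  }
  best
}
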