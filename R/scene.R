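#' Construct a decay cube
#'
#' Container for a 3-D TCSPC photon-count histogram stack: `counts` is an
#' `[y, x, time]` array plus acquisition metadata. Intensities follow the
#' 49-pixel binned photons/mW convention, so a structure of intensity `I`
#' contributes `I * power / 49` expected photons per pixel.
#'
#' @param counts numeric/integer array `[ny, nx, n_channels]`.
#' @param channel_width time-channel width in ps.
#' @param power excitation power in mW.
#' @param irf the `irf` the cube was (or is assumed) recorded with.
#' @param pixel_pitch lateral pixel size in um.
#' @param depth imaging depth in um.
#' @param seed RNG seed the cube was generated with (metadata only).
#' @return a `decay_cube` object.
#' @export
make_cube <- function(counts, channel_width, power, irf, pixel_pitch,
                      depth = NA_real_, seed = NA_integer_) {
  stopifnot(length(dim(counts)) == 3, all(counts >= 0, na.rm = TRUE),
            dim(counts)[3] == length(irf$kernel))
  structure(list(counts = counts, channel_width = channel_width,
                 power = power, irf = irf, pixel_pitch = pixel_pitch,
                 depth = depth, seed = seed, binning = 0L),
            class = "decay_cube")
}

#' Scene configuration for the image-mode generator
#'
#' Defaults reproduce the acquisition geometry of the imaging system the
#' package models: 512 x 512 pixels over a 150 um field (0.29 um pitch),
#' 256 time channels spanning the 12.5 ns period of an 80 MHz laser.
#' The extracellular background is elastin-dominated with a mean
#' lifetime of 1,600 +/- 110 ps; blood capillaries carry an ultrashort
#' 80 ps mono-exponential decay.
#'
#' @param image_size pixels per side (square image).
#' @param field_of_view field width in um.
#' @param depth imaging depth in um.
#' @param power excitation power in mW.
#' @param n_channels,channel_width TCSPC geometry.
#' @param irf an `irf` object; stored with every rendered cube.
#' @param background list: `tau_m_mean`, `tau_m_sd` (ps), `ratio` (fixed
#'   a1/a2 used to realize the drawn per-pixel mean lifetime as a
#'   bi-exponential), `intensity_mean`, `intensity_sd` (photons/mW,
#'   49-pixel binned convention).
#' @param capillary `NULL` or list `(center_um = c(x, y), radius_um, tau,
#'   intensity)` describing a circular capillary cross-section.
#' @param cells list of placements: each `list(class =, center_um = c(x, y))`
#'   with optional `params` (a one-row data.frame as returned by
#'   [sample_cell_params()]) to pin the ground truth.
#' @param granule_size_range diameter range of intracellular granule
#'   texture, um.
#' @param granule_contrast peak amplitude contrast of a granule over the
#'   cytoplasmic baseline.
#' @return a `scene_config` list.
#' @export
scene_config <- function(image_size = 512, field_of_view = 150,
                         depth = 80, power = 40,
                         n_channels = 256, channel_width = 12500 / 256,
                         irf = gaussian_irf(n_channels, channel_width),
                         background = list(tau_m_mean = 1600, tau_m_sd = 110,
                                           ratio = 1.2,
                                           intensity_mean = 250,
                                           intensity_sd = 40),
                         capillary = NULL,
                         cells = list(),
                         granule_size_range = c(0.5, 1.5),
                         granule_contrast = 2) {
  pitch <- field_of_view / image_size
  structure(list(image_size = as.integer(image_size),
                 field_of_view = field_of_view, depth = depth, power = power,
                 n_channels = as.integer(n_channels),
                 channel_width = channel_width, irf = irf,
                 background = background, capillary = capillary,
                 cells = cells, granule_size_range = granule_size_range,
                 granule_contrast = granule_contrast, pixel_pitch = pitch),
            class = "scene_config")
}

# bi-exponential (tau1, tau2) pair realizing a target amplitude-weighted
# mean lifetime at a fixed amplitude ratio r, with tau1 = 0.55 * tau_m
realize_tau_pair <- function(tau_m, r, frac = 0.55) {
  tau1 <- frac * tau_m
  tau2 <- tau_m * (1 + r) - r * tau1
  cbind(tau1 = tau1, tau2 = tau2)
}

# disc mask center (px, y/x), radius px -> logical matrix
disc_mask <- function(n, center, radius) {
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  (yy - center[1])^2 + (xx - center[2])^2 <= radius^2
}

# granule texture: dart-thrown blobs with minimum separation, as Gaussian
# bumps over a baseline of 1
granule_field <- function(mask, pitch, size_range, contrast) {
  n <- nrow(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(1, n, n))
  field <- matrix(1, n, n)
  area_um2 <- nrow(idx) * pitch^2
  n_blobs <- max(1L, round(area_um2 / 2)) # ~1 granule per 2 um^2
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < n_blobs && tries < 50 * n_blobs) {
    tries <- tries + 1
    cand <- idx[sample.int(nrow(idx), 1), ]
    if (nrow(centers) == 0 ||
        min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >
          (0.5 / pitch)^2) {
      centers <- rbind(centers, cand)
    }
  }
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  for (i in seq_len(nrow(centers))) {
    d_um <- stats::runif(1, size_range[1], size_range[2])
    sigma <- (d_um / pitch) / 2.355 # FWHM = granule diameter
    r2 <- (yy - centers[i, 1])^2 + (xx - centers[i, 2])^2
    field <- field + (contrast - 1) * exp(-r2 / (2 * sigma^2))
  }
  field[!mask] <- 1
  field
}

#' Render a synthetic TPE-FLIM scene
#'
#' Builds the expected per-pixel decay as the intensity-weighted
#' bi-exponential of the structure occupying the pixel (granule-textured
#' cell, elastin background, or capillary), convolves with the IRF, and
#' Poisson-samples every time channel.
#'
#' @param config a [scene_config()].
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @param poisson if `FALSE`, skip photon noise and return the noiseless
#'   expected counts (non-integer).
#' @return list with `cube` (a `decay_cube`), `truth` (data.frame of one
#'   row per placed cell: class, center, sampled parameters), and
#'   `mask` (integer matrix, 0 background / -1 capillary / cell id).
#' @export
render_scene <- function(config, seed = NULL, poisson = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$image_size
  pitch <- config$pixel_pitch
  nt <- config$n_channels
  catalogue <- cell_class_table()

  # per-pixel rate (photons / channel-sum), tau1, tau2, a1-fraction
  bg <- config$background
  tau_m_px <- matrix(rtrunc(n * n, bg$tau_m_mean, bg$tau_m_sd), n, n)
  taus <- realize_tau_pair(as.numeric(tau_m_px), bg$ratio)
  tau1_px <- matrix(taus[, "tau1"], n, n)
  tau2_px <- matrix(taus[, "tau2"], n, n)
  a1frac_px <- matrix(bg$ratio / (1 + bg$ratio), n, n)
  rate_px <- matrix(rtrunc(n * n, bg$intensity_mean, bg$intensity_sd),
                    n, n) * config$power / 49

  label <- matrix(0L, n, n)
  if (!is.null(config$capillary)) {
    cap <- config$capillary
    cmask <- disc_mask(n, rev(cap$center_um) / pitch, cap$radius_um / pitch)
    label[cmask] <- -1L
    tau1_px[cmask] <- cap$tau
    tau2_px[cmask] <- cap$tau
    a1frac_px[cmask] <- 1
    rate_px[cmask] <- cap$intensity * config$power / 49
  }

  truth <- NULL
  for (ci in seq_along(config$cells)) {
    placement <- config$cells[[ci]]
    ctx <- if (!is.null(placement$context)) placement$context else "in_vivo"
    spec <- catalogue[catalogue$class == placement$class &
                        catalogue$context == ctx, ]
    if (nrow(spec) == 0) {
      spec <- catalogue[catalogue$class == placement$class, ]
    }
    if (nrow(spec) == 0) stop("unknown cell class: ", placement$class)
    spec <- spec[1, ]
    params <- if (!is.null(placement$params)) placement$params else
      sample_cell_params(spec, 1)
    center_px <- rev(placement$center_um) / pitch # (y, x)
    radius_px <- (params$diameter / 2) / pitch
    if (any(center_px - radius_px < 1) || any(center_px + radius_px > n)) {
      stop("cell ", ci, " placed outside the field of view")
    }
    mask <- disc_mask(n, center_px, radius_px)
    if (!params$shape_flag) {
      # elongated cell: squeeze one axis to a 2:1 ellipse of equal area
      yy <- matrix(seq_len(n), n, n); xx <- t(yy)
      mask <- ((yy - center_px[1]) / (radius_px * sqrt(2)))^2 +
        ((xx - center_px[2]) / (radius_px / sqrt(2)))^2 <= 1
    }
    if (any(label[mask] != 0L)) stop("cell ", ci, " overlaps another structure")
    label[mask] <- ci
    tex <- granule_field(mask, pitch, config$granule_size_range,
                         config$granule_contrast)
    base_rate <- params$intensity * config$power / 49
    rate_cell <- base_rate * tex / mean(tex[mask])
    rate_px[mask] <- rate_cell[mask]
    tau1_px[mask] <- params$tau1
    tau2_px[mask] <- params$tau2
    a1frac_px[mask] <- params$ratio / (1 + params$ratio)
    truth <- rbind(truth, cbind(
      data.frame(cell = ci, class = placement$class,
                 center_x_um = placement$center_um[1],
                 center_y_um = placement$center_um[2],
                 area_px = sum(mask)),
      params))
  }

  # render decays: group pixels by (tau1, tau2, a1frac) to share convolutions
  key <- paste(tau1_px, tau2_px, a1frac_px)
  counts <- array(0, c(n, n, nt))
  for (px in split(seq_len(n * n), key)) {
    shape <- model_decay(a1frac_px[px[1]], tau1_px[px[1]],
                         1 - a1frac_px[px[1]], tau2_px[px[1]],
                         config$irf, nt, config$channel_width)
    shape <- shape / sum(shape)
    lam <- outer(rate_px[px], shape) # pixels x channels
    counts[cbind(rep(row(label)[px], nt), rep(col(label)[px], nt),
                 rep(seq_len(nt), each = length(px)))] <-
      if (poisson) stats::rpois(length(lam), as.numeric(lam)) else
        as.numeric(lam)
  }
  cube <- make_cube(counts, config$channel_width, config$power, config$irf,
                    pitch, config$depth,
                    if (is.null(seed)) NA_integer_ else seed)
  list(cube = cube, truth = truth, mask = label)
}
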