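#' Catalogue of dermal cell classes and their TPE-FLIM distributions
#'
#' One row per (cell class, measurement context) with the mean +/- SD of
#' the bi-exponential lifetime components (`tau1`, `tau2`, ps), amplitude
#' ratio `a1/a2`, two-photon autofluorescence intensity (photons/mW),
#' equivalent diameter (um) and the probability that the cell presents a
#' circular outline. These are the published in vitro / ex vivo / in vivo
#' population statistics for resting and activated (degranulated) mast
#' cells, IgE-sensitized mast cells, short- and long-lifetime
#' macrophages, dendritic cells, fibroblasts and neutrophils. No
#' lifetime/amplitude statistics were published for macrophages measured
#' ex vivo or in vivo, so those rows reuse the in vitro distributions.
#'
#' @return data.frame with columns `class`, `context`, `cohort`,
#'   `activation`, `n`, `tau1_mean`, `tau1_sd`, `tau2_mean`, `tau2_sd`,
#'   `ratio_mean`, `ratio_sd`, `intensity_mean`, `intensity_sd`,
#'   `diameter_mean`, `diameter_sd`, `p_circular`.
#' @export
cell_class_table <- function() {
  tab <- rbind(
    # class, context, cohort, activation, n,
    #   tau1 m/sd, tau2 m/sd, ratio m/sd, intensity m/sd, diam m/sd, p_circ
    c("resting_mc", "in_vitro", "culture", "resting", 43,
      533, 266, 2289, 317, 1.5, 0.5, 1300, 400, 10.2, 0.8, 0.9),
    c("activated_mc", "in_vitro", "culture", "activated", 13,
      288, 130, 1920, 287, 2.5, 2.0, 900, 200, 8.7, 0.4, 0.3),
    c("ige_resting_mc", "in_vitro", "culture", "resting", 14,
      412, 83, 2427, 256, 1.9, 0.3, 800, 80, 10.2, 0.8, 0.9),
    c("ige_activated_mc", "in_vitro", "culture", "activated", 15,
      217, 21, 1877, 117, 2.1, 0.6, 1000, 120, 8.7, 0.4, 0.3),
    c("macrophage_short", "in_vitro", "culture", "other", 34,
      225, 84, 1289, 278, 4.8, 3.4, 3000, 500, 12, 2, 0.6),
    c("macrophage_long", "in_vitro", "culture", "other", 20,
      1016, 220, 2432, 239, 2.6, 1.0, 800, 200, 12, 2, 0.6),
    c("dendritic", "in_vitro", "culture", "other", 14,
      434, 188, 2578, 328, 1.6, 0.2, 538, 258, 10, 1.5, 0.4),
    c("fibroblast", "in_vitro", "culture", "other", 6,
      429, 51, 1983, 137, 0.5, 0.1, 469, 137, 22, 2, 0.2),
    c("neutrophil", "in_vitro", "culture", "other", 21,
      714, 250, 1795, 600, 1.5, 0.5, 500, 115, 9, 1, 0.9),
    c("resting_mc", "ex_vivo", "biopsy", "resting", 9,
      417, 86, 2181, 166, 1.7, 1.0, 1600, 300, 8, 1, 0.1),
    c("activated_mc", "ex_vivo", "biopsy", "activated", 8,
      243, 43, 1743, 167, 2.4, 0.7, 2000, 300, 8, 1, 0.1),
    c("macrophage_short", "ex_vivo", "biopsy", "other", 3,
      225, 84, 1289, 278, 4.8, 3.4, 3000, 500, 12, 2, 0.6),
    c("macrophage_long", "ex_vivo", "biopsy", "other", 1,
      1016, 220, 2432, 239, 2.6, 1.0, 800, 200, 12, 2, 0.6),
    c("resting_mc", "in_vivo", "healthy", "resting", 71,
      344, 49, 2301, 77, 1.5, 0.3, 300, 40, 10, 1, 0.8),
    c("activated_mc", "in_vivo", "healthy", "activated", 48,
      241, 59, 1947, 230, 3.0, 1.1, 800, 100, 9, 1, 0.5),
    c("resting_mc", "in_vivo", "mastocytosis", "resting", 9,
      360, 76, 2243, 141, 1.3, 0.2, 280, 40, 10, 1, 0.8),
    c("activated_mc", "in_vivo", "mastocytosis", "activated", 3,
      173, 31, 1902, 206, 3.5, 0.8, 700, 100, 9, 1, 0.5),
    c("resting_mc", "in_vivo", "allergy", "resting", 8,
      310, 58, 2204, 103, 1.8, 0.7, 320, 120, 10, 1, 0.8),
    c("activated_mc", "in_vivo", "allergy", "activated", 9,
      185, 20, 1925, 147, 4.6, 1.1, 840, 160, 9, 1, 0.5),
    c("macrophage_short", "in_vivo", "healthy", "other", 37,
      225, 84, 1289, 278, 4.8, 3.4, 3000, 500, 12, 2, 0.6),
    c("macrophage_long", "in_vivo", "healthy", "other", 21,
      1016, 220, 2432, 239, 2.6, 1.0, 800, 200, 12, 2, 0.6)
  )
  out <- data.frame(
    class = tab[, 1], context = tab[, 2], cohort = tab[, 3],
    activation = tab[, 4],
    apply(tab[, 5:15, drop = FALSE], 2, as.numeric),
    p_circular = as.numeric(tab[, 16]),
    stringsAsFactors = FALSE
  )
  names(out) <- c("class", "context", "cohort", "activation", "n",
                  "tau1_mean", "tau1_sd", "tau2_mean", "tau2_sd",
                  "ratio_mean", "ratio_sd", "intensity_mean", "intensity_sd",
                  "diameter_mean", "diameter_sd", "p_circular")
  stopifnot(sum(out$n) == 407, all(out$tau1_mean < out$tau2_mean))
  out
}

#' Mean of a normal distribution truncated below
#'
#' Closed form `mu + sd * phi(alpha) / (1 - Phi(alpha))` with
#' `alpha = (lower - mu)/sd`; the expectation targeted by the rejection
#' sampler in [sample_cell_params()].
#'
#' @param mu,sd untruncated mean and SD.
#' @param lower truncation point (default 0).
#' @export
truncnorm_mean <- function(mu, sd, lower = 0) {
  if (sd == 0) return(mu)
  a <- (lower - mu) / sd
  mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# one draw from N(mu, sd) truncated to (lower, Inf), by rejection
rtrunc <- function(n, mu, sd, lower = 0) {
  if (sd == 0) return(rep(mu, n))
  out <- stats::rnorm(n, mu, sd)
  bad <- which(out <= lower)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mu, sd)
    bad <- bad[out[bad] <= lower]
  }
  out
}

#' Sample ground-truth cell parameters for one class
#'
#' Each parameter is drawn from an independent normal truncated at zero;
#' (`tau1`, `tau2`) pairs violating `tau1 < tau2` are redrawn. Uses the
#' current R random-number stream, so results are deterministic after
#' `set.seed()`.
#'
#' @param spec one row of [cell_class_table()] (data.frame or list).
#' @param n number of cells to draw.
#' @return data.frame with `tau1`, `tau2`, `ratio` (a1/a2), `intensity`
#'   (photons/mW), `diameter` (um) and binary `shape_flag`.
#' @export
sample_cell_params <- function(spec, n = 1) {
  num <- c("tau1_mean", "tau1_sd", "tau2_mean", "tau2_sd", "ratio_mean",
           "ratio_sd", "intensity_mean", "intensity_sd", "diameter_mean",
           "diameter_sd", "p_circular")
  v <- unlist(spec[num])
  if (any(!is.finite(v))) stop("non-finite class specification")
  if (spec$tau1_mean >= spec$tau2_mean) stop("tau1_mean must be < tau2_mean")
  tau1 <- rtrunc(n, spec$tau1_mean, spec$tau1_sd)
  tau2 <- rtrunc(n, spec$tau2_mean, spec$tau2_sd)
  bad <- which(tau1 >= tau2)
  while (length(bad)) {
    tau1[bad] <- rtrunc(length(bad), spec$tau1_mean, spec$tau1_sd)
    tau2[bad] <- rtrunc(length(bad), spec$tau2_mean, spec$tau2_sd)
    bad <- bad[tau1[bad] >= tau2[bad]]
  }
  data.frame(
    tau1 = tau1, tau2 = tau2,
    ratio = rtrunc(n, spec$ratio_mean, spec$ratio_sd),
    intensity = rtrunc(n, spec$intensity_mean, spec$intensity_sd),
    diameter = rtrunc(n, spec$diameter_mean, spec$diameter_sd),
    shape_flag = as.integer(stats::runif(n) < spec$p_circular)
  )
}

#' Generate a labeled cell cohort (feature level, no image rendering)
#'
#' Draws one record per cell from the class catalogue, synthesizes each
#' cell's noiseless 256-channel decay curve (peak-normalized,
#' IRF-convolved model of its sampled parameters) and attaches labels
#' under both schemes: `label_binary` (0 mast cell, 1 other) and
#' `label_three` (0 activated MC, 1 resting MC, 2 other). Amplitudes are
#' stored normalized to `a1 + a2 = 1`, preserving the sampled `a1/a2`.
#'
#' @param counts class catalogue with an `n` column; defaults to
#'   [cell_class_table()] whose counts reproduce the 407-cell study
#'   composition.
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @param irf `irf` used to synthesize decay curves.
#' @param n_channels,channel_width decay-curve geometry.
#' @param activated_fraction_in_vitro optional override of the fraction of
#'   activated cells among the 56 pure (non-IgE) in vitro mast cells; the
#'   default keeps the published 43 resting / 13 activated split.
#' @return data.frame of one row per cell: provenance (`class`, `context`,
#'   `cohort`, `activation`), sampled parameters, derived `a1`, `a2`,
#'   `asym`, `tau_m`, labels, and decay-curve columns `d001`..`d256`.
#' @export
generate_cohort <- function(counts = cell_class_table(), seed = NULL,
                            irf = gaussian_irf(), n_channels = 256,
                            channel_width = 12500 / 256,
                            activated_fraction_in_vitro = NULL) {
  if (!is.null(seed)) set.seed(seed)
  known <- cell_class_table()$class
  if (!all(counts$class %in% known)) {
    stop("unknown cell class: ",
         paste(setdiff(counts$class, known), collapse = ", "))
  }
  stopifnot(all(counts$n >= 0))
  if (!is.null(activated_fraction_in_vitro)) {
    i_r <- which(counts$class == "resting_mc" & counts$context == "in_vitro")
    i_a <- which(counts$class == "activated_mc" & counts$context == "in_vitro")
    tot <- counts$n[i_r] + counts$n[i_a]
    counts$n[i_a] <- round(tot * activated_fraction_in_vitro)
    counts$n[i_r] <- tot - counts$n[i_a]
  }
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    spec <- counts[i, ]
    if (spec$n == 0) return(NULL)
    p <- sample_cell_params(spec, spec$n)
    cbind(data.frame(class = spec$class, context = spec$context,
                     cohort = spec$cohort, activation = spec$activation,
                     stringsAsFactors = FALSE), p)
  })
  out <- do.call(rbind, rows)
  out$a1 <- out$ratio / (1 + out$ratio)
  out$a2 <- 1 / (1 + out$ratio)
  out$asym <- (out$a1 - out$a2) / (out$a1 + out$a2)
  out$tau_m <- mean_lifetime(out$a1, out$tau1, out$a2, out$tau2)
  out$label_binary <- ifelse(grepl("mc$", out$class), 0L, 1L)
  out$label_three <- ifelse(out$label_binary == 1L, 2L,
                            ifelse(out$activation == "activated", 0L, 1L))
  curves <- t(vapply(seq_len(nrow(out)), function(i) {
    m <- model_decay(out$a1[i], out$tau1[i], out$a2[i], out$tau2[i], irf,
                     n_channels, channel_width)
    m / max(m)
  }, numeric(n_channels)))
  colnames(curves) <- sprintf("d%03d", seq_len(n_channels))
  rownames(out) <- NULL
  cbind(out, as.data.frame(curves))
}
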