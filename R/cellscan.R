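#' Criteria of the in vivo mast-cell search cascade
#'
#' The rule set used to screen detected bright spots in the papillary
#' dermis: mast cells sit deeper than 70 um, measure about 10 um
#' (6-14 um window), are far smaller than dermal fibroblasts (> 20 um),
#' and split into a resting population (mean lifetime above 1,000 ps,
#' dim, about 300 photons/mW) and an activated/degranulated population
#' (below 800 ps, bright, about 800 photons/mW). Records between the two
#' lifetime gates are labelled `ambiguous_mc` and deferred to the
#' classifier.
#'
#' @param min_depth minimum imaging depth, um.
#' @param diameter_window admissible equivalent-diameter window, um.
#' @param resting_tau_m_min lifetime gate for resting cells, ps.
#' @param activated_tau_m_max lifetime gate for activated cells, ps.
#' @param fibroblast_exclusion_diameter hard upper size cut, um.
#' @param intensity_floor minimum mean intensity, photons/mW.
#' @export
search_criteria <- function(min_depth = 70, diameter_window = c(6, 14),
                            resting_tau_m_min = 1000,
                            activated_tau_m_max = 800,
                            fibroblast_exclusion_diameter = 20,
                            intensity_floor = 200) {
  stopifnot(activated_tau_m_max < resting_tau_m_min,
            diameter_window[1] < diameter_window[2])
  structure(list(min_depth = min_depth, diameter_window = diameter_window,
                 resting_tau_m_min = resting_tau_m_min,
                 activated_tau_m_max = activated_tau_m_max,
                 fibroblast_exclusion_diameter = fibroblast_exclusion_diameter,
                 intensity_floor = intensity_floor),
            class = "search_criteria")
}

#' Detect bright fluorescent spots in an intensity map
#'
#' Thresholds the per-mW intensity map at the robust background level
#' (median + `k` * MAD computed outside the collagen mask), labels
#' connected components, and discards components whose equivalent
#' diameter falls outside the plausible cell-size range.
#'
#' @param intensity_map matrix of photons/mW (NA allowed for masked
#'   pixels).
#' @param pixel_pitch um per pixel.
#' @param k MAD multiplier for the detection threshold (default 4).
#' @param collagen_mask optional logical matrix of SHG-positive pixels
#'   excluded from the background estimate.
#' @param size_range_um admissible equivalent-diameter range.
#' @param split_touching if `TRUE`, split merged blobs by watershed on
#'   the distance map.
#' @return list of logical masks, one per candidate.
#' @export
detect_bright_spots <- function(intensity_map, pixel_pitch, k = 4,
                                collagen_mask = NULL,
                                size_range_um = c(3, 25),
                                split_touching = FALSE) {
  bg <- intensity_map
  if (!is.null(collagen_mask)) bg[collagen_mask] <- NA
  med <- stats::median(bg, na.rm = TRUE)
  madv <- stats::mad(bg, na.rm = TRUE)
  if (!is.finite(med)) return(list())
  binary <- !is.na(intensity_map) & intensity_map > med + k * madv
  if (!any(binary)) return(list())
  m <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  # granule texture fragments dim cells: close small gaps and fill holes
  m <- EBImage::fillHull(EBImage::closing(m, EBImage::makeBrush(5, "disc")))
  m <- EBImage::imageData(m)
  labels <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(m))
  } else {
    EBImage::bwlabel(m)
  }
  labels <- EBImage::imageData(labels)
  out <- list()
  for (id in setdiff(sort(unique(as.integer(labels))), 0L)) {
    mask <- labels == id
    d_eq <- 2 * sqrt(sum(mask) / pi) * pixel_pitch
    if (d_eq >= size_range_um[1] && d_eq <= size_range_um[2]) {
      out[[length(out) + 1L]] <- mask
    }
  }
  out
}

# contour perimeter in pixels (closed polygon through boundary pixels)
mask_perimeter <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ct <- EBImage::ocontour(EBImage::Image(m))[[1]]
  d <- sqrt(rowSums((ct - ct[c(2:nrow(ct), 1), ])^2))
  sum(d)
}

#' Measure one detected cell
#'
#' Morphology (equivalent diameter, contour circularity `4*pi*A/P^2`,
#' binary shape flag at circularity 0.8), the unweighted mean of the
#' per-pixel fit parameters over the mask, the peak-normalized aggregate
#' decay curve, and the mean per-mW intensity under the 49-pixel binned
#' convention.
#'
#' @param mask logical matrix selecting the cell's pixels.
#' @param fit_maps a `fit_maps` object covering the same image.
#' @param cube the (unbinned) `decay_cube`, for the aggregate decay.
#' @param pixel_pitch um per pixel (default: from `fit_maps`).
#' @param depth imaging depth, um (default: from `cube`).
#' @return a `cell_record` list.
#' @export
measure_cell <- function(mask, fit_maps, cube, pixel_pitch = fit_maps$pixel_pitch,
                         depth = cube$depth) {
  stopifnot(any(mask))
  area_px <- sum(mask)
  d_eq <- 2 * sqrt(area_px / pi) * pixel_pitch
  perim <- mask_perimeter(mask) * pixel_pitch
  circ <- min(4 * pi * (area_px * pixel_pitch^2) / perim^2, 1)
  partial <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  ok <- mask & fit_maps$valid
  use <- if (any(ok)) ok else mask
  fit_summary <- lapply(fit_maps$maps[c("a1", "a2", "tau1", "tau2", "tau_m",
                                        "ratio", "asym")],
                        function(m) mean(m[use], na.rm = TRUE))
  curve <- apply(cube$counts, 3, function(ch) sum(ch[mask]))
  if (max(curve) > 0) curve <- curve / max(curve)
  structure(list(mask = mask, area_px = area_px,
                 equivalent_diameter = d_eq, circularity = circ,
                 shape_flag = as.integer(circ >= 0.8),
                 mean_intensity = mean(fit_maps$maps$intensity[mask],
                                       na.rm = TRUE),
                 fit_summary = fit_summary, decay_curve = curve,
                 depth = depth, partial = partial),
            class = "cell_record")
}

#' Rule-based mast-cell search label
#'
#' Deterministic cascade over one measured cell: reject shallow records
#' (above the papillary dermis), fibroblast-sized and out-of-window
#' cells, and dim records; then gate on the mean lifetime — above
#' 1,000 ps is a resting MC, below 800 ps an activated MC, and the
#' 800-1,000 ps gap is returned as `ambiguous_mc` for the classifier.
#'
#' @param record a `cell_record` (or any list with `depth`,
#'   `equivalent_diameter`, `mean_intensity` and `fit_summary$tau_m`).
#' @param criteria a [search_criteria()].
#' @return one of `"resting_mc"`, `"activated_mc"`, `"ambiguous_mc"`,
#'   `"not_mc"`.
#' @export
mc_search <- function(record, criteria = search_criteria()) {
  if (is.na(record$depth) || record$depth < criteria$min_depth) return("not_mc")
  d <- record$equivalent_diameter
  if (d > criteria$fibroblast_exclusion_diameter) return("not_mc")
  if (d < criteria$diameter_window[1] || d > criteria$diameter_window[2]) {
    return("not_mc")
  }
  if (record$mean_intensity < criteria$intensity_floor) return("not_mc")
  tau_m <- record$fit_summary$tau_m
  if (is.na(tau_m)) return("ambiguous_mc")
  if (tau_m > criteria$resting_tau_m_min) return("resting_mc")
  if (tau_m < criteria$activated_tau_m_max) return("activated_mc")
  "ambiguous_mc"
}
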