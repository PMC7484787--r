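#' Write a decay cube as multi-page TIFF + JSON sidecar
#'
#' One 16-bit grayscale page per time channel, plus `<path>.json`
#' holding the acquisition metadata (channel width, power, pixel pitch,
#' depth, seed, IRF kernel). Round-trip lossless for integer counts up
#' to 65535.
#'
#' @param cube a `decay_cube`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "decay_cube"))
  nt <- dim(cube$counts)[3]
  if (max(cube$counts) > 65535) stop("counts exceed 16-bit range")
  pages <- lapply(seq_len(nt), function(k) cube$counts[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(n_channels = nt, channel_width = cube$channel_width,
               power = cube$power, pixel_pitch = cube$pixel_pitch,
               depth = cube$depth, seed = cube$seed,
               irf_kernel = cube$irf$kernel,
               irf_peak_channel = cube$irf$peak_channel)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a decay cube written by [write_cube()]
#'
#' @param path TIFF path; `<path>.json` must exist.
#' @return a `decay_cube`.
#' @export
read_cube <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("format error: missing sidecar ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  required <- c("n_channels", "channel_width", "power", "pixel_pitch",
                "irf_kernel", "irf_peak_channel")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("format error: sidecar missing field(s) ",
         paste(missing, collapse = ", "))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_channels) {
    stop("format error: n_channels declares ", meta$n_channels,
         " but TIFF has ", length(pages), " pages")
  }
  counts <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) counts[, , k] <- round(pages[[k]] * 65535)
  make_cube(counts, meta$channel_width, meta$power,
            new_irf(meta$irf_kernel, meta$irf_peak_channel),
            meta$pixel_pitch,
            if (is.null(meta$depth)) NA_real_ else meta$depth,
            if (is.null(meta$seed) || is.na(meta$seed)) NA_integer_ else
              meta$seed)
}

#' Write / read a labeled cohort as CSV
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
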