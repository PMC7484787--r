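#' Assemble the 265-dimensional feature vector of one cell
#'
#' Fixed order: circular-form flag (1), normalized intensity (1; the
#' per-pixel mean of the 49-pixel binned photons/mW intensity, i.e.
#' already normalized by cell area and excitation power), the
#' peak-normalized 256-channel decay curve, then the seven decay
#' parameters `tau1, tau2, tau_m, a1, a2, a1/a2, (a1-a2)/(a1+a2)` —
#' 265 values in total. Cell size is deliberately not a feature.
#'
#' @param record a `cell_record` (from [measure_cell()]) or a one-row
#'   data.frame from [generate_cohort()].
#' @return numeric vector of length 265.
#' @export
build_features <- function(record) {
  if (inherits(record, "cell_record")) {
    fs <- record$fit_summary
    if (any(!is.finite(unlist(fs)))) stop("record has no valid decay fit")
    c(record$shape_flag, record$mean_intensity, record$decay_curve,
      fs$tau1, fs$tau2, fs$tau_m, fs$a1, fs$a2, fs$ratio, fs$asym)
  } else {
    stopifnot(is.data.frame(record), nrow(record) == 1)
    curve <- as.numeric(record[, grep("^d\\d{3}$", names(record))])
    stopifnot(length(curve) == 256)
    as.numeric(c(record$shape_flag, record$intensity, curve,
                 record$tau1, record$tau2, record$tau_m,
                 record$a1, record$a2, record$ratio, record$asym))
  }
}

#' Feature matrix of a generated cohort
#'
#' @param cohort data.frame from [generate_cohort()].
#' @return numeric matrix, one 265-column row per cell.
#' @export
cohort_features <- function(cohort) {
  curve_cols <- grep("^d\\d{3}$", names(cohort))
  X <- as.matrix(cbind(cohort$shape_flag, cohort$intensity,
                       cohort[, curve_cols],
                       cohort$tau1, cohort$tau2, cohort$tau_m,
                       cohort$a1, cohort$a2, cohort$ratio, cohort$asym))
  dimnames(X) <- NULL
  stopifnot(ncol(X) == 265)
  X
}
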