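#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |F_x - F_y|` over the pooled sample with the asymptotic
#' Kolmogorov p-value at the effective sample size `n*m/(n+m)`.
#' Asymptotic p-values are approximate below roughly 10 observations per
#' group.
#'
#' @param x,y numeric samples, each with at least 2 observations.
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("both samples need at least 2 observations")
  }
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Compare a decay parameter between two cohort groups
#'
#' Mean +/- SD per group plus the two-sample KS test, flagged at the
#' 0.05 significance level. No multiple-testing correction is applied
#' (the number of flags is reported so callers can correct themselves).
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param parameter one of `tau1, tau2, tau_m, ratio, asym, intensity`.
#' @param group_a,group_b values of `by` selecting the two groups.
#' @param by grouping column (default `"class"`).
#' @return data.frame with group summaries, `D`, `p` and `significant`.
#' @export
population_compare <- function(cohort, parameter, group_a, group_b,
                               by = "class") {
  ok <- c("tau1", "tau2", "tau_m", "ratio", "asym", "intensity")
  if (!parameter %in% ok) {
    stop("unknown parameter '", parameter, "'; expected one of ",
         paste(ok, collapse = ", "))
  }
  a <- cohort[[parameter]][cohort[[by]] == group_a]
  b <- cohort[[parameter]][cohort[[by]] == group_b]
  if (length(a) == 0 || length(b) == 0) stop("empty comparison group")
  ks <- ks_two_sample(a, b)
  data.frame(parameter = parameter, group_a = group_a, group_b = group_b,
             n_a = length(a), mean_a = mean(a), sd_a = stats::sd(a),
             n_b = length(b), mean_b = mean(b), sd_b = stats::sd(b),
             D = ks$D, p = ks$p, significant = ks$p < 0.05)
}

#' Two-dimensional segmentation scatter of decay parameters
#'
#' Exports grouped coordinates plus per-group centroids and covariance
#' for the parameter pairs used for 2-D segmentation of cell types
#' (`tau1 x tau2`, `tau1 x ratio`, `tau2 x ratio`, `tau2 x asym`). Pure
#' bookkeeping: no decision logic.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param pair one of `"tau1-tau2"`, `"tau1-ratio"`, `"tau2-ratio"`,
#'   `"tau2-asym"`.
#' @param by grouping column (default `"class"`).
#' @return list with `points` (group, x, y) and `groups` (centroids,
#'   covariance entries, n); groups absent from the cohort yield no rows.
#' @export
segmentation_scatter <- function(cohort, pair = c("tau1-tau2", "tau1-ratio",
                                                  "tau2-ratio", "tau2-asym"),
                                 by = "class") {
  pair <- match.arg(pair)
  vars <- strsplit(pair, "-")[[1]]
  stopifnot(nrow(cohort) > 0)
  pts <- data.frame(group = cohort[[by]],
                    x = cohort[[vars[1]]], y = cohort[[vars[2]]])
  groups <- do.call(rbind, lapply(split(pts, pts$group), function(g) {
    cv <- if (nrow(g) > 1) stats::cov(cbind(g$x, g$y)) else
      matrix(NA_real_, 2, 2)
    data.frame(group = g$group[1], n = nrow(g),
               x_mean = mean(g$x), y_mean = mean(g$y),
               x_var = cv[1, 1], y_var = cv[2, 2], xy_cov = cv[1, 2])
  }))
  rownames(groups) <- NULL
  list(points = pts, groups = groups, pair = pair)
}
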