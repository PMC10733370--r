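#' Cortical plasticity index
#'
#' Normalized pre/post change of a neuron's response amplitude:
#' `PI = (R_post - R_pre) / (R_post + R_pre)`, in [-1, 1] when both
#' amplitudes are nonnegative. Related to the fractional change by
#' `PI = dR / (dR + 2)`.
#'
#' @param r_pre,r_post Response amplitudes before and after induction.
#' @return Dimensionless index.
#' @export
plasticity_index <- function(r_pre, r_post) {
  if (any(r_pre + r_post == 0)) stop("R_pre + R_post = 0; PI undefined")
  (r_post - r_pre) / (r_post + r_pre)
}

#' Cortical plasticity strength
#'
#' Fractional response change to the probe direction (temporo-nasal by
#' convention): `dR = (R_post - R_pre) / R_pre`.
#'
#' @param r_pre Pre-induction amplitude (> 0).
#' @param r_post Post-induction amplitude.
#' @return Dimensionless fractional change.
#' @export
plasticity_strength <- function(r_pre, r_post) {
  if (any(r_pre <= 0)) stop("r_pre must be > 0")
  (r_post - r_pre) / r_pre
}

#' Group-wise plasticity strength
#'
#' Categorizes neurons by their sampled preferred direction and averages
#' the plasticity strength dR within each group. Groups are keyed by
#' direction (0, 90, 180, 270 for the four-direction protocol, aliased
#' TN, UP, NT, DN). Empty groups are reported as missing (NA), not zero.
#'
#' @param records Data frame with columns `group` (direction in degrees
#'   or one of "TN", "UP", "NT", "DN"), `r_pre`, `r_post`.
#' @param groups Group labels expected in the output; defaults to the
#'   levels present plus any of the four cardinal groups.
#' @return Data frame `group`, `n`, `delta_r_mean`, `delta_r_sem`.
#' @export
group_plasticity_strength <- function(records,
                                      groups = unique(records$group)) {
  dr <- plasticity_strength(records$r_pre, records$r_post)
  out <- lapply(groups, function(g) {
    x <- dr[records$group == g]
    data.frame(group = g, n = length(x),
               delta_r_mean = if (length(x)) mean(x) else NA_real_,
               delta_r_sem = if (length(x) > 1)
                 stats::sd(x) / sqrt(length(x)) else NA_real_)
  })
  do.call(rbind, out)
}

#' Canonical direction-group labels
#'
#' Maps sampled preferred directions in the four-direction protocol to
#' the group labels TN (0, temporo-nasal), UP (90), NT (180,
#' naso-temporal), DN (270).
#'
#' @param sampled_pref_deg Sampled preferred directions in degrees.
#' @return Character vector of group labels.
#' @export
direction_group <- function(sampled_pref_deg) {
  cardinal <- c(0, 90, 180, 270)
  labels <- c("TN", "UP", "NT", "DN")
  idx <- vapply(sampled_pref_deg, function(d)
    which.min(circ_dist(cardinal, d)), integer(1))
  labels[idx]
}

#' Regression of behavioral potentiation on cortical plasticity
#'
#' Fits a line to per-recording pairs of mean plasticity index (x) and
#' OKR potentiation (y) by either of two objectives: `gaussian_mle`,
#' the closed-form least-squares line (maximum likelihood under
#' Gaussian residuals), or `min_vertical_distance`, the line minimizing
#' the summed absolute vertical distances of the points to the line
#' (derivative-free Nelder-Mead started at the least-squares solution).
#' R-squared is `1 - SS_res / SS_tot` under the fitted line.
#'
#' @param x,y Numeric vectors (>= 3 points; x must vary).
#' @param method "gaussian_mle" or "min_vertical_distance".
#' @return List with `slope`, `intercept`, `r_squared`, `method`.
#' @export
fit_potentiation_vs_plasticity <- function(x, y,
    method = c("gaussian_mle", "min_vertical_distance")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("x has zero variance; no fit")

  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  if (method == "min_vertical_distance") {
    obj <- function(p) sum(abs(y - p[1L] - p[2L] * x))
    fit <- stats::optim(c(intercept, slope), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 5000))
    intercept <- fit$par[1L]
    slope <- fit$par[2L]
  }
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r_squared = 1 - ss_res / ss_tot, method = method)
}
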