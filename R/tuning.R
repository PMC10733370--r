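#' Orientation selectivity index
#'
#' Vector-sum magnitude on the orientation circle:
#' `OSI = |sum R exp(2 i rho)| / sum R` over rectified (negative values
#' clipped to zero) responses. This is the estimator whose argument
#' gives the preferred orientation, so the same quantity gates which
#' preferred-direction rule applies.
#'
#' @param R Response amplitudes per direction.
#' @param directions_deg Stimulus directions in degrees.
#' @return OSI in [0, 1].
#' @export
osi <- function(R, directions_deg) {
  r <- pmax(R, 0)
  if (sum(r) == 0) stop("all responses are zero; OSI undefined")
  rad <- directions_deg * pi / 180
  Mod(sum(r * exp(2i * rad))) / sum(r)
}

#' Preferred direction by response-weighted vector summation
#'
#' For orientation-selective neurons (OSI >= `osi_threshold`) the
#' preferred orientation is the argument of the response-weighted vector
#' sum on the doubled circle, `theta_pref = arg(sum R exp(2 i rho)) / 2`;
#' the preferred direction is then the direction along the nearest
#' sampled orientation that evoked the stronger response. For
#' non-orientation-selective neurons the preferred direction is the
#' argument of the vector sum on the direction circle,
#' `rho_pref = arg(sum R exp(i rho))`, and the sampled preferred
#' direction is the nearest sampled direction. Negative responses are
#' clipped to zero inside the vector sums (their arguments are unstable
#' under sign flips); the DSI keeps signed responses.
#'
#' @param R Response amplitudes per direction (may be negative).
#' @param directions_deg Evenly spaced directions spanning 360 degrees.
#' @param osi_threshold OSI gate, default 0.1.
#' @param dsi_threshold Direction-selectivity gate, default 0.33 (the
#'   preferred response is more than double the null response).
#' @return A `direction_preference` list: `theta_pref_deg` (orientation,
#'   or NA), `rho_pref_deg` (direction, or NA), `sampled_pref_deg`,
#'   `osi`, `dsi`, `is_orientation_selective`, `is_direction_selective`.
#' @export
preferred_direction <- function(R, directions_deg, osi_threshold = 0.1,
                                dsi_threshold = 0.33) {
  stopifnot(length(R) == length(directions_deg))
  r <- pmax(R, 0)
  if (sum(r) == 0) stop("all responses are zero; preference undefined")
  rad <- directions_deg * pi / 180
  o <- osi(R, directions_deg)

  theta_pref <- rho_pref <- NA_real_
  if (o >= osi_threshold) {
    theta_pref <- (Arg(sum(r * exp(2i * rad))) * 180 / pi / 2) %% 180
    if (theta_pref >= 180 - 1e-9) theta_pref <- 0
    oris <- sort(unique(directions_deg %% 180))
    near <- oris[which.min(circ_dist(oris, theta_pref, period = 180))]
    cand <- directions_deg[directions_deg %% 180 == near]
    sampled <- cand[which.max(R[match(cand, directions_deg)])]
  } else {
    rho_pref <- (Arg(sum(r * exp(1i * rad))) * 180 / pi) %% 360
    if (rho_pref >= 360 - 1e-9) rho_pref <- 0
    sampled <- directions_deg[which.min(circ_dist(directions_deg,
                                                  rho_pref))]
  }

  null_dir <- (sampled + 180) %% 360
  i_pref <- match(sampled %% 360, directions_deg %% 360)
  i_null <- match(null_dir, directions_deg %% 360)
  d <- if (is.na(i_null)) NA_real_ else dsi(R[i_pref], R[i_null])

  structure(
    list(theta_pref_deg = theta_pref, rho_pref_deg = rho_pref,
         sampled_pref_deg = sampled, osi = o, dsi = d,
         is_orientation_selective = o >= osi_threshold,
         is_direction_selective = !is.na(d) && d >= dsi_threshold),
    class = "direction_preference")
}

circ_dist <- function(a, b, period = 360) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

#' Direction selectivity index
#'
#' `DSI = (R_pref - R_null) / (|R_pref| + |R_null|)`. The absolute
#' values in the denominator keep the index defined when visually driven
#' activity is negative. A DSI of 1/3 corresponds to a preferred
#' response exactly double the null response (both nonnegative). For
#' spiking data, evoked (baseline-subtracted) firing rates are used.
#'
#' @param r_pref Response to the sampled preferred direction.
#' @param r_null Response to the opposite direction.
#' @return DSI in [-1, 1] for nonnegative inputs.
#' @export
dsi <- function(r_pref, r_null) {
  denom <- abs(r_pref) + abs(r_null)
  if (any(denom == 0)) stop("R_pref = R_null = 0; DSI undefined")
  (r_pref - r_null) / denom
}

#' Spatial- or temporal-frequency selectivity
#'
#' The preferred frequency maximizes the response amplitude; the
#' selectivity is `(R_pref - R_base) / (R_pref + R_base)` where `R_base`
#' is the average of the two minimum response amplitudes. Lies in
#' [0, 1] whenever all amplitudes are nonnegative.
#'
#' @param values Sampled SF (cycles/degree) or TF (Hz) values (>= 3).
#' @param R Response amplitudes.
#' @return List with `preferred` and `selectivity`.
#' @export
sf_tf_selectivity <- function(values, R) {
  stopifnot(length(values) == length(R))
  if (length(R) < 3L) stop("need at least 3 sampled frequencies")
  i <- which.max(R)
  r_base <- mean(sort(R)[1:2])
  if (R[i] + r_base == 0) stop("selectivity undefined (zero denominator)")
  list(preferred = values[i],
       selectivity = (R[i] - r_base) / (R[i] + r_base))
}
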