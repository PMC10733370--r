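#' Reference population compositions and plasticity maps
#'
#' Four-group direction compositions and plasticity-strength maps that
#' emulate the two corticofugal populations of the study system. The
#' NOT-DTN-projecting population is enriched for the temporo-nasal
#' direction (27% of neurons in the TN bin of the eight-direction
#' histogram vs 8-14% elsewhere; collapsing diagonal bins onto the
#' nearest cardinal gives the four-group fractions used here), while the
#' midbrain-projecting population is nearly flat (13% TN vs 10-15%).
#'
#' The plasticity maps are derived from the reported group plasticity
#' indices of temporo-nasally evoked activity after OKR potentiation,
#' converted from PI to the fractional change dR via
#' `dR = 2 PI / (1 - PI)`: NOT-DTN-projecting PI = 0.29 (TN-biased) vs
#' 0.07 (NT-biased) and about -0.06 for vertically biased neurons;
#' midbrain-projecting PI = 0.19 vs 0.18, with the vertical groups set
#' between those weakly differentiated values.
#'
#' @return Named numeric vector over the groups TN, UP, NT, DN.
#' @name reference_populations
NULL

pi_to_dr <- function(pi_val) 2 * pi_val / (1 - pi_val)

#' @rdname reference_populations
#' @export
notdtn_composition <- function() {
  c(TN = 0.38, UP = 0.20, NT = 0.18, DN = 0.24)
}

#' @rdname reference_populations
#' @export
midbrain_composition <- function() {
  c(TN = 0.26, UP = 0.25, NT = 0.24, DN = 0.25)
}

#' @rdname reference_populations
#' @export
notdtn_plasticity <- function() {
  c(TN = pi_to_dr(0.29), UP = pi_to_dr(-0.06),
    NT = pi_to_dr(0.07), DN = pi_to_dr(-0.06))
}

#' @rdname reference_populations
#' @export
midbrain_plasticity <- function() {
  c(TN = pi_to_dr(0.19), UP = pi_to_dr(0.15),
    NT = pi_to_dr(0.18), DN = pi_to_dr(0.15))
}
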