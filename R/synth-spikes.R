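#' Generate a synthetic spiking unit
#'
#' Simulates trial-structured Poisson spiking of a direction-tuned unit
#' (homogeneous within the baseline / stimulation / post windows, tuned
#' via the same double von Mises shape as the calcium generator), and
#' optionally an optogenetic-tagging session in which each light pulse
#' evokes one near-deterministic antidromic spike at a fixed latency
#' with Gaussian jitter, superimposed on spontaneous firing.
#'
#' @param pref_direction_deg Preferred direction in degrees.
#' @param peak_rate_hz Peak evoked rate above baseline at the preferred
#'   direction (>= 0).
#' @param baseline_hz Spontaneous rate (>= 0).
#' @param directions Stimulus directions.
#' @param n_trials Trials per direction.
#' @param pre_s,stim_s,post_s Trial structure in seconds.
#' @param tuning_width_deg,dir_null_ratio Tuning parameters (see
#'   [tuning_shape()]).
#' @param antidromic `NULL`, or a list with `latency_ms`, `jitter_ms`,
#'   `n_pulses` (and optionally `pulse_rate_hz`, default 5, and
#'   `reliability`, default 1).
#' @param seed Integer seed.
#' @return A `unit_recording` list: `spikes` (data frame `direction_deg`,
#'   `trial`, `spike_time_s`), window durations, and if requested an
#'   `antidromic` element with `pulse_times_s` and `spike_times_s`.
#' @export
gen_spike_unit <- function(pref_direction_deg = 0, peak_rate_hz = 20,
                           baseline_hz = 4,
                           directions = seq(0, 330, by = 30),
                           n_trials = 25, pre_s = 1, stim_s = 2,
                           post_s = 1, tuning_width_deg = 30,
                           dir_null_ratio = 0.4, antidromic = NULL,
                           seed = 1L) {
  if (peak_rate_hz < 0 || baseline_hz < 0) stop("rates must be >= 0")
  set.seed(seed)
  shape <- neuron_spec(pref_direction_deg, tuning_width_deg, 1,
                       dir_null_ratio)

  draw <- function(rate, t0, t1) {
    n <- stats::rpois(1L, rate * (t1 - t0))
    if (n == 0) numeric(0) else sort(stats::runif(n, t0, t1))
  }
  rows <- list()
  for (d in directions) {
    stim_rate <- baseline_hz + peak_rate_hz * tuning_shape(d, shape)
    for (tr in seq_len(n_trials)) {
      st <- c(draw(baseline_hz, 0, pre_s),
              draw(stim_rate, pre_s, pre_s + stim_s),
              draw(baseline_hz, pre_s + stim_s, pre_s + stim_s + post_s))
      if (length(st))
        rows[[length(rows) + 1L]] <- data.frame(
          direction_deg = d, trial = tr, spike_time_s = st)
    }
  }
  spikes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction_deg = numeric(0), trial = integer(0),
               spike_time_s = numeric(0))

  out <- list(spikes = spikes, directions = directions,
              n_trials = n_trials, pre_s = pre_s, stim_s = stim_s,
              post_s = post_s,
              ground_truth = list(pref_direction_deg = pref_direction_deg,
                                  peak_rate_hz = peak_rate_hz,
                                  baseline_hz = baseline_hz,
                                  dir_null_ratio = dir_null_ratio,
                                  seed = seed))
  if (!is.null(antidromic)) {
    pr <- if (is.null(antidromic$pulse_rate_hz)) 5 else
      antidromic$pulse_rate_hz
    rel <- if (is.null(antidromic$reliability)) 1 else
      antidromic$reliability
    np <- antidromic$n_pulses
    pulses <- (seq_len(np) - 1L) / pr + 0.5
    evoked <- pulses + antidromic$latency_ms / 1000 +
      stats::rnorm(np, 0, antidromic$jitter_ms / 1000)
    evoked <- evoked[stats::runif(np) <= rel]
    total <- max(pulses) + 0.5
    spont <- draw(baseline_hz, 0, total)
    out$antidromic <- list(
      pulse_times_s = pulses,
      spike_times_s = sort(c(evoked, spont)),
      ground_truth = list(latency_ms = antidromic$latency_ms,
                          jitter_ms = antidromic$jitter_ms))
  }
  class(out) <- "unit_recording"
  out
}

#' Generate a spatial cell map with area-dependent density
#'
#' Homogeneous spatial Poisson point process within each of a set of
#' non-overlapping polygons (one per labelled cortical area), with a
#' stated intensity per area. Points are drawn by rejection sampling in
#' each polygon's bounding box.
#'
#' @param area_polygons Named list of data frames with columns `x_um`,
#'   `y_um` tracing each (non-overlapping) area outline.
#' @param per_area_density Named vector, cells per square micron,
#'   aligned with `area_polygons`.
#' @param seed Integer seed.
#' @return A `cell_map` data frame (`x_um`, `y_um`, `area`) with a
#'   `ground_truth` attribute holding the polygons and intensities.
#' @export
gen_cell_map <- function(area_polygons, per_area_density, seed = 1L) {
  set.seed(seed)
  nms <- names(area_polygons)
  rows <- list()
  for (a in nms) {
    poly <- area_polygons[[a]]
    area <- polygon_area(poly$x_um, poly$y_um)
    if (area <= 1e-12) stop("zero-area polygon: ", a)
    lambda <- per_area_density[[a]]
    n <- stats::rpois(1L, lambda * area)
    if (n == 0) next
    pts <- matrix(NA_real_, 0, 2)
    bbx <- range(poly$x_um); bby <- range(poly$y_um)
    while (nrow(pts) < n) {
      m <- 2L * (n - nrow(pts)) + 10L
      cand <- cbind(stats::runif(m, bbx[1], bbx[2]),
                    stats::runif(m, bby[1], bby[2]))
      keep <- point_in_polygon(cand[, 1], cand[, 2], poly$x_um, poly$y_um)
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    rows[[a]] <- data.frame(x_um = pts[, 1], y_um = pts[, 2], area = a)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x_um = numeric(0), y_um = numeric(0), area = character(0))
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(polygons = area_polygons,
                                    density = per_area_density,
                                    seed = seed)
  class(out) <- c("cell_map", "data.frame")
  out
}

# shoelace formula
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# even-odd ray casting
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
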