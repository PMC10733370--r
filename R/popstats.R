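#' Randomization test for direction-preference bias
#'
#' One-sided test of whether the focal bin of a preferred-direction
#' histogram holds more neurons than expected by chance. The null
#' assigns the `n_total` neurons uniformly at random to the bins
#' (uniform multinomial); the statistic is the count in the focal bin,
#' and the p-value is `(1 + #{null >= observed}) / (1 + n_permutations)`,
#' so the reported floor is `1 / (n_permutations + 1)`. The exact null
#' tail of the focal-bin count is Binomial(n_total, 1/n_bins) and is
#' returned alongside for reference.
#'
#' @param counts Integer histogram counts per bin.
#' @param focal_bin Index of the focal (for example temporo-nasal) bin.
#' @param n_permutations Number of null draws, default 10000.
#' @param seed Integer seed.
#' @return List with `p_value`, `exact_p` (binomial tail), `observed`,
#'   `n_total`, `n_permutations`.
#' @export
direction_bias_test <- function(counts, focal_bin = 1L,
                                n_permutations = 10000L, seed = 1L) {
  k <- length(counts)
  if (focal_bin < 1L || focal_bin > k) stop("focal_bin not in histogram")
  n <- sum(counts)
  if (n < 1L) stop("empty histogram")
  obs <- counts[focal_bin]
  set.seed(seed)
  null_counts <- stats::rmultinom(n_permutations, n,
                                  rep(1 / k, k))[focal_bin, ]
  p <- (1 + sum(null_counts >= obs)) / (1 + n_permutations)
  list(p_value = p,
       exact_p = stats::pbinom(obs - 1L, n, 1 / k, lower.tail = FALSE),
       observed = obs, n_total = n, n_permutations = n_permutations)
}

#' Volumetric cell density per area
#'
#' Number of labelled neurons in each area divided by the area's volume.
#' Areas listed in `volumes` but empty of points report density 0.
#'
#' @param map A `cell_map` data frame with an `area` column.
#' @param volumes Named vector of area volumes (e.g. cubic microns).
#' @return Data frame `area`, `n`, `density`.
#' @export
volumetric_density <- function(map, volumes) {
  if (any(volumes <= 0)) stop("volumes must be > 0")
  n <- vapply(names(volumes), function(a) sum(map$area == a), numeric(1))
  data.frame(area = names(volumes), n = n,
             density = n / as.numeric(volumes), row.names = NULL)
}

#' Area-density grid of a cell map
#'
#' Divides the plane into `grid_um` x `grid_um` squares (100 um default)
#' and computes the per-square area density (cells per square micron).
#' Square membership is half-open, `[x, x + grid_um)`, so a point on a
#' boundary belongs to the higher square.
#'
#' @param map A `cell_map` with `x_um`, `y_um`.
#' @param grid_um Square side in microns, default 100.
#' @param origin Lower-left corner of the grid, default snapped to
#'   `grid_um` below the data extent.
#' @param dims Optional `c(nx, ny)` forcing the grid dimensions.
#' @return A `density_grid` list: `origin_um`, `cell_um`, `counts`
#'   (nx x ny matrix), `density`.
#' @export
area_density_grid <- function(map, grid_um = 100, origin = NULL,
                              dims = NULL) {
  if (nrow(map) == 0 && is.null(origin))
    stop("empty map and no origin given")
  if (is.null(origin))
    origin <- c(floor(min(map$x_um) / grid_um),
                floor(min(map$y_um) / grid_um)) * grid_um
  ix <- floor((map$x_um - origin[1L]) / grid_um) + 1L
  iy <- floor((map$y_um - origin[2L]) / grid_um) + 1L
  if (is.null(dims)) dims <- c(max(ix, 1L), max(iy, 1L))
  counts <- matrix(0L, dims[1L], dims[2L])
  ok <- ix >= 1L & ix <= dims[1L] & iy >= 1L & iy <= dims[2L]
  for (j in which(ok))
    counts[ix[j], iy[j]] <- counts[ix[j], iy[j]] + 1L
  structure(
    list(origin_um = origin, cell_um = grid_um, counts = counts,
         density = counts / grid_um^2),
    class = "density_grid")
}

#' Per-square density ratio of two grids
#'
#' Elementwise ratio of two aligned density grids (for example
#' NOT-DTN-projecting over midbrain-projecting neuron density). Squares
#' where the denominator is zero are flagged undefined (NA), not
#' infinite.
#'
#' @param grid_a,grid_b Two [area_density_grid()] results with matching
#'   origin, cell size and dimensions.
#' @return List with `ratio` matrix and logical `undefined` mask.
#' @export
density_ratio <- function(grid_a, grid_b) {
  if (!identical(dim(grid_a$density), dim(grid_b$density)) ||
      any(grid_a$origin_um != grid_b$origin_um) ||
      grid_a$cell_um != grid_b$cell_um)
    stop("grids are not aligned")
  undef <- grid_b$density == 0
  ratio <- grid_a$density / grid_b$density
  ratio[undef] <- NA_real_
  list(ratio = ratio, undefined = undef)
}
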