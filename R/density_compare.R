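# Kernel-density comparison of log(delta) distributions across contexts.
#
# Each analysis cell (context x guild class) contributes a cloud of
# log(delta) values, one per stratum.  A Gaussian-kernel density estimate of
# that cloud is the visual object compared between contexts: a curve
# centred at 0 means diversity as expected from abundance; a curve shifted
# left means many strata are under-diversified.

#' Gaussian kernel density of log(delta) values
#'
#' @param log_deltas Numeric vector of at least 2 finite values.
#' @param bandwidth Kernel bandwidth; `"silverman"` (the default) uses
#'   Silverman's rule of thumb, or supply a positive number.
#' @param grid Optional vector of evaluation points.  By default, 512
#'   evenly spaced points spanning the data range extended by 3 bandwidths
#'   on each side.
#' @param n_grid Grid size when `grid` is not supplied; default 512.
#' @return data.frame of class `density_curve` with columns `x` and
#'   `density`; the trapezoidal integral over the grid is 1 within 1e-3.
#'   The input sample, bandwidth and sample size are kept as attributes
#'   `samples`, `bandwidth`, `n`.
#' @export
delta_density <- function(log_deltas, bandwidth = "silverman",
                          grid = NULL, n_grid = 512L) {
  x <- log_deltas[is.finite(log_deltas)]
  if (length(x) < 2L)
    stop("need at least 2 finite values for a density estimate",
         call. = FALSE)
  if (identical(bandwidth, "silverman")) {
    if (stats::sd(x) == 0)
      stop("zero variance: supply an explicit bandwidth", call. = FALSE)
    bandwidth <- stats::bw.nrd0(x)
  }
  stopifnot(is.numeric(bandwidth), bandwidth > 0)
  if (is.null(grid))
    grid <- seq(min(x) - 3 * bandwidth, max(x) + 3 * bandwidth,
                length.out = n_grid)
  dens <- vapply(grid, function(g)
    mean(stats::dnorm(g, mean = x, sd = bandwidth)), numeric(1L))
  # renormalize so the trapezoidal integral over the (finite) grid is 1:
  # the grid truncates the kernels' far tails
  dx <- diff(grid)
  integral <- sum(dx * (dens[-1L] + dens[-length(dens)]) / 2)
  dens <- dens / integral
  out <- data.frame(x = grid, density = dens)
  class(out) <- c("density_curve", "data.frame")
  attr(out, "samples") <- x
  attr(out, "bandwidth") <- bandwidth
  attr(out, "n") <- length(x)
  out
}

#' Density curves per context and guild class
#'
#' @param scores Guild scores (see [score_strata()]) with `log_delta`,
#'   `context` and a gene column mapped through `guilds`.
#' @param guilds Marker registry for the guild-class split; defaults to
#'   [n_cycle_markers()].  Pass `NULL` to pool all genes into one class
#'   `"all"`.
#' @param ... Passed to [delta_density()].
#' @return Named list of `density_curve` objects, names
#'   `"<context>|<guild_class>"`.
#' @export
delta_densities <- function(scores, guilds = n_cycle_markers(), ...) {
  cls <- if (is.null(guilds)) rep("all", nrow(scores)) else
    guild_class_of(scores$gene, guilds)
  key <- paste(scores$context, cls, sep = "|")
  out <- lapply(split(scores$log_delta, key), delta_density, ...)
  out
}

#' Compare two delta density curves
#'
#' Quantifies the displacement of curve `a` relative to curve `b`: the
#' difference of the curves' modes, the difference of the underlying sample
#' means, and a sign label.  `"centered"` is returned when the mode shift is
#' within a dead-band around 0 (a presentation convention, not a test).
#'
#' @param curve_a,curve_b `density_curve` objects on a common grid.
#' @param dead_band Half-width of the centred band on the natural-log
#'   scale; default 0.1.
#' @return list with `mode_shift`, `mean_shift`, `label` (one of
#'   `"left_shift"`, `"right_shift"`, `"centered"`).
#' @export
compare_densities <- function(curve_a, curve_b, dead_band = 0.1) {
  if (nrow(curve_a) != nrow(curve_b) ||
      max(abs(curve_a$x - curve_b$x)) > 1e-9)
    stop("density curves are not on a common grid", call. = FALSE)
  mode_a <- curve_a$x[which.max(curve_a$density)]
  mode_b <- curve_b$x[which.max(curve_b$density)]
  mode_shift <- mode_a - mode_b
  mean_shift <- mean(attr(curve_a, "samples")) -
    mean(attr(curve_b, "samples"))
  label <- if (abs(mode_shift) < dead_band) "centered"
    else if (mode_shift < 0) "left_shift" else "right_shift"
  list(mode_shift = mode_shift, mean_shift = mean_shift, label = label)
}

#' Evaluate two samples' densities on a shared grid
#'
#' Convenience wrapper for [compare_densities()]: estimates both densities
#' on one grid spanning the union of the two samples.
#'
#' @param log_deltas_a,log_deltas_b The two samples.
#' @param ... Passed to [delta_density()] (e.g. `bandwidth`).
#' @param n_grid Shared grid size; default 512.
#' @return list of `curve_a`, `curve_b` on the shared grid.
#' @export
paired_densities <- function(log_deltas_a, log_deltas_b, ...,
                             n_grid = 512L) {
  a <- log_deltas_a[is.finite(log_deltas_a)]
  b <- log_deltas_b[is.finite(log_deltas_b)]
  span <- range(c(a, b))
  pad <- 3 * stats::bw.nrd0(c(a, b))
  grid <- seq(span[1L] - pad, span[2L] + pad, length.out = n_grid)
  list(curve_a = delta_density(a, grid = grid, ...),
       curve_b = delta_density(b, grid = grid, ...))
}
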