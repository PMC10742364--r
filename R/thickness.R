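#' Measure cement-layer thickness between two interface curves
#'
#' Measures the cement gap at `n_stations` evenly spaced stations along the
#' die-side interface, from its margin end to its far (occlusal-middle) end.
#' Stations are placed at equal fractions of arc length along the die curve
#' (endpoints inclusive: fractions 0, 1/2, 1 for the default three
#' stations). At each station the thickness is the distance from the
#' die-curve point, along the local normal to the die curve, to the
#' restoration-side curve, converted to micrometres by the calibration
#' factor.
#'
#' A station whose normal ray does not intersect the restoration curve
#' within its fitted extent is flagged missing, excluded from the summary,
#' and reported with a warning.
#'
#' @param die_curve,resto_curve [fit_interface_curve()] results for the
#'   die--cement and cement--restoration interfaces, fitted over overlapping
#'   extents.
#' @param calibration A [calibration_spec()]; supplies mm/pixel.
#' @param n_stations Number of measurement stations (default 3).
#' @return An object of class `thickness_result` with fields
#'   `station_thickness_um` (per-station values, `NA` where missing),
#'   `mean_um`, `sd_um` and `n_stations`.
#' @export
measure_cement_thickness <- function(die_curve, resto_curve,
                                     calibration = calibration_spec(),
                                     n_stations = 3) {
  stopifnot(inherits(die_curve, "fitted_curve"),
            inherits(resto_curve, "fitted_curve"),
            inherits(calibration, "calibration_spec"))
  if (n_stations < 1) stop("n_stations must be at least 1")

  fracs <- if (n_stations == 1L) 0.5 else seq(0, 1, length.out = n_stations)
  total <- arc_length(die_curve)
  u_st <- vapply(fracs, function(f) {
    if (f <= 0) return(die_curve$x_lo)
    if (f >= 1) return(die_curve$x_hi)
    stats::uniroot(function(u) arc_length(die_curve, die_curve$x_lo, u) - f * total,
                   c(die_curve$x_lo, die_curve$x_hi), tol = 1e-6)$root
  }, numeric(1))

  um_per_px <- calibration$mm_per_pixel * 1000
  th <- vapply(u_st, function(u) {
    t_px <- normal_gap_px(die_curve, resto_curve, u)
    t_px * um_per_px
  }, numeric(1))

  if (anyNA(th))
    warning(sum(is.na(th)), " station(s) had no normal-ray intersection ",
            "with the restoration curve and were excluded")
  ok <- th[!is.na(th)]
  structure(
    list(station_thickness_um = th,
         mean_um = if (length(ok)) mean(ok) else NA_real_,
         sd_um = if (length(ok) > 1L) stats::sd(ok) else NA_real_,
         n_stations = as.integer(n_stations)),
    class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("<thickness_result: %d stations, mean %.1f um (sd %.1f)>\n",
              x$n_stations, x$mean_um,
              if (is.na(x$sd_um)) 0 else x$sd_um))
  invisible(x)
}

# Distance (px) from the die-curve point at local abscissa u, along the die
# curve's local normal, to the resto curve; NA when the ray misses the resto
# curve's fitted extent. Searches both normal directions and keeps the
# nearest crossing.
normal_gap_px <- function(die_curve, resto_curve, u) {
  p <- curve_to_image(die_curve, u)[1L, ]
  dcoef <- polyderiv_desc(die_curve$coefficients)
  slope <- polyval_desc(dcoef, u)
  # tangent in image (row, col) coords, then unit normal
  s <- sin(die_curve$theta); cth <- cos(die_curve$theta)
  tangent <- c(row = s + cth * slope, col = cth - s * slope)
  tangent <- tangent / sqrt(sum(tangent^2))
  normal <- c(row = unname(tangent["col"]), col = -unname(tangent["row"]))

  # residual of the ray point in the resto curve's local frame
  g <- function(t) {
    pts <- cbind(row = p["row"] + t * normal["row"],
                 col = p["col"] + t * normal["col"])
    loc <- image_to_curve(resto_curve, pts)
    loc[, "v"] - curve_eval(resto_curve, loc[, "u"])
  }
  # allow a small overhang at the curve ends: the foot of the normal from an
  # endpoint station legitimately lands just beyond the opposite fit bound
  slack <- max(5, 0.02 * (resto_curve$x_hi - resto_curve$x_lo))
  in_extent <- function(t) {
    pts <- cbind(row = p["row"] + t * normal["row"],
                 col = p["col"] + t * normal["col"])
    uu <- image_to_curve(resto_curve, pts)[, "u"]
    uu >= resto_curve$x_lo - slack & uu <= resto_curve$x_hi + slack
  }

  t_max <- max(500, 2 * (resto_curve$x_hi - resto_curve$x_lo))
  grid <- seq(-t_max, t_max, by = 0.5)
  gv <- g(grid)
  roots <- numeric(0)
  exact <- which(abs(gv) < 1e-9)
  if (length(exact)) roots <- c(roots, grid[exact])
  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    r <- tryCatch(
      stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-8)$root,
      error = function(e) NA_real_)
    if (!is.na(r)) roots <- c(roots, r)
  }
  roots <- roots[in_extent(roots)]
  if (!length(roots)) return(NA_real_)
  min(abs(roots))
}
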