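# Polynomial helpers on descending coefficients c(a, b, c, d, e):
# y = a x^4 + b x^3 + c x^2 + d x + e. Horner evaluation.
polyval_desc <- function(coef, x) {
  y <- rep(0, length(x))
  for (ci in coef) y <- y * x + ci
  y
}

polyderiv_desc <- function(coef) {
  n <- length(coef)
  if (n <= 1L) return(0)
  coef[-n] * ((n - 1L):1L)
}

#' Calibration of pixel measurements
#'
#' Holds the spatial calibration used to convert fitted arc lengths from
#' pixels to millimetres, and the complete-penetration cap. The default
#' conversion factor, 0.0013028 mm/pixel, corresponds to a microscope
#' graticule measurement at the capture setup the defaults assume; the
#' default cap of 7.18 mm is the margin-to-die-center distance assigned when
#' dye penetrates past the center of the die.
#'
#' @param mm_per_pixel Millimetres per image pixel; must be positive.
#' @param cap_mm Complete-penetration distance in mm; must be positive.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(mm_per_pixel = 0.0013028, cap_mm = 7.18) {
  if (!is.numeric(mm_per_pixel) || is.na(mm_per_pixel) || mm_per_pixel <= 0)
    stop("mm_per_pixel must be a positive number")
  if (!is.numeric(cap_mm) || is.na(cap_mm) || cap_mm <= 0)
    stop("cap_mm must be a positive number")
  structure(list(mm_per_pixel = mm_per_pixel, cap_mm = cap_mm),
            class = "calibration_spec")
}

#' Fit the interface polynomial to a marker trace
#'
#' Fits the quartic \eqn{y = a x^4 + b x^3 + c x^2 + d x + e} to the marker
#' positions by least squares. With `frame = "principal"` (the default) the
#' markers are first rotated into their principal-axis frame -- abscissa
#' along the least-squares line through the markers, origin at their
#' centroid -- so that near-vertical interfaces remain single-valued
#' functions of the abscissa; arc length is invariant under this rigid
#' transformation, so the measured penetration is unchanged for interfaces
#' that are already well-posed in image coordinates. With `frame = "image"`
#' the fit is performed on raw `(x = col, y = row)` coordinates.
#'
#' When the trace has fewer than `degree + 1` markers the fitted degree is
#' reduced to `n - 1` and reported in `degree_used`.
#'
#' @param trace A [marker_trace()] with at least 2 markers.
#' @param degree Maximum polynomial degree (default 4).
#' @param frame `"principal"` or `"image"` (see Details).
#' @return An object of class `fitted_curve` with fields `coefficients`
#'   (length 5, descending powers), `theta` and `center` (the local frame),
#'   `x_lo`, `x_hi` (local abscissae of the margin-end and far-end markers)
#'   and `degree_used`.
#' @examples
#' tr <- marker_trace(cbind(row = 2 * (0:10), col = 0:10))
#' cf <- fit_interface_curve(tr, frame = "image")
#' cf$coefficients  # d = 2, others ~ 0
#' @export
fit_interface_curve <- function(trace, degree = 4,
                                frame = c("principal", "image")) {
  stopifnot(inherits(trace, "marker_trace"))
  frame <- match.arg(frame)
  n <- n_markers(trace)
  if (n < 2L)
    stop("cannot fit an interface curve to fewer than 2 markers",
         call. = FALSE)
  x <- trace$markers[, "col"]
  y <- trace$markers[, "row"]

  if (frame == "principal") {
    cx <- mean(x); cy <- mean(y)
    cen <- cbind(x - cx, y - cy)
    ev <- eigen(crossprod(cen) / n, symmetric = TRUE)$vectors[, 1L]
    theta <- atan2(ev[2L], ev[1L])
    u <- cen %*% c(cos(theta), sin(theta))
    if (u[1L] > u[n]) {                 # margin end at the low abscissa
      theta <- theta + pi
      u <- -u
    }
    v <- cen %*% c(-sin(theta), cos(theta))
    center <- c(cx, cy)
  } else {
    theta <- 0; center <- c(0, 0)
    u <- x; v <- y
  }

  degree_used <- min(degree, n - 1L)
  X <- outer(as.numeric(u), degree_used:0, `^`)
  beta <- qr.coef(qr(X), as.numeric(v))
  beta[is.na(beta)] <- 0
  coef5 <- c(rep(0, 4L - degree_used), beta)
  structure(
    list(coefficients = coef5, theta = theta, center = center,
         x_lo = as.numeric(u[1L]), x_hi = as.numeric(u[n]),
         degree_used = as.integer(degree_used), n_markers = n),
    class = "fitted_curve")
}

#' @export
print.fitted_curve <- function(x, ...) {
  cat(sprintf(
    "<fitted_curve: degree %d over [%0.2f, %0.2f] px, rotation %0.4f rad>\n",
    x$degree_used, x$x_lo, x$x_hi, x$theta))
  invisible(x)
}

# Evaluate the curve at local abscissae u; returns local ordinates.
curve_eval <- function(curve, u) polyval_desc(curve$coefficients, u)

# Map local (u, v) to image (row, col).
curve_to_image <- function(curve, u, v = curve_eval(curve, u)) {
  s <- sin(curve$theta); cth <- cos(curve$theta)
  cbind(row = curve$center[2L] + s * u + cth * v,
        col = curve$center[1L] + cth * u - s * v)
}

# Map image (row, col) points to local (u, v).
image_to_curve <- function(curve, pts) {
  s <- sin(curve$theta); cth <- cos(curve$theta)
  dx <- pts[, 2L] - curve$center[1L]
  dy <- pts[, 1L] - curve$center[2L]
  cbind(u = cth * dx + s * dy, v = -s * dx + cth * dy)
}

#' Arc length of a fitted curve
#'
#' Evaluates \eqn{s = \int_a^b \sqrt{1 + (dy/dx)^2}\, dx} over the local
#' abscissa interval by adaptive quadrature (relative tolerance 1e-8). This
#' is the length, in pixels, of the fitted interface polynomial between the
#' two bounds.
#'
#' @param curve A [fit_interface_curve()] result.
#' @param x_lo,x_hi Integration bounds on the local abscissa, in pixels;
#'   default to the curve's fit bounds. `x_lo` must not exceed `x_hi`.
#' @return Arc length in pixels.
#' @examples
#' tr <- marker_trace(cbind(row = 0:100, col = 0:100))
#' arc_length(fit_interface_curve(tr, frame = "image"))  # 100 * sqrt(2)
#' @export
arc_length <- function(curve, x_lo = curve$x_lo, x_hi = curve$x_hi) {
  stopifnot(inherits(curve, "fitted_curve"))
  if (x_lo > x_hi) stop("x_lo must not exceed x_hi")
  if (x_lo == x_hi) return(0)
  dcoef <- polyderiv_desc(curve$coefficients)
  integrand <- function(x) sqrt(1 + polyval_desc(dcoef, x)^2)
  stats::integrate(integrand, x_lo, x_hi, rel.tol = 1e-8,
                   subdivisions = 500L)$value
}

#' Penetration measurement result
#'
#' Container for a specimen's dye-penetration measurement. `status` is one
#' of `"measured"`, `"complete_penetration"`, `"no_dye"` or `"delaminated"`.
#'
#' @param arc_length_px Fitted arc length in pixels.
#' @param penetration_mm Calibrated penetration distance in mm.
#' @param capped Whether the complete-penetration cap was applied.
#' @param status Measurement status string.
#' @param degree_used Polynomial degree actually fitted (NA when no fit).
#' @return An object of class `penetration_result`.
#' @export
penetration_result <- function(arc_length_px, penetration_mm, capped, status,
                               degree_used = NA_integer_) {
  status <- match.arg(status,
    c("measured", "complete_penetration", "no_dye", "delaminated"))
  structure(list(arc_length_px = arc_length_px,
                 penetration_mm = penetration_mm,
                 capped = capped, status = status,
                 degree_used = degree_used),
            class = "penetration_result")
}

#' @export
print.penetration_result <- function(x, ...) {
  cat(sprintf("<penetration_result: %s, %.4f mm (%.1f px)%s>\n",
              x$status, x$penetration_mm, x$arc_length_px,
              if (isTRUE(x$capped)) ", capped" else ""))
  invisible(x)
}

#' Measure calibrated dye penetration from a marker trace
#'
#' Fits the interface polynomial to the trace, integrates its arc length
#' between the margin-end and far-end markers, and converts pixels to mm by
#' the calibration factor. If the trace reaches or passes the die-center
#' landmark (when given), or the converted distance reaches `cap_mm`,
#' complete penetration is reported and the result is exactly `cap_mm`.
#'
#' An empty trace -- or one with a single marker, which cannot support a fit
#' -- yields `status = "no_dye"` with 0 mm.
#'
#' @param trace A [marker_trace()].
#' @param calibration A [calibration_spec()].
#' @param die_center Optional `(row, col)` of the die center landmark; when
#'   the trace's far end reaches it (in projection along the trace), the cap
#'   is applied regardless of the fitted length.
#' @param degree Maximum fit degree, passed to [fit_interface_curve()].
#' @return A [penetration_result()].
#' @export
measure_penetration <- function(trace, calibration = calibration_spec(),
                                die_center = NULL, degree = 4) {
  stopifnot(inherits(trace, "marker_trace"),
            inherits(calibration, "calibration_spec"))
  if (trace$is_empty || n_markers(trace) < 2L)
    return(penetration_result(0, 0, FALSE, "no_dye"))

  curve <- fit_interface_curve(trace, degree = degree)
  s_px <- arc_length(curve)
  mm <- s_px * calibration$mm_per_pixel

  capped <- mm >= calibration$cap_mm
  if (!capped && !is.null(die_center)) {
    uc <- image_to_curve(curve, matrix(die_center, 1L, 2L,
                                       dimnames = list(NULL, c("row", "col"))))[1L, "u"]
    capped <- curve$x_hi >= uc            # far end reaches/passes the center
  }
  if (capped)
    penetration_result(s_px, calibration$cap_mm, TRUE,
                       "complete_penetration", curve$degree_used)
  else
    penetration_result(s_px, mm, FALSE, "measured", curve$degree_used)
}

#' Overlay a fitted curve on an image
#'
#' Rasterizes the fitted polynomial over its fit bounds and paints it on a
#' copy of the image in a distinct colour (default red), for the visual
#' check of the final processing stage. The input image is not modified.
#'
#' @inheritParams classify_dye_pixels
#' @param curve A [fit_interface_curve()] result whose bounds map inside the
#'   image.
#' @param color Length-3 RGB triple for the curve.
#' @return The annotated `H x W x 3` raster array.
#' @export
render_overlay <- function(image, curve, color = c(255, 0, 0)) {
  image <- as_raster_image(image)
  stopifnot(inherits(curve, "fitted_curve"), length(color) == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  span <- max(curve$x_hi - curve$x_lo, 1)
  u <- seq(curve$x_lo, curve$x_hi, length.out = max(2L, ceiling(4 * span)))
  pts <- round(curve_to_image(curve, u))
  keep <- pts[, "row"] >= 1 & pts[, "row"] <= h &
          pts[, "col"] >= 1 & pts[, "col"] <= w
  pts <- pts[keep, , drop = FALSE]
  pts <- pts[!duplicated(pts), , drop = FALSE]
  if (nrow(pts)) {
    idx <- (pts[, "col"] - 1) * h + pts[, "row"]
    image[idx] <- color[1]
    image[idx + h * w] <- color[2]
    image[idx + 2 * h * w] <- color[3]
  }
  image
}
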