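# Composite-Simpson arc length of a descending-coefficient polynomial.
# Deliberately a different quadrature scheme from the measurement path's
# adaptive integrator, so the generator's ground truth is an independent
# oracle.
arc_length_oracle <- function(coef, x_lo, x_hi, n_panels = 4096L) {
  if (x_hi <= x_lo) return(0)
  dcoef <- polyderiv_desc(coef)
  x <- seq(x_lo, x_hi, length.out = 2L * n_panels + 1L)
  fx <- sqrt(1 + polyval_desc(dcoef, x)^2)
  h <- (x_hi - x_lo) / (2 * n_panels)
  w <- rep(c(4, 2), length.out = 2L * n_panels - 1L)   # 4,2,...,2,4 interior
  (h / 3) * (fx[1] + fx[2L * n_panels + 1L] + sum(w * fx[2:(2L * n_panels)]))
}

#' Synthetic cross-section scene specification
#'
#' Describes a synthetic specimen cross-section with analytically known
#' ground truth: a die region bounded above by a polynomial die--cement
#' interface, a cement band whose thickness profile is constant or a linear
#' wedge, a restoration region above the cement, and a dye band hugging the
#' die interface from the margin end over a prescribed arc length.
#'
#' The geometry convention is `row = f(col)` with the die below (larger
#' rows) and the restoration above. The default canvas (1400 x 2000 px) and
#' dye extent (1500 px, about 2.0 mm at the default calibration) emulate a
#' sectioned specimen imaged at reduced resolution with the dye front
#' mid-way along the interface. The `"stepped"` texture adds a square-wave
#' offset to the cement--restoration interface and lets the dye wick into
#' the layer grooves, emulating the staircase morphology of additively
#' manufactured fitting surfaces; `"smooth"` emulates milled or moulded
#' surfaces. Default `step_period` 40 px and `step_amplitude` 6 px
#' correspond to roughly 52 um print layers with 8 um ridges at the default
#' calibration.
#'
#' Default region colours are chosen so that the dye colour satisfies the
#' default [dye_threshold()] and all other regions violate it.
#'
#' @param image_size `(H, W)` in pixels.
#' @param die_curve_coeffs Descending coefficients (degree <= 4) of the
#'   die--cement interface `row = f(col)`.
#' @param cement_gap_um Length-2 vector: cement thickness in um at the
#'   margin (col 1) and at the far end (col W); equal values give a
#'   constant band, unequal a linear wedge.
#' @param dye_extent_px Ground-truth arc length of the dye front along the
#'   die interface, in pixels; 0 paints no dye.
#' @param dye_band_width Dye band thickness in pixels (centred on the
#'   interface).
#' @param dye_color,die_color,cement_color,resto_color RGB triples (0--255).
#' @param noise_sd Gaussian channel noise standard deviation (0 = clean).
#' @param texture `"smooth"` or `"stepped"`.
#' @param step_period,step_amplitude Square-wave period and amplitude in
#'   pixels (stepped texture only).
#' @param mm_per_pixel Calibration under which ground-truth mm values are
#'   stated.
#' @param seed RNG seed making the scene deterministic.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(1400L, 2000L),
                       die_curve_coeffs = c(0, 0, 1.5e-5, 0.05, 900),
                       cement_gap_um = c(100, 100),
                       dye_extent_px = 1500,
                       dye_band_width = 3,
                       dye_color = c(60, 60, 175),
                       die_color = c(230, 230, 230),
                       cement_color = c(200, 190, 160),
                       resto_color = c(240, 225, 210),
                       noise_sd = 0,
                       texture = c("smooth", "stepped"),
                       step_period = 40,
                       step_amplitude = 6,
                       mm_per_pixel = 0.0013028,
                       seed = 1L) {
  texture <- match.arg(texture)
  stopifnot(length(image_size) == 2L, all(image_size >= 8),
            length(die_curve_coeffs) <= 5L,
            length(cement_gap_um) == 2L, all(cement_gap_um > 0),
            dye_extent_px >= 0, dye_band_width >= 1,
            noise_sd >= 0, step_period >= 2, step_amplitude >= 0,
            mm_per_pixel > 0)
  coef5 <- c(rep(0, 5L - length(die_curve_coeffs)), die_curve_coeffs)
  spec <- structure(
    list(image_size = as.integer(image_size), die_curve_coeffs = coef5,
         cement_gap_um = cement_gap_um, dye_extent_px = dye_extent_px,
         dye_band_width = dye_band_width, dye_color = dye_color,
         die_color = die_color, cement_color = cement_color,
         resto_color = resto_color, noise_sd = noise_sd, texture = texture,
         step_period = step_period, step_amplitude = step_amplitude,
         mm_per_pixel = mm_per_pixel, seed = as.integer(seed)),
    class = "scene_spec")
  thr <- dye_threshold()
  if (!(dye_color[1] <= thr$r_max && dye_color[2] <= thr$g_max &&
        dye_color[3] >= thr$b_min && dye_color[3] <= thr$b_max))
    stop("dye_color must satisfy the default dye threshold")
  for (col in list(die_color, cement_color, resto_color))
    if (col[1] <= thr$r_max && col[2] <= thr$g_max &&
        col[3] >= thr$b_min && col[3] <= thr$b_max)
      stop("die/cement/restoration colors must violate the dye threshold")
  spec
}

#' Generate a synthetic cross-section with ground truth
#'
#' Renders the scene described by a [scene_spec()] and returns the image
#' together with its analytic ground truth. The dye band is painted along
#' the die interface from the margin (column 1) up to exactly
#' `dye_extent_px` of arc length; the cut-off column is found by root
#' solving on an independent composite-Simpson arc-length oracle, so the
#' ground truth does not depend on the measurement code it is used to test.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{image}{`H x W x 3` raster array.}
#'     \item{ground_truth}{List: `true_arc_length_px`,
#'       `true_penetration_mm` (uncapped, at the spec's calibration),
#'       `true_thickness_um` (cement gap at arc fractions 0, 1/2, 1),
#'       `curve_samples` (dense `(row, col)` samples of the die interface),
#'       `margin_anchor`, `die_curve_coeffs`, `dye_end_col`.}
#'   }
#' @examples
#' sc <- generate_cross_section(scene_spec(image_size = c(200, 300),
#'                                         dye_extent_px = 150,
#'                                         die_curve_coeffs = c(0.02, 100)))
#' dim(sc$image)
#' @export
generate_cross_section <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  coef <- spec$die_curve_coeffs
  xs <- seq_len(W)
  r_die <- polyval_desc(coef, xs)
  if (any(r_die < 1) || any(r_die > H))
    stop("die interface leaves the image; adjust die_curve_coeffs/image_size")

  total_arc <- arc_length_oracle(coef, 1, W)
  if (spec$dye_extent_px > total_arc)
    stop(sprintf("dye_extent_px (%g) exceeds total interface arc length (%g)",
                 spec$dye_extent_px, total_arc))

  um_per_px <- spec$mm_per_pixel * 1000
  gap_px <- (spec$cement_gap_um[1] +
             (spec$cement_gap_um[2] - spec$cement_gap_um[1]) *
               (xs - 1) / (W - 1)) / um_per_px

  step_wave <- if (spec$texture == "stepped")
    (floor(xs / spec$step_period) %% 2) * spec$step_amplitude
  else rep(0, W)
  r_resto <- r_die - gap_px - step_wave       # cement-restoration interface

  # dye cut-off column: arc length from the margin equals dye_extent_px
  x_end <- if (spec$dye_extent_px <= 0) 0 else if (spec$dye_extent_px >= total_arc) W
  else stats::uniroot(function(x) arc_length_oracle(coef, 1, x) - spec$dye_extent_px,
                      c(1, W), tol = 1e-6)$root

  rowm <- matrix(seq_len(H), H, W)
  die_row <- matrix(r_die, H, W, byrow = TRUE)
  resto_row <- matrix(r_resto, H, W, byrow = TRUE)

  die_mask <- rowm >= die_row
  cement_mask <- !die_mask & rowm >= resto_row

  half <- (spec$dye_band_width - 1) / 2
  widen <- matrix(step_wave / 2, H, W, byrow = TRUE)  # wicking into grooves
  colx <- matrix(xs, H, W, byrow = TRUE)
  dye_mask <- colx <= x_end &
    rowm >= die_row - half - widen & rowm <= die_row + half

  img <- blank_raster(H, W, spec$resto_color)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[cement_mask] <- spec$cement_color[ch]
    plane[die_mask] <- spec$die_color[ch]
    plane[dye_mask] <- spec$dye_color[ch]
    img[, , ch] <- plane
  }

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
    img[] <- round(pmin(pmax(img, 0), 255))
  }

  gap_at <- function(frac) {
    u <- if (frac <= 0) 1 else if (frac >= 1) W
    else stats::uniroot(function(x) arc_length_oracle(coef, 1, x) - frac * total_arc,
                        c(1, W), tol = 1e-6)$root
    spec$cement_gap_um[1] +
      (spec$cement_gap_um[2] - spec$cement_gap_um[1]) * (u - 1) / (W - 1)
  }

  xs_s <- seq(1, W, by = 8)
  list(
    image = img,
    ground_truth = list(
      true_arc_length_px = spec$dye_extent_px,
      true_penetration_mm = spec$dye_extent_px * spec$mm_per_pixel,
      true_thickness_um = vapply(c(0, 0.5, 1), gap_at, numeric(1)),
      curve_samples = cbind(row = polyval_desc(coef, xs_s), col = xs_s),
      margin_anchor = c(round(r_die[1]), 1),
      die_curve_coeffs = coef,
      dye_end_col = x_end))
}

#' Write a synthetic scene to disk
#'
#' Writes the rendered image as PNG with a JSON ground-truth sidecar
#' (`<image>.json`) next to it.
#'
#' @param scene A [generate_cross_section()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  write_raster(scene$image, path)
  jsonlite::write_json(scene$ground_truth, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate specimen-level penetration values for a group study
#'
#' Draws per-group penetration distances from a capped normal model: values
#' are sampled from Normal(mean, sd), truncated below at 0 (a physical
#' distance) and capped above at `cap` (the complete-penetration
#' assignment); each specimen independently delaminates with probability
#' `p_delam` and contributes to the delamination count instead of the
#' measurement list. Complete-penetration counts record capped specimens.
#'
#' @param n_per_group Specimens per group (>= 1).
#' @param group_params Named list; each element a list with `mean`, `sd`
#'   (mm), and optional `cap` (default 7.18) and `p_delam` (default 0).
#' @param seed RNG seed.
#' @return A [group_study()]. Groups whose specimens all delaminated keep a
#'   single `NA`-free placeholder value of 0 and a full delamination count.
#' @examples
#' gs <- generate_group_study(5, list(a = list(mean = 2, sd = 1),
#'                                    b = list(mean = 6, sd = 1)), seed = 7)
#' @export
generate_group_study <- function(n_per_group, group_params, seed = 1L) {
  stopifnot(n_per_group >= 1, is.list(group_params), length(group_params) >= 1L)
  if (is.null(names(group_params)) || any(!nzchar(names(group_params))))
    stop("group_params must be a named list")
  set.seed(seed)
  groups <- list(); delam <- integer(0); comp <- integer(0)
  for (g in names(group_params)) {
    p <- group_params[[g]]
    if (is.null(p$mean) || is.null(p$sd) || p$sd < 0)
      stop("each group needs mean and non-negative sd")
    cap <- if (is.null(p$cap)) 7.18 else p$cap
    if (cap <= 0) stop("cap must be positive")
    p_delam <- if (is.null(p$p_delam)) 0 else p$p_delam
    if (p_delam < 0 || p_delam > 1) stop("p_delam must lie in [0, 1]")
    raw <- stats::rnorm(n_per_group, p$mean, p$sd)
    vals <- pmin(cap, pmax(0, raw))
    is_delam <- stats::rbinom(n_per_group, 1L, p_delam) == 1L
    kept <- vals[!is_delam]
    groups[[g]] <- if (length(kept)) kept else 0
    delam[g] <- sum(is_delam)
    comp[g] <- sum(kept >= cap)
  }
  group_study(groups, delaminated_counts = delam,
              complete_penetration_counts = comp)
}
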