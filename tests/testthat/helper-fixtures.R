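# Shared fixtures: everything is generated in code at test time.

# Small, fast synthetic scene for unit tests (default canvas is larger).
small_scene_spec <- function(...) {
  args <- utils::modifyList(
    list(image_size = c(300L, 500L),
         die_curve_coeffs = c(0, 0, 4e-5, 0.05, 180),
         dye_extent_px = 300),
    list(...))
  do.call(scene_spec, args)
}

# Run the full measurement pipeline on a scene, returning the result and
# the relative error against the generator's ground truth.
measure_scene <- function(scene, bin_width = 5, die_center = NULL) {
  mask <- classify_dye_pixels(scene$image)
  tr <- extract_interface_markers(mask, scene$ground_truth$margin_anchor,
                                  bin_width = bin_width)
  res <- measure_penetration(tr, die_center = die_center)
  list(trace = tr, result = res,
       rel_err = (res$arc_length_px - scene$ground_truth$true_arc_length_px) /
         scene$ground_truth$true_arc_length_px)
}

# Markers sampled noiselessly from a descending-coefficient polynomial
# row = f(col).
poly_trace <- function(coef, cols) {
  y <- 0
  for (ci in coef) y <- y * cols + ci
  marker_trace(cbind(row = y, col = cols))
}

# Straight horizontal interface trace at a given row.
line_trace <- function(row, cols) marker_trace(cbind(row = rep(row, length(cols)),
                                                     col = cols))
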