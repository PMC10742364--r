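#' Dye-segmentation threshold
#'
#' Box constraints on the RGB channels that define a dye-positive pixel:
#' `R <= r_max`, `G <= g_max` and `b_min <= B <= b_max`, combined with AND.
#' The defaults select penetrated methylene blue on 8-bit images.
#'
#' @param r_max,g_max Upper bounds on the red and green channels.
#' @param b_min,b_max Closed interval for the blue channel.
#' @return An object of class `dye_threshold`.
#' @examples
#' thr <- dye_threshold()
#' thr$r_max
#' @export
dye_threshold <- function(r_max = 110, g_max = 160, b_min = 150, b_max = 200) {
  vals <- c(r_max = r_max, g_max = g_max, b_min = b_min, b_max = b_max)
  if (anyNA(vals) || any(vals < 0) || any(vals > 255))
    stop("threshold bounds must lie in [0, 255]")
  if (b_min > b_max) stop("b_min must not exceed b_max")
  structure(as.list(vals), class = "dye_threshold")
}

#' Classify dye-positive pixels
#'
#' Applies the RGB box threshold pointwise, producing a logical mask the same
#' size as the image. A pixel is dye-positive iff all three channel
#' conditions hold.
#'
#' @param image An `H x W x 3` raster array (0--255) or an image file path.
#' @param threshold A [dye_threshold()].
#' @return A logical `H x W` matrix.
#' @examples
#' img <- blank_raster(5, 5, c(100, 150, 175))
#' sum(classify_dye_pixels(img))  # all 25 pixels in threshold
#' @export
classify_dye_pixels <- function(image, threshold = dye_threshold()) {
  image <- as_raster_image(image)
  stopifnot(inherits(threshold, "dye_threshold"))
  r <- image[, , 1L]; g <- image[, , 2L]; b <- image[, , 3L]
  r <= threshold$r_max & g <= threshold$g_max &
    b >= threshold$b_min & b <= threshold$b_max
}

#' Marker traces along the die--cement interface
#'
#' A marker trace is an ordered set of single-pixel `(row, col)` positions
#' marking where dye penetrated along the interface, ordered starting from
#' the margin end. `margin_anchor` stores the first marker of the trace;
#' `is_empty` flags a specimen with no dye-positive pixels.
#'
#' @param markers An `n x 2` numeric matrix of `(row, col)` positions (may
#'   have zero rows).
#' @return An object of class `marker_trace`.
#' @export
marker_trace <- function(markers = matrix(numeric(0), 0L, 2L)) {
  markers <- as.matrix(markers)
  if (length(markers) == 0L) markers <- matrix(numeric(0), 0L, 2L)
  if (ncol(markers) != 2L) stop("markers must be an n x 2 (row, col) matrix")
  colnames(markers) <- c("row", "col")
  structure(
    list(markers = markers,
         margin_anchor = if (nrow(markers)) markers[1L, ] else NULL,
         is_empty = nrow(markers) == 0L),
    class = "marker_trace")
}

#' @rdname marker_trace
#' @param trace A `marker_trace`.
#' @export
n_markers <- function(trace) nrow(trace$markers)

#' @export
print.marker_trace <- function(x, ...) {
  if (x$is_empty) cat("<marker_trace: empty>\n")
  else cat(sprintf("<marker_trace: %d markers, margin end at (%g, %g)>\n",
                   n_markers(x), x$margin_anchor[1], x$margin_anchor[2]))
  invisible(x)
}

# Round to nearest integer, exact halves toward the smaller index.
round_half_down <- function(x) ceiling(x - 0.5)

#' Extract interface markers from a dye mask
#'
#' Reduces the segmented dye band to an ordered single-pixel trace along the
#' die--cement interface. Dye pixels are projected onto their principal axis
#' (the least-squares line through the dye region), partitioned into bins of
#' `bin_width` pixels along that axis, and each occupied bin contributes one
#' marker: the centroid of its dye pixels, rounded to the nearest pixel
#' (exact halves toward the smaller index). Markers are ordered starting
#' from the end nearest `margin_anchor`.
#'
#' @param mask A logical `H x W` matrix from [classify_dye_pixels()].
#' @param margin_anchor `(row, col)` of the margin end of the interface,
#'   1-based; must lie inside the mask bounds. Used to orient the trace.
#' @param bin_width Bin width in pixels along the principal axis; the default
#'   5 px suppresses sub-pixel jitter without losing interface curvature.
#' @return A [marker_trace()]; empty when the mask has no `TRUE` pixel.
#' @examples
#' mask <- matrix(FALSE, 10, 10)
#' mask[4, 2:9] <- TRUE
#' tr <- extract_interface_markers(mask, margin_anchor = c(4, 1), bin_width = 1)
#' n_markers(tr)
#' @export
extract_interface_markers <- function(mask, margin_anchor, bin_width = 5) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix")
  if (length(margin_anchor) != 2L || anyNA(margin_anchor))
    stop("margin_anchor must be (row, col)")
  if (margin_anchor[1] < 1 || margin_anchor[1] > nrow(mask) ||
      margin_anchor[2] < 1 || margin_anchor[2] > ncol(mask))
    stop("margin_anchor lies outside the image bounds")
  if (bin_width <= 0) stop("bin_width must be positive")

  px <- which(mask, arr.ind = TRUE)            # (row, col) of dye pixels
  if (nrow(px) == 0L) return(marker_trace())
  if (nrow(px) == 1L) return(marker_trace(px))

  ctr <- colMeans(px)
  cen <- sweep(px, 2L, ctr)
  # principal axis of the dye region
  ev <- eigen(crossprod(cen) / nrow(px), symmetric = TRUE)$vectors[, 1L]
  t_proj <- cen %*% ev
  bin <- floor((t_proj - min(t_proj)) / bin_width)
  ord_bins <- sort(unique(bin))
  centroids <- t(vapply(ord_bins, function(b) {
    colMeans(px[bin == b, , drop = FALSE])
  }, numeric(2)))
  markers <- cbind(round_half_down(centroids[, 1]), round_half_down(centroids[, 2]))
  markers <- markers[!duplicated(markers), , drop = FALSE]
  # orient: first marker is the one nearest the margin anchor
  d_first <- sum((markers[1L, ] - margin_anchor)^2)
  d_last <- sum((markers[nrow(markers), ] - margin_anchor)^2)
  if (d_last < d_first) markers <- markers[nrow(markers):1L, , drop = FALSE]
  marker_trace(markers)
}

#' Render markers on an image
#'
#' Returns a copy of the image with each marker pixel set to pure green
#' `(0, 255, 0)`; every other pixel is unchanged. This is the visual-check
#' overlay for the marker-placement stage.
#'
#' @inheritParams classify_dye_pixels
#' @param trace A [marker_trace()] whose markers lie inside the image.
#' @return The annotated `H x W x 3` raster array.
#' @export
render_markers <- function(image, trace) {
  image <- as_raster_image(image)
  stopifnot(inherits(trace, "marker_trace"))
  if (trace$is_empty) return(image)
  m <- round(trace$markers)
  if (any(m[, 1] < 1 | m[, 1] > dim(image)[1] |
          m[, 2] < 1 | m[, 2] > dim(image)[2]))
    stop("trace markers fall outside the image")
  h <- dim(image)[1]; w <- dim(image)[2]
  idx <- (m[, 2] - 1) * h + m[, 1]
  image[idx] <- 0                              # R channel
  image[idx + h * w] <- 255                    # G channel
  image[idx + 2 * h * w] <- 0                  # B channel
  image
}
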