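#' Raster images
#'
#' `leakfit` represents an RGB cross-section image as a numeric array of
#' dimension `H x W x 3` holding channel values on the 8-bit scale (0--255),
#' origin top-left, 1-based `(row, col)` indexing. [read_raster()] builds this
#' representation from PNG or TIFF files; [write_raster()] writes it back as
#' PNG. Images with higher bit depth are rescaled to 0--255 on read because
#' the dye threshold is defined on the 8-bit scale; an alpha channel, if
#' present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return `read_raster()`: an `H x W x 3` numeric array with values in
#'   0--255.
#' @examples
#' img <- blank_raster(10, 20, c(255, 255, 255))
#' dim(img)
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF): ", path)
  )
  if (length(dim(raw)) == 2L) {                 # greyscale -> replicate
    raw <- array(raw, c(dim(raw), 3L))
  } else if (dim(raw)[3] >= 4L) {               # drop alpha
    raw <- raw[, , 1:3, drop = FALSE]
  } else if (dim(raw)[3] == 2L) {               # grey + alpha
    raw <- array(raw[, , 1L], c(dim(raw)[1:2], 3L))
  }
  img <- round(raw * 255)
  storage.mode(img) <- "double"
  img
}

#' @rdname read_raster
#' @param image An `H x W x 3` raster array (0--255).
#' @return `write_raster()`: the path, invisibly.
#' @export
write_raster <- function(image, path) {
  image <- as_raster_image(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname read_raster
#' @param height,width Image dimensions in pixels.
#' @param color Length-3 RGB fill value (0--255).
#' @export
blank_raster <- function(height, width, color = c(0, 0, 0)) {
  stopifnot(height >= 1, width >= 1, length(color) == 3)
  array(rep(as.numeric(color), each = height * width), c(height, width, 3L))
}

# Validate/coerce an object to the H x W x 3 raster convention.
as_raster_image <- function(image) {
  if (is.character(image) && length(image) == 1L) return(read_raster(image))
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array of RGB values in 0-255")
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    stop("image has no pixels")
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop("channel values must lie in [0, 255]")
  image
}
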