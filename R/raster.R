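#' Construct a raster image
#'
#' An RGB raster image is stored as an `H x W x 3` numeric array with channel
#' values in `[0, 255]`. This is the input format for the pixel-art
#' decomposition pipeline ([bin_image()], [cluster_colors()],
#' [build_location_maps()]).
#'
#' @param pixels An `H x W x 3` array (or an `H x W` matrix, interpreted as
#'   grayscale and replicated across channels) with values in `[0, 255]`.
#' @return An object of class `raster_image` (the validated array).
#' @export
raster_image <- function(pixels) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L) {
    stop("invalid-input: `pixels` must be an H x W x 3 array", call. = FALSE)
  }
  d <- dim(pixels)
  if (d[1L] < 1L || d[2L] < 1L) {
    stop("invalid-input: empty image", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("invalid-input: channel values must lie in [0, 255]", call. = FALSE)
  }
  structure(pixels, class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image> %d x %d px, RGB\n", d[1L], d[2L]))
  invisible(x)
}

#' Read an RGB image from PNG or ASCII PPM
#'
#' @param path Path to a `.png` file or an ASCII (`P3`) PPM file.
#' @return A [raster_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("invalid-input: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
    if (dim(a)[3L] == 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    return(raster_image(round(a * 255)))
  }
  read_ppm(path)
}

#' @rdname read_image
#' @param img A [raster_image()] to write.
#' @export
write_image_png <- function(img, path) {
  img <- raster_image(unclass(img))
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

# ASCII (P3) PPM reader; text-only fixture format.
read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(toks) < 4L || toks[1L] != "P3") {
    stop("invalid-input: expected ASCII PPM (P3): ", path, call. = FALSE)
  }
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L]); mx <- as.numeric(toks[4L])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != 3L * w * h) stop("invalid-input: truncated PPM", call. = FALSE)
  # PPM is row-major, RGB interleaved
  a <- array(NA_real_, dim = c(h, w, 3L))
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  for (ch in 1:3) a[, , ch] <- matrix(m[, ch], nrow = h, byrow = TRUE)
  raster_image(a / mx * 255)
}

write_ppm <- function(img, path) {
  img <- raster_image(unclass(img))
  d <- dim(img)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2L], d[1L]), "255"), con)
  px <- round(unclass(img))
  # row-major interleaved triplets
  m <- cbind(as.vector(t(px[, , 1L])), as.vector(t(px[, , 2L])), as.vector(t(px[, , 3L])))
  writeLines(paste(m[, 1L], m[, 2L], m[, 3L]), con)
  invisible(path)
}

# Block boundaries for binning: n blocks tiling 1..len, remainder folded into
# the final block.
bin_breaks <- function(len, n) {
  b <- len %/% n
  starts <- (0:(n - 1L)) * b + 1L
  ends <- c((1:(n - 1L)) * b, len)
  cbind(start = starts, end = ends)
}

#' Bin an image into an n-by-n color grid
#'
#' Each cell of the grid carries the per-channel arithmetic mean of the source
#' pixels in its rectangular block, rounded to the nearest integer. Blocks tile
#' the image; when the image side is not divisible by `n`, remainder pixels are
#' folded into the final row/column block (e.g. a 355-px side with `n = 15`
#' uses fourteen 23-px blocks and one 33-px block).
#'
#' @param img A [raster_image()] (or a `binned_grid`, which is re-binned).
#' @param n Grid side length in cells; must satisfy `n <= min(H, W)`.
#' @return A `binned_grid`: an `n x n x 3` integer array of cell colors.
#' @export
bin_image <- function(img, n) {
  if (inherits(img, "binned_grid")) img <- raster_image(unclass(img))
  img <- raster_image(unclass(img))
  d <- dim(img)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("invalid-grid: n must be >= 1", call. = FALSE)
  if (n > min(d[1L], d[2L])) {
    stop("invalid-grid: n exceeds image dimensions", call. = FALSE)
  }
  rb <- bin_breaks(d[1L], n)
  cb <- bin_breaks(d[2L], n)
  g <- array(NA_real_, dim = c(n, n, 3L))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      block <- img[rb[i, 1L]:rb[i, 2L], cb[j, 1L]:cb[j, 2L], , drop = FALSE]
      g[i, j, ] <- round(apply(block, 3L, mean))
    }
  }
  structure(g, class = "binned_grid")
}

#' @export
print.binned_grid <- function(x, ...) {
  cat(sprintf("<binned_grid> %d x %d cells\n", dim(x)[1L], dim(x)[2L]))
  invisible(x)
}

# Cells of a binned grid as an (n*n) x 3 matrix, row-major cell order.
grid_cells <- function(grid) {
  n <- dim(grid)[1L]
  m <- matrix(NA_real_, nrow = n * dim(grid)[2L], ncol = 3L)
  for (ch in 1:3) m[, ch] <- as.vector(t(grid[, , ch]))
  m
}
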