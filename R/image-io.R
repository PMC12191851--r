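#' Read an ECG page image as a grayscale matrix
#'
#' Loads a PNG or JPEG raster image and converts it to a grayscale intensity
#' matrix in `[0, 1]`, row 1 at the top of the page. Color images are
#' converted with the standard luminance weights
#' `0.299 R + 0.587 G + 0.114 B`; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A numeric matrix (height rows x width cols) with values in `[0, 1]`.
#' @export
#' @examples
#' pg <- render_synthetic_page(page_spec(seed = 1))
#' f <- tempfile(fileext = ".png")
#' write_page(pg$page, f)
#' img <- read_page(f)
#' dim(img)
read_page <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read image: ", path), class = "ecgtrace_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    abort(paste0("unsupported image format: .", ext), class = "ecgtrace_io_error")
  )
  as_gray(raw)
}

#' Convert a raster array to a grayscale matrix
#'
#' @param img A numeric matrix, or an array with 3 (RGB) or 4 (RGBA) planes.
#' @return A numeric matrix of luminance values on the input's scale.
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    # alpha plane, if any, is ignored
    g <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    return(g)
  }
  abort("expected a matrix or an H x W x {3,4} array", class = "ecgtrace_type_error")
}

#' Write a grayscale image or binary mask as PNG
#'
#' Matrices on `[0, 1]` are written as-is; binary 0/1 masks are written with
#' foreground (1) as black ink on white paper, i.e. mask value 1 -> pixel 0.
#'
#' @param img Numeric matrix in `[0, 1]`, or a 0/1 mask with `binary = TRUE`.
#' @param path Output PNG path.
#' @param binary Treat `img` as a foreground mask and invert it for display.
#' @return `path`, invisibly.
#' @export
write_page <- function(img, path, binary = FALSE) {
  stopifnot(is.matrix(img))
  if (binary) img <- 1 - img
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image) || any(dim(image) < 1L)) {
    abort(paste0("`", arg, "` must be a non-empty numeric matrix"),
          class = "ecgtrace_type_error")
  }
  invisible(image)
}
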