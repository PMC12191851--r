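#' Define a crop box
#'
#' Rows and columns are 1-based and inclusive, row 1 at the top. The default
#' box suits full-page scans of the common 12-lead printout format (about
#' 1572 x 2213 pixels): it strips the header, footer and side borders and
#' keeps the 1240 x 2000 plotting region.
#'
#' @param row_start,row_end First and last row kept (inclusive).
#' @param col_start,col_end First and last column kept (inclusive).
#' @return A `crop_box` list.
#' @export
crop_box <- function(row_start = 281L, row_end = 1520L,
                     col_start = 151L, col_end = 2150L) {
  row_start <- as.integer(row_start); row_end <- as.integer(row_end)
  col_start <- as.integer(col_start); col_end <- as.integer(col_end)
  if (row_start < 1L || col_start < 1L || row_start > row_end || col_start > col_end) {
    abort("crop box must satisfy 1 <= start <= end on both axes",
          class = "ecgtrace_box_error")
  }
  structure(list(row_start = row_start, row_end = row_end,
                 col_start = col_start, col_end = col_end),
            class = "crop_box")
}

#' Crop a page image to its plotting region
#'
#' @param image Grayscale intensity matrix.
#' @param box A [crop_box()]; must lie entirely inside the image.
#' @return The sub-image, a matrix of shape
#'   `(row_end - row_start + 1) x (col_end - col_start + 1)`.
#' @export
#' @examples
#' img <- matrix(runif(100), 10, 10)
#' crop_roi(img, crop_box(3, 5, 4, 7))  # 3 x 4
crop_roi <- function(image, box) {
  check_image(image)
  stopifnot(inherits(box, "crop_box"))
  if (box$row_end > nrow(image) || box$col_end > ncol(image)) {
    abort(sprintf("crop box [%d,%d]x[%d,%d] exceeds image extent %dx%d",
                  box$row_start, box$row_end, box$col_start, box$col_end,
                  nrow(image), ncol(image)),
          class = "ecgtrace_box_error")
  }
  image[box$row_start:box$row_end, box$col_start:box$col_end, drop = FALSE]
}

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  w <- exp(-(seq(-r, r)^2) / (2 * sigma^2))
  w / sum(w)
}

# reflect an index vector into [1, n] with edge repetition: 0 -> 1, -1 -> 2, ...
reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  ifelse(i > n, 2L * n + 1L - i, i)
}

conv_sep <- function(x, w, dim) {
  r <- (length(w) - 1L) %/% 2L
  n <- if (dim == 1L) nrow(x) else ncol(x)
  idx <- reflect_index(seq(1L - r, n + r), n)
  # banded weight matrix acting on the reflect-padded axis
  W <- matrix(0, n, n + 2L * r)
  for (k in seq_along(w)) W[cbind(seq_len(n), seq_len(n) + k - 1L)] <- w[k]
  if (dim == 1L) W %*% x[idx, , drop = FALSE] else x[, idx, drop = FALSE] %*% t(W)
}

#' Gaussian smoothing of a page image
#'
#' Convolves the image with a normalized 2-D Gaussian kernel, truncated at
#' radius `ceiling(3 * sigma)`, using reflection (edge-repeating) padding so
#' the output has the same shape as the input. Smoothing reduces scanner
#' noise before binarization without displacing the thin waveform traces.
#'
#' @param image Grayscale intensity matrix.
#' @param sigma Gaussian standard deviation in pixels; must be positive.
#'   Default 0.7, tuned for ~1-3 px trace linewidths.
#' @return Smoothed matrix, same shape as `image`.
#' @export
gaussian_blur <- function(image, sigma = 0.7) {
  check_image(image)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    abort("`sigma` must be a single positive number", class = "ecgtrace_param_error")
  }
  w <- gaussian_kernel_1d(sigma)
  conv_sep(conv_sep(image, w, 1L), w, 2L)
}

#' Otsu binarization of a grayscale page
#'
#' Picks the global threshold maximizing the between-class variance of the
#' empirical intensity distribution, then marks every pixel strictly darker
#' than the threshold as foreground (traces are dark ink on light paper).
#' Candidate thresholds are the distinct intensity values present in the
#' image, so the search is exhaustive on the data; ties are broken toward
#' the lowest threshold.
#'
#' @param image Grayscale intensity matrix with at least two distinct values.
#' @return A list with `threshold` (on the image's intensity scale) and
#'   `mask`, an integer 0/1 matrix where 1 = foreground ink.
#' @export
#' @examples
#' img <- matrix(c(rep(20, 50), rep(220, 50)), 10, 10)
#' b <- otsu_binarize(img)
#' sum(b$mask)  # the 50 dark pixels
otsu_binarize <- function(image) {
  check_image(image)
  v <- sort(unique(as.vector(image)))
  if (length(v) < 2L) {
    abort("image has a single intensity; no threshold exists",
          class = "ecgtrace_degenerate_image")
  }
  tab <- tabulate(findInterval(image, v), nbins = length(v))
  n <- sum(tab)
  # class split at candidate t = v[i+1]: below = {x < t} = first i levels
  cw <- cumsum(tab)[-length(v)]            # n_below for each split
  cm <- cumsum(tab * v)[-length(v)]        # intensity sum below
  total <- sum(tab * v)
  w0 <- cw / n
  w1 <- 1 - w0
  mu0 <- cm / cw
  mu1 <- (total - cm) / (n - cw)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  thr <- v[which.max(bcv) + 1L]            # which.max takes the first max: lowest t
  mask <- matrix(0L, nrow(image), ncol(image))
  mask[image < thr] <- 1L
  list(threshold = thr, mask = mask)
}

#' Preprocess and binarize an ECG page
#'
#' Runs the preprocessing chain: optional crop to the plotting region,
#' Gaussian smoothing, and Otsu binarization.
#'
#' @param image Grayscale intensity matrix (see [read_page()]).
#' @param crop A [crop_box()], or `NULL` to skip cropping. The default box
#'   targets full-page scans; pass `NULL` for images that are already
#'   cropped (e.g. synthetic pages).
#' @param sigma Gaussian blur standard deviation; `NULL` or 0 skips blurring.
#' @return A list with `image` (the cropped, smoothed grayscale page),
#'   `threshold` and `mask` (0/1 foreground matrix).
#' @export
preprocess_page <- function(image, crop = NULL, sigma = 0.7) {
  check_image(image)
  if (!is.null(crop)) image <- crop_roi(image, crop)
  if (!is.null(sigma) && sigma > 0) image <- gaussian_blur(image, sigma)
  b <- otsu_binarize(image)
  list(image = image, threshold = b$threshold, mask = b$mask)
}
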