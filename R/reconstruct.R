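#' SSIM stabilizing constants
#'
#' `C1 = (K1 * L)^2` and `C2 = (K2 * L)^2` guard the luminance and contrast
#' terms against division by zero. `L` is the dynamic range of the pixel
#' values: 1 for binary masks and `[0, 1]` images, 255 for 8-bit images.
#'
#' @param K1,K2 Small positive dimensionless constants (defaults 0.01, 0.03).
#' @param L Dynamic range of the pixel values (default 1).
#' @return An `ssim_constants` list with `K1`, `K2`, `L`, `C1`, `C2`.
#' @export
ssim_constants <- function(K1 = 0.01, K2 = 0.03, L = 1) {
  stopifnot(K1 > 0, K2 > 0, L > 0)
  structure(list(K1 = K1, K2 = K2, L = L, C1 = (K1 * L)^2, C2 = (K2 * L)^2),
            class = "ssim_constants")
}

check_same_shape <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || !identical(dim(x), dim(y)) ||
      length(x) < 2L) {
    abort("`x` and `y` must be numeric arrays of identical shape (>= 2 pixels)",
          class = "ecgtrace_shape_mismatch")
  }
}

#' Global structural similarity index
#'
#' Single-window SSIM over the whole image: means, variances and covariance
#' are taken over all pixels with population (1/N) normalization, and
#' combined as
#' \deqn{SSIM(x,y) = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'                       {(\mu_x^2+\mu_y^2+C_1)(\sigma_x^2+\sigma_y^2+C_2)}}
#' SSIM is symmetric, lies in `[-1, 1]`, and equals 1 exactly when the two
#' images are identical.
#'
#' @param x,y Images (matrices or vectors) of identical shape.
#' @param consts An [ssim_constants()].
#' @return A single number in `[-1, 1]`.
#' @export
#' @examples
#' ssim(c(0, 1), c(1, 0))  # ~ -0.996
ssim <- function(x, y, consts = ssim_constants()) {
  check_same_shape(x, y)
  stopifnot(inherits(consts, "ssim_constants"))
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + consts$C1) * (2 * cxy + consts$C2)) /
    ((mx^2 + my^2 + consts$C1) * (vx + vy + consts$C2))
}

#' Mean squared error between two images
#'
#' `(1/N) * sum((x - y)^2)`. On 0/1 masks this is exactly the fraction of
#' mismatched pixels (normalized Hamming distance).
#'
#' @param x,y Images of identical shape.
#' @return A non-negative number; 0 iff the images are identical.
#' @export
mse <- function(x, y) {
  check_same_shape(x, y)
  mean((x - y)^2)
}

# Per-column row interval of an 8-connected polyline. Rows strictly between
# consecutive points are split between the two columns (the extra row of an
# odd split goes to the earlier column), so the drawn segment stays centered
# on each point and the per-column median stays close to the point itself.
trace_segments <- function(rows) {
  w <- length(rows)
  if (w == 1L) return(cbind(lo = rows, hi = rows))
  d <- diff(rows)
  n_fill <- pmax(abs(d) - 1L, 0L)
  out_ext <- sign(d) * ((n_fill + 1L) %/% 2L)   # fill attached below/after point i
  in_ext <- sign(d) * (n_fill %/% 2L)           # fill attached before point i+1
  a <- rows + c(out_ext, 0L)                    # far end of outgoing fill
  b <- rows - c(0L, in_ext)                     # far end of incoming fill
  cbind(lo = pmin(rows, a, b), hi = pmax(rows, a, b))
}

#' Render traces back onto a blank page
#'
#' Draws each trace at `baseline_row - offset` across its patch span,
#' connecting consecutive points with a midpoint-split vertical fill so each
#' polyline is 4-connected, then thickens it symmetrically to `thickness`
#' pixels vertically. Missing traces are skipped.
#'
#' @param traces An `ecg_traces` tibble (or any tibble with `baseline_row`,
#'   `col_start`, `missing`, `offsets` columns).
#' @param shape Page shape `c(rows, cols)`.
#' @param thickness Vertical line thickness in pixels (default 1).
#' @return A 0/1 integer mask of the given shape.
#' @export
render_traces <- function(traces, shape, thickness = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 1L), thickness >= 1L)
  mask <- matrix(0L, shape[1L], shape[2L])
  up <- (thickness - 1L) %/% 2L
  down <- thickness %/% 2L
  for (i in seq_len(nrow(traces))) {
    if (traces$missing[i]) next
    off <- traces$offsets[[i]]
    rows <- traces$baseline_row[i] - off
    cols <- traces$col_start[i] + seq_along(off) - 1L
    if (max(cols) > shape[2L] || any(rows < 1L) || any(rows > shape[1L])) {
      abort("trace extends outside the requested page shape",
            class = "ecgtrace_shape_mismatch")
    }
    seg <- trace_segments(rows)
    for (j in seq_along(cols)) {
      lo <- max(1L, seg[j, 1L] - up)
      hi <- min(shape[1L], seg[j, 2L] + down)
      mask[lo:hi, cols[j]] <- 1L
    }
  }
  mask
}

#' Score a reconstruction against the binarized original page
#'
#' Renders the traces and compares them with the original mask over the
#' union of the four margin-trimmed patch column spans (full row extent).
#' Separator lines and the trimmed guard bands are layout furniture that the
#' traces never encode, so they are excluded from the comparison, mirroring
#' per-patch alignment overlays. Reports global (pooled over all patch
#' pixels) and per-patch SSIM and MSE.
#'
#' @param original 0/1 mask of the binarized page (ground truth).
#' @param traces An `ecg_traces` tibble.
#' @param layout The `ecg_layout` used for extraction.
#' @param consts An [ssim_constants()].
#' @param thickness Render thickness in pixels; match the page's trace
#'   linewidth for a fair score (thickness mismatch lowers SSIM).
#' @return An `ecg_eval` object: `ssim`, `mse`, `n_pixels`, `per_patch`
#'   tibble, and the rendered `recon` mask.
#' @export
evaluate_page <- function(original, traces, layout, consts = ssim_constants(),
                          thickness = 1L) {
  check_mask(original)
  stopifnot(inherits(layout, "ecg_layout"))
  recon <- render_traces(traces, dim(original), thickness)
  per <- purrr::pmap_dfr(layout$patches, function(patch, col_start, col_end, width) {
    a <- original[, col_start:col_end]
    b <- recon[, col_start:col_end]
    tibble::tibble(patch = patch, ssim = ssim(a, b, consts), mse = mse(a, b),
                   n_pixels = length(a))
  })
  cols <- unlist(purrr::map2(layout$patches$col_start, layout$patches$col_end, seq))
  a <- original[, cols]
  b <- recon[, cols]
  structure(list(ssim = ssim(a, b, consts), mse = mse(a, b),
                 n_pixels = length(a), per_patch = per, recon = recon),
            class = "ecg_eval")
}

#' @export
print.ecg_eval <- function(x, ...) {
  cat(sprintf("<ecg_eval> SSIM %.4f | MSE %.6f over %d pixels\n",
              x$ssim, x$mse, x$n_pixels))
  print(x$per_patch)
  invisible(x)
}

#' @export
#' @method tidy ecg_eval
tidy.ecg_eval <- function(x, ...) x$per_patch

#' @export
#' @method glance ecg_eval
glance.ecg_eval <- function(x, ...) {
  tibble::tibble(ssim = x$ssim, mse = x$mse, n_pixels = x$n_pixels)
}

#' @rdname evaluate_page
#' @param report An `ecg_eval`.
#' @param path Output JSON path.
#' @export
write_eval_json <- function(report, path) {
  stopifnot(inherits(report, "ecg_eval"))
  jsonlite::write_json(
    list(ssim = report$ssim, mse = report$mse, n_pixels = report$n_pixels,
         per_patch = report$per_patch),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Alignment overlay of original vs reconstruction
#'
#' Original-only ink in red, reconstruction-only in cyan, agreement in
#' black, paper in white.
#'
#' @param original,recon 0/1 masks of identical shape.
#' @param path Output PNG path.
#' @export
write_overlay_png <- function(original, recon, path) {
  check_same_shape(original, recon)
  r <- 1 - recon                       # red channel off where recon ink
  g <- 1 - original                    # green+blue off where original ink
  png::writePNG(array(c(r, g, g), dim = c(dim(original), 3L)), path)
  invisible(path)
}

#' Plot an evaluation overlay
#'
#' @param object An `ecg_eval`.
#' @param original The 0/1 original mask compared against.
#' @param ... Unused.
#' @return A ggplot object: original-only ink red, reconstruction-only cyan,
#'   agreement black.
#' @export
#' @method autoplot ecg_eval
autoplot.ecg_eval <- function(object, original, ...) {
  check_same_shape(original, object$recon)
  cls <- matrix("paper", nrow(original), ncol(original))
  cls[original == 1L & object$recon == 0L] <- "original only"
  cls[original == 0L & object$recon == 1L] <- "reconstruction only"
  cls[original == 1L & object$recon == 1L] <- "agreement"
  d <- tibble::tibble(
    row = rep(seq_len(nrow(original)), times = ncol(original)),
    col = rep(seq_len(ncol(original)), each = nrow(original)),
    class = as.vector(cls)
  ) |> dplyr::filter(.data$class != "paper")
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(
      "agreement" = "black", "original only" = "red",
      "reconstruction only" = "cyan")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}
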