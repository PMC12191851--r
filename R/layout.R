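#' Projection histogram of a binary mask
#'
#' Counts foreground pixels per row (`axis = "horizontal"`) or per column
#' (`axis = "vertical"`). On a binarized ECG page the horizontal histogram
#' peaks at the isoelectric baseline rows, and the vertical histogram peaks
#' at the drawn lead-separator columns.
#'
#' @param mask 0/1 foreground matrix.
#' @param axis `"horizontal"` (per-row counts) or `"vertical"` (per-column).
#' @return A tibble with columns `position` (1-based row or column index)
#'   and `count`.
#' @export
projection_histogram <- function(mask, axis = c("horizontal", "vertical")) {
  check_mask(mask)
  axis <- match.arg(axis)
  counts <- if (axis == "horizontal") rowSums(mask) else colSums(mask)
  tibble::tibble(position = seq_along(counts), count = as.integer(counts))
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || any(dim(mask) < 1L)) {
    abort("`mask` must be a non-empty matrix", class = "ecgtrace_type_error")
  }
  if (!all(mask %in% c(0L, 1L))) {
    abort("`mask` values must be exactly 0 or 1", class = "ecgtrace_type_error")
  }
  invisible(mask)
}

#' Select the k dominant, well-separated peaks of a projection histogram
#'
#' Greedy selection: repeatedly take the position with the highest remaining
#' count (ties broken toward the lower index) and suppress every position
#' within `min_sep` pixels of it, until `k` peaks are found. A raw
#' "sort and take the top k" would return adjacent pixels of one thick line;
#' the suppression radius enforces one peak per physical line.
#'
#' @param hist Tibble from [projection_histogram()], or a bare numeric vector
#'   of counts.
#' @param k Number of peaks to return.
#' @param min_sep Minimum separation between selected peaks, in pixels.
#' @return Integer vector of `k` positions, sorted ascending.
#' @export
#' @examples
#' top_k_peaks(c(0, 10, 0, 9, 0, 8, 0), k = 3, min_sep = 2)  # 2 4 6
top_k_peaks <- function(hist, k, min_sep) {
  counts <- if (is.data.frame(hist)) hist$count else hist
  stopifnot(k >= 1, min_sep >= 0)
  counts <- as.numeric(counts)
  alive <- counts > 0
  picked <- integer(0)
  while (length(picked) < k && any(alive)) {
    cand <- counts
    cand[!alive] <- -Inf
    p <- which.max(cand)                       # first max = lowest index on ties
    picked <- c(picked, p)
    alive[abs(seq_along(counts) - p) < min_sep] <- FALSE
    alive[p] <- FALSE
  }
  if (length(picked) < k) {
    abort(sprintf("found only %d of %d requested peaks (min_sep = %g)",
                  length(picked), k, min_sep),
          class = "ecgtrace_insufficient_peaks")
  }
  sort(as.integer(picked))
}

#' Split a page mask into four lead-column patches
#'
#' Given the three detected separator columns, forms four column spans with
#' a `margin`-pixel guard band on each side of every separator (the guard
#' also drops the separator ink itself). The first patch starts `margin`
#' pixels from the left edge; the last patch extends to the right edge.
#' Full row extent is retained.
#'
#' @param mask 0/1 page mask.
#' @param separators Integer vector of exactly 3 separator columns, ascending.
#' @param margin Guard band half-width in pixels (default 5).
#' @return A tibble with one row per patch: `patch`, `col_start`, `col_end`
#'   (1-based inclusive) and `width`.
#' @export
split_patches <- function(mask, separators, margin = 5L) {
  check_mask(mask)
  separators <- as.integer(separators)
  margin <- as.integer(margin)
  if (length(separators) != 3L || is.unsorted(separators, strictly = TRUE)) {
    abort("`separators` must be 3 strictly increasing column indices",
          class = "ecgtrace_layout_error")
  }
  width <- ncol(mask)
  starts <- c(margin + 1L, separators + margin)
  ends <- c(separators - margin - 1L, width)
  if (any(starts > ends)) {
    abort("a patch span collapses under the separator margin",
          class = "ecgtrace_empty_patch")
  }
  tibble::tibble(patch = 1:4, col_start = starts, col_end = ends,
                 width = ends - starts + 1L)
}

#' Estimate the isoelectric baseline rows of one patch
#'
#' The flat (isoelectric) portions of each lead's trace dominate its row of
#' the patch's horizontal projection histogram, so the top `k` well-separated
#' row peaks are the lead baselines (three lead rows plus the rhythm strip).
#'
#' @param patch_mask 0/1 mask of one patch (full row extent).
#' @param k Number of baselines to find (default 4).
#' @param min_sep Minimum row separation between baselines; default one
#'   eighth of the patch height.
#' @return Integer vector of `k` baseline rows, ascending.
#' @export
estimate_baselines <- function(patch_mask, k = 4L, min_sep = NULL) {
  check_mask(patch_mask)
  if (is.null(min_sep)) min_sep <- nrow(patch_mask) / 8
  top_k_peaks(projection_histogram(patch_mask, "horizontal"), k, min_sep)
}

#' Detect the lead layout of a binarized ECG page
#'
#' Finds the three separator columns from the vertical projection histogram,
#' splits the page into four patches, and estimates four baseline rows per
#' patch from each patch's horizontal histogram. Per-patch baseline
#' estimation tolerates slightly tilted scans.
#'
#' @param mask 0/1 page mask.
#' @param margin Guard band beside separators, pixels (default 5).
#' @param sep_min_sep Minimum column separation between separator peaks;
#'   default one eighth of the page width.
#' @param base_min_sep Minimum row separation between baseline peaks;
#'   default one eighth of the page height.
#' @param n_baselines Baselines per patch (default 4: 3 lead rows + rhythm).
#' @return An `ecg_layout` object: list with `separators` (3 columns),
#'   `patches` (tibble of spans), `baselines` (tibble: `patch`, `row_index`,
#'   `row`), `margin`, and the page `shape`.
#' @export
detect_layout <- function(mask, margin = 5L, sep_min_sep = NULL,
                          base_min_sep = NULL, n_baselines = 4L) {
  check_mask(mask)
  if (is.null(sep_min_sep)) sep_min_sep <- ncol(mask) / 8
  seps <- top_k_peaks(projection_histogram(mask, "vertical"), 3L, sep_min_sep)
  patches <- split_patches(mask, seps, margin)
  baselines <- purrr::map_dfr(seq_len(4L), function(p) {
    sub <- mask[, patches$col_start[p]:patches$col_end[p], drop = FALSE]
    rows <- estimate_baselines(sub, k = n_baselines, min_sep = base_min_sep)
    tibble::tibble(patch = p, row_index = seq_along(rows), row = rows)
  })
  new_ecg_layout(separators = seps, patches = patches, baselines = baselines,
                 margin = as.integer(margin), shape = dim(mask))
}

new_ecg_layout <- function(separators, patches, baselines, margin, shape) {
  structure(list(separators = as.integer(separators), patches = patches,
                 baselines = baselines, margin = margin,
                 shape = as.integer(shape)),
            class = "ecg_layout")
}

#' @export
print.ecg_layout <- function(x, ...) {
  cat("<ecg_layout> page", x$shape[1], "x", x$shape[2], "\n")
  cat("  separators at columns:", x$separators, "\n")
  cat("  patch spans:", paste0("[", x$patches$col_start, ",", x$patches$col_end, "]",
                               collapse = " "), "\n")
  for (p in 1:4) {
    cat("  patch", p, "baseline rows:",
        x$baselines$row[x$baselines$patch == p], "\n")
  }
  invisible(x)
}

#' @rdname detect_layout
#' @param x An `ecg_layout`.
#' @param path Output JSON path.
#' @export
write_layout_json <- function(x, path) {
  stopifnot(inherits(x, "ecg_layout"))
  jsonlite::write_json(
    list(shape = x$shape, separators = x$separators, margin = x$margin,
         patches = x$patches, baselines = x$baselines),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname detect_layout
#' @export
read_layout_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_ecg_layout(separators = j$separators,
                 patches = tibble::as_tibble(j$patches),
                 baselines = tibble::as_tibble(j$baselines),
                 margin = as.integer(j$margin), shape = j$shape)
}

#' @export
#' @method tidy ecg_layout
tidy.ecg_layout <- function(x, ...) {
  dplyr::left_join(x$baselines,
                   dplyr::select(x$patches, "patch", "col_start", "col_end"),
                   by = "patch")
}
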