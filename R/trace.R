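#' Tracking parameters for trace extraction
#'
#' Window sizes are full heights centered on the reference row: a window of
#' `w` pixels around row `r` spans rows `[r - floor(w/2), r + floor(w/2)]`,
#' clipped to the patch.
#'
#' @param alpha Seed-search window height around the baseline, pixels
#'   (default 150). Must exceed the largest expected excursion of the trace
#'   at the patch's left edge.
#' @param beta Tracking window height around the previous signal point,
#'   pixels (default 75). Bounds the per-column search and so the biggest
#'   slope the tracker can follow.
#' @param gamma Validation margin, pixels (default 15): a candidate whose
#'   offset differs from the previous accepted offset by more than `gamma`
#'   is rejected as an outlier and the previous offset is carried forward.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(alpha = 150L, beta = 75L, gamma = 15L) {
  stopifnot(alpha > 0, beta > 0, gamma >= 0)
  structure(list(alpha = as.integer(alpha), beta = as.integer(beta),
                 gamma = as.integer(gamma)),
            class = "tracking_params")
}

window_rows <- function(center, size, nrows) {
  h <- size %/% 2L
  max(1L, center - h):min(nrows, center + h)
}

# median with the lower-middle convention on even counts (keeps integer rows)
median_low <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Find the seed point of a lead's trace
#'
#' Scans patch columns left to right and returns the first column holding at
#' least one foreground pixel within an `alpha`-pixel vertical window
#' centered on the baseline. The seed row is the median foreground row in
#' that window (lower middle on even counts), which is robust to trace
#' thickness.
#'
#' @param patch 0/1 mask of one patch.
#' @param baseline_row Baseline row (1-based, inside the patch).
#' @param alpha Seed-search window height, pixels.
#' @return A list with `col` and `row` of the seed point.
#' @export
find_seed <- function(patch, baseline_row, alpha = 150L) {
  check_mask(patch)
  stopifnot(baseline_row >= 1L, baseline_row <= nrow(patch))
  rows <- window_rows(baseline_row, alpha, nrow(patch))
  for (col in seq_len(ncol(patch))) {
    hit <- rows[patch[rows, col] == 1L]
    if (length(hit)) return(list(col = col, row = median_low(hit)))
  }
  abort("no signal found in the seed-search window for this baseline",
        class = "ecgtrace_no_signal")
}

#' Locate the next signal point in a column
#'
#' Returns the median foreground row (lower middle on even counts) of
#' column `col` within a `beta`-pixel window centered on the previous
#' point's row, or `NA` if the window holds no foreground pixel (a trace
#' discontinuity).
#'
#' @param patch 0/1 mask of one patch.
#' @param col Column to inspect.
#' @param prev_row Row of the previously identified signal point.
#' @param beta Tracking window height, pixels.
#' @return Integer row, or `NA_integer_`.
#' @export
next_point <- function(patch, col, prev_row, beta = 75L) {
  rows <- window_rows(prev_row, beta, nrow(patch))
  hit <- rows[patch[rows, col] == 1L]
  if (!length(hit)) return(NA_integer_)
  median_low(hit)
}

#' Track one lead's trace across a patch
#'
#' From the seed point rightward, each column's candidate point is the
#' windowed median of [next_point()]. A missing candidate (discontinuity)
#' or a candidate whose offset jumps more than `gamma` pixels from the
#' previous offset (validation failure) carries the previous offset
#' forward. Columns left of the seed are filled with the seed offset, so
#' the result always spans the full patch width. Offsets are signed pixel
#' distances from the baseline, positive above it (standard ECG display
#' orientation).
#'
#' @param patch 0/1 mask of one patch.
#' @param baseline_row Baseline row of this lead.
#' @param params A [tracking_params()].
#' @return A list with `offsets` (integer vector, length = patch width),
#'   `baseline_row`, and `seed_col`.
#' @export
track_trace <- function(patch, baseline_row, params = tracking_params()) {
  check_mask(patch)
  stopifnot(inherits(params, "tracking_params"))
  seed <- find_seed(patch, baseline_row, params$alpha)
  width <- ncol(patch)
  offsets <- integer(width)
  seed_offset <- baseline_row - seed$row
  if (seed$col > 1L) offsets[seq_len(seed$col - 1L)] <- seed_offset
  offsets[seed$col] <- seed_offset
  prev_row <- seed$row
  col <- seed$col + 1L
  while (col <= width) {
    cand <- next_point(patch, col, prev_row, params$beta)
    prev_offset <- offsets[col - 1L]
    if (is.na(cand) || abs((baseline_row - cand) - prev_offset) > params$gamma) {
      offsets[col] <- prev_offset         # gap or outlier: carry forward
    } else {
      offsets[col] <- baseline_row - cand
      prev_row <- cand
    }
    col <- col + 1L
  }
  list(offsets = offsets, baseline_row = baseline_row, seed_col = seed$col)
}

#' Extract every lead trace of a page
#'
#' Runs [track_trace()] for each (patch, baseline) pair of the layout: up to
#' 16 traces on the standard page. Baseline rows 1-3 are the 12 leads in
#' column-major order (patch 1 carries leads 1, 5, 9; lead = (row - 1) * 4 +
#' patch); row 4 is the rhythm strip, one segment per patch. A lead whose
#' seed search fails is returned as a missing trace (all-`NA` offsets), not
#' an error — real pages can lack the rhythm row.
#'
#' @param mask 0/1 page mask.
#' @param layout An `ecg_layout` from [detect_layout()].
#' @param params A [tracking_params()].
#' @return An `ecg_traces` tibble with one row per trace: `patch`,
#'   `row_index`, `lead` (`NA` for rhythm segments), `kind`
#'   (`"lead"`/`"rhythm"`), `baseline_row`, `seed_col`, `col_start`,
#'   `col_end`, `missing`, and list-column `offsets`.
#' @export
extract_page <- function(mask, layout, params = tracking_params()) {
  check_mask(mask)
  stopifnot(inherits(layout, "ecg_layout"))
  if (max(layout$patches$col_end) > ncol(mask) ||
      max(layout$baselines$row) > nrow(mask)) {
    abort("layout exceeds mask extent", class = "ecgtrace_layout_mismatch")
  }
  res <- purrr::pmap_dfr(layout$baselines, function(patch, row_index, row) {
    span <- layout$patches[layout$patches$patch == patch, ]
    sub <- mask[, span$col_start:span$col_end, drop = FALSE]
    tr <- tryCatch(track_trace(sub, row, params),
                   ecgtrace_no_signal = function(e) NULL)
    is_lead <- row_index <= 3L
    tibble::tibble(
      patch = patch, row_index = row_index,
      lead = if (is_lead) (row_index - 1L) * 4L + patch else NA_integer_,
      kind = if (is_lead) "lead" else "rhythm",
      baseline_row = row,
      seed_col = if (is.null(tr)) NA_integer_ else tr$seed_col,
      col_start = span$col_start, col_end = span$col_end,
      missing = is.null(tr),
      offsets = list(if (is.null(tr)) rep(NA_integer_, span$width) else tr$offsets)
    )
  })
  structure(res, class = c("ecg_traces", class(tibble::tibble())))
}

#' @export
#' @method tidy ecg_traces
tidy.ecg_traces <- function(x, ...) {
  tidyr::unnest_longer(tibble::as_tibble(x), "offsets",
                       values_to = "offset_px", indices_to = "col_local") |>
    dplyr::mutate(col = .data$col_start + .data$col_local - 1L) |>
    dplyr::select("lead", "kind", "patch", "row_index", "col", "offset_px")
}

#' @export
#' @method glance ecg_traces
glance.ecg_traces <- function(x, ...) {
  tibble::tibble(n_traces = nrow(x), n_leads = sum(x$kind == "lead"),
                 n_rhythm = sum(x$kind == "rhythm"),
                 n_missing = sum(x$missing))
}

#' @export
print.ecg_traces <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<ecg_traces> %d traces (%d leads, %d rhythm segments, %d missing)\n",
              g$n_traces, g$n_leads, g$n_rhythm, g$n_missing))
  NextMethod()
}

#' Write extracted traces to CSV
#'
#' Long format, one row per (trace, column): `lead`, `kind`, `patch`,
#' `row_index`, `col`, `offset_px`.
#'
#' @param traces An `ecg_traces` tibble.
#' @param path Output CSV path.
#' @export
write_traces_csv <- function(traces, path) {
  write.csv(tidy(traces), path, row.names = FALSE)
  invisible(path)
}

#' Write extracted traces to JSON (metadata plus offset arrays)
#'
#' @param traces An `ecg_traces` tibble.
#' @param path Output JSON path.
#' @export
write_traces_json <- function(traces, path) {
  jsonlite::write_json(tibble::as_tibble(traces), path,
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' Plot extracted lead traces
#'
#' One panel per trace row (lead rows 1-3 and the rhythm strip), offsets in
#' pixels above each lead's baseline.
#'
#' @param object An `ecg_traces` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot ecg_traces
autoplot.ecg_traces <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::filter(!is.na(.data$offset_px)) |>
    dplyr::mutate(label = ifelse(.data$kind == "lead",
                                 paste0("lead ", .data$lead),
                                 paste0("rhythm p", .data$patch)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$offset_px)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(ggplot2::vars(.data$row_index)) +
    ggplot2::labs(x = "page column (px)", y = "offset above baseline (px)") +
    ggplot2::theme_minimal()
}
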