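#' Beat-shape parameters for the synthetic waveform
#'
#' The waveform is a sum of Gaussian bumps — P wave, QRS complex (Q, R, S)
#' and T wave — repeated with a fixed period plus per-beat timing jitter.
#' This is a geometric model of how a printed trace looks, not a
#' physiological simulator: it exists to exercise seed search, windowed
#' median tracking, gap carry-forward and jump validation.
#'
#' Amplitudes are in pixels above (+) or below (-) the baseline; widths are
#' Gaussian standard deviations in pixels; centers are column offsets of
#' each bump from the R peak. Defaults keep the steepest per-column slope
#' (about 9 px at the R flanks) inside the validation margin gamma = 15, as
#' a printed trace's slope stays within what the tracker can follow.
#'
#' @param amplitudes Named numeric vector, bumps `p`, `q`, `r`, `s`, `t`.
#' @param widths Named numeric vector of bump standard deviations, px.
#' @param centers Named numeric vector of bump centers relative to R, px.
#' @param period Beat-to-beat period, px.
#' @param jitter Max absolute per-beat timing jitter, px (uniform integer).
#' @return A `beat_params` list.
#' @export
beat_params <- function(amplitudes = c(p = 6, q = -8, r = 40, s = -12, t = 10),
                        widths = c(p = 4, q = 2, r = 3, s = 2, t = 5),
                        centers = c(p = -30, q = -7, r = 0, s = 7, t = 35),
                        period = 180L, jitter = 5L) {
  nm <- c("p", "q", "r", "s", "t")
  if (!setequal(names(amplitudes), nm) || !setequal(names(widths), nm) ||
      !setequal(names(centers), nm) || period < 1L || jitter < 0L ||
      any(widths <= 0)) {
    abort("invalid beat parameters", class = "ecgtrace_spec_invalid")
  }
  structure(list(amplitudes = amplitudes[nm], widths = widths[nm],
                 centers = centers[nm], period = as.integer(period),
                 jitter = as.integer(jitter)),
            class = "beat_params")
}

#' Generate one synthetic lead waveform
#'
#' Produces integer pixel offsets (positive above baseline) for `length`
#' columns: Gaussian bumps at jittered beat positions, using the session's
#' current RNG stream (seed at page level for reproducibility).
#'
#' @param beat A [beat_params()].
#' @param length Number of columns (>= 1).
#' @param phase Column of the first R peak; `NULL` draws it uniformly from
#'   `[jitter + 1, period]`.
#' @return Integer vector of offsets, length `length`.
#' @export
synth_waveform <- function(beat, length, phase = NULL) {
  stopifnot(inherits(beat, "beat_params"), length >= 1L)
  if (is.null(phase)) phase <- sample(seq(beat$jitter + 1L, beat$period), 1L)
  n_beats <- (length %/% beat$period) + 2L
  jit <- if (beat$jitter > 0) sample(seq(-beat$jitter, beat$jitter), n_beats,
                                     replace = TRUE) else integer(n_beats)
  r_centers <- phase + (seq_len(n_beats) - 1L) * beat$period + jit
  cols <- seq_len(length)
  y <- numeric(length)
  for (b in seq_along(beat$amplitudes)) {
    ctr <- r_centers + beat$centers[b]
    for (ck in ctr) {
      y <- y + beat$amplitudes[b] * exp(-(cols - ck)^2 / (2 * beat$widths[b]^2))
    }
  }
  as.integer(round(y))
}

#' Specification of a synthetic ECG page
#'
#' Describes a rendered single-page 12-lead printout: four lead columns
#' separated by three full-height vertical lines, three lead rows plus a
#' bottom rhythm row, dark thin traces on light paper, with optional faint
#' background grid, label clutter near column starts, trace gaps and
#' salt-and-pepper noise. The defaults draw a 600 x 1000 page, a scaled-down
#' stand-in for ~1240 x 2000 cropped scans that keeps geometry ratios
#' (baseline spacing vs amplitude, beat period vs patch width) realistic.
#'
#' @param shape Page shape `c(rows, cols)`.
#' @param baseline_rows Four ascending isoelectric rows.
#' @param separator_cols Three ascending separator columns.
#' @param margin Guard band beside separators (px); traces are drawn on the
#'   margin-trimmed spans, as printed lead labels occupy the gaps.
#' @param thickness Trace linewidth, px (vertical).
#' @param beat A [beat_params()].
#' @param n_gaps Per-trace count of short gap erasures placed on isoelectric
#'   (flat) segments, emulating print dropouts of the isoelectric line.
#' @param gap_len Length of each auto-placed gap, px.
#' @param gap_spans Optional explicit gaps: tibble/data.frame with columns
#'   `patch`, `row_index`, `start`, `len` (local span columns); placed
#'   anywhere, for stress tests.
#' @param label_clutter Draw small dark pseudo-text near each span start.
#' @param grid Draw a background grid.
#' @param grid_gray Grid gray level; the default 0.85 sits above the
#'   trace/paper Otsu split so standard binarization removes the grid, while
#'   a dark value (e.g. 0.3) makes it survive, for stress tests.
#' @param noise_density Fraction of pixels hit by salt-and-pepper noise.
#' @param seed RNG seed; equal specs (incl. seed) give bit-identical pages.
#' @return A `page_spec` list.
#' @export
page_spec <- function(shape = c(600L, 1000L),
                      baseline_rows = c(110L, 255L, 400L, 530L),
                      separator_cols = c(250L, 500L, 750L),
                      margin = 5L, thickness = 1L,
                      beat = beat_params(),
                      n_gaps = 0L, gap_len = 10L, gap_spans = NULL,
                      label_clutter = FALSE,
                      grid = FALSE, grid_gray = 0.85,
                      noise_density = 0, seed = 1L) {
  shape <- as.integer(shape)
  baseline_rows <- as.integer(baseline_rows)
  separator_cols <- as.integer(separator_cols)
  ok <- length(shape) == 2L && all(shape >= 50L) &&
    length(baseline_rows) == 4L && !is.unsorted(baseline_rows, strictly = TRUE) &&
    length(separator_cols) == 3L && !is.unsorted(separator_cols, strictly = TRUE) &&
    all(baseline_rows >= 1L) && all(baseline_rows <= shape[1L]) &&
    all(separator_cols >= 1L) && all(separator_cols <= shape[2L]) &&
    thickness >= 1L && n_gaps >= 0L && gap_len >= 1L &&
    noise_density >= 0 && noise_density < 1
  if (!ok) abort("invalid page spec", class = "ecgtrace_spec_invalid")
  half_gap <- min(diff(baseline_rows)) / 2
  if (max(abs(beat$amplitudes)) + thickness >= half_gap) {
    abort("beat amplitudes must stay below half the baseline spacing",
          class = "ecgtrace_spec_invalid")
  }
  structure(list(shape = shape, baseline_rows = baseline_rows,
                 separator_cols = separator_cols, margin = as.integer(margin),
                 thickness = as.integer(thickness), beat = beat,
                 n_gaps = as.integer(n_gaps), gap_len = as.integer(gap_len),
                 gap_spans = gap_spans, label_clutter = isTRUE(label_clutter),
                 grid = isTRUE(grid), grid_gray = grid_gray,
                 noise_density = noise_density, seed = as.integer(seed)),
            class = "page_spec")
}

# run the code with a locally seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# flat (offset == 0) runs of at least len + 2*pad columns, away from bumps
flat_runs <- function(offsets, len, pad = 6L) {
  r <- rle(offsets == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= len + 2L * pad
  tibble::tibble(start = starts[keep] + pad, end = ends[keep] - pad - len + 1L)
}

PAPER_GRAY <- 0.95
INK_GRAY <- 0.10

#' Render a synthetic ECG page with exact ground truth
#'
#' Draws the page described by a [page_spec()] and returns it together with
#' the true layout and true per-lead offset vectors, so every stage of the
#' extraction pipeline can be scored against known truth.
#'
#' @param spec A [page_spec()].
#' @return An `ecg_ground_truth` list: `page` (grayscale matrix in `[0, 1]`),
#'   `layout` (`ecg_layout`), `traces` (`ecg_traces` tibble of true offsets,
#'   same schema as [extract_page()] output), `gaps` (tibble of applied gap
#'   spans) and `spec`.
#' @export
render_synthetic_page <- function(spec) {
  stopifnot(inherits(spec, "page_spec"))
  with_local_seed(spec$seed, {
    shape <- spec$shape
    dummy <- matrix(0L, shape[1L], shape[2L])
    patches <- split_patches(dummy, spec$separator_cols, spec$margin)
    baselines <- tidyr::expand_grid(patch = 1:4, row_index = 1:4) |>
      dplyr::mutate(row = spec$baseline_rows[.data$row_index])
    layout <- new_ecg_layout(spec$separator_cols, patches, baselines,
                             spec$margin, shape)

    # rhythm row: one continuous waveform across the page, sliced per span
    rhythm <- synth_waveform(spec$beat, shape[2L])
    traces <- purrr::pmap_dfr(baselines, function(patch, row_index, row) {
      span <- patches[patches$patch == patch, ]
      off <- if (row_index == 4L) {
        rhythm[span$col_start:span$col_end]
      } else {
        synth_waveform(spec$beat, span$width)
      }
      is_lead <- row_index <= 3L
      tibble::tibble(patch = patch, row_index = row_index,
                     lead = if (is_lead) (row_index - 1L) * 4L + patch else NA_integer_,
                     kind = if (is_lead) "lead" else "rhythm",
                     baseline_row = row, seed_col = 1L,
                     col_start = span$col_start, col_end = span$col_end,
                     missing = FALSE, offsets = list(off))
    })
    traces <- structure(traces, class = c("ecg_traces", class(tibble::tibble())))

    gaps <- auto_gaps(traces, spec)
    page <- matrix(PAPER_GRAY, shape[1L], shape[2L])
    if (spec$grid) {
      page[seq(1L, shape[1L], by = 25L), ] <- spec$grid_gray
      page[, seq(1L, shape[2L], by = 25L)] <- spec$grid_gray
    }
    page[, spec$separator_cols] <- INK_GRAY
    # per-trace masks so gap erasure cannot touch neighbouring traces
    for (i in seq_len(nrow(traces))) {
      m <- render_traces(traces[i, ], shape, spec$thickness)
      gi <- gaps[gaps$patch == traces$patch[i] &
                   gaps$row_index == traces$row_index[i], ]
      for (j in seq_len(nrow(gi))) {
        cols <- traces$col_start[i] + seq(gi$start[j], length.out = gi$len[j]) - 1L
        m[, cols] <- 0L
      }
      page[m == 1L] <- INK_GRAY
    }
    if (spec$label_clutter) {
      for (p in 1:4) {
        for (r in 1:4) {
          rr <- spec$baseline_rows[r] - 25L + sample(0:7, 12L, replace = TRUE)
          cc <- patches$col_start[p] + sample(0:24, 12L, replace = TRUE)
          page[cbind(rr, cc)] <- INK_GRAY
        }
      }
    }
    if (spec$noise_density > 0) {
      n_noise <- round(spec$noise_density * length(page))
      idx <- sample(length(page), n_noise)
      page[idx] <- ifelse(stats::runif(n_noise) < 0.5, INK_GRAY, 1)
    }
    structure(list(page = page, layout = layout, traces = traces,
                   gaps = gaps, spec = spec),
              class = "ecg_ground_truth")
  })
}

auto_gaps <- function(traces, spec) {
  explicit <- if (is.null(spec$gap_spans)) {
    tibble::tibble(patch = integer(), row_index = integer(),
                   start = integer(), len = integer())
  } else {
    tibble::as_tibble(spec$gap_spans)
  }
  if (spec$n_gaps == 0L) return(explicit)
  auto <- purrr::pmap_dfr(
    traces[, c("patch", "row_index", "offsets")],
    function(patch, row_index, offsets) {
      runs <- flat_runs(offsets, spec$gap_len)
      if (!nrow(runs)) return(NULL)
      picks <- runs[sample(nrow(runs), min(spec$n_gaps, nrow(runs))), ]
      tibble::tibble(patch = patch, row_index = row_index,
                     start = as.integer(purrr::map2_int(
                       picks$start, picks$end,
                       function(s, e) if (e > s) sample(s:e, 1L) else s)),
                     len = spec$gap_len)
    })
  dplyr::bind_rows(explicit, auto)
}

#' @export
print.ecg_ground_truth <- function(x, ...) {
  cat(sprintf("<ecg_ground_truth> %d x %d page, seed %d, thickness %d, %d gaps\n",
              x$spec$shape[1], x$spec$shape[2], x$spec$seed,
              x$spec$thickness, nrow(x$gaps)))
  invisible(x)
}

#' Generate a reproducible corpus of synthetic pages
#'
#' Page `i` uses seed `seed + i - 1` and the given spec overrides;
#' `thickness` may be a vector recycled across pages.
#'
#' @param n Number of pages.
#' @param seed Base seed.
#' @param thickness Trace linewidth(s), recycled over pages.
#' @param ... Further arguments passed to [page_spec()].
#' @return A list of `ecg_ground_truth` objects.
#' @export
synthetic_corpus <- function(n, seed = 1L, thickness = 1L, ...) {
  th <- rep_len(thickness, n)
  purrr::map(seq_len(n), function(i) {
    render_synthetic_page(page_spec(seed = seed + i - 1L, thickness = th[i], ...))
  })
}
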