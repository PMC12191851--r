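# Independent brute-force oracles used to cross-check the implementation.

# Otsu threshold by explicit exhaustive search: for every candidate split,
# compute the between-class variance from first principles.
otsu_brute <- function(image) {
  v <- sort(unique(as.vector(image)))
  x <- as.vector(image)
  best <- -Inf
  best_t <- NA_real_
  for (t in v[-1]) {
    lo <- x[x < t]
    hi <- x[x >= t]
    w0 <- length(lo) / length(x)
    w1 <- length(hi) / length(x)
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) {   # strict improvement: ties keep the lowest t
      best <- bcv
      best_t <- t
    }
  }
  best_t
}

# Literal, unoptimized transcription of the tracking procedure: seed search
# by double loop, then column-by-column windowed median with carry-forward
# on gaps and on validation failures. Kept deliberately naive.
track_trace_literal <- function(patch, baseline_row, params) {
  alpha <- params$alpha; beta <- params$beta; gamma <- params$gamma
  h <- nrow(patch); w <- ncol(patch)
  lo <- max(1, baseline_row - alpha %/% 2)
  hi <- min(h, baseline_row + alpha %/% 2)
  seed_col <- NA
  for (col in 1:w) {
    rows_hit <- c()
    for (r in lo:hi) if (patch[r, col] == 1) rows_hit <- c(rows_hit, r)
    if (length(rows_hit) > 0) {
      seed_col <- col
      rows_hit <- sort(rows_hit)
      seed_row <- rows_hit[ceiling(length(rows_hit) / 2)]
      break
    }
  }
  if (is.na(seed_col)) return(NULL)
  offsets <- rep(baseline_row - seed_row, w)
  prev_row <- seed_row
  if (seed_col < w) {
    for (col in (seed_col + 1):w) {
      wl <- max(1, prev_row - beta %/% 2)
      wh <- min(h, prev_row + beta %/% 2)
      rows_hit <- c()
      for (r in wl:wh) if (patch[r, col] == 1) rows_hit <- c(rows_hit, r)
      prev_offset <- offsets[col - 1]
      if (length(rows_hit) == 0) {
        offsets[col] <- prev_offset
      } else {
        rows_hit <- sort(rows_hit)
        cand <- rows_hit[ceiling(length(rows_hit) / 2)]
        if (abs((baseline_row - cand) - prev_offset) > gamma) {
          offsets[col] <- prev_offset
        } else {
          offsets[col] <- baseline_row - cand
          prev_row <- cand
        }
      }
    }
  }
  list(offsets = as.integer(offsets), seed_col = seed_col)
}

# small synthetic page for fast unit tests: 200 x 400, scaled-down beats
tiny_spec <- function(seed = 1L, ...) {
  page_spec(shape = c(200L, 400L),
            baseline_rows = c(40L, 90L, 140L, 180L),
            separator_cols = c(100L, 200L, 300L),
            beat = beat_params(
              amplitudes = c(p = 3, q = -4, r = 15, s = -5, t = 5),
              widths = c(p = 3, q = 1.5, r = 2, s = 1.5, t = 4),
              centers = c(p = -15, q = -4, r = 0, s = 4, t = 18),
              period = 80L, jitter = 3L),
            seed = seed, ...)
}

tiny_params <- function() tracking_params(alpha = 40L, beta = 30L, gamma = 15L)
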