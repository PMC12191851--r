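make_patch <- function(h, w) matrix(0L, h, w)

test_that("find_seed locates the first inked column near the baseline", {
  p <- make_patch(100, 30)
  p[50, ] <- 1L
  expect_equal(find_seed(p, 50), list(col = 1L, row = 50L))

  # trace sitting 10 px below the baseline: found with a wide window,
  # missed with a 10 px window (half-height 5)
  p <- make_patch(100, 30)
  p[60, 7:30] <- 1L
  expect_equal(find_seed(p, 50, alpha = 150L), list(col = 7L, row = 60L))
  expect_error(find_seed(p, 50, alpha = 10L), class = "ecgtrace_no_signal")

  # thick line: median row, lower middle on even counts
  p <- make_patch(100, 5)
  p[41:44, 2] <- 1L
  expect_equal(find_seed(p, 40, alpha = 20L), list(col = 2L, row = 42L))
})

test_that("next_point returns the windowed median or NA on a gap", {
  p <- make_patch(60, 4)
  p[18:22, 2] <- 1L
  expect_equal(next_point(p, 2, prev_row = 20, beta = 30), 20L)
  expect_true(is.na(next_point(p, 3, prev_row = 20, beta = 30)))
  p[10:11, 4] <- 1L
  expect_equal(next_point(p, 4, prev_row = 12, beta = 10), 10L)  # lower middle
})

test_that("track_trace follows a flat line exactly", {
  p <- make_patch(80, 50)
  p[30, ] <- 1L
  tr <- track_trace(p, 30, tiny_params())
  expect_equal(tr$offsets, rep(0L, 50))
  expect_equal(tr$seed_col, 1L)
})

test_that("track_trace carries the last offset across a gap", {
  p <- make_patch(80, 80)
  p[30, c(1:59, 70:80)] <- 1L
  tr <- track_trace(p, 30, tiny_params())
  expect_equal(tr$offsets, rep(0L, 80))
})

test_that("validation rejects jumps beyond gamma and carries forward", {
  p <- make_patch(100, 60)
  p[50, 1:30] <- 1L
  p[30, 31:60] <- 1L   # abrupt jump of 20 px, gamma = 15
  tr <- track_trace(p, 50, tracking_params(alpha = 40, beta = 75, gamma = 15))
  expect_equal(tr$offsets, rep(0L, 60))

  # same geometry with a tolerant gamma: the jump is accepted
  tr2 <- track_trace(p, 50, tracking_params(alpha = 40, beta = 75, gamma = 25))
  expect_equal(tr2$offsets[31:60], rep(20L, 30))
})

test_that("pre-seed columns are filled with the seed offset", {
  p <- make_patch(80, 40)
  p[25, 11:40] <- 1L
  tr <- track_trace(p, 30, tiny_params())
  expect_equal(tr$seed_col, 11L)
  expect_equal(tr$offsets, rep(5L, 40))
})

test_that("trace length equals patch width and jumps respect gamma", {
  set.seed(41)
  for (i in 1:20) {
    h <- sample(30:80, 1); w <- sample(10:50, 1)
    p <- matrix(rbinom(h * w, 1, 0.15), h, w)
    params <- tracking_params(alpha = sample(10:60, 1),
                              beta = sample(6:40, 1),
                              gamma = sample(0:12, 1))
    b <- sample(seq_len(h), 1)
    tr <- tryCatch(track_trace(p, b, params),
                   ecgtrace_no_signal = function(e) NULL)
    if (is.null(tr)) next
    expect_length(tr$offsets, w)
    if (tr$seed_col < w) {
      post <- tr$offsets[tr$seed_col:w]
      expect_lte(max(abs(diff(post))), params$gamma)
    }
  }
})

test_that("track_trace matches the literal step-by-step transcription", {
  set.seed(51)
  for (i in 1:30) {
    h <- sample(20:60, 1); w <- sample(5:50, 1)
    p <- matrix(rbinom(h * w, 1, 0.12), h, w)
    params <- tracking_params(alpha = sample(8:40, 1),
                              beta = sample(6:30, 1),
                              gamma = sample(0:15, 1))
    b <- sample(seq_len(h), 1)
    mine <- tryCatch(track_trace(p, b, params),
                     ecgtrace_no_signal = function(e) NULL)
    ref <- track_trace_literal(p, b, params)
    if (is.null(ref)) {
      expect_null(mine)
    } else {
      expect_equal(mine$offsets, ref$offsets)
      expect_equal(mine$seed_col, ref$seed_col)
    }
  }
})

test_that("extract_page yields 16 traces with column-major lead numbering", {
  gt <- render_synthetic_page(tiny_spec(seed = 6))
  mask <- otsu_binarize(gt$page)$mask
  tr <- extract_page(mask, gt$layout, tiny_params())
  g <- glance(tr)
  expect_equal(g$n_traces, 16L)
  expect_equal(g$n_leads, 12L)
  expect_equal(g$n_rhythm, 4L)
  expect_equal(g$n_missing, 0L)
  expect_equal(tr$lead[tr$patch == 1 & tr$kind == "lead"], c(1L, 5L, 9L))
  expect_equal(tr$lead[tr$patch == 4 & tr$kind == "lead"], c(4L, 8L, 12L))
  expect_true(all(lengths(tr$offsets) ==
                    tr$col_end - tr$col_start + 1L))

  td <- tidy(tr)
  expect_equal(nrow(td), sum(lengths(tr$offsets)))
  expect_true(all(c("lead", "kind", "patch", "row_index", "col", "offset_px")
                  %in% names(td)))
})

test_that("a lead with no ink becomes a missing trace, not an error", {
  gt <- render_synthetic_page(tiny_spec(seed = 7))
  mask <- otsu_binarize(gt$page)$mask
  # blank out the rhythm row's ink within the patch spans
  for (p in 1:4) {
    span <- gt$layout$patches[p, ]
    mask[160:200, span$col_start:span$col_end] <- 0L
  }
  tr <- extract_page(mask, gt$layout, tiny_params())
  expect_equal(sum(tr$missing), 4L)
  expect_true(all(tr$kind[tr$missing] == "rhythm"))
  expect_true(all(is.na(tr$offsets[[which(tr$missing)[1]]])))
  expect_equal(glance(tr)$n_leads, 12L)
})

test_that("clean thin-trace extraction recovers truth within one pixel", {
  gt <- render_synthetic_page(tiny_spec(seed = 8))
  mask <- otsu_binarize(gt$page)$mask
  tr <- extract_page(mask, gt$layout, tiny_params())
  te <- trace_errors(gt$traces, tr)
  expect_true(all(te$mae <= 1))
})

test_that("gap degradation changes trace values, never lengths", {
  gt0 <- render_synthetic_page(tiny_spec(seed = 9))
  gt1 <- render_synthetic_page(tiny_spec(seed = 9, n_gaps = 2L, gap_len = 8L))
  expect_identical(lengths(gt0$traces$offsets), lengths(gt1$traces$offsets))
  mask0 <- otsu_binarize(gt0$page)$mask
  mask1 <- otsu_binarize(gt1$page)$mask
  tr0 <- extract_page(mask0, gt0$layout, tiny_params())
  tr1 <- extract_page(mask1, gt1$layout, tiny_params())
  expect_identical(lengths(tr0$offsets), lengths(tr1$offsets))
})
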