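test_that("render_traces draws a flat trace as a one-pixel baseline line", {
  tr <- tibble::tibble(baseline_row = 20L, col_start = 3L, missing = FALSE,
                       offsets = list(rep(0L, 10)))
  m <- render_traces(tr, c(40L, 15L))
  expect_equal(sum(m), 10L)
  expect_true(all(m[20, 3:12] == 1L))
})

test_that("rendered polylines are 8-connected and thickness dilates rows", {
  tr <- tibble::tibble(baseline_row = 50L, col_start = 1L, missing = FALSE,
                       offsets = list(c(0L, 12L, -9L, -9L, 0L)))
  m <- render_traces(tr, c(100L, 5L))
  # every adjacent column pair shares or touches rows diagonally
  segs <- apply(m, 2, function(col) range(which(col == 1L)))
  for (j in 1:4) {
    expect_true(segs[1, j + 1] <= segs[2, j] + 1 &&
                  segs[2, j + 1] >= segs[1, j] - 1)
  }
  m3 <- render_traces(tr, c(100L, 5L), thickness = 3L)
  expect_true(all(m3[which(m == 1L)] == 1L))
  expect_gt(sum(m3), sum(m))
})

test_that("ssim satisfies the identity, symmetry and bound properties", {
  set.seed(61)
  for (i in 1:10) {
    x <- matrix(runif(64), 8, 8)
    y <- matrix(runif(64), 8, 8)
    expect_equal(ssim(x, x), 1)
    expect_equal(ssim(x, y), ssim(y, x))
    expect_gte(ssim(x, y), -1)
    expect_lte(ssim(x, y), 1)
  }
  expect_error(ssim(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "ecgtrace_shape_mismatch")
})

test_that("ssim matches direct evaluation of its defining formula", {
  # x = (0,1), y = (1,0): mu = 0.5 each, sigma^2 = 0.25 each, cov = -0.25
  cst <- ssim_constants(K1 = 0.01, K2 = 0.03, L = 1)
  direct <- ((2 * 0.5 * 0.5 + cst$C1) * (2 * -0.25 + cst$C2)) /
    ((0.5^2 + 0.5^2 + cst$C1) * (0.25 + 0.25 + cst$C2))
  expect_equal(ssim(c(0, 1), c(1, 0)), direct)
  expect_equal(direct, -0.996, tolerance = 5e-4)

  set.seed(62)
  x <- matrix(runif(100), 10, 10)
  y <- x + matrix(rnorm(100, sd = 0.1), 10, 10)
  n <- 100
  mx <- mean(x); my <- mean(y)
  direct2 <- ((2 * mx * my + cst$C1) * (2 * (sum((x - mx) * (y - my)) / n) + cst$C2)) /
    ((mx^2 + my^2 + cst$C1) * (sum((x - mx)^2) / n + sum((y - my)^2) / n + cst$C2))
  expect_equal(ssim(x, y), direct2, tolerance = 1e-12)
})

test_that("mse is zero iff identical, symmetric, and Hamming on masks", {
  set.seed(63)
  x <- matrix(rbinom(1000, 1, 0.3), 40, 25)
  expect_equal(mse(x, x), 0)
  y <- x
  flip <- sample(1000, 2)
  y[flip] <- 1L - y[flip]
  expect_equal(mse(x, y), 0.002)
  expect_equal(mse(x, y), mse(y, x))
  expect_equal(mse(x, y), mean(x != y))
  a <- matrix(runif(50), 5, 10); b <- matrix(runif(50), 5, 10)
  expect_gt(mse(a, b), 0)
})

test_that("evaluating ground-truth traces against a clean page is exact", {
  gt <- render_synthetic_page(tiny_spec(seed = 10))
  mask <- otsu_binarize(gt$page)$mask
  ev <- evaluate_page(mask, gt$traces, gt$layout)
  expect_identical(ev$ssim, 1)
  expect_identical(ev$mse, 0)
  expect_true(all(ev$per_patch$ssim == 1))
  expect_true(all(ev$per_patch$mse == 0))
})

test_that("thickness mismatch between page and rendering lowers SSIM", {
  gt <- render_synthetic_page(tiny_spec(seed = 11, thickness = 3L))
  mask <- otsu_binarize(gt$page)$mask
  matched <- evaluate_page(mask, gt$traces, gt$layout, thickness = 3L)
  thin <- evaluate_page(mask, gt$traces, gt$layout, thickness = 1L)
  expect_identical(matched$ssim, 1)
  expect_lt(thin$ssim, matched$ssim)
  expect_gt(thin$mse, matched$mse)
})

test_that("render-extract round trips are exact on flat pages, near-fixed otherwise", {
  # flat traces: extraction of a rendering is lossless, so the loop is a
  # fixed point immediately
  flat <- tibble::tibble(patch = 1:4, row_index = 1L, lead = 1:4,
                         kind = "lead", baseline_row = 30L,
                         seed_col = 1L,
                         col_start = c(6L, 105L, 205L, 305L),
                         col_end = c(94L, 194L, 294L, 400L),
                         missing = FALSE)
  flat$offsets <- purrr::map(flat$col_end - flat$col_start + 1L,
                             function(w) rep(2L, w))
  with_seps <- render_traces(flat, c(100L, 400L))
  with_seps[, c(100, 200, 300)] <- 1L
  lay <- detect_layout(with_seps, margin = 5L, n_baselines = 1L)
  m1 <- render_traces(flat, c(100L, 400L))
  tr <- extract_page(m1, lay, tiny_params())
  m2 <- render_traces(tr, c(100L, 400L))
  expect_identical(m2, m1)

  # curved traces: per-column medians of a connected polyline sit up to a
  # pixel off on steep slopes, so one pass perturbs a small ink fraction
  gt <- render_synthetic_page(tiny_spec(seed = 12))
  m1 <- render_traces(gt$traces, gt$spec$shape)
  tr <- extract_page(m1, gt$layout, tiny_params())
  m2 <- render_traces(tr, dim(m1))
  expect_lt(sum(m1 != m2) / sum(m1), 0.1)   # confined to steep slope columns
})

test_that("overlay and report artifacts are written faithfully", {
  gt <- render_synthetic_page(tiny_spec(seed = 13))
  mask <- otsu_binarize(gt$page)$mask
  ev <- evaluate_page(mask, gt$traces, gt$layout)
  f <- withr::local_tempfile(fileext = ".json")
  write_eval_json(ev, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$ssim, ev$ssim)
  expect_equal(j$mse, ev$mse)
  expect_equal(nrow(j$per_patch), 4L)

  g <- withr::local_tempfile(fileext = ".png")
  write_overlay_png(mask, ev$recon, g)
  arr <- png::readPNG(g)
  expect_equal(dim(arr), c(dim(mask), 3L))
  agree <- mask == 1L & ev$recon == 1L
  expect_true(all(arr[, , 1][agree] == 0))   # agreement drawn black
})
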