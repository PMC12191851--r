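#' Segment one page image in memory
#'
#' The full pipeline on a loaded grayscale page: optional crop, Gaussian
#' blur, Otsu binarization, layout detection, trace tracking, reconstruction
#' and fidelity scoring.
#'
#' @param image Grayscale page matrix (see [read_page()]).
#' @param config An [ecg_config()].
#' @return A list: `pre` (preprocessing result), `layout`, `traces`
#'   (`ecg_traces`), `eval` (`ecg_eval`).
#' @export
segment_page <- function(image, config = ecg_config()) {
  stopifnot(inherits(config, "ecg_config"))
  pre <- preprocess_page(image,
                         crop = if (config$apply_crop) config$crop else NULL,
                         sigma = config$sigma)
  layout <- detect_layout(pre$mask, margin = config$margin,
                          sep_min_sep = config$sep_min_sep,
                          base_min_sep = config$base_min_sep)
  params <- tracking_params(config$alpha, config$beta, config$gamma)
  traces <- extract_page(pre$mask, layout, params)
  consts <- ssim_constants(config$K1, config$K2, config$L)
  ev <- evaluate_page(pre$mask, traces, layout, consts, config$thickness)
  list(pre = pre, layout = layout, traces = traces, eval = ev)
}

#' Run the segmentation pipeline on an image file, writing artifacts
#'
#' Writes, under `out_dir` (created if needed): `mask.png` (binarized page),
#' `layout.json`, `traces.csv`, `traces.json`, `recon.png` (reconstructed
#' page), `overlay.png` (original red / reconstruction cyan) and
#' `eval.json`. Leads whose seed search fails are recorded as missing
#' traces, not an error.
#'
#' @param input_path PNG or JPEG page image.
#' @param out_dir Output directory.
#' @param config An [ecg_config()].
#' @return The [segment_page()] result, invisibly.
#' @export
run_segment <- function(input_path, out_dir, config = ecg_config()) {
  img <- read_page(input_path)
  res <- segment_page(img, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_page(res$pre$mask, file.path(out_dir, "mask.png"), binary = TRUE)
  write_layout_json(res$layout, file.path(out_dir, "layout.json"))
  write_traces_csv(res$traces, file.path(out_dir, "traces.csv"))
  write_traces_json(res$traces, file.path(out_dir, "traces.json"))
  write_page(res$eval$recon, file.path(out_dir, "recon.png"), binary = TRUE)
  write_overlay_png(res$pre$mask, res$eval$recon,
                    file.path(out_dir, "overlay.png"))
  write_eval_json(res$eval, file.path(out_dir, "eval.json"))
  invisible(res)
}

#' Generate synthetic pages on disk with truth and a manifest
#'
#' Page `i` is rendered from `page_spec(seed = seed + i - 1, ...)` and saved
#' as `page_<i>.png` with `truth_<i>.json` (layout + offsets) and
#' `truth_<i>.csv` (same schema as [write_traces_csv()]); `manifest.json`
#' lists seeds and file names so a benchmark run is reproducible.
#'
#' @param out_dir Output directory.
#' @param n Number of pages.
#' @param seed Base seed.
#' @param ... Passed to [page_spec()].
#' @return Manifest as a tibble, invisibly.
#' @export
run_synth <- function(out_dir, n = 1L, seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- purrr::map_dfr(seq_len(n), function(i) {
    gt <- render_synthetic_page(page_spec(seed = seed + i - 1L, ...))
    page_file <- sprintf("page_%03d.png", i)
    truth_json <- sprintf("truth_%03d.json", i)
    truth_csv <- sprintf("truth_%03d.csv", i)
    write_page(gt$page, file.path(out_dir, page_file))
    jsonlite::write_json(
      list(seed = gt$spec$seed, shape = gt$spec$shape,
           separators = gt$layout$separators,
           baselines = gt$layout$baselines,
           traces = tibble::as_tibble(gt$traces)),
      file.path(out_dir, truth_json), auto_unbox = FALSE, digits = NA,
      na = "null")
    write_traces_csv(gt$traces, file.path(out_dir, truth_csv))
    tibble::tibble(page = i, seed = gt$spec$seed, image = page_file,
                   truth_json = truth_json, truth_csv = truth_csv)
  })
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(man)
}

#' Per-lead errors of extracted traces against ground truth
#'
#' @param truth,extracted `ecg_traces` tibbles over the same layout.
#' @return A tibble with one row per trace: `patch`, `row_index`, `lead`,
#'   `missing`, `rmse`, `mae`, `max_jump` (largest successive-offset step in
#'   the extracted trace).
#' @export
trace_errors <- function(truth, extracted) {
  stopifnot(nrow(truth) == nrow(extracted))
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    a <- truth$offsets[[i]]
    b <- extracted$offsets[[i]]
    stopifnot(length(a) == length(b))
    err <- b - a
    tibble::tibble(patch = truth$patch[i], row_index = truth$row_index[i],
                   lead = truth$lead[i], missing = extracted$missing[i],
                   rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                   max_jump = if (all(is.na(b))) NA_real_
                              else max(abs(diff(b)), 0))
  })
}

layout_errors <- function(truth_layout, layout) {
  sep_err <- max(abs(sort(layout$separators) - sort(truth_layout$separators)))
  b <- dplyr::inner_join(truth_layout$baselines, layout$baselines,
                         by = c("patch", "row_index"),
                         suffix = c("_true", "_est"))
  list(sep_err = sep_err, base_err = max(abs(b$row_est - b$row_true)))
}

#' Benchmark the pipeline on a synthetic corpus
#'
#' Runs binarization, layout detection, extraction and evaluation on each
#' ground-truth page and scores every stage against the known truth.
#' Reconstruction is rendered at each page's true trace thickness, and
#' pages are binarized without blurring by default (synthetic pages are
#' noise-free; blurring a 1-px trace widens the binarized line, which is a
#' thickness mismatch, not a tracking error).
#'
#' @param truths List of `ecg_ground_truth` pages (see [synthetic_corpus()]).
#' @param config An [ecg_config()]; its `sigma` is applied before
#'   binarization (`NULL` = none) and its windows drive tracking.
#' @return A tibble, one row per page: `seed`, `thickness`, `sep_err`,
#'   `base_err`, `ssim`, `mse`, `max_rmse`, `mean_rmse`, `max_jump`,
#'   `n_missing`.
#' @export
benchmark_pages <- function(truths, config = ecg_config(sigma = NULL)) {
  stopifnot(inherits(config, "ecg_config"))
  params <- tracking_params(config$alpha, config$beta, config$gamma)
  consts <- ssim_constants(config$K1, config$K2, config$L)
  purrr::map_dfr(truths, function(gt) {
    pre <- preprocess_page(gt$page, crop = NULL, sigma = config$sigma)
    layout <- detect_layout(pre$mask, margin = config$margin,
                            sep_min_sep = config$sep_min_sep,
                            base_min_sep = config$base_min_sep)
    traces <- extract_page(pre$mask, layout, params)
    ev <- evaluate_page(pre$mask, traces, layout, consts,
                        thickness = gt$spec$thickness)
    le <- layout_errors(gt$layout, layout)
    te <- trace_errors(gt$traces, traces)
    tibble::tibble(seed = gt$spec$seed, thickness = gt$spec$thickness,
                   sep_err = le$sep_err, base_err = le$base_err,
                   ssim = ev$ssim, mse = ev$mse,
                   max_rmse = max(te$rmse[!te$missing]),
                   mean_rmse = mean(te$rmse[!te$missing]),
                   max_jump = max(te$max_jump, na.rm = TRUE),
                   n_missing = sum(te$missing))
  })
}
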