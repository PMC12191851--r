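#' Pipeline run configuration
#'
#' Bundles every tunable of the segmentation pipeline. Defaults are the
#' tuned operating point for printed 12-lead pages: Gaussian blur
#' `sigma = 0.7`, seed-search window `alpha = 150` px, tracking window
#' `beta = 75` px, validation margin `gamma = 15` px, separator guard band
#' `margin = 5` px.
#'
#' @param sigma Gaussian blur standard deviation, px; `NULL` disables.
#' @param alpha,beta,gamma Tracking windows/margin, px (see
#'   [tracking_params()]).
#' @param margin Guard band beside separator lines, px.
#' @param apply_crop Crop full-page scans to the plotting region first.
#' @param crop A [crop_box()] used when `apply_crop` is `TRUE`.
#' @param sep_min_sep,base_min_sep Peak separation minima (px); `NULL` means
#'   width/8 and height/8.
#' @param K1,K2,L SSIM constants (see [ssim_constants()]).
#' @param thickness Render linewidth for reconstruction, px.
#' @return An `ecg_config` list.
#' @export
ecg_config <- function(sigma = 0.7, alpha = 150L, beta = 75L, gamma = 15L,
                       margin = 5L, apply_crop = FALSE, crop = crop_box(),
                       sep_min_sep = NULL, base_min_sep = NULL,
                       K1 = 0.01, K2 = 0.03, L = 1, thickness = 1L) {
  structure(list(sigma = sigma, alpha = as.integer(alpha),
                 beta = as.integer(beta), gamma = as.integer(gamma),
                 margin = as.integer(margin), apply_crop = isTRUE(apply_crop),
                 crop = crop, sep_min_sep = sep_min_sep,
                 base_min_sep = base_min_sep, K1 = K1, K2 = K2, L = L,
                 thickness = as.integer(thickness)),
            class = "ecg_config")
}

#' @rdname ecg_config
#' @param path YAML file with a subset of the fields above; unlisted fields
#'   keep their defaults.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- ecg_config()
  unknown <- setdiff(names(y), names(cfg))
  if (length(unknown)) {
    abort(paste("unknown config fields:", paste(unknown, collapse = ", ")),
          class = "ecgtrace_config_error")
  }
  if (!is.null(y$crop)) y$crop <- do.call(crop_box, y$crop)
  args <- utils::modifyList(unclass(cfg), y, keep.null = TRUE)
  do.call(ecg_config, args)
}

#' @export
print.ecg_config <- function(x, ...) {
  cat("<ecg_config>\n")
  cat(sprintf("  sigma: %s   alpha: %d   beta: %d   gamma: %d   margin: %d\n",
              format(x$sigma), x$alpha, x$beta, x$gamma, x$margin))
  cat(sprintf("  apply_crop: %s   crop: rows %d..%d cols %d..%d\n",
              x$apply_crop, x$crop$row_start, x$crop$row_end,
              x$crop$col_start, x$crop$col_end))
  cat(sprintf("  ssim: K1 %g K2 %g L %g   render thickness: %d\n",
              x$K1, x$K2, x$L, x$thickness))
  invisible(x)
}
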