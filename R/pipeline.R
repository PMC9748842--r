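# Pipeline configuration and the register entry point tying the stages
# together: preprocess -> select landmarks -> predict homologous points ->
# fit TPS -> warp.

pipeline_defaults <- function() {
  list(image_size = 512L, patch_size = 16L, embed_dim = 128L, n_blocks = 6L,
       n_heads = 4L, L = 75L, ffn_expansion = 4L, use_layernorm = TRUE,
       temperature = 1,
       contrast_threshold = 0.04, edge_fraction = 0.19, min_dist = 30,
       pad = 50L, tps_lambda = 1,
       epochs = 128L, tps_max_dev = 16, rotation_range = 20,
       same_modality_fraction = 0.5, lr = 1e-4, batch_size = 4L)
}

#' Pipeline configuration
#'
#' Aggregates the network configuration with the landmark, preprocessing,
#' TPS and training parameters. Defaults are the pipeline's published
#' operating point (contrast 0.04, edge fraction 0.19, 50-px padding,
#' L = 75, d = 128, six blocks, 128 epochs, 16-px TPS augmentation, +/-20
#' degree rotations).
#'
#' @param ... named overrides of the default fields.
#' @return list of class `hp_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("pipeline_config: unknown field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "hp_pipeline_config")
}

#' Extract the network configuration from a pipeline configuration
#' @param cfg `hp_pipeline_config`.
#' @return `hp_model_config`.
#' @export
as_model_config <- function(cfg) {
  model_config(cfg$image_size, cfg$patch_size, cfg$embed_dim, cfg$n_blocks,
               cfg$n_heads, cfg$L, cfg$ffn_expansion, cfg$use_layernorm,
               cfg$temperature)
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Missing fields take their defaults; an empty file yields the full default
#' configuration; unknown keys are rejected with a listing.
#'
#' @param path file path (.yaml/.yml/.json).
#' @return `hp_pipeline_config`.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop("load_config: parse error in ", path,
                                      ": ", conditionMessage(e)))
  } else if (ext == "json") {
    if (file.size(path) == 0) NULL
    else tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("load_config: parse error in ",
                                           path, ": ", conditionMessage(e)))
  } else {
    stop("load_config: unsupported extension '", ext, "'")
  }
  if (is.null(obj)) obj <- list()
  do.call(pipeline_config, obj)
}

#' Save a pipeline configuration to YAML or JSON
#' @param cfg `hp_pipeline_config`.
#' @param path output path (.yaml/.yml/.json).
#' @export
save_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(unclass(cfg), path)
  } else if (ext == "json") {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("save_config: unsupported extension '", ext, "'")
  }
  invisible(path)
}

#' Register a moving (histology) image onto a fixed (MR) image
#'
#' Runs the full pipeline: normalize both inputs, center-zoom each on its
#' foreground with the configured padding, select landmarks on the moving
#' image, predict their homologous fixed-space points with the network, fit
#' a thin-plate spline on the predicted pairs and warp the moving image into
#' fixed-image space. Output files: `<out_prefix>_warped.png`,
#' `<out_prefix>_transform.json`, `<out_prefix>_points_moving.csv`,
#' `<out_prefix>_points_fixed.csv`.
#'
#' @param moving_path,fixed_path input raster paths (PNG/TIFF).
#' @param weights_path model checkpoint path (see [save_model()]).
#' @param config `hp_pipeline_config`.
#' @param out_prefix output path prefix.
#' @param dry_run validate inputs and write nothing (default `FALSE`).
#' @return (invisibly) list with `warped`, `transform`, `landmarks`,
#'   `predicted`, and the two zoom transforms.
#' @export
run_register <- function(moving_path, fixed_path, weights_path,
                         config = pipeline_config(), out_prefix = "registered",
                         dry_run = FALSE) {
  for (p in c(moving_path, fixed_path)) {
    if (!file.exists(p)) stop("run_register [input]: file not found: ", p)
  }
  if (!file.exists(weights_path)) {
    stop("run_register [weights]: weights not found: ", weights_path)
  }
  if (dry_run) return(invisible(NULL))
  model <- load_model(weights_path)
  mov <- tryCatch(normalize_image(read_raster(moving_path), "histology"),
                  error = function(e) stop("run_register [preprocess]: ",
                                           conditionMessage(e)))
  fix <- normalize_image(read_raster(fixed_path), "mr")
  mz <- center_zoom(mov, foreground_bbox(mov), pad = config$pad,
                    out_size = config$image_size)
  fz <- center_zoom(fix, foreground_bbox(fix), pad = config$pad,
                    out_size = config$image_size)
  X <- tryCatch(select_landmarks(mz$image, min_dist = config$min_dist,
                                 max_points = config$L,
                                 contrast_threshold = config$contrast_threshold,
                                 edge_fraction = config$edge_fraction),
                error = function(e) stop("run_register [landmarks]: ",
                                         conditionMessage(e)))
  Xp <- pad_points(X, config$L)
  Y <- tryCatch(predict_points(mz$image, fz$image, Xp, model),
                error = function(e) stop("run_register [network]: ",
                                         conditionMessage(e)))
  keep <- Xp$valid
  src <- hp_points(Xp$coords[keep, , drop = FALSE])
  dst <- hp_points(unclass_mat(Y)[keep, , drop = FALSE])
  t_fit <- tryCatch(fit_tps(src, dst, lambda = config$tps_lambda),
                    error = function(e) stop("run_register [tps]: ",
                                             conditionMessage(e)))
  warped <- warp_image(mz$image, src, dst, out_size = config$image_size,
                       lambda = config$tps_lambda)
  write_raster(warped, paste0(out_prefix, "_warped.png"))
  write_tps(t_fit, paste0(out_prefix, "_transform.json"))
  write_points(X, paste0(out_prefix, "_points_moving.csv"))
  write_points(dst, paste0(out_prefix, "_points_fixed.csv"))
  invisible(list(warped = warped, transform = t_fit, landmarks = X,
                 predicted = dst, moving_zoom = mz$zoom, fixed_zoom = fz$zoom))
}
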