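#' Read a grayscale micrograph
#'
#' Reads a single-plane grayscale TIFF (8/16-bit) or PNG and scales values
#' to \[0,1\] by the stored dtype maximum.
#'
#' @param path File path; format chosen by extension (`.tif`, `.tiff`,
#'   `.png`).
#' @return Numeric matrix with values in \[0,1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (is.list(img)) stop("multi-plane image: expected one 2-D plane",
                         call. = FALSE)
  if (length(dim(img)) == 3L) {
    stop("multi-channel image (", dim(img)[3L],
         " channels): expected single-channel grayscale", call. = FALSE)
  }
  img
}

#' Write a grayscale image
#'
#' @param image Numeric matrix in \[0,1\].
#' @param path Output path (`.tif`/`.tiff`/`.png`).
#' @param bits Bit depth, 8 or 16. Default 16.
#' @export
write_image <- function(image, path, bits = 16L) {
  assert_field(image)
  stopifnot(bits %in% c(8L, 16L))
  img <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = bits),
         png = png::writePNG(img, path),
         stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Write / read a detection or centroid table
#'
#' CSV dialect: comma separator, dot decimal, UTF-8, header line required.
#' Coordinates are 0-based with `x_px` = column and `y_px` = row.
#'
#' @param detections Data frame with at least `x_px`, `y_px`.
#' @param path CSV path.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(as.data.frame(detections), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("x_px", "y_px") %in% names(df))) {
    stop("expected columns x_px, y_px in ", path, call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Run configuration
#'
#' Bundles every tunable of the pipeline. Physical radii (`r_min`, `r_max`,
#' in `units = "um"`) are converted to pixels through `pixel_size_um` before
#' the dictionary is built.
#'
#' @param r_min,r_max Expected nucleus radius range.
#' @param r_step Dictionary radius step (same units). Default 1 px.
#' @param units `"px"` or `"um"` for the radius range.
#' @param pixel_size_um Micrometers per pixel. Default 1.
#' @param norm_radius Preprocessing normalization radius in px; default
#'   `NULL` resolves to `1.5 * r_max` (px).
#' @param gamma Gamma-correction exponent. Default 2.
#' @param match_radius_um Detection match radius for evaluation. Default 3.2.
#' @param energy An [energy_params()] object.
#' @param detection A [detection_config()] object.
#' @return A `run_config` list.
#' @export
run_config <- function(r_min = 8, r_max = 12, r_step = 1,
                       units = c("px", "um"),
                       pixel_size_um = 1,
                       norm_radius = NULL, gamma = 2,
                       match_radius_um = 3.2,
                       energy = energy_params(),
                       detection = detection_config()) {
  units <- match.arg(units)
  scale <- if (units == "um") 1 / pixel_size_um else 1
  r_min_px <- r_min * scale; r_max_px <- r_max * scale
  step_px <- r_step * scale
  if (is.null(norm_radius)) norm_radius <- 1.5 * r_max_px
  structure(list(r_min_px = r_min_px, r_max_px = r_max_px,
                 r_step_px = step_px,
                 pixel_size_um = pixel_size_um,
                 preprocess = preprocess_config(norm_radius, gamma),
                 match_radius_um = match_radius_um,
                 energy = energy, detection = detection),
            class = "run_config")
}

#' Serialize / load a run configuration as YAML
#'
#' The effective configuration is written next to every batch output so a
#' run can be reproduced exactly.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  flat <- list(
    r_min_px = config$r_min_px, r_max_px = config$r_max_px,
    r_step_px = config$r_step_px, pixel_size_um = config$pixel_size_um,
    norm_radius = config$preprocess$norm_radius,
    gamma = config$preprocess$gamma,
    match_radius_um = config$match_radius_um,
    energy = unclass(config$energy),
    detection = unclass(config$detection))
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  en <- do.call(energy_params, y$energy[!vapply(y$energy, is.null, logical(1))])
  de <- do.call(detection_config,
                y$detection[!vapply(y$detection, is.null, logical(1))])
  run_config(r_min = y$r_min_px, r_max = y$r_max_px, r_step = y$r_step_px,
             units = "px", pixel_size_um = y$pixel_size_um,
             norm_radius = y$norm_radius, gamma = y$gamma,
             match_radius_um = y$match_radius_um,
             energy = en, detection = de)
}

#' Detect nuclei in one image end to end
#'
#' Preprocess, estimate intensities, segment and detect with one call.
#'
#' @param image Raw intensity matrix (or path readable by [read_image()]).
#' @param config A [run_config()].
#' @return List with `detections` (tibble), `segmentation`
#'   (`nuclei_segmentation`) and `preprocessed` (matrix).
#' @export
detect_nuclei <- function(image, config = run_config()) {
  if (is.character(image)) image <- read_image(image)
  pre <- preprocess(image, config$preprocess)
  dict <- build_dictionary(config$r_min_px, config$r_max_px, config$r_step_px)
  seg <- segment(pre, dict, config$energy)
  det <- detect(seg, pre, config$detection)
  list(detections = det, segmentation = seg, preprocessed = pre)
}

#' Batch detection over image files
#'
#' Runs [detect_nuclei()] on every image, writing one detection CSV per
#' image plus the effective configuration; failures are logged and skipped.
#'
#' @param config A [run_config()].
#' @param image_paths Character vector of image files.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a tibble with one row per image (`image`, `csv`,
#'   `n_detections`, `ok`).
#' @export
run_detect <- function(config, image_paths, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(out_dir, "effective-config.yaml"))
  rows <- lapply(image_paths, function(p) {
    csv <- file.path(out_dir,
                     paste0(tools::file_path_sans_ext(basename(p)),
                            "_detections.csv"))
    res <- tryCatch({
      out <- detect_nuclei(p, config)
      write_detections(out$detections, csv)
      tibble::tibble(image = p, csv = csv,
                     n_detections = nrow(out$detections), ok = TRUE)
    }, error = function(e) {
      message("detection failed for ", p, ": ", conditionMessage(e))
      tibble::tibble(image = p, csv = NA_character_,
                     n_detections = NA_integer_, ok = FALSE)
    })
    res
  })
  manifest <- do.call(rbind, rows)
  if (any(!manifest$ok)) {
    warning(sum(!manifest$ok), " image(s) failed; see messages")
  }
  invisible(manifest)
}

#' Batch evaluation of detection CSVs against ground truth
#'
#' @param config A [run_config()] (supplies match radius and pixel size).
#' @param detection_csvs,truth_csvs Aligned character vectors of CSV files.
#' @param out_path Optional path for the metrics report CSV.
#' @return One-row metrics tibble (see [evaluate()]).
#' @export
run_evaluate <- function(config, detection_csvs, truth_csvs,
                         out_path = NULL) {
  stopifnot(length(detection_csvs) == length(truth_csvs))
  missing <- !file.exists(truth_csvs)
  if (any(missing)) {
    stop("missing ground-truth file(s): ",
         paste(truth_csvs[missing], collapse = ", "), call. = FALSE)
  }
  dets <- lapply(detection_csvs, read_detections)
  truths <- lapply(truth_csvs, read_detections)
  report <- evaluate(dets, truths,
                     match_radius_um = config$match_radius_um,
                     pixel_size_um = config$pixel_size_um)
  message(sprintf("P=%.4f R=%.4f F=%.4f RMSE=%.3f",
                  report$precision, report$recall, report$f_measure,
                  report$rmse))
  if (!is.null(out_path)) {
    utils::write.csv(as.data.frame(report), out_path, row.names = FALSE)
  }
  report
}

#' Write a synthetic fixture corpus to disk
#'
#' @param fixture_cfg A [fixture_config()].
#' @param n_images Number of images.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest tibble (`image`, `truth`, `mask`,
#'   `n_nuclei`).
#' @export
run_fixtures <- function(fixture_cfg, n_images, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  suite <- generate_suite(fixture_cfg, n_images)
  rows <- lapply(seq_along(suite), function(i) {
    s <- suite[[i]]
    stem <- sprintf("fixture_%03d", i)
    img <- file.path(out_dir, paste0(stem, ".tif"))
    tru <- file.path(out_dir, paste0(stem, "_truth.csv"))
    msk <- file.path(out_dir, paste0(stem, "_mask.tif"))
    write_image(s$image, img)
    write_detections(s$truth, tru)
    write_image(s$truth_mask, msk, bits = 8L)
    tibble::tibble(image = img, truth = tru, mask = msk,
                   n_nuclei = nrow(s$truth))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(as.data.frame(manifest),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
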