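#' Detection configuration
#'
#' Parameters for turning a segmentation result into individual nucleus
#' detections.
#'
#' @param t_binarize_mode `"auto"` (Otsu threshold computed over the strictly
#'   positive values of the merged coefficient map) or `"fixed"`.
#' @param t_binarize_level Threshold used in `"fixed"` mode (the merged map
#'   is kept where strictly above it).
#' @param closing_radius Disk radius (px) of the morphological closing that
#'   re-merges fragments of a single nucleus response. Default 2.
#' @param clutter_opening_radius Disk radius (px) of the opening that
#'   isolates oversized objects (e.g. apoptotic debris); must exceed every
#'   dictionary radius so legal nuclei survive. Default `NULL` resolves to
#'   `1.5 * max(dict$radii)` at detection time.
#' @return A `detection_config` list.
#' @export
detection_config <- function(t_binarize_mode = c("auto", "fixed"),
                             t_binarize_level = 0.1,
                             closing_radius = 2,
                             clutter_opening_radius = NULL) {
  t_binarize_mode <- match.arg(t_binarize_mode)
  stopifnot(closing_radius >= 0,
            is.null(clutter_opening_radius) || clutter_opening_radius > 0)
  structure(list(t_binarize_mode = t_binarize_mode,
                 t_binarize_level = t_binarize_level,
                 closing_radius = closing_radius,
                 clutter_opening_radius = clutter_opening_radius),
            class = "detection_config")
}

resolve_clutter_radius <- function(cfg, dict) {
  r <- cfg$clutter_opening_radius
  if (is.null(r)) r <- 1.5 * max(dict$radii)
  if (r <= max(dict$radii)) {
    stop("clutter_opening_radius must exceed the largest dictionary radius",
         call. = FALSE)
  }
  r
}

#' Per-pixel dominant radius
#'
#' For every pixel, the dictionary radius whose coefficient is largest
#' there; ties (including the all-zero stack) break toward the smaller
#' radius.
#'
#' @param t_stack Coefficient stack.
#' @param dict Disk dictionary.
#' @return Matrix of radii (same units as `dict$radii`).
#' @export
dominant_radius_map <- function(t_stack, dict) {
  assert_stack(t_stack, dict)
  d <- dim(t_stack)
  flat <- matrix(t_stack, d[1L] * d[2L], d[3L])
  idx <- max.col(flat, ties.method = "first")  # radii increasing => smaller wins
  matrix(dict$radii[idx], d[1L], d[2L])
}

#' Merged coefficient map
#'
#' Per-pixel sum of the coefficient maps over all radii; high values occur
#' at nucleus centers.
#'
#' @param t_stack Coefficient stack.
#' @return Numeric matrix.
#' @export
merge_coefficients <- function(t_stack) {
  if (!is.array(t_stack) || length(dim(t_stack)) != 3L) {
    stop("coefficient stack must be a 3-d array", call. = FALSE)
  }
  rowSums(t_stack, dims = 2L)
}

#' Clutter mask from the binary segmentation
#'
#' Opens the binary segmentation with a disk larger than any legal nucleus;
#' what survives the opening is oversized clutter (e.g. apoptotic nuclei),
#' so the mask keeps `u_binary` minus the opened image.
#'
#' @param u_binary Binary segmentation (0/1 matrix).
#' @param cfg [detection_config()].
#' @param dict Disk dictionary (used to resolve the default opening radius).
#' @return Binary matrix: 1 on plausibly nucleus-sized foreground.
#' @export
clutter_mask <- function(u_binary, cfg, dict) {
  assert_field(u_binary)
  r <- resolve_clutter_radius(cfg, dict)
  opened <- open_disk(u_binary, r)
  (u_binary > 0 & opened == 0) * 1
}

#' Candidate nucleus components
#'
#' Binarizes the merged coefficient map (Otsu over its strictly positive
#' values, or a fixed level), applies a morphological closing so fragments
#' of one nucleus merge, intersects with the clutter mask, and extracts
#' 8-connected components.
#'
#' @param t_merged Merged coefficient map ([merge_coefficients()]).
#' @param u_binary Binary segmentation ([threshold_u()]).
#' @param cfg [detection_config()].
#' @param dict Disk dictionary.
#' @return List of components, each an integer matrix of `(row, col)` pixel
#'   coordinates (1-based).
#' @export
candidate_components <- function(t_merged, u_binary, cfg, dict) {
  assert_field(t_merged)
  assert_same_grid(t_merged, u_binary)
  pos <- t_merged[t_merged > 0]
  if (length(pos) == 0L) return(list())
  if (cfg$t_binarize_mode == "auto") {
    lvl <- if (length(unique(pos)) == 1L) {
      pos[1L] / 2  # single positive value: keep it
    } else {
      EBImage::otsu(matrix(pos, 1L), range = range(pos), levels = 256L)
    }
  } else {
    lvl <- cfg$t_binarize_level
  }
  tb <- (t_merged > lvl) * 1
  tb <- close_disk(tb, cfg$closing_radius)
  tb <- tb * clutter_mask(u_binary, cfg, dict)
  lab <- label_components(tb)
  n <- max(lab)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(k) which(lab == k, arr.ind = TRUE))
}

#' Score candidate components
#'
#' Each component is scored by the mean intensity of the preprocessed image
#' over its pixels (a measure of how likely the component marks a nucleus
#' centroid); its centroid is the unweighted pixel mean and its dominant
#' radius the mode of the dominant-radius map over the component (ties
#' toward the smaller radius).
#'
#' @param components List of `(row, col)` pixel-coordinate matrices.
#' @param preprocessed Preprocessed intensity image.
#' @param radius_map Matrix from [dominant_radius_map()].
#' @return Tibble with columns `row`, `col` (1-based, fractional),
#'   `radius_px`, `score`, `area`.
#' @export
score_components <- function(components, preprocessed, radius_map) {
  assert_field(preprocessed)
  keep <- vapply(components, nrow, integer(1)) > 0L
  if (any(!keep)) warning("skipping ", sum(!keep), " empty component(s)")
  components <- components[keep]
  rows <- lapply(components, function(px) {
    vals <- preprocessed[px]
    radii <- radius_map[px]
    tab <- table(radii)
    mode_r <- as.numeric(names(tab)[tab == max(tab)])
    tibble::tibble(row = mean(px[, 1L]),
                   col = mean(px[, 2L]),
                   radius_px = min(mode_r),
                   score = mean(vals),
                   area = nrow(px))
  })
  if (length(rows) == 0L) {
    return(tibble::tibble(row = numeric(0), col = numeric(0),
                          radius_px = numeric(0), score = numeric(0),
                          area = integer(0)))
  }
  do.call(rbind, rows)
}

#' Greedy non-maximum suppression of scored candidates
#'
#' Repeatedly accepts the highest-scoring candidate and removes every
#' remaining candidate whose centroid lies within the accepted candidate's
#' dominant radius (Euclidean, pixel units) — nuclei may touch but cannot
#' overlap. Score ties break toward the larger component area, then
#' row-major centroid order, making the procedure deterministic.
#'
#' @param candidates Tibble from [score_components()].
#' @return Tibble of accepted detections (same columns).
#' @export
greedy_select <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  ord <- order(-candidates$score, -candidates$area,
               candidates$row, candidates$col)
  cand <- candidates[ord, , drop = FALSE]
  kept <- cand[0, , drop = FALSE]
  while (nrow(cand) > 0L) {
    best <- cand[1L, , drop = FALSE]
    kept <- rbind(kept, best)
    d2 <- (cand$row - best$row)^2 + (cand$col - best$col)^2
    cand <- cand[d2 > best$radius_px^2 + 1e-9, , drop = FALSE]
  }
  tibble::as_tibble(kept)
}

#' Detect individual nuclei from a segmentation result
#'
#' Full detection chain: threshold the relaxed labeling, compute the clutter
#' mask, the dominant-radius and merged-coefficient maps, extract candidate
#' components, score them against the preprocessed image and run greedy
#' non-maximum suppression.
#'
#' @param result A `nuclei_segmentation` from [segment()].
#' @param preprocessed Preprocessed intensity image (defaults to the image
#'   stored in `result`).
#' @param cfg [detection_config()].
#' @return Tibble with one row per detected nucleus: `x_px`, `y_px`
#'   (0-based, `x` = column), `radius_px`, `score`, `area`.
#' @export
detect <- function(result, preprocessed = result$image,
                   cfg = detection_config()) {
  stopifnot(inherits(result, "nuclei_segmentation"),
            inherits(cfg, "detection_config"))
  u_binary <- threshold_u(result$u, result$params$u_threshold)
  t_merged <- merge_coefficients(result$t)
  radius_map <- dominant_radius_map(result$t, result$dict)
  comps <- candidate_components(t_merged, u_binary, cfg, result$dict)
  scored <- score_components(comps, preprocessed, radius_map)
  sel <- greedy_select(scored)
  tibble::tibble(x_px = sel$col - 1, y_px = sel$row - 1,
                 radius_px = sel$radius_px, score = sel$score,
                 area = sel$area)
}
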