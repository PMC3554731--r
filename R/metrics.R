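#' Match detections to ground-truth centroids
#'
#' One-to-one matching under a physical distance threshold (default 3.2 um):
#' candidate pairs within the threshold are accepted closest-first, so each
#' ground-truth centroid can be claimed by at most one detection (its
#' closest available one) and the outcome does not depend on input order.
#'
#' @param detections Data frame with `x_px`, `y_px` columns (0-based pixel
#'   coordinates; `x` = column).
#' @param truth Data frame with `x_px`, `y_px` columns.
#' @param match_radius_um Match radius in micrometers. Default 3.2.
#' @param pixel_size_um Pixel size in micrometers per pixel, > 0. Default 1.
#' @return List with counts `tp`, `fp`, `fn` and `pairs`, a tibble with
#'   `detection` and `truth` row indices and the pair `distance_px`.
#' @export
match_detections <- function(detections, truth,
                             match_radius_um = 3.2, pixel_size_um = 1) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0", call. = FALSE)
  }
  if (match_radius_um <= 0) stop("match_radius_um must be > 0", call. = FALSE)
  nd <- nrow(detections); nt <- nrow(truth)
  thr_px <- match_radius_um / pixel_size_um
  pairs <- tibble::tibble(detection = integer(0), truth = integer(0),
                          distance_px = numeric(0))
  if (nd > 0L && nt > 0L) {
    dmat <- sqrt(outer(detections$x_px, truth$x_px, `-`)^2 +
                 outer(detections$y_px, truth$y_px, `-`)^2)
    dmat[dmat > thr_px] <- Inf
    free_d <- rep(TRUE, nd); free_t <- rep(TRUE, nt)
    repeat {
      sub <- dmat[free_d, free_t, drop = FALSE]
      if (length(sub) == 0L || !any(is.finite(sub))) break
      k <- which(sub == min(sub), arr.ind = TRUE)[1L, , drop = TRUE]
      di <- which(free_d)[k[1L]]; ti <- which(free_t)[k[2L]]
      pairs <- rbind(pairs,
                     tibble::tibble(detection = di, truth = ti,
                                    distance_px = dmat[di, ti]))
      free_d[di] <- FALSE; free_t[ti] <- FALSE
    }
  }
  stopifnot(!anyDuplicated(pairs$detection), !anyDuplicated(pairs$truth))
  list(tp = nrow(pairs), fp = nd - nrow(pairs), fn = nt - nrow(pairs),
       pairs = pairs)
}

#' Precision, recall and F-measure from match counts
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F = 2PR/(P+R)` (balanced F1).
#' Conventions: `P = 1` when no detections were made, `R = 1` when there is
#' no ground truth, `F = 0` when `P = R = 0`.
#'
#' @param tp,fp,fn Nonnegative counts.
#' @return List with `precision`, `recall`, `f_measure`.
#' @export
precision_recall_f <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 1
  r <- if (tp + fn > 0) tp / (tp + fn) else 1
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f_measure = f)
}

#' Root-mean-square error of per-image nucleus counts
#'
#' @param detected_counts,true_counts Equal-length numeric vectors of
#'   per-image counts.
#' @return Nonnegative scalar.
#' @export
count_rmse <- function(detected_counts, true_counts) {
  if (length(detected_counts) != length(true_counts)) {
    stop("count vectors must have equal length", call. = FALSE)
  }
  sqrt(mean((detected_counts - true_counts)^2))
}

#' Dice coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, computed over full images (not per
#' nucleus); defined as 1 when both masks are empty.
#'
#' @param seg_binary,truth_mask Binary (0/1) matrices on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(seg_binary, truth_mask) {
  assert_field(seg_binary); assert_field(truth_mask)
  assert_same_grid(seg_binary, truth_mask)
  if (!all(seg_binary %in% c(0, 1)) || !all(truth_mask %in% c(0, 1))) {
    stop("dice() expects binary (0/1) masks", call. = FALSE)
  }
  a <- sum(seg_binary); b <- sum(truth_mask)
  if (a + b == 0) return(1)
  2 * sum(seg_binary * truth_mask) / (a + b)
}

#' Pooled evaluation over a set of images
#'
#' Pools true/false positives and false negatives across images for
#' (micro-averaged) precision/recall/F, computes the count RMSE over
#' per-image detection counts, and averages the Dice coefficient over the
#' images for which masks are supplied.
#'
#' @param detections_list List of per-image detection tables (`x_px`,
#'   `y_px`).
#' @param truth_list List of per-image ground-truth centroid tables.
#' @param seg_masks,truth_masks Optional lists of binary matrices (aligned
#'   with the images) for the Dice average; `NULL` entries are skipped.
#' @param match_radius_um,pixel_size_um Passed to [match_detections()].
#' @return One-row tibble: `n_images`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f_measure`, `rmse`, `dice` (`NA` if no masks).
#' @export
evaluate <- function(detections_list, truth_list,
                     seg_masks = NULL, truth_masks = NULL,
                     match_radius_um = 3.2, pixel_size_um = 1) {
  stopifnot(length(detections_list) == length(truth_list))
  tp <- fp <- fn <- 0L
  for (i in seq_along(detections_list)) {
    m <- match_detections(detections_list[[i]], truth_list[[i]],
                          match_radius_um, pixel_size_um)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  prf <- precision_recall_f(tp, fp, fn)
  rmse <- count_rmse(vapply(detections_list, nrow, integer(1)),
                     vapply(truth_list, nrow, integer(1)))
  dice_mean <- NA_real_
  if (!is.null(seg_masks) && !is.null(truth_masks)) {
    stopifnot(length(seg_masks) == length(truth_masks))
    ds <- mapply(function(s, g) {
      if (is.null(s) || is.null(g)) NA_real_ else dice(s, g)
    }, seg_masks, truth_masks)
    if (any(!is.na(ds))) dice_mean <- mean(ds, na.rm = TRUE)
  }
  tibble::tibble(n_images = length(detections_list),
                 tp = tp, fp = fp, fn = fn,
                 precision = prf$precision, recall = prf$recall,
                 f_measure = prf$f_measure, rmse = rmse, dice = dice_mean)
}
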