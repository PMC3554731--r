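#' Preprocessing configuration
#'
#' @param norm_radius Radius (pixels, >= 1) of the disk neighborhood used for
#'   local illumination normalization. Choose it large enough that the disk
#'   contains at least one whole nucleus, since the local maximum acts as the
#'   local illumination estimate; 1.5 x the largest expected nucleus radius
#'   is a good default.
#' @param gamma Gamma-correction exponent, >= 1. Values above 1 suppress low
#'   intensities such as residual dye from apoptotic cells. Default 2.
#' @param epsilon Positive floor for the local maximum, guarding division in
#'   flat dark regions. Default `NULL` resolves at run time to
#'   `1e-6 * max(image)`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(norm_radius, gamma = 2, epsilon = NULL) {
  if (!is.numeric(norm_radius) || length(norm_radius) != 1L || norm_radius < 1) {
    stop("norm_radius must be a single number >= 1", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 1) {
    stop("gamma must be >= 1 (values below 1 would amplify low intensities)",
         call. = FALSE)
  }
  if (!is.null(epsilon) && (!is.numeric(epsilon) || epsilon <= 0)) {
    stop("epsilon must be a positive number", call. = FALSE)
  }
  structure(list(norm_radius = norm_radius, gamma = gamma, epsilon = epsilon),
            class = "preprocess_config")
}

# Integer offsets (drow, dcol) whose Euclidean norm is <= radius (closed disk).
disk_offsets <- function(radius) {
  r <- floor(radius + 1e-9)
  d <- seq.int(-r, r)
  g <- expand.grid(dr = d, dc = d)
  keep <- g$dr^2 + g$dc^2 <= radius^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# Per-pixel maximum over the disk neighborhood, window clipped at the image
# border (no padding value is invented).
local_max_disk <- function(field, radius) {
  assert_field(field)
  h <- nrow(field); w <- ncol(field)
  off <- disk_offsets(radius)
  r <- max(abs(off))
  padded <- matrix(-Inf, h + 2L * r, w + 2L * r)
  padded[(r + 1L):(r + h), (r + 1L):(r + w)] <- field
  out <- matrix(-Inf, h, w)
  for (k in seq_len(nrow(off))) {
    sub <- padded[(r + 1L + off[k, 1L]):(r + h + off[k, 1L]),
                  (r + 1L + off[k, 2L]):(r + w + off[k, 2L]), drop = FALSE]
    out <- pmax(out, sub)
  }
  out
}

#' Local illumination normalization
#'
#' Divides every pixel by the maximum intensity over the disk of radius
#' `norm_radius` centered at it (clipped at the image border), removing
#' smooth illumination differences across the field of view. The divisor is
#' floored at `epsilon` so flat dark regions stay at zero.
#'
#' @param image Numeric matrix with nonnegative values.
#' @param cfg A [preprocess_config()].
#' @return Matrix with values in \[0, 1\].
#' @export
normalize_local <- function(image, cfg) {
  assert_field(image)
  stopifnot(inherits(cfg, "preprocess_config"))
  if (any(image < 0)) stop("image values must be >= 0", call. = FALSE)
  gmax <- max(image)
  if (gmax == 0) {
    warning("all-zero image: normalization returns it unchanged")
    return(image)
  }
  eps <- if (is.null(cfg$epsilon)) 1e-6 * gmax else cfg$epsilon
  lm <- local_max_disk(image, cfg$norm_radius)
  image / pmax(lm, eps)
}

#' Gamma correction
#'
#' Pointwise power transform `value^gamma` with `gamma >= 1`, suppressing low
#' intensities (e.g. faint dye from apoptotic cells) while keeping the range
#' \[0, 1\] fixed.
#'
#' @inheritParams normalize_local
#' @return Matrix with values in \[0, 1\].
#' @export
gamma_correct <- function(image, cfg) {
  assert_field(image)
  stopifnot(inherits(cfg, "preprocess_config"))
  if (any(image < 0) || any(image > 1)) {
    stop("gamma correction expects values in [0, 1]; normalize first",
         call. = FALSE)
  }
  image^cfg$gamma
}

#' Full preprocessing: normalization, then gamma correction
#'
#' The order matters: normalizing first makes the gamma suppression act on
#' illumination-corrected intensities, so nuclei reach comparable brightness
#' regardless of their position in the field of view.
#'
#' @inheritParams normalize_local
#' @return Matrix with values in \[0, 1\].
#' @export
preprocess <- function(image, cfg) {
  gamma_correct(normalize_local(image, cfg), cfg)
}
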