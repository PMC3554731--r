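#' Discrete field operators
#'
#' Images and all intermediate fields are plain numeric matrices indexed
#' `[row, col]`. Pixel centers sit at integer coordinates, reported 0-based
#' with `x = col` and `y = row`. Distances are Euclidean in pixel units and
#' converted to micrometers through an isotropic `pixel_size` (um/px) where a
#' physical unit is needed.
#'
#' @name core-operators
#' @keywords internal
NULL

assert_field <- function(field, arg = deparse(substitute(field))) {
  if (!is.matrix(field) || !is.numeric(field) || length(field) == 0L) {
    stop(sprintf("'%s' must be a nonempty numeric matrix", arg), call. = FALSE)
  }
  invisible(field)
}

assert_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("grid mismatch: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Forward-difference gradient of a scalar field
#'
#' Forward differences along rows and columns with replicate (Neumann)
#' boundary handling, so the difference at the last row/column is zero.
#'
#' @param field Numeric matrix.
#' @return List with components `dr` (row difference) and `dc` (column
#'   difference), each a matrix of the same shape as `field`.
#' @export
field_gradient <- function(field) {
  assert_field(field)
  h <- nrow(field); w <- ncol(field)
  dr <- matrix(0, h, w)
  dc <- matrix(0, h, w)
  if (h > 1L) dr[-h, ] <- field[-1L, , drop = FALSE] - field[-h, , drop = FALSE]
  if (w > 1L) dc[, -w] <- field[, -1L, drop = FALSE] - field[, -w, drop = FALSE]
  list(dr = dr, dc = dc)
}

#' Negative adjoint of [field_gradient()] (discrete divergence)
#'
#' Satisfies `sum(p_r * dr + p_c * dc) == -sum(u * field_divergence(p_r, p_c))`
#' for any field u with gradient (dr, dc); used in the Newton stationarity
#' condition of the labeling update.
#'
#' @param pr,pc Numeric matrices (a vector field on the grid).
#' @return Numeric matrix.
#' @keywords internal
field_divergence <- function(pr, pc) {
  assert_same_grid(pr, pc)
  h <- nrow(pr); w <- ncol(pr)
  div <- matrix(0, h, w)
  if (h > 1L) {
    div[1L, ] <- div[1L, ] + pr[1L, ]
    if (h > 2L) div[2:(h - 1L), ] <- div[2:(h - 1L), ] + pr[2:(h - 1L), , drop = FALSE] - pr[1:(h - 2L), , drop = FALSE]
    div[h, ] <- div[h, ] - pr[h - 1L, ]
  }
  if (w > 1L) {
    div[, 1L] <- div[, 1L] + pc[, 1L]
    if (w > 2L) div[, 2:(w - 1L)] <- div[, 2:(w - 1L), drop = FALSE] + pc[, 2:(w - 1L), drop = FALSE] - pc[, 1:(w - 2L), drop = FALSE]
    div[, w] <- div[, w] - pc[, w - 1L]
  }
  div
}

#' Inner product of two scalar fields
#'
#' @param a,b Numeric matrices on the same grid.
#' @return Scalar sum over all pixels of `a * b`.
#' @export
inner_product <- function(a, b) {
  assert_field(a); assert_field(b)
  assert_same_grid(a, b)
  sum(a * b)
}

#' Isotropic total variation of a scalar field
#'
#' Sum over pixels of `sqrt(dr^2 + dc^2)` with forward differences and
#' Neumann boundaries. Zero iff the field is constant.
#'
#' @param field Numeric matrix.
#' @return Nonnegative scalar.
#' @export
tv_norm <- function(field) {
  g <- field_gradient(field)
  sum(sqrt(g$dr^2 + g$dc^2))
}
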