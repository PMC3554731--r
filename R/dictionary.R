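#' Binary disk kernel
#'
#' Square matrix of side `2*floor(radius)+1` holding the closed Euclidean
#' disk: entries are 1 exactly where the offset from the center has norm
#' `<= radius` (ties at exactly `radius` are inside).
#'
#' @param radius Disk radius in pixels, >= 0.
#' @return Binary matrix with odd side length.
#' @export
disk_kernel <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0) {
    stop("radius must be a single nonnegative number", call. = FALSE)
  }
  r <- floor(radius + 1e-9)
  d <- seq.int(-r, r)
  k <- outer(d^2, d^2, `+`) <= radius^2 + 1e-9
  storage.mode(k) <- "double"
  k
}

#' Single disk atom on a grid
#'
#' The ideal binary segmentation of one nucleus: 1 exactly where the
#' Euclidean distance to `center` is `<= radius`, 0 elsewhere. Disks are
#' clipped by the image border.
#'
#' @param radius Disk radius in pixels.
#' @param center Length-2 vector `c(row, col)`, 1-based, inside the grid.
#' @param dim Length-2 vector `c(height, width)`.
#' @return Binary matrix of shape `dim`.
#' @export
make_disk_atom <- function(radius, center, dim) {
  h <- dim[1L]; w <- dim[2L]
  if (center[1L] < 1 || center[1L] > h || center[2L] < 1 || center[2L] > w) {
    stop("center must lie inside the grid", call. = FALSE)
  }
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  out <- (rows - center[1L])^2 + (cols - center[2L])^2 <= radius^2 + 1e-9
  storage.mode(out) <- "double"
  out
}

#' Build the disk-atom dictionary
#'
#' Radii form the arithmetic sequence `r_min, r_min + step, ...` up to
#' `r_max`; `r_max` is always included (appended when the sequence misses
#' it). One binary kernel per radius.
#'
#' @param r_min,r_max Smallest and largest nucleus radius, pixels,
#'   `1 <= r_min <= r_max`.
#' @param step Radius discretization step in pixels, > 0. Default 1.
#' @return A `disk_dictionary`: list with `radii` (increasing numeric
#'   vector), `kernels` (list of binary matrices) and `areas` (pixel counts).
#' @export
build_dictionary <- function(r_min, r_max, step = 1) {
  if (r_min < 1 || r_min > r_max) {
    stop("need 1 <= r_min <= r_max", call. = FALSE)
  }
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  radii <- seq(r_min, r_max, by = step)
  if (max(radii) < r_max - 1e-9) radii <- c(radii, r_max)
  kernels <- lapply(radii, disk_kernel)
  structure(list(radii = radii,
                 kernels = kernels,
                 areas = vapply(kernels, sum, numeric(1))),
            class = "disk_dictionary")
}

#' @export
print.disk_dictionary <- function(x, ...) {
  cat(sprintf("<disk_dictionary> %d radii: %s (areas %s px)\n",
              length(x$radii),
              paste(signif(x$radii, 4), collapse = ", "),
              paste(x$areas, collapse = ", ")))
  invisible(x)
}

new_coefficient_stack <- function(dim, n_radii) {
  array(0, c(dim[1L], dim[2L], n_radii))
}

assert_stack <- function(t_stack, dict) {
  if (!is.array(t_stack) || length(dim(t_stack)) != 3L) {
    stop("coefficient stack must be a 3-d array (height x width x radii)",
         call. = FALSE)
  }
  if (dim(t_stack)[3L] != length(dict$radii)) {
    stop("stack depth must equal the dictionary length", call. = FALSE)
  }
  invisible(TRUE)
}

# Zero-padded 2-d convolution; disk kernels are symmetric so convolution and
# correlation coincide and the operator is self-adjoint per radius.
conv_disk <- function(field, kernel) {
  kh <- nrow(kernel)
  if (kh >= 2L * nrow(field) || kh >= 2L * ncol(field)) {
    # brute-force fallback when the kernel dwarfs the field (tiny test grids)
    h <- nrow(field); w <- ncol(field); r <- (kh - 1L) %/% 2L
    out <- matrix(0, h, w)
    idx <- which(field != 0, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1L]; j <- idx[k, 2L]
      ri <- max(1L, i - r):min(h, i + r)
      cj <- max(1L, j - r):min(w, j + r)
      out[ri, cj] <- out[ri, cj] +
        field[i, j] * kernel[ri - i + r + 1L, cj - j + r + 1L]
    }
    return(out)
  }
  EBImage::filter2(field, kernel, boundary = 0)
}

#' Dictionary synthesis: coefficients to segmentation-shaped field
#'
#' Linear map summing, over radii, the coefficient map convolved with the
#' binary disk kernel of that radius (zero padding outside the image, so a
#' disk centered near the border contributes its clipped part). Values may
#' exceed 1 where synthesized disks overlap, which is what penalizes
#' overlapping nuclei in the coupled energy.
#'
#' @param t_stack 3-d array `height x width x length(dict$radii)` of
#'   per-radius coefficient maps.
#' @param dict A [build_dictionary()] result.
#' @return Numeric matrix `height x width`.
#' @export
synthesize <- function(t_stack, dict) {
  assert_stack(t_stack, dict)
  out <- matrix(0, dim(t_stack)[1L], dim(t_stack)[2L])
  for (k in seq_along(dict$radii)) {
    m <- matrix(t_stack[, , k], dim(t_stack)[1L], dim(t_stack)[2L])
    if (any(m != 0)) out <- out + conv_disk(m, dict$kernels[[k]])
  }
  out
}

#' Adjoint of [synthesize()]
#'
#' Per radius, the correlation of the field with the disk kernel (equal to
#' convolution since disks are symmetric). Satisfies
#' `inner_product(synthesize(t, d), f) == sum(t * adjoint_synthesize(f, d))`.
#'
#' @param field Numeric matrix on the dictionary grid.
#' @param dict A [build_dictionary()] result.
#' @return 3-d coefficient-stack array.
#' @export
adjoint_synthesize <- function(field, dict) {
  assert_field(field)
  out <- new_coefficient_stack(dim(field), length(dict$radii))
  for (k in seq_along(dict$radii)) {
    out[, , k] <- conv_disk(field, dict$kernels[[k]])
  }
  out
}

# --- cached Fourier plan for repeated synthesis/adjoint on one grid -------
#
# Linear (zero-padded) convolution of every dictionary kernel with fields of
# a fixed size, via FFTs with the kernel transforms precomputed once. The
# padded size h + 2*r_max gives room so circular wrap never touches the
# h x w window for any radius in the dictionary.

prepare_synthesis_plan <- function(dict, dim) {
  h <- dim[1L]; w <- dim[2L]
  rmax <- max(vapply(dict$kernels, function(k) (nrow(k) - 1L) %/% 2L,
                     integer(1)))
  Ph <- h + 2L * rmax; Pw <- w + 2L * rmax
  khat <- lapply(dict$kernels, function(k) {
    rk <- (nrow(k) - 1L) %/% 2L
    km <- matrix(0, Ph, Pw)
    ri <- c(seq_len(rk + 1L), if (rk > 0L) (Ph - rk + 1L):Ph)  # centered at origin
    ci <- c(seq_len(rk + 1L), if (rk > 0L) (Pw - rk + 1L):Pw)
    km[ri, ci] <- k[c((rk + 1L):(2L * rk + 1L), if (rk > 0L) seq_len(rk)),
                    c((rk + 1L):(2L * rk + 1L), if (rk > 0L) seq_len(rk))]
    stats::fft(km)
  })
  list(h = h, w = w, Ph = Ph, Pw = Pw, khat = khat)
}

plan_pad <- function(field, plan) {
  p <- matrix(0, plan$Ph, plan$Pw)
  p[seq_len(plan$h), seq_len(plan$w)] <- field
  p
}

fast_synthesize <- function(t_stack, plan) {
  acc <- matrix(0 + 0i, plan$Ph, plan$Pw)
  for (k in seq_along(plan$khat)) {
    m <- matrix(t_stack[, , k], plan$h, plan$w)
    if (any(m != 0)) acc <- acc + plan$khat[[k]] * stats::fft(plan_pad(m, plan))
  }
  Re(stats::fft(acc, inverse = TRUE))[seq_len(plan$h), seq_len(plan$w)] /
    (plan$Ph * plan$Pw)
}

fast_adjoint <- function(field, plan) {
  fhat <- stats::fft(plan_pad(field, plan))
  out <- array(0, c(plan$h, plan$w, length(plan$khat)))
  for (k in seq_along(plan$khat)) {
    out[, , k] <- Re(stats::fft(plan$khat[[k]] * fhat, inverse = TRUE)
                     )[seq_len(plan$h), seq_len(plan$w)] / (plan$Ph * plan$Pw)
  }
  out
}
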