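#' Binary morphology with closed Euclidean disk structuring elements
#'
#' Erosion/dilation are min/max filters over [disk_offsets()] neighborhoods;
#' pixels outside the image count as background (0), the usual set-morphology
#' convention for a finite image.
#'
#' @name binary-morphology
#' @keywords internal
NULL

shift_filter <- function(bin, radius, pad, reduce, init) {
  assert_field(bin)
  h <- nrow(bin); w <- ncol(bin)
  off <- disk_offsets(radius)
  r <- max(abs(off), 1L)
  padded <- matrix(pad, h + 2L * r, w + 2L * r)
  padded[(r + 1L):(r + h), (r + 1L):(r + w)] <- bin
  out <- matrix(init, h, w)
  for (k in seq_len(nrow(off))) {
    sub <- padded[(r + 1L + off[k, 1L]):(r + h + off[k, 1L]),
                  (r + 1L + off[k, 2L]):(r + w + off[k, 2L]), drop = FALSE]
    out <- reduce(out, sub)
  }
  out
}

#' @rdname binary-morphology
#' @param bin Binary (0/1) matrix.
#' @param radius Structuring-element radius in pixels.
#' @export
erode_disk <- function(bin, radius) {
  if (radius <= 0) return(bin)
  shift_filter(bin, radius, pad = 0, reduce = pmin, init = Inf)
}

#' @rdname binary-morphology
#' @export
dilate_disk <- function(bin, radius) {
  if (radius <= 0) return(bin)
  shift_filter(bin, radius, pad = 0, reduce = pmax, init = -Inf)
}

#' @rdname binary-morphology
#' @export
open_disk <- function(bin, radius) {
  dilate_disk(erode_disk(bin, radius), radius)
}

#' @rdname binary-morphology
#' @export
close_disk <- function(bin, radius) {
  erode_disk(dilate_disk(bin, radius), radius)
}

#' 8-connected component labeling
#'
#' Labels connected sets of nonzero pixels under 8-connectivity (edge or
#' corner adjacency). Labels are assigned in scan order of each component's
#' first pixel.
#'
#' @param bin Binary (0/1) matrix.
#' @return Integer matrix; 0 is background, components are numbered from 1.
#' @export
label_components <- function(bin) {
  assert_field(bin)
  h <- nrow(bin); w <- ncol(bin)
  fg <- which(bin != 0)
  if (length(fg) == 0L) return(matrix(0L, h, w))
  id <- matrix(0L, h, w)
  id[fg] <- seq_along(fg)
  edges <- integer(0)
  # neighbor offsets covering all 8-adjacencies once: E, S, SE, SW
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    di <- off[1L]; dj <- off[2L]
    ri <- max(1L, 1L - di):min(h, h - di)
    cj <- max(1L, 1L - dj):min(w, w - dj)
    a <- id[ri, cj, drop = FALSE]
    b <- id[ri + di, cj + dj, drop = FALSE]
    both <- a > 0L & b > 0L
    if (any(both)) edges <- c(edges, rbind(a[both], b[both]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber in scan order of first appearance
  relabel <- integer(max(comp))
  nxt <- 0L
  for (k in seq_along(fg)) {
    c0 <- comp[k]
    if (relabel[c0] == 0L) {
      nxt <- nxt + 1L
      relabel[c0] <- nxt
    }
  }
  lab <- matrix(0L, h, w)
  lab[fg] <- relabel[comp]
  lab
}
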