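# Brute-force oracles, written as plain loops independent of the package's
# vectorized/FFT implementations.

bf_gradient <- function(m) {
  h <- nrow(m); w <- ncol(m)
  dr <- matrix(0, h, w); dc <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    if (i < h) dr[i, j] <- m[i + 1, j] - m[i, j]
    if (j < w) dc[i, j] <- m[i, j + 1] - m[i, j]
  }
  list(dr = dr, dc = dc)
}

bf_inner <- function(a, b) {
  s <- 0
  for (i in 1:nrow(a)) for (j in 1:ncol(a)) s <- s + a[i, j] * b[i, j]
  s
}

bf_tv <- function(m) {
  g <- bf_gradient(m)
  s <- 0
  for (i in 1:nrow(m)) for (j in 1:ncol(m)) {
    s <- s + sqrt(g$dr[i, j]^2 + g$dc[i, j]^2)
  }
  s
}

# sum of clipped disks placed one atom at a time
bf_synthesize <- function(t_stack, radii) {
  h <- dim(t_stack)[1]; w <- dim(t_stack)[2]
  out <- matrix(0, h, w)
  for (k in seq_along(radii)) {
    for (i in 1:h) for (j in 1:w) {
      v <- t_stack[i, j, k]
      if (v != 0) {
        out <- out + v * make_disk_atom(radii[k], c(i, j), c(h, w))
      }
    }
  }
  out
}

bf_local_max <- function(m, radius) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  r <- ceiling(radius)
  for (i in 1:h) for (j in 1:w) {
    best <- -Inf
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 <= radius^2 + 1e-9) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
          best <- max(best, m[ii, jj])
        }
      }
    }
    out[i, j] <- best
  }
  out
}

# exhaustive between-class-variance-maximizing threshold over 256 bins
bf_otsu <- function(x, levels = 256) {
  lo <- min(x); hi <- max(x)
  breaks <- seq(lo, hi, length.out = levels + 1)
  best_thr <- lo; best_var <- -Inf
  for (b in 2:levels) {
    thr <- breaks[b]
    below <- x[x <= thr]; above <- x[x > thr]
    if (length(below) == 0 || length(above) == 0) next
    wb <- length(below) / length(x); wa <- 1 - wb
    v <- wb * wa * (mean(below) - mean(above))^2
    if (v > best_var) { best_var <- v; best_thr <- thr }
  }
  best_thr
}

# exhaustive one-to-one assignment maximizing matches, then minimizing total
# distance; feasible only for small point sets
bf_match_count <- function(det, tru, thr) {
  nd <- nrow(det); nt <- nrow(tru)
  if (nd == 0 || nt == 0) return(0)
  dmat <- sqrt(outer(det$x_px, tru$x_px, `-`)^2 +
               outer(det$y_px, tru$y_px, `-`)^2)
  ok <- dmat <= thr
  best <- 0
  assign_rec <- function(ti, used, count) {
    if (count + (nt - ti + 1) <= best) return()  # cannot beat best
    if (ti > nt) { best <<- max(best, count); return() }
    assign_rec(ti + 1, used, count)              # leave this truth unmatched
    for (di in seq_len(nd)) {
      if (!used[di] && ok[di, ti]) {
        used[di] <- TRUE
        assign_rec(ti + 1, used, count + 1)
        used[di] <- FALSE
      }
    }
  }
  assign_rec(1, rep(FALSE, nd), 0)
  best
}

# literal simulation of greedy non-maximum suppression with list mutation
bf_greedy <- function(cand) {
  kept <- cand[0, , drop = FALSE]
  pool <- cand
  while (nrow(pool) > 0) {
    ord <- order(-pool$score, -pool$area, pool$row, pool$col)
    pool <- pool[ord, , drop = FALSE]
    best <- pool[1, , drop = FALSE]
    kept <- rbind(kept, best)
    keep <- sqrt((pool$row - best$row)^2 + (pool$col - best$col)^2) >
      best$radius_px + 1e-9
    pool <- pool[keep, , drop = FALSE]
  }
  kept
}

# small high-contrast disk image with exact truth, no degradation
clean_disk_image <- function(dim, centers, radii, fg = 0.9, bg = 0.1) {
  img <- matrix(bg, dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    a <- make_disk_atom(radii[i], centers[i, ], dim)
    img[a == 1] <- fg
  }
  img
}
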