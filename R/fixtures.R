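# Run expr with a private RNG stream; the caller's .Random.seed is restored
# afterwards so no global random state leaks.
with_fixture_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic micrograph configuration
#'
#' Describes one synthetic fluorescence micrograph: bright blurred disks
#' (nuclei) on a dark background, a fraction of them placed in touching
#' pairs/chains, degraded by a linear illumination gradient, oversized
#' clutter blobs (apoptotic debris), Gaussian blur and additive Gaussian
#' noise. Exposure-time-style degradation can be emulated by shrinking
#' `fg_level - bg_level` while raising `noise_sd`.
#'
#' @param dim Image size `c(height, width)` in pixels. Default 256 x 256.
#' @param n_nuclei Number of nuclei. Default 30.
#' @param radius_range `c(r_min, r_max)` nucleus radii in pixels. Default
#'   `c(10, 10)` (the 20 px diameter of the synthetic benchmark setting).
#' @param touching_fraction Fraction of nuclei placed in touching groups
#'   (boundary contact, overlap < 2 px). Default 0.3.
#' @param fg_level,bg_level Nucleus and background intensity before
#'   degradation. Defaults 0.8 / 0.1.
#' @param blur_sigma Gaussian blur sigma in pixels. Default 2.
#' @param illumination_gradient Fractional intensity drop across the field
#'   (left to right). Default 0.3.
#' @param clutter_blobs Number of oversized clutter blobs. Default 0.
#' @param clutter_radius_multiplier Clutter radius as a multiple of `r_max`.
#'   Default 2.
#' @param noise_sd Additive zero-mean Gaussian noise sd. Default 0.05.
#' @param seed Integer seed; every sample is fully reproducible from it.
#' @param pixel_size_um Micrometers per pixel. Default 1 (pixel-unit
#'   fixtures, so the 3.2 um match radius is 3.2 px).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(dim = c(256L, 256L),
                           n_nuclei = 30L,
                           radius_range = c(10, 10),
                           touching_fraction = 0.3,
                           fg_level = 0.8, bg_level = 0.1,
                           blur_sigma = 2,
                           illumination_gradient = 0.3,
                           clutter_blobs = 0L,
                           clutter_radius_multiplier = 2,
                           noise_sd = 0.05,
                           seed = 0L,
                           pixel_size_um = 1) {
  stopifnot(n_nuclei >= 0, radius_range[1L] <= radius_range[2L],
            radius_range[1L] >= 1,
            touching_fraction >= 0, touching_fraction <= 1,
            fg_level > bg_level, bg_level >= 0, fg_level <= 1,
            blur_sigma >= 0, noise_sd >= 0, clutter_blobs >= 0,
            pixel_size_um > 0)
  structure(list(dim = as.integer(dim), n_nuclei = as.integer(n_nuclei),
                 radius_range = radius_range,
                 touching_fraction = touching_fraction,
                 fg_level = fg_level, bg_level = bg_level,
                 blur_sigma = blur_sigma,
                 illumination_gradient = illumination_gradient,
                 clutter_blobs = as.integer(clutter_blobs),
                 clutter_radius_multiplier = clutter_radius_multiplier,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 pixel_size_um = pixel_size_um),
            class = "fixture_config")
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  d <- seq.int(-r, r)
  k <- exp(-outer(d^2, d^2, `+`) / (2 * sigma^2))
  k / sum(k)
}

place_centers <- function(cfg) {
  h <- cfg$dim[1L]; w <- cfg$dim[2L]
  n <- cfg$n_nuclei
  radii <- stats::runif(n, cfg$radius_range[1L], cfg$radius_range[2L])
  n_touch <- round(n * cfg$touching_fraction)
  # touching nuclei come in pairs; an odd remainder forms one chain of three
  groups <- if (n_touch %% 2L == 1L && n_touch >= 3L) {
    c(rep(2L, (n_touch - 3L) / 2L), 3L)
  } else {
    rep(2L, n_touch %/% 2L)
  }
  margin <- cfg$radius_range[2L] + 2
  centers <- matrix(numeric(0), 0L, 2L)
  sep_ok <- function(p, r, exclude = integer(0)) {
    if (nrow(centers) == 0L) return(TRUE)
    keep <- setdiff(seq_len(nrow(centers)), exclude)
    if (length(keep) == 0L) return(TRUE)
    d <- sqrt((centers[keep, 1L] - p[1L])^2 + (centers[keep, 2L] - p[2L])^2)
    all(d > r + radii[keep] + 4)
  }
  rand_pos <- function() c(stats::runif(1, margin, h - margin + 1),
                           stats::runif(1, margin, w - margin + 1))
  in_bounds <- function(p) p[1L] >= margin && p[1L] <= h - margin + 1 &&
    p[2L] >= margin && p[2L] <= w - margin + 1
  k <- 0L
  add_center <- function(p) centers <<- rbind(centers, p)
  for (g in groups) {
    placed <- FALSE
    for (try in 1:500) {
      p1 <- rand_pos()
      if (!sep_ok(p1, radii[k + 1L])) next
      grp <- list(p1)
      ok <- TRUE
      for (m in 2:g) {
        found <- FALSE
        for (try2 in 1:100) {
          ri <- radii[k + m - 1L]; rj <- radii[k + m]
          dist <- stats::runif(1, max(ri + rj - 2, 2), ri + rj)
          ang <- stats::runif(1, 0, 2 * pi)
          p2 <- grp[[m - 1L]] + dist * c(cos(ang), sin(ang))
          prev_ok <- TRUE
          if (m > 2L) {  # keep chain links from collapsing onto link m-2
            d0 <- sqrt(sum((p2 - grp[[m - 2L]])^2))
            prev_ok <- d0 >= radii[k + m - 2L] + rj - 2
          }
          if (in_bounds(p2) && prev_ok && sep_ok(p2, rj)) {
            grp[[m]] <- p2; found <- TRUE; break
          }
        }
        if (!found) { ok <- FALSE; break }
      }
      if (ok) {
        for (p in grp) add_center(p)
        k <- k + g
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place touching group after bounded retries; ",
           "reduce n_nuclei or enlarge the image", call. = FALSE)
    }
  }
  while (k < n) {
    placed <- FALSE
    for (try in 1:500) {
      p <- rand_pos()
      if (sep_ok(p, radii[k + 1L])) {
        add_center(p); k <- k + 1L; placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place isolated nucleus after bounded retries; ",
           "reduce n_nuclei or enlarge the image", call. = FALSE)
    }
  }
  list(centers = centers, radii = radii)
}

render_disks <- function(centers, radii, dim) {
  mask <- matrix(0, dim[1L], dim[2L])
  for (i in seq_len(nrow(centers))) {
    mask <- pmax(mask, make_disk_atom(radii[i],
                                      pmin(pmax(centers[i, ], 1), dim),
                                      dim))
  }
  mask
}

#' Generate one synthetic micrograph with exact ground truth
#'
#' @param cfg A [fixture_config()].
#' @return A `fixture_sample` list: `image` (degraded intensity matrix in
#'   \[0,1\]), `truth` (tibble `x_px`, `y_px`, `radius_px`, 0-based),
#'   `truth_mask` (binary union of the true disks, pre-degradation),
#'   `clutter_mask_truth` (binary union of the clutter blobs) and `cfg`.
#' @export
generate_fixture <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_fixture_seed(cfg$seed, {
    h <- cfg$dim[1L]; w <- cfg$dim[2L]
    if (cfg$n_nuclei > 0L) {
      pl <- place_centers(cfg)
    } else {
      pl <- list(centers = matrix(numeric(0), 0L, 2L), radii = numeric(0))
    }
    truth_mask <- render_disks(pl$centers, pl$radii, cfg$dim)
    img <- cfg$bg_level + (cfg$fg_level - cfg$bg_level) * truth_mask
    clutter <- matrix(0, h, w)
    if (cfg$clutter_blobs > 0L) {
      cr <- cfg$clutter_radius_multiplier * cfg$radius_range[2L]
      cm <- cr + 1
      placed <- 0L
      for (try in 1:2000) {
        if (placed >= cfg$clutter_blobs) break
        p <- c(stats::runif(1, cm, h - cm + 1), stats::runif(1, cm, w - cm + 1))
        if (nrow(pl$centers) > 0L) {
          d <- sqrt((pl$centers[, 1L] - p[1L])^2 + (pl$centers[, 2L] - p[2L])^2)
          if (any(d <= cr + pl$radii + 4)) next
        }
        clutter <- pmax(clutter, make_disk_atom(cr, p, cfg$dim))
        placed <- placed + 1L
      }
      if (placed < cfg$clutter_blobs) {
        stop("could not place clutter blobs; reduce their count or size",
             call. = FALSE)
      }
      # clutter glows at the same level as nuclei
      img <- pmax(img, cfg$bg_level + (cfg$fg_level - cfg$bg_level) * clutter)
    }
    if (cfg$illumination_gradient > 0) {
      ramp <- 1 - cfg$illumination_gradient * (seq_len(w) - 1) / max(w - 1, 1)
      img <- img * matrix(ramp, h, w, byrow = TRUE)
    }
    if (cfg$blur_sigma > 0) {
      img <- EBImage::filter2(img, gaussian_kernel(cfg$blur_sigma),
                              boundary = "replicate")
    }
    if (cfg$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, cfg$noise_sd), h, w)
    }
    img <- pmin(pmax(img, 0), 1)
    truth <- tibble::tibble(x_px = pl$centers[, 2L] - 1,
                            y_px = pl$centers[, 1L] - 1,
                            radius_px = pl$radii)
    structure(list(image = img, truth = truth, truth_mask = truth_mask,
                   clutter_mask_truth = clutter, cfg = cfg),
              class = "fixture_sample")
  })
}

#' Generate a suite of synthetic micrographs
#'
#' Independent samples sharing one configuration, with seeds `seed`,
#' `seed + 1`, ....
#'
#' @param base_cfg A [fixture_config()]; its own `seed` is ignored.
#' @param n_images Number of images, >= 1.
#' @param seed Seed of the first image.
#' @return List of `fixture_sample` objects.
#' @export
generate_suite <- function(base_cfg, n_images, seed = base_cfg$seed) {
  stopifnot(n_images >= 1)
  lapply(seq_len(n_images) - 1L, function(i) {
    cfg <- base_cfg
    cfg$seed <- as.integer(seed + i)
    generate_fixture(cfg)
  })
}
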