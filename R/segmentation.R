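#' Energy parameters for the joint segmentation model
#'
#' The model couples a convex active-contour-without-edges (ACWE) energy on a
#' relaxed labeling `u` in \[0,1\] with a sparse decomposition of `u` over a
#' dictionary of binary disk atoms with coefficient stack `t`:
#'
#' `E(u, t) = TV(u) + mu * <u, s> + lambda * ||t||_1 + (alpha/2) * ||u - D t||^2`
#'
#' where `s` is the ACWE data term (see [data_term()]) and `D t` the
#' dictionary synthesis ([synthesize()]). The energy is jointly convex, so
#' the minimizer does not depend on initialization.
#'
#' @param mu Weight of the data-fit term relative to total-variation
#'   regularization, > 0. A nucleus survives segmentation when its data gain
#'   (roughly `mu * |s| * area`) exceeds its TV perimeter cost plus the
#'   sparsity charge, so `mu` sets the faintest recoverable nucleus; the
#'   default 2 keeps partially dimmed nuclei (about half the nominal
#'   foreground contrast) above that bar for 20 px diameter disks.
#' @param lambda_sparsity Weight of the L1 penalty on the atom coefficients
#'   (the convex surrogate for the nucleus count), >= 0. Default `NULL`
#'   resolves to `0.05 * median atom area * alpha_coupling`, which scales the
#'   per-nucleus sparsity cost with the least-squares gain of placing one
#'   atom.
#' @param alpha_coupling Weight of the quadratic term tying `u` to the
#'   dictionary synthesis, > 0. Kept finite (rather than enforcing
#'   `u = D t` exactly) so nuclei that deviate slightly from the disk model,
#'   or partially overlap, can still be segmented. Default 0.5.
#' @param c_fg,c_bg Expected foreground/background intensity in \[0,1\],
#'   `c_bg < c_fg`. Default `NULL`: estimated from the image by Otsu
#'   thresholding ([estimate_intensities()]).
#' @param max_outer_iters Maximum alternating (u, t) iterations. Default 300.
#' @param inner_u_iters Newton-type labeling updates per outer iteration.
#'   Default 5.
#' @param inner_t_iters Proximal coefficient sweeps per outer iteration.
#'   Default 1.
#' @param tol Relative energy-change stopping threshold, applied over a\n#'   five-iteration window. Default 1e-5.
#' @param u_threshold Binarization level for the relaxed labeling, in (0,1).
#'   Any level gives a global minimizer of the binary problem; default 0.5.
#' @return An `energy_params` list.
#' @export
energy_params <- function(mu = 2,
                          lambda_sparsity = NULL,
                          alpha_coupling = 0.5,
                          c_fg = NULL, c_bg = NULL,
                          max_outer_iters = 300L,
                          inner_u_iters = 5L,
                          inner_t_iters = 1L,
                          tol = 1e-5,
                          u_threshold = 0.5) {
  stopifnot(mu > 0, alpha_coupling > 0,
            is.null(lambda_sparsity) || lambda_sparsity >= 0,
            u_threshold > 0, u_threshold < 1,
            max_outer_iters >= 1, inner_u_iters >= 1, inner_t_iters >= 1,
            tol > 0)
  if (!is.null(c_fg) && !is.null(c_bg)) {
    stopifnot(c_bg >= 0, c_fg <= 1, c_bg < c_fg)
  }
  structure(list(mu = mu, lambda_sparsity = lambda_sparsity,
                 alpha_coupling = alpha_coupling,
                 c_fg = c_fg, c_bg = c_bg,
                 max_outer_iters = as.integer(max_outer_iters),
                 inner_u_iters = as.integer(inner_u_iters),
                 inner_t_iters = as.integer(inner_t_iters),
                 tol = tol, u_threshold = u_threshold),
            class = "energy_params")
}

resolve_lambda <- function(params, dict) {
  if (!is.null(params$lambda_sparsity)) return(params$lambda_sparsity)
  med_area <- stats::median(dict$areas)
  0.05 * med_area * params$alpha_coupling
}

#' Estimate expected foreground/background intensities by Otsu thresholding
#'
#' @param image Preprocessed image in \[0,1\].
#' @return List with `c_fg` (mean intensity above the Otsu threshold) and
#'   `c_bg` (mean at or below it).
#' @export
estimate_intensities <- function(image) {
  assert_field(image)
  if (max(image) - min(image) < .Machine$double.eps) {
    stop("constant image: intensity histogram is degenerate", call. = FALSE)
  }
  thr <- EBImage::otsu(image, range = range(image), levels = 256L)
  fg <- image > thr
  list(c_fg = mean(image[fg]), c_bg = mean(image[!fg]))
}

#' ACWE data term
#'
#' `s(x) = (c_fg - f(x))^2 - (c_bg - f(x))^2`: negative where the pixel
#' resembles foreground, positive where it resembles background, zero at the
#' midpoint `(c_fg + c_bg)/2`.
#'
#' @param image Numeric matrix in \[0,1\].
#' @param params [energy_params()] with `c_fg`, `c_bg` set.
#' @return Numeric matrix.
#' @export
data_term <- function(image, params) {
  assert_field(image)
  if (is.null(params$c_fg) || is.null(params$c_bg)) {
    stop("c_fg / c_bg are not set; call estimate_intensities() first",
         call. = FALSE)
  }
  (params$c_fg - image)^2 - (params$c_bg - image)^2
}

#' Joint segmentation energy
#'
#' Evaluates `TV(u) + mu*<u,s> + lambda*||t||_1 + (alpha/2)*||u - D t||^2`
#' with exact (unsmoothed) isotropic TV.
#'
#' @param u Relaxed labeling matrix in \[0,1\].
#' @param t_stack Coefficient stack (3-d array).
#' @param image Preprocessed image.
#' @param dict A [build_dictionary()] result.
#' @param params [energy_params()] with intensities set.
#' @return Scalar energy.
#' @export
energy <- function(u, t_stack, image, dict, params) {
  assert_same_grid(u, image)
  assert_stack(t_stack, dict)
  s <- data_term(image, params)
  lambda <- resolve_lambda(params, dict)
  resid <- u - synthesize(t_stack, dict)
  tv_norm(u) + params$mu * inner_product(u, s) +
    lambda * sum(abs(t_stack)) +
    (params$alpha_coupling / 2) * sum(resid^2)
}

# u-subproblem energy (t, hence Dt, fixed); exact TV so the backtracking
# guard makes the recorded trace monotone by construction.
u_subenergy <- function(u, s, Dt, mu, alpha) {
  tv_norm(u) + mu * sum(u * s) + (alpha / 2) * sum((u - Dt)^2)
}

#' Labeling update (u-subproblem)
#'
#' Runs `inner_u_iters` primal-dual proximal iterations on the u-subproblem
#' `TV(u) + mu*<u,s> + (alpha/2)*||u - D t||^2` over the box \[0,1\]. The
#' dual variable handles the (nonsmooth) TV term exactly; the box barrier —
#' a piecewise-linear penalty whose minima are the interval bounds — enters
#' through exact projection onto \[0,1\] inside the primal proximal step.
#' The iterate is accepted through a backtracking line search on the exact
#' subproblem energy, which therefore never increases.
#'
#' @param u Current labeling matrix.
#' @param t_stack Current coefficient stack (held fixed).
#' @param image Preprocessed image.
#' @param dict Disk dictionary.
#' @param params [energy_params()] with intensities set.
#' @return Updated labeling matrix in \[0,1\].
#' @export
update_u <- function(u, t_stack, image, dict, params) {
  s <- data_term(image, params)
  Dt <- synthesize(t_stack, dict)
  update_u_given(u, s, Dt, params)
}

# state: environment carrying the warm-started dual field (pr, pc) across
# outer iterations; NULL runs cold.
update_u_given <- function(u, s, Dt, params, state = NULL) {
  mu <- params$mu; alpha <- params$alpha_coupling
  h <- nrow(u); w <- ncol(u)
  if (!is.null(state) && !is.null(state$pr)) {
    pr <- state$pr; pc <- state$pc
  } else {
    pr <- matrix(0, h, w); pc <- matrix(0, h, w)
  }
  tau <- 0.3                      # primal step; sigma*tau*||grad||^2 <= 1
  sigma <- 1 / (8 * tau)
  e_cur <- u_subenergy(u, s, Dt, mu, alpha)
  u0 <- u
  ubar <- u
  for (it in seq_len(params$inner_u_iters)) {
    g <- field_gradient(ubar)
    pr <- pr + sigma * g$dr
    pc <- pc + sigma * g$dc
    nrm <- pmax(1, sqrt(pr^2 + pc^2))
    pr <- pr / nrm; pc <- pc / nrm
    v <- u + tau * field_divergence(pr, pc)
    u_new <- (v - tau * mu * s + tau * alpha * Dt) / (1 + tau * alpha)
    u_new <- pmin(pmax(u_new, 0), 1)
    ubar <- 2 * u_new - u
    u <- u_new
  }
  if (any(!is.finite(u))) {
    stop("labeling update produced non-finite values (mu=", mu,
         ", alpha=", alpha, ")", call. = FALSE)
  }
  # monotonicity guard: line search from the entry point toward the iterate
  step <- 1
  for (bt in 1:25) {
    u_try <- u0 + step * (u - u0)
    if (u_subenergy(u_try, s, Dt, mu, alpha) <= e_cur) {
      if (!is.null(state)) { state$pr <- pr; state$pc <- pc }
      return(u_try)
    }
    step <- step / 2
  }
  u0  # no descent found: keep the entry point (dual still warm-starts later)
}

# t-subproblem objective (u fixed)
t_subenergy <- function(t_stack, u, dict, lambda, alpha) {
  lambda * sum(abs(t_stack)) +
    (alpha / 2) * sum((u - synthesize(t_stack, dict))^2)
}

# full energy with the synthesis field already at hand
energy_from_parts <- function(u, s, t_stack, Dt, params, lambda) {
  tv_norm(u) + params$mu * sum(u * s) + lambda * sum(abs(t_stack)) +
    (params$alpha_coupling / 2) * sum((u - Dt)^2)
}

#' Coefficient update (t-subproblem)
#'
#' Performs `inner_t_iters` clipped soft-threshold sweeps on
#' `lambda*||t||_1 + (alpha/2)*||u - D t||^2`. Each sweep solves, for every
#' coefficient simultaneously, the scalar optimality condition with all
#' other coefficients held at their current values — the unconstrained
#' solution `soft(<atom, residual_without_self>, lambda/alpha) / atom_area`,
#' clipped to \[0,1\] because the quadratic is monotone on an interval not
#' containing its extremum — then moves toward that candidate with a
#' backtracked damping factor so the exact subproblem energy never increases
#' (simultaneous updates of heavily overlapping atoms can otherwise
#' overshoot).
#'
#' @param u Current labeling (held fixed).
#' @param t_stack Current coefficient stack.
#' @param dict Disk dictionary.
#' @param params [energy_params()].
#' @return Updated coefficient stack with all entries in \[0,1\].
#' @export
update_t <- function(u, t_stack, dict, params) {
  assert_stack(t_stack, dict)
  plan <- prepare_synthesis_plan(dict, dim(u))
  update_t_impl(u, t_stack, dict, params, plan,
                Dt = fast_synthesize(t_stack, plan))$t
}

# One monotone sweep (plus optional Nesterov extrapolation carried in
# `state` across outer iterations; a sweep that would raise the subproblem
# energy is rejected, which also restarts the momentum sequence).
update_t_impl <- function(u, t_stack, dict, params, plan, Dt, state = NULL) {
  lambda <- resolve_lambda(params, dict)
  alpha <- params$alpha_coupling
  areas <- array(rep(dict$areas, each = length(u)),
                 c(dim(u), length(dict$radii)))
  for (sweep in seq_len(params$inner_t_iters)) {
    v <- t_stack
    Dv <- Dt
    if (!is.null(state) && !is.null(state$t_old)) {
      th_new <- (1 + sqrt(1 + 4 * state$theta^2)) / 2
      om <- (state$theta - 1) / th_new
      state$theta <- th_new
      v <- pmin(pmax(t_stack + om * (t_stack - state$t_old), 0), 1)
      Dv <- fast_synthesize(v, plan)
    }
    r0 <- u - Dv
    corr <- fast_adjoint(r0, plan)
    if (any(!is.finite(corr))) {
      stop("coefficient update produced non-finite values", call. = FALSE)
    }
    z <- v * areas + corr  # <atom, residual with own term added back>
    cand <- pmin(pmax(sign(z) * pmax(abs(z) - lambda / alpha, 0), 0) / areas, 1)
    dirn <- cand - v
    Dd <- fast_synthesize(dirn, plan)
    # along v + step*dirn the quadratic part is closed-form in step
    rd <- sum(r0 * Dd); dd <- sum(Dd^2)
    r0sq <- sum(r0^2)
    step_energy <- function(b) {
      lambda * sum(abs(v + b * dirn)) +
        (alpha / 2) * (b^2 * dd - 2 * b * rd + r0sq)
    }
    e_cur <- lambda * sum(abs(t_stack)) + (alpha / 2) * sum((u - Dt)^2)
    b_q <- if (dd > 0) max(0, min(rd / dd, 1)) else 0  # quadratic-part optimum
    steps <- unique(c(1, b_q, b_q / 2, 2^-(1:8)))
    es <- vapply(steps, step_energy, numeric(1))
    bi <- which.min(es)
    if (!is.null(state)) state$t_old <- t_stack
    if (es[bi] <= e_cur) {
      t_stack <- v + steps[bi] * dirn
      Dt <- Dv + steps[bi] * Dd
    }  # else: keep the current iterate (and restart any momentum)
    else if (!is.null(state)) { state$t_old <- NULL; state$theta <- 1 }
  }
  list(t = t_stack, Dt = Dt)
}

#' Joint dictionary-regularized segmentation
#'
#' Alternates the labeling update ([update_u()]) and the coefficient update
#' ([update_t()]) from `u = u_init` (default 0.5 everywhere) and `t = 0`
#' until the relative energy change drops below `params$tol` or
#' `params$max_outer_iters` is reached. Both updates carry backtracking
#' guards on their exact subproblem energies, so the recorded `energy_trace`
#' is non-increasing. Because the joint energy is convex, the minimizer —
#' and hence the thresholded segmentation — does not depend on `u_init`.
#'
#' @param image Preprocessed image in \[0,1\].
#' @param dict Disk dictionary spanning the expected nucleus radii.
#' @param params [energy_params()]. Missing `c_fg`/`c_bg` are estimated from
#'   `image` by Otsu thresholding.
#' @param u_init Initial labeling value (scalar in \[0,1\]) or full matrix.
#' @return A `nuclei_segmentation` object: list with `u` (relaxed labeling),
#'   `t` (coefficient stack), `dict`, `params` (with resolved intensities),
#'   `energy_trace`, `converged` and `image` (the input).
#' @export
segment <- function(image, dict, params = energy_params(), u_init = 0.5) {
  assert_field(image)
  stopifnot(inherits(dict, "disk_dictionary"), inherits(params, "energy_params"))
  if (max(image) - min(image) < .Machine$double.eps) {
    warning("constant image: returning an empty segmentation")
    t0 <- new_coefficient_stack(dim(image), length(dict$radii))
    res <- list(u = matrix(0, nrow(image), ncol(image)), t = t0,
                dict = dict, params = params,
                energy_trace = numeric(0), converged = TRUE, image = image)
    class(res) <- "nuclei_segmentation"
    return(res)
  }
  if (is.null(params$c_fg) || is.null(params$c_bg)) {
    ci <- estimate_intensities(image)
    params$c_fg <- ci$c_fg; params$c_bg <- ci$c_bg
  }
  s <- data_term(image, params)
  u <- if (is.matrix(u_init)) u_init else matrix(u_init, nrow(image), ncol(image))
  t_stack <- new_coefficient_stack(dim(image), length(dict$radii))
  plan <- prepare_synthesis_plan(dict, dim(image))
  lambda <- resolve_lambda(params, dict)
  Dt <- matrix(0, nrow(image), ncol(image))
  trace <- energy_from_parts(u, s, t_stack, Dt, params, lambda)
  converged <- FALSE
  dual_state <- new.env(parent = emptyenv())
  mom_state <- new.env(parent = emptyenv())
  mom_state$theta <- 1
  for (it in seq_len(params$max_outer_iters)) {
    u <- update_u_given(u, s, Dt, params, state = dual_state)
    upd <- update_t_impl(u, t_stack, dict, params, plan, Dt,
                         state = mom_state)
    t_stack <- upd$t; Dt <- upd$Dt
    e <- energy_from_parts(u, s, t_stack, Dt, params, lambda)
    trace <- c(trace, e)
    # stop when the energy has been flat over a short window (momentum can
    # plateau briefly before dropping again, so one small step is not enough)
    if (it >= 5L) {
      win <- trace[(length(trace) - 5L):length(trace)]
      if (max(abs(diff(win))) <=
          params$tol * max(abs(win[1L]), .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warning("segmentation did not converge within max_outer_iters; ",
            "returning the best iterate")
  }
  res <- list(u = u, t = t_stack, dict = dict, params = params,
              energy_trace = trace, converged = converged, image = image)
  class(res) <- "nuclei_segmentation"
  res
}

#' @export
print.nuclei_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<nuclei_segmentation> %dx%d, %d radii, %d outer ",
                     "iterations, converged: %s\n"),
              nrow(x$u), ncol(x$u), length(x$dict$radii),
              max(length(x$energy_trace) - 1L, 0L), x$converged))
  if (length(x$energy_trace)) {
    cat(sprintf("  energy %.6g -> %.6g\n",
                x$energy_trace[1L], x$energy_trace[length(x$energy_trace)]))
  }
  invisible(x)
}

#' Binarize the relaxed labeling
#'
#' `1` where `u > level`, else `0` (strict inequality, so a field exactly at
#' the level maps to background). Any level in (0,1) yields a global
#' minimizer of the underlying binary segmentation problem.
#'
#' @param u Labeling matrix in \[0,1\].
#' @param level Threshold in (0,1).
#' @return Binary matrix.
#' @export
threshold_u <- function(u, level = 0.5) {
  assert_field(u)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("threshold level must lie strictly inside (0, 1)", call. = FALSE)
  }
  (u > level) * 1
}
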