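# Dynamical-systems engine for the two-transcription-factor motif with
# mutual cross-inhibition and positive autoregulation.
#
# The motif is written in dimensionless form (degradation rate rescaled to 1):
#   dx/dt = beta1 + b * A(x; k_auto_x, n) * R(y; k_cross_x, n) - x
#   dy/dt = beta2 + b * A(y; k_auto_y, n) * R(x; k_cross_y, n) - y
# with activating Hill A(u; k, n) = u^n / (u^n + k^n) and repressing Hill
# R(v; k, n) = k^n / (v^n + k^n).  beta1 and beta2 carry the external inputs
# (IL-12- and IL-4-driven production for the Th1-Th2 interpretation), b is
# the maximal feedback production rate, and n the Hill exponent.

#' Parameters of the two-TF differentiation motif
#'
#' Constructs and validates the parameter set of the cross-inhibition /
#' autoactivation motif.  `x` plays the role of the Th1 master regulator
#' (T-bet analog) and `y` the Th2 one (GATA3 analog).
#'
#' The defaults put the system in the gradual-feedback, monostable regime
#' (Hill exponent 1, cross-inhibition thresholds four times the
#' autoregulation thresholds) in which the steady state tunes continuously
#' with the inputs.
#'
#' @param beta1,beta2 basal production rates driven by the two external
#'   inputs (dimensionless, >= 0).
#' @param b maximal feedback production rate (dimensionless, >= 0).
#' @param k_auto_x,k_auto_y autoregulation half-activation thresholds (> 0).
#' @param k_cross_x,k_cross_y cross-inhibition half-repression thresholds:
#'   `k_cross_x` is the threshold on `y` felt by `x`, and vice versa (> 0).
#' @param n Hill exponent (>= 1).
#' @return An object of class `grn_params`.
#' @seealso [grn_drift()], [find_fixed_points()], [classify_region()]
#' @examples
#' p <- grn_params(beta1 = 0.3, beta2 = 0.05)
#' k_ratios(p)
#' @export
grn_params <- function(beta1 = 0.05, beta2 = 0.05, b = 1,
                       k_auto_x = 0.5, k_auto_y = 0.5,
                       k_cross_x = 2, k_cross_y = 2, n = 1) {
  for (nm in c("beta1", "beta2", "b", "k_auto_x", "k_auto_y",
               "k_cross_x", "k_cross_y", "n")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a finite numeric scalar", call. = FALSE)
  }
  if (beta1 < 0 || beta2 < 0 || b < 0)
    stop("'beta1', 'beta2' and 'b' must be non-negative", call. = FALSE)
  if (k_auto_x <= 0 || k_auto_y <= 0 || k_cross_x <= 0 || k_cross_y <= 0)
    stop("all thresholds must be strictly positive", call. = FALSE)
  if (n < 1) stop("Hill exponent 'n' must be >= 1", call. = FALSE)
  structure(list(beta1 = beta1, beta2 = beta2, b = b,
                 k_auto_x = k_auto_x, k_auto_y = k_auto_y,
                 k_cross_x = k_cross_x, k_cross_y = k_cross_y, n = n),
            class = "grn_params")
}

#' @export
print.grn_params <- function(x, ...) {
  kr <- k_ratios(x)
  cat("Two-TF motif parameters (n =", x$n, ")\n")
  cat(sprintf("  inputs      beta1 = %.4g, beta2 = %.4g\n", x$beta1, x$beta2))
  cat(sprintf("  feedback    b = %.4g\n", x$b))
  cat(sprintf("  thresholds  k_auto = (%.4g, %.4g), k_cross = (%.4g, %.4g)\n",
              x$k_auto_x, x$k_auto_y, x$k_cross_x, x$k_cross_y))
  cat(sprintf("  ratios      k1 = %.4g, k2 = %.4g\n", kr[1], kr[2]))
  invisible(x)
}

#' Cross-to-auto threshold ratios
#'
#' The ratios `k1 = k_cross_x / k_auto_x` and `k2 = k_cross_y / k_auto_y`
#' measure the strength of the negative relative to the positive feedback;
#' they organise the motif's phase diagram.
#'
#' @param params a [grn_params()] object.
#' @return Named numeric vector `c(k1 = , k2 = )`.
#' @export
k_ratios <- function(params) {
  stopifnot(inherits(params, "grn_params"))
  c(k1 = params$k_cross_x / params$k_auto_x,
    k2 = params$k_cross_y / params$k_auto_y)
}

hill_act <- function(u, k, n) {
  un <- u^n
  un / (un + k^n)
}
hill_rep <- function(v, k, n) {
  kn <- k^n
  kn / (v^n + kn)
}

#' Instantaneous drift of the motif
#'
#' Evaluates the right-hand side of the motif's rate equations at a state.
#'
#' @param state numeric vector `c(x, y)` with non-negative entries.
#' @param params a [grn_params()] object.
#' @return Numeric vector `c(dx, dy)` of time derivatives.
#' @examples
#' grn_drift(c(1, 1), grn_params(beta1 = 0.1, beta2 = 0.1, b = 1,
#'                               k_auto_x = 0.5, k_auto_y = 0.5,
#'                               k_cross_x = 0.5, k_cross_y = 0.5))
#' @export
grn_drift <- function(state, params) {
  stopifnot(inherits(params, "grn_params"))
  if (length(state) != 2L || !all(is.finite(state)))
    stop("'state' must be a finite (x, y) pair", call. = FALSE)
  if (any(state < 0)) stop("state components must be non-negative", call. = FALSE)
  x <- state[[1]]; y <- state[[2]]; n <- params$n
  c(params$beta1 + params$b * hill_act(x, params$k_auto_x, n) *
      hill_rep(y, params$k_cross_x, n) - x,
    params$beta2 + params$b * hill_act(y, params$k_auto_y, n) *
      hill_rep(x, params$k_cross_y, n) - y)
}

# Jacobian of the drift at (x, y).
grn_jacobian <- function(state, params) {
  x <- state[[1]]; y <- state[[2]]; n <- params$n; b <- params$b
  dA <- function(u, k) n * k^n * u^(n - 1) / (u^n + k^n)^2
  dR <- function(v, k) -n * k^n * v^(n - 1) / (v^n + k^n)^2
  matrix(c(b * dA(x, params$k_auto_x) * hill_rep(y, params$k_cross_x, n) - 1,
           b * hill_act(x, params$k_auto_x, n) * dR(y, params$k_cross_x),
           b * hill_act(y, params$k_auto_y, n) * dR(x, params$k_cross_y),
           b * dA(y, params$k_auto_y) * hill_rep(x, params$k_cross_y, n) - 1),
         2, 2, byrow = TRUE)
}

# vectorised drift norm over grids, used for root seeding
drift_norm_grid <- function(gx, gy, p) {
  X <- matrix(gx, length(gx), length(gy))
  Y <- matrix(gy, length(gx), length(gy), byrow = TRUE)
  F1 <- p$beta1 + p$b * hill_act(X, p$k_auto_x, p$n) *
    hill_rep(Y, p$k_cross_x, p$n) - X
  F2 <- p$beta2 + p$b * hill_act(Y, p$k_auto_y, p$n) *
    hill_rep(X, p$k_cross_y, p$n) - Y
  sqrt(F1^2 + F2^2)
}

# damped Newton polishing from a seed; returns NULL on failure
newton_polish <- function(z, params, maxit = 80L) {
  for (it in seq_len(maxit)) {
    f <- grn_drift(pmax(z, 0), params)
    if (max(abs(f)) < 1e-12) break
    J <- grn_jacobian(pmax(z, 0), params)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      zn <- pmax(z + lam * step, 0)
      fn <- grn_drift(zn, params)
      if (sum(fn^2) < sum(f^2) || lam < 1e-4) break
      lam <- lam / 2
    }
    z <- pmax(z + lam * step, 0)
  }
  z <- pmax(z, 0)
  if (max(abs(grn_drift(z, params))) < 1e-9) z else NULL
}

#' Find all fixed points of the motif
#'
#' Locates the steady states of the rate equations inside a search box by
#' multi-start damped Newton iteration seeded from local minima of the drift
#' norm on a combined linear/logarithmic grid, then classifies stability from
#' the real parts of the Jacobian eigenvalues (stability margin `1e-8`).
#' Duplicates are merged at relative distance `tol`.
#'
#' The degenerate case `b = 0` is handled analytically: the system is linear
#' decay towards `(beta1, beta2)`.
#'
#' @param params a [grn_params()] object.
#' @param search_box upper corner `c(x_max, y_max)` of the search region
#'   (lower corner is the origin).  Default covers `[0, max(beta) + b + 0.5]`
#'   in each coordinate.
#' @param tol relative merge tolerance for duplicate roots.
#' @param grid_n seeding grid resolution per axis (each of the linear and
#'   logarithmic grids).
#' @return A `data.frame` of class `fixed_points` with columns `x`, `y`,
#'   `stable`, `eig1`, `eig2` (real parts of the Jacobian spectrum), sorted
#'   by `x`.
#' @examples
#' find_fixed_points(grn_params())
#' @export
find_fixed_points <- function(params, search_box = NULL, tol = 1e-6,
                              grid_n = 48L) {
  stopifnot(inherits(params, "grn_params"))
  if (params$b == 0) {
    J <- diag(-1, 2)
    return(structure(
      data.frame(x = params$beta1, y = params$beta2, stable = TRUE,
                 eig1 = -1, eig2 = -1),
      class = c("fixed_points", "data.frame")))
  }
  hi <- if (is.null(search_box)) {
    rep(max(params$beta1, params$beta2) + params$b + 0.5, 2)
  } else {
    if (length(search_box) == 1L) search_box <- rep(search_box, 2)
    if (any(search_box <= 0)) stop("'search_box' must be positive", call. = FALSE)
    search_box
  }
  axis_grid <- function(h)
    unique(sort(c(seq(1e-7, h, length.out = grid_n),
                  exp(seq(log(1e-4 * h), log(h), length.out = grid_n)))))
  gx <- axis_grid(hi[1]); gy <- axis_grid(hi[2])
  M <- drift_norm_grid(gx, gy, params)
  ni <- nrow(M); nj <- ncol(M)
  # local minima of the drift norm over 3x3 neighbourhoods, vectorised
  interior <- M[2:(ni - 1), 2:(nj - 1)]
  ismin <- matrix(TRUE, ni - 2, nj - 2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismin <- ismin & interior <= M[(2 + di):(ni - 1 + di), (2 + dj):(nj - 1 + dj)]
  }
  idx <- which(ismin, arr.ind = TRUE)
  seeds <- lapply(seq_len(nrow(idx)), function(r)
    c(gx[idx[r, 1] + 1], gy[idx[r, 2] + 1]))
  seeds <- c(seeds, list(c(params$beta1 + 1e-9, params$beta2 + 1e-9),
                         c(hi[1], 1e-6), c(1e-6, hi[2]), hi))
  roots <- list()
  for (s in seeds) {
    r <- newton_polish(s, params)
    if (!is.null(r) && all(r <= hi * (1 + 1e-6)))
      roots[[length(roots) + 1L]] <- r
  }
  if (!length(roots)) stop("no fixed point found", call. = FALSE)
  R <- do.call(rbind, roots)
  R <- R[order(R[, 1], R[, 2]), , drop = FALSE]
  keep <- rep(TRUE, nrow(R))
  for (i in seq_len(nrow(R))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(R))) {
      if (j > i && keep[j] &&
          sqrt(sum((R[i, ] - R[j, ])^2)) < tol * (1 + sqrt(sum(R[i, ]^2))))
        keep[j] <- FALSE
    }
  }
  R <- R[keep, , drop = FALSE]
  ev <- t(apply(R, 1, function(z)
    sort(Re(eigen(grn_jacobian(z, params), only.values = TRUE)$values))))
  structure(
    data.frame(x = R[, 1], y = R[, 2],
               stable = ev[, 2] < -1e-8, eig1 = ev[, 1], eig2 = ev[, 2]),
    class = c("fixed_points", "data.frame"))
}

#' Classify the motif's dynamical regime
#'
#' Labels a parameter set by its fixed-point structure: `"IV"` if at least
#' two stable fixed points exist (bistability), otherwise by the location of
#' the unique stable fixed point -- `"I"` (high x, low y), `"II"` (low x,
#' high y) or `"III"` (co-expression).  "High" means at least
#' `expression_threshold` times the largest stable coordinate.
#'
#' @param params a [grn_params()] object.
#' @param expression_threshold fraction of the maximal stable coordinate
#'   used to call a coordinate "high" (default 0.5).
#' @return Character scalar: one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
classify_region <- function(params, expression_threshold = 0.5) {
  stopifnot(inherits(params, "grn_params"),
            expression_threshold > 0, expression_threshold < 1)
  fp <- find_fixed_points(params)
  st <- fp[fp$stable, , drop = FALSE]
  if (nrow(st) > 2)
    warning("more than two stable fixed points; labelling as region IV",
            call. = FALSE)
  if (nrow(st) >= 2) return("IV")
  if (nrow(st) == 0) stop("no stable fixed point found", call. = FALSE)
  m <- max(st$x, st$y)
  high_x <- st$x >= expression_threshold * m
  high_y <- st$y >= expression_threshold * m
  if (high_x && !high_y) "I" else if (high_y && !high_x) "II" else "III"
}

#' Phase diagram over the threshold-ratio plane
#'
#' Sweeps the `(k1, k2)` plane of cross-to-auto threshold ratios at fixed
#' inputs and labels every grid point via [classify_region()].
#'
#' @param k1_grid,k2_grid strictly positive grids of threshold ratios.
#' @param base_params a [grn_params()] object fixing `beta1`, `beta2`, `b`,
#'   `n` and the autoregulation thresholds; the cross thresholds are set to
#'   `ratio * k_auto` per grid point.
#' @param expression_threshold passed to [classify_region()].
#' @return An object of class `region_map`: list with `k1_axis`, `k2_axis`,
#'   a character `labels` matrix (rows index `k1`), `inputs` and
#'   `regions_present`.
#' @export
phase_diagram <- function(k1_grid, k2_grid, base_params,
                          expression_threshold = 0.5) {
  stopifnot(inherits(base_params, "grn_params"),
            all(k1_grid > 0), all(k2_grid > 0),
            length(k1_grid) >= 1, length(k2_grid) >= 1)
  lab <- matrix(NA_character_, length(k1_grid), length(k2_grid))
  for (i in seq_along(k1_grid)) {
    for (j in seq_along(k2_grid)) {
      p <- base_params
      p$k_cross_x <- k1_grid[i] * p$k_auto_x
      p$k_cross_y <- k2_grid[j] * p$k_auto_y
      lab[i, j] <- classify_region(p, expression_threshold)
    }
  }
  structure(list(k1_axis = k1_grid, k2_axis = k2_grid, labels = lab,
                 inputs = c(beta1 = base_params$beta1,
                            beta2 = base_params$beta2),
                 regions_present = sort(unique(as.vector(lab)))),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("Region map:", length(x$k1_axis), "x", length(x$k2_axis),
      "grid at inputs (", x$inputs[1], ",", x$inputs[2], ")\n")
  cat("  regimes present:", paste(x$regions_present, collapse = ", "), "\n")
  invisible(x)
}

#' Map a cytokine concentration to a model input rate
#'
#' Saturating first-order map `beta = beta_max * c / (c + K)` from an
#' extracellular cytokine concentration (ng/ml) to the motif's basal
#' production rate; the experimental 0-540 ng/ml range spans saturation.
#'
#' @param conc concentration(s) in ng/ml, >= 0.
#' @param beta_max saturating input rate.
#' @param K half-saturation concentration (ng/ml).
#' @return Numeric vector of input rates.
#' @export
beta_from_concentration <- function(conc, beta_max = 0.9, K = 50) {
  stopifnot(all(conc >= 0), beta_max >= 0, K > 0)
  beta_max * conc / (conc + K)
}

# stable steady state(s) at given inputs; helper shared by map/trajectory
steady_states_at <- function(params, beta1, beta2) {
  p <- params; p$beta1 <- beta1; p$beta2 <- beta2
  fp <- find_fixed_points(p)
  fp[fp$stable, c("x", "y"), drop = FALSE]
}

#' Steady-state co-expression map over the input plane
#'
#' Computes the steady state at every input pair on a grid and assigns one
#' of four co-expression patterns by comparing each coordinate to
#' `T_frac` times its maximum over the map (the expression threshold `T`).
#'
#' @param params a [grn_params()] object; must be monostable at every grid
#'   point, otherwise an error names the offending inputs.
#' @param beta1_grid,beta2_grid input grids (model units, >= 0).
#' @param T_frac threshold fraction of the per-coordinate map maximum.
#' @return An object of class `coexpression_map`: list with the axes, `x`
#'   and `y` steady-state matrices (rows index `beta1`), a `pattern` matrix
#'   with entries in `{"neither", "X-only", "Y-only", "both"}`, and the
#'   thresholds used.
#' @export
input_response_map <- function(params, beta1_grid, beta2_grid, T_frac = 0.5) {
  stopifnot(inherits(params, "grn_params"), all(beta1_grid >= 0),
            all(beta2_grid >= 0), T_frac > 0, T_frac < 1)
  n1 <- length(beta1_grid); n2 <- length(beta2_grid)
  X <- Y <- matrix(NA_real_, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      st <- steady_states_at(params, beta1_grid[i], beta2_grid[j])
      if (nrow(st) != 1)
        stop(sprintf(
          "ambiguous steady state: %d stable fixed points at inputs (%.4g, %.4g)",
          nrow(st), beta1_grid[i], beta2_grid[j]), call. = FALSE)
      X[i, j] <- st$x; Y[i, j] <- st$y
    }
  }
  tx <- T_frac * max(X); ty <- T_frac * max(Y)
  pattern <- matrix("neither", n1, n2)
  pattern[X >= tx & Y < ty] <- "X-only"
  pattern[X < tx & Y >= ty] <- "Y-only"
  pattern[X >= tx & Y >= ty] <- "both"
  structure(list(beta1_axis = beta1_grid, beta2_axis = beta2_grid,
                 x = X, y = Y, pattern = pattern,
                 thresholds = c(x = tx, y = ty), T_frac = T_frac),
            class = "coexpression_map")
}

#' Steady-state trajectory along a path in the input plane
#'
#' Interpolates linearly between two input pairs and records the stable
#' steady state at each step.  With `select = "error"` (default) any
#' bistable point along the path aborts; with `select = "continuation"` the
#' stable fixed point nearest the previous state is followed, which exposes
#' hysteresis when the path crosses a bistable pocket.
#'
#' @param params a [grn_params()] object.
#' @param start_inputs,end_inputs input pairs `c(beta1, beta2)`.
#' @param n_steps number of interpolation steps (the path has
#'   `n_steps + 1` points).
#' @param select `"error"` or `"continuation"` (see above).
#' @return An object of class `input_trajectory`: data.frame with columns
#'   `beta1`, `beta2`, `x`, `y` plus attributes `max_jump` (largest
#'   step-to-step Euclidean jump) and `dynamic_range`.
#' @export
input_trajectory <- function(params, start_inputs, end_inputs, n_steps = 50,
                             select = c("error", "continuation")) {
  select <- match.arg(select)
  stopifnot(inherits(params, "grn_params"), length(start_inputs) == 2,
            length(end_inputs) == 2, n_steps >= 1)
  tt <- seq(0, 1, length.out = n_steps + 1)
  out <- matrix(NA_real_, n_steps + 1, 2)
  prev <- NULL
  for (k in seq_along(tt)) {
    bet <- (1 - tt[k]) * start_inputs + tt[k] * end_inputs
    st <- steady_states_at(params, bet[1], bet[2])
    if (nrow(st) == 0) stop("no stable fixed point on path", call. = FALSE)
    if (nrow(st) > 1) {
      if (select == "error")
        stop(sprintf(
          "ambiguous steady state: %d stable fixed points at inputs (%.4g, %.4g)",
          nrow(st), bet[1], bet[2]), call. = FALSE)
      d <- (st$x - prev[1])^2 + (st$y - prev[2])^2
      st <- st[which.min(d), , drop = FALSE]
    }
    out[k, ] <- c(st$x[1], st$y[1])
    prev <- out[k, ]
  }
  jumps <- sqrt(rowSums((out[-1, , drop = FALSE] -
                           out[-nrow(out), , drop = FALSE])^2))
  betas <- outer(1 - tt, start_inputs) + outer(tt, end_inputs)
  res <- data.frame(beta1 = betas[, 1], beta2 = betas[, 2],
                    x = out[, 1], y = out[, 2])
  structure(res, class = c("input_trajectory", "data.frame"),
            max_jump = if (length(jumps)) max(jumps) else 0,
            dynamic_range = max(dist(out)))
}

#' Detect a sharp transition (hysteresis) along an input path
#'
#' Runs forward and backward continuation trajectories at `n_steps` and at
#' `2 * n_steps` steps.  A continuous (monostable) response shows a maximum
#' jump that shrinks roughly in half when the step count doubles and no gap
#' between the two sweep directions; a path crossing a bistable pocket shows
#' a persistent jump and a forward/backward branch gap.
#'
#' @inheritParams input_trajectory
#' @param jump_tol fraction of the dynamic range above which a persistent
#'   jump is reported as sharp (default 0.1).
#' @return An object of class `transition_report`: list with fields
#'   `sharp` (logical), `max_jump`, `max_jump_refined`, `hysteresis_gap`
#'   (largest distance between forward and backward branches at matched
#'   inputs) and `dynamic_range`.
#' @export
detect_sharp_transition <- function(params, start_inputs, end_inputs,
                                    n_steps = 50, jump_tol = 0.1) {
  fwd <- input_trajectory(params, start_inputs, end_inputs, n_steps,
                          select = "continuation")
  bwd <- input_trajectory(params, end_inputs, start_inputs, n_steps,
                          select = "continuation")
  fwd2 <- input_trajectory(params, start_inputs, end_inputs, 2 * n_steps,
                           select = "continuation")
  dr <- max(attr(fwd, "dynamic_range"), 1e-12)
  gap <- max(sqrt((fwd$x - rev(bwd$x))^2 + (fwd$y - rev(bwd$y))^2))
  mj <- attr(fwd, "max_jump"); mj2 <- attr(fwd2, "max_jump")
  structure(list(sharp = mj2 > jump_tol * dr,
                 max_jump = mj, max_jump_refined = mj2,
                 hysteresis_gap = gap, dynamic_range = dr),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(if (x$sharp) "Sharp transition detected" else "Continuous response", "\n")
  cat(sprintf("  max jump %.4g (refined %.4g) over dynamic range %.4g\n",
              x$max_jump, x$max_jump_refined, x$dynamic_range))
  cat(sprintf("  forward/backward hysteresis gap %.4g\n", x$hysteresis_gap))
  invisible(x)
}

#' Export a labelled grid map as TSV with a JSON sidecar
#'
#' Writes a [phase_diagram()] or [input_response_map()] result as a
#' tab-separated grid (axis values in the first row/column) plus a
#' `<path>.json` sidecar holding the parameters.
#'
#' @param map a `region_map` or `coexpression_map` object.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_grid_map <- function(map, path) {
  if (inherits(map, "region_map")) {
    ax1 <- map$k1_axis; ax2 <- map$k2_axis; M <- map$labels
    meta <- list(kind = "region_map", inputs = as.list(map$inputs),
                 regions_present = map$regions_present)
  } else if (inherits(map, "coexpression_map")) {
    ax1 <- map$beta1_axis; ax2 <- map$beta2_axis; M <- map$pattern
    meta <- list(kind = "coexpression_map", T_frac = map$T_frac,
                 thresholds = as.list(map$thresholds))
  } else stop("unsupported map object", call. = FALSE)
  tab <- cbind(format(ax1, digits = 10), M)
  colnames(tab) <- c("axis1\\axis2", format(ax2, digits = 10))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
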