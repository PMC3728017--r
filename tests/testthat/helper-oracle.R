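# Independent oracles used by the tests.  These deliberately re-derive the
# motif equations and solve them by a different route (dense 1D nullcline
# scans + bisection) than the package's multi-start Newton finder.

o_act <- function(u, k, n) u^n / (u^n + k^n)
o_rep <- function(v, k, n) k^n / (v^n + k^n)

o_drift <- function(x, y, p) {
  c(p$beta1 + p$b * o_act(x, p$k_auto_x, p$n) * o_rep(y, p$k_cross_x, p$n) - x,
    p$beta2 + p$b * o_act(y, p$k_auto_y, p$n) * o_rep(x, p$k_cross_y, p$n) - y)
}

o_jac <- function(x, y, p) {
  n <- p$n
  dA <- function(u, k) n * k^n * u^(n - 1) / (u^n + k^n)^2
  dR <- function(v, k) -n * k^n * v^(n - 1) / (v^n + k^n)^2
  matrix(c(p$b * dA(x, p$k_auto_x) * o_rep(y, p$k_cross_x, n) - 1,
           p$b * o_act(x, p$k_auto_x, n) * dR(y, p$k_cross_x),
           p$b * o_act(y, p$k_auto_y, n) * dR(x, p$k_cross_y),
           p$b * dA(y, p$k_auto_y) * o_rep(x, p$k_cross_y, n) - 1),
         2, 2, byrow = TRUE)
}

# All fixed points by dense scanning along both nullcline reductions.
# On the x-nullcline y is an explicit function of x (and symmetrically),
# so roots appear as sign changes of a 1D residual, refined by bisection.
oracle_fixed_points <- function(p, npts = 8000) {
  hi <- max(p$beta1, p$beta2) + p$b + 0.5
  scan1 <- function(b1, b2, kax, kay, kcx, kcy) {
    y_of_x <- function(x) {
      r <- p$b * o_act(x, kax, p$n) / (x - b1) - 1
      ifelse(r > 0, kcx * r^(1 / p$n), NA_real_)
    }
    g <- function(x) {
      y <- y_of_x(x)
      b2 + p$b * o_act(y, kay, p$n) * o_rep(x, kcy, p$n) - y
    }
    scan_grid <- function(xs, depth) {
      gv <- suppressWarnings(g(xs))
      fin <- is.finite(gv)
      idx <- which(fin[-length(gv)] & fin[-1] &
                     gv[-length(gv)] * gv[-1] < 0)
      roots <- lapply(idx, function(i) {
        r <- tryCatch(
          stats::uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-13)$root,
          error = function(e) NA_real_)
        if (is.na(r)) NULL else c(r, y_of_x(r))
      })
      # the residual's domain edge (r -> 0+) can hide a crossing inside one
      # grid cell; refine across finite/NA boundaries
      if (depth > 0) {
        edge <- which(fin[-length(gv)] != fin[-1])
        for (i in edge) {
          sub <- seq(xs[i], xs[i + 1], length.out = 400)
          roots <- c(roots, scan_grid(sub, depth - 1))
        }
      }
      roots
    }
    xs <- b1 + (hi - b1) * sort(unique(c(
      10^seq(-13, 0, length.out = npts / 2),
      seq(1e-13, 1, length.out = npts / 2))))
    do.call(rbind, scan_grid(xs, depth = 2))
  }
  R1 <- scan1(p$beta1, p$beta2, p$k_auto_x, p$k_auto_y,
              p$k_cross_x, p$k_cross_y)
  R2 <- scan1(p$beta2, p$beta1, p$k_auto_y, p$k_auto_x,
              p$k_cross_y, p$k_cross_x)
  if (!is.null(R2) && nrow(R2)) R2 <- R2[, 2:1, drop = FALSE]
  R <- rbind(R1, R2)
  if (is.null(R) || !nrow(R)) return(NULL)
  R <- R[order(R[, 1], R[, 2]), , drop = FALSE]
  keep <- rep(TRUE, nrow(R))
  for (i in seq_len(nrow(R))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(R)))
      if (j > i && keep[j] &&
          sqrt(sum((R[i, ] - R[j, ])^2)) < 1e-5 * (1 + sqrt(sum(R[i, ]^2))))
        keep[j] <- FALSE
  }
  R <- R[keep, , drop = FALSE]
  st <- apply(R, 1, function(z)
    all(Re(eigen(o_jac(z[1], z[2], p))$values) < -1e-8))
  cbind(x = R[, 1], y = R[, 2], stable = st)
}

# classic fixed-step RK4 integrator, independent of any package code
rk4_integrate <- function(z0, p, t_end = 60, dt = 0.01) {
  z <- z0
  steps <- ceiling(t_end / dt)
  for (i in seq_len(steps)) {
    k1 <- o_drift(z[1], z[2], p)
    k2 <- o_drift(z[1] + dt / 2 * k1[1], z[2] + dt / 2 * k1[2], p)
    k3 <- o_drift(z[1] + dt / 2 * k2[1], z[2] + dt / 2 * k2[2], p)
    k4 <- o_drift(z[1] + dt * k3[1], z[2] + dt * k3[2], p)
    z <- pmax(z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  z
}

# random valid parameter draw for property tests
random_grn_params <- function(nset = 1:3) {
  grn_params(beta1 = runif(1, 0.01, 0.5), beta2 = runif(1, 0.01, 0.5),
             b = runif(1, 0.2, 3),
             k_auto_x = runif(1, 0.05, 2), k_auto_y = runif(1, 0.05, 2),
             k_cross_x = runif(1, 0.02, 5), k_cross_y = runif(1, 0.02, 5),
             n = sample(nset, 1))
}

# region-IV (bistable) reference parameterization
grn_params_iv <- function()
  grn_params(beta1 = 0.02, beta2 = 0.02, k_cross_x = 0.125, k_cross_y = 0.125)
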