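# Two-TF motif: drift, fixed points, regimes, maps, trajectories.

test_that("drift matches the motif equations", {
  # basal-free system: the origin is a fixed point since A(0) = 0
  p0 <- grn_params(beta1 = 0, beta2 = 0, b = 2)
  expect_equal(grn_drift(c(0, 0), p0), c(0, 0))

  # symmetric parameters: the diagonal is invariant
  ps <- grn_params(beta1 = 0.2, beta2 = 0.2)
  d <- grn_drift(c(0.7, 0.7), ps)
  expect_equal(d[1], d[2])

  # hand evaluation: beta 0.1, b 1, all k 0.5, n 1, state (1, 1)
  ph <- grn_params(beta1 = 0.1, beta2 = 0.1, b = 1,
                   k_auto_x = 0.5, k_auto_y = 0.5,
                   k_cross_x = 0.5, k_cross_y = 0.5, n = 1)
  expect_equal(grn_drift(c(1, 1), ph),
               rep(0.1 + 1 * (1 / 1.5) * (0.5 / 1.5) - 1, 2))

  expect_error(grn_drift(c(-0.1, 0), ps), "non-negative")
  expect_error(grn_params(k_cross_x = 0), "positive")
  expect_error(grn_params(n = 0.5), "Hill")
})

test_that("find_fixed_points handles the linear-decay degenerate case", {
  fp <- find_fixed_points(grn_params(beta1 = 0.3, beta2 = 0.7, b = 0))
  expect_equal(nrow(fp), 1L)
  expect_equal(c(fp$x, fp$y), c(0.3, 0.7))
  expect_true(fp$stable)
})

test_that("strong symmetric cross-inhibition yields two stable fixed points", {
  fp <- find_fixed_points(grn_params_iv())
  expect_equal(sum(fp$stable), 2L)
  # the two stable states are mirror images flanking a symmetric saddle
  st <- fp[fp$stable, ]
  expect_equal(st$x, rev(st$y), tolerance = 1e-8)
})

test_that("finder agrees with the dense nullcline-scanning oracle", {
  set.seed(101)
  for (i in 1:30) {
    p <- random_grn_params()
    fo <- oracle_fixed_points(p)
    ff <- find_fixed_points(p)
    expect_equal(nrow(ff), nrow(fo), info = paste("draw", i))
    expect_equal(unname(sort(ff$x)), unname(sort(fo[, "x"])), tolerance = 1e-6,
                 info = paste("draw", i))
    expect_equal(sum(ff$stable), sum(fo[, "stable"]),
                 info = paste("draw", i))
  }
})

test_that("every parameterization has at least one fixed point", {
  set.seed(7)
  for (i in 1:20) {
    fp <- find_fixed_points(random_grn_params(nset = 1:4))
    expect_gte(nrow(fp), 1L)
    expect_gte(sum(fp$stable), 1L)
  }
})

test_that("swap symmetry maps the fixed-point set to its mirror image", {
  set.seed(11)
  for (i in 1:10) {
    p <- random_grn_params()
    q <- grn_params(beta1 = p$beta2, beta2 = p$beta1, b = p$b,
                    k_auto_x = p$k_auto_y, k_auto_y = p$k_auto_x,
                    k_cross_x = p$k_cross_y, k_cross_y = p$k_cross_x,
                    n = p$n)
    fp <- find_fixed_points(p)
    fq <- find_fixed_points(q)
    expect_equal(nrow(fp), nrow(fq))
    expect_equal(sort(fp$x), sort(fq$y), tolerance = 1e-7)
    expect_equal(sort(fp$y), sort(fq$x), tolerance = 1e-7)
  }
})

test_that("reported stable fixed points attract perturbed trajectories", {
  set.seed(23)
  for (p in list(grn_params(), grn_params_iv(),
                 grn_params(beta1 = 0.3, beta2 = 0.005,
                            k_cross_x = 0.075, k_cross_y = 0.075))) {
    fp <- find_fixed_points(p)
    st <- fp[fp$stable, , drop = FALSE]
    for (r in seq_len(nrow(st))) {
      z0 <- pmax(c(st$x[r], st$y[r]) * (1 + runif(2, -0.02, 0.02)), 1e-6)
      zT <- rk4_integrate(z0, p)
      expect_equal(zT, c(st$x[r], st$y[r]), tolerance = 1e-5)
    }
  }
})

test_that("classify_region labels the reference parameterizations", {
  # weak cross-inhibition, balanced inputs: single co-expressed state
  expect_identical(classify_region(grn_params()), "III")
  # strong symmetric cross-inhibition, balanced inputs: bistable
  expect_identical(classify_region(grn_params_iv()), "IV")
  # dominant input A with strong cross-inhibition: Th1-like monostable
  p1 <- grn_params(beta1 = 0.3, beta2 = 0.005,
                   k_cross_x = 0.075, k_cross_y = 0.075)
  expect_identical(classify_region(p1), "I")
  # swap symmetry: II
  p2 <- grn_params(beta1 = 0.005, beta2 = 0.3,
                   k_cross_x = 0.075, k_cross_y = 0.075)
  expect_identical(classify_region(p2), "II")
})

test_that("phase diagram shows the expected regime structure", {
  kg <- exp(seq(log(0.05), log(20), length.out = 12))
  base <- grn_params(beta1 = 0.02, beta2 = 0.02)
  pd <- phase_diagram(kg, kg, base)
  expect_setequal(pd$regions_present, c("I", "II", "III", "IV"))

  # single-point grid
  pd1 <- phase_diagram(4, 4, base)
  expect_equal(dim(pd1$labels), c(1L, 1L))
  expect_length(pd1$regions_present, 1L)

  # swapping the axes and the input roles transposes the map with I <-> II
  pd_sw <- phase_diagram(kg, kg,
                         grn_params(beta1 = base$beta2, beta2 = base$beta1))
  remap <- c(I = "II", II = "I", III = "III", IV = "IV")
  expect_identical(pd_sw$labels, t(matrix(remap[pd$labels],
                                          nrow(pd$labels), ncol(pd$labels))))
})

test_that("input_response_map assigns the four co-expression patterns", {
  b <- seq(0, 0.82, length.out = 7)
  m <- input_response_map(grn_params(), b, b, T_frac = 0.5)
  expect_identical(m$pattern[1, 1], "neither")        # no-input corner
  expect_identical(m$pattern[7, 1], "X-only")         # Th1 corner
  expect_identical(m$pattern[1, 7], "Y-only")         # Th2 corner
  expect_true(any(m$pattern == "both"))
  # monotone response: x non-increasing in beta2 along every row,
  # y non-decreasing
  for (i in seq_along(b)) {
    expect_true(all(diff(m$x[i, ]) <= 1e-8))
    expect_true(all(diff(m$y[i, ]) >= -1e-8))
  }
})

test_that("input_response_map refuses bistable grid points", {
  p <- grn_params_iv()
  expect_error(input_response_map(p, c(0.005, 0.02), c(0.005, 0.02)),
               "ambiguous steady state")
})

test_that("trajectories are continuous in the monostable regime", {
  start <- c(beta_from_concentration(540), 0)
  end <- c(0, beta_from_concentration(540))
  tr0 <- input_trajectory(grn_params(), start, start, n_steps = 5)
  expect_equal(diff(range(tr0$x)), 0)
  expect_equal(diff(range(tr0$y)), 0)

  tr <- input_trajectory(grn_params(), start, end, n_steps = 50)
  # monotone crossover from the x-dominant to the y-dominant state
  expect_true(all(diff(tr$x) < 1e-8))
  expect_true(all(diff(tr$y) > -1e-8))
  dr <- attr(tr, "dynamic_range")
  expect_lt(attr(tr, "max_jump"), 0.1 * dr)

  # continuity certificate: refining the path shrinks the largest jump
  tr2 <- input_trajectory(grn_params(), start, end, n_steps = 100)
  expect_lt(attr(tr2, "max_jump"), 0.6 * attr(tr, "max_jump"))

  rep3 <- detect_sharp_transition(grn_params(), start, end, n_steps = 50)
  expect_false(rep3$sharp)
  expect_lt(rep3$hysteresis_gap, 1e-6)
})

test_that("bistable parameters produce a persistent jump and hysteresis", {
  p <- grn_params_iv()
  start <- c(0.03, 0.001); end <- c(0.001, 0.03)
  rep <- detect_sharp_transition(p, start, end, n_steps = 40)
  expect_true(rep$sharp)
  # the jump does not vanish under refinement
  expect_gt(rep$max_jump_refined, 0.5 * rep$max_jump)
  expect_gt(rep$hysteresis_gap, 0.05)
  # error route when following is disabled
  expect_error(input_trajectory(p, start, end, 40, select = "error"),
               "ambiguous steady state")
})

test_that("grid maps export as TSV with a JSON sidecar", {
  tmp <- withr::local_tempdir()
  pd <- phase_diagram(c(0.1, 4), c(0.1, 4),
                      grn_params(beta1 = 0.02, beta2 = 0.02))
  path <- file.path(tmp, "pd.tsv")
  write_grid_map(pd, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  tab <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(tab), 2L)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$kind, "region_map")
})
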