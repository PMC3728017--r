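# Analysis statistics: transforms, normalization, angles, separability,
# noise, bias curves, mutual information, modality, quadrants, ratios.

test_that("display transforms are monotone, linear near zero and log at
           high intensity", {
  expect_equal(transform_channel(0), 0)
  x <- sort(c(0, 10^seq(-2, 5, length.out = 100)))
  y <- transform_channel(x, cofactor = 5)
  expect_true(all(diff(y) > 0))
  # asymptotics: asinh(x / c) -> ln(2 x / c) for x >> c, within 1%
  big <- x[x > 500]
  expect_equal(transform_channel(big, cofactor = 5), log(2 * big / 5),
               tolerance = 0.01)
  expect_error(transform_channel(1, cofactor = 0), "cofactor")

  lg <- transform_channel(c(-100, 0, 10, 1000, 262144), "logicle")
  expect_true(all(diff(lg) > 0))
  # top of scale maps to the full decade count
  expect_equal(lg[5], 4.5, tolerance = 1e-6)
  # linear near zero: equal small steps give nearly equal display steps
  small <- transform_channel(c(-20, 0, 20), "logicle")
  expect_equal(diff(small)[1], diff(small)[2], tolerance = 0.06)
})

test_that("isotype-anchored normalization satisfies its anchor invariants", {
  set.seed(8)
  iso <- 10^rnorm(5000, 2, 0.25)
  v <- 10^rnorm(5000, 2.4, 0.25)
  nl <- normalize_to_isotype(v, iso, method = "log")
  # isotype median -> 1 under the log convention
  self <- normalize_to_isotype(iso, iso, method = "log")
  expect_equal(median(self$values), 1, tolerance = 1e-6)
  # experiment 95th percentile -> 10 (both conventions)
  expect_equal(as.numeric(quantile(nl$values, 0.95)), 10, tolerance = 1e-6)
  nlin <- normalize_to_isotype(v, iso, method = "linear")
  expect_equal(as.numeric(quantile(nlin$values, 0.95)), 10, tolerance = 1e-6)
  # order preservation
  expect_identical(order(nl$values), order(v))
  # global rescaling of experiment and isotype together changes nothing
  n2 <- normalize_to_isotype(3.7 * v, 3.7 * iso, method = "log")
  expect_equal(n2$values, nl$values, tolerance = 1e-12)
  expect_error(normalize_to_isotype(v, numeric(0)), "empty")
  expect_error(normalize_to_isotype(v, rep(0, 10)), "degenerate")
})

test_that("alpha angles are ratiometric and flag bad cells", {
  a <- alpha_angle(c(1, 2, 5), c(1, 2, 5))
  expect_equal(as.numeric(a), rep(45, 3))
  # per-cell shared factors cancel exactly for linearly normalized values
  set.seed(9)
  x <- 10^rnorm(1000, 1, 0.3); y <- 10^rnorm(1000, 0.5, 0.3)
  f <- 10^rnorm(1000, 0, 0.2)
  expect_equal(as.numeric(alpha_angle(x * f, y * f)),
               as.numeric(alpha_angle(x, y)), tolerance = 1e-12)
  bad <- alpha_angle(c(1, -1, 2), c(1, 1, 0))
  expect_equal(attr(bad, "n_excluded"), 2L)
  expect_true(is.na(bad[2]) && is.na(bad[3]))
})

test_that("a synthetic Th1 population peaks near 90 degrees", {
  cfg <- generator_config()
  th1 <- generate_sample(th1_condition(), cfg, 10000, seed = 21)
  iso <- generate_sample(flow_condition(0, 0), cfg, 10000, seed = 22,
                         sample_kind = "isotype")
  wt <- normalize_to_isotype(th1$tbet, iso$tbet)
  wg <- normalize_to_isotype(th1$gata3, iso$gata3)
  mode <- density_mode(alpha_angle(wt, wg))
  expect_gt(mode, 80)
  # and the Th2 population peaks near 0
  th2 <- generate_sample(th2_condition(), cfg, 10000, seed = 23)
  wt2 <- normalize_to_isotype(th2$tbet, iso$tbet)
  wg2 <- normalize_to_isotype(th2$gata3, iso$gata3)
  expect_lt(density_mode(alpha_angle(wt2, wg2)), 10)
})

test_that("MFI matrices are robust medians over the grid", {
  cfg <- generator_config()
  ds <- generate_matrix_dataset(cfg, c(0, 20, 540), c(0, 20, 540),
                                n_cells = 4000, seed = 33)
  M <- mfi_matrix(ds, "tbet")
  # non-decreasing in IL-12 at fixed IL-4 (up to sampling noise)
  for (j in 1:3) expect_true(all(diff(M[, j]) > -0.03 * M[1, j]))
  # medians shrug off a 10% outlier contamination that wrecks the mean
  s <- ds$samples[[5]]
  v <- s$tbet
  v[1:200] <- v[1:200] * 1000
  v[201:400] <- v[201:400] / 1000
  expect_lt(abs(median(v) - median(s$tbet)) / median(s$tbet), 0.01)
  expect_gt(mean(v) / mean(s$tbet), 5)
  expect_error(mfi_matrix(ds, "cd19"), "unknown channel")
})

test_that("separable matrices decompose exactly and rank-2 ones do not", {
  f1 <- c(2, 5, 11, 30); f2 <- c(1, 1.7, 4)
  M <- outer(f1, f2) + 80
  d <- decompose_separable(M, background = 80)
  expect_lt(d$residual, 1e-8)
  expect_equal(d$f2, f2 / f2[1], tolerance = 1e-10)
  expect_equal(d$f1, f1 * f2[1], tolerance = 1e-10)

  dc <- decompose_separable(matrix(7, 3, 4))
  expect_equal(dc$residual, 0, tolerance = 1e-12)
  expect_equal(dc$f1, rep(7, 3), tolerance = 1e-10)

  # equal-weight sum of two separable terms resists a rank-1 fit
  M2 <- outer(c(1, 10, 100), c(1, 1, 1)) + outer(c(100, 10, 1), c(1, 2, 4))
  d2 <- decompose_separable(M2)
  expect_gt(d2$residual, 0.01)

  expect_error(decompose_separable(M, background = 200), "non-positive")
})

test_that("decomposing generator output recovers the configured factors", {
  cfg <- generator_config()
  g12 <- c(3, 15, 75, 540); g4 <- c(2, 20, 200)
  ds <- generate_matrix_dataset(cfg, g12, g4, n_cells = 5000, seed = 55)
  M <- mfi_matrix(ds, "gata3")
  d <- decompose_separable(M, background = cfg$response$gata3$background)
  expect_lt(d$residual, 1e-3)
  truth <- cfg$response$gata3$F2(g4)
  expect_gt(cor(log(d$f2), log(truth / truth[1])), 0.999)
})

test_that("the noise level is constant across input conditions", {
  cfg <- generator_config()
  ds <- generate_matrix_dataset(cfg, c(0, 30, 540), c(0, 30, 540),
                                n_cells = 4000, seed = 44)
  for (ch in c("tbet", "gata3")) {
    np <- noise_profile(ds, ch)
    expect_lt(attr(np, "max_min_ratio"), 1.2)
    # lognormal closed form: CV = sqrt(exp(sigma_ln^2) - 1)
    s_ln <- log(10) * sqrt(cfg$sigma_intrinsic^2 + cfg$sigma_extrinsic^2)
    expect_equal(mean(np$cv), sqrt(exp(s_ln^2) - 1), tolerance = 0.05)
  }
  # degenerate input: a constant channel has zero CV
  ds$samples[[1]]$tbet <- rep(5, nrow(ds$samples[[1]]))
  expect_equal(noise_profile(ds, "tbet")$cv[1], 0)
})

test_that("the alpha statistic strips the extrinsic factor the MFI keeps", {
  # under mixed conditions both TF channels are elevated similarly, so the
  # shared size factor cancels in the angle but not in the raw intensities
  cfg <- generator_config()
  n <- 8000
  mx <- generate_sample(mixed_condition(), cfg, n, seed = 66)
  iso <- generate_sample(flow_condition(0, 0), cfg, n, seed = 67,
                         sample_kind = "isotype")
  expect_gt(cor(log(mx$tbet), log(mx$gata3)), 0.15)
  wt <- normalize_to_isotype(mx$tbet, iso$tbet)
  wg <- normalize_to_isotype(mx$gata3, iso$gata3)
  al <- as.numeric(alpha_angle(wt, wg))
  size <- log(mx$tbet) + log(mx$gata3)  # extrinsic-dominated proxy
  expect_lt(abs(cor(al, size)), 0.1)
})

test_that("bias curves recover flat and biased probabilities", {
  set.seed(12)
  n <- 5000
  s <- data.frame(tbet = 10^rnorm(n, 2.4, 0.25),
                  ifng = ifelse(rbinom(n, 1, 0.3) == 1, 2000, 50))
  bc <- bin_bias_curve(s, "tbet", "ifng", bin_size = 500, threshold = 300)
  expect_equal(nrow(bc), 10L)
  expect_false(attr(bc, "short_bin_dropped"))
  # constant probability: every bin within 3 binomial SE of 0.3
  se <- sqrt(0.3 * 0.7 / 500)
  expect_true(all(abs(bc$positive_fraction - 0.3) < 3 * se))
  expect_equal(attr(bc, "population_fraction"), 0.3, tolerance = 3 * se)

  expect_error(bin_bias_curve(s[1:100, ], "tbet", "ifng", 500, 300),
               "exceeds sample size")
  # a trailing short bin is dropped and flagged
  bc2 <- bin_bias_curve(s[1:1250, ], "tbet", "ifng", 500, 300)
  expect_equal(nrow(bc2), 2L)
  expect_true(attr(bc2, "short_bin_dropped"))

  # generator output: the curve rises monotonically after isotonic smoothing
  th1 <- generate_sample(th1_condition(), n_cells = 20000, seed = 71)
  bc3 <- bin_bias_curve(th1, "tbet", "ifng", 500, threshold = 300)
  iso_fit <- stats::isoreg(bc3$bin_mean_tf, bc3$positive_fraction)
  expect_gt(cor(iso_fit$yf, bc3$positive_fraction), 0.95)
  expect_gt(bc3$positive_fraction[40] - bc3$positive_fraction[1], 0.3)
})

test_that("binary mutual information matches closed forms", {
  # identical fair coins share 1 bit
  a <- rep(c(0L, 1L), 50)
  expect_equal(mutual_information_binary(a, a), 1)
  # a uniform 2x2 table carries none
  b <- rep(c(0L, 1L, 0L, 1L), 25)
  cc <- rep(c(0L, 0L, 1L, 1L), 25)
  expect_equal(mutual_information_binary(b, cc), 0)
  # symmetry and non-negativity on random tables
  set.seed(14)
  for (i in 1:10) {
    u <- rbinom(200, 1, runif(1, 0.2, 0.8))
    v <- rbinom(200, 1, runif(1, 0.2, 0.8))
    expect_gte(mutual_information_binary(u, v), 0)
    expect_equal(mutual_information_binary(u, v),
                 mutual_information_binary(v, u))
  }
  # independent coins at n = 1e5: plug-in bias is far below 0.005 bits
  set.seed(15)
  u <- rbinom(1e5, 1, 0.55); v <- rbinom(1e5, 1, 0.2)
  expect_lt(mutual_information_binary(u, v), 0.005)
  expect_error(mutual_information_binary(1:3, 1:4), "length mismatch")
})

test_that("BIC selects the generating component count", {
  set.seed(16)
  x1 <- 10^rnorm(5000, 2, 0.2)
  hits <- sum(vapply(1:10, function(s)
    as.integer(bic_modality(x1, seed = s)) == 1L, logical(1)))
  expect_gte(hits, 9L)

  # two components six SDs apart
  x2 <- 10^c(rnorm(2500, 1.6, 0.1), rnorm(2500, 2.2, 0.1))
  expect_equal(as.integer(bic_modality(x2, seed = 1)), 2L)
  expect_error(bic_modality(x1[1:10]), "at least 50")
})

test_that("quadrant tables count and factorize correctly", {
  cfg <- generator_config()
  iso <- generate_sample(flow_condition(0, 0), cfg, 10000, seed = 81,
                         sample_kind = "isotype")
  # all cells below both thresholds
  s_off <- data.frame(ifng = rep(1, 100), il4 = rep(1, 100))
  qt <- quadrant_fractions(s_off, thresholds = c(ifng = 10, il4 = 10))
  expect_equal(unname(qt$counts), c(100L, 0L, 0L, 0L))

  th1 <- generate_sample(th1_condition(), cfg, 20000, seed = 82)
  q1 <- quadrant_fractions(th1, isotype = iso)
  expect_equal(sum(q1$counts), 20000L)
  # the IFN-gamma-only quadrant dominates the positives under Th1
  expect_identical(names(which.max(q1$counts[c("+/-", "-/+", "+/+")])),
                   "+/-")
  # independence: +/+ fraction is the product of the marginals
  pa <- mean(th1$ifng > q1$thresholds["ifng"])
  pb <- mean(th1$il4 > q1$thresholds["il4"])
  se <- 3 * sqrt(pa * pb * (1 - pa * pb) / 20000)
  expect_lt(abs(q1$fractions[["+/+"]] - pa * pb), se + 1e-12)
})

test_that("the ratio statistic is scale-free and anchored at 1", {
  set.seed(17)
  iso <- data.frame(tbet = 10^rnorm(5000, 2, 0.25),
                    gata3 = 10^rnorm(5000, 2, 0.25))
  s <- data.frame(tbet = 10^rnorm(5000, 2.5, 0.25),
                  gata3 = 10^rnorm(5000, 2.5, 0.25))
  s$gata3 <- s$tbet  # identical channels
  iso$gata3 <- iso$tbet
  expect_equal(ratio_statistic(s, iso), 1, tolerance = 1e-10)

  # shared per-cell multiplicative noise leaves the statistic unchanged
  cfg <- generator_config()
  mx <- generate_sample(mixed_condition(), cfg, 10000, seed = 91)
  iso2 <- generate_sample(flow_condition(0, 0), cfg, 10000, seed = 92,
                          sample_kind = "isotype")
  r0 <- ratio_statistic(mx, iso2)
  f <- 10^rnorm(10000, 0, 0.15)
  mx2 <- mx; mx2$tbet <- mx$tbet * f; mx2$gata3 <- mx$gata3 * f
  expect_equal(ratio_statistic(mx2, iso2), r0, tolerance = 0.02)
})
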