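# Single-cell statistics: display transforms, isotype-anchored
# normalization, alpha angles, MFI matrices, rank-1 separability, noise
# profiles, binned bias curves, binary mutual information, BIC modality,
# quadrant tables and the GATA3/T-bet ratio statistic.

#' Display transform for fluorescence intensities
#'
#' Monotone transforms that are linear near zero and logarithmic at high
#' intensity.  `"asinh"` is `asinh(x / cofactor)`; `"logicle"` is the
#' biexponential display scale common in flow cytometry, computed by
#' numerical inversion (result in display decades).
#'
#' @param values numeric intensities (finite; may be negative for logicle).
#' @param method `"asinh"` (default) or `"logicle"`.
#' @param cofactor positive asinh cofactor (ignored for logicle).
#' @param T,M,W logicle parameters: top of scale, number of decades and
#'   linearization width in decades.
#' @return Transformed values, same length as `values`.
#' @export
transform_channel <- function(values, method = c("asinh", "logicle"),
                              cofactor = 5, T = 262144, M = 4.5, W = 0.5) {
  method <- match.arg(method)
  if (any(!is.finite(values))) stop("'values' must be finite", call. = FALSE)
  if (method == "asinh") {
    if (!is.numeric(cofactor) || cofactor <= 0)
      stop("'cofactor' must be positive", call. = FALSE)
    return(asinh(values / cofactor))
  }
  logicle_transform(values, T = T, M = M, W = W)
}

# Logicle scale: inverse of the biexponential
#   B(y) = a*10^(b*y) - c*10^(-d*y) + f,  y in [0, 1] (fraction of M decades)
# parameterized so that B is linear around y = W/M with slope continuity.
logicle_transform <- function(values, T = 262144, M = 4.5, W = 0.5) {
  stopifnot(T > 0, M > 0, W >= 0, W < M / 2)
  b <- M * log(10)
  w <- W / M
  # solve for d: w = 2 ln(b/d) / (b + d)  (Parks-Moore parameter relation)
  d <- if (w == 0) b else
    stats::uniroot(function(d) 2 * log(b / d) / (b + d) - w,
                   c(1e-8, b - 1e-8), tol = 1e-12)$root
  x2 <- w; x1 <- x2 + w
  ca <- exp(b * x1); cb <- exp(-d * x1)
  # scale so B(1) = T and B(x1) = 0 with slope matching at x1
  fa <- T / (exp(b) - ca - (exp(-d) - cb) * ca * b / (cb * d))
  fc <- fa * ca * b / (cb * d)
  f0 <- -(fa * ca - fc * cb)
  biexp <- function(y) fa * exp(b * y) - fc * exp(-d * y) + f0
  vapply(values, function(v) {
    lo <- -0.5; hi <- 1.5
    stats::uniroot(function(y) biexp(y) - v, c(lo, hi), tol = 1e-10,
                   extendInt = "upX")$root * M
  }, numeric(1))
}

#' Isotype-anchored channel normalization
#'
#' Rescales a channel against its isotype control so that the isotype
#' median maps to 1 and the 95th percentile of the experiment sample maps
#' to 10.  Two conventions are provided:
#'
#' * `"log"` (default): the shift and rescale are applied in log space --
#'   `w = 10^(z / z95)` with `z = log10(v / median(isotype))` and `z95` the
#'   95th percentile of `z`.  Both anchor invariants hold exactly
#'   (isotype median -> 1, experiment 95th percentile -> 10).
#' * `"linear"`: `w = 10 * (v / median(isotype)) / q95(v / median(isotype))`.
#'   The 95th percentile maps to 10 but the isotype median is carried to
#'   `10 * median/q95` rather than 1; ratios of two linearly normalized
#'   channels are exactly invariant to per-cell shared factors.
#'
#' @param values experiment-channel intensities (> 0 for `"log"`).
#' @param isotype_values isotype-control intensities for the same channel.
#' @param method `"log"` or `"linear"`.
#' @return An object of class `norm_channel`: list with `values`, `anchor`
#'   (isotype median), `scale` (95th-percentile scale) and `method`.
#' @export
normalize_to_isotype <- function(values, isotype_values,
                                 method = c("log", "linear")) {
  method <- match.arg(method)
  if (!length(isotype_values)) stop("empty isotype sample", call. = FALSE)
  anchor <- stats::median(isotype_values)
  if (anchor <= 0 || !is.finite(anchor))
    stop("degenerate isotype sample (non-positive median)", call. = FALSE)
  if (method == "log") {
    if (any(values <= 0)) stop("log normalization needs positive values",
                               call. = FALSE)
    z <- log10(values / anchor)
    z95 <- as.numeric(stats::quantile(z, 0.95))
    if (z95 <= 0)
      stop("experiment 95th percentile does not exceed the isotype median",
           call. = FALSE)
    out <- 10^(z / z95)
    scale <- z95
  } else {
    u <- values / anchor
    q95 <- as.numeric(stats::quantile(u, 0.95))
    if (q95 <= 0) stop("non-positive 95th percentile", call. = FALSE)
    out <- 10 * u / q95
    scale <- q95
  }
  structure(list(values = out, anchor = anchor, scale = scale,
                 method = method), class = "norm_channel")
}

norm_values <- function(x) if (inherits(x, "norm_channel")) x$values else x

#' Per-cell expression angle
#'
#' The ratiometric angle `alpha = atan(x / y)` in degrees, computed per cell
#' from two normalized channels.  With `x` = normalized T-bet and `y` =
#' normalized GATA3, a Th1 population peaks near 90 degrees and a Th2
#' population near 0.  Cells with a non-positive normalized value are
#' excluded (returned as `NA`) and counted in attribute `n_excluded`.
#'
#' @param x_norm,y_norm numeric vectors or `norm_channel` objects.
#' @return Numeric vector of angles in (0, 90), with attribute `n_excluded`.
#' @export
alpha_angle <- function(x_norm, y_norm) {
  x <- norm_values(x_norm); y <- norm_values(y_norm)
  stopifnot(length(x) == length(y))
  bad <- !is.finite(x) | !is.finite(y) | x <= 0 | y <= 0
  out <- rep(NA_real_, length(x))
  out[!bad] <- atan(x[!bad] / y[!bad]) * 180 / pi
  structure(out, n_excluded = sum(bad))
}

#' Histogram mode of a bounded statistic
#'
#' Robust mode estimate: fine histogram plus a short moving-average smooth,
#' returning the midpoint of the modal bin.  Used for the mode of alpha
#' distributions.
#'
#' @param values numeric vector.
#' @param lower,upper histogram support.
#' @param bin bin width.
#' @param smooth odd moving-average window length (bins).
#' @return The modal bin midpoint.
#' @export
density_mode <- function(values, lower = 0, upper = 90, bin = 1, smooth = 5) {
  values <- values[is.finite(values)]
  br <- seq(lower, upper, by = bin)
  h <- graphics::hist(pmin(pmax(values, lower), upper), breaks = br,
                      plot = FALSE)
  cnt <- as.numeric(stats::filter(h$counts, rep(1 / smooth, smooth),
                                  sides = 2))
  cnt[is.na(cnt)] <- -Inf
  h$mids[which.max(cnt)]
}

#' Median-fluorescence matrix over the input grid
#'
#' @param dataset a `flow_dataset`.
#' @param channel channel name.
#' @return Matrix of per-condition medians (rows index `il12_grid`, columns
#'   `il4_grid`); empty samples yield `NA` with a warning.
#' @export
mfi_matrix <- function(dataset, channel) {
  stopifnot(inherits(dataset, "flow_dataset"))
  n1 <- length(dataset$il12_grid); n2 <- length(dataset$il4_grid)
  M <- matrix(NA_real_, n1, n2,
              dimnames = list(format(dataset$il12_grid, digits = 4),
                              format(dataset$il4_grid, digits = 4)))
  k <- 0L
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      k <- k + 1L
      s <- dataset$samples[[k]]
      if (!nrow(s)) {
        warning("empty sample at grid point (", i, ", ", j, ")",
                call. = FALSE)
        next
      }
      if (!channel %in% names(s)) stop("unknown channel: ", channel,
                                       call. = FALSE)
      M[i, j] <- stats::median(s[[channel]])
    }
  }
  M
}

#' Rank-1 (separable) decomposition of an MFI matrix
#'
#' Subtracts the channel background and extracts the leading singular pair
#' of the result: the best separable approximation
#' `MFI - background ~ F1(IL-12) * F2(IL-4)`.  A matrix is exactly
#' separable iff its background-subtracted form is rank 1, so the relative
#' residual `1 - s1^2 / sum(s^2)` vanishes (to numerical precision) for
#' generator-style input.  `F2` is normalized to 1 at `ref_col`, with the
#' scale absorbed into `F1`.
#'
#' @param mfi numeric matrix of medians (rows = IL-12 levels).
#' @param background scalar channel background to subtract.
#' @param ref_col reference column for the `F2 = 1` normalization.
#' @param floor values at or below `floor` after subtraction raise an error
#'   naming the entry.
#' @return List with `f1`, `f2` (positive factors) and `residual`.
#' @export
decompose_separable <- function(mfi, background = 0, ref_col = 1,
                                floor = 0) {
  stopifnot(is.matrix(mfi), is.numeric(background))
  S <- mfi - background
  bad <- which(S <= floor, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "non-positive entry after background subtraction at (%d, %d)",
      bad[1, 1], bad[1, 2]), call. = FALSE)
  sv <- svd(S)
  res <- 1 - sv$d[1]^2 / sum(sv$d^2)
  u <- sv$u[, 1]; v <- sv$v[, 1]
  if (u[1] < 0) { u <- -u; v <- -v }  # Perron pair of a positive matrix
  f2 <- v / v[ref_col]
  f1 <- sv$d[1] * u * v[ref_col]
  list(f1 = as.numeric(f1), f2 = as.numeric(f2), residual = max(res, 0),
       singular_values = sv$d)
}

#' Noise profile across conditions
#'
#' Per-condition coefficient of variation (SD/mean) of a channel, with the
#' max/min ratio across the grid as summary.
#'
#' @param dataset a `flow_dataset`.
#' @param channel channel name.
#' @return data.frame with `il12`, `il4`, `cv`; attribute `max_min_ratio`.
#' @export
noise_profile <- function(dataset, channel) {
  stopifnot(inherits(dataset, "flow_dataset"))
  rows <- lapply(dataset$samples, function(s) {
    cond <- attr(s, "condition")
    m <- mean(s[[channel]])
    cv <- if (!nrow(s)) NA_real_ else if (m == 0) NA_real_ else
      stats::sd(s[[channel]]) / m
    data.frame(il12 = cond$il12, il4 = cond$il4, cv = cv)
  })
  out <- do.call(rbind, rows)
  ok <- is.finite(out$cv) & out$cv > 0
  attr(out, "max_min_ratio") <- if (any(ok))
    max(out$cv[ok]) / min(out$cv[ok]) else NA_real_
  out
}

#' Binned cytokine-bias curve
#'
#' Sorts cells by a TF channel, partitions them into consecutive bins of
#' `bin_size` cells and reports the cytokine-positive fraction per bin
#' against the mean TF level of the bin.  A trailing short bin is dropped
#' and flagged.  Also records the population positive fraction (the "green
#' line") and the population TF median (the "red line").
#'
#' @param sample a `flow_sample` (or data.frame with the two channels).
#' @param tf_channel,cytokine_channel channel names.
#' @param bin_size cells per bin (default 500).
#' @param threshold positivity threshold for the cytokine channel intensity.
#' @return data.frame of class `bias_curve` with `bin_mean_tf`,
#'   `positive_fraction`, `n`; attributes `population_fraction`,
#'   `tf_median`, `bin_size`, `short_bin_dropped`.
#' @export
bin_bias_curve <- function(sample, tf_channel, cytokine_channel,
                           bin_size = 500, threshold) {
  stopifnot(bin_size >= 1)
  n <- nrow(sample)
  if (bin_size > n)
    stop("bin_size (", bin_size, ") exceeds sample size (", n, ")",
         call. = FALSE)
  tf <- sample[[tf_channel]]; cy <- sample[[cytokine_channel]]
  ord <- order(tf)
  tf <- tf[ord]; pos <- cy[ord] > threshold
  nb <- n %/% bin_size
  idx <- rep(seq_len(nb), each = bin_size)
  used <- seq_len(nb * bin_size)
  out <- data.frame(
    bin_mean_tf = as.numeric(tapply(tf[used], idx, mean)),
    positive_fraction = as.numeric(tapply(pos[used], idx, mean)),
    n = as.integer(table(idx)))
  structure(out, class = c("bias_curve", "data.frame"),
            population_fraction = mean(pos),
            tf_median = stats::median(tf),
            bin_size = bin_size,
            short_bin_dropped = (n %% bin_size) > 0)
}

#' Plug-in mutual information of two binary vectors
#'
#' MI in bits from the empirical 2x2 contingency table, with the
#' convention `0 * log 0 = 0`.  Non-negative and symmetric.
#'
#' @param a,b equal-length binary (0/1 or logical) vectors.
#' @return MI in bits.
#' @export
mutual_information_binary <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (!length(a)) stop("empty input", call. = FALSE)
  a <- as.integer(as.logical(a)); b <- as.integer(as.logical(b))
  n <- length(a)
  mi <- 0
  for (va in 0:1) {
    for (vb in 0:1) {
      pij <- sum(a == va & b == vb) / n
      if (pij > 0) {
        pa <- sum(a == va) / n; pb <- sum(b == vb) / n
        mi <- mi + pij * log2(pij / (pa * pb))
      }
    }
  }
  max(mi, 0)
}

# --- 1D Gaussian mixture by EM (for the BIC modality test) ------------------

gmm_em <- function(x, k, init_means, maxit = 300, tol = 1e-8) {
  n <- length(x)
  mu <- init_means
  sd2 <- rep(stats::var(x) / k, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sqrt(pmax(sd2[j], 1e-12))), numeric(n))
    dens <- matrix(dens, n, k)
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_))
    r <- dens / rowsum_
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)  # collapsed component
    w <- nk / n
    mu <- colSums(r * x) / nk
    sd2 <- colSums(r * (x - rep(mu, each = n))^2) / nk
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(loglik = ll, mu = mu, sd2 = sd2, w = w,
       bic = -2 * ll + (3 * k - 1) * log(n))
}

#' Modality by Gaussian-mixture BIC
#'
#' Fits Gaussian mixtures with 1..`max_components` components to
#' asinh-transformed values by seeded multi-restart EM and returns the
#' component count with the lowest BIC (ties favour fewer components).
#' Unimodal (TF-like) channels yield 1, well-separated bimodal
#' (cytokine-like) channels yield 2.
#'
#' @param values raw intensities (>= 50 values).
#' @param max_components maximum number of components to consider.
#' @param n_restarts EM restarts per component count.
#' @param seed integer seed for the restarts.
#' @param cofactor asinh cofactor applied before fitting.
#' @return Integer component count; attribute `bic` holds the BIC per
#'   component count.
#' @export
bic_modality <- function(values, max_components = 2, n_restarts = 5,
                         seed = 1L, cofactor = 5) {
  if (length(values) < 50) stop("need at least 50 values", call. = FALSE)
  x <- transform_channel(values, "asinh", cofactor = cofactor)
  bics <- rep(NA_real_, max_components)
  with_seed(seed, {
    for (k in seq_len(max_components)) {
      best <- Inf
      for (r in seq_len(n_restarts)) {
        init <- if (r == 1 && k > 1)
          stats::quantile(x, probs = seq(0.1, 0.9, length.out = k))
        else sample(x, k)
        fit <- gmm_em(x, k, as.numeric(init))
        if (!is.null(fit) && fit$bic < best) best <- fit$bic
      }
      bics[k] <- best
    }
  })
  if (all(!is.finite(bics))) stop("EM did not converge", call. = FALSE)
  structure(which.min(round(bics, 6)), bic = bics)
}

#' Quadrant analysis of two cytokine channels
#'
#' Classifies cells into the four quadrants -/-, +/-, -/+, +/+ by
#' thresholding two cytokine channels (first channel's state first).
#' Thresholds default to the 99th percentile of the matching isotype
#' channels.
#'
#' @param sample a `flow_sample`.
#' @param channels two cytokine channel names (default `ifng`, `il4`).
#' @param thresholds named numeric thresholds per channel; if missing,
#'   computed from `isotype`.
#' @param isotype an isotype `flow_sample` (needed when `thresholds` is
#'   missing).
#' @param probs isotype quantile used for the default thresholds.
#' @return An object of class `quadrant_table`: list with `counts`,
#'   `fractions` (named by quadrant) and `thresholds`.
#' @export
quadrant_fractions <- function(sample, channels = c("ifng", "il4"),
                               thresholds = NULL, isotype = NULL,
                               probs = 0.99) {
  stopifnot(length(channels) == 2)
  if (is.null(thresholds)) {
    if (is.null(isotype))
      stop("supply 'thresholds' or an 'isotype' sample", call. = FALSE)
    thresholds <- vapply(channels, function(ch)
      as.numeric(stats::quantile(isotype[[ch]], probs)), numeric(1))
  }
  a <- sample[[channels[1]]] > thresholds[[1]]
  b <- sample[[channels[2]]] > thresholds[[2]]
  counts <- c("-/-" = sum(!a & !b), "+/-" = sum(a & !b),
              "-/+" = sum(!a & b), "+/+" = sum(a & b))
  structure(list(counts = counts, fractions = counts / max(nrow(sample), 1L),
                 thresholds = stats::setNames(as.numeric(thresholds),
                                              channels)),
            class = "quadrant_table")
}

#' @export
print.quadrant_table <- function(x, ...) {
  cat("Quadrant table (n =", sum(x$counts), ")\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Normalized GATA3/T-bet ratio statistic
#'
#' Normalizes the two TF channels against their isotype controls
#' ([normalize_to_isotype()], log convention by default) and returns the
#' population median of the per-cell normalized GATA3/T-bet ratio.
#' Values near 1 indicate the mixed state; Th1-polarized populations sit
#' well below 1 and Th2-polarized ones well above.
#'
#' @param sample a `flow_sample` with `tbet` and `gata3` columns.
#' @param isotype matching isotype `flow_sample`.
#' @param method normalization convention, see [normalize_to_isotype()].
#' @return Scalar ratio (>= 0).
#' @export
ratio_statistic <- function(sample, isotype, method = "log") {
  wg <- normalize_to_isotype(sample$gata3, isotype$gata3, method = method)
  wt <- normalize_to_isotype(sample$tbet, isotype$tbet, method = method)
  stats::median(wg$values / wt$values)
}
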