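# Two-stage stochastic model of cytokine expression: continuous TF levels
# bias two independent Bernoulli ("biased coin") processes, one per
# cytokine.  The bias is a logistic in log10 TF level with a floor and a
# ceiling standing in for TF-independent influences.

#' Construct a cytokine-expression bias function
#'
#' A monotone map from a (positive) TF fluorescence level to the probability
#' that the corresponding cytokine is expressed upon restimulation:
#' `p(v) = p_min + (p_max - p_min) * plogis(slope * (log10(v) - midpoint))`.
#'
#' @param p_min,p_max probability floor and ceiling, `0 <= p_min <= p_max <= 1`.
#'   The floor and ceiling absorb cytokine-gating factors other than the TF.
#' @param midpoint TF level (log10 fluorescence units) at the half-rise.
#' @param slope steepness per decade of TF level (> 0).
#' @return An object of class `bias_function`.
#' @seealso [bias_probability()], [default_biases()]
#' @export
bias_function <- function(p_min, p_max, midpoint, slope) {
  stopifnot(is.numeric(p_min), is.numeric(p_max), is.numeric(midpoint),
            is.numeric(slope), length(p_min) == 1, length(p_max) == 1)
  if (p_min < 0 || p_max > 1 || p_min > p_max)
    stop("need 0 <= p_min <= p_max <= 1", call. = FALSE)
  if (slope <= 0) stop("'slope' must be positive", call. = FALSE)
  structure(list(p_min = p_min, p_max = p_max,
                 midpoint = midpoint, slope = slope),
            class = "bias_function")
}

#' @export
print.bias_function <- function(x, ...) {
  cat(sprintf(
    "Bias function: p in [%.3g, %.3g], midpoint %.4g (log10 units), slope %.4g\n",
    x$p_min, x$p_max, x$midpoint, x$slope))
  invisible(x)
}

#' Evaluate a bias function
#'
#' @param tf_level positive TF fluorescence level(s).
#' @param bias a [bias_function()] object.
#' @return Probabilities in `[p_min, p_max]`, monotone in `tf_level`.
#' @export
bias_probability <- function(tf_level, bias) {
  stopifnot(inherits(bias, "bias_function"))
  if (any(!is.finite(tf_level)) || any(tf_level <= 0))
    stop("'tf_level' must be positive and finite", call. = FALSE)
  bias$p_min + (bias$p_max - bias$p_min) *
    stats::plogis(bias$slope * (log10(tf_level) - bias$midpoint))
}

#' Default bias calibrations
#'
#' The shipped calibrations tie each cytokine to its driving TF
#' (IFN-gamma to T-bet; IL-4, IL-13 and IL-5 to GATA3) and were fitted so
#' that, under the default generator, the Th1 population expresses IFN-gamma
#' at ~60% overall and ~85% in the top 500-cell T-bet bin, and the Th2
#' population expresses IL-4 at ~20% overall and ~40% at the highest GATA3
#' levels (IL-5: ~10% under Th2, ~1% under Th1).
#'
#' @return Named list of [bias_function()] objects with a `tf_channel`
#'   attribute mapping each cytokine to its TF channel.
#' @export
default_biases <- function() {
  biases <- list(
    ifng = bias_function(0.02, 0.90, midpoint = 2.151911, slope = 3.553376),
    il4  = bias_function(0.01, 0.45, midpoint = 3.225075, slope = 3.467052),
    il13 = bias_function(0.01, 0.40, midpoint = 3.150000, slope = 4.000000),
    il5  = bias_function(0.01, 0.22, midpoint = 3.195051, slope = 4.164611))
  attr(biases, "tf_channel") <- c(ifng = "tbet", il4 = "gata3",
                                  il13 = "gata3", il5 = "gata3")
  biases
}

# subset a bias list while preserving the tf_channel mapping
subset_biases <- function(biases, channels) {
  out <- biases[channels]
  attr(out, "tf_channel") <- attr(biases, "tf_channel")[channels]
  out
}

#' Draw binary cytokine states from per-cell TF levels
#'
#' Each cytokine is drawn independently per cell as a Bernoulli variable
#' with probability given by its bias function evaluated at the cell's
#' driving-TF level: two (or more) independent biased coins per cell.
#'
#' @param tf_levels data.frame of per-cell TF intensities containing the
#'   channels named by the biases' `tf_channel` attribute (at least `tbet`
#'   and `gata3`).
#' @param biases named list of [bias_function()] objects (default
#'   [default_biases()]); names are cytokine channels.
#' @param seed integer seed.  If omitted a fresh seed is drawn and reported
#'   via a message.
#' @return data.frame of 0/1 columns named `<cytokine>_on`, with the seed
#'   used stored in attribute `seed`.
#' @export
draw_cytokine_states <- function(tf_levels, biases = default_biases(),
                                 seed = NULL) {
  tfmap <- attr(biases, "tf_channel")
  if (is.null(tfmap))
    stop("'biases' must carry a 'tf_channel' attribute", call. = FALSE)
  missing_ch <- setdiff(unique(tfmap[names(biases)]), names(tf_levels))
  if (length(missing_ch))
    stop("missing TF channel(s) in 'tf_levels': ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    message("draw_cytokine_states: no seed supplied; using seed ", seed)
  }
  n <- nrow(tf_levels)
  out <- with_seed(seed, {
    states <- lapply(names(biases), function(cy) {
      p <- bias_probability(tf_levels[[tfmap[[cy]]]], biases[[cy]])
      stats::rbinom(n, 1L, p)
    })
    names(states) <- paste0(names(biases), "_on")
    as.data.frame(states)
  })
  attr(out, "seed") <- seed
  out
}

#' Simulate the sort-and-reculture experiment
#'
#' Cells from one cytokine-expression quadrant of a population are sorted
#' out, their TF levels carried over (optionally relaxed towards the
#' condition median according to the generator's persistence parameter) and
#' their cytokine coins re-thrown for a new restimulation.  Because the
#' coins are memoryless given the TF state, every quadrant repopulates all
#' four quadrants whenever the bias probabilities are interior to (0, 1).
#'
#' @param population a [generate_sample()] result (must contain `ifng_on`
#'   and `il4_on` state columns).
#' @param sort_quadrant one of `"-/-"`, `"+/-"`, `"-/+"`, `"+/+"`
#'   (IFN-gamma state / IL-4 state).
#' @param condition a [flow_condition()]; the re-culture condition (defaults
#'   to the population's own condition).
#' @param config a [generator_config()]; supplies biases, intensity model
#'   and the TF `persistence` correlation.
#' @param seed integer seed.
#' @return List with `population` (the re-stimulated sorted cells, a
#'   `flow_sample`), `fractions` (named quadrant fractions) and
#'   `n_sorted`.
#' @export
reculture_simulation <- function(population, sort_quadrant,
                                 condition = attr(population, "condition"),
                                 config = generator_config(), seed = 1L) {
  stopifnot(sort_quadrant %in% c("-/-", "+/-", "-/+", "+/+"))
  if (!all(c("ifng_on", "il4_on") %in% names(population)))
    stop("'population' must carry ifng_on and il4_on state columns",
         call. = FALSE)
  want <- switch(sort_quadrant,
                 "-/-" = population$ifng_on == 0 & population$il4_on == 0,
                 "+/-" = population$ifng_on == 1 & population$il4_on == 0,
                 "-/+" = population$ifng_on == 0 & population$il4_on == 1,
                 "+/+" = population$ifng_on == 1 & population$il4_on == 1)
  if (!any(want)) stop("empty sort gate: ", sort_quadrant, call. = FALSE)
  sorted <- population[want, , drop = FALSE]
  n <- nrow(sorted)
  cyto <- intersect(names(config$biases), config$cytokine_channels)
  res <- with_seed(seed, {
    rho <- config$persistence
    tf <- sorted[c("tbet", "gata3")]
    if (rho < 1) {
      # partial persistence: shrink log-deviation from the condition median
      for (ch in c("tbet", "gata3")) {
        med <- channel_median(ch, condition, config)
        z <- log10(tf[[ch]] / med)
        sd_tot <- sqrt(config$sigma_intrinsic^2 + config$sigma_extrinsic^2)
        tf[[ch]] <- med * 10^(rho * z +
                                stats::rnorm(n, 0, sqrt(1 - rho^2) * sd_tot))
      }
    }
    states <- draw_cytokine_states(tf, subset_biases(config$biases, cyto),
                                   seed = derive_seed(seed, 1L))
    ext <- 10^stats::rnorm(n, 0, config$sigma_extrinsic)
    out <- sorted
    out$tbet <- tf$tbet; out$gata3 <- tf$gata3
    for (cy in cyto) {
      on <- states[[paste0(cy, "_on")]] == 1L
      v <- numeric(n)
      v[on] <- config$on_median[[cy]] * ext[on] *
        10^stats::rnorm(sum(on), 0, config$sigma_on)
      v[!on] <- config$background[[cy]] * ext[!on] *
        10^stats::rnorm(sum(!on), 0, config$sigma_intrinsic)
      out[[cy]] <- v
      out[[paste0(cy, "_on")]] <- as.integer(on)
    }
    out
  })
  fr <- c("-/-" = mean(res$ifng_on == 0 & res$il4_on == 0),
          "+/-" = mean(res$ifng_on == 1 & res$il4_on == 0),
          "-/+" = mean(res$ifng_on == 0 & res$il4_on == 1),
          "+/+" = mean(res$ifng_on == 1 & res$il4_on == 1))
  list(population = res, fractions = fr, n_sorted = n)
}
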