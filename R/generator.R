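# Synthetic flow-cytometry data generator.
#
# Statistical model per experiment sample (all intensities in arbitrary
# fluorescence units, strictly positive):
#   TF channel:      v = (floor + F1(IL-12) * F2(IL-4)) * E * eps
#   cytokine (off):  v = background * E * eps
#   cytokine (on):   v = on_median * E * eps_on        (condition-independent)
# where E is a per-cell extrinsic size factor shared by all channels
# (lognormal, log10-sd sigma_extrinsic) and eps a per-channel intrinsic
# factor (lognormal, log10-sd sigma_intrinsic; sigma_on for "on" cytokine
# levels).  Cytokine on/off states come from the two-stage model
# (draw_cytokine_states), so their positive fractions are TF-biased while
# the "on" level is constant across conditions.  Isotype-control samples sit
# at per-channel isotype medians, slightly above the specific-antibody
# floors (non-specific isotype binding); a T-bet knockout sample has its
# T-bet channel at the isotype level and all other channels as in the
# matched condition.

#' Culture condition
#'
#' @param il12,il4 cytokine concentrations in ng/ml (0-540 in the emulated
#'   experiments; values outside are accepted but extrapolate the response).
#' @param label free-text label; defaults to `"Th1"`, `"Th2"`, `"mixed"` or
#'   `"il12=<a> il4=<b>"` based on the concentrations.
#' @return An object of class `flow_condition`.
#' @export
flow_condition <- function(il12, il4, label = NULL) {
  stopifnot(is.numeric(il12), is.numeric(il4), il12 >= 0, il4 >= 0)
  if (is.null(label)) {
    label <- if (il12 > 0 && il4 == 0) "Th1"
    else if (il12 == 0 && il4 > 0) "Th2"
    else if (il12 > 0 && il4 > 0) "mixed"
    else "unstimulated"
  }
  structure(list(il12 = il12, il4 = il4, label = label),
            class = "flow_condition")
}

#' Standard polarizing and mixed conditions
#'
#' `th1_condition()` is saturating IL-12 with no IL-4; `th2_condition()` the
#' reverse; `mixed_condition()` is the 100 ng/ml IL-12 + 4 ng/ml IL-4
#' condition used for sorting experiments.
#'
#' @return A [flow_condition()].
#' @export
th1_condition <- function() flow_condition(540, 0, "Th1")

#' @rdname th1_condition
#' @export
th2_condition <- function() flow_condition(0, 540, "Th2")

#' @rdname th1_condition
#' @export
mixed_condition <- function() flow_condition(100, 4, "mixed")

#' Separable input-response functions of the TF channels
#'
#' Median TF expression over the input matrix factorizes as
#' `F1(IL-12) * F2(IL-4)` (separation of variables; rank 1 in log space
#' after background subtraction).  The default parametric forms are
#' saturating first-order (Hill) curves in concentration:
#' T-bet rises with IL-12 and is weakly repressed by IL-4; GATA3 rises with
#' IL-4 and is weakly enhanced by IL-12.
#'
#' @param tbet,gata3 lists with functions `F1(il12)` and `F2(il4)` and a
#'   `background` floor (autofluorescence plus non-specific staining, au).
#' @return An object of class `separable_response`.
#' @export
separable_response <- function(
    tbet = list(
      F1 = function(c) 140.9 * c / (c + 30),
      F2 = function(c) 1 - 0.25 * c / (c + 20),
      background = 100),
    gata3 = list(
      F1 = function(c) 1 + 0.3 * c / (c + 50),
      F2 = function(c) 1506.8 * c / (c + 137.5),
      background = 100)) {
  for (ch in list(tbet, gata3))
    stopifnot(is.function(ch$F1), is.function(ch$F2),
              is.numeric(ch$background), ch$background > 0)
  structure(list(tbet = tbet, gata3 = gata3), class = "separable_response")
}

#' Median channel intensity under a condition
#'
#' Evaluates `F1(il12) * F2(il4) + background` for a TF channel.
#'
#' @param condition a [flow_condition()].
#' @param response a [separable_response()].
#' @param channel `"tbet"` or `"gata3"`.
#' @return Median intensity (au).
#' @export
separable_median <- function(condition, response = separable_response(),
                             channel) {
  stopifnot(inherits(condition, "flow_condition"),
            inherits(response, "separable_response"))
  if (!channel %in% names(response))
    stop("unknown channel: ", channel, call. = FALSE)
  ch <- response[[channel]]
  ch$F1(condition$il12) * ch$F2(condition$il4) + ch$background
}

#' Generator configuration
#'
#' Bundles every tunable of the synthetic-data generator.  The defaults are
#' calibrated so that the analysis module reproduces the reference summary
#' statistics (Th1 IFN-gamma+ fraction ~60% with ~85% in the top T-bet bin;
#' Th2 IL-4+ fraction ~20% with ~40% at high GATA3; normalized GATA3/T-bet
#' ratio ~0.4 / ~1 / ~20 for Th1 / mixed / Th2; Th1 alpha mode near 90
#' degrees).
#'
#' @param response a [separable_response()].
#' @param biases bias calibrations, see [default_biases()].
#' @param sigma_intrinsic per-channel intrinsic lognormal noise
#'   (log10-sd).
#' @param sigma_extrinsic shared per-cell extrinsic factor (log10-sd).
#' @param sigma_on lognormal spread of the cytokine "on" level (log10-sd).
#' @param isotype named isotype-control medians per channel (au); the TF
#'   isotype levels sit above the specific-antibody floors because isotype
#'   antibodies bind non-specifically.
#' @param background named cytokine-channel off/background medians (au).
#' @param on_median named cytokine "on" medians (au), condition-independent.
#' @param cytokine_channels cytokine channels to generate; `"ifng"` and
#'   `"il4"` are always present, `"il13"`/`"il5"` optional.
#' @param persistence TF log-level retention across a week of re-culture
#'   (1 = levels carried over unchanged).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(response = separable_response(),
                             biases = default_biases(),
                             sigma_intrinsic = 0.2193,
                             sigma_extrinsic = 0.12,
                             sigma_on = 0.3,
                             isotype = c(tbet = 141.2538, gata3 = 104.7129,
                                         ifng = 80, il4 = 80, il13 = 80,
                                         il5 = 80),
                             background = c(ifng = 80, il4 = 80,
                                            il13 = 80, il5 = 80),
                             on_median = c(ifng = 2000, il4 = 1500,
                                           il13 = 1200, il5 = 900),
                             cytokine_channels = c("ifng", "il4"),
                             persistence = 1) {
  stopifnot(sigma_intrinsic >= 0, sigma_extrinsic >= 0, sigma_on >= 0,
            persistence >= 0, persistence <= 1,
            all(c("ifng", "il4") %in% cytokine_channels))
  if (!all(background[cytokine_channels] < on_median[cytokine_channels]))
    stop("cytokine background must lie below the on-level median",
         call. = FALSE)
  structure(list(response = response, biases = biases,
                 sigma_intrinsic = sigma_intrinsic,
                 sigma_extrinsic = sigma_extrinsic, sigma_on = sigma_on,
                 isotype = isotype, background = background,
                 on_median = on_median,
                 cytokine_channels = cytokine_channels,
                 persistence = persistence),
            class = "generator_config")
}

# median of a TF channel under a condition (experiment samples)
channel_median <- function(channel, condition, config) {
  separable_median(condition, config$response, channel)
}

#' Generate one synthetic flow-cytometry sample
#'
#' @param condition a [flow_condition()].
#' @param config a [generator_config()].
#' @param n_cells number of cells (>= 0; 0 yields an empty sample with
#'   intact metadata).
#' @param seed integer seed (required for reproducibility).
#' @param sample_kind `"experiment"`, `"isotype"` or `"knockout"` (T-bet
#'   knockout: the T-bet channel is indistinguishable from its isotype
#'   control, every other channel follows the condition).
#' @return A data.frame of class `flow_sample` with columns `cell_id`, the
#'   intensity channels, and 0/1 `<cytokine>_on` state columns for
#'   experiment/knockout samples; attributes `condition`, `sample_kind`,
#'   `seed`.
#' @export
generate_sample <- function(condition, config = generator_config(), n_cells,
                            seed = 1L,
                            sample_kind = c("experiment", "isotype",
                                            "knockout")) {
  sample_kind <- match.arg(sample_kind)
  stopifnot(inherits(condition, "flow_condition"),
            inherits(config, "generator_config"),
            is.numeric(n_cells), n_cells >= 0)
  n <- as.integer(n_cells)
  cyto <- config$cytokine_channels
  cols <- c("tbet", "gata3", cyto)
  if (n == 0L) {
    df <- c(list(cell_id = integer(0)),
            stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    if (sample_kind != "isotype")
      df <- c(df, stats::setNames(rep(list(integer(0)), length(cyto)),
                                  paste0(cyto, "_on")))
    return(structure(as.data.frame(df),
                     class = c("flow_sample", "data.frame"),
                     condition = condition, sample_kind = sample_kind,
                     seed = as.integer(seed)))
  }
  df <- with_seed(seed, {
    ext <- 10^stats::rnorm(n, 0, config$sigma_extrinsic)
    intr <- function(sd = config$sigma_intrinsic) 10^stats::rnorm(n, 0, sd)
    out <- data.frame(cell_id = seq_len(n))
    if (sample_kind == "isotype") {
      for (ch in cols) out[[ch]] <- config$isotype[[ch]] * ext * intr()
    } else {
      med_t <- if (sample_kind == "knockout") config$isotype[["tbet"]]
      else channel_median("tbet", condition, config)
      med_g <- channel_median("gata3", condition, config)
      out$tbet <- med_t * ext * intr()
      out$gata3 <- med_g * ext * intr()
      states <- draw_cytokine_states(out[c("tbet", "gata3")],
                                     subset_biases(config$biases, cyto),
                                     seed = derive_seed(seed, 7L))
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
    }
    out
  })
  structure(df, class = c("flow_sample", "data.frame"),
            condition = condition, sample_kind = sample_kind,
            seed = as.integer(seed))
}

#' Default IL-12/IL-4 concentration grid
#'
#' Zero plus log-spaced concentrations up to 540 ng/ml.
#'
#' @param n_levels total number of levels including zero.
#' @param c_min,c_max smallest non-zero and largest concentration (ng/ml).
#' @return Numeric vector of concentrations.
#' @export
default_grid <- function(n_levels = 8, c_min = 2, c_max = 540) {
  c(0, exp(seq(log(c_min), log(c_max), length.out = n_levels - 1)))
}

#' Generate a full input-matrix dataset
#'
#' One experiment sample per grid point of the IL-12 x IL-4 concentration
#' matrix, plus one isotype-control sample and one T-bet-knockout sample
#' (generated at the Th1 condition).  Per-sample seeds are derived
#' deterministically from the master seed.
#'
#' @param config a [generator_config()].
#' @param il12_grid,il4_grid concentration grids (ng/ml).
#' @param n_cells cells per sample.
#' @param seed master seed.
#' @return An object of class `flow_dataset`: list with `samples` (list of
#'   `flow_sample`, row-major over the grid), `isotype`, `knockout`,
#'   `il12_grid`, `il4_grid`, `master_seed`.
#' @export
generate_matrix_dataset <- function(config = generator_config(),
                                    il12_grid = default_grid(),
                                    il4_grid = default_grid(),
                                    n_cells = 5000, seed = 1L) {
  stopifnot(length(il12_grid) >= 1, length(il4_grid) >= 1)
  samples <- list()
  k <- 0L
  for (c12 in il12_grid) {
    for (c4 in il4_grid) {
      k <- k + 1L
      samples[[k]] <- generate_sample(flow_condition(c12, c4), config,
                                      n_cells, seed = derive_seed(seed, k))
    }
  }
  iso <- generate_sample(flow_condition(0, 0, "isotype"), config, n_cells,
                         seed = derive_seed(seed, k + 1L),
                         sample_kind = "isotype")
  ko <- generate_sample(th1_condition(), config, n_cells,
                        seed = derive_seed(seed, k + 2L),
                        sample_kind = "knockout")
  structure(list(samples = samples, isotype = iso, knockout = ko,
                 il12_grid = il12_grid, il4_grid = il4_grid,
                 master_seed = as.integer(seed)),
            class = "flow_dataset")
}

#' @export
print.flow_dataset <- function(x, ...) {
  cat("Flow dataset:", length(x$samples), "experiment samples over a",
      length(x$il12_grid), "x", length(x$il4_grid), "grid",
      "(+ isotype, + knockout), master seed", x$master_seed, "\n")
  invisible(x)
}

sample_filename <- function(i) sprintf("sample_%03d.tsv", i)

write_one_sample <- function(sample, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cond <- attr(sample, "condition")
  writeLines(c(
    sprintf("# il12_ng_ml\t%.10g", cond$il12),
    sprintf("# il4_ng_ml\t%.10g", cond$il4),
    sprintf("# label\t%s", cond$label),
    sprintf("# sample_kind\t%s", attr(sample, "sample_kind")),
    sprintf("# seed\t%d", attr(sample, "seed"))), con)
  utils::write.table(as.data.frame(sample), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_one_sample <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "\t", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed header line in ", path, ": ", h,
                              call. = FALSE)
    meta[[kv[1]]] <- kv[2]
  }
  need <- c("il12_ng_ml", "il4_ng_ml", "label", "sample_kind", "seed")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("parse error in ", path, ": missing header field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(df))
    stop("parse error in ", path, ": missing 'cell_id' column", call. = FALSE)
  structure(df, class = c("flow_sample", "data.frame"),
            condition = flow_condition(as.numeric(meta$il12_ng_ml),
                                       as.numeric(meta$il4_ng_ml),
                                       meta$label),
            sample_kind = meta$sample_kind, seed = as.integer(meta$seed))
}

#' Write / read a flow dataset as plain text
#'
#' Each sample becomes a TSV file with a commented metadata header; a
#' `manifest.json` lists the files, grids and master seed.
#'
#' @param dataset a `flow_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_flow_dataset()` invisibly returns `dir`;
#'   `read_flow_dataset()` returns the reconstructed `flow_dataset`.
#' @export
write_flow_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "flow_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(dataset$samples))
  for (i in seq_along(dataset$samples)) {
    files[i] <- sample_filename(i)
    write_one_sample(dataset$samples[[i]], file.path(dir, files[i]))
  }
  write_one_sample(dataset$isotype, file.path(dir, "isotype.tsv"))
  write_one_sample(dataset$knockout, file.path(dir, "knockout.tsv"))
  jsonlite::write_json(
    list(samples = files, isotype = "isotype.tsv", knockout = "knockout.tsv",
         il12_grid = dataset$il12_grid, il4_grid = dataset$il4_grid,
         master_seed = dataset$master_seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_flow_dataset
#' @export
read_flow_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  samples <- lapply(manifest$samples, function(f)
    read_one_sample(file.path(dir, f)))
  structure(list(samples = samples,
                 isotype = read_one_sample(file.path(dir, manifest$isotype)),
                 knockout = read_one_sample(file.path(dir, manifest$knockout)),
                 il12_grid = manifest$il12_grid,
                 il4_grid = manifest$il4_grid,
                 master_seed = as.integer(manifest$master_seed)),
            class = "flow_dataset")
}

#' Round-trip a dataset through disk
#'
#' Writes `dataset` to `path` and reads it back; the result compares equal
#' to the input (values, conditions, seeds).
#'
#' @param dataset a `flow_dataset`.
#' @param path directory to write to.
#' @return The re-read `flow_dataset`.
#' @export
dataset_roundtrip <- function(dataset, path) {
  write_flow_dataset(dataset, path)
  read_flow_dataset(path)
}
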