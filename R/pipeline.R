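# Configuration-driven orchestration: simulate -> model -> analyze -> report,
# with a thin command-line interface.

pipeline_defaults <- function() {
  list(master_seed = 1L,
       n_cells = 5000L,
       il12_grid = default_grid(),
       il4_grid = default_grid(),
       output_dir = "thmix_out",
       analyses = c("mfi", "separability", "noise", "alpha", "bias_curves",
                    "mi", "bic", "quadrants", "ratio"),
       model = list(k_grid_n = 15L, k_min = 0.05, k_max = 20,
                    sweep_beta = 0.02, trajectory_steps = 50L))
}

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults and overrides them with the supplied
#' values; unknown keys are rejected.  A configuration can also be read
#' from a JSON file with [read_pipeline_config()].
#'
#' @param ... scalar or vector overrides of the default fields
#'   (`master_seed`, `n_cells`, `il12_grid`, `il4_grid`, `output_dir`,
#'   `analyses`, `model`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration entries must be named", call. = FALSE)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if ("model" %in% names(over)) {
    um <- setdiff(names(over$model), names(cfg$model))
    if (length(um))
      stop("unknown model configuration key(s): ",
           paste(um, collapse = ", "), call. = FALSE)
    cfg$model[names(over$model)] <- over$model
    over$model <- NULL
  }
  cfg[names(over)] <- over
  if (is.null(cfg$master_seed) || !is.finite(cfg$master_seed))
    stop("'master_seed' is mandatory", call. = FALSE)
  cfg$master_seed <- as.integer(cfg$master_seed)
  cfg$n_cells <- as.integer(cfg$n_cells)
  stopifnot(cfg$n_cells >= 0, all(cfg$il12_grid >= 0), all(cfg$il4_grid >= 0))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file holding configuration overrides.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  writeLines(msg, con)
  message(msg)
}

#' Recompute the package's headline summary statistics
#'
#' Generates the calibrated Th1, Th2 and mixed populations plus isotype
#' controls from scratch and computes the eight reference quantities:
#' Th1 IFN-gamma-positive fraction and its top-bin value, Th2
#' IL-4-positive fraction and its high-GATA3 value (percent), the
#' normalized GATA3/T-bet ratio under mixed/Th1/Th2 conditions, and the
#' mode of the Th1 alpha distribution (degrees).
#'
#' @param seed master seed; all per-sample seeds derive from it.
#' @param n_cells cells per condition for the fraction/ratio statistics.
#' @param n_alpha cells for the alpha-mode statistic.
#' @param config a [generator_config()].
#' @return Named list (`t4` .. `t11`); each element is
#'   `list(value = , n = )`.
#' @export
report_targets <- function(seed = 1L, n_cells = 20000L, n_alpha = 10000L,
                           config = generator_config()) {
  th1 <- generate_sample(th1_condition(), config, n_cells,
                         seed = derive_seed(seed, 11L))
  th2 <- generate_sample(th2_condition(), config, n_cells,
                         seed = derive_seed(seed, 12L))
  mix <- generate_sample(mixed_condition(), config, n_cells,
                         seed = derive_seed(seed, 13L))
  iso <- generate_sample(flow_condition(0, 0, "isotype"), config, n_cells,
                         seed = derive_seed(seed, 14L),
                         sample_kind = "isotype")
  thr_if <- as.numeric(stats::quantile(iso$ifng, 0.99))
  thr_i4 <- as.numeric(stats::quantile(iso$il4, 0.99))

  bc1 <- bin_bias_curve(th1, "tbet", "ifng", 500, thr_if)
  bc2 <- bin_bias_curve(th2, "gata3", "il4", 500, thr_i4)

  th1b <- generate_sample(th1_condition(), config, n_alpha,
                          seed = derive_seed(seed, 15L))
  isob <- generate_sample(flow_condition(0, 0, "isotype"), config, n_alpha,
                          seed = derive_seed(seed, 16L),
                          sample_kind = "isotype")
  wt <- normalize_to_isotype(th1b$tbet, isob$tbet)
  wg <- normalize_to_isotype(th1b$gata3, isob$gata3)
  amode <- density_mode(alpha_angle(wt, wg))

  list(
    t4 = list(value = 100 * attr(bc1, "population_fraction"), n = n_cells),
    t5 = list(value = 100 * bc1$positive_fraction[nrow(bc1)], n = n_cells),
    t6 = list(value = 100 * attr(bc2, "population_fraction"), n = n_cells),
    t7 = list(value = 100 * bc2$positive_fraction[nrow(bc2)], n = n_cells),
    t8 = list(value = ratio_statistic(mix, iso), n = n_cells),
    t9 = list(value = ratio_statistic(th1, iso), n = n_cells),
    t10 = list(value = ratio_statistic(th2, iso), n = n_cells),
    t11 = list(value = amode, n = n_alpha))
}

target_reference <- function() {
  data.frame(
    id = paste0("t", 4:11),
    reference = c(60, 85, 20, 40, 1, 0.4, 20, 90),
    rel_tol = c(0.10, 0.10, 0.10, 0.10, 0.10, 0.15, 0.10, 0.10),
    stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Stages: `simulate` (input-matrix dataset), `model` (phase diagram,
#' co-expression map, trajectory continuity), `analyze` (statistics tables)
#' and `report` (headline summary statistics with pass/fail lines).  All
#' outputs are plain TSV/JSON under `output_dir`; a run log records the
#' package version, configuration hash and derived seeds.  Runs are
#' deterministic for a fixed configuration.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of the four stage names (default: all).
#' @return Invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "model", "analyze",
                                    "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$output_dir, "run_log.txt"), "w")
  on.exit(close(logf))
  ver <- as.character(utils::packageVersion("thmix"))
  hash <- config_hash(config)
  log_line(logf, "thmix ", ver, " | config hash ", hash,
           " | master seed ", config$master_seed)
  out <- list(version = ver, config_hash = hash)
  stage <- function(name, code) {
    log_line(logf, "stage ", name, " started")
    r <- tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_line(logf, "stage ", name, " done")
    r
  }

  gcfg <- generator_config()
  dataset <- NULL
  if ("simulate" %in% stages) {
    dataset <- stage("simulate", {
      ds <- generate_matrix_dataset(gcfg, config$il12_grid, config$il4_grid,
                                    config$n_cells, seed = config$master_seed)
      write_flow_dataset(ds, file.path(config$output_dir, "dataset"))
      ds
    })
    out$dataset <- file.path(config$output_dir, "dataset")
  }

  if ("model" %in% stages) {
    out$model <- stage("model", {
      mc <- config$model
      kg <- exp(seq(log(mc$k_min), log(mc$k_max),
                    length.out = mc$k_grid_n))
      base <- grn_params(beta1 = mc$sweep_beta, beta2 = mc$sweep_beta)
      pd <- phase_diagram(kg, kg, base)
      write_grid_map(pd, file.path(config$output_dir, "phase_diagram.tsv"))
      bgrid <- beta_from_concentration(config$il12_grid)
      bgrid2 <- beta_from_concentration(config$il4_grid)
      irm <- input_response_map(grn_params(), bgrid, bgrid2)
      write_grid_map(irm, file.path(config$output_dir,
                                    "coexpression_map.tsv"))
      tr <- detect_sharp_transition(
        grn_params(),
        c(beta_from_concentration(540), 0),
        c(0, beta_from_concentration(540)),
        n_steps = config$model$trajectory_steps)
      jsonlite::write_json(
        list(regions_present = pd$regions_present,
             trajectory = unclass(tr)),
        file.path(config$output_dir, "model_summary.json"),
        auto_unbox = TRUE, digits = NA)
      list(phase_diagram = pd, coexpression_map = irm, trajectory = tr)
    })
  }

  if ("analyze" %in% stages) {
    out$analysis <- stage("analyze", {
      if (is.null(dataset)) {
        ddir <- file.path(config$output_dir, "dataset")
        if (!dir.exists(ddir))
          stop("no dataset available; run the simulate stage first")
        dataset <- read_flow_dataset(ddir)
      }
      adir <- file.path(config$output_dir, "analysis")
      dir.create(adir, showWarnings = FALSE)
      res <- list()
      iso <- dataset$isotype
      if ("mfi" %in% config$analyses) {
        for (ch in c("tbet", "gata3", "ifng", "il4")) {
          M <- mfi_matrix(dataset, ch)
          utils::write.table(M, file.path(adir, paste0("mfi_", ch, ".tsv")),
                             sep = "\t", quote = FALSE)
          res$mfi[[ch]] <- M
        }
      }
      if ("separability" %in% config$analyses) {
        pos1 <- dataset$il12_grid > 0; pos2 <- dataset$il4_grid > 0
        M <- mfi_matrix(dataset, "tbet")[pos1, pos2, drop = FALSE]
        res$separability <- decompose_separable(
          M, background = gcfg$response$tbet$background)
      }
      if ("noise" %in% config$analyses)
        res$noise <- noise_profile(dataset, "tbet")
      if ("mi" %in% config$analyses) {
        mis <- vapply(dataset$samples, function(s)
          mutual_information_binary(s$ifng_on, s$il4_on), numeric(1))
        res$mi <- list(per_condition = mis, median = stats::median(mis))
      }
      if ("quadrants" %in% config$analyses) {
        mixs <- generate_sample(mixed_condition(), gcfg, config$n_cells,
                                seed = derive_seed(config$master_seed, 99L))
        res$quadrants <- quadrant_fractions(mixs, isotype = iso)
      }
      if ("ratio" %in% config$analyses) {
        th1 <- generate_sample(th1_condition(), gcfg, config$n_cells,
                               seed = derive_seed(config$master_seed, 101L))
        res$ratio_th1 <- ratio_statistic(th1, iso)
      }
      jsonlite::write_json(
        list(mi_median = res$mi$median,
             separability_residual = res$separability$residual,
             config_hash = hash, master_seed = config$master_seed),
        file.path(adir, "analysis_summary.json"), auto_unbox = TRUE,
        digits = NA)
      res
    })
  }

  if ("report" %in% stages) {
    out$report <- stage("report", {
      tg <- report_targets(config$master_seed, n_cells = config$n_cells,
                           n_alpha = max(config$n_cells %/% 2L, 1000L))
      ref <- target_reference()
      lines <- character(nrow(ref))
      for (i in seq_len(nrow(ref))) {
        v <- tg[[ref$id[i]]]$value
        ok <- abs(v - ref$reference[i]) <= ref$rel_tol[i] * ref$reference[i]
        lines[i] <- sprintf("%s: value %.4g, reference %.4g -> %s",
                            ref$id[i], v, ref$reference[i],
                            if (ok) "PASS" else "FAIL")
        log_line(logf, lines[i])
      }
      jsonlite::write_json(
        list(version = ver, config_hash = hash,
             master_seed = config$master_seed, targets = tg,
             lines = lines),
        file.path(config$output_dir, "report.json"),
        auto_unbox = TRUE, digits = NA)
      list(targets = tg, lines = lines)
    })
  }
  invisible(out)
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `model`, `analyze`, `report` (each takes
#' `--config <json>` and `--out <dir>`), or `all` to run every stage.
#' Returns (invisibly) 0 on success; parse errors and stage failures
#' signal conditions, which the bundled `inst/cli/thmix.R` script converts
#' to a non-zero exit status.
#'
#' @param args character vector of command-line arguments.
#' @return Invisibly, 0.
#' @export
thmix_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: thmix <simulate|model|analyze|report|all> [--config C] [--out DIR] [--seed S]"
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  if (!cmd %in% c("simulate", "model", "analyze", "report", "all"))
    stop(usage, call. = FALSE)
  rest <- args[-1]
  opt <- list(config = NULL, out = NULL, seed = NULL)
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opt) || i == length(rest))
      stop(usage, call. = FALSE)
    opt[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
  else pipeline_config()
  if (!is.null(opt$out)) cfg$output_dir <- opt$out
  if (!is.null(opt$seed)) cfg$master_seed <- as.integer(opt$seed)
  stages <- if (cmd == "all") c("simulate", "model", "analyze", "report")
  else cmd
  run_pipeline(cfg, stages = stages)
  invisible(0L)
}
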