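#' Run the full analysis pipeline
#'
#' Binds the stages end to end under one configuration: simulate
#' individual-level data (or read provided `women.csv`/`births.csv`),
#' aggregate to survey level, fit the per-category models, and run the
#' scale-up scenarios. Each stage logs its parameters, row counts and timing
#' via `message()`.
#'
#' @param config Named list as returned by [read_run_config()], or a path to
#'   a flat key-value config file. Recognised keys (all optional):
#'   `stages` (subset of `simulate,aggregate,fit,predict`; default all),
#'   `out_dir` (default `"."`), `seed` (default 1), `n_countries`,
#'   `surveys_per_country`, `n_women`, `variants` (default `m1,m2,m3`),
#'   `predict_variant` (default `m3`), `scenarios` (default `A,B,C`),
#'   `delta_mcpr_pp` (default 10), `fallback` (default `zero`),
#'   `region_table` (path to a `country_id,region` CSV), `women`, `births`,
#'   `survey_meta`, `aggregates` (input paths overriding simulation),
#'   `zero_rule` (default `continuity`).
#' @return Invisibly, a list with the in-memory `aggregates`, `fits` and
#'   `predictions` produced by the enabled stages.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  get1 <- function(key, default) {
    v <- config[[key]]
    if (is.null(v) || !length(v)) default else v[[1]]
  }
  stages <- config$stages
  if (is.null(stages)) stages <- c("simulate", "aggregate", "fit", "predict")
  out_dir <- get1("out_dir", ".")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(get1("seed", 1))
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(...) message(sprintf("[%7.2fs] ",
                                             proc.time()[["elapsed"]] - t0), ...)
  women <- births <- survey_meta <- aggregates <- NULL
  fits <- predictions <- NULL

  if ("simulate" %in% stages) {
    n_surveys <- as.integer(get1("n_surveys", 20))
    hp <- history_params(n_women = as.integer(get1("n_women", 500)),
                         seed = seed)
    n_countries <- as.integer(get1("n_countries", max(2, n_surveys %/% 3)))
    sim <- generate_birth_histories(
      hp, n_surveys = n_surveys,
      survey_cmc = 1400L + 12L * (seq_len(n_surveys) %% 5L),
      country_ids = sprintf("C%03d", 1L + (seq_len(n_surveys) %% n_countries)))
    women <- sim$women; births <- sim$births; survey_meta <- sim$survey_meta
    write_women(women, file.path(out_dir, "women.csv"))
    write_births(births, file.path(out_dir, "births.csv"))
    .write_table(survey_meta, file.path(out_dir, "survey_meta.csv"))
    log_stage("simulate: seed ", seed, ", ", n_surveys, " surveys, ",
              nrow(women), " women, ", nrow(births), " births")
  }

  if ("aggregate" %in% stages) {
    if (is.null(women)) {
      women <- read_women(get1("women", stop("no women input configured")))
      births <- read_births(get1("births", stop("no births input configured")))
      survey_meta <- read.csv(get1("survey_meta",
                                   stop("no survey_meta input configured")),
                              stringsAsFactors = FALSE)
    }
    aggregates <- aggregate_surveys(women, births, survey_meta)
    write_aggregates(aggregates, file.path(out_dir, "aggregates.csv"))
    log_stage("aggregate: ", nrow(aggregates), " survey rows")
  }

  if ("fit" %in% stages || "predict" %in% stages) {
    if (is.null(aggregates)) {
      path <- get1("aggregates", file.path(out_dir, "aggregates.csv"))
      if (!file.exists(path)) stop("no aggregates available for fitting")
      aggregates <- read_aggregates(path)
    }
    if (nrow(aggregates) < 6L)
      stop("insufficient data: ", nrow(aggregates),
           " survey rows; need more surveys than model coefficients")
    variants <- config$variants
    if (is.null(variants)) variants <- c("m1", "m2", "m3")
    fits <- fit_all_categories(aggregates, variants = variants,
                               zero_rule = get1("zero_rule", "continuity"))
    if ("fit" %in% stages) {
      write_fits(fits, file.path(out_dir, "fits.csv"))
      if ("m3" %in% variants)
        write_random_effects(fits, file.path(out_dir, "random_effects.csv"))
      log_stage("fit: ", length(variants), " variant(s) on ",
                nrow(aggregates), " surveys")
    }
  }

  if ("predict" %in% stages) {
    scen_labels <- config$scenarios
    if (is.null(scen_labels)) scen_labels <- c("A", "B", "C")
    delta <- as.numeric(get1("delta_mcpr_pp", 10))
    scen <- lapply(scen_labels, scenario_spec, delta_mcpr_pp = delta)
    region_table <- if (!is.null(config$region_table))
      read.csv(get1("region_table", NULL), stringsAsFactors = FALSE) else NULL
    # most recent survey per country as the scenario baseline
    o <- order(aggregates$country_id, -aggregates$year)
    latest <- aggregates[o, ][!duplicated(aggregates[o, "country_id"]), ]
    predictions <- run_scenarios(fits, latest, scenarios = scen,
                                 fallback = get1("fallback", "zero"),
                                 region_table = region_table,
                                 variant = get1("predict_variant", "m3"))
    write_predictions(predictions, file.path(out_dir, "predictions.csv"))
    log_stage("predict: ", length(unique(predictions$country_id)),
              " countries x ", length(scen_labels), " scenarios")
  }
  invisible(list(aggregates = aggregates, fits = fits,
                 predictions = predictions))
}

#' Command-line entry point
#'
#' In-process implementation of the shell interface: subcommands `simulate`,
#' `aggregate`, `fit`, `predict` (each running that stage) and `pipeline`
#' (all stages), with `--config FILE` for a flat key-value configuration,
#' `--seed N`, `--out DIR`, and `--version`. A thin wrapper script suitable
#' for `Rscript` ships in `inst/scripts/birthrisk.R`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code: 0 on success, 1 on a validation/run failure,
#'   2 on unknown usage.
#' @export
birthrisk_cli <- function(argv = character()) {
  usage <- paste(
    "usage: birthrisk <simulate|aggregate|fit|predict|pipeline>",
    "[--config FILE] [--seed N] [--out DIR] [--version]")
  if ("--version" %in% argv) {
    message("birthrisk ",
            as.character(utils::packageVersion("birthrisk")),
            " (schema 1)")
    return(0L)
  }
  if (!length(argv)) { message(usage); return(2L) }
  cmd <- argv[[1]]
  if (!cmd %in% c("simulate", "aggregate", "fit", "predict", "pipeline")) {
    message("unknown subcommand '", cmd, "'\n", usage)
    return(2L)
  }
  opts <- list()
  rest <- argv[-1]
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[[i]]
    if (a %in% c("--config", "--seed", "--out")) {
      if (i == length(rest)) { message("missing value for ", a, "\n", usage); return(2L) }
      opts[[sub("^--", "", a)]] <- rest[[i + 1L]]
      i <- i + 2L
    } else {
      message("unknown flag '", a, "'\n", usage)
      return(2L)
    }
  }
  config <- if (!is.null(opts$config)) read_run_config(opts$config) else list()
  if (!is.null(opts$seed)) config$seed <- opts$seed
  if (!is.null(opts$out)) config$out_dir <- opts$out
  config$stages <- if (cmd == "pipeline")
    c("simulate", "aggregate", "fit", "predict") else cmd
  code <- tryCatch({ run_pipeline(config); 0L },
                   error = function(e) { message("error: ",
                                                 conditionMessage(e)); 1L })
  code
}
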