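#' Assemble and validate a pipeline run configuration
#'
#' @param input Path to a daily-series CSV, or `NULL` to simulate input with
#'   [simulate_daily_series()].
#' @param sim Named list of arguments for [simulate_daily_series()] when
#'   `input` is `NULL`.
#' @param pollutants Pollutants to scan in the RR stage.
#' @param windows Lag windows for the RR scan and the index grid.
#' @param sex,season Subgroup for the RR scan and the state labelling
#'   response.
#' @param q_high Target top share of high-admission days.
#' @param standards Threshold registry for the index grid.
#' @param bootstrap_B Bootstrap replicates for transition CIs (0 disables).
#' @param seed Integer seed governing every stochastic step.
#' @param outdir Output directory (created if needed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim = list(),
                            pollutants = pollutant_cols(), windows = 1:6,
                            sex = "all", season = "both", q_high = 0.3,
                            standards = pollution_standards(),
                            bootstrap_B = 200, seed = 1,
                            outdir = tempfile("airadmit_run_")) {
  stopifnot(q_high > 0, q_high < 1, bootstrap_B >= 0)
  sex <- match.arg(sex, c("all", "male", "female"))
  season <- match.arg(season, c("both", "warm", "cold"))
  structure(list(input = input, sim = sim, pollutants = pollutants,
                 windows = windows, sex = sex, season = season,
                 q_high = q_high, standards = standards,
                 bootstrap_B = bootstrap_B, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  hashable <- config[setdiff(names(config), "outdir")]
  rlang::hash(hashable)
}

stage_log <- function(stage, ...) {
  message(sprintf("[airadmit] %-10s %s", stage, sprintf(...)))
}

write_stage_csv <- function(tbl, path, hash) {
  tbl$config_hash <- hash
  readr::write_csv(tbl, path, progress = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one daily series: ingest (or simulate) and
#' summarise; lag-scan RR regressions per pollutant; Lorenz-curve state
#' labelling; odds-ratio index grid and severity-index selection; stratified
#' Markov transition estimation with bootstrap CIs and the severe-vs-mild
#' comparison. All intermediate tables are written as plain CSV (each
#' carrying the configuration hash) together with a JSON manifest, and the
#' run is a pure function of (input data, configuration, seed).
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with every stage result and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  files <- character(0)
  out <- function(name) file.path(config$outdir, name)

  if (is.null(config$input)) {
    data <- rlang::exec(simulate_daily_series, !!!config$sim,
                        seed = config$seed)
    stage_log("simulate", "%d days (seed %d)", nrow(data), config$seed)
  } else {
    data <- read_daily_csv(config$input)
    stage_log("ingest", "%d days from %s", nrow(data), config$input)
  }
  files["daily"] <- write_stage_csv(data, out("daily.csv"), hash)

  summ <- daily_summary(data)
  files["summary"] <- write_stage_csv(summ, out("summary.csv"), hash)
  corr <- pollutant_correlations(data)
  corr_tbl <- as_tibble(corr, rownames = "pollutant")
  files["correlations"] <- write_stage_csv(corr_tbl, out("correlations.csv"),
                                           hash)
  stage_log("summary", "%d variables summarised", nrow(summ))

  rr <- purrr::map_dfr(
    intersect(config$pollutants, names(data)),
    function(p) lag_scan(data, p, windows = config$windows,
                         sex = config$sex, season = config$season))
  files["rr"] <- write_stage_csv(rr, out("rr_results.csv"), hash)
  stage_log("rr", "%d pollutant x lag fits, %d significant", nrow(rr),
            sum(rr$significant))

  response <- subgroup_response(data, config$sex)
  season_keep <- if (config$season == "both") rep(TRUE, nrow(data)) else
    season_of(data$date) == config$season
  counts <- ifelse(season_keep, data[[response]], NA_integer_)
  curve <- lorenz_curve(counts)
  files["lorenz"] <- write_stage_csv(
    as_tibble(curve[c("p_days", "p_admissions")]), out("lorenz.csv"), hash)
  threshold <- high_day_threshold(counts, q = config$q_high)
  state <- label_states(counts, threshold)
  states_tbl <- tibble(date = data$date, counts = counts, state = state)
  files["states"] <- write_stage_csv(states_tbl, out("states.csv"), hash)
  stage_log("states", "high-day threshold %d, %d/%d high days", threshold,
            sum(state == 2, na.rm = TRUE), sum(!is.na(state)))

  grid <- index_grid_search(data, state, standards = config$standards,
                            windows = config$windows)
  files["index"] <- write_stage_csv(grid, out("index_grid.csv"), hash)
  sel <- selected_index(grid)
  stage_log("index", "selected %s %s (>%g ug/m3, >=%d of %d days), OR %.2f",
            sel$pollutant, sel$lag, sel$threshold, sel$k, sel$w, sel$or)

  severity <- severity_series(data, sel)
  fit <- fit_markov(state, severity, boot_B = config$bootstrap_B,
                    boot_seed = config$seed + 1L)
  trans <- tidy(fit)
  files["transitions"] <- write_stage_csv(trans, out("transitions.csv"), hash)
  n_undef <- sum(is.na(severity) | is.na(state))
  stage_log("markov", "%d day pairs (%d days dropped undefined)",
            fit$n_pairs, n_undef)

  comparison <- NULL
  if (all(c("mild", "severe") %in% names(fit$P))) {
    comparison <- compare_conditions(fit)
    files["comparison"] <- write_stage_csv(comparison, out("comparison.csv"),
                                           hash)
  } else {
    stage_log("markov", "single severity stratum: no comparison written")
  }

  manifest <- list(
    package = "airadmit",
    version = as.character(utils::packageVersion("airadmit")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = hash,
    config = config[c("pollutants", "windows", "sex", "season", "q_high",
                      "bootstrap_B", "seed")],
    state_threshold = threshold,
    selected_index = as.list(sel[c("pollutant", "standard", "threshold",
                                   "w", "k", "or")]),
    files = as.list(files)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  stage_log("done", "outputs in %s", config$outdir)

  invisible(list(data = data, summary = summ, correlations = corr, rr = rr,
                 lorenz = curve, state_threshold = threshold,
                 states = states_tbl, index_grid = grid,
                 selected = sel, severity = severity, markov = fit,
                 comparison = comparison, manifest = manifest))
}
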