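#' Model calendar
#'
#' One time step is 1 model MINUTE; 60 MINUTES = 1 HOUR, 12 HOURS = 1 DAY,
#' 7 DAYS = 1 WEEK, 50 WEEKS = 1 YEAR. All derived durations are recomputed
#' from these primitives. The default recording interval is 3.5 DAYS
#' (2,520 minutes = 42 hours), giving 100 intervals per YEAR.
#'
#' @param minutes_per_hour,hours_per_day,days_per_week,weeks_per_year
#'   Calendar primitives.
#' @param sample_days Recording/sampling interval in DAYS.
#' @return A named list of class `emo_calendar` with derived fields `hour`,
#'   `day`, `week`, `year`, `sample_interval` (minutes) and
#'   `interval_hours`.
#' @export
model_calendar <- function(minutes_per_hour = 60, hours_per_day = 12,
                           days_per_week = 7, weeks_per_year = 50,
                           sample_days = 3.5) {
  hour <- minutes_per_hour
  day <- hour * hours_per_day
  week <- day * days_per_week
  year <- week * weeks_per_year
  cal <- list(minutes_per_hour = minutes_per_hour,
              hours_per_day = hours_per_day, days_per_week = days_per_week,
              weeks_per_year = weeks_per_year, hour = hour, day = day,
              week = week, year = year,
              sample_interval = sample_days * day,
              interval_hours = sample_days * hours_per_day)
  class(cal) <- "emo_calendar"
  cal
}

#' Full run configuration
#'
#' Bundles every model constant for one simulation run: the variant switch
#' (dynamic emotional bookkeeping vs fixed rank-distance LIKE attitudes),
#' the LIKE-partner-selectivity `lps`, the dominance hierarchy, durations,
#' and the world / affect / behaviour parameter blocks. Defaults reproduce
#' the full-scale experiment: 20 agents with dominance 0.05, 0.10, ...,
#' 1.00, a 21,600-minute stabilization (burn-in), a 504,000-minute
#' (2-YEAR) run and statistics recorded over the final YEAR.
#'
#' @param variant `"dynamic"` or `"fixed"`.
#' @param lps LIKE-partner selectivity in `[0, 1)`; the experiment sweep
#'   uses 0, 0.5, 0.9, 0.95, 0.99.
#' @param n_agents Group size.
#' @param dom Strictly increasing dominance vector in `(0, 1]`; default
#'   evenly spaced `0.05 * (1:n_agents)` for `n_agents = 20`.
#' @param burn_in Stabilization period in minutes, excluded from recording.
#' @param run_length Simulated minutes after the burn-in.
#' @param record_window Final portion of the run used for statistics,
#'   minutes; must be a multiple of the sampling interval.
#' @param world,affect,behavior,calendar Parameter blocks; see
#'   [world_config()], [affect_params()], [behavior_params()],
#'   [model_calendar()].
#' @param salience Salience table, see [default_salience_table()].
#' @param like_L0,like_LS Conversion parameters of the fixed-attitude LIKE
#'   function.
#' @param record_events Keep the directed event log (needed for rate
#'   matrices; switch off only for state-only experiments).
#' @param replicates Default number of replicate runs per condition in
#'   [run_sweep()].
#' @param validate Internal switch to skip cross-field validation.
#' @return A list of class `emo_config`.
#' @export
run_config <- function(variant = c("dynamic", "fixed"), lps = 0,
                       n_agents = 20, dom = NULL, burn_in = 21600,
                       run_length = 504000, record_window = 252000,
                       world = world_config(), affect = affect_params(),
                       behavior = behavior_params(),
                       calendar = model_calendar(),
                       salience = default_salience_table(),
                       like_L0 = 0.243, like_LS = 0.36,
                       record_events = TRUE, replicates = 10,
                       validate = TRUE) {
  variant <- match.arg(variant)
  if (is.null(dom)) dom <- seq_len(n_agents) / n_agents
  cfg <- list(variant = variant, lps = lps, n_agents = n_agents, dom = dom,
              burn_in = burn_in, run_length = run_length,
              record_window = record_window, world = world, affect = affect,
              behavior = behavior, calendar = calendar, salience = salience,
              like_L0 = like_L0, like_LS = like_LS,
              record_events = record_events, replicates = replicates)
  class(cfg) <- "emo_config"
  if (validate) validate_config(cfg)
  cfg
}

#' @rdname run_config
#' @param cfg An `emo_config`.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "emo_config"),
            cfg$lps >= 0, cfg$lps < 1,
            cfg$n_agents >= 4,
            length(cfg$dom) == cfg$n_agents,
            all(cfg$dom > 0), all(cfg$dom <= 1),
            all(diff(cfg$dom) > 0),
            cfg$burn_in >= 0, cfg$run_length > 0,
            cfg$record_window > 0,
            cfg$record_window <= cfg$run_length,
            cfg$replicates >= 1)
  k <- cfg$record_window / cfg$calendar$sample_interval
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("record_window must be a positive multiple of the sampling ",
         "interval (", cfg$calendar$sample_interval, " min)", call. = FALSE)
  validate_salience(cfg$salience)
  invisible(cfg)
}

#' Desk-scale configuration
#'
#' The scaled-down setup used by the test-suite and examples: a 1-WEEK
#' burn-in and an 8-WEEK run that is recorded in full (16 sampling
#' intervals). All rules and rates are identical to the full-scale model;
#' only the horizon shrinks.
#'
#' @param ... Overrides passed on to [run_config()].
#' @export
scaled_config <- function(...) {
  cal <- model_calendar()
  run_config(burn_in = cal$week, run_length = 8 * cal$week,
             record_window = 8 * cal$week, ...)
}

# Flatten a config into the named numeric vector the C++ engine reads.
# Exported because the R-level action_probabilities() shares it.
#' @rdname run_config
#' @export
flatten_params <- function(cfg) {
  c(unlist(unclass(cfg$world)), unlist(unclass(cfg$affect)),
    unlist(unclass(cfg$behavior)),
    lps = cfg$lps, dynamic_like = as.numeric(cfg$variant == "dynamic"),
    burn_in = cfg$burn_in, run_length = cfg$run_length,
    record_window = cfg$record_window,
    sample_interval = cfg$calendar$sample_interval)
}

#' Write / read a run configuration as JSON
#'
#' A flat-text config echo: every numeric block plus the salience table.
#' Reading it back reproduces a configuration that validates and drives an
#' identical run.
#'
#' @param cfg An `emo_config`.
#' @param path File path.
#' @export
write_config <- function(cfg, path) {
  out <- list(variant = cfg$variant, lps = cfg$lps,
              n_agents = cfg$n_agents, dom = cfg$dom, burn_in = cfg$burn_in,
              run_length = cfg$run_length,
              record_window = cfg$record_window,
              world = unclass(cfg$world), affect = unclass(cfg$affect),
              behavior = unclass(cfg$behavior),
              calendar = unclass(cfg$calendar)[c("minutes_per_hour",
                                                 "hours_per_day",
                                                 "days_per_week",
                                                 "weeks_per_year")],
              sample_days = cfg$calendar$sample_interval / cfg$calendar$day,
              salience = as.data.frame(cfg$salience),
              salience_events = rownames(cfg$salience),
              like_L0 = cfg$like_L0, like_LS = cfg$like_LS,
              record_events = cfg$record_events,
              replicates = cfg$replicates)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sal <- as.matrix(x$salience)
  rownames(sal) <- x$salience_events
  colnames(sal) <- c("d_arousal", "d_anxiety")
  run_config(variant = x$variant, lps = x$lps, n_agents = x$n_agents,
             dom = x$dom, burn_in = x$burn_in, run_length = x$run_length,
             record_window = x$record_window,
             world = do.call(world_config, as.list(x$world)),
             affect = do.call(affect_params, as.list(x$affect)),
             behavior = do.call(behavior_params, as.list(x$behavior)),
             calendar = do.call(model_calendar,
                                c(as.list(x$calendar),
                                  sample_days = x$sample_days)),
             salience = sal, like_L0 = x$like_L0, like_LS = x$like_LS,
             record_events = x$record_events, replicates = x$replicates)
}

#' @export
print.emo_config <- function(x, ...) {
  cat("<emo_config> ", x$variant, " attitude model, LPS = ", x$lps,
      ", n = ", x$n_agents, "\n", sep = "")
  cat("  horizon: ", x$burn_in, " (burn-in) + ", x$run_length,
      " min; recorded: final ", x$record_window, " min\n", sep = "")
  invisible(x)
}
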