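#' Initialize a group
#'
#' Draws the initial spatial configuration and attitude matrices: positions
#' uniform in a 50 m-diameter disc at the torus centre, headings uniform on
#' 1-360 degrees, arousal at the baseline 0.09 with anxiety and
#' satisfaction at 0, FEAR from the dominance differences, and LIKE at 0
#' (dynamic variant) or at the fixed rank-distance function (fixed
#' variant). First activations are drawn from the truncated normal
#' inter-activation distribution (mean 1 min, sd 0.05 min).
#'
#' Uses the current R random number stream; callers seed via `set.seed()`.
#'
#' @param cfg An [run_config()].
#' @return List with `pos` (n x 2), `heading`, `t0`, `fear`, `like`.
#' @export
init_group <- function(cfg) {
  n <- cfg$n_agents
  r <- 25 * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  pos <- cbind(cfg$world$width / 2 + r * cos(a),
               cfg$world$height / 2 + r * sin(a))
  heading <- runif(n, 1, 360)
  t0 <- pmax(rnorm(n, cfg$behavior$act_mean, cfg$behavior$act_sd),
             cfg$behavior$act_floor)
  like <- if (cfg$variant == "dynamic") matrix(0, n, n) else
    fixed_like_matrix(cfg$dom, cfg$like_L0, cfg$like_LS)
  list(pos = pos, heading = heading, t0 = t0, fear = fear_matrix(cfg$dom),
       like = like)
}

#' Run one simulation
#'
#' Executes the event-driven model over `burn_in + run_length` minutes and
#' applies the observation protocol to the final `record_window` minutes:
#' dyadic behaviours accumulate per 3.5-DAY recording interval into hourly
#' rates which are then averaged over the window, while proximity, LIKE
#' attitudes and the emotional state are point-sampled at the interval
#' boundaries and averaged. Identical `(cfg, seed)` pairs give bit-identical
#' results.
#'
#' @param cfg A [run_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, the run bundle (CSV
#'   matrices, JSON summary, config echo) is written there.
#' @return An object of class `emo_run`: the configuration, the directed
#'   event log, per-behaviour yearly-average hourly-rate matrices
#'   (`rates`), the mean proximity (`proximity`) and LIKE (`like_mean`)
#'   matrices, the final LIKE matrix, and per-agent mean emotional states.
#' @export
run_simulation <- function(cfg, seed, out_dir = NULL) {
  validate_config(cfg)
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  init <- init_group(cfg)
  eng <- cpp_run_engine(flatten_params(cfg), cfg$dom, init$fear, init$like,
                        init$pos, init$heading, init$t0, cfg$salience,
                        cfg$record_events)
  n <- cfg$n_agents
  cal <- cfg$calendar
  codes <- behavior_codes()
  events <- eng$events
  events$behavior <- names(codes)[events$behavior]

  k <- eng$n_samples
  starts <- eng$record_start + (seq_len(k) - 1L) * cal$sample_interval
  rates <- NULL
  if (cfg$record_events) {
    per_int <- lapply(starts, function(s)
      interval_rates(events, s, cal$sample_interval, n, cal))
    rates <- lapply(setNames(names(per_int[[1]]), names(per_int[[1]])),
                    function(b) yearly_average(lapply(per_int, `[[`, b)))
  }
  prox <- yearly_average(lapply(seq_len(k), function(j)
    sample_proximity(eng$sample_x[, j], eng$sample_y[, j], cfg$world)))
  like_mean <- apply(eng$sample_like, c(1, 2), mean)
  emotion_means <- data.frame(agent = seq_len(n), dom = cfg$dom,
                              arousal = rowMeans(eng$sample_arousal),
                              anxiety = rowMeans(eng$sample_anxiety),
                              satisfaction =
                                rowMeans(eng$sample_satisfaction))
  run <- structure(list(config = cfg, seed = as.integer(seed),
                        events = events, rates = rates, proximity = prox,
                        like_mean = like_mean, like_final = eng$like_final,
                        emotion_means = emotion_means,
                        record_start = eng$record_start,
                        record_end = eng$record_end, n_samples = k),
                   class = "emo_run")
  if (!is.null(out_dir)) write_run_bundle(run, out_dir)
  run
}

#' @export
print.emo_run <- function(x, ...) {
  cat("<emo_run> ", x$config$variant, " model, LPS = ", x$config$lps,
      ", seed = ", x$seed, "\n", sep = "")
  cat("  ", nrow(x$events), " directed events recorded over ",
      x$record_end - x$record_start, " min (", x$n_samples,
      " samples)\n", sep = "")
  if (!is.null(x$rates)) {
    gr <- sum(x$rates$groom) / nrow(x$rates$groom)
    cat("  mean grooming given: ", format(gr, digits = 3),
        " min/h per individual\n", sep = "")
  }
  invisible(x)
}

#' Write a run bundle
#'
#' One directory per run: a CSV per dyadic measure (rows = actors, columns
#' = receivers, ids ordered by ascending dominance), a JSON summary of the
#' social-matrix statistics and a JSON config echo with the seed.
#'
#' @param run An `emo_run`.
#' @param dir Output directory (created if needed).
#' @export
write_run_bundle <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- paste0("a", seq_len(run$config$n_agents))
  wmat <- function(m, name) {
    dimnames(m) <- list(ids, ids)
    write.csv(m, file.path(dir, paste0(name, ".csv")))
  }
  if (!is.null(run$rates))
    for (b in names(run$rates)) wmat(run$rates[[b]], b)
  wmat(run$proximity, "proximity")
  wmat(run$like_mean, "like_mean")
  write_config(run$config, file.path(dir, "config.json"))
  meta <- list(seed = run$seed, variant = run$config$variant,
               lps = run$config$lps, record_start = run$record_start,
               record_end = run$record_end, n_samples = run$n_samples,
               summary = summarize_run(run))
  jsonlite::write_json(meta, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Sweep over variants and selectivity values
#'
#' The full experiment is a cross product of the attitude variants and the
#' LPS values with `replicates` independent runs each (the default design:
#' 2 variants x 5 LPS values x 10 replicates = 100 runs). Replicate seeds
#' are derived deterministically from `base_seed`; replicate `r` of every
#' condition shares a seed so paired contrasts are possible.
#'
#' @param cfg Base [run_config()]; its `variant` and `lps` are overridden.
#' @param base_seed Integer base seed.
#' @param variants Character vector of variants to run.
#' @param lps_values Numeric vector of LPS settings.
#' @param replicates Runs per condition (default from `cfg`).
#' @param out_dir Optional directory for per-run bundles plus an aggregate
#'   `sweep.json`; completed bundles (with a `summary.json`) are skipped on
#'   resume.
#' @return List with `results` (one row per run x measure) and `aggregate`
#'   (per-condition mean and SD across replicates).
#' @export
run_sweep <- function(cfg, base_seed, variants = c("dynamic", "fixed"),
                      lps_values = c(0, 0.5, 0.9, 0.95, 0.99),
                      replicates = cfg$replicates, out_dir = NULL) {
  stopifnot(base_seed + replicates < 2^31)
  rows <- list()
  for (variant in variants) {
    for (lps in lps_values) {
      for (r in seq_len(replicates)) {
        seed <- as.integer(base_seed + r - 1L)
        run_dir <- if (is.null(out_dir)) NULL else
          file.path(out_dir, sprintf("run_%s_lps%s_rep%02d", variant,
                                     format(lps), r))
        if (!is.null(run_dir) &&
            file.exists(file.path(run_dir, "summary.json"))) {
          meta <- jsonlite::read_json(file.path(run_dir, "summary.json"),
                                      simplifyVector = TRUE)
          summ <- meta$summary
        } else {
          cfg_i <- cfg
          cfg_i$variant <- variant
          cfg_i$lps <- lps
          run <- run_simulation(cfg_i, seed, out_dir = run_dir)
          summ <- summarize_run(run)
        }
        for (measure in names(summ)) {
          s <- summ[[measure]]
          rows[[length(rows) + 1L]] <- data.frame(
            variant = variant, lps = lps, rep = r, seed = seed,
            measure = measure, taukr = null_na(s$taukr),
            mean_h_star = null_na(s$mean_h_star),
            partner_specificity = null_na(s$partner_specificity),
            pearson_rankdist = null_na(s$pearson_rankdist),
            pearson_like = null_na(s$pearson_like),
            uphill_fraction = null_na(s$uphill_fraction))
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  stats_cols <- c("taukr", "mean_h_star", "partner_specificity",
                  "pearson_rankdist", "pearson_like", "uphill_fraction")
  key <- interaction(results$variant, results$lps, results$measure,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(results, key), function(d) {
    out <- d[1, c("variant", "lps", "measure")]
    for (cc in stats_cols) {
      out[[paste0(cc, "_mean")]] <- mean(d[[cc]], na.rm = TRUE)
      out[[paste0(cc, "_sd")]] <- sd(d[[cc]], na.rm = TRUE)
    }
    out
  }))
  rownames(agg) <- NULL
  if (!is.null(out_dir))
    jsonlite::write_json(list(base_seed = base_seed, aggregate = agg),
                         file.path(out_dir, "sweep.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(results = results, aggregate = agg)
}

null_na <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else
  as.numeric(x)
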