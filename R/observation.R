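#' One-zero proximity sample
#'
#' Scores every dyad 1 or 0 according to whether its members are within
#' close proximity (the interaction distance, 1 m) at the sampling instant.
#' The result is symmetric with a zero diagonal; an individual's score (row
#' sum) therefore ranges from 0 to n - 1.
#'
#' @param x,y Agent coordinates at the sampling instant.
#' @param world A [world_config()].
#' @return n x n 0/1 matrix.
#' @export
sample_proximity <- function(x, y, world = world_config()) {
  n <- length(x)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- cpp_torus_distance(x[i], y[i], x[j], y[j], world$width,
                              world$height)
      if (d <= world$interact_dist) m[i, j] <- m[j, i] <- 1
    }
  }
  m
}

#' Dyadic hourly rates over one recording interval
#'
#' Counts (or, for grooming, minutes) of each directed behaviour per dyad
#' within `[interval_start, interval_start + interval_length)`, divided by
#' the interval duration in hours. Grooming bouts are apportioned to
#' intervals by overlap, so a bout spanning an interval boundary
#' contributes to both.
#'
#' @param events Event log data.frame with columns `time`, `actor`,
#'   `receiver`, `behavior` (name or code) and `value` (bout duration in
#'   minutes for grooming, count otherwise).
#' @param interval_start Interval start, minutes.
#' @param interval_length Interval length, minutes (default one recording
#'   interval of 3.5 DAYS).
#' @param n Group size.
#' @param cal A [model_calendar()].
#' @return Named list of n x n matrices, one per directed behaviour.
#' @export
interval_rates <- function(events, interval_start,
                           interval_length = model_calendar()$sample_interval,
                           n, cal = model_calendar()) {
  hours <- interval_length / cal$minutes_per_hour
  codes <- behavior_codes()
  dyadic <- setdiff(names(codes), c("rest", "random_move"))
  beh <- events$behavior
  if (is.numeric(beh)) beh <- names(codes)[beh]
  out <- lapply(setNames(dyadic, dyadic), function(b) matrix(0, n, n))
  end <- interval_start + interval_length
  for (b in dyadic) {
    idx <- which(beh == b)
    if (!length(idx)) next
    m <- out[[b]]
    if (b == "groom") {
      s <- events$time[idx]
      e <- s + events$value[idx]
      ov <- pmin(e, end) - pmax(s, interval_start)
      keep <- which(ov > 0)
      for (k in keep)
        m[events$actor[idx[k]], events$receiver[idx[k]]] <-
          m[events$actor[idx[k]], events$receiver[idx[k]]] + ov[k]
    } else {
      keep <- which(events$time[idx] >= interval_start &
                      events$time[idx] < end)
      for (k in keep)
        m[events$actor[idx[k]], events$receiver[idx[k]]] <-
          m[events$actor[idx[k]], events$receiver[idx[k]]] +
          events$value[idx[k]]
    }
    out[[b]] <- m / hours
  }
  out
}

#' Average per-interval matrices over the recording window
#'
#' The yearly (or scaled-window) average is the arithmetic mean of the
#' per-interval values: a full YEAR of 3.5-DAY intervals gives 100 of them.
#'
#' @param mats List of equally sized matrices (one per interval).
#' @return Their element-wise mean.
#' @export
yearly_average <- function(mats) {
  stopifnot(length(mats) >= 1)
  Reduce(`+`, mats) / length(mats)
}

#' Per-individual totals of a dyadic matrix
#'
#' The individual score is the sum of all dyadic values the individual
#' directs at others (row sums, diagonal excluded).
#'
#' @param m n x n dyadic matrix.
#' @export
aggregate_individual <- function(m) {
  diag(m) <- 0
  rowSums(m)
}

#' Means per rank category and rank-distance category
#'
#' Splits the group into the lower-ranking half (subordinates) and the
#' higher-ranking half (dominants) and, separately, splits dyads into
#' similar-ranking (absolute dominance difference below the threshold) and
#' distant-ranking, then averages the matrix values per category.
#'
#' @param m n x n dyadic matrix.
#' @param doms Dominance vector (ascending).
#' @param threshold Rank-distance threshold (0.35).
#' @return List with `subordinate`/`dominant` means of individual totals
#'   and `similar`/`distant` dyadic means.
#' @export
rank_category_means <- function(m, doms, threshold = 0.35) {
  n <- length(doms)
  stopifnot(nrow(m) == n, ncol(m) == n)
  totals <- aggregate_individual(m)
  half <- n %/% 2
  lower <- order(doms)[seq_len(half)]
  upper <- setdiff(seq_len(n), lower)
  rd <- round(abs(outer(doms, doms, "-")), 9)  # fp-safe thresholding
  off <- row(m) != col(m)
  list(subordinate = mean(totals[lower]), dominant = mean(totals[upper]),
       similar = mean(m[off & rd < threshold]),
       distant = mean(m[off & rd >= threshold]))
}
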