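# Independent brute-force oracles. These deliberately do NOT share code
# with the package: tau-b from explicit pair counting, Pearson from the
# raw covariance sums.

oracle_taub <- function(x, y) {
  n <- length(x)
  nc <- nd <- 0L
  tx <- ty <- 0L
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      sx <- sign(x[b] - x[a])
      sy <- sign(y[b] - y[a])
      if (sx == 0 && sy == 0) {
        tx <- tx + 1L
        ty <- ty + 1L
      } else if (sx == 0) {
        tx <- tx + 1L
      } else if (sy == 0) {
        ty <- ty + 1L
      } else if (sx == sy) {
        nc <- nc + 1L
      } else {
        nd <- nd + 1L
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

oracle_taukr <- function(X) {
  n <- nrow(X)
  taus <- c()
  for (i in seq_len(n)) {
    out <- X[i, -i]
    inc <- X[-i, i]
    if (length(unique(out)) == 1 || length(unique(inc)) == 1) next
    taus <- c(taus, oracle_taub(out, inc))
  }
  if (!length(taus)) NA_real_ else mean(taus)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# Quick configurations. tiny: ~1.5 simulated days; desk: the scaled-down
# experiment setup (1-week burn-in, 8-week recorded window).
tiny_cfg <- function(...) {
  cal <- model_calendar()
  run_config(burn_in = 720, run_length = 2 * cal$sample_interval,
             record_window = 2 * cal$sample_interval, ...)
}
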