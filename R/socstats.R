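#' Shannon / Buzas-Gibson evenness of a partner distribution
#'
#' For one actor's row of outgoing values over its n - 1 possible partners,
#' computes the Shannon index `H = -sum(p * log(p))` (natural log,
#' `0 * log 0 = 0`) of the relative proportions and normalizes it to the
#' Buzas-Gibson evenness `H* = exp(H) / (N - 1)`, where `N` is group size.
#' `H* = 1` means the behaviour is spread perfectly evenly; values near
#' `1 / (N - 1)` mean it is restricted to a single partner.
#'
#' @param row Nonnegative vector of an actor's outgoing values towards its
#'   n - 1 partners (the actor itself excluded).
#' @return `H*`, or `NA` for an all-zero row (undefined; such individuals
#'   are excluded from group means).
#' @export
shannon_evenness <- function(row) {
  stopifnot(all(row >= 0))
  s <- sum(row)
  if (s == 0) return(NA_real_)
  p <- row / s
  p <- p[p > 0]
  h <- -sum(p * log(p))
  exp(h) / length(row)
}

#' Rowwise Kendall matrix reciprocity (Tau-Kr)
#'
#' Correlates a directed dyadic matrix with its transpose row by row: for
#' every actor `i`, Kendall's tau-b between the outgoing vector
#' `(X[i, j])` and the incoming vector `(X[j, i])`, `j != i`. Rows without
#' variation in either vector carry no ordinal information and are
#' skipped; the statistic is the unweighted mean over usable rows.
#' Positive values indicate reciprocated behaviour, negative values
#' indicate imbalance (one-way flows).
#'
#' @param X Square numeric matrix (n >= 3), diagonal ignored.
#' @param max_skip_frac If more than this fraction of rows is unusable the
#'   matrix is too sparse and `NA` is returned (with attribute
#'   `n_rows_used`).
#' @return Mean rowwise tau-b in `[-1, 1]`, with attribute `n_rows_used`.
#' @export
taukr <- function(X, max_skip_frac = 0.9) {
  n <- nrow(X)
  stopifnot(is.matrix(X), ncol(X) == n, n >= 3)
  taus <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    out <- X[i, -i]
    inc <- X[-i, i]
    if (sd(out) == 0 || sd(inc) == 0) next
    taus[i] <- cor(out, inc, method = "kendall")
  }
  used <- sum(!is.na(taus))
  res <- if (used == 0 || (n - used) / n > max_skip_frac) NA_real_ else
    mean(taus, na.rm = TRUE)
  attr(res, "n_rows_used") <- used
  res
}

#' Rank-distance dyad categories
#'
#' Splits dyads at the absolute-dominance-difference threshold: strictly
#' below it, a dyad is similar-ranking; at or above, distant-ranking. With
#' the default 20-agent hierarchy (0.05 ... 1.00, threshold 0.35) this
#' yields 99 similar and 91 distant unordered dyads, i.e. 198 and 182
#' directed ones.
#'
#' @param doms Dominance vector.
#' @param threshold Absolute rank-distance threshold (0.35).
#' @return List with data.frames `similar` and `distant` of unordered pairs
#'   (`i < j`) and the four counts (`n_similar`, `n_distant`,
#'   `n_similar_directed`, `n_distant_directed`).
#' @export
rank_distance_categorize <- function(doms, threshold = 0.35) {
  n <- length(doms)
  stopifnot(n >= 2)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  colnames(pairs) <- c("i", "j")
  # round before thresholding: dominance grids like 0.05 * k are not
  # binary-exact and |0.40 - 0.05| must count as exactly 0.35
  rd <- round(abs(doms[pairs[, "j"]] - doms[pairs[, "i"]]), 9)
  sim <- as.data.frame(pairs[rd < threshold, , drop = FALSE])
  dis <- as.data.frame(pairs[rd >= threshold, , drop = FALSE])
  list(similar = sim, distant = dis, n_similar = nrow(sim),
       n_distant = nrow(dis), n_similar_directed = 2L * nrow(sim),
       n_distant_directed = 2L * nrow(dis))
}

#' Partner-specificity: SD across dyads of equal rank distance
#'
#' Groups dyads by rank distance -- signed (`dom_j - dom_i`, directed
#' matrices) or absolute over unordered pairs (symmetric matrices) -- and
#' computes the sample standard deviation of the dyadic values within each
#' group, then averages the SDs over groups. Groups with fewer than two
#' dyads (for the default hierarchy, the single dyads at rank distance
#' -0.95 and +0.95) are excluded since no SD exists there. A measure fully
#' determined by rank distance (e.g. the fixed-attitude LIKE matrix) gives
#' exactly zero; individualized relationships give positive values.
#'
#' @param X n x n dyadic matrix.
#' @param doms Dominance vector.
#' @param directed Use signed rank distance over ordered dyads (TRUE) or
#'   absolute rank distance over unordered dyads (FALSE).
#' @return Mean within-group SD.
#' @export
partner_specificity_sd <- function(X, doms, directed = TRUE) {
  n <- length(doms)
  stopifnot(nrow(X) == n, ncol(X) == n)
  if (directed) {
    idx <- which(row(X) != col(X), arr.ind = TRUE)
    vals <- X[idx]
    rd <- doms[idx[, 2]] - doms[idx[, 1]]
  } else {
    idx <- which(upper.tri(X), arr.ind = TRUE)
    vals <- X[idx]
    rd <- abs(doms[idx[, 2]] - doms[idx[, 1]])
  }
  grp <- factor(round(rd, 9))
  sds <- tapply(vals, grp, function(v) if (length(v) >= 2) sd(v) else
    NA_real_)
  mean(sds, na.rm = TRUE)
}

#' Rowwise Pearson predictability
#'
#' How well a predictor matrix (absolute rank distance or LIKE attitudes)
#' accounts for a behavioural matrix: the Pearson correlation between the
#' matrices is computed row by row (diagonal excluded), rows lacking
#' variance in either vector are skipped, the usable per-row coefficients
#' are pooled with a Fisher-z mean, and the absolute value of the pooled
#' coefficient is reported.
#'
#' @param X Behavioural n x n matrix.
#' @param P Predictor n x n matrix.
#' @return Absolute pooled rowwise correlation, with attribute
#'   `n_rows_used`; `NA` when no row is usable.
#' @export
rowwise_pearson <- function(X, P) {
  n <- nrow(X)
  stopifnot(ncol(X) == n, nrow(P) == n, ncol(P) == n)
  rs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- X[i, -i]
    b <- P[i, -i]
    if (sd(a) == 0 || sd(b) == 0) next
    rs[i] <- cor(a, b)
  }
  used <- sum(!is.na(rs))
  res <- if (used == 0) NA_real_ else abs(fisher_z_mean(rs[!is.na(rs)]))
  attr(res, "n_rows_used") <- used
  res
}

#' Fisher-z pooled mean of correlation coefficients
#'
#' `tanh(mean(atanh(r)))`; inputs are clipped just inside the open interval
#' (-1, 1) (with a warning) because `atanh(+-1)` is infinite.
#'
#' @param rs Vector of correlation coefficients.
#' @export
fisher_z_mean <- function(rs) {
  stopifnot(length(rs) >= 1, all(is.finite(rs)))
  lim <- 1 - 1e-12
  if (any(abs(rs) > lim)) {
    warning("correlations at +-1 clipped for the Fisher-z transform")
    rs <- pmin(lim, pmax(-lim, rs))
  }
  tanh(mean(atanh(rs)))
}

#' Fraction of a directed behaviour flowing up the hierarchy
#'
#' The share of the matrix total contributed by actors whose dominance is
#' below their receiver's. Submissive behaviour in a stable hierarchy is
#' expected to flow almost exclusively up (values near 1).
#'
#' @param X Directed n x n matrix of counts or rates.
#' @param doms Dominance vector.
#' @return Fraction in `[0, 1]`, or `NA` for an all-zero matrix.
#' @export
uphill_fraction <- function(X, doms) {
  n <- length(doms)
  stopifnot(nrow(X) == n, ncol(X) == n)
  diag(X) <- 0
  tot <- sum(X)
  if (tot == 0) return(NA_real_)
  up <- doms[row(X)] < doms[col(X)]
  sum(X[up]) / tot
}

#' Social-matrix summary of one run
#'
#' Applies the full statistics battery to a run's yearly-averaged
#' matrices: Tau-Kr reciprocity, group-mean Buzas-Gibson evenness,
#' partner-specificity SD, and rowwise Pearson predictability against
#' absolute rank distance and against the mean LIKE matrix.
#'
#' @param run An `emo_run` from [run_simulation()].
#' @return Nested list, one entry per dyadic measure.
#' @export
summarize_run <- function(run) {
  doms <- run$config$dom
  rdist <- abs(outer(doms, doms, "-"))
  mats <- c(run$rates, list(proximity = run$proximity, like = run$like_mean))
  lapply(mats, function(m) {
    hs <- vapply(seq_len(nrow(m)), function(i) shannon_evenness(m[i, -i]),
                 numeric(1))
    tk <- taukr(m)
    list(taukr = as.numeric(tk), taukr_rows_used = attr(tk, "n_rows_used"),
         mean_h_star = if (all(is.na(hs))) NA_real_ else mean(hs,
                                                              na.rm = TRUE),
         partner_specificity = partner_specificity_sd(m, doms),
         pearson_rankdist = as.numeric(rowwise_pearson(m, rdist)),
         pearson_like = as.numeric(rowwise_pearson(m, run$like_mean)),
         uphill_fraction = uphill_fraction(m, doms))
  })
}
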