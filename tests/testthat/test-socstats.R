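test_that("evenness: uniform, single-partner, two-partner cases", {
  expect_equal(shannon_evenness(rep(1 / 19, 19)), 1)
  expect_equal(shannon_evenness(c(5, rep(0, 18))), 1 / 19)
  expect_equal(shannon_evenness(c(0.5, 0.5, rep(0, 17))), 2 / 19)
  expect_true(is.na(shannon_evenness(rep(0, 19))))
  # scale invariance
  expect_equal(shannon_evenness(c(1, 2, 3)), shannon_evenness(c(2, 4, 6)))
})

test_that("evenness: permutation-invariant, uniquely maximal at uniform", {
  set.seed(3)
  for (k in seq_len(50)) {
    v <- runif(19)
    expect_equal(shannon_evenness(v), shannon_evenness(sample(v)))
    if (sd(v) > 1e-6) expect_lt(shannon_evenness(v), 1)
  }
  # agrees with an independent Shannon implementation
  skip_if_not_installed("vegan")
  for (k in seq_len(20)) {
    v <- runif(19)
    expect_equal(shannon_evenness(v),
                 exp(vegan::diversity(v, index = "shannon")) / 19)
  }
})

test_that("Tau-Kr: perfect reciprocity, perfect imbalance, fixed case", {
  sym <- matrix(0, 4, 4)
  sym[upper.tri(sym)] <- c(1, 2, 3, 4, 5, 6)
  sym <- sym + t(sym)
  expect_equal(as.numeric(taukr(sym)), 1)

  # X[i, j] = 10 + j - i: each outgoing row is ordered opposite to the
  # incoming column, so every rowwise tau is -1
  anti <- 10 + outer(1:4, 1:4, function(i, j) j - i)
  diag(anti) <- 0
  expect_equal(as.numeric(taukr(anti)), -1)
  expect_equal(oracle_taukr(anti), -1)

  fixed <- rbind(c(0, 3, 1, 2),
                 c(2, 0, 3, 1),
                 c(1, 2, 0, 3),
                 c(3, 1, 2, 0))
  expect_equal(as.numeric(taukr(fixed)), oracle_taukr(fixed))
})

test_that("Tau-Kr equals the pair-counting oracle on random matrices", {
  set.seed(17)
  for (k in seq_len(100)) {
    X <- matrix(sample.int(4, 25, replace = TRUE), 5, 5)
    diag(X) <- 0
    got <- taukr(X)
    want <- oracle_taukr(X)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      expect_equal(as.numeric(got), want, tolerance = 1e-12)
    }
    # transposition symmetry
    expect_equal(as.numeric(taukr(X)), as.numeric(taukr(t(X))))
  }
})

test_that("Tau-Kr flags sparse matrices as undefined", {
  X <- matrix(0, 6, 6)
  X[1, 2] <- 1  # only row 1 has variance out, only row 2 in
  expect_true(is.na(taukr(X)))
})

test_that("rank-distance categories reproduce the printed dyad counts", {
  doms <- seq(0.05, 1, by = 0.05)
  rc <- rank_distance_categorize(doms, 0.35)
  expect_equal(rc$n_similar, 99)
  expect_equal(rc$n_distant, 91)
  expect_equal(rc$n_similar_directed, 198)
  expect_equal(rc$n_distant_directed, 182)
  expect_equal(rc$n_similar + rc$n_distant, choose(20, 2))
  rc2 <- rank_distance_categorize(c(0.3, 0.8), 0.35)
  expect_equal(rc2$n_similar, 0)
  expect_equal(rc2$n_distant, 1)
})

test_that("partner-specificity SD: zero for rank-determined measures", {
  doms <- seq(0.05, 1, by = 0.05)
  expect_equal(partner_specificity_sd(fixed_like_matrix(doms), doms), 0)
  expect_equal(partner_specificity_sd(matrix(7, 20, 20), doms), 0)
})

test_that("partner-specificity SD: toy case against a direct oracle", {
  doms <- c(0.2, 0.4, 0.6, 0.8)
  X <- matrix(0, 4, 4)
  X[1, 2] <- 5  # one deviating dyad in the +0.2 class
  X[2, 3] <- 1
  X[3, 4] <- 1
  # directed groups by signed distance with >= 2 dyads:
  # +0.2: {5,1,1}, -0.2: {0,0,0}, +0.4: {0,0}, -0.4: {0,0}
  want <- mean(c(sd(c(5, 1, 1)), 0, 0, 0))
  expect_equal(partner_specificity_sd(X, doms), want)
  # shift invariance and linear scaling
  off <- row(X) != col(X)
  Y <- X
  Y[off] <- X[off] + 3
  expect_equal(partner_specificity_sd(Y, doms),
               partner_specificity_sd(X, doms))
  expect_equal(partner_specificity_sd(2 * X, doms),
               2 * partner_specificity_sd(X, doms))
})

test_that("rowwise Pearson: identity, affine invariance, oracle", {
  set.seed(29)
  X <- matrix(runif(16), 4, 4)
  # self-correlation hits r = 1 exactly, which the Fisher-z pooling clips
  # with a warning by design
  expect_warning(r_self <- rowwise_pearson(X, X), "clipped")
  expect_equal(as.numeric(r_self), 1)
  expect_warning(r_aff <- rowwise_pearson(X, 2 + 3 * X), "clipped")
  expect_equal(as.numeric(r_aff), 1)
  P <- matrix(runif(16), 4, 4)
  rs <- vapply(1:4, function(i) oracle_pearson(X[i, -i], P[i, -i]),
               numeric(1))
  want <- abs(tanh(mean(atanh(rs))))
  expect_equal(as.numeric(rowwise_pearson(X, P)), want, tolerance = 1e-12)
  # rows without variance are skipped
  X2 <- X
  X2[2, ] <- 1
  got <- rowwise_pearson(X2, P)
  expect_equal(attr(got, "n_rows_used"), 3)
})

test_that("Fisher-z pooling: fixed point, antisymmetry, closed form", {
  expect_equal(fisher_z_mean(c(0.4, 0.4, 0.4)), 0.4)
  expect_equal(fisher_z_mean(c(-0.7, 0.7)), 0)
  expect_equal(fisher_z_mean(c(0.5, 0.8)),
               tanh((atanh(0.5) + atanh(0.8)) / 2), tolerance = 1e-12)
  expect_warning(fisher_z_mean(c(1, 0.5)), "clipped")
})

test_that("uphill fraction identifies direction of flow", {
  doms <- c(0.2, 0.5, 0.8)
  up <- matrix(0, 3, 3)
  up[1, 2] <- up[1, 3] <- up[2, 3] <- 1
  expect_equal(uphill_fraction(up, doms), 1)
  expect_equal(uphill_fraction(t(up), doms), 0)
  expect_true(is.na(uphill_fraction(matrix(0, 3, 3), doms)))
})
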