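test_that("FEAR is the dominance difference, spanning +-0.95", {
  expect_equal(fear(0.05, 1.0), 0.95)
  expect_equal(fear(1.0, 0.05), -0.95)
  expect_equal(fear(0.4, 0.4), 0)
  doms <- seq(0.05, 1, by = 0.05)
  Fm <- fear_matrix(doms)
  expect_equal(Fm, -t(Fm))                      # antisymmetric
  expect_equal(range(Fm), c(-0.95, 0.95))
  # stored matrix is consistent with the elementwise definition
  expect_equal(Fm[3, 17], fear(doms[3], doms[17]))
})

test_that("fixed LIKE: peak, slope, floor, symmetry", {
  expect_equal(fixed_like(0.5, 0.5), 0.243)
  expect_equal(fixed_like(0.2, 0.4), 0.171)     # 0.243 - 0.36 * 0.2
  expect_equal(fixed_like(0.05, 0.725), 0)      # floor at |dd| = 0.675
  expect_equal(fixed_like(0.1, 0.9), fixed_like(0.9, 0.1))
  m <- fixed_like_matrix(seq(0.05, 1, by = 0.05))
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 0.243))
})

test_that("LIKE update: fixed point, decay arithmetic, floor branch", {
  expect_equal(update_like(0.5, 0.5, dt = 123), 0.5)
  expect_equal(update_like(0.8, 0, dt = 720, lhw = 720), 0.4)
  expect_equal(update_like(0.2, 0.9, dt = 5), 0.9)   # max() branch
  expect_equal(update_like(0.2, 0.9, dt = 0), 0.9)
  expect_equal(update_like(0.9, 0.2, dt = 0), 0.9)   # identity at dt = 0
  expect_error(update_like(0.5, 0.5, dt = -1), "scheduling bug")
})

test_that("LIKE update properties: monotone decay towards PARTNER_SAT", {
  set.seed(31)
  for (k in seq_len(200)) {
    lp <- runif(1)
    ps <- runif(1)
    dt <- runif(1, 0, 2000)
    got <- update_like(lp, ps, dt)
    expect_gte(got, min(lp, ps))
    expect_lte(got, max(lp, ps))
    if (ps >= lp) expect_identical(got, ps)
  }
  # strictly decreasing in dt when psat < like, with limit psat
  dts <- c(1, 10, 100, 1000, 1e6)
  vals <- update_like(rep(0.8, 5), rep(0.1, 5), dts)
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[5], 0.1, tolerance = 1e-2)
})

test_that("LIKE update: subdivision discrepancy is bounded", {
  # the update is written for arbitrary (t_{n-1}, t_n]; under a constant
  # PARTNER_SAT it is only approximately divisible, so the engine applies
  # it at every state advance. The discrepancy between one step over d1+d2
  # and two chained steps stays small relative to the state scale.
  worst <- 0
  for (lp in c(0, 0.3, 0.8, 1)) {
    for (ps in c(0, 0.4, 1)) {
      for (d1 in c(30, 360, 720)) {
        for (d2 in c(30, 360, 720)) {
          one <- update_like(lp, ps, d1 + d2)
          two <- update_like(update_like(lp, ps, d1), ps, d2)
          worst <- max(worst, abs(one - two))
        }
      }
    }
  }
  # analytic worst case for substeps up to LHW: |1/3 - 1/4| = 1/12 at
  # like_prev - psat = 1 and d1 = d2 = lhw
  expect_lt(worst, 0.1)
  expect_equal(worst, 1 / 12, tolerance = 1e-9)
})

test_that("satisfaction kinetics: printed rates, full decay, clamping", {
  s <- emotional_state(satisfaction = 0)
  expect_equal(tick_satisfaction(s, "groomee", dt = 5)$satisfaction, 0.5)
  expect_equal(tick_satisfaction(s, "groomer", dt = 5)$satisfaction, 0.25)
  s1 <- emotional_state(satisfaction = 1)
  expect_equal(tick_satisfaction(s1, "none", dt = 50)$satisfaction, 0)
  expect_equal(tick_satisfaction(s1, "none", dt = 500)$satisfaction, 0)
  s2 <- emotional_state(satisfaction = 0.98)
  expect_equal(tick_satisfaction(s2, "groomer", dt = 1)$satisfaction, 1)
})

test_that("partner-specific satisfaction: exclusive credit, decay", {
  p <- matrix(0, 4, 4)
  p2 <- tick_partner_sat(p, receiver_id = 1, groomer_id = 3, dt = 3)
  expect_equal(p2[1, 3], 0.3)
  expect_equal(p2[1, c(2, 4)], c(0, 0))   # non-groomers unaffected
  expect_equal(p2[2, ], rep(0, 4))        # other receivers untouched
  p3 <- matrix(0.15, 4, 4)
  p4 <- tick_partner_sat(p3, 2, NA, dt = 10)
  expect_equal(p4[2, -2], rep(0, 3))      # clamped decay
})

test_that("event salience moves arousal/anxiety with clamping", {
  s <- emotional_state(arousal = 0.2, anxiety = 0.2)
  hit <- apply_event(s, "receive_attack")
  expect_gt(hit$arousal, s$arousal)
  expect_gt(hit$anxiety, s$anxiety)
  calm <- apply_event(s, "receive_submissive_signal")
  expect_lt(calm$arousal, s$arousal)
  expect_lt(calm$anxiety, s$anxiety)
  top <- apply_event(emotional_state(anxiety = 1), "receive_attack")
  expect_equal(top$anxiety, 1)
  expect_error(apply_event(s, "sneeze"), "unknown event kind")
})

test_that("salience validation enforces the sign structure", {
  expect_silent(validate_salience(default_salience_table()))
  bad <- default_salience_table()
  bad["receive_attack", "d_anxiety"] <- -0.1
  expect_error(validate_salience(bad), "raise anxiety")
  bad2 <- default_salience_table()
  bad2["receive_affiliative_signal", "d_arousal"] <- 0.2
  expect_error(validate_salience(bad2))
})

test_that("relaxation towards a limit: identity, convergence, semigroup", {
  expect_equal(relax_toward_limit(0.09, 0.09, 10), 0.09)
  expect_equal(relax_toward_limit(0.9, 0.09, 1e6), 0.09)
  two_steps <- relax_toward_limit(relax_toward_limit(0.5, 0.09, 1), 0.09, 1)
  expect_equal(two_steps, relax_toward_limit(0.5, 0.09, 2))
  # monotone approach from both sides
  expect_lt(relax_toward_limit(0.5, 0.09, 1), 0.5)
  expect_gt(relax_toward_limit(0.01, 0.09, 1), 0.01)
})

test_that("scanning probability is monotone in arousal and clamped", {
  expect_equal(scan_probability(0), affect_params()$scan_base)
  expect_gte(scan_probability(0.9), scan_probability(0.1))
  hot <- affect_params(scan_base = 0.9, scan_gain = 5)
  expect_equal(scan_probability(1, hot), 1)
})

test_that("emotional state stays in [0,1] under random event sequences", {
  set.seed(47)
  kinds <- rownames(default_salience_table())
  s <- emotional_state()
  for (k in seq_len(500)) {
    u <- runif(1)
    if (u < 0.5) {
      s <- apply_event(s, sample(kinds, 1))
    } else if (u < 0.8) {
      s <- tick_satisfaction(s, sample(c("none", "groomer", "groomee"), 1),
                             runif(1, 0, 30))
    } else {
      s$arousal <- relax_toward_limit(s$arousal, s$arousal_limit,
                                      runif(1, 0, 60))
    }
    vals <- unlist(s[c("arousal", "anxiety", "satisfaction")])
    expect_true(all(vals >= 0 & vals <= 1))
  }
})
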