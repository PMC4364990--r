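test_that("group initialization matches the stated start conditions", {
  cfg <- run_config()
  set.seed(1)
  g <- init_group(cfg)
  ctr <- c(cfg$world$width / 2, cfg$world$height / 2)
  d <- sqrt((g$pos[, 1] - ctr[1])^2 + (g$pos[, 2] - ctr[2])^2)
  expect_true(all(d <= 25))                      # 50 m-diameter disc
  expect_true(all(g$heading >= 1 & g$heading <= 360))
  expect_true(all(g$t0 > 0))
  expect_equal(mean(replicate(200, mean(init_group(cfg)$t0))), 1,
               tolerance = 0.01)
  expect_true(all(g$like == 0))                  # dynamic: LIKE starts at 0
  set.seed(1)
  gf <- init_group(run_config(variant = "fixed"))
  expect_equal(gf$like, fixed_like_matrix(cfg$dom))
  expect_equal(gf$fear, fear_matrix(cfg$dom))
})

test_that("runs are deterministic and correctly windowed", {
  cfg <- tiny_cfg()
  r1 <- run_simulation(cfg, 5)
  r2 <- run_simulation(cfg, 5)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$rates, r2$rates)
  expect_identical(r1$like_mean, r2$like_mean)
  r3 <- run_simulation(cfg, 6)
  expect_false(identical(r1$events, r3$events))
  expect_equal(r1$record_end - r1$record_start, cfg$record_window)
  expect_equal(r1$n_samples, 2)
})

test_that("the event stream respects time order and distance gating", {
  run <- run_simulation(tiny_cfg(), 21)
  ev <- run$events
  inst <- ev[ev$behavior != "groom", ]   # grooms are logged at bout end
  expect_true(all(diff(inst$time) >= 0))
  expect_true(all(ev$actor != ev$receiver))
  w <- run$config$world
  contact <- ev$behavior %in% c("groom", "leave", "attack")
  expect_true(all(ev$dist[contact] <= w$interact_dist))
  signals <- ev$behavior %in% c("affiliative_signal", "submissive_signal",
                                "aggressive_signal", "avoid")
  expect_true(all(ev$dist[signals] <= w$pers_dist))
  expect_true(all(ev$dist[ev$behavior == "approach"] <= w$max_dist))
  # grooming bouts have positive duration and plausible lengths
  gr <- ev[ev$behavior == "groom", ]
  expect_true(all(gr$value > 0))
  expect_true(all(gr$value <= run$config$behavior$bout_max + 1e-9))
})

test_that("LIKE stays in [0,1] and only the dynamic variant updates it", {
  cfg <- tiny_cfg()
  r <- run_simulation(cfg, 8)
  expect_true(all(r$like_mean >= 0 & r$like_mean <= 1))
  expect_true(any(r$like_final > 0))             # bookkeeping happened
  cfgf <- tiny_cfg(variant = "fixed")
  rf <- run_simulation(cfgf, 8)
  expect_equal(rf$like_final, fixed_like_matrix(cfg$dom))
  expect_equal(rf$like_mean, fixed_like_matrix(cfg$dom))
})

test_that("crediting given grooming widens LIKE without touching events", {
  cfg <- tiny_cfg()                      # dynamic, lps = 0
  cfg2 <- tiny_cfg(affect = affect_params(like_credit_given = TRUE))
  a <- run_simulation(cfg, 14)
  b <- run_simulation(cfg2, 14)
  expect_identical(a$events, b$events)   # bookkeeping consumes no RNG
  expect_true(all(b$like_final >= a$like_final - 1e-12))
  expect_gt(sum(b$like_final), sum(a$like_final))
})

test_that("run bundles round-trip through disk", {
  dir <- tempfile("bundle")
  run <- suppressWarnings(run_simulation(tiny_cfg(), 4, out_dir = dir))
  expect_true(file.exists(file.path(dir, "groom.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  m <- as.matrix(read.csv(file.path(dir, "groom.csv"), row.names = 1))
  expect_equal(unname(m), unname(run$rates$groom), tolerance = 1e-12)
  meta <- jsonlite::read_json(file.path(dir, "summary.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$seed, 4)
  expect_true("groom" %in% names(meta$summary))
  unlink(dir, recursive = TRUE)
})

test_that("sweeps cover the design grid with derived seeds", {
  cfg <- tiny_cfg(replicates = 2)
  sw <- suppressWarnings(run_sweep(cfg, base_seed = 100,
                                   variants = "dynamic",
                                   lps_values = c(0, 0.9), replicates = 2))
  res <- sw$results
  expect_setequal(unique(res$lps), c(0, 0.9))
  expect_equal(sort(unique(res$seed)), c(100, 101))
  expect_equal(nrow(sw$aggregate), 2 * length(unique(res$measure)))
  expect_true(all(c("taukr_mean", "taukr_sd") %in% names(sw$aggregate)))
})

test_that("the CLI validates, runs and recomputes statistics", {
  cfgf <- tempfile(fileext = ".json")
  write_config(tiny_cfg(), cfgf)
  expect_message(emosim_cli(c("validate", "--config", cfgf)), "config OK")
  dir <- tempfile("clirun")
  out <- tempfile(fileext = ".json")
  suppressWarnings(
    expect_output(emosim_cli(c("run", "--config", cfgf, "--seed", "2",
                               "--out", dir)), "emo_run"))
  suppressWarnings(emosim_cli(c("stats", "--matrices", dir, "--out", out)))
  s <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_true(all(c("groom", "attack", "proximity") %in% names(s)))
  expect_error(emosim_cli(c("run", "--config", cfgf)), "--seed")
  unlink(c(cfgf, out))
  unlink(dir, recursive = TRUE)
})
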