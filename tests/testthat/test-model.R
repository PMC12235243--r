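test_that("growth rate follows the senescence sigmoid", {
  bm <- bm_fixture()
  # half-maximal rate at cPDL = K_50
  expect_equal(growth_rate(bm, 29.2), 1.40e-2, tolerance = 1e-12)
  # naive rate at cPDL = 0, frozen from scalar evaluation
  expect_equal(growth_rate(bm, 0), 0.0271824382848, tolerance = 1e-9)
  # K_sr = 0 collapses the sigmoid to mu_m / 2 at any cPDL
  flat <- cell_source_params(3e-2, 0, 10)
  expect_equal(growth_rate(flat, c(0, 5, 100)), rep(1.5e-2, 3))
  expect_error(growth_rate(bm, -1), "cPDL")
})

test_that("growth rate decreases strictly with cPDL when K_sr > 0", {
  set.seed(42)
  for (i in 1:20) {
    p <- cell_source_params(runif(1, 0.01, 0.05), runif(1, 0.05, 0.5),
                            runif(1, 10, 60))
    mu <- growth_rate(p, seq(0, 80, by = 0.5))
    expect_true(all(diff(mu) < 0))
    expect_true(all(mu > 0 & mu < p$mu_m))
  }
})

test_that("single cultivation grows exponentially after 1-day attachment, capped at Xm", {
  expect_equal(growth_hours(4), 72)
  expect_error(growth_hours(1), "th")
  # zero growth leaves the seeding density unchanged
  expect_equal(single_cultivation(5e3, 0, th = 4, Xm = 6.41e4), 5e3)
  # uncapped value frozen from scalar evaluation: 5e3 * exp(1e-2 * 48)
  expect_equal(single_cultivation(5e3, 1.0e-2, th = 3, Xm = 6.41e4),
               8080.37201096, tolerance = 1e-9)
  # contact inhibition caps the harvest
  expect_equal(single_cultivation(5e3, 3.6e-2, th = 4, Xm = 6.41e4), 6.41e4)
  expect_error(single_cultivation(5e3, 1e-2, th = 0.5, Xm = 6.41e4), "th")
  expect_error(single_cultivation(5e3, -1e-3, th = 4, Xm = 6.41e4), "mu")
})

test_that("cPDL accumulates log2 doublings", {
  expect_equal(update_cpdl(0, 1.0e4, 5.0e3), list(PDL = 1.0, cPDL = 1.0))
  expect_equal(update_cpdl(10, 5.0e3, 5.0e3), list(PDL = 0.0, cPDL = 10.0))
  u <- update_cpdl(0, 6.41e4, 5.0e3)
  expect_equal(u$PDL, 3.68032435684, tolerance = 1e-9)
  expect_equal(u$cPDL, u$PDL)
  expect_error(update_cpdl(0, 4.9e3, 5.0e3), "Xh")
})

test_that("flask count scales out with harvest and is capped by the stock", {
  expect_identical(update_flasks(1, 6.41e4, 5.0e3, 10), 10)
  expect_identical(update_flasks(1, 5.0e3, 5.0e3, 10), 1)
  expect_identical(update_flasks(3, 1.0e4, 5.0e3, 10), 6)
  expect_error(update_flasks(0, 1e4, 5e3, 10), "nflask")
})

test_that("quality indicators combine the final passage state", {
  bm <- bm_fixture()
  cfg <- small_config()
  st <- list(Xh = 6.41e4, nflask = 10)
  qi <- quality_indicators(st, mu_next = growth_rate(bm, 0), bm, cfg)
  expect_equal(qi$P_sene, 1.0)
  expect_equal(qi$P_conf, 1.0)
  expect_equal(qi$N_cell, 1102520000)
})

test_that("deterministic chain matches an independent reference loop on a Np x th grid", {
  bm <- bm_fixture()
  uc <- uc_fixture()
  cfg <- small_config()
  for (p in list(bm, uc)) {
    for (Np in 1:5) {
      for (th in c(2.5, 3, 3.5, 4, 4.5)) {
        run <- run_passage_culture(p, cfg, Np, th)
        ref <- oracle_chain(p$mu_m, p$K_sr, p$K_50, Np, th)
        expect_equal(run$qi$P_sene, ref$P_sene, tolerance = 1e-12)
        expect_equal(run$qi$P_conf, ref$P_conf, tolerance = 1e-12)
        expect_equal(run$qi$N_cell, ref$N_cell, tolerance = 1e-12)
        expect_equal(run$trajectory$cPDL[Np], ref$cPDL, tolerance = 1e-12)
        expect_equal(run$trajectory$mu, ref$mus, tolerance = 1e-12)
        expect_identical(run$trajectory$nflask[Np], as.integer(ref$nflask))
      }
    }
  }
})

test_that("trajectories respect the physical invariants", {
  cfg <- small_config()
  for (p in list(bm_fixture(), uc_fixture())) {
    for (th in c(2.5, 3.5, 5)) {
      run <- run_passage_culture(p, cfg, Np = 12, th = th)
      tr <- run$trajectory
      expect_true(all(tr$Xh <= cfg$X_m + 1e-9))
      expect_true(all(tr$Xh > cfg$X_s))
      expect_true(all(diff(tr$cPDL) >= 0))
      expect_true(all(diff(tr$nflask) >= 0))
      expect_true(all(tr$nflask <= cfg$n_flask_max))
      expect_lte(run$qi$P_sene, 1)
    }
  }
})

test_that("deterministic senescence level falls with passage number and cPDL rises with th", {
  bm <- bm_fixture()
  cfg <- small_config()
  psene <- sapply(1:10, function(np)
    run_passage_culture(bm, cfg, np, 4)$qi$P_sene)
  expect_true(all(diff(psene) < 0))
  cpdl <- sapply(seq(2.5, 5, 0.5), function(th) {
    run <- run_passage_culture(bm, cfg, 5, th)
    run$trajectory$cPDL[5]
  })
  expect_true(all(diff(cpdl) >= 0))
})

test_that("a zero noise stream reproduces the deterministic run bit for bit", {
  bm <- bm_fixture()
  cfg <- small_config()
  a <- run_passage_culture(bm, cfg, 6, 3.75)
  b <- run_passage_culture(bm, cfg, 6, 3.75, noise_stream = rep(0, 7))
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$qi, b$qi)
  expect_error(run_passage_culture(bm, cfg, 6, 3.75, noise_stream = rep(0, 6)),
               "Np \\+ 1")
})

test_that("total process time is passages times harvesting time", {
  expect_equal(total_process_time(3, 3.5), 10.5)
  expect_equal(total_process_time(3, 3), 9)
})
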