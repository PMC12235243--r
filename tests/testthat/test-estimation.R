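make_clean_obs <- function(params, cPDL = seq(0, 45, by = 5),
                           sample_id = "s1") {
  data.frame(sample_id = sample_id,
             passage = seq_along(cPDL),
             cPDL = cPDL,
             mu_exp = growth_rate(params, cPDL))
}

test_that("nrmse is range-normalised RMSE in percent", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(0.02, 0.04), c(0.03, 0.03)), 50)
  # constant offset: 100 * |c| / range
  obs <- c(0.01, 0.02, 0.05)
  expect_equal(nrmse(obs, obs + 0.004), 100 * 0.004 / 0.04)
  # scale-aware: common rescaling leaves it unchanged
  pred <- c(0.012, 0.019, 0.048)
  expect_equal(nrmse(obs * 3, pred * 3), nrmse(obs, pred))
  expect_error(nrmse(c(1, 1), c(1, 2)), "range")
  expect_error(nrmse(1:3, 1:4), "length")
})

test_that("noise-free observations recover the generating parameters", {
  bm <- bm_fixture()
  fit <- fit_passage_model(make_clean_obs(bm))
  expect_equal(fit$params$mu_m, bm$mu_m, tolerance = 1e-6)
  expect_equal(fit$params$K_sr, bm$K_sr, tolerance = 1e-6)
  expect_equal(fit$params$K_50, bm$K_50, tolerance = 1e-6)
  expect_lt(fit$nrmse_fit, 1e-4)
})

test_that("the fit matches a brute-force grid-search oracle on noisy data", {
  bm <- bm_fixture()
  synth <- generate_experiment(bm, process_config(), n_samples = 2,
                               n_passages = 15, seed = 101)
  obs <- synth$observations
  fit <- fit_passage_model(obs)
  ref <- grid_fit_oracle(obs)
  # the continuous optimum can only improve on the dense grid optimum
  expect_lte(fit$rss, ref$rss + 1e-12)
  # and must sit within one grid step of the grid argmin
  expect_lt(abs(fit$params$mu_m - ref$mu_m), 2.5e-4)
  expect_lt(abs(fit$params$K_sr - ref$K_sr), 5e-3)
  expect_lt(abs(fit$params$K_50 - ref$K_50), 0.25)
})

test_that("fit is invariant to observation order and to duplicating samples", {
  bm <- bm_fixture()
  synth <- generate_experiment(bm, process_config(), n_samples = 1,
                               n_passages = 15, seed = 11)
  obs <- synth$observations
  f1 <- fit_passage_model(obs)
  f2 <- fit_passage_model(obs[sample(nrow(obs)), ])
  expect_equal(f1$params$mu_m, f2$params$mu_m, tolerance = 1e-8)
  expect_equal(f1$params$K_50, f2$params$K_50, tolerance = 1e-7)
  dup <- rbind(obs, transform(obs, sample_id = "copy"))
  f3 <- fit_passage_model(dup)
  expect_equal(f3$params$mu_m, f1$params$mu_m, tolerance = 1e-6)
  expect_equal(f3$params$K_sr, f1$params$K_sr, tolerance = 1e-4)
  expect_equal(f3$rss, 2 * f1$rss, tolerance = 1e-6)
})

test_that("fitted RSS never exceeds the RSS of the generating parameters", {
  bm <- bm_fixture()
  synth <- generate_experiment(bm, process_config(), n_samples = 3,
                               n_passages = 15, seed = 5)
  obs <- synth$observations
  fit <- fit_passage_model(obs)
  rss_truth <- sum((obs$mu_exp - growth_rate(bm, obs$cPDL))^2)
  expect_lte(fit$rss, rss_truth)
})

test_that("degenerate flat data trigger a flat-fit warning", {
  obs <- data.frame(sample_id = "s", passage = 1:5, cPDL = seq(0, 20, 5),
                    mu_exp = rep(0.02, 5))
  expect_warning(try(fit_passage_model(obs), silent = TRUE), "flat")
})

test_that("pooled SD averages per-passage sample SDs", {
  obs <- rbind(make_clean_obs(bm_fixture(), sample_id = "a"),
               make_clean_obs(bm_fixture(), sample_id = "b"))
  expect_equal(pooled_sd(obs), 0)
  # two samples offset by a constant d: SD at every passage is d / sqrt(2)
  obs2 <- obs
  obs2$mu_exp[obs2$sample_id == "b"] <-
    obs2$mu_exp[obs2$sample_id == "b"] + 2e-3
  expect_equal(pooled_sd(obs2), 2e-3 / sqrt(2))
  expect_error(pooled_sd(make_clean_obs(bm_fixture())), "single observation")
})

test_that("pooled SD of triplicate normals matches the c4-corrected expectation", {
  # sample SD of n = 3 normals has mean sigma * c4,
  # c4(n) = sqrt(2/(n-1)) * gamma(n/2) / gamma((n-1)/2) = 0.8862 for n = 3
  sigma <- 1.8e-3
  c4 <- sqrt(2 / 2) * gamma(3 / 2) / gamma(2 / 2)
  set.seed(99)
  n_pass <- 4000
  obs <- data.frame(
    sample_id = rep(c("a", "b", "c"), each = n_pass),
    passage = rep(seq_len(n_pass), 3),
    cPDL = rep(seq_len(n_pass), 3) * 0.1,
    mu_exp = 0.02 + rnorm(3 * n_pass, 0, sigma))
  expect_equal(pooled_sd(obs), sigma * c4, tolerance = 0.02)
})

test_that("rotating hold-one-out validation is exact on noise-free triplicates", {
  bm <- bm_fixture(sd_e = 0)
  synth <- generate_experiment(bm, process_config(), n_samples = 3,
                               n_passages = 15, seed = 1)
  cv <- cross_validate(synth$observations, process_config(), th_exp = 4)
  expect_equal(cv$params$mu_m, bm$mu_m, tolerance = 1e-5)
  expect_equal(cv$params$K_sr, bm$K_sr, tolerance = 1e-4)
  expect_equal(cv$params$K_50, bm$K_50, tolerance = 1e-4)
  expect_true(all(cv$folds$nrmse_val < 1e-3))
})

test_that("cross-validation mean is invariant to sample order", {
  bm <- bm_fixture()
  synth <- generate_experiment(bm, process_config(), seed = 21)
  obs <- synth$observations
  cv1 <- cross_validate(obs, process_config())
  perm <- obs[order(rev(obs$sample_id), obs$passage), ]
  cv2 <- cross_validate(perm, process_config())
  expect_equal(cv1$params$mu_m, cv2$params$mu_m, tolerance = 1e-8)
  expect_equal(cv1$params$K_sr, cv2$params$K_sr, tolerance = 1e-8)
  expect_equal(cv1$params$K_50, cv2$params$K_50, tolerance = 1e-8)
  expect_equal(sort(cv1$folds$nrmse_val), sort(cv2$folds$nrmse_val),
               tolerance = 1e-5)
})
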