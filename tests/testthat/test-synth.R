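# Synthetic study generator: config invariants, marginal fidelity,
# effect directions, determinism.

test_that("condition mixtures are valid reweightings of the baseline", {
  cfg <- synth_config(seed = 1)
  for (mix in cfg$iti_mixture)
    expect_equal(sum(mix$weight), 1, tolerance = 1e-12)
  base <- cfg$iti_mixture$baseline$weight
  expect_equal(cfg$iti_mixture$tapering$weight[1], base[1] + 0.15)
  expect_equal(cfg$iti_mixture$convulsion$weight[1], base[1] - 0.30)
  expect_error(synth_config(n_pre = -1), "non-negative")
  expect_error(synth_config(base_mixture = list(weight = c(0.5, 0.4),
                                                mean = c(0, 1),
                                                sd = c(0.3, 0.3))),
               "sum to 1")
  expect_error(synth_config(seizure_day_index = 500), "outside")
})

test_that("a forced daily count of 2 yields a minimal stream", {
  cfg <- synth_config(daily_count_law = list(name = "fixed", n = 2),
                      seed = 4)
  s <- generate_day(cfg, "baseline", 0)
  expect_length(s$timestamps, 2L)
  itis <- diff(s$timestamps) / 1000
  expect_length(itis, 1L)
  expect_gt(itis, 0)
  expect_identical(nrow(make_pairs(itis)), 0L)
})

test_that("invalid condition tags are rejected", {
  cfg <- small_config()
  expect_error(generate_day(cfg, "weekend", 0), "invalid condition")
})

test_that("empirical log10-ITI mean matches the closed-form mixture mean", {
  cfg <- synth_config(daily_count_law = list(name = "fixed", n = 10001),
                      pair_correlation = 0, day_weight_sd = 0, seed = 11,
                      sleep_window = list(start_hour = 23.99, end_hour = 0.01,
                                          jitter_sd_min = 0))
  s <- generate_day(cfg, "baseline", 0)
  z <- log10(diff(s$timestamps) / 1000)
  mix <- cfg$iti_mixture$baseline
  mu <- tapjid:::mixture_log10_mean(mix)
  v <- sum(mix$weight * (mix$mean^2 + mix$sd^2)) - mu^2
  expect_equal(mean(z), mu, tolerance = 3 * sqrt(v / length(z)) / abs(mu))
})

test_that("the convulsion condition slows ITIs relative to baseline", {
  cfg <- synth_config(daily_count_law = list(name = "fixed", n = 2001),
                      day_weight_sd = 0, seed = 5)
  base <- generate_day(cfg, "baseline", 0)
  conv <- generate_day(cfg, "convulsion", 0)
  expect_gt(median(diff(conv$timestamps)), median(diff(base$timestamps)))
})

test_that("consecutive log10-ITIs carry the configured rank correlation", {
  cfg <- synth_config(daily_count_law = list(name = "fixed", n = 5001),
                      day_weight_sd = 0, seed = 9,
                      sleep_window = list(start_hour = 23.99, end_hour = 0.01,
                                          jitter_sd_min = 0))
  z <- log10(diff(generate_day(cfg, "baseline", 0)$timestamps) / 1000)
  ns <- qnorm(rank(z) / (length(z) + 1))  # normal scores recover the copula
  expect_equal(cor(ns[-1], ns[-length(ns)]), cfg$pair_correlation,
               tolerance = 0.05)
})

test_that("study structure: ordering, label counts, seizure flag, determinism", {
  cfg <- synth_config(daily_count_law = list(name = "fixed", n = 50),
                      seed = 2)
  st <- generate_study(cfg)
  expect_length(st$days, 185L)
  expect_equal(as.integer(table(st$labels)), c(82L, 12L, 91L))
  expect_identical(sum(st$seizure_flag), 1L)
  expect_true(st$labels[which(st$seizure_flag)] == "taper")
  # day ordering pre -> taper -> post and increasing time
  starts <- vapply(st$days, function(d) d$timestamps[1], numeric(1))
  expect_true(all(diff(starts) > 0))
  st2 <- generate_study(cfg)
  expect_identical(lapply(st$days, `[[`, "timestamps"),
                   lapply(st2$days, `[[`, "timestamps"))
})

test_that("an empty study is allowed; summaries of it are not", {
  st <- generate_study(synth_config(n_pre = 0, n_taper = 0, n_post = 0,
                                    seed = 1))
  expect_length(st$days, 0L)
  expect_error(summarize_study(st), "empty")
})

test_that("no events fall inside the sleep window beyond jitter tolerance", {
  cfg <- small_config(seed = 6)
  st <- generate_study(cfg)
  secs <- unlist(lapply(st$days, `[[`, "timestamps")) / 1000
  hours <- (secs %% 86400) / 3600
  # window 23.5-7.5 with 20-min jitter: [0.84, 6.16] must be silent
  expect_false(any(hours > 0.84 & hours < 6.16))
})

test_that("study summary reproduces hand-computable statistics", {
  cfg <- synth_config(n_pre = 3, n_taper = 0, n_post = 0,
                      daily_count_law = list(name = "fixed", n = 100),
                      seed = 3)
  sm <- summarize_study(generate_study(cfg))
  expect_equal(sm$median_daily, 100)
  expect_equal(sm$q75 - sm$q25, 0)

  fake <- structure(list(
    days = list(day_record("a", cumsum(rep(1000, 10))),
                day_record("b", cumsum(rep(1000, 20))),
                day_record("c", cumsum(rep(1000, 30)))),
    labels = factor(rep("pre", 3), c("pre", "taper", "post")),
    seizure_flag = rep(FALSE, 3)), class = "tap_study")
  expect_equal(summarize_study(fake)$median_daily, 20)
})

test_that("default daily-count law hits the study-scale median target", {
  sm <- summarize_study(default_study())
  expect_lt(abs(sm$median_daily - 3311) / 3311, 0.10)
  expect_true(sm$q25 > 1800 && sm$q75 < 6500)
})
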