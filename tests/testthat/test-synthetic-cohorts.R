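test_that("lifetime sampling is deterministic under a fixed seed", {
  p <- gm_params(0.002, 0.25)
  expect_identical(sample_gm_lifetimes(p, 50, seed = 7),
                   sample_gm_lifetimes(p, 50, seed = 7))
  expect_false(identical(sample_gm_lifetimes(p, 50, seed = 7),
                         sample_gm_lifetimes(p, 50, seed = 8)))
  ev <- simulate_cohort(p, 40, 2, censor_prob_per_day = 0.02, seed = 3)
  expect_identical(ev, simulate_cohort(p, 40, 2, censor_prob_per_day = 0.02,
                                       seed = 3))
})

test_that("G = 0 sampling reduces to the exponential distribution", {
  t <- sample_gm_lifetimes(gm_params(0.5, 0), 2e4, seed = 1)
  expect_equal(mean(t), 2, tolerance = 0.05)
})

test_that("sample median matches the closed-form Gompertz median", {
  p <- gm_params(0.002, 0.25)
  t <- sample_gm_lifetimes(p, 1e5, seed = 21)
  expect_equal(median(t), (1 / 0.25) * log(1 + (0.25 / 0.002) * log(2)),
               tolerance = 0.01)
})

test_that("empirical survival converges to the closed form (KS)", {
  p <- gm_params(0.004, 0.3, 0.002)
  ks_dist <- function(n, seed) {
    t <- sort(sample_gm_lifetimes(p, n, seed = seed))
    max(abs(seq_len(n) / n - (1 - gm_survival(p, t))))
  }
  d_small <- ks_dist(500, 5)
  d_large <- ks_dist(2e4, 5)
  expect_lt(d_large, d_small)
  expect_lt(d_large, 1.63 / sqrt(2e4))  # 1% KS critical value
})

test_that("with Minf >> M0 and small G, lifetimes look exponential", {
  t <- sample_gm_lifetimes(gm_params(1e-4, 0.01, 0.5), 200, seed = 13)
  set.seed(14)
  ref <- stats::rexp(200, 0.5)
  expect_gt(suppressWarnings(stats::ks.test(t, ref)$p.value), 0.01)
})

test_that("discretisation uses the ceiling rule and never precedes death", {
  ev <- discretize_and_censor(c(0.3, 1.0, 1.7), censor_prob_per_day = 0)
  expect_equal(ev$event_day, c(1L, 1L, 2L))
  expect_equal(ev$status, rep("death", 3))
  t <- sample_gm_lifetimes(gm_params(0.004, 0.25), 3000, seed = 31)
  ev <- discretize_and_censor(t, censor_prob_per_day = 0)
  expect_true(all(ev$event_day >= t))
  expect_lt(mean(ev$event_day) - mean(t), 1)
  expect_equal(sum(ev$status == "censored"), 0)
})

test_that("per-day geometric censoring matches its analytic rate", {
  # long-lived cohort so early censoring is essentially pure geometric
  t <- sample_gm_lifetimes(gm_params(1e-5, 0.05), 1e4, seed = 41)
  ev <- discretize_and_censor(t, censor_prob_per_day = 0.1, seed = 42)
  for (d in c(3, 5, 10)) {
    frac <- mean(ev$status == "censored" & ev$event_day <= d)
    expected <- 1 - 0.9^d
    expect_equal(frac, expected,
                 tolerance = 4 * sqrt(expected * (1 - expected) / 1e4) /
                   expected)
  }
})

test_that("individuals alive at the horizon are censored there", {
  ev <- discretize_and_censor(c(2.5, 9.9, 30.2), max_day = 10)
  expect_equal(ev$event_day, c(3L, 10L, 10L))
  expect_equal(ev$status, c("death", "death", "censored"))
})

test_that("progeny schedules respect the cessation day", {
  pr <- simulate_repro_schedules(rep(40, 12),
                                 cessation = list(name = "fixed", day = 7),
                                 n_individuals = 30, seed = 5)
  after <- pr$progeny_count[pr$day > 7]
  expect_true(all(after == 0))
  pr1 <- simulate_repro_schedules(c(40, 40, 40),
                                  cessation = list(name = "fixed", day = 1),
                                  n_individuals = 20, seed = 5)
  expect_true(all(pr1$progeny_count[pr1$day > 1] == 0))
})

test_that("total progeny matches the truncated analytic expectation", {
  daily <- c(50, 120, 90, 40, 15, 5, 2)
  pr <- simulate_repro_schedules(daily, cessation = list(name = "fixed", day = 4),
                                 n_individuals = 400, seed = 8)
  totals <- tapply(pr$progeny_count, pr$individual_id, sum)
  expected <- sum(daily[1:4])
  expect_equal(mean(totals), expected,
               tolerance = 4 * sqrt(expected / 400) / expected)
  expect_error(simulate_repro_schedules(numeric(0),
                                        cessation = list(name = "fixed", day = 2),
                                        n_individuals = 5, seed = 1),
               "non-empty")
})
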