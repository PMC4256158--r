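test_that("log-rank is zero for identical cohorts and symmetric", {
  a <- toy_events(group = "a")
  b <- toy_events(group = "b")
  res <- logrank_test(a, b)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_raw, 1)
  ev1 <- simulate_cohort(gm_params(0.004, 0.25), 80, 1, seed = 71, group = "a")
  ev2 <- simulate_cohort(gm_params(0.002, 0.3), 80, 1, seed = 72, group = "b")
  r12 <- logrank_test(ev1, ev2)
  r21 <- logrank_test(ev2, ev1)
  expect_equal(r12$statistic, r21$statistic)
  expect_equal(r12$p_raw, r21$p_raw)
})

test_that("log-rank errors with zero deaths and matches a hand computation", {
  censored <- event_table(data.frame(individual_id = 1:3, group = "a",
                                     replicate = "1", event_day = c(2, 3, 4),
                                     status = "censored"))
  expect_error(logrank_test(censored, censored), "zero deaths")

  # independent oracle: observed-minus-expected over shared risk sets
  a <- deaths_at(c(2, 3, 3, 5, 8), group = "a")
  b <- deaths_at(c(4, 6, 7, 9, 9), group = "b")
  days <- sort(unique(c(a$event_day, b$event_day)))
  oe_a <- 0; oe_b <- 0; v <- 0
  for (d in days) {
    na <- sum(a$event_day >= d); nb <- sum(b$event_day >= d)
    da <- sum(a$event_day == d); db <- sum(b$event_day == d)
    n <- na + nb; dd <- da + db
    oe_a <- oe_a + da - dd * na / n
    oe_b <- oe_b + db - dd * nb / n
    if (n > 1) v <- v + dd * (na / n) * (nb / n) * (n - dd) / (n - 1)
  }
  expect_equal(logrank_test(a, b)$statistic, oe_a^2 / v, tolerance = 1e-12)
  # observed-minus-expected contributions sum to zero across the two arms
  expect_equal(oe_a + oe_b, 0)
})

test_that("Holm adjustment matches hand values and the brute-force rule", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.9, 0.9, 0.9)), c(1, 1, 1))
  expect_identical(holm_adjust(numeric(0)), numeric(0))
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(81)
  for (i in 1:50) {
    p <- round(stats::runif(sample(1:4, 1)), 2)
    expect_equal(holm_adjust(p), holm_brute(p))
  }
})

test_that("t-test handles identical, separated and degenerate inputs", {
  res <- two_sample_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(res$percent_change, 0)
  expect_equal(res$p_raw, 1)
  sep <- two_sample_t(c(10.0001, 10.0002, 10.0001), c(5.0001, 5.0002, 5.0001))
  expect_lt(sep$p_raw, 1e-6)
  const <- two_sample_t(c(3, 3), c(3, 3))
  expect_equal(const$p_raw, 1)
  expect_error(two_sample_t(1, c(1, 2)), ">= 2 values")
})

test_that("t-test p agrees with an exhaustive permutation oracle", {
  a <- c(7.1, 8.3, 6.9, 9.0, 7.7, 8.8)
  b <- a - 0.8 + c(0.3, -0.5, 0.4, -0.6, 0.2, 0.1)
  obs <- abs(two_sample_t(a, b)$statistic)
  pool <- c(a, b)
  idx <- utils::combn(12, 6)
  perm_t <- apply(idx, 2, function(ii)
    abs(two_sample_t(pool[ii], pool[-ii])$statistic))
  perm_p <- mean(perm_t >= obs - 1e-12)
  expect_lt(abs(two_sample_t(a, b)$p_raw - perm_p), 0.02)
})

test_that("demographic groups follow the published effect patterns", {
  up <- fake_comparison(0.001, 30)
  none <- fake_comparison(0.8, 0.5)
  lo_imr <- fake_replicate_fits(c(0.001, 0.0011, 0.0009), c(0.25, 0.26, 0.24))
  hi_imr <- fake_replicate_fits(c(0.004, 0.0041, 0.0039), c(0.25, 0.26, 0.24))
  lo_roa <- fake_replicate_fits(c(0.004, 0.0041, 0.0039), c(0.05, 0.06, 0.055))
  hi_roa_lo_imr <- fake_replicate_fits(c(4e-4, 4.1e-4, 3.9e-4),
                                       c(0.45, 0.44, 0.46))
  ctrl <- fake_replicate_fits(c(0.004, 0.0042, 0.0038), c(0.25, 0.255, 0.245))

  expect_equal(classify_demographic_group(lo_roa, ctrl, up)$group, 1L)
  expect_equal(classify_demographic_group(lo_imr, ctrl, up)$group, 2L)
  expect_equal(classify_demographic_group(hi_roa_lo_imr, ctrl, none)$group, 3L)
  expect_true(is.na(classify_demographic_group(hi_imr, ctrl, none)$group) ||
                classify_demographic_group(hi_imr, ctrl, none)$group == 4L)
  null_call <- classify_demographic_group(ctrl, ctrl, none)
  expect_equal(null_call$group, 4L)
  # unobserved pattern (IMR up) is unclassified, not forced into a group
  imr_up <- fake_replicate_fits(c(0.02, 0.021, 0.019), c(0.25, 0.255, 0.245))
  expect_true(is.na(classify_demographic_group(imr_up, ctrl, up)$group))
})

test_that("classification is invariant to replicate order", {
  up <- fake_comparison(0.001, 30)
  trt <- fake_replicate_fits(c(0.001, 0.0011, 0.0009), c(0.25, 0.26, 0.24))
  trt_rev <- fake_replicate_fits(rev(c(0.001, 0.0011, 0.0009)),
                                 rev(c(0.25, 0.26, 0.24)))
  ctrl <- fake_replicate_fits(c(0.004, 0.0042, 0.0038), c(0.25, 0.255, 0.245))
  c1 <- classify_demographic_group(trt, ctrl, up)
  c2 <- classify_demographic_group(trt_rev, ctrl, up)
  expect_identical(c1[c("imr_effect", "roa_effect", "group")],
                   c2[c("imr_effect", "roa_effect", "group")])
})

test_that("parameter percent changes use the reduction sign convention", {
  trt <- fake_replicate_fits(c(0.001, 0.001), c(0.3, 0.3))
  ctrl <- fake_replicate_fits(c(0.010, 0.010), c(0.25, 0.25))
  pc <- percent_change_params(trt, ctrl)
  expect_equal(pc[["imr_pct"]], 90)
  expect_lt(pc[["roa_pct"]], 0)  # RoA increase reads as a negative reduction
  expect_equal(percent_change_params(ctrl, ctrl)[["imr_pct"]], 0)
})

test_that("mean-lifespan comparison targets means, not curve shape", {
  # same mean, different spread: log-rank sensitive design but t-test null
  a <- deaths_at(rep(c(5, 15), each = 30), group = "a")
  b <- deaths_at(rep(10, 60), group = "b")
  res <- mean_lifespan_test(a, b)
  expect_equal(res$percent_change, 0)
  expect_gt(res$p_raw, 0.9)
})
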