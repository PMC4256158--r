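test_that("self-fertilising RLS is indexed from the first reproductive day", {
  expect_equal(self_rls(c(10, 20, 30, 15, 8, 4, 1)), 7)
  expect_equal(self_rls(c(5)), 1)
  expect_equal(self_rls(c(0, 3, 4, 0, 2)), 4)  # first day 2, last day 5
  expect_error(self_rls(c(0, 0, 0)), "no reproduction")
})

test_that("interior zero days do not terminate the reproductive span", {
  expect_equal(self_rls(c(4, 0, 0, 6)), 4)
  expect_equal(mated_cessation_day(c(4, 0, 0, 6)), 4)
})

test_that("mated cessation day is the absolute last reproductive day", {
  expect_equal(mated_cessation_day(c(3, 2, 1, 1, 1)), 5)
  expect_equal(mated_cessation_day(c(0, 0, 0, 0, 0, 0, 0, 0, 2)), 9)
  df <- data.frame(day = c(2, 5, 9), progeny_count = c(4, 0, 1))
  expect_equal(mated_cessation_day(df), 9)
  expect_equal(self_rls(df), 8)
})

test_that("cessation days compose with KM as reproductive survival", {
  cess <- c(3, 8)
  ev <- deaths_at(cess, group = "mated")
  km <- km_survival(ev, "mated")
  expect_equal(km$survival[km$day == 2], 1)
  expect_equal(km$survival[km$day == 3], 0.5)
  expect_equal(km$survival[km$day == 8], 0)
})

test_that("total brood sums daily counts and matches the generator", {
  expect_equal(total_brood(c(0, 0)), 0)
  expect_equal(total_brood(c(100, 150)), 250)
  daily <- c(60, 110, 80, 30, 10)
  pr <- simulate_repro_schedules(daily, cessation = list(name = "fixed", day = 3),
                                 n_individuals = 300, seed = 9)
  scored <- score_progeny_table(pr)
  expect_equal(mean(scored$total_brood), sum(daily[1:3]), tolerance = 0.03)
  expect_true(all(scored$cessation_day <= 3))
})

test_that("hit calls need the threshold plus every replicate significant", {
  set.seed(91)
  ctrl <- replicate(3, stats::rnorm(10, 7, 0.5), simplify = FALSE)
  strong <- lapply(ctrl, function(x) x + 2.5)
  weak2of3 <- list(ctrl[[1]] + 2.8, ctrl[[2]] + 2.8, ctrl[[3]])
  expect_true(call_hit(strong, ctrl)$hit)
  expect_false(call_hit(ctrl, ctrl)$hit)
  expect_false(call_hit(weak2of3, ctrl)$hit)  # all-replicate rule
  sc <- call_hit(list(c(9, 9, 9.0001)), list(c(7, 7, 7.0001)))
  expect_equal(sc$extension_pct, 200 / 7, tolerance = 1e-4)
})

test_that("hit calling is monotone in threshold and alpha", {
  set.seed(93)
  for (i in 1:20) {
    trt <- replicate(3, stats::rnorm(8, 8 + stats::runif(1, -1, 2), 1),
                     simplify = FALSE)
    ctrl <- replicate(3, stats::rnorm(8, 7, 1), simplify = FALSE)
    loose <- call_hit(trt, ctrl, threshold_pct = 0, alpha = 1)$hit
    mid <- call_hit(trt, ctrl, threshold_pct = 25, alpha = 0.05)$hit
    tight <- call_hit(trt, ctrl, threshold_pct = 40, alpha = 0.01)$hit
    expect_true(!mid || loose)
    expect_true(!tight || mid)
  }
  # threshold 0, alpha 1 reduces to "any extension"
  up <- call_hit(list(c(8, 9), c(7.5, 8)), list(c(7, 7.2), c(7, 7.1)),
                 threshold_pct = 0, alpha = 1)
  expect_true(up$hit)
})

test_that("epistasis classification matches the hand-derived truth table", {
  grid <- expand.grid(d2 = c(TRUE, FALSE), d16 = c(TRUE, FALSE),
                      sm = c(TRUE, FALSE))
  res <- classify_epistasis(grid$d2, grid$d16, grid$sm)
  expected_iis <- ifelse(grid$d2 & grid$d16, "independent",
                  ifelse(grid$d16, "non_additive_daf2",
                  ifelse(grid$d2, "daf16_dependent_additive", "fully_dependent")))
  expect_equal(res$iis_relation, expected_iis)
  expect_equal(res$pathway_class[grid$d2 & grid$d16 & grid$sm],
               "independent_of_both")
  expect_equal(res$pathway_class[grid$d2 & grid$d16 & !grid$sm],
               "tgfb_specific")
  expect_equal(res$pathway_class[!(grid$d2 & grid$d16) & grid$sm],
               rep("iis_specific", 3))
  expect_equal(res$pathway_class[!(grid$d2 & grid$d16) & !grid$sm],
               rep("both_pathways", 3))
})

test_that("pathway classes partition every flag combination", {
  grid <- expand.grid(d2 = c(TRUE, FALSE), d16 = c(TRUE, FALSE),
                      sm = c(TRUE, FALSE))
  res <- classify_epistasis(grid$d2, grid$d16, grid$sm)
  expect_setequal(unique(res$pathway_class),
                  c("both_pathways", "independent_of_both", "iis_specific",
                    "tgfb_specific"))
  expect_equal(nrow(res), 8)
})
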