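test_that("the cohort fixtures satisfy the structural invariants", {
  co <- load_cohort()
  expect_equal(nrow(co), 19)
  expect_equal(co$id[co$dead], c(2L, 6L))
  expect_equal(co$id[is.na(co$msts)], 14L)
  expect_true(all(co$msts >= 0 & co$msts <= 30, na.rm = TRUE))
  expect_true(all(co$margin_mm %in% c(10, 15, 20)))
  expect_true(all(co$follow_up_months > 0))
})

test_that("descriptive statistics reproduce the published operative summaries", {
  co <- load_cohort()
  ot <- descriptive(co$operative_time_min)
  expect_equal(round_half_up(ot$mean), 252)
  expect_equal(ot$median, 240)
  expect_equal(c(ot$min, ot$max), c(120, 570))
  bl <- descriptive(co$blood_loss_ml)
  expect_equal(round_half_up(bl$mean), 1358)
  expect_equal(bl$median, 1200)
  fu <- descriptive(co$follow_up_months)
  expect_equal(round_half_up(fu$mean), 37)
  expect_equal(fu$median, 31)
  expect_equal(descriptive(7), list(mean = 7, median = 7, min = 7, max = 7))
  expect_error(descriptive(numeric(0)), "nonempty")
})

test_that("the product-limit curve matches closed forms and a hand oracle", {
  # no events: survival stays at 1
  km0 <- km_curve(c(3, 8, 12), c(FALSE, FALSE, FALSE))
  expect_true(all(survival_at(km0, c(0, 5, 50)) == 1))
  # four distinct events, no censoring: S = (4-k)/4
  km4 <- km_curve(c(2, 4, 6, 8), rep(TRUE, 4))
  expect_equal(survival_at(km4, c(1.9, 2, 4, 6, 8)),
               c(1, 3 / 4, 2 / 4, 1 / 4, 0))
  # right-continuity / step evaluation
  expect_equal(survival_at(km4, 3.999), 0.75)
  expect_equal(survival_at(km4, 0), 1)
  # random censored samples against an independent product-limit implementation
  set.seed(8)
  for (i in 1:5) {
    tm <- sample(1:20, 12, replace = TRUE)
    ev <- runif(12) < 0.5
    km <- km_curve(tm, ev)
    for (tq in c(0, 5, 10, 20, 25))
      expect_equal(survival_at(km, tq), product_limit(tm, ev, tq),
                   tolerance = 1e-12)
  }
  expect_error(km_curve(1:3, c(TRUE, FALSE)), "length")
})

test_that("MSTS recovery reproduces the published functional results", {
  co <- load_cohort()
  eligible <- co$msts[!co$dead & !is.na(co$msts)]
  expect_length(eligible, 16)
  ms <- msts_recovery(eligible)
  expect_equal(round_half_up(ms$mean_score, 1), 26.6)
  expect_equal(round_half_up(ms$mean_recovery_pct, 1), 88.5)
  expect_equal(median(eligible), 27)
  expect_equal(range(eligible) / 30 * 100, c(70, 100))
  expect_equal(msts_recovery(30)$mean_recovery_pct, 100)
  expect_error(msts_recovery(c(10, 31)), "30")
})

test_that("the marginal-resection pair is identified uniquely by operative time", {
  co <- load_cohort()
  pair <- find_marginal_pair(co)
  expect_length(pair, 2)
  types <- sort(co$tumor_position[co$id %in% pair])
  expect_equal(types, c("type I + II", "type II + III"))
  expect_equal(mean(co$operative_time_min[co$id %in% pair]), 367.5)
  # wide group then reproduces the published subgroup mean
  wide <- co[!co$id %in% pair, ]
  expect_equal(round_half_up(mean(wide$operative_time_min), 1), 238.5)
  expect_error(find_marginal_pair(co, mean_time_min = 1000), "unique")
})

test_that("five-year overall survival evaluates to the published rates", {
  co <- load_cohort()
  km <- km_curve(co$follow_up_months, co$dead)
  expect_equal(round_half_up(100 * survival_at(km, 60), 1), 75.6)
  pair <- find_marginal_pair(co)
  wide <- co[!co$id %in% pair, ]
  kmw <- km_curve(wide$follow_up_months, wide$dead)
  expect_equal(round_half_up(100 * survival_at(kmw, 60), 1), 80.0)
})
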