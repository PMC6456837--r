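test_that("nrr computes the compound per-period rate", {
  expect_equal(nrr(10, 10, 5), 0)
  expect_equal(nrr(20, 10, 1), 1)
  expect_equal(round(nrr(36.5, 10, 12), 3), 0.114)
  expect_error(nrr(-1, 10, 12), "positive")
  expect_error(nrr(10, 0, 12), "positive")
})

test_that("nrr inverts: compounding V0 at the rate recovers In", {
  set.seed(11)
  for (i in 1:25) {
    v0 <- runif(1, 0.5, 100)
    vn <- runif(1, 0.5, 100)
    n <- sample(1:40, 1)
    r <- nrr(vn, v0, n)
    expect_equal(v0 * (1 + r)^n, vn, tolerance = 1e-10)
  }
})

test_that("monthly_nrr reproduces the published returns column to 1 d.p.", {
  net <- c(14.5, 18.5, 22.5, 26.5, 30.5, 34.5)
  cost <- c(7, 8, 9, 10, 12, 14)
  expect_equal(round(monthly_nrr(net, cost), 1),
               c(9.8, 10.5, 11.0, 11.4, 11.1, 10.9))
  expect_error(monthly_nrr(14.5, 0), "cost")
})

test_that("monthly_nrr is monotone: decreasing in cost, increasing in net", {
  costs <- seq(2, 30, by = 0.5)
  expect_true(all(diff(monthly_nrr(20, costs)) < 0))
  nets <- seq(5, 60, by = 0.5)
  expect_true(all(diff(monthly_nrr(nets, 10)) > 0))
})

test_that("diminishing_returns marks the maximum, first row on ties", {
  dr <- diminishing_returns(c(14.5, 18.5, 22.5, 26.5, 30.5, 34.5),
                            c(7, 8, 9, 10, 12, 14))
  expect_equal(attr(dr, "peak"), 4L)
  expect_equal(dr$cost[dr$is_max], 10)
  expect_equal(round(max(dr$nrr_pct), 1), 11.4)
  one <- diminishing_returns(20, 8)
  expect_true(one$is_max)
  tie <- diminishing_returns(c(20, 20), c(8, 8))
  expect_equal(attr(tie, "peak"), 1L)
  expect_error(diminishing_returns(numeric(0), numeric(0)), "non-empty")
})

test_that("Sturges rule gives six width-4 classes for the income survey", {
  # 30 households with incomes spanning 13-36 million IDR
  expect_equal(round(sturges_class_width(23, 30), 2), 3.88)
  expect_equal(round(sturges_class_width(23, 30)), 4)
  expect_equal(sturges_class_count(30), 6)
  expect_equal(sturges_class_count(10), 4)  # 1 + 3.332*log10(10) = 4.332
  expect_error(sturges_class_width(0, 30), "range")
  expect_error(sturges_class_count(0), "n must")
})

test_that("classify_households builds Sturges classes from raw incomes", {
  hh <- data.frame(net_income = seq(13, 36, length.out = 30),
                   household_size = rep(4L, 30))
  cls <- classify_households(hh)
  expect_equal(nrow(cls), 6L)
  expect_equal(cls$lower, c(13, 17, 21, 25, 29, 33))
  expect_equal(cls$upper, c(16, 20, 24, 28, 32, 36))
  expect_equal(cls$median_income, (cls$lower + cls$upper) / 2)
})

test_that("classify_households reproduces the published class summary", {
  cfg <- valuation_config()
  ref <- balikpapan_reference()$income_classes
  cls <- classify_households(balikpapan_households(), cfg,
                             bounds = ref[c("lower", "upper")])
  expect_equal(cls$n_households, ref$n_households)
  expect_equal(cls$total_persons, ref$total_persons)
  expect_equal(cls$total_net_income, ref$total_net_midr)
  # US$ person^-1 day^-1 column to 3 significant figures
  expect_equal(signif(cls$usd_per_person_day, 3),
               signif(ref$usd_per_person_day, 3))
})

test_that("classify_households conserves totals and handles edge cases", {
  for (seed in 1:5) {
    hh <- generate_household_incomes(income_model_params(), seed = seed)
    cls <- classify_households(hh)
    expect_equal(sum(cls$total_net_income), sum(hh$net_income))
    expect_equal(sum(cls$total_persons), sum(hh$household_size))
    expect_equal(sum(cls$n_households), nrow(hh))
    expect_true(all(cls$lower <= cls$median_income &
                      cls$median_income <= cls$upper))
  }
  one <- classify_households(data.frame(net_income = 20,
                                        household_size = 1L))
  expect_equal(nrow(one), 1L)
  expect_equal(one$usd_per_person_day, 20e6 / 365 / 13300)
  expect_error(classify_households(data.frame()), "non-empty")
  expect_error(
    classify_households(data.frame(net_income = 50, household_size = 1L),
                        bounds = data.frame(lower = 13, upper = 16)),
    "cover")
})

test_that("wood_annual_income implements area x volume x price / rotation", {
  cfg <- valuation_config()
  expect_equal(wood_annual_income(cfg, 98.99), 742425000)
  expect_equal(wood_annual_income(valuation_config(area_ha = 1,
                                                   price_idr_per_m3 = 1,
                                                   rotation_years = 1), 1), 1)
  expect_equal(wood_annual_income(cfg, 0), 0)
  expect_error(valuation_config(rotation_years = 0), "positive")
})

test_that("per_person_per_day converts annual IDR to daily income", {
  cfg <- valuation_config()  # population 164, fx 13300
  expect_equal(round(per_person_per_day(1080353280, cfg)), 18048)
  expect_equal(round(per_person_per_day(742425000, cfg, in_usd = TRUE), 3),
               0.933)
  expect_equal(per_person_per_day(0, cfg), 0)
  # linearity
  x <- per_person_per_day(1e9, cfg)
  expect_equal(per_person_per_day(3.7e9, cfg), 3.7 * x)
})

test_that("overfishing_rate is zero at parity and scale-invariant", {
  expect_equal(round(overfishing_rate(18048.3, 12402.6), 1), 45.5)
  expect_equal(overfishing_rate(5, 5), 0)
  expect_equal(overfishing_rate(10, 5), 100)
  for (k in c(0.01, 1, 13300)) {
    expect_equal(overfishing_rate(18048.3 * k, 12402.6 * k),
                 overfishing_rate(18048.3, 12402.6))
  }
  expect_error(overfishing_rate(10, 0), "positive")
})
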