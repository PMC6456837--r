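test_that("tree_volume matches hand-computed form-factor volumes", {
  # (pi/4)(0.05)^2 * 2.0 * 0.85, frozen by hand arithmetic
  expect_equal(tree_volume(5.0, 2.0, 0.85), 0.0033379, tolerance = 1e-4)
  expect_equal(tree_volume(12.0, 9.0, 0.7), 0.0712514, tolerance = 1e-5)
  # a stem of unit basal area, unit height and cylindrical form is 1 m^3
  expect_equal(tree_volume(100 * sqrt(4 / pi), 1, 1.0), 1.0)
})

test_that("tree_volume and stand_volume reject out-of-domain inputs", {
  expect_error(tree_volume(-1, 2, 0.8), "diameter")
  expect_error(tree_volume(5, 0, 0.8), "height")
  expect_error(tree_volume(5, 2, 1.5), "form factor")
  expect_error(tree_volume(5, 2, 0), "form factor")
  expect_error(stand_volume(-10, 5, 2, 0.8), "stocking")
})

test_that("stand_volume reproduces measured stand-table cells", {
  expect_rel_equal(stand_volume(2500, 5.0, 2.0, 0.85), 8.34, 0.005)
  expect_rel_equal(stand_volume(780, 19.0, 11.5, 0.66), 167.77, 0.005)
  expect_equal(stand_volume(0, 5, 2, 0.8), 0)
})

test_that("mai and pai match the published increment arithmetic", {
  expect_equal(round(mai(134.64, 25), 2), 5.39)
  expect_equal(round(mai(167.77, 25), 2), 6.71)
  expect_equal(mai(0, 17), 0)
  expect_error(mai(10, 0), "age")
  # (98.99 - 83.90)/2 = 7.545, printed half-up as 7.55
  expect_equal(pai(98.99, 83.90, 2), 7.55, tolerance = 0.001)
  expect_equal(round(pai(153.88, 116.08, 3), 2), 12.60)
  expect_equal(pai(50, 50, 4), 0)
  expect_error(pai(10, 5, 0), "interval")
})

test_that("growth_table recomputes the packaged tables within tolerance", {
  st <- balikpapan_stand_tables()
  ref <- balikpapan_reference()
  g_pre <- growth_table(st$pre)
  expect_equal(nrow(g_pre), 12L)
  expect_true(all(abs(g_pre$tv - ref$pre$tv) / ref$pre$tv < 0.005))
  # post-thinning: all cells agree except the known-inconsistent age-40 TV
  g_post <- growth_table(st$post)
  keep <- g_post$age != 40
  expect_true(all(abs(g_post$tv - ref$post$tv)[keep] /
                    ref$post$tv[keep] < 0.005))
  expect_gt(abs(g_post$tv[!keep] - ref$post$tv[!keep]) /
              ref$post$tv[!keep], 0.04)  # the flagged cell really disagrees
  # MAI column still tracks the published one away from the flagged cell
  expect_true(all(abs(g_post$mai - ref$post$mai)[keep] < 0.05))
})

test_that("growth_table handles single-row tables and rejects empties", {
  one <- stand_table(5, 1000, 6, 3, 0.8)
  g <- growth_table(one)
  expect_equal(nrow(g), 1L)
  expect_true(is.na(g$pai))
  expect_error(growth_table(data.frame()), "missing column")
})

test_that("MAI reconstruction identity holds on arbitrary observations", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(100:3000, 1)
    d <- runif(1, 2, 40); h <- runif(1, 1, 20); f <- runif(1, 0.4, 1)
    t <- sample(1:50, 1)
    v <- stand_volume(n, d, h, f)
    expect_equal(mai(v, t) * t, v, tolerance = 1e-12)
  }
})

test_that("stand_volume is strictly increasing in each attribute", {
  base <- list(n = 1000, d = 12, h = 8, f = 0.7)
  v0 <- do.call(stand_volume, base)
  for (arg in names(base)) {
    up <- base
    up[[arg]] <- base[[arg]] * 1.1
    expect_gt(do.call(stand_volume, up), v0)
  }
})

test_that("PAI telescopes: first TV plus interval-weighted PAIs gives last TV", {
  g <- growth_table(balikpapan_stand_tables()$pre)
  dt <- diff(g$age)
  expect_equal(g$tv[1] + sum(g$pai[-1] * dt), g$tv[nrow(g)],
               tolerance = 1e-10)
})

test_that("peak_mai finds the culmination and breaks ties by earliest age", {
  st <- balikpapan_stand_tables()
  pk_pre <- peak_mai(growth_table(st$pre))
  expect_equal(pk_pre$age, 25)
  expect_equal(round(pk_pre$mai, 2), 5.39)
  pk_post <- peak_mai(growth_table(st$post))
  expect_equal(pk_post$age, 25)
  expect_equal(round(pk_post$mai, 2), 6.71)
  # tie -> earliest age
  tie <- data.frame(age = c(10, 20), mai = c(5, 5))
  expect_equal(peak_mai(tie)$age, 10)
  one <- growth_table(stand_table(5, 1000, 6, 3, 0.8))
  expect_equal(peak_mai(one)$age, 5)
  expect_error(peak_mai(data.frame()), "non-empty")
})

test_that("MAI culminates where PAI crosses below it on an annual grid", {
  g <- growth_table(generate_stand_trajectory(growth_curve_params(),
                                              ages = 1:45))
  # unimodal check
  m <- g$mai
  pk <- which.max(m)
  expect_true(all(diff(m[seq_len(pk)]) >= 0))
  expect_true(all(diff(m[pk:length(m)]) <= 0))
  # classical culmination: PAI first drops below MAI at (or one step after)
  # the MAI peak on a unit-interval grid
  first_drop <- which(g$pai < g$mai)[1]
  expect_true(g$age[pk] %in% c(g$age[first_drop] - 1, g$age[first_drop]))
})
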