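# Oxygen transport: content, advection, pulmonary mixing, myocardial
# demand, systemic consumption.

test_that("oxygen content follows the clinical convention", {
  expect_equal(o2_content(140, 0, 1000), 0)
  expect_equal(o2_content(140, 96.2, 1000), 0.0000136 * 140 * 96.2 * 1000)
  expect_equal(o2_content(140, 96.2, 1000), 183.16, tolerance = 1e-04)
  # linear in each argument
  expect_equal(o2_content(280, 50, 100), 2 * o2_content(140, 50, 100))
  expect_equal(o2_content(140, 50, 200), 2 * o2_content(140, 50, 100))
})

test_that("advection conserves oxygen and leaves uniform saturations unchanged", {
  set.seed(3)
  vol <- runif(6, 50, 500)
  # uniform saturations: any volume-conserving (divergence-free) flow
  # pattern leaves them unchanged
  ring <- data.frame(from = c(1, 2, 3, 4, 5, 6),
                     to = c(2, 3, 4, 5, 6, 1), q = 55)
  s1 <- o2_advect(vol, rep(75, 6), ring, 140, 0.001, 500)
  expect_equal(s1, rep(75, 6), tolerance = 1e-12)
  edges <- data.frame(from = c(1, 2, 3, 4, 5, 6),
                      to = c(2, 3, 4, 5, 6, 1),
                      q = runif(6, -80, 80))
  # conservation over 1e4 steps with mixed saturations
  s0 <- runif(6, 40, 99)
  s2 <- o2_advect(vol, s0, edges, 140, 0.00025, 10000)
  expect_equal(sum(o2_content(140, s2, vol)),
               sum(o2_content(140, s0, vol)),
               tolerance = 1e-08 * sum(o2_content(140, s0, vol)))
})

test_that("two-compartment exchange matches the closed-form solution", {
  v1 <- 120; v2 <- 400; q <- 25
  s1 <- 95; s2 <- 60
  edges <- data.frame(from = c(1, 2), to = c(2, 1), q = c(q, q))
  dt <- 0.00025; n <- 40000   # 10 s
  s <- o2_advect(c(v1, v2), c(s1, s2), edges, 140, dt, n)
  # analytic: the difference decays at rate q (1/v1 + 1/v2), the
  # content-weighted mean is conserved
  tt <- dt * n
  k <- q * (1 / v1 + 1 / v2)
  mean_s <- (v1 * s1 + v2 * s2) / (v1 + v2)
  d0 <- s1 - s2
  s1_pred <- mean_s + d0 * exp(-k * tt) * v2 / (v1 + v2)
  s2_pred <- mean_s - d0 * exp(-k * tt) * v1 / (v1 + v2)
  expect_lt(abs(s[1] - s1_pred) / abs(d0), 0.001)
  expect_lt(abs(s[2] - s2_pred) / abs(d0), 0.001)
})

test_that("pulmonary oxygenation is flow-weighted shunt mixing", {
  expect_equal(pulmonary_oxygenation(68.3, 0), 99.4)
  expect_equal(pulmonary_oxygenation(68.3, 1), 68.3)
  expect_equal(pulmonary_oxygenation(68.3, 0.1), 0.9 * 99.4 + 0.1 * 68.3)
  expect_equal(pulmonary_oxygenation(68.3, 0.1), 96.29, tolerance = 1e-09)
  expect_error(pulmonary_oxygenation(68, 1.2), "shunt_fraction")
})

test_that("myocardial oxygen demand follows the pressure-volume area", {
  # zero PVA and elastance: basal term only
  expect_equal(myocardial_vo2(0, 0, 10, 10, 0, 150, 72),
               0.014 * 1.5 * 72)
  # doubling PVA at fixed elastance adds a * PVA exactly
  v1 <- myocardial_vo2(4000, 90, 30, 0, 2.4, 150, 72)
  v2 <- myocardial_vo2(8000, 90, 30, 0, 2.4, 150, 72)
  pe <- 0.5 * 90 * 30
  expect_equal(v2 - v1, 1.8e-05 * 4000 * 1.5 * 72)
  expect_equal(v1, (1.8e-05 * (4000 + pe) + 0.0024 * 2.4 + 0.014) *
                 1.5 * 72)
})

test_that("systemic consumption drains content proportionally and floors at zero", {
  s <- consume_systemic(c(80, 80), c(100, 300), 140, 0, 0.1)
  expect_equal(s, c(80, 80))
  s2 <- consume_systemic(c(80, 80), c(100, 300), 140, 250, 0.5,
                         weights = c(1, 1))
  drop1 <- (80 - s2[1]) * o2_content(140, 1, 100)
  drop2 <- (80 - s2[2]) * o2_content(140, 1, 300)
  expect_equal(drop1, 250 / 60 * 0.5 / 2, tolerance = 1e-09)
  expect_equal(drop2, 250 / 60 * 0.5 / 2, tolerance = 1e-09)
  expect_warning(consume_systemic(0.01, 10, 140, 5000, 10), "floored")
})

test_that("saturations stay within [0, 100] and SvO2 falls as VO2 rises", {
  tr <- baseline_trace()
  sats <- as.data.frame(tr)[grep("^sat_", names(tr))]
  expect_true(all(sats >= 0 & sats <= 100))
  p <- cv_preset()
  p$global$vo2_systemic <- 320
  hi <- beat_metrics(cv_run(p, 30, record_dt = 0.005), "last")$svo2
  lo <- beat_metrics(cv_run(cv_set(p, "global.vo2_systemic", 180), 30,
                            record_dt = 0.005), "last")$svo2
  base <- beat_metrics(tr, "last")$svo2
  expect_lt(hi, base)
  expect_gt(lo, base)
})
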