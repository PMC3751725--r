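# Valve operations: inertance, Bernoulli gradient, opening dynamics,
# Gorlin shunt flow.

test_that("valve inertance: unit conversion and area scaling", {
  # r = 1 cm, rho 1.060: L = 2 rho/(pi r) g/cm^4 -> mmHg s^2/ml
  expect_equal(valve_inertance(pi, 1.060), 2 * 1.060 / pi / 1333.22,
               tolerance = 1e-09)
  # L ~ a_eff^(-1/2)
  expect_equal(valve_inertance(4 * 2.5) / valve_inertance(2.5), 0.5,
               tolerance = 1e-09)
  expect_equal(valve_inertance(3, rho = 0), 0)
  expect_error(valve_inertance(0), "positive")
})

test_that("valve gradient: Bernoulli plus inertial term in mmHg", {
  expect_equal(valve_gradient(0, 0, 5), 0)
  # steady 200 ml/s through 5 cm^2: 848 dyn/cm^2 = 0.636 mmHg
  expect_equal(valve_gradient(200, 0, 5, 1.060),
               1.060 / 50 * 200^2 / 1333.22, tolerance = 1e-09)
  # odd in q
  expect_equal(valve_gradient(-200, 0, 5), -valve_gradient(200, 0, 5))
  # inertial term adds L * dq/dt
  expect_equal(valve_gradient(0, 1000, 2, 1.060),
               valve_inertance(2, 1.060) * 1000, tolerance = 1e-09)
})

test_that("valve opening dynamics: fixed points, monotone opening, clamped", {
  expect_equal(update_valve_opening(0.4, 0, 0.001, 30, 30), 0.4)
  # sustained positive gradient drives zeta monotonically to 1
  z <- 0
  zs <- numeric(200)
  for (i in 1:200) {
    z <- update_valve_opening(z, 5, 0.002, 30, 30)
    zs[i] <- z
  }
  expect_true(all(diff(zs) >= 0))
  expect_gt(zs[200], 0.95)
  # property: zeta never leaves [0, 1] for random gradient sequences
  set.seed(7)
  for (rep in 1:20) {
    z <- runif(1)
    for (i in 1:500) {
      z <- update_valve_opening(z, rnorm(1, 0, 40), 0.001,
                                runif(1, 5, 60), runif(1, 5, 60))
      expect_true(z >= 0 && z <= 1)
    }
  }
})

test_that("Gorlin orifice flow reproduces the printed coefficient", {
  expect_equal(shunt_flow(0, 10), 0)
  # A = 1 cm^2, dP = 1 mmHg: C sqrt(2g) = sqrt(1960) = 44.27 ~ 44.3 ml/s
  expect_equal(shunt_flow(1, 1), sqrt(2 * 980), tolerance = 1e-09)
  expect_equal(shunt_flow(1, 1), 44.3, tolerance = 0.001)
  expect_equal(shunt_flow(0.2, 4), 44.27189 * 0.2 * 2, tolerance = 1e-04)
  # odd in dp, homogeneous of degree 1 in area
  dp <- c(-9, -1, 0.25, 4, 16)
  expect_equal(shunt_flow(0.5, dp), -shunt_flow(0.5, -dp))
  expect_equal(shunt_flow(0.6, dp), 3 * shunt_flow(0.2, dp))
  expect_error(shunt_flow(-1, 1), "non-negative")
})

test_that("healthy valves show small closure backflow only; regurgitation sustains it", {
  tr <- baseline_trace()
  m <- beat_metrics(tr)
  last <- tr[tr$t >= max(m$t_start), ]
  # transient negative aortic flow at closure exists but is small
  expect_lt(min(last$q_aortic), 0)
  backflow <- sum(pmin(last$q_aortic, 0)) * 0.002   # ml per beat
  expect_gt(backflow, -5)
  # aortic regurgitation preset: sustained diastolic backflow
  ar <- scenario_cached("aortic_regurgitation")$trace
  mar <- beat_metrics(ar, "last")
  lar <- ar[ar$t >= mar$t_start, ]
  back_ar <- sum(pmin(lar$q_aortic, 0)) * 0.002
  expect_lt(back_ar, -20)
})
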