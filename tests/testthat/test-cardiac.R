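# Cardiac chamber operations: Double-Hill activation, Starling roll-off,
# passive diastole, chamber pressure, septal coupling, pericardium, ECG.

test_that("Double-Hill activation: zero at onset, unit peak, frozen peak location", {
  T <- 60 / 72
  expect_equal(double_hill_activation(0, T, 0.303, 0.508, 1.32, 27.4), 0)
  grid <- seq(0, T, length.out = 20001)[-20001]
  a <- double_hill_activation(grid, T, 0.303, 0.508, 1.32, 27.4)
  expect_lt(abs(max(a) - 1), 1e-06)
  expect_true(all(a >= 0 & a <= 1 + 1e-12))
  # peak location for the classic constants, frozen from a 1e5-point
  # brute-force scan computed independently of the implementation
  expect_equal(grid[which.max(a)] / T, 0.43928, tolerance = 1e-03)
  expect_error(double_hill_activation(0.1, -1, 0.3, 0.5), "period")
  expect_error(double_hill_activation(0.1, 1, 0, 0.5), "alpha")
  # normalisation is recomputed for any parameter combination
  for (pars in list(c(0.29, 0.48, 5, 27.4), c(0.07, 0.125, 1.32, 27.4),
                    c(0.2, 0.6, 2, 15))) {
    a <- double_hill_activation(grid, T, pars[1], pars[2], pars[3], pars[4])
    expect_lt(abs(max(a) - 1), 1e-06)
  }
})

test_that("Starling roll-off: identity below threshold, monotone saturating above", {
  sp <- list(v_th = 100, width = 70, depth = 0.5)
  expect_equal(effective_emax(2.8, 50, sp), 2.8)
  expect_equal(effective_emax(2.8, 100, sp), 2.8)
  v <- seq(0, 400, by = 2)
  em <- effective_emax(2.8, v, sp)
  expect_true(all(diff(em) <= 1e-12))
  expect_gt(min(em), 2.8 * (1 - sp$depth) - 1e-09)
})

test_that("passive diastolic relation: anchor, slope and closed-form ratio", {
  e_min <- 0.05; v0 <- 10; phi <- 40
  expect_equal(passive_pressure(v0, e_min, v0, phi), 0)
  h <- 1e-04
  slope <- (passive_pressure(v0 + h, e_min, v0, phi) -
            passive_pressure(v0 - h, e_min, v0, phi)) / (2 * h)
  expect_equal(slope, e_min, tolerance = 1e-06)
  # p(v0 + 2 phi)/p(v0 + phi) = (e^2 - 1)/(e - 1) for this form
  r <- passive_pressure(v0 + 2 * phi, e_min, v0, phi) /
       passive_pressure(v0 + phi, e_min, v0, phi)
  expect_equal(r, (exp(2) - 1) / (exp(1) - 1), tolerance = 1e-09)
})

test_that("chamber pressure blends active and passive limbs with viscous wall", {
  # activation 0 at the passive unstressed volume: zero pressure
  expect_equal(chamber_pressure(60, 0, 2.8, 0.05, 0, 60, 40), 0)
  # activation 1, effective elastance 2.43 at v = v0 + 50 (Starling off)
  expect_equal(chamber_pressure(50, 1, 2.43, 0.05, 0, 60, 40), 121.5)
  # the viscous term raises pressure during filling (dv/dt > 0)
  p0 <- chamber_pressure(80, 0.3, 2.8, 0.05, 0, 60, 40)
  p1 <- chamber_pressure(80, 0.3, 2.8, 0.05, 0, 60, 40,
                         dv_dt = 300, r_wall = 0.002)
  expect_equal(p1 - p0, 0.6)
})

test_that("septal pressure transmission follows the weighted coupling", {
  # worked arithmetic: Esv = 10 * 2 = 20
  expect_equal(septal_coupled_pressure(2, 100, 20, 10),
               (20 / 22) * 200 + (2 / 22) * 20)
  # rigid septum limit: no interaction
  expect_equal(septal_coupled_pressure(2, 100, 20, 1e09), 200,
               tolerance = 1e-06)
  # Esv = elv: symmetric half weights
  expect_equal(septal_coupled_pressure(2, 100, 20, 1), 0.5 * 200 + 0.5 * 20)
  expect_error(septal_coupled_pressure(0, 100, 20, 10), "positive")
})

test_that("pericardial relation: negative floor, monotone, log-slope halves with phi", {
  pars <- list(p_min = -2, p_scale = 0.5, v_pc0 = 720, phi = 50)
  # very small contained volume: pressure approaches the (negative) floor
  expect_equal(pericardial_pressure(0, -2, 0.5, 720, 50), -2,
               tolerance = 1e-04)
  v <- seq(100, 1200, by = 10)
  pp <- pericardial_pressure(v, -2, 0.5, 720, 50)
  expect_true(all(diff(pp) > 0))
  # doubling phi halves d log(p - p_min)/dv
  s1 <- diff(log(pericardial_pressure(c(700, 701), -2, 0.5, 720, 50) + 2))
  s2 <- diff(log(pericardial_pressure(c(700, 701), -2, 0.5, 720, 100) + 2))
  expect_equal(s1 / s2, 2, tolerance = 1e-06)
})

test_that("ECG: flat with zero weights, advanced by the electromechanical delay", {
  chs <- lapply(cv_preset()$chambers, function(c)
    c[c("alpha1", "alpha2", "n1", "n2", "onset")])
  t <- seq(0, 60 / 72, length.out = 800)
  expect_equal(ecg_trace(t, 60 / 72, chs, rep(0, 4)), rep(0, length(t)))
  # ventricular-only trace with delay peaks 60 ms before the zero-delay one
  e_del <- ecg_trace(t, 60 / 72, chs, c(1, 0, 0, 0), delay = 0.06)
  e_raw <- ecg_trace(t, 60 / 72, chs, c(1, 0, 0, 0), delay = 0)
  shift <- t[which.max(e_raw)] - t[which.max(e_del)]
  expect_lt(abs(shift - 0.06), 0.003)
  # atrial-only peaks precede ventricular activation by the AV interval
  e_at <- ecg_trace(t, 60 / 72, chs, c(0, 0, 1, 0), delay = 0)
  gap <- t[which.max(e_raw)] - t[which.max(e_at)]
  ch <- cv_preset()$chambers
  expect_gt(gap, ch$lv$onset * 0.8)
})

test_that("instantaneous elastance stays within [e_min, effective e_max]", {
  sp <- list(v_th = 100, width = 70, depth = 0.5)
  set.seed(42)
  for (i in 1:200) {
    act <- runif(1); v <- runif(1, 5, 300)
    em_eff <- effective_emax(2.8, v, sp)
    # activation-weighted blend of systolic and passive tangent stiffness
    epas <- 0.05 * exp((v - 4) / 145)
    elin <- act * em_eff + (1 - act) * epas
    expect_gte(elin, min(0.05, em_eff) - 1e-12)
    expect_lte(elin, max(em_eff, epas) + 1e-12)
  }
})
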