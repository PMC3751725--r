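# Solver engine: assembly, determinism, fixed point, conservation,
# step-size robustness, external pressures, timed events.

test_that("assembly distributes the configured blood volume deterministically", {
  p <- cv_preset()
  st <- cv_assemble(p)
  expect_length(st$x, 62)
  expect_equal(sum(st$x[1:30]), 5600, tolerance = 1e-09)
  expect_identical(unclass(cv_assemble(p)), unclass(st))
  # flows zero, AV valves open / semilunar closed at end-diastole
  expect_equal(st$x[31:58], rep(0, 28))
  expect_equal(st$x[59:62], c(1, 0, 1, 0))
  # invalid initial volumes are rejected
  bad <- p
  bad$chambers$lv$init_volume <- -10
  expect_error(cv_assemble(bad), "init_volume")
})

test_that("removing a leaf segment shrinks the state accordingly", {
  p <- cv_preset()
  # drop the right coronary branch (two segments, one stateful edge,
  # two algebraic edges)
  p$segments$r_cor_epi <- NULL
  p$segments$r_cor_micro <- NULL
  topo <- p$topology
  keep <- !(topo$from %in% c("r_cor_epi", "r_cor_micro") |
            topo$to %in% c("r_cor_epi", "r_cor_micro"))
  p$topology <- topo[keep, ]
  p$oxygen$myo_sink_right <- NA
  st <- cv_assemble(p)
  expect_length(st$x, 62 - 2 - 1)   # two volumes and one flow state fewer
  tr <- cv_run(p, 1, record_dt = 0.01)
  expect_gt(nrow(tr), 50)
})

test_that("an equilibrated quiescent circulation is a fixed point of step()", {
  p <- cv_preset()
  p$global$heart_rate <- 0
  p$global$vo2_systemic <- 0
  p$pericardium$p_scale <- 0
  p$pericardium$p_min <- 0
  p$segments$l_cor_micro$compress_k <- 0
  p$segments$r_cor_micro$compress_k <- 0
  st <- equilibrium_state(p, p_star = 30)
  tr <- cv_run(p, 0.01, init = st, record_dt = 0.0025)
  fin <- attr(tr, "final_state")
  expect_lt(max(abs(fin$x - st$x) / (1 + abs(st$x))), 1e-10)
})

test_that("runs are deterministic and run(0) yields an empty trace", {
  p <- cv_preset()
  t1 <- cv_run(p, 2, record_dt = 0.005)
  t2 <- cv_run(p, 2, record_dt = 0.005)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "final_state")$x, attr(t2, "final_state")$x)
  t0 <- cv_run(p, 0)
  expect_equal(nrow(t0), 0)
  expect_error(cv_run(p, -1), "non-negative")
})

test_that("volume is conserved over 1e5 steps to 1e-6 of blood volume", {
  tr <- baseline_trace()
  tot <- rowSums(as.data.frame(tr)[grep("^v_", names(tr))])
  expect_lt(max(abs(tot - 5600)), 1e-06 * 5600)
})

test_that("refining dt from 0.25 ms to 0.05 ms changes beat CO by < 1%", {
  p <- cv_preset()
  m1 <- beat_metrics(cv_run(p, 16, record_dt = 0.001), "last")
  p$global$dt <- 5e-05
  m2 <- beat_metrics(cv_run(p, 16, record_dt = 0.001), "last")
  expect_lt(abs(m1$co - m2$co) / m1$co, 0.01)
})

test_that("external pressure groups behave as specified", {
  peri <- list(p_min = -2, p_scale = 0.5, v_pc0 = 720, phi = 50)
  expect_equal(external_pressure("extrathoracic", p_thorax = 25), 0)
  expect_equal(external_pressure("intrathoracic", p_thorax = 10), 10)
  expect_equal(external_pressure("pericardial", p_thorax = 10,
                                 v_heart_total = 100, pericardium = peri),
               10 + pericardial_pressure(100, -2, 0.5, 720, 50))
  # small contained volume: pericardial group near the negative floor
  expect_lt(external_pressure("pericardial", 0, 50, peri), -1.9)
  expect_error(external_pressure("orbital"), "unknown")
  expect_error(external_pressure("pericardial"), "requires")
})

test_that("timed events change parameters mid-run and are ramped", {
  p <- cv_preset()
  ev <- data.frame(t = 2, path = "global.intrathoracic_pressure",
                   value = 8)
  tr <- cv_run(p, 5, events = ev, record_dt = 0.01)
  expect_equal(max(tr$p_thorax), 8)
  expect_equal(tr$p_thorax[tr$t < 2][100], 0)
  # ramped: intermediate values appear during the following second
  mid <- tr$p_thorax[tr$t > 2.05 & tr$t < 2.95]
  expect_true(any(mid > 0.5 & mid < 7.5))
  # intrathoracic luminal pressures shift upward with p_thorax
  before <- mean(tr$p_pulm_trunk[tr$t > 1 & tr$t < 2])
  after <- mean(tr$p_pulm_trunk[tr$t > 4 & tr$t < 5])
  expect_gt(after, before + 3)
})

test_that("solver diagnostics report a steady baseline without failures", {
  tr <- baseline_trace()
  d <- attr(tr, "diag")
  expect_lt(d$substeps, 50)   # only the start-up transient may sub-step
  expect_lt(d$newton_iters / d$steps, 12)
  m <- beat_metrics(tr)
  co <- tail(m$co, 6)
  expect_lt(max(abs(co - mean(co))) / mean(co), 0.005)
})
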