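# Scenario runner, directional pathology checks, rhythm modes and the
# sensitivity analysis.

test_that("unknown scenarios fail with the list of valid names", {
  expect_error(run_scenario("mitral_prolapse"), "valid scenarios")
})

test_that("pathologies move the clinical metrics in the published directions", {
  base <- beat_metrics(baseline_trace(), "last")
  shf <- scenario_cached("systolic_hf")$report
  dhf <- scenario_cached("diastolic_hf")$report
  as <- scenario_cached("aortic_stenosis")$report
  ar <- scenario_cached("aortic_regurgitation")$report

  # systolic heart failure: EF and stroke work fall, EDV and LAP rise
  expect_lt(shf$lvef, base$lv_ef - 20)
  expect_lt(shf$lvsw, base$lv_sw)
  expect_gt(shf$lvedv, base$lv_edv + 20)
  expect_gt(shf$lap, base$lap + 2)
  expect_lt(shf$sap_sys, base$sap_sys)

  # diastolic heart failure: EF preserved, EDV falls, LAP rises
  expect_gt(dhf$lvef, base$lv_ef - 10)
  expect_lt(dhf$lvedv, base$lv_edv - 5)
  expect_gt(dhf$lap, base$lap + 2)

  # aortic stenosis: intraventricular pressure and stroke work rise
  # while systemic pressure falls (pressure load)
  expect_gt(as$lvesp, base$lv_esp + 50)
  expect_gt(as$lvsw, base$lv_sw)
  expect_lt(as$sap_sys, base$sap_sys)
  expect_gt(as$lvedv, base$lv_edv)

  # aortic regurgitation: apparent stroke volume rises, diastolic
  # pressure falls (volume load)
  expect_gt(ar$lvsv, base$lv_sv + 20)
  expect_lt(ar$sap_dia, base$sap_dia - 5)
  expect_gt(ar$lvsw, base$lv_sw)
})

test_that("left coronary flow is impeded in systole by wall compression", {
  tr <- baseline_trace()
  w <- tr[tr$t > 58, ]
  systole <- w$zeta_aortic > 0.5
  qs <- mean(w$q_l_cor_epi__l_cor_micro[systole])
  qd <- mean(w$q_l_cor_epi__l_cor_micro[!systole])
  expect_lt(qs, qd)
  # removing the compression raises the systolic/diastolic ratio
  p <- cv_preset()
  p$segments$l_cor_micro$compress_k <- 0
  tr0 <- cv_run(p, 20, record_dt = 0.002)
  w0 <- tr0[tr0$t > 18, ]
  s0 <- w0$zeta_aortic > 0.5
  r0 <- mean(w0$q_l_cor_epi__l_cor_micro[s0]) /
        mean(w0$q_l_cor_epi__l_cor_micro[!s0])
  expect_gt(r0, qs / qd)
  expect_gt(r0, 1)
})

test_that("atrial fibrillation mode lowers output and is seed-reproducible", {
  p <- cv_preset()
  p$af$enabled <- TRUE
  p$af$rr_jitter <- 0.25
  p$af$seed <- 11
  p$chambers$la$e_max <- p$chambers$la$e_min
  p$chambers$ra$e_max <- p$chambers$ra$e_min
  af <- beat_metrics(cv_run(p, 30, record_dt = 0.005))
  sr <- beat_metrics(cv_run(cv_preset(), 30, record_dt = 0.005))
  expect_lt(mean(tail(af$co, 8)), mean(tail(sr$co, 8)))
  # RR intervals are actually irregular, and reproducible for a seed
  expect_gt(stats::sd(tail(af$hr, 12)), 1)
  af2 <- beat_metrics(cv_run(p, 30, record_dt = 0.005))
  expect_equal(af$hr, af2$hr)
})

test_that("sensitivity analysis ranks blood volume first and zeroes dead inputs", {
  s <- sensitivity_analysis(
    parameters = c("global.blood_volume", "chambers.lv.e_max",
                   "segments.sys_arteriolae.radius0",
                   "pericardium.v_pc0", "baroreflex.gain_hr"),
    settle = 30, record_dt = 0.005)
  expect_setequal(unique(s$output),
                  c("LVESP", "RVESP", "LAP", "RAP", "LVSW", "RVSW", "CO"))
  rank <- attr(s, "ranking")
  expect_equal(names(rank)[1], "global.blood_volume")
  # a parameter with no downstream connection has S = 0 everywhere
  expect_equal(s$s_norm[s$parameter == "baroreflex.gain_hr"], rep(0, 7))
  # the headline table filters |S| < 10 %
  hl <- attr(s, "headline")
  expect_false("baroreflex.gain_hr" %in% hl$parameter)
  # near-linearity: half the perturbation gives about half the response
  y0 <- s$baseline[s$parameter == "global.blood_volume" & s$output == "CO"]
  y10 <- s$perturbed[s$parameter == "global.blood_volume" & s$output == "CO"]
  s5 <- sensitivity_analysis(parameters = "global.blood_volume",
                             delta = 0.05, settle = 30,
                             record_dt = 0.005)
  y5 <- s5$perturbed[s5$output == "CO"]
  expect_equal((y5 - y0) / (y10 - y0), 0.5, tolerance = 0.2)
})
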