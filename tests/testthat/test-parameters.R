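# Parameter model: presets, config I/O, paths, scenario application.

test_that("baseline preset carries the documented global settings", {
  p <- cv_preset("normal")
  expect_equal(p$global$heart_rate, 72)
  expect_equal(p$global$blood_volume, 5600)
  expect_equal(p$global$blood_viscosity, 0.00024)
  expect_equal(p$global$blood_density, 1.060)
  expect_equal(p$global$hb, 140)
  expect_equal(p$global$vo2_systemic, 250)
  expect_equal(p$global$pulm_cap_sat, 99.4)
  expect_equal(p$global$pulm_shunt_fraction, 0.10)
  expect_equal(p$global$young_modulus, 3000)
  expect_equal(p$global$damping_lambda, 0.5)
  expect_equal(p$global$dt, 0.00025)
  expect_equal(p$chambers$lv$e_max, 2.8)
  expect_equal(p$chambers$lv$e_min, 0.05)
  expect_equal(p$valves$aortic$a_max, 5.0)
  expect_length(p$segments, 26)
  expect_equal(sum(p$topology$stateful), 24)
})

test_that("config files load, validate and round-trip field for field", {
  p <- cv_preset()
  path <- withr::local_tempfile(fileext = ".json")
  write_config(p, path)
  q <- load_config(path)
  expect_s3_class(q, "cvloop_params")
  skip_fields <- "topology"
  expect_equal(unclass(q)[setdiff(names(q), skip_fields)],
               unclass(p)[setdiff(names(p), skip_fields)],
               tolerance = 1e-12)
  expect_identical(as.data.frame(q$topology), as.data.frame(p$topology))
  # the shipped baseline file equals the coded preset
  shipped <- load_config(system.file("extdata", "normal_config.json",
                                     package = "cvloop"))
  expect_equal(unclass(shipped)[setdiff(names(shipped), skip_fields)],
               unclass(p)[setdiff(names(p), skip_fields)],
               tolerance = 1e-12)
})

test_that("schema violations are rejected with the offending field named", {
  p <- cv_preset()
  p$segments$sys_cap$radius0 <- -1
  expect_error(cv_validate(p), "segments.sys_cap.radius0")
  p <- cv_preset()
  p$global$damping_lambda <- 1.5
  expect_error(cv_validate(p), "damping_lambda")
  p <- cv_preset()
  p$valves$mitral$a_min <- 0.4
  p$valves$mitral$a_max <- 0.2
  expect_error(cv_validate(p), "valves.mitral")
  expect_error(load_config(tempfile()), "not found")
})

test_that("parameter paths resolve, patch non-destructively, and unknown paths fail", {
  p <- cv_preset()
  expect_true("chambers.lv.e_max" %in% cv_paths(p))
  expect_equal(cv_get(p, "chambers.lv.e_max"), 2.8)
  q <- cv_set(p, "chambers.lv.e_max", 1.0)
  expect_equal(cv_get(q, "chambers.lv.e_max"), 1.0)
  expect_equal(cv_get(p, "chambers.lv.e_max"), 2.8)  # base unmodified
  expect_error(cv_get(p, "chambers.lv.nonsense"), "valid paths")
})

test_that("scenarios apply the published patches and are idempotent", {
  p <- cv_preset()
  as <- apply_scenario(p, "aortic_stenosis")
  expect_equal(as$valves$aortic$a_max, 0.7)
  dhf <- apply_scenario(p, "diastolic_hf")
  expect_equal(dhf$chambers$lv$e_min, 0.12)
  shf <- apply_scenario(p, "systolic_hf")
  expect_equal(shf$chambers$lv$e_max, 1.0)
  ar <- apply_scenario(p, "aortic_regurgitation")
  expect_equal(ar$valves$aortic$a_min, 0.2)
  # identity scenario and idempotence of absolute patches
  norm <- apply_scenario(p, "normal")
  expect_equal(unclass(norm)[names(norm) != "topology"],
               unclass(p)[names(p) != "topology"])
  twice <- apply_scenario(apply_scenario(p, "aortic_stenosis"),
                          "aortic_stenosis")
  expect_equal(twice$valves$aortic$a_max, 0.7)
  expect_error(cv_scenario("no_such_scenario"), "valid scenarios")
  expect_setequal(cv_scenarios(),
                  c("normal", "systolic_hf", "diastolic_hf",
                    "aortic_stenosis", "aortic_regurgitation", "valsalva",
                    "exercise", "arteriosclerosis"))
})

test_that("valsalva events expand to set/restore pairs", {
  p <- apply_scenario(cv_preset(), "valsalva")
  ev <- attr(p, "events")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$t, c(20, 40))
  expect_equal(ev$value, c(10, 0))
  expect_true(all(ev$path == "global.intrathoracic_pressure"))
})
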