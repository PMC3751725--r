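# Vascular segment operations: base properties, transmural relation,
# instantaneous updates, wall damping.

test_that("base resistance follows Poiseuille with parallel-vessel scaling", {
  expect_equal(base_resistance(0.00024, 10, 0.5, 1),
               8 * 0.00024 * 10 / (pi * 0.5^4), tolerance = 1e-09)
  expect_equal(base_resistance(0.00024, 10, 0.5, 2),
               base_resistance(0.00024, 10, 0.5, 1) / 2)
  expect_equal(base_resistance(0.00024, 10, 1, 1),
               base_resistance(0.00024, 10, 0.5, 1) / 16)
})

test_that("base inertance converts CGS and scales with length and count", {
  expect_equal(base_inertance(1.060, 10, 1, 1),
               1.060 * 10 / pi / 1333.22, tolerance = 1e-09)
  expect_equal(base_inertance(1.060, 20, 1, 1),
               2 * base_inertance(1.060, 10, 1, 1))
  expect_lt(base_inertance(1.060, 10, 1, 1e09), 1e-10)
})

test_that("base elastance is linear in Young's modulus and halves with count", {
  expect_equal(base_elastance(3000, 0.1, 1, 10, 1),
               3000 * 0.1 / (2 * pi * 10), tolerance = 1e-09)
  expect_equal(base_elastance(6000, 0.1, 1, 10, 1),
               2 * base_elastance(3000, 0.1, 1, 10, 1))
  expect_equal(base_elastance(3000, 0.1, 1, 10, 2),
               base_elastance(3000, 0.1, 1, 10, 1) / 2)
})

test_that("transmural relation: anchor, slope, and e-fold at p0/e0", {
  v0 <- 100; p0 <- 20; e0 <- 0.5
  expect_equal(transmural_pressure(v0, v0, p0, e0), p0)
  h <- 1e-04
  slope <- (transmural_pressure(v0 + h, v0, p0, e0) -
            transmural_pressure(v0 - h, v0, p0, e0)) / (2 * h)
  expect_equal(slope, e0, tolerance = 1e-06)
  expect_equal(transmural_pressure(v0 + p0 / e0, v0, p0, e0) / p0, exp(1),
               tolerance = 1e-09)
  # linearised variant
  expect_equal(transmural_pressure(v0 + 8, v0, p0, e0, linear = TRUE),
               p0 + 8 * e0)
})

test_that("instantaneous properties update with volume via the radius", {
  st <- list(v = 100, v_ref = 100, r0 = 0.1, i0 = 0.002, e0 = 4,
             lambda = 0.5)
  now <- update_segment_properties(st)
  expect_equal(unname(now["r_now"]), 0.1)
  expect_equal(unname(now["i_now"]), 0.002)
  expect_equal(unname(now["e_now"]), 4)
  # quadrupled volume: radius doubles, resistance / 16
  st$v <- 400
  now4 <- update_segment_properties(st)
  expect_equal(unname(now4["r_now"]), 0.1 / 16)
  expect_equal(unname(now4["i_now"]), 0.002 / 4)
  expect_equal(unname(now4["e_now"]), 4 / 8)
  expect_error(update_segment_properties(list(v = -1, v_ref = 100,
                                              r0 = 1, i0 = 1, e0 = 1,
                                              lambda = 0.5)),
               "collapse")
  # property: continuity of E over a dense volume grid
  set.seed(5)
  v <- sort(c(seq(20, 400, length.out = 150), runif(50, 20, 400)))
  e <- vapply(v, function(vv) {
    st$v <- vv
    unname(update_segment_properties(st)["e_now"])
  }, 0)
  expect_true(all(abs(diff(e)) / e[-1] < 0.25))
})

test_that("wall damping is the scaled characteristic impedance", {
  i0 <- 1.060 * 10 / pi / 1333.22
  e0 <- 3000 * 0.1 / (2 * pi * 10)
  expect_equal(wall_damping(i0, e0, 0.5), 0.5 * sqrt(i0 * e0),
               tolerance = 1e-09)
  expect_equal(wall_damping(i0, e0, 0.5), 0.05496, tolerance = 1e-04)
  expect_equal(wall_damping(i0, e0, 0), 0)
  expect_equal(wall_damping(i0, e0, 1), 2 * wall_damping(i0, e0, 0.5))
  expect_error(wall_damping(1, 1, 1.2), "lambda")
})

test_that("flow continuity: compartment volume rates sum to zero", {
  p <- cv_preset()
  pack <- cvloop:::cv_pack(p)
  st <- cv_assemble(p)
  set.seed(11)
  for (i in 1:25) {
    x <- st$x
    n <- 30
    x[1:n] <- x[1:n] * runif(n, 0.8, 1.2)
    x[31:58] <- rnorm(28, 0, 150)
    x[59:62] <- runif(4)
    f <- cvloop:::cpp_rhs(pack, x, runif(1))
    expect_lt(abs(sum(f[1:n])), 1e-08 * max(abs(f[1:n])) + 1e-10)
  }
})
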