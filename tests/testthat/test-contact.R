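test_that("layer compression inverts the uniaxial stress law", {
  lay <- cartilage_layer(2.0, yeoh_params(1, 0))
  expect_identical(layer_compression(lay, 0), 0)
  # inverse of the lam = 0.9 stress example
  p09 <- -uniaxial_cauchy_stress(yeoh_params(1, 0), 0.9)
  expect_equal(layer_compression(lay, p09), 0.2, tolerance = 1e-9)
  expect_error(layer_compression(lay, -1), ">= 0")
  # strictly increasing in pressure
  ps <- seq(0, 5, by = 0.25)
  expect_true(all(diff(layer_compression(lay, ps)) > 0))
})

test_that("layer compression agrees with a plain bisection oracle", {
  set.seed(11)
  for (p in random_yeoh(25, seed = 11)) {
    lay <- cartilage_layer(runif(1, 1.5, 3), p)
    for (pr in runif(4, 0, 5)) {
      expect_equal(layer_compression(lay, pr),
                   oracle_layer_compression(lay, pr), tolerance = 1e-8)
    }
  }
})

test_that("column pressure balances the two layers in series", {
  spec <- midrange_spec("healthy")
  expect_identical(column_pressure(spec, 0), 0)
  # identical layers split the interpenetration evenly
  lay <- cartilage_layer(2.2, yeoh_params(1.5, 3))
  spec2 <- contact_pair_spec(femoral = lay, tibial = lay)
  for (u in c(0.2, 0.6, 1.0)) {
    p <- column_pressure(spec2, u)
    expect_equal(layer_compression(lay, p), u / 2, tolerance = 1e-7)
  }
  # strictly increasing in u
  us <- seq(0, 1.05, by = 0.05)
  expect_true(all(diff(column_pressure(spec, us)) > 0))
  expect_error(column_pressure(spec, 4.4), "thickness")
})

test_that("column pressure matches the nested-bisection oracle", {
  for (g in c("healthy", "oa")) {
    spec <- midrange_spec(g)
    for (u in c(0.1, 0.5, 0.9)) {
      expect_equal(column_pressure(spec, u),
                   oracle_column_pressure(spec, u), tolerance = 1e-8)
    }
  }
})

test_that("small indentations approach the linear elastic-foundation form", {
  # F = pi R delta^2 / (t_f/E_f + t_t/E_t), E = 6 C10, valid as delta -> 0
  for (g in c("healthy", "oa")) {
    spec <- midrange_spec(g)
    Ef <- 6 * spec$femoral$material$C10
    Et <- 6 * spec$tibial$material$C10
    closed <- pi * spec$sphere_radius * 0.01^2 /
      (spec$femoral$thickness / Ef + spec$tibial$thickness / Et)
    expect_equal(indentation_force(spec, 0.01), closed, tolerance = 0.02)
  }
})

test_that("radial quadrature is converged against a 10x finer grid", {
  for (g in c("healthy", "oa")) {
    spec <- midrange_spec(g)
    for (d in c(0.25, 1.00)) {
      coarse <- indentation_force(spec, d)
      fine <- indentation_force(spec, d, n_radial = 4000)
      expect_equal(coarse, fine, tolerance = 1e-3)
    }
  }
})

test_that("contact force scales linearly with a neo-Hookean stiffness factor", {
  s1 <- contact_pair_spec(femoral = cartilage_layer(2.3, yeoh_params(1.0, 0)),
                          tibial = cartilage_layer(2.1, yeoh_params(1.6, 0)))
  s2 <- contact_pair_spec(femoral = cartilage_layer(2.3, yeoh_params(2.0, 0)),
                          tibial = cartilage_layer(2.1, yeoh_params(3.2, 0)))
  c1 <- compute_curve(s1); c2 <- compute_curve(s2)
  expect_equal(c2$forces[-1] / c1$forces[-1], rep(2, 20), tolerance = 1e-6)
})

test_that("computed curves hit the printed grid and are monotone", {
  spec <- midrange_spec("healthy")
  cv <- compute_curve(spec)
  expect_length(cv$indentations, 21L)
  expect_identical(cv$indentations, seq(0, 1, by = 0.05))
  expect_identical(cv$forces[1], 0)
  expect_true(all(diff(cv$forces) > 0))
  expect_error(indentation_force(spec, -0.1), ">= 0")
  expect_error(indentation_force(spec, 1.2), "working range")
})

test_that("curve evaluation interpolates, extrapolates and clamps", {
  cv <- fi_curve(c(0, 0.5, 1), c(0, 100, 300))
  expect_identical(eval_curve(cv, -0.3), 0)
  expect_identical(eval_curve(cv, 0.5), 100)
  expect_equal(eval_curve(cv, 0.25), 50)
  expect_equal(eval_curve(cv, 1.25), 400)
  expect_equal(eval_curve(cv, c(-1, 0.75, 2)), c(0, 200, 700))
  expect_error(fi_curve(c(0, 1), c(5, 10)), "start")
  expect_error(fi_curve(c(0, 1, 0.5), c(0, 1, 2)), "increasing")
  expect_error(fi_curve(c(0, 0.5, 1), c(0, 2, 1)), "non-decreasing")
})

test_that("curves round-trip through their CSV export", {
  cv <- compute_curve(midrange_spec("oa"), n_steps = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fi_curve(cv, path)
  back <- read_fi_curve(path)
  expect_equal(back$forces, cv$forces, tolerance = 1e-12)
  expect_equal(back$indentations, cv$indentations)
})
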