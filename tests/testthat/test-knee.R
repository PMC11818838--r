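test_that("ligament law has a smooth toe and a continuous linear branch", {
  lig <- ligament("ACL", c(0, 0), c(0, 0), k = 1000, L0 = 100)
  expect_identical(ligament_force(lig, 100), 0)   # slack at L0
  expect_identical(ligament_force(lig, 90), 0)    # never pushes
  expect_equal(ligament_force(lig, 106), 30)      # toe branch at eps = 0.06
  expect_equal(1000 * (0.06 - 0.03), 30)          # linear branch agrees there
  expect_equal(ligament_force(lig, 110), 70)      # linear branch
  # first derivative is continuous across the toe-linear transition:
  # one-sided slopes agree to O(h)
  h <- 1e-6
  sl_left <- (ligament_force(lig, 100 * 1.06) -
                ligament_force(lig, 100 * (1.06 - h))) / (100 * h)
  sl_right <- (ligament_force(lig, 100 * (1.06 + h)) -
                 ligament_force(lig, 100 * 1.06)) / (100 * h)
  expect_equal(sl_left, sl_right, tolerance = 1e-4)
  expect_error(ligament_force(lig, 0), "> 0")
})

test_that("contact state passes curve forces through at the penetration depth", {
  model <- default_model()
  cv <- linear_curve()
  curves <- list(cv, cv)
  # condyles lifted far above the plateau: no force
  up <- planar_state(q = c(0, 80, 55))
  cs <- contact_state(model, up, curves)
  expect_true(all(cs$indentation_mm == 0))
  expect_true(all(cs$force_N == 0))
  # grazing: center exactly radius-high gives zero indentation
  m2 <- knee_model(model$ligaments, condyle_centers = matrix(0, 2, 2),
                   condyle_radius = 40, mass = 4, inertia = 0.02,
                   damping_lin = 0, damping_ang = 0, theta0_deg = 0,
                   q0 = c(0, 40))
  cs2 <- contact_state(m2, planar_state(q = c(0, 40, 0)), curves)
  expect_equal(cs2$force_N, c(0, 0))
  # indentation of exactly 1 mm reproduces the curve value
  real <- compute_curve(midrange_spec("healthy"))
  cs3 <- contact_state(m2, planar_state(q = c(0, 39, 0)), list(real, real))
  expect_equal(cs3$indentation_mm, c(1, 1))
  expect_equal(cs3$force_N, rep(real$forces[21], 2))
})

test_that("net wrench reduces to statics in elementary configurations", {
  # free-floating femur: only the applied moment remains
  ligs <- list(ligament("ACL", c(0, 0), c(0, -1000), k = 1, L0 = 2000),
               ligament("PCL", c(0, 0), c(0, -1000), k = 1, L0 = 2000),
               ligament("MCL", c(0, 0), c(0, -1000), k = 1, L0 = 2000),
               ligament("LCL", c(0, 0), c(0, -1000), k = 1, L0 = 2000))
  m <- knee_model(ligs, condyle_centers = matrix(c(0, 0, 200, 200), 2, 2),
                  condyle_radius = 40, mass = 4, inertia = 0.02,
                  damping_lin = 0, damping_ang = 0, theta0_deg = 0,
                  q0 = c(0, 400))
  cv <- list(linear_curve(), linear_curve())
  w <- net_wrench(m, planar_state(q = c(0, 400, 0)), cv, M_ext = 1)
  expect_equal(w, c(0, 0, 1))
  # one taut vertical cable through the reference point: pure downward pull
  ligs2 <- ligs
  ligs2[[1]] <- ligament("ACL", c(0, 0), c(0, 0), k = 1000, L0 = 100)
  m2 <- knee_model(ligs2, condyle_centers = matrix(c(0, 0, 200, 200), 2, 2),
                   condyle_radius = 40, mass = 4, inertia = 0.02,
                   damping_lin = 0, damping_ang = 0, theta0_deg = 0,
                   q0 = c(0, 400))
  st <- planar_state(q = c(0, 110, 0))  # cable length 110 mm, eps = 0.10
  w2 <- net_wrench(m2, st, cv, M_ext = 0)
  expect_equal(w2, c(0, -70, 0))
})

test_that("net wrench equals minus the gradient of the elastic energy", {
  model <- default_model()
  real <- compute_curve(midrange_spec("healthy"))
  curves <- list(real, real)
  set.seed(5)
  for (i in 1:5) {
    q <- c(runif(1, -3, 3) / 1000, (39 + runif(1, -0.5, 0.3)) / 1000,
           (55 + runif(1, -25, 25)) * pi / 180)
    st <- planar_state(q = c(q[1] * 1000, q[2] * 1000, q[3] * 180 / pi))
    w <- net_wrench(model, st, curves, M_ext = 0)
    g <- pracma::grad(function(qq) knee_energy(model, qq, curves), q,
                      heps = 1e-7)
    expect_equal(w, -g, tolerance = 1e-5)
  }
})

test_that("semi-implicit Euler matches its closed form under constant force", {
  model <- default_model()
  st <- planar_state(q = c(0, 0, 0))
  w <- c(0.8, 0, 0)   # constant 0.8 N on the mass, no moment
  dt <- 0.001
  n <- 250
  for (i in seq_len(n)) st <- step_semi_implicit(st, w, dt, model)
  # q_n = F/m * dt^2 * n(n+1)/2 (in m), interface reports mm
  expect_equal(st$q[1], 0.8 / model$mass * dt^2 * n * (n + 1) / 2 * 1000,
               tolerance = 1e-12)
  expect_equal(st$v[1], 0.8 / model$mass * dt * n * 1000, tolerance = 1e-12)
  # zero wrench at rest: state unchanged
  s0 <- planar_state(q = c(1, 2, 3))
  expect_equal(step_semi_implicit(s0, c(0, 0, 0), dt, model)$q, s0$q)
})

test_that("symplectic integration keeps a stiff spring bounded over 16 s", {
  # two opposed pre-strained cables form a two-sided spring on the femur;
  # with no damping the oscillation must not grow over the full protocol
  # horizon at dt = 0.001 s
  ligs <- list(ligament("ACL", c(0, 0), c(0, -1000), k = 4e4, L0 = 950),
               ligament("PCL", c(0, 0), c(0, 1000), k = 4e4, L0 = 950),
               ligament("MCL", c(0, 0), c(0, -2000), k = 1, L0 = 5000),
               ligament("LCL", c(0, 0), c(0, -2000), k = 1, L0 = 5000))
  m <- knee_model(ligs, condyle_centers = matrix(c(0, 0, 900, 900), 2, 2),
                  condyle_radius = 40, mass = 4, inertia = 0.02,
                  damping_lin = 0, damping_ang = 0, theta0_deg = 0,
                  q0 = c(0, 0))
  cv <- list(linear_curve(), linear_curve())
  st <- planar_state(q = c(0, 2, 0))  # 2 mm off the symmetric equilibrium
  dt <- 0.001
  ymax <- -Inf
  for (i in 1:16000) {
    w <- net_wrench(m, st, cv, M_ext = 0)
    st <- step_semi_implicit(st, w, dt, m)
    ymax <- max(ymax, abs(st$q[2]))
  }
  expect_lt(ymax, 3)  # bounded oscillation, no secular energy growth
})

test_that("branch runs settle, respect conventions and record maxima", {
  model <- default_model()
  cv <- compute_curve(midrange_spec("healthy"))
  curves <- list(cv, cv)
  # no external moment: the model stays at its static equilibrium
  still <- run_branch(model, curves, load_protocol("extension", M_max = 0))
  again <- run_branch(model, curves, load_protocol("extension", M_max = 0))
  expect_equal(still$final_state$q[3], again$final_state$q[3],
               tolerance = 1e-9)
  expect_lt(abs(still$final_state$q[3] - tail(still$plateau$theta_deg, 1)),
            1e-3)
  ext <- run_branch(model, curves, load_protocol("extension"))
  flex <- run_branch(model, curves, load_protocol("flexion"))
  # extension-positive moment reduces the flexion angle
  expect_lt(ext$final_state$q[3], model$theta0_deg)
  expect_gt(flex$final_state$q[3], model$theta0_deg)
  expect_gte(angular_range(ext, flex), 0)
  expect_identical(angular_range(ext, ext), 0)
  # every plateau reaches quasi-static equilibrium
  expect_lt(max(ext$plateau$residual), 1e-3)
  expect_lt(max(flex$plateau$residual), 1e-3)
  expect_lt(ext$kinetic_energy_J, 1e-6)
  expect_lt(flex$kinetic_energy_J, 1e-6)
  # unilateral contact and tension-only cables throughout the recording
  expect_true(all(ext$contact_forces_N >= 0))
  expect_true(all(ext$lig_forces_N >= 0))
  # recorded maxima dominate the decimated trajectory
  expect_true(all(apply(flex$lig_forces_N, 2, max) <= flex$max_lig_N + 1e-9))
})

test_that("diverging integrations are reported with the failing step", {
  model <- default_model()
  m <- knee_model(model$ligaments, model$condyle_centers,
                  condyle_radius = 40, mass = 0.001, inertia = 1e-7,
                  damping_lin = 0, damping_ang = 0,
                  theta0_deg = 55, q0 = model$q0)
  stiff <- fi_curve(c(0, 1), c(0, 1e7))
  expect_error(
    run_branch(m, list(stiff, stiff),
               load_protocol("flexion", duration = 2)),
    "diverged")
})
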