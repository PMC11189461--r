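## Allen-Cahn dynamics: initial condition, stationarity, consistency with
## explicit Euler, energy descent, relaxation to the equilibrium radius
## and time-step convergence of the fission time.

test_that("initial tubule is the exact tanh profile", {
  g <- small_grid(L_z = 64)
  pars <- small_params()
  phi <- initial_tubule(8, pars, g)
  ## interpolated contour sits on R_in
  ct <- extract_midplane_contour(phi, g)
  expect_lt(max(abs(ct$r_mid - 8)), g$dr / 10)
  ## bulk values at the axis and the outer wall
  expect_gt(min(phi[1, ]), 1 - 5e-6)
  expect_lt(max(phi[g$N_r, ]), -1 + 1e-3)
  ## too-large tubules are rejected
  expect_error(initial_tubule(13, pars, g), "radial boundary")
})

test_that("a relaxed unforced tubule is stationary", {
  g <- small_grid(L_z = 64)
  pars <- small_params()
  st <- allen_cahn_step(initial_tubule(pars$R_in, pars, g), NULL, pars, g,
                        nsteps = 3000)
  ## the raw residual force (tiny-step probe; includes truncation-
  ## boundary components the dynamics never integrates) is small ...
  probe <- allen_cahn_step(st$phi, NULL, pars, g, dt = 1e-6, nsteps = 1)
  expect_lt(probe$max_dphi / (1e-6 * pars$M_pf), 5e-3)
  ## ... and the dynamically effective force of a production step is at
  ## the equilibrium tolerance scale
  st2 <- allen_cahn_step(st$phi, NULL, pars, g, nsteps = 1)
  expect_lt(st2$max_dphi, 1e-5)
  ## the relaxed radius stays at R_in
  ct <- extract_midplane_contour(st2$phi, g)
  expect_equal(mean(ct$r_mid), pars$R_in, tolerance = 0.02)
})

test_that("interfaces advance at the sharp-interface mobility", {
  ## a uniform weak pressure drives the tubule wall inward at
  ## v = M_sharp p; checked at a small step where the semi-implicit
  ## damping of interface modes is negligible
  pars <- default_params()
  g <- axisym_grid(24, 16, 60, 40)
  p0 <- 0.01
  pmat <- matrix(p0, 60, 40)
  phi0 <- initial_tubule(16.6, pars, g)
  dt <- 4.4e-5
  n <- round(0.4 / dt)
  phi_f <- allen_cahn_step(phi0, pmat, pars, g, dt = dt, nsteps = n)$phi
  phi_u <- allen_cahn_step(phi0, NULL, pars, g, dt = dt, nsteps = n)$phi
  dR <- mean(extract_midplane_contour(phi_f, g)$r_mid -
             extract_midplane_contour(phi_u, g)$r_mid)
  v <- dR / 0.4
  expect_equal(v, -mobility_sharp(pars$M_pf, pars$eps) * p0,
               tolerance = 0.05)
})

test_that("semi-implicit step agrees with explicit Euler to O(dt^2)", {
  ## a smooth wide-interface slab normal to z keeps the spectral content
  ## where the implicit symbol is small (and has no unsaturated tail at
  ## the axis whose mirror extension would kink), isolating the O(dt^2)
  ## splitting error of the scheme itself
  g <- small_grid(L_z = 64)
  pars <- small_params()
  phi <- outer(rep(1, g$N_r), g$z_centers, function(r, z)
    tanh((z - 19.2) / (sqrt(2) * 2)) - tanh((z - 44.8) / (sqrt(2) * 2)) - 1)
  coat <- suppressWarnings(dynamin_coat(H = 16, z0 = 32, F_tau = 3.25))
  p <- pressure_field(coat_set(coat), g)
  err <- vapply(c(2e-5, 1e-5), function(dt) {
    st <- allen_cahn_step(phi, p, pars, g,
                          stepper = time_stepper(dealias = FALSE),
                          dt = dt, nsteps = 1)
    V <- variational_derivative_elastic(phi, g, pars) +
      0.75 * (1 - phi^2) * p
    expl <- phi - dt * pars$M_pf * V
    mean(abs(st$phi - expl))
  }, numeric(1))
  ## halving dt quarters the difference
  expect_gt(err[1] / err[2], 3.3)
  expect_lt(err[1] / err[2], 4.7)
})

test_that("forced evolution dissipates the total free energy", {
  g <- small_grid(L_z = 96)
  pars <- small_params()
  coat <- dynamin_coat(H = 16, z0 = 48, F_tau = 3.25)
  p <- pressure_field(coat_set(coat), g)
  phi <- initial_tubule(pars$R_in, pars, g)
  Ftot <- function(f) elastic_energy(f, g, pars, coats = p)$F
  F_series <- Ftot(phi)
  for (b in 1:6) {
    phi <- allen_cahn_step(phi, p, pars, g, nsteps = 300)$phi
    F_series <- c(F_series, Ftot(phi))
  }
  expect_true(all(diff(F_series) < 0))
})

test_that("unforced tubules relax monotonically toward R_in", {
  g <- small_grid(L_z = 64)
  pars <- small_params()
  for (fac in c(0.9, 1.1)) {
    phi <- initial_tubule(fac * pars$R_in, pars, g)
    devs <- numeric(0)
    for (b in 1:4) {
      phi <- allen_cahn_step(phi, NULL, pars, g, nsteps = 800)$phi
      ct <- extract_midplane_contour(phi, g)
      devs <- c(devs, abs(mean(ct$r_mid) - pars$R_in))
    }
    expect_true(all(diff(devs) < 1e-6))
  }
})

test_that("run_simulation reaches equilibrium for an uncoated tubule", {
  g <- small_grid(L_z = 64)
  pars <- small_params()
  cfg <- simulation_config(g, pars, coat_set(list()),
                           stepper = time_stepper(block = 400,
                                                  equilibrium_tol = 5e-4),
                           t_max = 30)
  traj <- run_simulation(cfg)
  expect_equal(traj$events$outcome, "equilibrium")
  expect_equal(traj$events$worst_energy_ascent, 0)
  last <- traj$observables[nrow(traj$observables), ]
  ## elastic energy stays at the unperturbed baseline
  expect_lt(abs(last$F_e - traj$E0) / traj$E0, 5e-3)
  expect_false(any(traj$observables$fission_flag))
})

test_that("fission time converges under dt halving and scales with mobility", {
  ## a fast fission case on a short periodic tubule: small tubule,
  ## strong power stroke.  Fission times converge first-order in the
  ## step (the semi-implicit stabilizer lags interface modes), so the
  ## halving is checked at a step well below the stability cap.
  g <- axisym_grid(16, 64, 40, 160)
  base_cfg <- function(dt, Mfac = 1) {
    pars <- elastic_params(k_b = 16, gamma_si = 5e-4, M_pf = 4.04 * Mfac)
    suppressWarnings(simulation_config(
      g, pars, coat_set(dynamin_coat(H = 16, z0 = 32, F_tau = 4.5)),
      stepper = time_stepper(dt = dt, block = 200, adapt = TRUE),
      t_max = 60, post_fission_time = 0))
  }
  dt0 <- 3.5e-4
  tf1 <- fission_time(suppressWarnings(run_simulation(base_cfg(dt0))))
  tf2 <- fission_time(suppressWarnings(run_simulation(base_cfg(dt0 / 2))))
  expect_false(is.na(tf1) || is.na(tf2))
  expect_lt(abs(tf1 - tf2) / tf2, 0.10)
  ## doubling the mobility at half the step halves the fission time
  ## exactly: the overdamped dynamics depends on time only through
  ## M_pf * t, so this is a strict rescaling identity of the scheme
  cfgM <- base_cfg(dt0 / 2, Mfac = 2)
  stM <- allen_cahn_step(initial_tubule(8.11, cfgM$params, g),
                         pressure_field(cfgM$coats, g), cfgM$params, g,
                         cfgM$stepper, dt = dt0 / 2, nsteps = 50)
  cfg1 <- base_cfg(dt0)
  st1 <- allen_cahn_step(initial_tubule(8.11, cfg1$params, g),
                         pressure_field(cfg1$coats, g), cfg1$params, g,
                         cfg1$stepper, dt = dt0, nsteps = 50)
  expect_equal(stM$phi, st1$phi, tolerance = 1e-12)
})
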