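## The dynamin coat pressure model, mediating function, interaction
## energy, spread force and depolymerization.

test_that("pressure has the printed normalization on the coat interior", {
  g <- axisym_grid(24, 300, 60, 750)
  coat <- dynamin_coat(H = 20, z0 = 150)
  p <- pressure_field(coat_set(coat), g, units = "pn")
  ## p(R_in, z0) = N_d F_tau / (h R_in), cutoff and taper inactive there
  R_in <- 16.6
  i <- which.min(abs(g$r_centers - R_in))
  j <- which.min(abs(g$z_centers - 150))
  expect_equal(p[i, j], 13 * 2.5 / (10 * g$r_centers[i]), tolerance = 1e-12)
  expect_equal(coat_pressure_peak(coat, R_in), 13 * 2.5 / (10 * R_in))
  ## zero beyond the taper
  far <- g$z_centers > 150 + 10 + coat$edge_width
  expect_true(all(p[, far] == 0))
  ## non-negative everywhere
  expect_true(all(p >= 0))
})

test_that("radial cutoff kills the 1/r growth near the axis", {
  g <- axisym_grid(24, 100, 120, 250)  # fine radial sampling
  coat <- dynamin_coat(H = 40, z0 = 50)
  p <- pressure_field(coat_set(coat), g, units = "pn")
  j <- which.min(abs(g$z_centers - 50))
  pr <- p[, j]
  r <- g$r_centers
  ## p -> 0 monotonically as r -> 0 below the cutoff ramp (the ramp is
  ## centered at R_cut - 3 w)
  below <- r < coat$R_cut - 4 * coat$cutoff_width
  expect_true(all(diff(pr[below]) >= -1e-14))
  expect_lt(pr[1], 1e-3 * max(pr))
  ## the cutoff beats the 1/r growth: p(R_cut/2) is far below the
  ## uncut 1/r extrapolation from r = 3 R_cut
  i_half <- which.min(abs(r - coat$R_cut / 2))
  i_3 <- which.min(abs(r - 3 * coat$R_cut))
  expect_lt(pr[i_half], 0.01 * pr[i_3] * (3 * coat$R_cut / (coat$R_cut / 2)))
  ## monotonically decreasing for r > 2 R_cut
  above <- r > 2 * coat$R_cut & r < 20
  expect_true(all(diff(pr[above]) <= 1e-14))
})

test_that("coat-set pressure is the sum of single-coat pressures", {
  g <- axisym_grid(16, 448, 40, 1120)
  c1 <- dynamin_coat(H = 20, z0 = 130, F_tau = 3.25)
  c2 <- dynamin_coat(H = 20, z0 = 320, F_tau = 3.25)
  p12 <- pressure_field(coat_set(c1, c2), g)
  expect_equal(p12, pressure_field(coat_set(c1), g) +
                     pressure_field(coat_set(c2), g), tolerance = 1e-14)
  ## inactive coats exert nothing
  c1$active <- FALSE
  expect_equal(pressure_field(coat_set(c1), g), matrix(0, 40, 1120))
  ## coats outside the domain are rejected
  expect_error(pressure_field(coat_set(dynamin_coat(H = 100, z0 = 20)), g),
               "outside")
  ## sub-turn coats warn
  expect_warning(dynamin_coat(H = 5, z0 = 100), "full turn")
})

test_that("mediating function is the printed cubic", {
  expect_equal(mediating(1), 0.5)
  expect_equal(mediating(-1), -0.5)
  expect_equal(mediating(0), 0)
  expect_equal(mediating(0.5), 0.75 * (0.5 - 0.125 / 3))
})

test_that("interaction energy is the mediated volume integral", {
  g <- axisym_grid(20, 60, 50, 150)
  phi <- tanh_tubule(12, g)
  coat <- dynamin_coat(H = 20, z0 = 30)
  expect_equal(interaction_energy(matrix(0, 50, 150), coat_set(coat), g), 0)
  expect_equal(interaction_energy(phi, matrix(0, 50, 150), g), 0)
  ## uniform pressure over a sub-cylinder deep inside the phi = +1 phase:
  ## I = h(1) p V = 0.5 p V up to the exponentially small tanh tail
  p0 <- 0.05
  pm <- matrix(0, 50, 150)
  sub <- g$r_centers < 12 - 5 * EPS_BILAYER
  pm[sub, ] <- p0
  V_sub <- pi * max(g$r_centers[sub] + g$dr / 2)^2 * g$L_z
  I <- interaction_energy(phi, pm, g)
  expect_equal(I, 0.5 * p0 * V_sub, tolerance = 1e-4)
  ## exact agreement with an independently coded quadrature
  w <- 2 * pi * g$r_centers * g$dr * g$dz
  I_oracle <- 0
  for (j in seq_len(g$N_z))
    I_oracle <- I_oracle +
      sum(0.75 * (phi[, j] - phi[, j]^3 / 3) * pm[, j] * w)
  expect_equal(I, I_oracle, tolerance = 1e-12)
})

test_that("spread force is the weak-limit surface delta", {
  g <- axisym_grid(20, 80, 50, 200)
  ## planar slab: the line integral of (3/4)(1-phi^2)|grad phi| along the
  ## normal through one interface equals h(1) - h(-1) = 1
  phi <- tanh_slab(g)
  fd <- external_force_density(phi, matrix(1, 50, 200), g)
  grad <- gradient_axisym(phi, g)
  integrand <- 0.75 * (1 - phi^2) * abs(grad$dz)
  half <- g$z_centers < g$L_z / 2  # one of the two interfaces
  expect_equal(sum(integrand[1, half]) * g$dz, 1, tolerance = 1e-6)
  ## force vanishes in the bulk phases
  bulkish <- abs(phi) > 0.999999
  expect_lt(max(abs(fd$dI_dphi[bulkish])), 1e-4)
  expect_equal(fd$dI_dphi, 0.75 * (1 - phi^2), tolerance = 1e-12)
})

test_that("depolymerization deactivates exactly the coats at the site", {
  c_single <- coat_set(dynamin_coat(H = 20, z0 = 150))
  expect_identical(depolymerize_on_fission(c_single, FALSE), c_single)
  out <- depolymerize_on_fission(c_single, TRUE, fission_z = 150)
  expect_false(out[[1]]$active)
  ## five collars ~90 nm apart, fission under the third
  collars <- coat_set(lapply(1:5, function(i)
    dynamin_coat(H = 20, z0 = 90 * i, F_tau = 3.25)))
  out5 <- depolymerize_on_fission(collars, TRUE, fission_z = 270)
  expect_equal(vapply(out5, function(ct) ct$active, TRUE),
               c(TRUE, TRUE, FALSE, TRUE, TRUE))
  g <- axisym_grid(16, 540, 40, 1350)
  expect_equal(pressure_field(depolymerize_on_fission(
    coat_set(dynamin_coat(H = 20, z0 = 270)), TRUE, 270), g),
    matrix(0, 40, 1350))
})

test_that("long-coat plateau pressure reproduces the modified tension", {
  ## integrating the plateau pressure as an effective tension on the
  ## cylinder patch gives gamma_bar = gamma + N_d F_tau / h
  gam <- tension_si_to_kbt(1.5e-4)
  coat <- dynamin_coat(H = 300, z0 = 200)
  g <- axisym_grid(24, 400, 60, 1000)
  p <- pressure_field(coat_set(coat), g, units = "pn")
  i <- which.min(abs(g$r_centers - 16.6))
  j <- which.min(abs(g$z_centers - 200))
  ## p * r on the plateau = N_d F_tau / h, the added tension (pN/nm)
  expect_equal(p[i, j] * g$r_centers[i] / kbt_pN_nm(),
               modified_tension(gam, coat) - gam, tolerance = 1e-12)
})
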