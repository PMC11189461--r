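## Closed-form sharp-interface results and the linearized tubule response.

test_that("equilibrium radius reproduces the printed values", {
  expect_equal(equilibrium_radius(20, tension_si_to_kbt(1.5e-4)), 16.6,
               tolerance = 0.005)
  expect_equal(equilibrium_radius(16, tension_si_to_kbt(5e-4)), 8,
               tolerance = 0.02)
  ## scaling: quadrupling the tension halves the radius
  g <- tension_si_to_kbt(1.5e-4)
  expect_equal(equilibrium_radius(20, 4 * g),
               equilibrium_radius(20, g) / 2)
  expect_error(equilibrium_radius(-1, g))
})

test_that("modified tension and constricted radius match the coat model", {
  gam <- tension_si_to_kbt(1.5e-4)
  coat <- dynamin_coat(H = 200, z0 = 0)  # defaults N_d=13, F_tau=2.5, h=10
  gb <- modified_tension(gam, coat)
  expect_equal(gb, gam + 13 * 2.5 / 10 / kbt_pN_nm())
  expect_equal(constricted_radius(20, gb), 3.5, tolerance = 0.02)
  ## F_tau = 0 recovers the bare tubule
  coat0 <- dynamin_coat(H = 200, z0 = 0, F_tau = 0)
  expect_equal(modified_tension(gam, coat0), gam)
  expect_equal(constricted_radius(20, modified_tension(gam, coat0)),
               equilibrium_radius(20, gam))
})

test_that("cylinder Hamiltonian is stationary at the constricted radius", {
  gam <- tension_si_to_kbt(1.5e-4)
  coat <- dynamin_coat(H = 200, z0 = 0)
  gb <- modified_tension(gam, coat)
  Rc <- constricted_radius(20, gb)
  h <- 1e-5
  dH <- (cylinder_hamiltonian(Rc + h, 100, 20, gb) -
         cylinder_hamiltonian(Rc - h, 100, 20, gb)) / (2 * h)
  expect_lt(abs(dH), 1e-6 * cylinder_hamiltonian(Rc, 100, 20, gb))
})

test_that("sharp mobility conversion", {
  expect_equal(mobility_sharp(4.04, 5 / 6), 3.57, tolerance = 0.002)
  expect_equal(mobility_sharp(0, 1), 0)
  expect_equal(mobility_sharp(4.04, 2 * 5 / 6),
               2 * mobility_sharp(4.04, 5 / 6))
})

test_that("fission-time formula and its force correction", {
  expect_equal(alpha_fission(2.318), 2)
  expect_equal(alpha_fission(4), 1 + exp((2.318 - 4) / 0.805))
  coat <- dynamin_coat(H = 200, z0 = 0, F_tau = 4, N_d = 15)
  tf <- fission_time_prediction(16, tension_si_to_kbt(5e-4), coat,
                                M_sharp = 3.57)
  expect_equal(tf, 7.06, tolerance = 0.01)
  ## short coats trigger the long-coat warning
  expect_warning(
    fission_time_prediction(16, tension_si_to_kbt(5e-4),
                            dynamin_coat(H = 20, z0 = 0, F_tau = 4)),
    "long coats")
})

test_that("Green's function: value, parity, envelope", {
  R <- 16.6
  expect_equal(greens_function(0, R), sqrt(2) / (4 * R))
  z <- seq(-200, 200, by = 0.5)
  expect_equal(greens_function(z, R), greens_function(-z, R))
  env <- sqrt(2) / (2 * R) * exp(-abs(z) / (sqrt(2) * R))
  expect_true(all(abs(greens_function(z, R)) <= env + 1e-12))
})

test_that("linear deformation agrees with a direct spectral solve", {
  ## independent oracle: solve R^4 u'''' + u = RHS by Fourier series on a
  ## long periodic box, with the exact Fourier coefficients of the
  ## rectangular window
  R <- 16.6; kb <- 20
  for (H in c(2 * R, 1.5 * sqrt(2) * pi * R)) {
    Lbox <- 80 * R
    z <- seq(-Lbox / 2, Lbox / 2, length.out = 4001)[-1]
    u <- linear_deformation(H, R, kb, z_grid = z)
    nmax <- 4000
    kn <- 2 * pi * (1:nmax) / Lbox
    ## RHS = -Pi(z/H): exact Fourier series with mean -H/L and cosine
    ## coefficients -4 sin(k H/2)/(k L); each mode responds by
    ## 1/(R^4 k^4 + 1)
    u_or <- rep(-H / Lbox, length(z))
    coef <- -4 * sin(kn * H / 2) / (kn * Lbox) / (R^4 * kn^4 + 1)
    for (i in seq_along(kn)) u_or <- u_or + coef[i] * cos(kn[i] * z)
    expect_lt(max(abs(u - u_or)) / max(abs(u)), 1e-6)
  }
})

test_that("delta-width limit of the deformation is the Green's function", {
  R <- 10; kb <- 20
  z <- seq(-600, 600, by = 0.25)
  H <- 0.01
  u <- linear_deformation(H, R, kb, p_amplitude = kb / R^4 / H, z_grid = z)
  expect_equal(u / max(abs(u)), -greens_function(z, R) / greens_function(0, R),
               tolerance = 1e-4)
})

test_that("minima count flips across the splitting threshold", {
  R <- 16.6; kb <- 20
  Hs <- linear_threshold(R)
  expect_equal(Hs, 2 * sqrt(2) * pi * R)
  expect_equal(linear_threshold(2 * R), 2 * Hs)
  z <- seq(-40 * R, 40 * R, by = 0.1)
  u_below <- linear_deformation(0.9 * Hs, R, kb, z_grid = z)
  u_above <- linear_deformation(1.1 * Hs, R, kb, z_grid = z)
  expect_equal(count_linear_minima(u_below), 1L)
  expect_equal(count_linear_minima(u_above), 2L)
  ## H = 2 R_in: single central dimple
  u_short <- linear_deformation(2 * R, R, kb, z_grid = z)
  expect_equal(count_linear_minima(u_short), 1L)
  expect_equal(z[which.min(u_short)], 0, tolerance = 0.11)
})

test_that("shape-equation residual vanishes on the equilibrium cylinder", {
  kb <- 20; gam <- tension_si_to_kbt(1.5e-4)
  R <- equilibrium_radius(kb, gam)
  n <- 256; Lz <- 400
  res <- shape_equation_residual(rep(R, n), rep(pi / 2, n), 0, kb, gam, Lz)
  expect_lt(max(abs(res)), 1e-12)
  ## off-equilibrium cylinder picks up the tension imbalance
  res2 <- shape_equation_residual(rep(1.2 * R, n), rep(pi / 2, n), 0,
                                  kb, gam, Lz)
  expect_gt(max(abs(res2)), 1e-3)
})

test_that("shape-equation residual linearizes to the quartic response", {
  ## for r = R + a u with u a solution of the linear response to p = a pbar,
  ## the residual is O(a^2): halving a quarters the residual
  kb <- 20; gam <- tension_si_to_kbt(1.5e-4)
  R <- equilibrium_radius(kb, gam)
  n <- 512; Lz <- 60 * R
  z <- ((seq_len(n) - 0.5) * Lz / n) - Lz / 2
  kw <- 2 * pi * 3 / Lz
  pbar <- kb / R^4 * cos(kw * z)          # O(1) pressure shape
  u <- (R^4 / kb) / (R^4 * kw^4 + 1) * (kb / R^4) * cos(kw * z)
  du <- -(R^4 / kb) / (R^4 * kw^4 + 1) * (kb / R^4) * kw * sin(kw * z)
  resid_at <- function(a) {
    ## tangent angle from dr/dz = cos(psi)/sin(psi)
    psi <- pi / 2 - atan(a * du)
    max(abs(shape_equation_residual(R + a * u, psi, a * pbar, kb, gam, Lz)))
  }
  r1 <- resid_at(1e-2)
  r2 <- resid_at(5e-3)
  expect_lt(r1 / r2, 4.6)
  expect_gt(r1 / r2, 3.4)
  ## doubling p doubles the residual imbalance of a fixed profile
  rfix <- R + 0.5 * cos(kw * z)
  psif <- pi / 2 - atan(-0.5 * kw * sin(kw * z))
  base <- shape_equation_residual(rfix, psif, 0, kb, gam, Lz)
  r_p <- shape_equation_residual(rfix, psif, 0.01, kb, gam, Lz) - base
  r_2p <- shape_equation_residual(rfix, psif, 0.02, kb, gam, Lz) - base
  expect_equal(r_2p, 2 * r_p, tolerance = 1e-9)
})

test_that("sharp_prediction bundles all quantities consistently", {
  pars <- elastic_params()
  coat <- dynamin_coat(H = 200, z0 = 0)
  sp <- sharp_prediction(pars, coat)
  expect_equal(sp$R_in, pars$R_in)
  expect_equal(sp$R_c, constricted_radius(pars$k_b, sp$gamma_bar))
  expect_equal(sp$H_star_le, 2 * sqrt(2) * pi * sp$R_in)
  expect_equal(sp$L_dec, sqrt(2) * sp$R_in)
  expect_lt(sp$R_c, sp$R_in)
})
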