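#' Initial tubule configuration
#'
#' The undeformed cylindrical tubule represented as the exact profile
#' \eqn{\phi(r, z) = \tanh((R_{in} - r)/(\sqrt{2}\epsilon))} evaluated at
#' cell centers.
#'
#' @param R_in tubule radius (nm).
#' @param params an \code{\link{elastic_params}} (for \code{eps}).
#' @param grid an \code{\link{axisym_grid}}.
#' @return phase field matrix.
#' @export
initial_tubule <- function(R_in, params, grid) {
  if (R_in + 5 * params$eps >= grid$L_r)
    stop(sprintf("tubule too close to the radial boundary: need R_in + 5 eps < L_r (%.3g + %.3g >= %g)",
                 R_in, 5 * params$eps, grid$L_r))
  outer(grid$r_centers, grid$z_centers,
        function(r, z) tanh((R_in - r) / (sqrt(2) * params$eps)))
}

#' Time stepper configuration for the Allen-Cahn dynamics
#'
#' The phase field is evolved by semi-implicit Euler: the stiff
#' constant-coefficient part of the elastic force (the
#' \eqn{\epsilon^4}-biharmonic and \eqn{\epsilon^2}-Laplacian terms) is
#' treated implicitly in Fourier space, all nonlinear and forcing terms
#' explicitly.  The implicit symbol vanishes as \eqn{k \to 0}, so slow
#' shape modes are integrated without bias; the time step is then capped
#' by the explicit bulk reaction rate at about
#' \eqn{dt < 2/(M\,4 c_b)} with \eqn{c_b = 3 k_b/(2\sqrt2\epsilon^3)}
#' (~3e-3 s at default parameters).  \code{dt = NULL} picks 85% of that
#' cap.  When \code{adapt} is TRUE the step is reduced whenever the
#' per-step field change exceeds \code{dphi_target} (fast stages around
#' pinch-off).
#'
#' @param dt time step (s), or NULL for the automatic default.
#' @param dphi_target largest acceptable per-step change of phi.
#' @param adapt logical, adaptive step reduction.
#' @param max_steps hard cap on total steps.
#' @param block steps between observable recordings.
#' @param equilibrium_tol threshold on \eqn{\|\delta F/\delta\phi\|_\infty}
#'   (k_BT/nm^3) below which the run is declared at equilibrium.
#' @param a2,m4,s0 implicit-splitting constants (Laplacian multiplier,
#'   biharmonic multiplier, constant shift); certified by the dt-halving
#'   convergence test.
#' @param dealias apply the 2/3-rule spectral truncation (recommended; the
#'   high-order Gaussian nonlinearities alias at the grid scale otherwise).
#' @param with_gauss include the Gaussian-curvature force.
#' @return object of class \code{time_stepper}.
#' @export
time_stepper <- function(dt = NULL, dphi_target = 0.05, adapt = TRUE,
                         max_steps = 2e5, block = 100,
                         equilibrium_tol = 1e-5, a2 = 2, m4 = 3, s0 = 0,
                         dealias = TRUE, with_gauss = TRUE) {
  st <- list(dt = dt, dphi_target = dphi_target, adapt = adapt,
             max_steps = as.integer(max_steps), block = as.integer(block),
             equilibrium_tol = equilibrium_tol, a2 = a2, m4 = m4, s0 = s0,
             dealias = dealias, with_gauss = with_gauss)
  class(st) <- "time_stepper"
  st
}

## bulk reaction rate that caps the explicit step
bulk_rate <- function(params) {
  cbf <- 3 * params$k_b / (2 * sqrt(2) * params$eps^3)
  cgf <- 3 * params$gamma / (2 * sqrt(2) * params$eps)
  params$M_pf * (4 * cbf + 2 * cgf)
}

default_dt <- function(params, stepper) {
  if (!is.null(stepper$dt)) return(stepper$dt)
  0.85 * 2 / bulk_rate(params)
}

#' One Allen-Cahn step
#'
#' Advances \eqn{\partial\phi/\partial t = -M_{pf}\,(\delta F_e/\delta\phi
#' + \frac34 (1-\phi^2) p)} by \code{nsteps} semi-implicit Euler steps.
#'
#' @param phi phase field matrix.
#' @param coats \code{coat_set} (or pressure matrix in k_BT/nm^3, or NULL
#'   for unforced relaxation).
#' @param params an \code{\link{elastic_params}}.
#' @param grid an \code{\link{axisym_grid}}.
#' @param stepper a \code{\link{time_stepper}}.
#' @param dt time step override (s).
#' @param nsteps number of steps to take.
#' @return list with \code{phi} (updated field), \code{max_dphi} (largest
#'   per-step change during the last step), \code{steps} taken and
#'   \code{finite} (FALSE after numerical blow-up).
#' @export
allen_cahn_step <- function(phi, coats, params, grid,
                            stepper = time_stepper(), dt = NULL,
                            nsteps = 1L) {
  check_field(phi, grid)
  check_resolution(grid, params)
  p <- if (is.null(coats)) NULL
       else if (is.matrix(coats)) coats
       else pressure_field(coats, grid)
  if (is.null(dt)) dt <- default_dt(params, stepper)
  pf_step_block(grid$engine, phi, p, params$k_b, params$k_G, params$gamma,
                params$eps, params$M_pf, dt, as.integer(nsteps),
                stepper$a2, stepper$s0, stepper$m4, stepper$with_gauss,
                stepper$dealias)
}

#' Run a constriction/fission simulation
#'
#' Evolves the phase field from the undisturbed tubule under the pressure
#' of the configured dynamin coats until either (a) equilibrium
#' (\eqn{\|\delta F/\delta\phi\|_\infty} below tolerance: no fission), or
#' (b) fission is detected, after which the coats at the fission site
#' depolymerize (pressure removed) and the run continues for a short
#' post-fission relaxation.  Deterministic given the configuration; no
#' randomness anywhere.
#'
#' @param config a configuration list as built by
#'   \code{\link{simulation_config}}.
#' @param verbose print progress lines.
#' @return an object of class \code{pf_trajectory}: \code{times} (s),
#'   \code{observables} (data frame: t_s, F_b, F_G, F_gamma, I, F_e,
#'   F_total, R_n_nm, R_c_nm, n_necks, D_nm, G_n, fission_flag),
#'   \code{events} (named list: outcome, t_fission, depolymerized, max
#'   energy-ascent violation), \code{critical} (max-F_e pre-fission
#'   snapshot: phi, t, contour), \code{phi_final}, \code{phi_initial},
#'   \code{config}, \code{E0} (reference elastic energy).
#' @export
run_simulation <- function(config, verbose = FALSE) {
  cfg <- validate_config(config)
  grid <- cfg$grid
  params <- cfg$params
  stepper <- cfg$stepper
  coats <- cfg$coats

  phi <- if (!is.null(cfg$initial_contour))
    phase_field_from_contour(cfg$initial_contour, grid, eps = params$eps)
  else initial_tubule(cfg$R_in, params, grid)
  ## the reference (unperturbed) state for energy differences is always
  ## the undisturbed tubule
  phi0 <- initial_tubule(cfg$R_in, params, grid)
  pmat <- if (length(coats)) pressure_field(coats, grid) else NULL
  lam_D <- if (!is.null(cfg$lambda_D)) cfg$lambda_D else 1.0

  E0 <- elastic_energy(phi0, grid, params)$F_e
  Fe_min_seen <- Inf
  z0 <- if (length(coats)) coats[[1L]]$z0 else grid$L_z / 2

  dt <- default_dt(params, stepper)
  t <- 0
  rec <- list()
  Fprev <- NULL
  worst_ascent <- 0
  crit <- list(F_e = -Inf)
  outcome <- "inconclusive"
  t_fission <- NA_real_
  depolymerized <- FALSE
  t_stop <- Inf
  steps_done <- 0L
  G0 <- NULL

  record <- function(st, fission) {
    en <- elastic_energy(phi, grid, params, coats = pmat)
    ct <- extract_midplane_contour(phi, grid)
    na <- if (any(ct$closed))
      list(R_n = 0, R_c = NA_real_, n_necks = NA_integer_, D = NA_real_)
    else analyze_necks(ct, z0 = z0, R_ref = cfg$R_in)
    G <- conductance(ct, l_me = params$l_me, lambda_D = lam_D)
    if (is.null(G0)) G0 <<- G
    Gn <- if (G0 > 0) G / G0 else 0
    ## the critical state is the maximum of F_e on the final ascent: any
    ## initial relaxation transient (e.g. from a continuation start)
    ## resets the tracker at each new pre-fission global minimum
    if (!fission && !depolymerized) {
      if (en$F_e < Fe_min_seen) {
        Fe_min_seen <<- en$F_e
        crit <<- list(F_e = -Inf)
      }
      if (en$F_e > crit$F_e)
        crit <<- list(F_e = en$F_e, t = t, phi = phi, contour = ct)
    }
    if (!is.null(Fprev) && en$F > Fprev + cfg$lyapunov_tol &&
        !depolymerized)
      worst_ascent <<- max(worst_ascent, en$F - Fprev)
    Fprev <<- en$F
    rec[[length(rec) + 1L]] <<- data.frame(
      t_s = t, F_b = en$F_b, F_G = en$F_G, F_gamma = en$F_gamma, I = en$I,
      F_e = en$F_e, F_total = en$F, R_n_nm = na$R_n, R_c_nm = na$R_c,
      n_necks = na$n_necks, D_nm = na$D, G_n = Gn,
      fission_flag = fission, max_dphi = st$max_dphi)
  }

  repeat {
    st <- allen_cahn_step(phi, pmat, params, grid, stepper, dt = dt,
                          nsteps = stepper$block)
    if (!st$finite || st$steps < stepper$block) {
      ## blow-up: dump diagnostic state and abort
      bad <- list(phi = st$phi, t = t, dt = dt)
      stop(structure(class = c("pf_blowup", "error", "condition"),
                     list(message = sprintf("numerical blow-up at t = %.4g s (dt = %.3g)", t, dt),
                          call = sys.call(-1), state = bad)))
    }
    phi <- st$phi
    t <- t + stepper$block * dt
    steps_done <- steps_done + stepper$block

    fis <- detect_fission(phi, grid)
    record(st, fis$fission)

    ## outer-boundary sanity: perturbations must decay before L_r
    edge <- max(abs(phi[grid$N_r, ] + 1))
    if (edge > 1e-3)
      warning(sprintf("phase field not in bulk at the radial boundary (|phi+1| = %.2g); enlarge L_r", edge))

    if (fis$fission && !depolymerized) {
      outcome <- "fission"
      t_fission <- t
      coats <- depolymerize_on_fission(coats, TRUE, fis$z)
      pmat <- if (any(vapply(coats, function(ct) ct$active, TRUE)))
        pressure_field(coats, grid) else NULL
      depolymerized <- TRUE
      t_stop <- t + cfg$post_fission_time
      if (verbose) message(sprintf("fission at t = %.3f s (z = %.1f nm)", t, fis$z))
    }

    if (t >= t_stop) break
    if (!depolymerized &&
        st$max_dphi / (dt * params$M_pf) < stepper$equilibrium_tol) {
      outcome <- "equilibrium"
      break
    }
    if (steps_done >= stepper$max_steps) break
    if (!is.null(cfg$t_max) && t >= cfg$t_max) {
      if (outcome == "inconclusive") outcome <- "t_max"
      break
    }

    if (stepper$adapt) {
      dt_cap <- default_dt(params, time_stepper(dt = stepper$dt))
      if (st$max_dphi > stepper$dphi_target)
        dt <- max(dt * 0.5, 1e-7)
      else if (st$max_dphi < 0.25 * stepper$dphi_target && dt < dt_cap)
        dt <- min(dt * 1.25, dt_cap)
    }
    if (verbose && length(rec) %% 10 == 0)
      message(sprintf("t = %.3f s  R_n = %.2f nm  dFe = %.1f k_BT",
                      t, rec[[length(rec)]]$R_n_nm,
                      rec[[length(rec)]]$F_e - E0))
  }

  obs <- do.call(rbind, rec)
  out <- list(times = obs$t_s, observables = obs,
              events = list(outcome = outcome, t_fission = t_fission,
                            t_onset = 0, depolymerized = depolymerized,
                            worst_energy_ascent = worst_ascent),
              critical = if (is.finite(crit$F_e)) crit else NULL,
              phi_final = phi, phi_initial = phi0, config = cfg, E0 = E0,
              grid = grid, params = params, z0 = z0)
  class(out) <- "pf_trajectory"
  out
}

#' @export
print.pf_trajectory <- function(x, ...) {
  n <- nrow(x$observables)
  cat(sprintf("pf_trajectory: %d records, t in [0, %.4g] s, outcome: %s\n",
              n, max(x$times), x$events$outcome))
  if (!is.na(x$events$t_fission))
    cat(sprintf("  fission at t = %.4g s\n", x$events$t_fission))
  invisible(x)
}
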