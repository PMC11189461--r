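#' Elastic parameters of the diffuse-interface membrane model
#'
#' Bundles all physical constants of the membrane model in the package unit
#' system (nm, k_BT, s, pN).  The interface-width parameter defaults to
#' \code{eps = l_me / 6}, matching the diffuse interface thickness
#' (\code{~6 eps}) to the bilayer thickness, and the Gaussian modulus
#' defaults to \code{k_G = -k_b}.
#'
#' @param k_b bending rigidity (k_BT), default 20.
#' @param k_G Gaussian modulus (k_BT), default \code{-k_b}.
#' @param gamma surface tension in k_BT/nm^2.  Give either this or
#'   \code{gamma_si}.
#' @param gamma_si surface tension in N/m (converted internally); default
#'   1.5e-4 N/m.
#' @param l_me bilayer thickness (nm), default 5.
#' @param eps interface-width parameter (nm), default \code{l_me/6}.
#' @param M_pf phase-field mobility (nm^3/(s k_BT)), default 4.04.
#' @return object of class \code{elastic_params}; includes the derived
#'   equilibrium tubule radius \code{R_in = sqrt(k_b/(2 gamma))}.
#' @examples
#' p <- elastic_params()      # k_b = 20 k_BT, gamma = 1.5e-4 N/m
#' p$R_in                     # 16.6 nm
#' @export
elastic_params <- function(k_b = 20, k_G = -k_b, gamma = NULL,
                           gamma_si = 1.5e-4, l_me = 5, eps = l_me / 6,
                           M_pf = 4.04) {
  if (is.null(gamma)) gamma <- tension_si_to_kbt(gamma_si)
  stopifnot(k_b > 0, gamma > 0, eps > 0, l_me > 0, M_pf >= 0)
  p <- list(k_b = k_b, k_G = k_G, gamma = gamma, eps = eps, l_me = l_me,
            M_pf = M_pf, R_in = sqrt(k_b / (2 * gamma)))
  class(p) <- "elastic_params"
  p
}

#' @export
print.elastic_params <- function(x, ...) {
  cat(sprintf(paste0("elastic_params: k_b = %g k_BT, k_G = %g k_BT, ",
                     "gamma = %.4g k_BT/nm^2,\n  eps = %.4g nm, l_me = %g nm, ",
                     "M_pf = %g nm^3/(s k_BT)  [R_in = %.3g nm]\n"),
              x$k_b, x$k_G, x$gamma, x$eps, x$l_me, x$M_pf, x$R_in))
  invisible(x)
}

check_resolution <- function(grid, params) {
  if (grid$dr > params$eps / 2 + 1e-12 || grid$dz > params$eps / 2 + 1e-12)
    stop(sprintf(paste0("grid too coarse for the interface width: need dr, dz",
                        " <= eps/2 = %.4g nm (got dr = %.4g, dz = %.4g)"),
                 params$eps / 2, grid$dr, grid$dz))
  invisible(TRUE)
}

#' Diffuse-interface chemical potentials psi_b and psi_G
#'
#' \code{psi_b} is the field \eqn{\phi(\phi^2 - 1) - \epsilon^2 \nabla^2
#' \phi} whose square, suitably normalized, integrates to the bending
#' energy; it vanishes identically on an equilibrium planar interface
#' \eqn{\phi = \tanh(x/(\sqrt{2}\epsilon))}.  \code{psi_G} is the
#' Gaussian-curvature density built from \eqn{|\nabla\phi|^2} and its
#' derivatives; its integral, normalized, gives the Gaussian energy (zero
#' for planes and cylinders, \eqn{4\pi} per sphere by Gauss-Bonnet).
#'
#' @param phi phase field matrix.
#' @param grid an \code{\link{axisym_grid}}.
#' @param params an \code{\link{elastic_params}} (for \code{eps}).
#' @return field matrix.
#' @export
psi_b <- function(phi, grid, params) {
  check_field(phi, grid)
  pf_psi_b(grid$engine, phi, params$eps)
}

#' @rdname psi_b
#' @export
psi_G <- function(phi, grid) {
  check_field(phi, grid)
  pf_psi_g(grid$engine, phi)
}

#' Diffuse-interface elastic free energy
#'
#' Evaluates the three contributions of the elastic free energy
#' \eqn{F_e = F_b + F_G + F_\gamma}:
#' \deqn{F_b = \frac{k_b}{2}\frac{3}{2\sqrt{2}\epsilon^3}\int \psi_b^2\,dV,
#'   \quad F_G = k_G \frac{35}{16\sqrt 2}\epsilon^3 \int \psi_G\, dV, \quad
#'   F_\gamma = \gamma\frac{3}{2\sqrt 2 \epsilon}\int \left[
#'   \tfrac14(\phi^2-1)^2 + \tfrac{\epsilon^2}{2}(\nabla\phi)^2\right] dV.}
#' In the sharp-interface limit these converge to the Canham-Helfrich
#' bending, Gaussian and tension energies of the midplane surface.
#'
#' @param phi phase field matrix.
#' @param grid an \code{\link{axisym_grid}}.
#' @param params an \code{\link{elastic_params}}.
#' @param coats optional \code{\link{coat_set}} (or pressure matrix in
#'   k_BT/nm^3) used to add the dynamin interaction energy \code{I} to the
#'   breakdown.
#' @return \code{elastic_energy}: an \code{energy_breakdown} list with
#'   components \code{F_b}, \code{F_G}, \code{F_gamma}, \code{F_e}
#'   (= their exact sum), \code{I} and \code{F = F_e + I}, all in k_BT.
#'   The single-term helpers return scalars.
#' @examples
#' g <- axisym_grid(30, 100, 72, 240)
#' pars <- elastic_params()
#' phi <- initial_tubule(16.6, pars, g)
#' e <- elastic_energy(phi, g, pars)
#' e$F_b  # ~ pi * k_b * L / R
#' @export
elastic_energy <- function(phi, grid, params, coats = NULL) {
  check_field(phi, grid)
  en <- pf_energies(grid$engine, phi, params$k_b, params$k_G, params$gamma,
                    params$eps)
  I <- 0
  if (!is.null(coats)) {
    p <- if (is.matrix(coats)) coats else pressure_field(coats, grid)
    I <- interaction_energy(phi, p, grid)
  }
  out <- list(F_b = en$F_b, F_G = en$F_G, F_gamma = en$F_gamma,
              F_e = en$F_b + en$F_G + en$F_gamma, I = I,
              F = en$F_b + en$F_G + en$F_gamma + I)
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("F_b = %.4g  F_G = %.4g  F_gamma = %.4g  ->  F_e = %.4g k_BT\n",
              x$F_b, x$F_G, x$F_gamma, x$F_e))
  if (x$I != 0) cat(sprintf("I = %.4g  ->  F = %.4g k_BT\n", x$I, x$F))
  invisible(x)
}

#' @rdname elastic_energy
#' @export
bending_energy <- function(phi, grid, params)
  elastic_energy(phi, grid, params)$F_b

#' @rdname elastic_energy
#' @export
gaussian_energy <- function(phi, grid, params)
  elastic_energy(phi, grid, params)$F_G

#' @rdname elastic_energy
#' @export
tension_energy <- function(phi, grid, params)
  elastic_energy(phi, grid, params)$F_gamma

#' Axial density of the elastic energy
#'
#' Elastic energy integrated over r only, per z cell column (k_BT per
#' column), used to split critical-state energy into the inner constricted
#' region and the outer flanks.
#'
#' @inheritParams elastic_energy
#' @return numeric vector of length N_z summing to \code{F_e}.
#' @export
elastic_energy_z_density <- function(phi, grid, params) {
  check_field(phi, grid)
  en <- pf_energies(grid$engine, phi, params$k_b, params$k_G, params$gamma,
                    params$eps)
  en$fez_b + en$fez_G + en$fez_gamma
}

#' Variational derivative of the elastic free energy
#'
#' Returns \eqn{\delta F_e/\delta\phi} (k_BT/nm^3), the generalized force
#' that drives the Allen-Cahn dynamics.  The bending part is the analytic
#' expression \eqn{\frac{3 k_b}{2\sqrt2 \epsilon^3}[(3\phi^2-1)\psi_b -
#' \epsilon^2\nabla^2\psi_b]}; the tension part is
#' \eqn{\frac{3\gamma}{2\sqrt2\epsilon}\psi_b}; the Gaussian part is
#' assembled from the analytic variation of the \eqn{\psi_G} density using
#' repeated divergence/gradient/Laplacian applications, and is certified by
#' a directional-derivative (finite difference of the functional) test.
#'
#' @inheritParams elastic_energy
#' @param with_gauss include the Gaussian-curvature force (default TRUE).
#' @return field matrix, \eqn{\delta F_e/\delta\phi} in k_BT/nm^3.
#' @export
variational_derivative_elastic <- function(phi, grid, params,
                                           with_gauss = TRUE) {
  check_field(phi, grid)
  check_resolution(grid, params)
  pf_var_deriv(grid$engine, phi, params$k_b, params$k_G, params$gamma,
               params$eps, with_gauss)
}
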