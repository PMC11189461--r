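## Sharp-interface and linearized-elasticity theory of the constricted
## tubule: closed forms for the equilibrium and constricted radii, the
## modified tension, the fission-time formula, the linear-response Green's
## function and the neck-splitting threshold.

#' Equilibrium tubule radius
#'
#' A cylindrical membrane of radius \eqn{R_{in} = \sqrt{k_b/(2\gamma)}}
#' minimizes the Canham-Helfrich Hamiltonian at tension \eqn{\gamma}.
#'
#' @param k_b bending rigidity (k_BT).
#' @param gamma surface tension in k_BT/nm^2 (use
#'   \code{\link{tension_si_to_kbt}} for N/m values).
#' @return radius in nm.
#' @examples
#' equilibrium_radius(20, tension_si_to_kbt(1.5e-4))  # 16.6 nm
#' equilibrium_radius(16, tension_si_to_kbt(5e-4))    # ~8 nm
#' @export
equilibrium_radius <- function(k_b, gamma) {
  stopifnot(k_b > 0, gamma > 0)
  sqrt(k_b / (2 * gamma))
}

#' Modified tension under dynamin constriction
#'
#' For a long coat the axially-uniform chain pressure
#' \eqn{p(r) = N_d F_\tau/(h r)} acts on the cylindrical patch Hamiltonian
#' exactly like an added tension, \eqn{\bar\gamma = \gamma + N_d F_\tau/h}.
#'
#' @param gamma bare tension (k_BT/nm^2).
#' @param coat a \code{\link{dynamin_coat}} (uses N_d, F_tau, pitch).
#' @return modified tension in k_BT/nm^2.
#' @export
modified_tension <- function(gamma, coat) {
  stopifnot(gamma > 0)
  gamma + coat$N_d * coat$F_tau / coat$pitch / kbt_pN_nm()
}

#' Constricted equilibrium radius
#'
#' \eqn{R_c = \sqrt{k_b/(2\bar\gamma)}}: the radius of the central
#' cylindrical region of a tubule constricted by a long dynamin coat.
#'
#' @param k_b bending rigidity (k_BT).
#' @param gamma_bar modified tension (k_BT/nm^2).
#' @return radius in nm (about 3.5 nm at default parameters).
#' @export
constricted_radius <- function(k_b, gamma_bar) equilibrium_radius(k_b, gamma_bar)

#' Cylindrical-patch Hamiltonian
#'
#' \eqn{H = k_b \pi L/R + \bar\gamma\, 2\pi R L} (bending plus full
#' effective tension); stationary in R exactly at
#' \eqn{R = \sqrt{k_b/(2\bar\gamma)}}.
#'
#' @param R cylinder radius (nm).
#' @param L cylinder length (nm).
#' @param k_b bending rigidity (k_BT).
#' @param gamma_bar effective tension (k_BT/nm^2).
#' @return energy in k_BT.
#' @export
cylinder_hamiltonian <- function(R, L, k_b, gamma_bar)
  k_b * pi * L / R + gamma_bar * 2 * pi * R * L

#' Sharp-interface mobility
#'
#' Conversion of the phase-field mobility to its sharp-interface
#' counterpart, \eqn{M_{sharp} = 3 \epsilon M_{pf} / \sqrt 8}.
#'
#' @param M_pf phase-field mobility (nm^3/(s k_BT)).
#' @param eps interface-width parameter (nm).
#' @return M_sharp in nm^4/(s k_BT) (3.57 at default parameters).
#' @export
mobility_sharp <- function(M_pf, eps) {
  stopifnot(M_pf >= 0, eps > 0)
  3 * eps * M_pf / sqrt(8)
}

#' Analytic fission-time prediction for long coats
#'
#' The constriction of the central cylindrical region under an
#' axially-uniform dynamin pressure relaxes analytically, giving
#' \deqn{t_f = \alpha(F_\tau)\, \frac{R_{in}^2}{2 M_{sharp}}
#'   \frac{\gamma + \bar\gamma}{\bar\gamma^2},\qquad
#'   \alpha(F_\tau) = 1 + \exp[(2.318\,\mathrm{pN} - F_\tau)/0.805\,
#'   \mathrm{pN}],}
#' valid for coats longer than the neck-splitting threshold (a warning is
#' emitted otherwise).
#'
#' @param k_b bending rigidity (k_BT).
#' @param gamma bare tension (k_BT/nm^2).
#' @param coat a \code{\link{dynamin_coat}}.
#' @param M_sharp sharp-interface mobility (nm^4/(s k_BT)), default 3.57.
#' @return fission time in seconds.
#' @examples
#' coat <- dynamin_coat(H = 200, z0 = 0, F_tau = 4, N_d = 15)
#' fission_time_prediction(16, tension_si_to_kbt(5e-4), coat)  # ~7 s
#' @export
fission_time_prediction <- function(k_b, gamma, coat, M_sharp = 3.57) {
  R_in <- equilibrium_radius(k_b, gamma)
  if (coat$H < linear_threshold(R_in))
    warning("fission-time formula derived for long coats (H > H*); extrapolating")
  gb <- modified_tension(gamma, coat)
  alpha_fission(coat$F_tau) * R_in^2 / (2 * M_sharp) * (gamma + gb) / gb^2
}

#' @rdname fission_time_prediction
#' @param F_tau power-stroke force (pN).
#' @export
alpha_fission <- function(F_tau) 1 + exp((2.318 - F_tau) / 0.805)

#' Green's function of the linearized tubule shape equation
#'
#' The linearized Canham-Helfrich response of a nearly cylindrical tubule,
#' \eqn{R_{in}^4 u^{(4)} + u = \bar p R_{in}^4/k_b}, has the Green's
#' function
#' \deqn{g(x) = \frac{\sqrt2}{4 R_{in}} e^{-|x|/(\sqrt2 R_{in})}
#'   \left(\cos\frac{|x|}{\sqrt2 R_{in}} + \sin\frac{|x|}{\sqrt2 R_{in}}
#'   \right),}
#' an even function whose oscillations decay on the elastic relaxation
#' length \eqn{L_{dec} = \sqrt2 R_{in}}.
#'
#' @param z axial offsets (nm), vectorized.
#' @param R_in tubule radius (nm).
#' @return g(z) in 1/nm.
#' @export
greens_function <- function(z, R_in) {
  stopifnot(R_in > 0)
  a <- abs(z) / (sqrt(2) * R_in)
  sqrt(2) / (4 * R_in) * exp(-a) * (cos(a) + sin(a))
}

## closed-form antiderivative: int_0^x g = (1/2)(1 - e^-a cos a), odd in x
greens_antiderivative <- function(x, R_in) {
  a <- abs(x) / (sqrt(2) * R_in)
  0.5 * (1 - exp(-a) * cos(a)) * sign(x)
}

#' Linear-response deformation under a rectangular pressure window
#'
#' Convolution \eqn{u(z) = \int g(z - y)\, \bar p(y)\, R_{in}^4/k_b\, dy}
#' of the Green's function with a rectangular pressure of width H,
#' \eqn{\bar p(z) = -p_0\,\Pi(z/H)}, evaluated in closed form from the
#' antiderivative of g.  With the natural amplitude
#' \eqn{p_0 = k_b/R_{in}^4} the plateau deformation for a long window is
#' \code{-1} nm per unit amplitude.
#'
#' @param H window width (nm).
#' @param R_in tubule radius (nm).
#' @param k_b bending rigidity (k_BT).
#' @param p_amplitude pressure amplitude \eqn{p_0} (k_BT/nm^3); default
#'   \code{k_b/R_in^4}.
#' @param z_grid axial evaluation points (nm), centered on the window.
#' @return deformation u(z) in nm (negative = constriction).
#' @export
linear_deformation <- function(H, R_in, k_b, p_amplitude = k_b / R_in^4,
                               z_grid) {
  if (max(abs(z_grid)) < H / 2 + 10 * sqrt(2) * R_in)
    stop("z_grid must extend at least 10 decay lengths beyond the window")
  scale <- -p_amplitude * R_in^4 / k_b
  scale * (greens_antiderivative(z_grid + H / 2, R_in) -
           greens_antiderivative(z_grid - H / 2, R_in))
}

#' Neck-splitting threshold of the linearized theory
#'
#' In linearized elasticity the single central dimple of the deformation
#' splits into two off-center minima when the coat length exceeds
#' \eqn{H^*_{l.e.} = 2\sqrt2 \pi R_{in}}.
#'
#' @param R_in tubule radius (nm).
#' @return threshold length in nm.
#' @examples
#' linear_threshold(16.6)  # ~147.5 nm
#' @export
linear_threshold <- function(R_in) {
  stopifnot(R_in > 0)
  2 * sqrt(2) * pi * R_in
}

#' Count the constriction dimples of a linear deformation profile
#'
#' Numerical counterpart of the stationary-point analysis of the
#' convolution.  The deformation has infinitely many stationary points
#' (the Green's function oscillates), so only local minima whose depth is
#' at least \code{frac} of the global constriction depth are counted: one
#' below the splitting threshold, two above it.
#'
#' @param u deformation values on a regular grid (negative = inward).
#' @param frac depth fraction of the global minimum below which a local
#'   minimum counts (default 0.5).
#' @return integer count.
#' @export
count_linear_minima <- function(u, frac = 0.5) {
  n <- length(u)
  umin <- min(u)
  if (umin >= 0) return(0L)
  i <- 2:(n - 1)
  mins <- which(u[i] < u[i - 1] & u[i] <= u[i + 1] &
                  u[i] <= frac * umin) + 1L
  length(mins)
}

#' Residual of the axisymmetric shape equation
#'
#' Evaluates, term by term, the perturbed axisymmetric shape equation of
#' the Canham-Helfrich functional for a profile parametrized by the
#' distance r(z) from the axis and the tangent angle \eqn{\psi(z)}
#' (\eqn{s = \sin\psi}, \eqn{c = \cos\psi}, primes = d/dz, spectral
#' derivatives on the periodic z grid):
#' \deqn{2 r^2 s^3 \psi''' + 8 r^2 s^2 c\, \psi''\psi' +
#'   r s (2c^2 - s^2) \psi'^3 + 4 r c s^2 \psi'' + r s (4 - 7 s^2)\psi'^2
#'   - (3 c^2 - 1) s \psi' - 2 r^2 s \psi' \gamma/k_b - 2 r s \gamma/k_b
#'   + \frac{1 + c^2}{r} s + 2 r^2 \frac{p}{k_b} = \mathrm{residual}.}
#' A cylinder at \eqn{R_{in}} with p = 0 has zero residual; it is used as
#' a verification instrument, not as a solver.
#'
#' @param r_profile r(z) (nm).
#' @param psi_profile tangent angle (rad); \eqn{\pi/2} for a cylinder.
#' @param p_profile imposed pressure (k_BT/nm^3), vectorized over z.
#' @param k_b bending rigidity (k_BT).
#' @param gamma tension (k_BT/nm^2).
#' @param L_z period of the z grid (nm); defaults to n*dz assuming the
#'   profiles sample a full period uniformly.
#' @return residual vector over z.
#' @export
shape_equation_residual <- function(r_profile, psi_profile, p_profile,
                                    k_b, gamma, L_z) {
  n <- length(r_profile)
  stopifnot(length(psi_profile) == n)
  if (length(p_profile) == 1L) p_profile <- rep(p_profile, n)
  k <- 2 * pi / L_z * c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  dspec <- function(f, ord) {
    fh <- stats::fft(f)
    mul <- (1i * k)^ord
    if (ord %% 2 == 1) mul[n %/% 2 + 1] <- 0
    Re(stats::fft(fh * mul, inverse = TRUE)) / n
  }
  s <- sin(psi_profile); cc <- cos(psi_profile)
  p1 <- dspec(psi_profile, 1); p2 <- dspec(psi_profile, 2)
  p3 <- dspec(psi_profile, 3)
  r <- r_profile
  2 * r^2 * s^3 * p3 + 8 * r^2 * s^2 * cc * p2 * p1 +
    r * s * (2 * cc^2 - s^2) * p1^3 + 4 * r * cc * s^2 * p2 +
    r * s * (4 - 7 * s^2) * p1^2 - (3 * cc^2 - 1) * s * p1 -
    2 * r^2 * s * p1 * gamma / k_b - 2 * r * s * gamma / k_b +
    (1 + cc^2) / r * s + 2 * r^2 * p_profile / k_b
}

#' Bundle of sharp-theory predictions
#'
#' Convenience table of all closed-form quantities for a parameter set and
#' coat: \code{R_in}, \code{gamma_bar}, \code{R_c}, \code{H_star_le},
#' \code{L_dec}, \code{M_sharp}, \code{alpha} and \code{t_f}.
#'
#' @param params an \code{\link{elastic_params}}.
#' @param coat a \code{\link{dynamin_coat}}.
#' @return object of class \code{sharp_prediction} (named list).
#' @export
sharp_prediction <- function(params, coat) {
  R_in <- equilibrium_radius(params$k_b, params$gamma)
  gb <- modified_tension(params$gamma, coat)
  Msh <- mobility_sharp(params$M_pf, params$eps)
  out <- list(
    R_in = R_in, gamma_bar = gb,
    R_c = constricted_radius(params$k_b, gb),
    H_star_le = linear_threshold(R_in), L_dec = sqrt(2) * R_in,
    M_sharp = Msh, alpha = alpha_fission(coat$F_tau),
    t_f = suppressWarnings(
      fission_time_prediction(params$k_b, params$gamma, coat, Msh)))
  class(out) <- "sharp_prediction"
  out
}

#' @export
print.sharp_prediction <- function(x, ...) {
  cat(sprintf(paste0("sharp_prediction:\n  R_in = %.3g nm   gamma_bar = %.4g",
                     " k_BT/nm^2   R_c = %.3g nm\n  H*_le = %.4g nm   ",
                     "L_dec = %.3g nm   M_sharp = %.3g nm^4/(s k_BT)\n",
                     "  alpha = %.4g   t_f = %.4g s\n"),
              x$R_in, x$gamma_bar, x$R_c, x$H_star_le, x$L_dec, x$M_sharp,
              x$alpha, x$t_f))
  invisible(x)
}
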