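#' Axisymmetric differential operators
#'
#' Spectral evaluation of the 3D axisymmetric Laplacian
#' \eqn{\nabla^2 f = \partial^2 f/\partial r^2 + (1/r)\,\partial f/\partial r
#' + \partial^2 f/\partial z^2} and of the gradient
#' \eqn{(\partial f/\partial r, \partial f/\partial z)} for fields on a
#' cell-centered \code{\link{axisym_grid}}.  z is periodic; r uses an even
#' mirror extension across the axis (zero normal derivative at the outer
#' wall), so perturbations must decay before \code{L_r}.
#'
#' @param f field matrix (N_r x N_z).
#' @param grid an \code{\link{axisym_grid}}.
#' @return \code{laplacian_axisym}: a matrix; \code{gradient_axisym}: a list
#'   with components \code{dr} and \code{dz}.
#' @examples
#' g <- axisym_grid(30, 30, 108, 108)
#' f <- outer(g$r_centers, g$z_centers, function(r, z) tanh((16.6 - r) / 1.18))
#' lap <- laplacian_axisym(f, g)
#' @export
laplacian_axisym <- function(f, grid) {
  check_field(f, grid)
  pf_laplacian(grid$engine, f)
}

#' @rdname laplacian_axisym
#' @export
gradient_axisym <- function(f, grid) {
  check_field(f, grid)
  pf_gradient(grid$engine, f)
}

#' Volume integral with the axisymmetric metric
#'
#' \eqn{\int f\, dV = \sum f \cdot 2\pi r\, dr\, dz} over all cells; exact
#' for fields constant per cell.
#'
#' @param f field matrix.
#' @param grid an \code{\link{axisym_grid}}.
#' @return scalar integral value.
#' @examples
#' g <- axisym_grid(30, 100, 60, 200)
#' volume_integral(matrix(1, 60, 200), g)  # pi * 30^2 * 100
#' @export
volume_integral <- function(f, grid) {
  check_field(f, grid)
  sum(f * (2 * pi * grid$r_centers)) * grid$dr * grid$dz
}

## 2 pi r dr dz weights as a matrix (internal)
volume_weights <- function(grid) {
  matrix(2 * pi * grid$r_centers, grid$N_r, grid$N_z) * grid$dr * grid$dz
}
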