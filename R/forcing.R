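#' Dynamin coat model
#'
#' A dynamin helix is reduced to its mesoscale geometry: polymerization
#' length \code{H}, pitch \code{h}, dimers per turn \code{N_d} and the
#' tangential power-stroke force \code{F_tau} exchanged by dimers of
#' adjacent rungs upon GTP hydrolysis.  The chain tension loads the
#' membrane with an inward radial pressure
#' \deqn{p(r, z) = \frac{N_d F_\tau}{h\, r}\, A(z)\, C(r),}
#' exactly \eqn{N_d F_\tau/(h r)} on the coat interior, tapered axially by
#' \code{A} (a smooth half-ramp of width \code{edge_width} centered on each
#' coat edge: the tension builds up in the two extremal rungs and is
#' constant in the inner ones) and cut off radially by \code{C} (a smooth
#' tanh ramp: the helix cannot follow the tubule below a maximum admitted
#' curvature, around \code{R_cut = 3} nm of tubule radius).
#'
#' @param H polymerization length (nm).
#' @param z0 coat center along the tubule axis (nm).
#' @param F_tau tangential power-stroke force (pN), default 2.5.
#' @param pitch helix pitch (nm), default 10.
#' @param N_d dimers per turn, default 13.
#' @param R_cut curvature-cutoff radius (nm), default 3: the maximum
#'   admitted curvature of the helix, below which \code{C(r)} fades to
#'   zero (ramp centered at \code{R_cut - 3 cutoff_width}).
#' @param cutoff_width width of the radial cutoff ramp (nm), default 0.28.
#' @param edge_width axial taper width (nm), default one pitch.
#' @param active logical; inactive coats exert no pressure.
#' @return object of class \code{dynamin_coat}.
#' @examples
#' coat <- dynamin_coat(H = 20, z0 = 150)
#' coat_pressure_peak(coat, 16.6)  # N_d F_tau / (h R_in) ~ 0.196 pN/nm^2
#' @export
dynamin_coat <- function(H, z0, F_tau = 2.5, pitch = 10, N_d = 13,
                         R_cut = 3, cutoff_width = 0.28, edge_width = pitch,
                         active = TRUE) {
  stopifnot(H > 0, pitch > 0, N_d > 0, R_cut > 0, cutoff_width > 0,
            edge_width > 0)
  if (H < pitch)
    warning(sprintf(paste0("coat H = %g nm is below one full turn ",
                           "(pitch %g nm); the chain pressure model assumes ",
                           "polymers completing at least one turn"), H, pitch))
  ct <- list(H = H, z0 = z0, F_tau = F_tau, pitch = pitch, N_d = N_d,
             R_cut = R_cut, cutoff_width = cutoff_width,
             edge_width = edge_width, active = isTRUE(active))
  class(ct) <- "dynamin_coat"
  ct
}

#' @export
print.dynamin_coat <- function(x, ...) {
  cat(sprintf("dynamin_coat: H = %g nm at z0 = %g nm, F_tau = %g pN, N_d = %d, pitch = %g nm%s\n",
              x$H, x$z0, x$F_tau, x$N_d, x$pitch,
              if (x$active) "" else " [inactive]"))
  invisible(x)
}

#' Pressure value at the center of the undeformed tubule (pN/nm^2)
#' @param coat a \code{\link{dynamin_coat}}.
#' @param R_in tubule radius (nm).
#' @export
coat_pressure_peak <- function(coat, R_in)
  coat$N_d * coat$F_tau / (coat$pitch * R_in)

#' A set of dynamin coats
#'
#' @param ... \code{\link{dynamin_coat}} objects (or a single list of them).
#' @return object of class \code{coat_set}.  Warns when coat footprints
#'   overlap in z; the total pressure of a set is the sum over coats.
#' @export
coat_set <- function(...) {
  coats <- list(...)
  if (length(coats) == 1L && !inherits(coats[[1L]], "dynamin_coat"))
    coats <- coats[[1L]]
  stopifnot(all(vapply(coats, inherits, TRUE, "dynamin_coat")))
  if (length(coats) > 1L) {
    iv <- t(vapply(coats, function(ct)
      c(ct$z0 - ct$H / 2 - ct$edge_width / 2,
        ct$z0 + ct$H / 2 + ct$edge_width / 2), numeric(2)))
    o <- order(iv[, 1])
    if (any(iv[o[-1], 1] < iv[o[-length(o)], 2]))
      warning("coat footprints overlap in z; pressures add")
  }
  class(coats) <- "coat_set"
  coats
}

#' @export
print.coat_set <- function(x, ...) {
  cat(sprintf("coat_set of %d dynamin coat(s)\n", length(x)))
  for (ct in x) print(ct)
  invisible(x)
}

as_coat_set <- function(coats) {
  if (inherits(coats, "coat_set")) coats
  else if (inherits(coats, "dynamin_coat")) coat_set(list(coats))
  else coat_set(coats)
}

## smooth half-sine step: 0 below -w/2, 1 above w/2
smooth_step <- function(x, w) {
  y <- 0.5 * (1 + sin(pi * pmax(-w / 2, pmin(w / 2, x)) / w))
  y[x <= -w / 2] <- 0
  y[x >= w / 2] <- 1
  y
}

## axial taper (ramps centered on the coat edges, integral = H for H >= w)
coat_axial_profile <- function(coat, z) {
  smooth_step(z - (coat$z0 - coat$H / 2), coat$edge_width) *
    smooth_step((coat$z0 + coat$H / 2) - z, coat$edge_width)
}

## Radial curvature cutoff: ~1 at and above R_cut, fading to 0 over a few
## widths below it (ramp centered at R_cut - 3w), so the coat keeps
## squeezing down to the spontaneous-collapse radius of the neck while the
## pressure still vanishes for radii the helix cannot follow.  The
## gaussian axis factor keeps p = C(r)/r monotonically vanishing at the
## axis; it is exp-close to 1 beyond ~3 cutoff widths.
coat_radial_cutoff <- function(coat, r) {
  w <- coat$cutoff_width
  0.5 * (1 + tanh((r - (coat$R_cut - 3 * w)) / w)) * (1 - exp(-(r / w)^2))
}

#' Dynamin pressure field on the grid
#'
#' Sums the pressure of all active coats on the Eulerian grid (independent
#' of the phase field; the coupling to the membrane happens only through
#' the mediating function in the interaction energy).
#'
#' @param coats a \code{\link{coat_set}} or single \code{dynamin_coat}.
#' @param grid an \code{\link{axisym_grid}}.
#' @param units \code{"kbt"} (k_BT/nm^3, the internal unit entering the
#'   interaction integral) or \code{"pn"} (pN/nm^2).
#' @return pressure matrix (N_r x N_z), everywhere \code{>= 0}.
#' @export
pressure_field <- function(coats, grid, units = c("kbt", "pn")) {
  units <- match.arg(units)
  coats <- as_coat_set(coats)
  p <- matrix(0, grid$N_r, grid$N_z)
  for (ct in coats) {
    if (!ct$active) next
    lo <- ct$z0 - ct$H / 2 - ct$edge_width / 2
    hi <- ct$z0 + ct$H / 2 + ct$edge_width / 2
    if (lo < 0 || hi > grid$L_z)
      stop(sprintf("coat at z0 = %g nm (footprint [%g, %g]) extends outside the domain",
                   ct$z0, lo, hi))
    radial <- ct$N_d * ct$F_tau / (ct$pitch * grid$r_centers) *
      coat_radial_cutoff(ct, grid$r_centers)
    p <- p + outer(radial, coat_axial_profile(ct, grid$z_centers))
  }
  if (units == "kbt") pressure_pn_to_kbt(p) else p
}

#' Mediating function h(phi)
#'
#' The cubic \eqn{h(\phi) = \frac34(\phi - \phi^3/3)} that spreads the
#' external pressure over the full width of the diffuse interface;
#' \eqn{h(\pm 1) = \pm 1/2}, and \eqn{h'(\phi)|\nabla\phi| =
#' \frac34(1-\phi^2)|\nabla\phi|} tends weakly to the surface delta
#' function in the sharp limit.
#'
#' @param phi phase field (matrix or numeric).
#' @return same shape as \code{phi}.
#' @export
mediating <- function(phi) 0.75 * (phi - phi^3 / 3)

#' Dynamin-membrane interaction energy
#'
#' \eqn{I[\phi] = \int h(\phi)\, p\, dV} in k_BT.
#'
#' @param phi phase field matrix.
#' @param coats a \code{coat_set}, single coat, or a precomputed pressure
#'   matrix in k_BT/nm^3.
#' @param grid an \code{\link{axisym_grid}}.
#' @export
interaction_energy <- function(phi, coats, grid) {
  check_field(phi, grid)
  p <- if (is.matrix(coats)) coats else pressure_field(coats, grid)
  volume_integral(mediating(phi) * p, grid)
}

#' External (dynamin) force density
#'
#' The spread force \eqn{f_{ext} = \frac{\delta I}{\delta\phi}\nabla\phi =
#' p\,\frac34(1-\phi^2)\nabla\phi} (pN/nm^3 when converted; here in
#' k_BT/nm^4), plus the scalar \eqn{\delta I/\delta\phi = \frac34(1-\phi^2)p}
#' used directly by the Allen-Cahn dynamics.
#'
#' @inheritParams interaction_energy
#' @return list with \code{fr}, \code{fz} (force density components) and
#'   \code{dI_dphi} (k_BT/nm^3).
#' @export
external_force_density <- function(phi, coats, grid) {
  check_field(phi, grid)
  p <- if (is.matrix(coats)) coats else pressure_field(coats, grid)
  dI <- 0.75 * (1 - phi^2) * p
  gr <- gradient_axisym(phi, grid)
  list(fr = dI * gr$dr, fz = dI * gr$dz, dI_dphi = dI)
}

#' Dynamin disassembly upon fission
#'
#' Whenever tubule rupture is achieved the dynamin polymers disassemble and
#' their pressure vanishes; no depolymerization energy is deposited on the
#' membrane.  Coats whose footprint overlaps the fission site are set
#' inactive; the others are untouched.
#'
#' @param coats a \code{\link{coat_set}} (or single coat).
#' @param fission_flag logical, from \code{\link{detect_fission}}.
#' @param fission_z axial location of the fission site (nm); required when
#'   \code{fission_flag} is TRUE.
#' @param margin extra tolerance (nm) around the coat footprint, default
#'   5 nm.
#' @return the updated \code{coat_set}.
#' @export
depolymerize_on_fission <- function(coats, fission_flag, fission_z = NULL,
                                    margin = 5) {
  coats <- as_coat_set(coats)
  if (!isTRUE(fission_flag)) return(coats)
  if (is.null(fission_z)) stop("fission_z required when fission occurred")
  out <- lapply(unclass(coats), function(ct) {
    lo <- ct$z0 - ct$H / 2 - ct$edge_width / 2 - margin
    hi <- ct$z0 + ct$H / 2 + ct$edge_width / 2 + margin
    if (fission_z >= lo && fission_z <= hi) ct$active <- FALSE
    ct
  })
  class(out) <- "coat_set"
  out
}
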