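## Synthetic fixtures: deformation profiles and phase fields built from
## prescribed midplane contours, used to exercise the observables in
## isolation from the dynamics.

#' Synthetic midplane deformation profile
#'
#' Builds r(z) = R0 plus a sum of cosine bumps, as ground truth for
#' contour extraction and neck analysis.
#'
#' @param grid an \code{\link{axisym_grid}} (only z is used).
#' @param R0 base radius (nm).
#' @param amplitude,wavelength,center bump parameters (vectorized: several
#'   bumps may be superposed).  Each bump is a raised cosine
#'   \code{amplitude/2 * (1 + cos(2 pi (z - center)/wavelength))} with
#'   compact support of one wavelength, so the profile joins R0 smoothly.
#' @param global_cos if TRUE (default when no center given) a single
#'   domain-wide cosine \code{amplitude * cos(2 pi z / wavelength)} is
#'   used instead.
#' @return numeric vector r_mid(z).
#' @export
synthetic_contour <- function(grid, R0, amplitude = 0, wavelength = grid$L_z,
                              center = NULL, global_cos = is.null(center)) {
  z <- grid$z_centers
  r <- rep(R0, length(z))
  if (isTRUE(global_cos)) {
    r <- r + amplitude * cos(2 * pi * z / wavelength)
  } else {
    for (i in seq_along(center)) {
      x <- z - center[i]
      w <- abs(x) <= wavelength[i] / 2
      r[w] <- r[w] +
        amplitude[i] / 2 * (1 + cos(2 * pi * x[w] / wavelength[i]))
    }
  }
  r
}

#' Phase field with a prescribed midplane contour
#'
#' \eqn{\phi(r, z) = \tanh((r_{mid}(z) - r)/(\sqrt2\epsilon))}: the
#' \eqn{\phi = 0} level set lies exactly on the prescribed contour (up to
#' interpolation), giving ground truth for
#' \code{\link{extract_midplane_contour}}.
#'
#' @param r_mid contour radii (nm), one per z cell.
#' @param grid an \code{\link{axisym_grid}}.
#' @param eps interface width parameter (nm).
#' @return phase field matrix.
#' @export
phase_field_from_contour <- function(r_mid, grid, eps = 5 / 6) {
  stopifnot(length(r_mid) == grid$N_z)
  vapply(seq_len(grid$N_z),
         function(j) tanh((r_mid[j] - grid$r_centers) / (sqrt(2) * eps)),
         numeric(grid$N_r))
}

#' Minimal synthetic trajectory
#'
#' A hand-built \code{pf_trajectory}-shaped object (energies, fission
#' flags, times) for testing trajectory observables such as
#' \code{\link{fission_time}} without running the dynamics.
#'
#' @param times time points (s).
#' @param F_e elastic energy series (k_BT).
#' @param fission_at index of the first fission record (NA for none).
#' @return a list of class \code{pf_trajectory} (reduced: no fields).
#' @export
synthetic_trajectory <- function(times, F_e, fission_at = NA) {
  n <- length(times)
  flag <- rep(FALSE, n)
  outcome <- "equilibrium"
  tf <- NA_real_
  if (!is.na(fission_at)) {
    flag[fission_at:n] <- TRUE
    outcome <- "fission"
    tf <- times[fission_at]
  }
  obs <- data.frame(t_s = times, F_e = F_e, fission_flag = flag)
  out <- list(times = times, observables = obs,
              events = list(outcome = outcome, t_fission = tf, t_onset = 0,
                            depolymerized = !is.na(fission_at),
                            worst_energy_ascent = 0),
              critical = NULL, E0 = F_e[1])
  class(out) <- "pf_trajectory"
  out
}
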