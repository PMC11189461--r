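#' Neck analysis of a midplane contour
#'
#' The neck of the tubule is the site of maximum constriction.  Local
#' minima of the midplane radius \code{r(z)} are counted as necks when
#' they are at least \code{prominence} below the surrounding local maxima
#' (suppresses grid-scale ripples); a perfect cylinder therefore has zero
#' necks.  \code{R_n} is the global minimum radius, \code{R_c} the radius
#' at the coat center \code{z0}, and \code{D} the distance between the two
#' outermost necks (0 for a single neck).
#'
#' @param contour a \code{midplane_contour} from
#'   \code{\link{extract_midplane_contour}}, or any data frame with
#'   columns \code{z}, \code{r_mid}.
#' @param coats optional \code{coat_set}; its first active coat provides
#'   \code{z0}.
#' @param z0 coat-center position (nm) when no coats are given.
#' @param R_ref reference (undeformed) radius; defaults to the largest
#'   contour radius.
#' @param prominence minimum depth (nm) for a local minimum to count as a
#'   neck; default 0.5.
#' @return object of class \code{neck_analysis}: \code{neck_positions}
#'   (z, nm), \code{n_necks}, \code{R_n}, \code{R_c}, \code{D}.
#' @export
analyze_necks <- function(contour, coats = NULL, z0 = NULL, R_ref = NULL,
                          prominence = 0.5) {
  if (any(contour$closed))
    stop("contour has closed columns (post-fission state); use detect_fission")
  z <- contour$z
  r <- contour$r_mid
  if (is.null(z0)) {
    if (!is.null(coats)) {
      cs <- as_coat_set(coats)
      act <- Filter(function(ct) ct$active, unclass(cs))
      z0 <- if (length(act)) act[[1L]]$z0 else stats::median(z)
    } else z0 <- stats::median(z)
  }
  if (is.null(R_ref)) R_ref <- max(r)
  n <- length(z)
  ## local minima on the periodic signal
  rp <- r[c(n, seq_len(n - 1L))]  # r[i-1]
  rn <- r[c(seq_len(n - 1L) + 1L, 1L)]  # r[i+1]
  is_min <- which(r < rp & r <= rn)
  necks <- numeric(0)
  for (i in is_min) {
    ## prominence: highest level reached on each side before descending
    ## below r[i] again (periodic walk)
    climb <- function(step) {
      top <- r[i]
      j <- i
      for (k in seq_len(n - 1L)) {
        j <- ((j - 1L + step) %% n) + 1L
        if (r[j] < r[i]) break
        top <- max(top, r[j])
      }
      top
    }
    prom <- min(climb(1L), climb(-1L)) - r[i]
    if (prom >= prominence) necks <- c(necks, z[i])
  }
  necks <- sort(unique(necks))
  R_c <- stats::approx(z, r, xout = z0, rule = 2)$y
  out <- list(neck_positions = necks, n_necks = length(necks),
              R_n = min(r), R_c = R_c,
              D = if (length(necks) >= 2L) max(necks) - min(necks) else 0)
  class(out) <- "neck_analysis"
  out
}

#' @export
print.neck_analysis <- function(x, ...) {
  cat(sprintf("neck_analysis: %d neck(s), R_n = %.2f nm, R_c = %.2f nm, D = %.1f nm\n",
              x$n_necks, x$R_n, x$R_c, x$D))
  invisible(x)
}

#' Fission detection
#'
#' Fission is flagged when the internal (phi > 0) phase is disconnected
#' along the axis: at least one z column has \code{phi < 0} for all r
#' (closed lumen).  The location is the centroid of the contiguous closed
#' band (a single-field model does not distinguish hemifission from full
#' fission).
#'
#' @param phi phase field matrix.
#' @param grid optional \code{\link{axisym_grid}}; when given, \code{z} is
#'   reported in nm, otherwise as a column index.
#' @return list with \code{fission} (logical), \code{z} (centroid of the
#'   largest contiguous closed band; NA when intact) and \code{n_closed}
#'   (number of closed columns).
#' @export
detect_fission <- function(phi, grid = NULL) {
  closed <- apply(phi, 2L, max) < 0
  if (!any(closed)) return(list(fission = FALSE, z = NA_real_, n_closed = 0L))
  ## largest contiguous run of closed columns (periodic runs are rare and
  ## split here; adequate for locating the site)
  rl <- rle(closed)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- which(rl$values)
  best <- runs[which.max(rl$lengths[runs])]
  zc <- mean(c(starts[best], ends[best]))
  if (!is.null(grid)) zc <- (zc - 0.5) * grid$dz
  list(fission = TRUE, z = zc, n_closed = sum(closed))
}

#' Critical state of a fission trajectory
#'
#' The critical state is the state of maximum elastic energy
#' \eqn{F_e = F_b + F_G + F_\gamma} when it is followed by fission (the
#' activation state); there is no critical state when no fission occurs.
#'
#' @param traj a \code{pf_trajectory} from \code{\link{run_simulation}}.
#' @param prominence passed to \code{\link{analyze_necks}}.
#' @return object of class \code{critical_state} with \code{t} (s),
#'   \code{dF_e} (activation energy above the unperturbed tubule, k_BT),
#'   \code{phi}, \code{contour}, \code{necks} (neck analysis) and
#'   \code{split} (inner/flank energy split, k_BT); or \code{NULL} (with a
#'   message) for no-fission trajectories.
#' @export
critical_state <- function(traj, prominence = 0.5) {
  stopifnot(inherits(traj, "pf_trajectory"))
  if (traj$events$outcome != "fission" || is.null(traj$critical)) {
    message("no critical state: trajectory did not end in fission")
    return(NULL)
  }
  cr <- traj$critical
  na <- analyze_necks(cr$contour, z0 = traj$z0, prominence = prominence)
  sp <- energy_split(cr$phi, traj$grid, traj$params, na$neck_positions,
                     baseline = traj$phi_initial)
  out <- list(t = cr$t, dF_e = cr$F_e - traj$E0, F_e = cr$F_e,
              phi = cr$phi, contour = cr$contour, necks = na, split = sp)
  class(out) <- "critical_state"
  out
}

#' @export
print.critical_state <- function(x, ...) {
  cat(sprintf("critical_state: t = %.4g s, dF_e = %.1f k_BT, %d neck(s), R_n = %.2f, R_c = %.2f nm\n",
              x$t, x$dF_e, x$necks$n_necks, x$necks$R_n, x$necks$R_c))
  invisible(x)
}

#' Inner/flank split of the critical elastic energy
#'
#' Splits the elastic energy increase over the unperturbed tubule into the
#' contribution of the central constricted region (between the two
#' outermost necks) and of the outer flanks, by integrating the axial
#' energy density between and outside the neck planes.  With fewer than
#' two necks the inner part is zero by convention; inner + flanks equals
#' the total to round-off.
#'
#' @param phi phase field of the state to split.
#' @param grid,params grid and elastic parameters.
#' @param neck_positions z positions (nm) of the necks.
#' @param baseline reference field (the unperturbed tubule) whose density
#'   is subtracted.
#' @return list with \code{inner}, \code{flanks}, \code{total} (k_BT).
#' @export
energy_split <- function(phi, grid, params, neck_positions, baseline) {
  fz <- elastic_energy_z_density(phi, grid, params)
  fz0 <- elastic_energy_z_density(baseline, grid, params)
  d <- fz - fz0
  total <- sum(d)
  if (length(neck_positions) < 2L)
    return(list(inner = 0, flanks = total, total = total))
  zlo <- min(neck_positions)
  zhi <- max(neck_positions)
  inside <- grid$z_centers >= zlo & grid$z_centers <= zhi
  list(inner = sum(d[inside]), flanks = sum(d[!inside]), total = total)
}

#' Normalized lumenal conductance
#'
#' Series-resistor model of the tubule lumen along z with a Debye-layer
#' correction: the conducting radius is the midplane radius minus half the
#' bilayer thickness minus one Debye length,
#' \eqn{r_{lum}(z) = \max(0, r_{mid}(z) - l_{me}/2 - \lambda_D)}, and
#' \deqn{G = \left[\int \frac{dz}{\pi r_{lum}(z)^2}\right]^{-1},}
#' which is zero as soon as the lumen closes anywhere.  Traces are
#' normalized to the initial value, \eqn{G_n(t) = G(t)/G(0)}, so the
#' leading dependence on the exact correction cancels.
#'
#' @param contour a \code{midplane_contour}.
#' @param l_me bilayer thickness (nm).
#' @param lambda_D Debye length (nm), default 1 (physiological ionic
#'   strength).
#' @return conductance in arbitrary units (nm); use ratios.
#' @export
conductance <- function(contour, l_me = 5, lambda_D = 1) {
  if (any(contour$closed)) return(0)
  r_lum <- pmax(0, contour$r_mid - l_me / 2 - lambda_D)
  if (any(r_lum == 0)) return(0)
  dz <- diff(contour$z[1:2])
  1 / sum(dz / (pi * r_lum^2))
}

#' Conductance trace of a trajectory
#'
#' @param traj a \code{pf_trajectory}.
#' @return data frame with \code{t_s} and \code{G_n}.
#' @export
conductance_trace <- function(traj) {
  data.frame(t_s = traj$observables$t_s, G_n = traj$observables$G_n)
}

#' Fission time
#'
#' Time elapsed from the onset of constriction forcing to the first
#' detection of fission.
#'
#' @param traj a \code{pf_trajectory}.
#' @return time in seconds, or NA when no fission occurred.
#' @export
fission_time <- function(traj) {
  if (is.na(traj$events$t_fission)) return(NA_real_)
  traj$events$t_fission - traj$events$t_onset
}
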