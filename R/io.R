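## Plain-text I/O: observable tables as CSV, field snapshots as a
## self-describing directory (CSV array + JSON attribute sidecar), and a
## JSON run manifest with all resolved parameters.

#' Write trajectory observables as CSV
#'
#' Columns: t_s, F_b, F_G, F_gamma, I, F_e, F_total (k_BT), R_n_nm,
#' R_c_nm, n_necks, D_nm, G_n, fission_flag.
#'
#' @param traj a \code{pf_trajectory}.
#' @param path output file.
#' @export
write_observables_csv <- function(traj, path) {
  utils::write.csv(traj$observables, path, row.names = FALSE)
  invisible(path)
}

#' Field snapshot I/O
#'
#' A snapshot is a directory holding the field values
#' (\code{values.csv}, N_r x N_z), the cell-center coordinates and all
#' physical parameters and time-stamp attributes (\code{meta.json}) — a
#' self-describing array container in portable plain text.
#'
#' @param phi field matrix.
#' @param grid an \code{\link{axisym_grid}}.
#' @param params an \code{\link{elastic_params}}.
#' @param path snapshot directory (created).
#' @param time simulated time (s).
#' @param step step counter.
#' @export
write_snapshot <- function(phi, grid, params, path, time = NA, step = NA) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(phi, file.path(path, "values.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(
    dataset = "phi", nrow = grid$N_r, ncol = grid$N_z,
    r_centers = grid$r_centers, z_centers = grid$z_centers,
    attrs = list(L_r = grid$L_r, L_z = grid$L_z, k_b = params$k_b,
                 k_G = params$k_G, gamma = params$gamma, eps = params$eps,
                 l_me = params$l_me, M_pf = params$M_pf,
                 time_s = time, step = step))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_snapshot
#' @return \code{read_snapshot}: list with \code{phi}, \code{r_centers},
#'   \code{z_centers}, \code{attrs}.
#' @export
read_snapshot <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  phi <- as.matrix(utils::read.table(file.path(path, "values.csv"),
                                     sep = ","))
  dimnames(phi) <- NULL
  list(phi = phi, r_centers = meta$r_centers, z_centers = meta$z_centers,
       attrs = meta$attrs)
}

#' Write a JSON run manifest
#'
#' All resolved parameters of a configuration plus the package version,
#' for reproducibility of sweeps.
#'
#' @param config a \code{pf_config}.
#' @param path output file.
#' @export
write_run_manifest <- function(config, path) {
  cf <- list(
    package = "tubefission",
    version = as.character(utils::packageVersion("tubefission")),
    grid = config$grid[c("L_r", "L_z", "N_r", "N_z", "dr", "dz")],
    params = unclass(config$params),
    coats = lapply(unclass(config$coats), unclass),
    stepper = unclass(config$stepper),
    R_in = config$R_in, t_max = config$t_max,
    post_fission_time = config$post_fission_time,
    lambda_D = config$lambda_D)
  jsonlite::write_json(cf, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
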