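## Orchestrated sweeps and figure-level reproductions at configurable
## (reduced) scale: H-sweeps, neck-splitting threshold bracketing, and
## conductance scenarios.

#' Sweep over dynamin polymerization lengths
#'
#' Runs one simulation per coat length H and collects the summary used to
#' characterize fission efficacy and efficiency: equilibrium or critical
#' neck radius, central radius, activation energy, neck count and
#' spacing, and fission time.
#'
#' @param H_values coat lengths to run (nm).
#' @param base_config_fn function(H) returning a \code{pf_config}; default
#'   builds \code{\link{reduced_config}}s.
#' @param runner simulation runner, by default
#'   \code{\link{run_simulation}} (injectable for testing).
#' @param verbose print per-run progress.
#' @return data frame with one row per H: \code{H_nm}, \code{fission},
#'   \code{R_n_end}, \code{R_n_crit}, \code{R_c_crit}, \code{dFe_crit},
#'   \code{n_necks_crit}, \code{D_crit}, \code{t_f_s}.  Failed runs are
#'   recorded with NAs and the sweep continues.
#' @export
h_sweep <- function(H_values, base_config_fn = reduced_config,
                    runner = run_simulation, verbose = FALSE) {
  rows <- lapply(H_values, function(H) {
    res <- tryCatch({
      traj <- runner(base_config_fn(H))
      cs <- if (traj$events$outcome == "fission")
        suppressMessages(critical_state(traj)) else NULL
      last <- traj$observables[nrow(traj$observables), ]
      data.frame(
        H_nm = H, fission = traj$events$outcome == "fission",
        outcome = traj$events$outcome,
        R_n_end = last$R_n_nm,
        R_n_crit = if (!is.null(cs)) cs$necks$R_n else NA_real_,
        R_c_crit = if (!is.null(cs)) cs$necks$R_c else NA_real_,
        dFe_crit = if (!is.null(cs)) cs$dF_e else NA_real_,
        n_necks_crit = if (!is.null(cs)) cs$necks$n_necks else NA_integer_,
        D_crit = if (!is.null(cs)) cs$necks$D else NA_real_,
        t_f_s = fission_time(traj))
    }, error = function(e) {
      warning(sprintf("H = %g nm run failed: %s", H, conditionMessage(e)))
      data.frame(H_nm = H, fission = NA, outcome = "error",
                 R_n_end = NA_real_, R_n_crit = NA_real_,
                 R_c_crit = NA_real_, dFe_crit = NA_real_,
                 n_necks_crit = NA_integer_, D_crit = NA_real_,
                 t_f_s = NA_real_)
    })
    if (verbose) message(sprintf("H = %g nm: %s", H, res$outcome))
    res
  })
  do.call(rbind, rows)
}

#' Bracket the neck-splitting threshold H*
#'
#' Bisection on the number of necks of the critical state (one neck:
#' fission at the coat center; two necks: fission at the edges).  The
#' detection criterion is the package's standard one: the maximum
#' constriction sites of the maximum-elastic-energy state anticipate the
#' fission sites.
#'
#' @param H_lo,H_hi initial bracket (nm); \code{H_lo} must give one neck
#'   and \code{H_hi} two (checked).
#' @param base_config_fn function(H) returning a \code{pf_config}.
#' @param runner simulation runner (injectable; the default runs the full
#'   phase-field dynamics).
#' @param width_target bracket width at which bisection stops (nm).
#' @param max_iter bisection iteration cap.
#' @return list with \code{H_below}, \code{H_above}, \code{H_star}
#'   (midpoint), \code{runs} (evaluated H with neck counts).
#' @export
find_threshold <- function(H_lo, H_hi, base_config_fn = reduced_config,
                           runner = run_simulation, width_target = 5,
                           max_iter = 6) {
  neck_count <- function(H) {
    traj <- runner(base_config_fn(H))
    if (traj$events$outcome != "fission")
      stop(sprintf("H = %g nm: no fission; threshold search needs fission runs", H))
    suppressMessages(critical_state(traj))$necks$n_necks
  }
  runs <- data.frame(H = numeric(0), n_necks = integer(0))
  note <- function(H, n) runs <<- rbind(runs, data.frame(H = H, n_necks = n))
  n_lo <- neck_count(H_lo); note(H_lo, n_lo)
  n_hi <- neck_count(H_hi); note(H_hi, n_hi)
  if (n_lo >= 2 || n_hi < 2)
    stop(sprintf("bracket [%g, %g] does not straddle the splitting (necks %d -> %d)",
                 H_lo, H_hi, n_lo, n_hi))
  for (i in seq_len(max_iter)) {
    if (H_hi - H_lo <= width_target) break
    H_mid <- (H_lo + H_hi) / 2
    n_mid <- neck_count(H_mid); note(H_mid, n_mid)
    if (n_mid >= 2) H_hi <- H_mid else H_lo <- H_mid
  }
  list(H_below = H_lo, H_above = H_hi, H_star = (H_lo + H_hi) / 2,
       runs = runs)
}

#' Conductance scenarios
#'
#' Runs the configured coat scenarios and returns one normalized
#' conductance trace per configuration (single short coat, single long
#' coat, multiple collars, ...).
#'
#' @param configs named list of \code{pf_config}s.
#' @param runner simulation runner.
#' @return named list of data frames (\code{t_s}, \code{G_n}), each with
#'   attribute \code{t_fission}.
#' @export
conductance_experiment <- function(configs, runner = run_simulation) {
  out <- lapply(configs, function(cfg) {
    traj <- runner(cfg)
    tr <- conductance_trace(traj)
    attr(tr, "t_fission") <- traj$events$t_fission
    tr
  })
  out
}
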