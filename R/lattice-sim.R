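#' Lattice and run configuration for a TASEP-LK simulation
#'
#' @param lattice_length_um Track length in micrometres; converted internally
#'   to sites of one motor step.
#' @param duration_s Simulated time in seconds (must exceed the burn-in).
#' @param concentration Bulk motor concentration, in the unit given by
#'   \code{conc_unit}. Ignored when \code{langmuir = FALSE}.
#' @param conc_unit Either \code{"per_um3"} (motors/um^3) or \code{"nM"}.
#' @param boundary \code{"open"} (motors stepping past the plus end leave the
#'   lattice; their runs are censored) or \code{"ring"} (periodic).
#' @param langmuir Enable Langmuir kinetics (attachment/detachment exchange
#'   with solution). With \code{langmuir = FALSE} a fixed number of motors
#'   \code{n_motors} is placed at time zero and never detaches.
#' @param n_motors Initial motor count (fixed-number mode). Mutually
#'   exclusive with \code{langmuir = TRUE} on a ring.
#' @param burn_in_s Time discarded before averaging. Default
#'   \code{max(5 / omega_D, lattice_length / v0)}, chosen at simulation time.
#' @param snapshot_interval_s Interval between occupancy snapshots (Inf for
#'   none); snapshots start at the end of the burn-in.
#' @param seed Integer RNG seed; identical seeds give bit-identical event
#'   sequences.
#' @param n_batches Number of time batches used for batch-means standard
#'   errors of density and velocity.
#' @return An object of class \code{lattice_config}.
#' @export
lattice_config <- function(lattice_length_um, duration_s,
                           concentration = 0, conc_unit = c("per_um3", "nM"),
                           boundary = c("open", "ring"), langmuir = TRUE,
                           n_motors = 0L, burn_in_s = NULL,
                           snapshot_interval_s = Inf, seed = 1L,
                           n_batches = 10L) {
  boundary <- match.arg(boundary)
  conc_unit <- match.arg(conc_unit)
  if (!is.numeric(lattice_length_um) || lattice_length_um <= 0)
    stop("lattice_length_um must be > 0", call. = FALSE)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  conc <- if (conc_unit == "nM") nM_to_per_um3(concentration) else concentration
  if (boundary == "ring" && langmuir && n_motors > 0)
    stop("ring boundary with Langmuir kinetics and a fixed motor number ",
         "are mutually exclusive", call. = FALSE)
  if (!is.null(burn_in_s) && (burn_in_s < 0 || burn_in_s >= duration_s))
    stop("need duration_s > burn_in_s >= 0", call. = FALSE)
  structure(list(lattice_length_um = lattice_length_um,
                 duration_s = duration_s,
                 concentration_per_um3 = conc,
                 boundary = boundary, langmuir = langmuir,
                 n_motors = as.integer(n_motors),
                 burn_in_s = burn_in_s,
                 snapshot_interval_s = snapshot_interval_s,
                 seed = as.integer(seed),
                 n_batches = as.integer(n_batches)),
            class = "lattice_config")
}

default_burn_in <- function(params, config) {
  v0 <- analytic_low_density(params)$v0_um_s
  cand <- c(if (params$omega_D > 0 && config$langmuir) 5 / params$omega_D,
            if (v0 > 0) config$lattice_length_um / v0)
  b <- if (length(cand)) max(cand) else 0
  min(b, 0.5 * config$duration_s)
}

#' Simulate motor traffic on a multi-lane lattice
#'
#' Runs the exact continuous-time (Gillespie) realisation of the multi-lane
#' TASEP-LK: motors attach wherever a full footprint of sites is free (rate
#' \code{omega_A0 * c} per site per lane), step one site towards the plus
#' end at \code{step_rate} when the target sites are empty and the gap to
#' the motor ahead stays at least \code{interaction_range} motor sizes, and
#' detach at \code{omega_D} (or \code{omega_DC} while blocked). Lanes are
#' independent; there is no side-stepping.
#'
#' @param params A \code{\link{kinetic_params}} object.
#' @param config A \code{\link{lattice_config}} object.
#' @return A \code{trajectory_set}: list with \code{runs} (one row per
#'   binding event: lane, bind/unbind time, bind/unbind front site, censored
#'   flag), \code{snapshots} (front sites at snapshot times), \code{stats}
#'   (post-burn-in counters and batch accumulators), \code{params},
#'   \code{config} and \code{site_um}. On rings, \code{unbind_site} is
#'   unwrapped (\code{bind_site + steps}) so displacement is always
#'   \code{unbind_site - bind_site}.
#' @export
simulate_traffic <- function(params, config) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(config, "lattice_config"))
  site_um <- params$motor_step_nm / 1000
  L <- max(params$footprint_sites,
           as.integer(round(config$lattice_length_um / site_um)))
  burn_in <- config$burn_in_s
  if (is.null(burn_in)) burn_in <- default_burn_in(params, config)
  if (burn_in >= config$duration_s)
    stop("burn-in (", signif(burn_in, 3), " s) must be shorter than ",
         "duration_s", call. = FALSE)
  if (config$boundary == "open" && config$langmuir && params$omega_D > 0) {
    min_len <- 5 * (params$step_rate / params$omega_D) *
      params$motor_step_nm / 1000
    if (config$lattice_length_um < min_len)
      warning(sprintf(paste0("open lattice (%g um) shorter than 5 mean run",
                             " lengths (%g um); end-censoring will be common"),
                      config$lattice_length_um, min_len), call. = FALSE)
  }
  ka_site <- if (config$langmuir)
    params$omega_A0 * config$concentration_per_um3 else 0
  snap <- if (is.finite(config$snapshot_interval_s))
    seq(burn_in, config$duration_s, by = config$snapshot_interval_s)
  else numeric(0)

  set.seed(config$seed)
  res <- .sim_core(L, params$n_lanes, params$footprint_sites,
                   params$step_rate, ka_site, params$omega_D,
                   params$omega_DC, params$interaction_range,
                   config$boundary == "ring", config$langmuir,
                   config$n_motors, config$duration_s, burn_in,
                   snap, config$n_batches)
  structure(list(runs = res$runs, snapshots = res$snapshots,
                 stats = res$stats, params = params, config = config,
                 site_um = site_um, burn_in_s = burn_in,
                 seed = config$seed, source = "lattice"),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set (%s): %d runs (%.1f%% censored)\n",
              x$source, nrow(x$runs),
              if (nrow(x$runs)) 100 * mean(x$runs$censored) else 0))
  invisible(x)
}

#' Continuous-time motor paths of a trajectory set
#'
#' Returns one straight space-time segment per run: position in um along the
#' track axis from binding to unbinding. Lattice runs are interpolated
#' linearly between their bound and unbound front sites, which matches the
#' stepping path to within one step at the densities where paths are
#' rendered into images.
#'
#' @param ts A \code{trajectory_set}.
#' @return Data frame with columns \code{id, t0_s, t1_s, x0_um, x1_um,
#'   censored}.
#' @export
motor_paths <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  if (!is.null(ts$paths)) return(ts$paths)
  r <- ts$runs
  data.frame(id = seq_len(nrow(r)), t0_s = r$bind_time_s,
             t1_s = r$unbind_time_s,
             x0_um = (r$bind_site - 1) * ts$site_um,
             x1_um = (r$unbind_site - 1) * ts$site_um,
             censored = r$censored)
}

#' Summarise a simulation into density, velocity and run length
#'
#' Density is the time-averaged motor count per micrometre of track (all
#' lanes summed) after the burn-in, with a batch-means standard error.
#' Velocity is the displacement-weighted ensemble mean, total displacement
#' over total attached time -- on open lattices over all post-burn-in runs
#' (censored included), on rings from the exact post-burn-in step counters.
#' Run length is the maximum-likelihood mean of an exponential in which
#' right-censored runs (lattice exit or simulation end) contribute survival
#' terms: \code{sum(all lengths) / n_uncensored}.
#'
#' @param ts A \code{trajectory_set} from \code{\link{simulate_traffic}} or
#'   \code{\link{parametric_trajectories}}.
#' @param min_uncensored Minimum number of uncensored post-burn-in runs
#'   required for the run-length fit.
#' @return An object of class \code{sim_observables}: density, velocity and
#'   run length with standard errors, plus run counts and the seed.
#' @export
summarize_traffic <- function(ts, min_uncensored = 100) {
  stopifnot(inherits(ts, "trajectory_set"))
  paths <- motor_paths(ts)
  burn_in <- if (!is.null(ts$burn_in_s)) ts$burn_in_s else 0
  duration <- if (!is.null(ts$config$duration_s)) ts$config$duration_s
    else max(paths$t1_s, 0)
  length_um <- if (!is.null(ts$config$lattice_length_um))
    ts$config$lattice_length_um else ts$config$length_um
  post <- paths[paths$t0_s >= burn_in, , drop = FALSE]

  n_unc <- sum(!post$censored)
  if (n_unc == 0)
    stop(sprintf(paste0("no uncensored runs after burn-in (%d runs, 100%%",
                        " censored); cannot estimate a run length"),
                 nrow(post)), call. = FALSE)
  if (n_unc < min_uncensored)
    stop(sprintf(paste0("only %d uncensored runs after burn-in (censoring ",
                        "fraction %.2f); need >= %d"),
                 n_unc, mean(post$censored), min_uncensored), call. = FALSE)

  # velocity: total displacement / total attached time
  disp <- post$x1_um - post$x0_um
  dur <- post$t1_s - post$t0_s
  if (!is.null(ts$stats) && ts$config$boundary == "ring") {
    st <- ts$stats
    v <- st$steps_post * ts$site_um / st$motor_time_s
    bv <- st$batch_steps * ts$site_um / st$batch_motor_time_s
    bv <- bv[is.finite(bv)]
    v_se <- stats::sd(bv) / sqrt(length(bv))
  } else {
    v <- sum(disp) / sum(dur)
    # ratio-estimator (delta method) SE over runs
    v_se <- sqrt(sum((disp - v * dur)^2)) / sum(dur)
  }

  # exponential MLE with right censoring
  rl <- sum(disp) / n_unc
  rl_se <- rl / sqrt(n_unc)

  # density from batch-means when available, else from path overlap
  if (!is.null(ts$stats)) {
    st <- ts$stats
    dens <- st$motor_time_s / (duration - burn_in) / length_um
    bd <- st$batch_motor_time_s / st$batch_duration_s / length_um
    dens_se <- stats::sd(bd) / sqrt(length(bd))
  } else {
    ov <- pmax(0, pmin(paths$t1_s, duration) - pmax(paths$t0_s, burn_in))
    dens <- sum(ov) / (duration - burn_in) / length_um
    dens_se <- dens / sqrt(max(1, nrow(post)))
  }

  structure(list(density_per_um = dens, density_se = dens_se,
                 velocity_um_s = v, velocity_se = v_se,
                 run_length_um = rl, run_length_se = rl_se,
                 n_runs = nrow(post), n_uncensored = n_unc,
                 censoring_fraction = mean(post$censored),
                 seed = ts$seed),
            class = "sim_observables")
}

#' Time-averaged ensemble velocity from post-burn-in step counters
#'
#' Velocity as (steps taken) * (step size) / (motor-bound time), accumulated
#' exactly after the burn-in, with a batch-means standard error. Unlike
#' \code{\link{summarize_traffic}} this needs no completed runs, so it also
#' applies to fixed-number ring simulations where every run is censored.
#'
#' @param ts A \code{trajectory_set} from \code{\link{simulate_traffic}}.
#' @return List with \code{velocity_um_s}, \code{se}, \code{n_steps} and
#'   \code{motor_time_s}.
#' @export
ensemble_velocity <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"), !is.null(ts$stats))
  st <- ts$stats
  if (st$motor_time_s <= 0)
    stop("no motor-bound time after burn-in", call. = FALSE)
  bv <- st$batch_steps * ts$site_um / st$batch_motor_time_s
  bv <- bv[is.finite(bv)]
  list(velocity_um_s = st$steps_post * ts$site_um / st$motor_time_s,
       se = if (length(bv) > 1) stats::sd(bv) / sqrt(length(bv)) else NA_real_,
       n_steps = st$steps_post, motor_time_s = st$motor_time_s)
}

#' @export
print.sim_observables <- function(x, ...) {
  cat("Simulated motility observables\n")
  cat(sprintf("  density    %.3g +/- %.2g motors/um\n",
              x$density_per_um, x$density_se))
  cat(sprintf("  velocity   %.3g +/- %.2g um/s\n",
              x$velocity_um_s, x$velocity_se))
  cat(sprintf("  run length %.3g +/- %.2g um  (%d runs, %d uncensored)\n",
              x$run_length_um, x$run_length_se, x$n_runs, x$n_uncensored))
  invisible(x)
}
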