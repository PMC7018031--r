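#' Assemble a concentration series of motility observables
#'
#' @param conc_nM Total motor concentration (nM).
#' @param density,density_se Motor density on the track (motors/um).
#' @param velocity,velocity_se Velocity (um/s).
#' @param runlength,runlength_se Run length (um).
#' @return A \code{concentration_series} data frame.
#' @export
concentration_series <- function(conc_nM, density, density_se,
                                 velocity, velocity_se,
                                 runlength, runlength_se) {
  if (any(conc_nM <= 0)) stop("concentrations must be > 0", call. = FALSE)
  df <- data.frame(conc_nM = conc_nM, density = density,
                   density_se = density_se, velocity = velocity,
                   velocity_se = velocity_se, runlength = runlength,
                   runlength_se = runlength_se)
  class(df) <- c("concentration_series", "data.frame")
  df
}

#' Stage-1 rates from the low-concentration linear regime
#'
#' At low concentrations density, velocity and run length depend linearly
#' (density) or not at all (velocity, run length) on concentration, so the
#' elementary rates can be read off directly: the step rate is the
#' velocity plateau divided by the motor step, the detachment rate is the
#' velocity plateau divided by the run-length plateau, and the volumetric
#' affinity follows from the through-origin slope of density against
#' concentration using the per-site attachment convention of
#' \code{\link{simulate_traffic}} (density per lane per site =
#' \code{omega_A0 * c / omega_D} at equilibrium).
#'
#' A curvature check refuses series that leave the linear regime: the
#' quadratic term of a through-origin fit must stay below
#' \code{max_curvature} of the linear prediction at the largest
#' concentration.
#'
#' @param series A \code{concentration_series} with >= 3 concentrations.
#' @param params A \code{\link{kinetic_params}} template supplying the
#'   geometry (motor step, lane count) of the attachment convention.
#' @param max_curvature Allowed relative quadratic contribution.
#' @return List with \code{omega_A0}, \code{omega_D}, \code{step_rate},
#'   \code{v0_um_s}, \code{run_length_um} and standard errors.
#' @export
fit_low_density <- function(series, params, max_curvature = 0.1) {
  stopifnot(inherits(series, "data.frame"),
            inherits(params, "kinetic_params"))
  s <- series[is.finite(series$density) & is.finite(series$velocity) &
              is.finite(series$runlength), ]
  if (length(unique(s$conc_nM)) < 3)
    stop("need >= 3 distinct concentrations with finite observables",
         call. = FALSE)
  if (all(s$density <= 0))
    stop("all densities are zero; nothing to fit", call. = FALSE)
  c3 <- nM_to_per_um3(s$conc_nM)              # motors/um^3
  wd <- 1 / pmax(s$density_se, 1e-12)^2
  lin <- stats::lm(density ~ 0 + c3, data = cbind(s, c3 = c3), weights = wd)
  quad <- stats::lm(density ~ 0 + c3 + I(c3^2), data = cbind(s, c3 = c3),
                    weights = wd)
  b <- stats::coef(quad)
  curv <- abs(b[["I(c3^2)"]] * max(c3)) / abs(b[["c3"]])
  if (is.finite(curv) && curv > max_curvature) {
    # admissible range: concentrations where the quadratic term stays small
    c_adm <- max_curvature * abs(b[["c3"]] / b[["I(c3^2)"]])
    stop(sprintf(paste0("density vs concentration is non-linear (relative ",
                        "curvature %.2f at %.3g nM); restrict the series ",
                        "to <= %.3g nM"),
                 curv, max(s$conc_nM), per_um3_to_nM(c_adm)), call. = FALSE)
  }
  slope <- unname(stats::coef(lin)["c3"])     # (motors/um) per (motors/um^3)
  slope_se <- summary(lin)$coefficients["c3", 2]

  wmean <- function(x, se) {
    w <- 1 / pmax(se, 1e-12)^2
    c(mean = sum(w * x) / sum(w), se = sqrt(1 / sum(w)))
  }
  v0 <- wmean(s$velocity, s$velocity_se)
  rl0 <- wmean(s$runlength, s$runlength_se)
  if (v0["mean"] <= 0 || rl0["mean"] <= 0)
    stop("velocity / run-length plateaus must be positive", call. = FALSE)
  omega_D <- v0[["mean"]] / rl0[["mean"]]
  omega_D_se <- omega_D * sqrt((v0[["se"]] / v0[["mean"]])^2 +
                               (rl0[["se"]] / rl0[["mean"]])^2)
  step_um <- params$motor_step_nm / 1000
  step_rate <- v0[["mean"]] / step_um
  sites_per_um <- 1000 / params$motor_step_nm
  cal <- params$n_lanes * sites_per_um
  omega_A0 <- slope * omega_D / cal
  omega_A0_se <- omega_A0 * sqrt((slope_se / slope)^2 +
                                 (omega_D_se / omega_D)^2)
  list(omega_A0 = omega_A0, omega_A0_se = omega_A0_se,
       omega_D = omega_D, omega_D_se = omega_D_se,
       step_rate = step_rate, step_rate_se = v0[["se"]] / step_um,
       v0_um_s = v0[["mean"]], v0_se = v0[["se"]],
       run_length_um = rl0[["mean"]], run_length_se = rl0[["se"]],
       density_slope_um2 = slope)
}

#' Model-predicted concentration series from simulations
#'
#' For each concentration the multi-lane TASEP-LK is simulated
#' \code{reps} times with distinct derived seeds and summarised; the
#' returned series carries the mean and standard error of density,
#' velocity and run length per concentration.
#'
#' @param params A \code{\link{kinetic_params}}.
#' @param concentrations_nM Concentrations to simulate (nM).
#' @param reps Replicate simulations per concentration.
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @param lattice_length_um,duration_s,burn_in_s Simulation extent.
#' @param min_uncensored Passed to \code{\link{summarize_traffic}}.
#' @return A \code{concentration_series}; failed points carry \code{NA}
#'   and a warning, the sweep continues.
#' @export
predict_series <- function(params, concentrations_nM, reps = 3, seed = 1L,
                           lattice_length_um = 5, duration_s = 80,
                           burn_in_s = 25, min_uncensored = 20) {
  stopifnot(inherits(params, "kinetic_params"), reps >= 1)
  rows <- lapply(seq_along(concentrations_nM), function(i) {
    cc <- concentrations_nM[i]
    obs <- lapply(seq_len(reps), function(r) {
      cfg <- lattice_config(lattice_length_um, duration_s,
                            concentration = cc, conc_unit = "nM",
                            burn_in_s = burn_in_s,
                            seed = derive_seed(seed, 1000L * i + r))
      # short sweep lattices censor many runs; the summariser treats those
      # as survival terms, so the advisory warning is muffled here
      ts <- withCallingHandlers(
        simulate_traffic(params, cfg),
        warning = function(w) {
          if (grepl("end-censoring", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      if (nrow(ts$runs) == 0) {
        # nothing ever bound: the density is genuinely zero
        structure(list(density_per_um = 0, density_se = 0,
                       velocity_um_s = NA_real_, velocity_se = NA_real_,
                       run_length_um = NA_real_, run_length_se = NA_real_),
                  class = "sim_observables")
      } else {
        tryCatch(summarize_traffic(ts, min_uncensored = min_uncensored),
                 error = function(e) {
                   warning("concentration ", cc, " nM, rep ", r, ": ",
                           conditionMessage(e), call. = FALSE)
                   NULL
                 })
      }
    })
    obs <- obs[!vapply(obs, is.null, logical(1))]
    if (!length(obs))
      return(data.frame(conc_nM = cc, density = NA, density_se = NA,
                        velocity = NA, velocity_se = NA,
                        runlength = NA, runlength_se = NA))
    agg <- function(field, sefield) {
      x <- vapply(obs, `[[`, numeric(1), field)
      se_w <- vapply(obs, `[[`, numeric(1), sefield)
      se <- if (length(x) > 1)
        max(stats::sd(x) / sqrt(length(x)),
            sqrt(mean(se_w^2) / length(x)))
      else se_w
      c(mean(x), se)
    }
    d <- agg("density_per_um", "density_se")
    v <- agg("velocity_um_s", "velocity_se")
    rl <- agg("run_length_um", "run_length_se")
    data.frame(conc_nM = cc, density = d[1], density_se = d[2],
               velocity = v[1], velocity_se = v[2],
               runlength = rl[1], runlength_se = rl[2])
  })
  df <- do.call(rbind, rows)
  class(df) <- c("concentration_series", "data.frame")
  attr(df, "params") <- params
  attr(df, "seed") <- seed
  df
}

#' Grid search for lane count, interaction range and detachment ratio
#'
#' Stage 2 of the fitting procedure: with the stage-1 rates fixed, every
#' triple (number of lanes, interaction range, omega_DC/omega_D ratio) on
#' the grid is simulated across the observed concentrations and scored by
#' the sum over density, velocity and run length of SE-weighted squared
#' log-residuals. Ties are broken towards smaller lane counts, then
#' smaller interaction ranges, then smaller ratios.
#'
#' @param observed A \code{concentration_series} with standard errors.
#' @param params A \code{\link{kinetic_params}} carrying the stage-1 rates
#'   (\code{omega_A0}, \code{omega_D}, \code{step_rate}).
#' @param lanes,ranges,ratios Grid values; must lie in 1..13, 0..20 and
#'   0..10 respectively.
#' @param reps,seed,... Passed to \code{\link{predict_series}}.
#' @return A \code{fit_result}: \code{best} triple (with the implied
#'   \code{omega_DC}), \code{loss}, the full \code{loss_table}, and the
#'   seeds used.
#' @export
grid_search_fit <- function(observed, params, lanes = 1:13,
                            ranges = 0:20, ratios = 0:10,
                            reps = 3, seed = 1L, ...) {
  stopifnot(inherits(observed, "data.frame"))
  if (!length(lanes) || !length(ranges) || !length(ratios))
    stop("empty grid", call. = FALSE)
  if (any(lanes < 1 | lanes > 13) || any(ranges < 0 | ranges > 20) ||
      any(ratios < 0 | ratios > 10))
    stop("grid bounds: lanes in 1..13, interaction range in 0..20, ",
         "omega_DC/omega_D ratio in 0..10", call. = FALSE)
  grid <- expand.grid(ratio = sort(ratios), interaction_range = sort(ranges),
                      n_lanes = sort(lanes))
  grid <- grid[order(grid$n_lanes, grid$interaction_range, grid$ratio), ]

  # offsets for log-residuals: smallest positive SE per observable
  eps <- vapply(c("density_se", "velocity_se", "runlength_se"),
                function(f) {
                  v <- observed[[f]][observed[[f]] > 0]
                  if (length(v)) min(v) else 1e-6
                }, numeric(1))
  names(eps) <- c("density", "velocity", "runlength")

  score <- function(pred) {
    tot <- 0
    for (f in c("density", "velocity", "runlength")) {
      o <- observed[[f]]; se <- observed[[paste0(f, "_se")]]
      p <- pred[[f]][match(observed$conc_nM, pred$conc_nM)]
      ok <- is.finite(o) & is.finite(p) & is.finite(se)
      if (!any(ok)) next
      rel <- pmax(se[ok] / pmax(o[ok], eps[[f]]), 1e-3)   # SE on log scale
      tot <- tot + sum(((log(p[ok] + eps[[f]]) -
                         log(o[ok] + eps[[f]])) / rel)^2)
    }
    tot
  }

  losses <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pg <- kinetic_params(motor_size_nm = params$motor_size_nm,
                         motor_step_nm = params$motor_step_nm,
                         step_rate = params$step_rate,
                         omega_A0 = params$omega_A0,
                         omega_D = params$omega_D,
                         omega_DC = grid$ratio[g] * params$omega_D,
                         n_lanes = grid$n_lanes[g],
                         interaction_range = grid$interaction_range[g])
    pred <- suppressWarnings(
      predict_series(pg, observed$conc_nM, reps = reps,
                     seed = derive_seed(seed, g), ...))
    losses[g] <- score(pred)
  }
  grid$loss <- losses
  best_i <- which.min(losses)          # first minimum = smallest triple
  best <- grid[best_i, ]
  structure(list(best = list(n_lanes = best$n_lanes,
                             interaction_range = best$interaction_range,
                             ratio = best$ratio,
                             omega_DC = best$ratio * params$omega_D),
                 loss = best$loss,
                 loss_table = grid,
                 stage1 = list(omega_A0 = params$omega_A0,
                               omega_D = params$omega_D,
                               step_rate = params$step_rate),
                 seed = seed, reps = reps),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("TASEP-LK grid-search fit\n")
  cat(sprintf("  best triple: %d lanes, interaction range %d, ",
              x$best$n_lanes, x$best$interaction_range))
  cat(sprintf("omega_DC/omega_D = %d (omega_DC = %.3g /s)\n",
              x$best$ratio, x$best$omega_DC))
  cat(sprintf("  loss %.4g over %d grid points\n", x$loss,
              nrow(x$loss_table)))
  invisible(x)
}
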