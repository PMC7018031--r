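#' Kinetic parameter set for the multi-lane TASEP-LK motor-traffic model
#'
#' Bundles the rates and geometry of the lattice-gas model of processive
#' motors on a microtubule: motors bind anywhere a full footprint of lattice
#' sites is empty (rate \code{omega_A0 * concentration} per site), step
#' towards the plus end at \code{step_rate} when exclusion and the
#' interaction range allow it, and detach at \code{omega_D} when free to
#' step or at \code{omega_DC} when constrained (blocked). Defaults are the
#' fitted kinesin-II values in low-salt (PEM12) conditions.
#'
#' @param motor_size_nm Length a motor occupies on one protofilament (nm).
#'   Must be an integer multiple of \code{motor_step_nm}.
#' @param motor_step_nm Step size and lattice constant (nm).
#' @param step_rate Stepping frequency of an unobstructed motor (1/s).
#' @param omega_A0 Volumetric binding affinity (um^3/s): the per-site
#'   attachment rate is \code{omega_A0} times the bulk motor concentration
#'   in motors/um^3.
#' @param omega_D Detachment rate of unconstrained motors (1/s).
#' @param omega_DC Detachment rate of constrained motors, i.e. motors whose
#'   forward step is blocked (1/s). Used *instead of* \code{omega_D} while
#'   the motor is blocked.
#' @param n_lanes Number of accessible protofilaments (independent lanes),
#'   between 1 and 13.
#' @param interaction_range Extra gap, in units of motor sizes, a motor must
#'   keep to the motor ahead after stepping; 0 is plain hard-core exclusion.
#' @return An object of class \code{kinetic_params}.
#' @examples
#' p <- kinetic_params()
#' analytic_low_density(p)
#' @export
kinetic_params <- function(motor_size_nm = 16, motor_step_nm = 8,
                           step_rate = 37.5, omega_A0 = 1.53e-4,
                           omega_D = 0.25, omega_DC = 0.75,
                           n_lanes = 13, interaction_range = 0) {
  stopifnot(motor_size_nm > 0, motor_step_nm > 0)
  rates <- c(step_rate = step_rate, omega_A0 = omega_A0,
             omega_D = omega_D, omega_DC = omega_DC)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0", call. = FALSE)
  f <- motor_size_nm / motor_step_nm
  if (abs(f - round(f)) > 1e-9)
    stop("motor_size_nm must be an integer multiple of motor_step_nm",
         call. = FALSE)
  if (n_lanes < 1 || n_lanes > 13 || n_lanes != round(n_lanes))
    stop("n_lanes must be an integer in 1..13", call. = FALSE)
  if (interaction_range < 0 || interaction_range != round(interaction_range))
    stop("interaction_range must be a non-negative integer", call. = FALSE)
  if (omega_DC < omega_D)
    warning("omega_DC < omega_D: constrained motors detach more slowly ",
            "than free ones", call. = FALSE)
  structure(list(motor_size_nm = motor_size_nm,
                 motor_step_nm = motor_step_nm,
                 step_rate = step_rate, omega_A0 = omega_A0,
                 omega_D = omega_D, omega_DC = omega_DC,
                 n_lanes = as.integer(n_lanes),
                 interaction_range = as.integer(interaction_range),
                 footprint_sites = as.integer(round(f))),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("TASEP-LK kinetic parameters\n")
  cat(sprintf("  motor size %g nm (footprint %d sites), step %g nm\n",
              x$motor_size_nm, x$footprint_sites, x$motor_step_nm))
  cat(sprintf("  step rate %g /s, omega_A0 %g um^3/s\n",
              x$step_rate, x$omega_A0))
  cat(sprintf("  omega_D %g /s, omega_DC %g /s\n", x$omega_D, x$omega_DC))
  cat(sprintf("  lanes %d, interaction range %d motor sizes\n",
              x$n_lanes, x$interaction_range))
  invisible(x)
}

#' Convert bulk concentrations between nM and motors per cubic micrometre
#'
#' 1 nM corresponds to 0.6022 molecules/um^3 (Avogadro's number times
#' 1e-9 mol/L times 1e-15 L/um^3).
#'
#' @param x Concentration value(s).
#' @return Converted concentration value(s).
#' @export
nM_to_per_um3 <- function(x) x * 0.6022

#' @rdname nM_to_per_um3
#' @export
per_um3_to_nM <- function(x) x / 0.6022

#' Closed-form low-density limits of the motor-traffic model
#'
#' At vanishing occupancy motors never block each other, so the velocity is
#' \code{v0 = motor_step * step_rate}, the mean run length is
#' \code{v0 / omega_D} (exponential detachment), and a single protofilament
#' can hold at most \code{floor(1000 / motor_size_nm)} motors per
#' micrometre.
#'
#' @param params A \code{\link{kinetic_params}} object.
#' @return List with \code{v0_um_s}, \code{run_length_um} (with attribute-free
#'   \code{Inf} and \code{run_length_infinite = TRUE} when
#'   \code{omega_D = 0}), and \code{capacity_per_um_lane}.
#' @examples
#' analytic_low_density(kinetic_params())  # 0.3 um/s, 1.2 um, 62 motors/um
#' @export
analytic_low_density <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  v0 <- params$motor_step_nm * params$step_rate / 1000
  if (params$omega_D > 0) {
    rl <- v0 / params$omega_D
    inf <- FALSE
  } else {
    rl <- if (v0 > 0) Inf else 0
    inf <- v0 > 0
  }
  list(v0_um_s = v0, run_length_um = rl, run_length_infinite = inf,
       capacity_per_um_lane = floor(1000 / params$motor_size_nm))
}

#' Mean-field velocity under uncorrelated site occupancy
#'
#' If site occupancy were uncorrelated, a motor's forward site would be
#' blocked with probability equal to the site occupancy, giving
#' \code{v = v0 * (1 - rho_site)} -- e.g. a 50% velocity drop at half
#' occupancy. The simulated exclusion process deviates from this because
#' elevated detachment of blocked motors decorrelates the occupancy.
#'
#' @param params A \code{\link{kinetic_params}} object.
#' @param rho_site Site occupancy fraction in \code{[0, 1]}.
#' @return Velocity in um/s.
#' @export
mean_field_velocity <- function(params, rho_site) {
  stopifnot(inherits(params, "kinetic_params"),
            all(rho_site >= 0), all(rho_site <= 1))
  analytic_low_density(params)$v0_um_s * (1 - rho_site)
}
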