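#' Subtract the per-frame background from a kymograph
#'
#' Subtracts, for every frame, the mean intensity of the off-axis
#' background bands from all positions of that frame. Negative residuals
#' are kept (not clipped) so that fluctuation statistics stay unbiased.
#'
#' @param kymo A \code{kymograph} with background-band statistics.
#' @return The background-subtracted \code{kymograph}.
#' @export
background_subtract <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"))
  if (is.null(kymo$bg_mean) || !length(kymo$bg_mean))
    stop("kymograph carries no background-band statistics; re-extract it ",
         "with a background band", call. = FALSE)
  if (kymo$background_subtracted) return(kymo)
  kymo$intensity <- sweep(kymo$intensity, 2, kymo$bg_mean)
  kymo$background_subtracted <- TRUE
  kymo
}

#' Motor density from temporal intensity fluctuations (FCS)
#'
#' The spatially summed, background-subtracted intensity \eqn{F(t)} of a
#' track segment fluctuates because the number of labeled motors \eqn{N}
#' fluctuates (Poisson statistics), so the normalized autocorrelation
#' \eqn{G(\tau) = \langle\delta F(t)\,\delta F(t+\tau)\rangle / \langle
#' F\rangle^2} has amplitude \eqn{G(0^+) = 1/\langle N\rangle}. The
#' amplitude is taken from a linear extrapolation of \eqn{G} at lags 1-3
#' frames to lag zero, which excludes the shot-noise spike at lag 0.
#' The labeled density is scaled to total density by the ratio of total to
#' labeled motor concentration (spiking with unlabeled motors).
#'
#' @param kymo A background-subtracted \code{kymograph}.
#' @param labeled_conc_nM,total_conc_nM Labeled and total motor
#'   concentrations; \code{total >= labeled > 0}.
#' @param extrapolation_lags Frame lags used for the amplitude
#'   extrapolation.
#' @return List with labeled motor number \code{N}, \code{labeled_per_um},
#'   \code{density_per_um} (total), standard errors, \code{G0} and the
#'   segment length.
#' @export
fcs_density <- function(kymo, labeled_conc_nM, total_conc_nM,
                        extrapolation_lags = 1:3) {
  stopifnot(inherits(kymo, "kymograph"))
  if (!(total_conc_nM >= labeled_conc_nM && labeled_conc_nM > 0))
    stop("need total_conc_nM >= labeled_conc_nM > 0", call. = FALSE)
  if (!kymo$background_subtracted)
    kymo <- background_subtract(kymo)
  Fte <- colSums(kymo$intensity)
  Fbar <- mean(Fte)
  if (abs(Fbar) < 1e-9 * stats::sd(Fte) || Fbar <= 0)
    stop("mean segment intensity is ~0; no signal to correlate",
         call. = FALSE)
  dF <- Fte - Fbar
  Tn <- length(Fte)
  lags <- extrapolation_lags
  if (max(lags) >= Tn - 1) stop("record too short for FCS lags", call. = FALSE)
  G <- vapply(lags, function(l)
    mean(dF[1:(Tn - l)] * dF[(1 + l):Tn]) / Fbar^2, numeric(1))
  fit <- stats::lm(G ~ lags)
  G0 <- unname(stats::coef(fit)[1])
  G0_se <- summary(fit)$coefficients[1, 2]
  if (G0 <= 0)
    stop("extrapolated G(0+) <= 0: no number-fluctuation signal ",
         "(is the intensity constant?)", call. = FALSE)
  N <- 1 / G0
  N_se <- G0_se / G0^2
  seg <- max(kymo$x_um) - min(kymo$x_um) + kymo$pixel_um
  scale <- total_conc_nM / labeled_conc_nM
  list(N = N, N_se = N_se,
       labeled_per_um = N / seg, density_per_um = N / seg * scale,
       density_se = N_se / seg * scale,
       G0 = G0, G0_se = G0_se, segment_um = seg, scale = scale)
}

#' Spatiotemporal correlation of a kymograph
#'
#' Computes \eqn{C(\xi,\tau)}, the mean over valid position/time pairs of
#' \eqn{\delta I(x,t)\,\delta I(x+\xi,t+\tau)} with per-position temporal
#' means removed, no wraparound, and each lag pair normalized by its
#' overlap count. For every time lag a Gaussian plus constant offset is
#' fitted around the correlation maximum, giving the peak position
#' \eqn{x_p(\tau)} (which drifts at the ensemble velocity) and the Gaussian
#' area \eqn{A(\tau)} (which decays with the effective detachment rate).
#'
#' @param kymo A background-subtracted \code{kymograph} with >= 100 frames.
#' @param max_lag_s Largest time lag (s); at most 20% of the record.
#' @param max_xi_px Largest spatial lag in pixels (default covers the
#'   expected peak drift plus the fit window).
#' @param window_px Half-width of the Gaussian fit window around the peak.
#' @param r2_min Per-lag fits with R^2 below this are flagged and excluded
#'   downstream.
#' @return A \code{correlation_surface}: \code{C} matrix (spatial lag x
#'   time lag), \code{xi_um}, \code{tau_s}, and per-lag fit table
#'   \code{fits} (peak position/area with SEs, R^2, accepted flag).
#' @export
spatiotemporal_correlation <- function(kymo, max_lag_s = 10,
                                       max_xi_px = 80, window_px = 10,
                                       r2_min = 0.8) {
  stopifnot(inherits(kymo, "kymograph"))
  if (!kymo$background_subtracted)
    kymo <- background_subtract(kymo)
  I <- kymo$intensity
  L <- nrow(I); Tn <- ncol(I)
  if (Tn < 100) stop("need >= 100 frames for the correlation analysis",
                     call. = FALSE)
  max_lag <- as.integer(round(max_lag_s / kymo$dt_s))
  if (max_lag > 0.2 * Tn)
    stop("max_lag_s exceeds 20% of the record length", call. = FALSE)
  max_lag <- max(1L, max_lag)
  xi_max <- min(L - 1L, as.integer(max_xi_px))

  dI <- I - rowMeans(I)
  # full 2-D correlation via zero-padded FFT, then overlap-count normalized
  nx <- stats::nextn(L + xi_max, 2)
  nt <- stats::nextn(Tn + max_lag, 2)
  P <- matrix(0, nx, nt)
  P[seq_len(L), seq_len(Tn)] <- dI
  FP <- stats::fft(P)
  CC <- Re(stats::fft(Conj(FP) * FP, inverse = TRUE)) / length(P)
  xi <- (-xi_max):xi_max
  taus <- 0:max_lag
  Cm <- matrix(0, length(xi), length(taus))
  for (j in seq_along(taus)) {
    tt <- taus[j]
    col <- tt + 1L
    pos <- CC[c(nx - rev(seq_len(xi_max)) + 1L, 1L, seq_len(xi_max) + 1L), col]
    # row order above: xi = -max..-1 come from the wrapped tail
    Cm[, j] <- pos / ((L - abs(xi)) * (Tn - tt))
  }
  dimnames(Cm) <- NULL

  # per-lag Gaussian + offset fits (skip tau = 0 for the motility fits)
  pix <- kymo$pixel_um
  xi_um <- xi * pix
  fit_one <- function(j) {
    y <- Cm[, j]
    ctr <- which.max(y)
    fit_window <- function(ctr) {
      idx <- max(1, ctr - window_px):min(length(y), ctr + window_px)
      xs <- xi_um[idx]; ys <- y[idx]
      st <- list(a = max(ys) - min(ys), mu = xi_um[ctr],
                 sg = 2 * pix, c0 = min(ys))
      fit <- tryCatch(
        minpack.lm::nlsLM(ys ~ c0 + a * exp(-(xs - mu)^2 / (2 * sg^2)),
                          start = st,
                          lower = c(a = 0, mu = min(xs), sg = pix / 4,
                                    c0 = -Inf),
                          upper = c(a = Inf, mu = max(xs), sg = Inf,
                                    c0 = Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      list(fit = fit, idx = idx)
    }
    f1 <- fit_window(ctr)
    if (!is.null(f1$fit)) {  # refit once, re-centered on the fitted peak
      mu1 <- stats::coef(f1$fit)[["mu"]]
      ctr2 <- which.min(abs(xi_um - mu1))
      if (ctr2 != ctr) {
        f2 <- fit_window(ctr2)
        if (!is.null(f2$fit)) f1 <- f2
      }
    }
    if (is.null(f1$fit))
      return(data.frame(tau_s = taus[j] * kymo$dt_s, x_peak_um = NA,
                        x_peak_se = NA, area = NA, area_se = NA,
                        sigma_um = NA, r2 = NA, ok = FALSE))
    fit <- f1$fit
    co <- stats::coef(fit)
    vc <- tryCatch(stats::vcov(fit), error = function(e)
      matrix(NA, 4, 4, dimnames = list(names(co), names(co))))
    ys <- Cm[f1$idx, j]
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((ys - mean(ys))^2)
    a <- co[["a"]]; sg <- co[["sg"]]
    area <- a * sg * sqrt(2 * pi)
    # delta method for the area from the (a, sg) covariance block
    g <- c(sg, a) * sqrt(2 * pi)
    vsub <- vc[c("a", "sg"), c("a", "sg")]
    area_se <- sqrt(max(0, as.numeric(t(g) %*% vsub %*% g)))
    data.frame(tau_s = taus[j] * kymo$dt_s, x_peak_um = co[["mu"]],
               x_peak_se = sqrt(vc["mu", "mu"]), area = area,
               area_se = area_se, sigma_um = sg, r2 = r2,
               ok = is.finite(r2) && r2 >= r2_min)
  }
  fits <- do.call(rbind, lapply(seq_along(taus), fit_one))
  structure(list(C = Cm, xi_um = xi_um, tau_s = taus * kymo$dt_s,
                 fits = fits, dt_s = kymo$dt_s, pixel_um = pix,
                 r2_min = r2_min),
            class = "correlation_surface")
}

#' @export
print.correlation_surface <- function(x, ...) {
  cat(sprintf("correlation_surface: %d spatial x %d time lags; %d/%d lag %s\n",
              nrow(x$C), ncol(x$C), sum(x$fits$ok, na.rm = TRUE),
              nrow(x$fits), "fits accepted"))
  invisible(x)
}

#' Velocity, detachment rate and run length from a correlation surface
#'
#' The velocity is the slope of a weighted least-squares line through the
#' Gaussian peak positions \eqn{x_p(\tau)} (weights from the per-lag fit
#' covariance). The detachment rate is the decay constant of an
#' exponential fitted to the peak areas \eqn{A(\tau)} (nonlinear least
#' squares; a semi-log linear fit is reported alongside). The run length
#' is velocity over detachment rate, with both uncertainties propagated.
#'
#' At late lags the correlation peak sinks into the correlated noise floor
#' of a finite record and the fitted areas flatten; the exponential fit is
#' therefore restricted, self-consistently, to lags within
#' \code{decay_window} decay times of the current rate estimate (iterated
#' twice, never below \code{min_lags} lags).
#'
#' @param surface A \code{correlation_surface}.
#' @param min_lags Minimum number of accepted per-lag fits required.
#' @param decay_window Largest lag used in the area fit, in units of the
#'   fitted decay time (default 1.5, past which the areas of a finite
#'   record flatten into the noise floor).
#' @return A \code{motility_estimates} list: velocity, detachment rate and
#'   run length with SEs, fit diagnostics, and an \code{undetermined} flag
#'   when the areas do not decay.
#' @export
extract_velocity_runlength <- function(surface, min_lags = 5,
                                       decay_window = 1.5) {
  stopifnot(inherits(surface, "correlation_surface"))
  f <- surface$fits
  f <- f[f$tau_s > 0 & f$ok & is.finite(f$x_peak_se) & f$x_peak_se > 0, ]
  if (nrow(f) < min_lags)
    stop("only ", nrow(f), " accepted lag fits; need >= ", min_lags,
         call. = FALSE)
  wv <- 1 / f$x_peak_se^2
  vfit <- stats::lm(x_peak_um ~ tau_s, data = f, weights = wv)
  v <- unname(stats::coef(vfit)["tau_s"])
  v_se <- summary(vfit)$coefficients["tau_s", 2]
  v_r2 <- summary(vfit)$r.squared

  fa <- f[is.finite(f$area) & f$area > 0, ]
  # semi-log linear fit (reference) and nonlinear fit on A itself
  slfit <- stats::lm(log(area) ~ tau_s, data = fa)
  k0 <- -unname(stats::coef(slfit)["tau_s"])
  undetermined <- FALSE
  k <- k_se <- NA_real_
  if (!is.finite(k0) || k0 <= 0) {
    undetermined <- TRUE
  } else {
    fit_exp <- function(d, k_start) {
      wa <- ifelse(is.finite(d$area_se) & d$area_se > 0,
                   1 / d$area_se^2, 0)
      if (!any(wa > 0)) wa <- rep(1, nrow(d))
      tryCatch(
        minpack.lm::nlsLM(area ~ A0 * exp(-k * tau_s), data = d,
                          start = list(A0 = max(d$area), k = k_start),
                          weights = wa, lower = c(A0 = 0, k = 0)),
        error = function(e) NULL)
    }
    k_cur <- k0
    efit <- NULL
    for (it in 1:3) {   # iterate the lag window to self-consistency
      use <- fa[fa$tau_s <= decay_window / k_cur, ]
      if (nrow(use) < min_lags)
        use <- fa[seq_len(min(nrow(fa), min_lags)), ]
      efit <- fit_exp(use, k_cur)
      if (is.null(efit)) break
      k_new <- stats::coef(efit)[["k"]]
      if (k_new <= 0 || abs(k_new - k_cur) < 0.01 * k_cur) {
        k_cur <- k_new
        break
      }
      k_cur <- k_new
    }
    if (is.null(efit)) {
      undetermined <- TRUE
    } else {
      k <- stats::coef(efit)[["k"]]
      k_se <- sqrt(stats::vcov(efit)["k", "k"])
      if (k <= 0) undetermined <- TRUE
    }
  }
  if (undetermined) {
    rl <- Inf; rl_se <- NA_real_
  } else {
    rl <- v / k
    rl_se <- abs(rl) * sqrt((v_se / v)^2 + (k_se / k)^2)
  }
  structure(list(velocity_um_s = v, velocity_se = v_se,
                 detachment_rate = k, detachment_rate_se = k_se,
                 run_length_um = rl, run_length_se = rl_se,
                 undetermined = undetermined,
                 velocity_r2 = v_r2,
                 semilog_rate = k0,
                 n_lags = nrow(f)),
            class = "motility_estimates")
}

#' @export
print.motility_estimates <- function(x, ...) {
  cat("Correlation-imaging motility estimates\n")
  if (!is.null(x$density_per_um))
    cat(sprintf("  density     %.3g +/- %.2g motors/um\n",
                x$density_per_um, x$density_se))
  cat(sprintf("  velocity    %.3g +/- %.2g um/s (R2 %.3f)\n",
              x$velocity_um_s, x$velocity_se, x$velocity_r2))
  if (isTRUE(x$undetermined)) {
    cat("  run length  undetermined (areas do not decay)\n")
  } else {
    cat(sprintf("  detachment  %.3g +/- %.2g /s\n",
                x$detachment_rate, x$detachment_rate_se))
    cat(sprintf("  run length  %.3g +/- %.2g um\n",
                x$run_length_um, x$run_length_se))
  }
  invisible(x)
}

#' One-call correlation-imaging analysis of a kymograph
#'
#' Background-subtracts, runs the FCS density estimate and the
#' spatiotemporal correlation, and extracts velocity and run length.
#'
#' @param kymo A \code{kymograph}.
#' @param labeled_conc_nM,total_conc_nM Concentrations for the density
#'   scaling (omit both to skip the density estimate).
#' @param ... Passed to \code{\link{spatiotemporal_correlation}}.
#' @return A \code{motility_estimates} with density fields added and the
#'   \code{correlation_surface} attached as \code{surface}.
#' @export
correlation_motility <- function(kymo, labeled_conc_nM = NULL,
                                 total_conc_nM = NULL, ...) {
  kymo <- background_subtract(kymo)
  surf <- spatiotemporal_correlation(kymo, ...)
  est <- extract_velocity_runlength(surf)
  if (!is.null(labeled_conc_nM) && !is.null(total_conc_nM)) {
    d <- fcs_density(kymo, labeled_conc_nM, total_conc_nM)
    est$density_per_um <- d$density_per_um
    est$density_se <- d$density_se
    est$N_labeled <- d$N
  }
  est$surface <- surf
  est
}
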