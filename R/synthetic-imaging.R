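#' Optical and camera settings for synthetic TIRF image stacks
#'
#' Defaults emulate the acquisition conditions of the motility assays this
#' package models: 80 nm effective pixels, 200 ms exposure, 1000 frames,
#' a diffraction-limited Gaussian point-spread function for GFP emission,
#' Poisson shot noise and 16-bit digitization.
#'
#' @param pixel_size_nm Effective pixel size in the sample plane (nm).
#' @param psf_sigma_nm Gaussian PSF standard deviation (nm).
#' @param exposure_s Exposure time per frame (s); frames are contiguous.
#' @param n_frames Number of frames.
#' @param photons_per_motor Mean detected photons per labeled motor per
#'   frame (before thinning by sub-exposure residence).
#' @param background_photons Mean background photons per pixel per frame.
#' @param bleach_rate Photobleaching rate of the label (1/s); 0 disables.
#' @param labeled_fraction Fraction of motors carrying a visible label;
#'   applied by independent thinning.
#' @param camera_offset,camera_gain Digitization: DN = offset + gain *
#'   photon count, clipped to the 16-bit range (with a warning).
#' @param shot_noise Draw per-pixel Poisson photon counts; \code{FALSE}
#'   renders the noiseless expectation (useful for exact checks).
#' @param n_subframes Sub-exposure positions averaged per frame to model
#'   motion blur.
#' @param fov_height_px Field-of-view height in pixels; the microtubule is
#'   rendered along the central row.
#' @param seed Integer RNG seed for thinning, bleaching and shot noise.
#' @return An object of class \code{optics_config}.
#' @export
optics_config <- function(pixel_size_nm = 80, psf_sigma_nm = 130,
                          exposure_s = 0.2, n_frames = 1000,
                          photons_per_motor = 2000,
                          background_photons = 20, bleach_rate = 0,
                          labeled_fraction = 1, camera_offset = 100,
                          camera_gain = 1, shot_noise = TRUE,
                          n_subframes = 10L, fov_height_px = 15L,
                          seed = 1L) {
  stopifnot(pixel_size_nm > 0, psf_sigma_nm > 0, exposure_s > 0,
            n_frames >= 1, photons_per_motor >= 0, background_photons >= 0,
            bleach_rate >= 0, labeled_fraction >= 0, labeled_fraction <= 1,
            camera_gain > 0, n_subframes >= 1, fov_height_px >= 1)
  structure(list(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                 exposure_s = exposure_s, n_frames = as.integer(n_frames),
                 photons_per_motor = photons_per_motor,
                 background_photons = background_photons,
                 bleach_rate = bleach_rate,
                 labeled_fraction = labeled_fraction,
                 camera_offset = camera_offset, camera_gain = camera_gain,
                 shot_noise = shot_noise,
                 n_subframes = as.integer(n_subframes),
                 fov_height_px = as.integer(fov_height_px),
                 seed = as.integer(seed)),
            class = "optics_config")
}

#' Effective pixel size from camera pixel and magnification
#'
#' @param camera_pixel_um Physical camera pixel size (um).
#' @param magnification Total optical magnification.
#' @return Effective pixel size in the sample plane, in nm.
#' @examples
#' effective_pixel_size_nm(16, 200)  # 80 nm
#' @export
effective_pixel_size_nm <- function(camera_pixel_um, magnification) {
  stopifnot(camera_pixel_um > 0, magnification > 0)
  camera_pixel_um / magnification * 1000
}

#' Exclusion-free parametric motor trajectories
#'
#' Generates motors as a Poisson process in space-time on a track of given
#' length: binding positions uniform, binding times uniform, lifetimes
#' exponential with rate \code{omega_D}, motion at exactly \code{v_um_s}
#' towards the plus end. Runs truncated by the track end or the end of the
#' observation window are marked censored. No exclusion is applied, so the
#' analysis modules can be tested independently of the lattice simulator.
#'
#' @param v_um_s Motor velocity (um/s).
#' @param omega_D Detachment rate (1/s); 0 gives runs that persist to the
#'   end of the window (all censored).
#' @param binding_rate_per_um Binding events per second per micrometre.
#' @param length_um Track length (um).
#' @param duration_s Observation window (s).
#' @param seed Integer RNG seed.
#' @return A \code{trajectory_set} with a \code{paths} table.
#' @export
parametric_trajectories <- function(v_um_s, omega_D, binding_rate_per_um,
                                    length_um, duration_s, seed = 1L) {
  stopifnot(v_um_s >= 0, omega_D >= 0, binding_rate_per_um >= 0,
            length_um > 0, duration_s > 0)
  set.seed(seed)
  n <- stats::rpois(1, binding_rate_per_um * length_um * duration_s)
  if (n == 0) {
    paths <- data.frame(id = integer(0), t0_s = numeric(0),
                        t1_s = numeric(0), x0_um = numeric(0),
                        x1_um = numeric(0), censored = logical(0))
  } else {
    t0 <- stats::runif(n, 0, duration_s)
    x0 <- stats::runif(n, 0, length_um)
    life <- if (omega_D > 0) stats::rexp(n, omega_D) else rep(Inf, n)
    t_exit <- if (v_um_s > 0) (length_um - x0) / v_um_s else Inf
    t1 <- t0 + pmin(life, t_exit, duration_s - t0)
    censored <- (life > pmin(t_exit, duration_s - t0))
    paths <- data.frame(id = seq_len(n), t0_s = t0, t1_s = t1,
                        x0_um = x0, x1_um = x0 + v_um_s * (t1 - t0),
                        censored = censored)
    paths <- paths[order(paths$t0_s), ]
    paths$id <- seq_len(n)
    rownames(paths) <- NULL
  }
  structure(list(paths = paths, runs = NULL, stats = NULL,
                 params = list(v_um_s = v_um_s, omega_D = omega_D,
                               binding_rate_per_um = binding_rate_per_um),
                 config = list(lattice_length_um = length_um,
                               duration_s = duration_s, boundary = "open",
                               langmuir = TRUE),
                 site_um = NA_real_, burn_in_s = 0, seed = as.integer(seed),
                 source = "parametric"),
            class = "trajectory_set")
}

#' Mean number of motors present in a space-time window
#'
#' Ground-truth time-averaged motor count from the continuous paths of a
#' trajectory set; the oracle for FCS particle-number estimates.
#'
#' @param ts A \code{trajectory_set}.
#' @param t_min,t_max Time window (s); defaults to the full record.
#' @return Mean motor count.
#' @export
mean_motor_count <- function(ts, t_min = 0, t_max = NULL) {
  paths <- motor_paths(ts)
  if (is.null(t_max)) t_max <- ts$config$duration_s
  ov <- pmax(0, pmin(paths$t1_s, t_max) - pmax(paths$t0_s, t_min))
  sum(ov) / (t_max - t_min)
}

#' Render motor trajectories into a synthetic TIRF image stack
#'
#' Each labeled, unbleached motor contributes an isotropic Gaussian spot
#' integrated over the pixel grid; motion blur is modelled by averaging
#' \code{n_subframes} sub-exposure positions. Per-pixel photon counts are
#' Poisson (signal plus uniform background), then digitized with the camera
#' offset and gain into the 16-bit range.
#'
#' @param ts A \code{trajectory_set} (lattice or parametric).
#' @param optics An \code{\link{optics_config}}.
#' @param length_um Track length imaged; defaults to the trajectory set's
#'   lattice length. Trajectory coordinates must fit inside it.
#' @return An \code{image_stack}: \code{frames} array (y, x, frame) of
#'   integer-valued DN, \code{optics}, \code{mt_axis} (pixel endpoints of
#'   the track, plus-end towards increasing x), \code{pixel_um}, and
#'   \code{ground_truth} (the trajectory set).
#' @export
render_stack <- function(ts, optics, length_um = NULL) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(optics, "optics_config"))
  if (is.null(length_um)) length_um <- ts$config$lattice_length_um
  pix <- optics$pixel_size_nm / 1000
  sigma <- optics$psf_sigma_nm / 1000
  W <- as.integer(ceiling(length_um / pix))
  H <- optics$fov_height_px
  Tn <- optics$n_frames
  E <- optics$exposure_s
  paths <- motor_paths(ts)
  if (nrow(paths) &&
      (min(paths$x0_um) < -1e-9 || max(paths$x1_um) > W * pix + 1e-9))
    stop("trajectory coordinates fall outside the field of view (0..",
         round(W * pix, 3), " um)", call. = FALSE)

  set.seed(optics$seed)
  # label thinning and bleaching per motor
  if (nrow(paths)) {
    labeled <- stats::runif(nrow(paths)) < optics$labeled_fraction
    t_bleach <- if (optics$bleach_rate > 0)
      paths$t0_s + stats::rexp(nrow(paths), optics$bleach_rate)
    else rep(Inf, nrow(paths))
  } else {
    labeled <- logical(0); t_bleach <- numeric(0)
  }
  vis <- which(labeled)
  y_mt <- (H + 1) / 2              # central row (pixel-center coordinates)
  y_um <- (y_mt - 0.5) * pix
  yedges <- (0:H) * pix
  yprof <- diff(stats::pnorm(yedges, mean = y_um, sd = sigma))
  halfw <- max(1L, ceiling(4 * sigma / pix))
  S <- optics$n_subframes
  flux <- optics$photons_per_motor / S

  frames <- array(0, dim = c(H, W, Tn))
  if (length(vis)) {
    p <- paths[vis, , drop = FALSE]
    tb <- t_bleach[vis]
    vmot <- ifelse(p$t1_s > p$t0_s,
                   (p$x1_um - p$x0_um) / (p$t1_s - p$t0_s), 0)
    f0 <- pmax(1L, as.integer(floor(p$t0_s / E)) + 1L)
    f1 <- pmin(Tn, as.integer(ceiling(pmin(p$t1_s, tb) / E)))
    for (f in seq_len(Tn)) {
      act <- which(f0 <= f & f1 >= f)
      if (!length(act)) next
      tsub <- (f - 1) * E + ((seq_len(S)) - 0.5) * E / S
      for (m in act) {
        ok <- tsub >= p$t0_s[m] & tsub <= min(p$t1_s[m], tb[m])
        if (!any(ok)) next
        xs <- p$x0_um[m] + vmot[m] * (tsub[ok] - p$t0_s[m])
        i0 <- max(1L, floor(min(xs) / pix) - halfw + 1L)
        i1 <- min(W, ceiling(max(xs) / pix) + halfw)
        edges <- (seq.int(i0 - 1L, i1)) * pix
        # integrated Gaussian over pixels, summed over sub-positions
        cdf <- stats::pnorm(outer(edges, xs, "-") / sigma)
        xprof <- rowSums(cdf[-1, , drop = FALSE] -
                         cdf[-nrow(cdf), , drop = FALSE])
        frames[, i0:i1, f] <- frames[, i0:i1, f] +
          flux * outer(yprof, xprof)
      }
    }
  }
  frames <- frames + optics$background_photons
  if (optics$shot_noise)
    frames <- array(stats::rpois(length(frames), frames), dim = dim(frames))
  frames <- optics$camera_offset + optics$camera_gain * frames
  if (any(frames > 65535)) {
    warning("rendered intensities exceed the 16-bit range; clipping",
            call. = FALSE)
    frames[frames > 65535] <- 65535
  }
  frames <- round(frames)
  structure(list(frames = frames, optics = optics,
                 mt_axis = list(x0_px = 0.5, y0_px = y_mt,
                                x1_px = W - 0.5, y1_px = y_mt),
                 pixel_um = pix, n_frames = Tn,
                 ground_truth = ts),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px (%.0f nm pixels, %g s)\n",
              d[3], d[1], d[2], x$pixel_um * 1000, x$optics$exposure_s))
  invisible(x)
}

#' Extract a kymograph (position along the track vs time) from a stack
#'
#' Samples the intensity along the microtubule axis at pixel-center spacing
#' by bilinear interpolation, averaged over \code{width_pixels} positions
#' perpendicular to the axis. Background statistics are taken from two
#' parallel bands offset perpendicular to the axis.
#'
#' @param stack An \code{image_stack} (or any list with \code{frames},
#'   \code{mt_axis}, \code{pixel_um}, and optics exposure).
#' @param width_pixels Averaging width across the axis (pixels, >= 1).
#' @param background_offset_px Perpendicular distance of the background
#'   bands from the axis (pixels).
#' @return A \code{kymograph}: \code{intensity} matrix (position x frame),
#'   \code{x_um}, \code{dt_s}, per-frame background mean/sd, and bookkeeping
#'   flags.
#' @export
make_kymograph <- function(stack, width_pixels = 3,
                           background_offset_px = 5) {
  stopifnot(inherits(stack, "image_stack"), width_pixels >= 1)
  ax <- stack$mt_axis
  d <- dim(stack$frames)
  H <- d[1]; W <- d[2]; Tn <- d[3]
  dx <- ax$x1_px - ax$x0_px; dy <- ax$y1_px - ax$y0_px
  len <- sqrt(dx^2 + dy^2)
  if (len <= 0) stop("degenerate microtubule axis", call. = FALSE)
  ux <- dx / len; uy <- dy / len          # along-axis unit vector
  px <- -uy; py <- ux                     # perpendicular unit vector
  ns <- floor(len) + 1L
  s <- seq(0, by = 1, length.out = ns)
  offs <- seq_len(width_pixels) - (width_pixels + 1) / 2

  sample_band <- function(perp_shift) {
    xs <- outer(ax$x0_px + s * ux, offs * px + perp_shift * px, "+")
    ys <- outer(ax$y0_px + s * uy, offs * py + perp_shift * py, "+")
    if (min(xs) < 0.5 - 1e-9 || max(xs) > W - 0.5 + 1e-9 ||
        min(ys) < 0.5 - 1e-9 || max(ys) > H - 0.5 + 1e-9)
      stop("sampling band falls outside the image; check the axis ",
           "annotation and background offset", call. = FALSE)
    # bilinear interpolation on pixel centers
    xc <- pmin(pmax(xs - 0.5, 0), W - 1); yc <- pmin(pmax(ys - 0.5, 0), H - 1)
    jx0 <- pmin(floor(xc), W - 2); jy0 <- pmin(floor(yc), H - 2)
    fx <- xc - jx0; fy <- yc - jy0
    w00 <- (1 - fx) * (1 - fy); w01 <- fx * (1 - fy)
    w10 <- (1 - fx) * fy;       w11 <- fx * fy
    i00 <- jx0 * H + jy0 + 1    # column-major linear index of (jy0+1, jx0+1)
    out <- matrix(0, ns, Tn)
    for (f in seq_len(Tn)) {
      fr <- stack$frames[, , f]
      v <- w00 * fr[i00] + w01 * fr[i00 + H] +
           w10 * fr[i00 + 1] + w11 * fr[i00 + H + 1]
      out[, f] <- rowMeans(matrix(v, ns, length(offs)))
    }
    out
  }
  kym <- sample_band(0)
  bg1 <- sample_band(background_offset_px)
  bg2 <- sample_band(-background_offset_px)
  bg <- (bg1 + bg2) / 2
  structure(list(intensity = kym,
                 x_um = (s + 0.5) * stack$pixel_um,
                 dt_s = stack$optics$exposure_s,
                 pixel_um = stack$pixel_um,
                 bg_mean = colMeans(bg),
                 bg_sd = apply(bg, 2, stats::sd),
                 n_bg_samples = nrow(bg) * 2,
                 background_subtracted = FALSE),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d positions x %d frames (dx %.0f nm, dt %g s)%s\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_um * 1000,
              x$dt_s,
              if (x$background_subtracted) ", background-subtracted" else ""))
  invisible(x)
}
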