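#' Detect fluorescent spots and link them into single-particle tracks
#'
#' Per frame, candidate spots are local maxima above the background by a
#' threshold, refined to sub-pixel positions by a 2-D Gaussian fit (falling
#' back to an intensity centroid when the fit fails). Detections in
#' consecutive frames are linked greedily by mutual nearest neighbours
#' within a displacement gate; gap closing and merge/split handling are
#' deliberately not attempted, which is adequate at single-molecule
#' densities. Tracks shorter than \code{min_track_frames} are discarded.
#'
#' @param stack An \code{image_stack}.
#' @param intensity_threshold Counts above the frame background required
#'   for a candidate maximum; default 5 robust standard deviations.
#' @param max_disp_per_frame_um Linking gate: largest allowed displacement
#'   between consecutive frames (um).
#' @param min_track_frames Minimum track length in frames.
#' @param fit_radius_px Half-size of the square patch used for the
#'   Gaussian refinement.
#' @return A \code{track_set}: data frame \code{tracks} with columns
#'   \code{track_id, frame, t_s, x_um, y_um, amplitude}, plus detection
#'   counts and settings.
#' @export
detect_and_link <- function(stack, intensity_threshold = NULL,
                            max_disp_per_frame_um = 0.25,
                            min_track_frames = 5L, fit_radius_px = 3L) {
  stopifnot(inherits(stack, "image_stack"), max_disp_per_frame_um > 0)
  d <- dim(stack$frames)
  H <- d[1]; W <- d[2]; Tn <- d[3]
  pix <- stack$pixel_um
  sigma_px <- stack$optics$psf_sigma_nm / stack$optics$pixel_size_nm
  r <- as.integer(fit_radius_px)

  if (any(stack$frames >= 65535))
    warning("saturated pixels present; positions near saturation may be ",
            "biased", call. = FALSE)

  detections <- vector("list", Tn)
  for (f in seq_len(Tn)) {
    fr <- stack$frames[, , f]
    bg <- stats::median(fr)
    noise <- stats::mad(fr)
    thr <- if (is.null(intensity_threshold)) 5 * noise
           else intensity_threshold
    cand <- which(fr > bg + thr, arr.ind = TRUE)
    if (!nrow(cand)) next
    # keep 3x3 local maxima away from the border
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      y <- cand[i, 1]; x <- cand[i, 2]
      if (y <= r || y > H - r || x <= r || x > W - r) next
      nb <- fr[(y - 1):(y + 1), (x - 1):(x + 1)]
      # ties allowed: integer counts tie often; nearby duplicates are
      # removed by the proximity suppression below
      keep[i] <- fr[y, x] == max(nb)
    }
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) next
    # suppress maxima closer than 3 px (keep the brighter one)
    if (nrow(cand) > 1) {
      o <- order(fr[cand], decreasing = TRUE)
      cand <- cand[o, , drop = FALSE]
      taken <- rep(TRUE, nrow(cand))
      for (i in 2:nrow(cand)) {
        di <- sqrt((cand[i, 1] - cand[seq_len(i - 1), 1])^2 +
                   (cand[i, 2] - cand[seq_len(i - 1), 2])^2)
        if (any(di[taken[seq_len(i - 1)]] < 3)) taken[i] <- FALSE
      }
      cand <- cand[taken, , drop = FALSE]
    }
    res <- lapply(seq_len(nrow(cand)), function(i) {
      y <- cand[i, 1]; x <- cand[i, 2]
      patch <- fr[(y - r):(y + r), (x - r):(x + r)]
      pg <- expand.grid(dy = -r:r, dx = -r:r)
      pg$z <- as.vector(patch)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          z ~ b + a * exp(-((dx - x0)^2 + (dy - y0)^2) / (2 * s^2)),
          data = pg,
          start = list(b = bg, a = fr[y, x] - bg, x0 = 0, y0 = 0,
                       s = sigma_px),
          lower = c(b = -Inf, a = 0, x0 = -r, y0 = -r, s = 0.5),
          upper = c(b = Inf, a = Inf, x0 = r, y0 = r, s = 2 * r),
          control = minpack.lm::nls.lm.control(maxiter = 60)),
        error = function(e) NULL)
      if (is.null(fit)) {
        w <- pmax(patch - bg, 0)
        if (sum(w) == 0) return(NULL)
        x0 <- sum(pg$dx * w) / sum(w); y0 <- sum(pg$dy * w) / sum(w)
        amp <- fr[y, x] - bg; sg <- sigma_px
      } else {
        co <- stats::coef(fit)
        x0 <- co[["x0"]]; y0 <- co[["y0"]]; amp <- co[["a"]]; sg <- co[["s"]]
        if (amp <= 0) return(NULL)
      }
      data.frame(frame = f, x_um = (x + x0 - 0.5) * pix,
                 y_um = (y + y0 - 0.5) * pix, amplitude = amp,
                 sigma_px = sg)
    })
    dd <- do.call(rbind, res)
    if (!is.null(dd) && nrow(dd) > 1) {
      # candidate pixels can refine onto the same molecule: keep the
      # brightest of any detections closer than 2 px after the fit
      o <- order(dd$amplitude, decreasing = TRUE)
      dd <- dd[o, , drop = FALSE]
      keep2 <- rep(TRUE, nrow(dd))
      for (i in 2:nrow(dd)) {
        di <- sqrt((dd$x_um[i] - dd$x_um[seq_len(i - 1)])^2 +
                   (dd$y_um[i] - dd$y_um[seq_len(i - 1)])^2)
        if (any(di[keep2[seq_len(i - 1)]] < 2 * pix)) keep2[i] <- FALSE
      }
      dd <- dd[keep2, , drop = FALSE]
    }
    detections[[f]] <- dd
  }
  det <- do.call(rbind, detections)
  if (is.null(det) || !nrow(det)) {
    return(structure(list(tracks = data.frame(track_id = integer(0),
                                              frame = integer(0),
                                              t_s = numeric(0),
                                              x_um = numeric(0),
                                              y_um = numeric(0),
                                              amplitude = numeric(0)),
                          n_detections = 0L, n_tracks = 0L,
                          exposure_s = stack$optics$exposure_s),
                     class = "track_set"))
  }

  # greedy mutual-nearest-neighbour frame-to-frame linking
  det$track_id <- NA_integer_
  next_id <- 0L
  bylist <- split(seq_len(nrow(det)), det$frame)
  frames_present <- as.integer(names(bylist))
  prev_idx <- integer(0)
  for (f in seq_len(Tn)) {
    cur_idx <- if (as.character(f) %in% names(bylist))
      bylist[[as.character(f)]] else integer(0)
    if (length(cur_idx)) {
      if (length(prev_idx)) {
        dmat <- outer(det$x_um[prev_idx], det$x_um[cur_idx], "-")^2 +
                outer(det$y_um[prev_idx], det$y_um[cur_idx], "-")^2
        dmat <- sqrt(dmat)
        dmat[dmat > max_disp_per_frame_um] <- Inf
        for (i in seq_along(prev_idx)) {
          j <- which.min(dmat[i, ])
          if (!length(j) || !is.finite(dmat[i, j])) next
          if (which.min(dmat[, j]) == i) {   # mutual nearest neighbours
            det$track_id[cur_idx[j]] <- det$track_id[prev_idx[i]]
            dmat[i, ] <- Inf; dmat[, j] <- Inf
          }
        }
      }
      new <- cur_idx[is.na(det$track_id[cur_idx])]
      if (length(new)) {
        det$track_id[new] <- next_id + seq_along(new)
        next_id <- next_id + length(new)
      }
    }
    prev_idx <- cur_idx
  }
  len <- table(det$track_id)
  keep_ids <- as.integer(names(len)[len >= min_track_frames])
  tr <- det[det$track_id %in% keep_ids, ]
  tr <- tr[order(tr$track_id, tr$frame), ]
  tr$track_id <- match(tr$track_id, unique(tr$track_id))
  tr$t_s <- (tr$frame - 0.5) * stack$optics$exposure_s
  rownames(tr) <- NULL
  structure(list(tracks = tr[, c("track_id", "frame", "t_s", "x_um",
                                 "y_um", "amplitude")],
                 n_detections = nrow(det),
                 n_tracks = length(unique(tr$track_id)),
                 exposure_s = stack$optics$exposure_s),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks from %d detections\n",
              x$n_tracks, x$n_detections))
  invisible(x)
}

#' Ensemble velocity from mean displacements versus time lag
#'
#' For every time lag the mean along-axis displacement over all track
#' segments is computed; a weighted linear fit through the origin of mean
#' displacement against lag gives the velocity.
#'
#' @param tracks A \code{track_set} (or its \code{tracks} data frame plus
#'   an \code{exposure_s} attribute).
#' @param max_lag_frames Largest lag used in the fit.
#' @param min_tracks Minimum number of tracks required.
#' @return List with \code{velocity_um_s}, \code{se}, \code{r2} and the
#'   per-lag mean-displacement table.
#' @export
mean_displacement_velocity <- function(tracks, max_lag_frames = 10L,
                                       min_tracks = 20L) {
  stopifnot(inherits(tracks, "track_set"))
  tr <- tracks$tracks
  if (tracks$n_tracks < min_tracks)
    stop("only ", tracks$n_tracks, " tracks; need >= ", min_tracks,
         call. = FALSE)
  E <- tracks$exposure_s
  bytrack <- split(tr$x_um, tr$track_id)
  if (max(lengths(bytrack)) < 2)
    stop("all tracks are single-frame; no displacements to average",
         call. = FALSE)
  md <- lapply(seq_len(max_lag_frames), function(lag) {
    d <- unlist(lapply(bytrack, function(x) {
      n <- length(x)
      if (n > lag) x[(lag + 1):n] - x[1:(n - lag)] else numeric(0)
    }))
    if (length(d) < 2) return(NULL)
    data.frame(lag_s = lag * E, mean_disp_um = mean(d),
               se = stats::sd(d) / sqrt(length(d)), n = length(d))
  })
  md <- do.call(rbind, md)
  # zero-variance lags (noise-free fixtures) get the smallest positive SE
  se_floor <- min(md$se[md$se > 0], 1e-9)
  md$se <- pmax(md$se, se_floor)
  fit <- stats::lm(mean_disp_um ~ 0 + lag_s, data = md,
                   weights = 1 / md$se^2)
  list(velocity_um_s = unname(stats::coef(fit)["lag_s"]),
       se = summary(fit)$coefficients["lag_s", 2],
       r2 = summary(fit)$r.squared,
       mean_displacements = md)
}

#' Net along-axis run lengths of a track set
#'
#' @param tracks A \code{track_set}.
#' @param drop_last_frame Drop tracks still present in the final frame
#'   (their runs are censored by the end of the recording).
#' @return Numeric vector of net displacements (um).
#' @export
track_run_lengths <- function(tracks, drop_last_frame = FALSE) {
  stopifnot(inherits(tracks, "track_set"))
  tr <- tracks$tracks
  if (!nrow(tr)) return(numeric(0))
  last <- max(tr$frame)
  sapply(split(tr, tr$track_id), function(d) {
    if (drop_last_frame && max(d$frame) >= last) return(NA_real_)
    d$x_um[nrow(d)] - d$x_um[1]
  }) |> stats::na.omit() |> as.numeric()
}

#' Mean run length from the cumulative distribution of track lengths
#'
#' Fits the empirical cumulative distribution of net track lengths with
#' the shifted exponential \eqn{1 - \exp(-(x - x_0)/\lambda)} for
#' \eqn{x \ge x_0}, where \eqn{x_0} is the shortest observable run (set by
#' the minimum track length). By the memorylessness of the exponential the
#' fitted \eqn{\lambda} is the mean run length. The standard error comes
#' from refitting bootstrap resamples.
#'
#' @param lengths Numeric vector of run lengths (um), or a
#'   \code{track_set} whose net lengths are used.
#' @param min_observable_um Detection floor \eqn{x_0} (um).
#' @param n_boot Bootstrap resamples for the SE.
#' @param min_tracks Minimum number of usable lengths.
#' @return List with \code{run_length_um}, \code{se}, \code{n} and the
#'   fitted CDF function.
#' @export
runlength_cdf_fit <- function(lengths, min_observable_um = 0,
                              n_boot = 200L, min_tracks = 50L) {
  if (inherits(lengths, "track_set"))
    lengths <- track_run_lengths(lengths)
  x <- lengths[is.finite(lengths) & lengths >= min_observable_um]
  if (length(x) < min_tracks)
    stop("only ", length(x), " usable run lengths; need >= ", min_tracks,
         call. = FALSE)
  if (stats::sd(x) < 1e-12 * max(abs(x), 1))
    stop("run lengths are (near-)identical; an exponential distribution ",
         "cannot be fitted (sd ~ 0)", call. = FALSE)
  fit_lambda <- function(x) {
    xs <- sort(x)
    Fe <- (seq_along(xs) - 0.5) / length(xs)
    start <- max(mean(xs) - min_observable_um, 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(Fe ~ 1 - exp(-(xs - min_observable_um) / lambda),
                        start = list(lambda = start),
                        lower = c(lambda = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) start else stats::coef(fit)[["lambda"]]
  }
  lambda <- fit_lambda(x)
  boots <- replicate(n_boot, fit_lambda(sample(x, replace = TRUE)))
  list(run_length_um = lambda, se = stats::sd(boots), n = length(x),
       min_observable_um = min_observable_um,
       cdf = function(q) 1 - exp(-pmax(q - min_observable_um, 0) / lambda))
}
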