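#' Derive a reproducible child seed from a base seed
#'
#' Stages of a pipeline each receive their own deterministic seed derived
#' from the single global seed, so any stage can be re-run in isolation.
#'
#' @param seed Base integer seed.
#' @param k Stage / replicate index.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483647)
}

#' Write / read a multi-page 16-bit TIFF image stack
#'
#' Integer-valued stacks in the 16-bit range round-trip losslessly.
#'
#' @param stack An \code{image_stack}, or a plain (y, x, frame) array.
#' @param path Output / input file path.
#' @return \code{write_stack_tiff} returns the path invisibly;
#'   \code{read_stack_tiff} returns an \code{image_stack} (optics fields
#'   populated from a JSON sidecar when present).
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  stopifnot(length(dim(frames)) == 3)
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(f) frames[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (inherits(stack, "image_stack")) {
    meta <- list(pixel_size_nm = stack$optics$pixel_size_nm,
                 exposure_s = stack$optics$exposure_s,
                 psf_sigma_nm = stack$optics$psf_sigma_nm,
                 mt_axis = stack$mt_axis,
                 seed = stack$optics$seed)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits != 16L)
    warning("TIFF is ", bits, "-bit; converting to the 16-bit scale",
            call. = FALSE)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- round(pages[[f]] * 65535)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  px_nm <- if (!is.null(meta$pixel_size_nm)) meta$pixel_size_nm else 80
  optics <- optics_config(pixel_size_nm = px_nm,
                          psf_sigma_nm = meta$psf_sigma_nm %||% 130,
                          exposure_s = meta$exposure_s %||% 0.2,
                          n_frames = length(pages))
  mt <- if (!is.null(meta$mt_axis))
    lapply(meta$mt_axis, as.numeric)
  else list(x0_px = 0.5, y0_px = (nrow(pages[[1]]) + 1) / 2,
            x1_px = ncol(pages[[1]]) - 0.5,
            y1_px = (nrow(pages[[1]]) + 1) / 2)
  structure(list(frames = frames, optics = optics, mt_axis = mt,
                 pixel_um = px_nm / 1000, n_frames = length(pages),
                 ground_truth = NULL),
            class = "image_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

runs_schema <- c("lane", "bind_time_s", "unbind_time_s", "bind_site",
                 "unbind_site", "censored")

#' Write / read the runs table of a trajectory set as CSV
#'
#' @param ts A \code{trajectory_set} (or a runs data frame).
#' @param path File path.
#' @return The path (write) or a validated runs data frame (read).
#' @export
write_runs_csv <- function(ts, path) {
  runs <- if (inherits(ts, "trajectory_set")) ts$runs else ts
  stopifnot(all(runs_schema %in% names(runs)))
  utils::write.csv(runs[, runs_schema], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_runs_csv
#' @export
read_runs_csv <- function(path) {
  runs <- utils::read.csv(path)
  extra <- setdiff(names(runs), runs_schema)
  if (length(extra))
    stop("unknown columns in runs CSV: ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(runs_schema, names(runs))
  if (length(missing))
    stop("missing columns in runs CSV: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(runs$bind_time_s < 0) || any(runs$unbind_time_s < 0))
    stop("runs CSV schema violation: negative times", call. = FALSE)
  if (any(runs$unbind_time_s < runs$bind_time_s))
    stop("runs CSV schema violation: unbind_time_s < bind_time_s",
         call. = FALSE)
  if (any(runs$unbind_site < runs$bind_site))
    stop("runs CSV schema violation: unbind_site < bind_site (motion is ",
         "unidirectional)", call. = FALSE)
  runs$censored <- as.logical(runs$censored)
  runs
}

#' Write / read a kymograph as CSV (positions x frames)
#'
#' The first column holds the position in um; remaining columns one frame
#' each. Metadata (frame interval, background means) goes to a JSON
#' sidecar.
#'
#' @param kymo A \code{kymograph}.
#' @param path File path.
#' @export
write_kymograph_csv <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  df <- data.frame(x_um = kymo$x_um, kymo$intensity)
  names(df) <- c("x_um", paste0("frame_", seq_len(ncol(kymo$intensity))))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(dt_s = kymo$dt_s, pixel_um = kymo$pixel_um,
                            bg_mean = kymo$bg_mean,
                            background_subtracted =
                              kymo$background_subtracted),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kymograph_csv
#' @export
read_kymograph_csv <- function(path) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "x_um")
    stop("kymograph CSV must start with an x_um column", call. = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(intensity = as.matrix(df[, -1, drop = FALSE]),
                 x_um = df$x_um, dt_s = meta$dt_s,
                 pixel_um = meta$pixel_um,
                 bg_mean = meta$bg_mean,
                 bg_sd = NULL, n_bg_samples = NA,
                 background_subtracted =
                   isTRUE(meta$background_subtracted)),
            class = "kymograph")
}

write_manifest <- function(dir, config, seed) {
  jsonlite::write_json(
    list(package = "motortraffic",
         version = as.character(utils::packageVersion("motortraffic")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         seed = seed, config = config),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, pretty = TRUE)
}

#' Run a staged analysis pipeline from a configuration
#'
#' Executes one pipeline stage (\code{simulate}, \code{render},
#' \code{kymo}, \code{analyze-corr}, \code{analyze-spt}, \code{series}, or
#' the end-to-end \code{demo}) with all settings taken from a plain list
#' or JSON file, writes the stage outputs in the documented formats into
#' \code{out_dir}, and drops a manifest (configuration, seeds, package
#' version) next to them. Given identical seeds, outputs are
#' byte-identical across runs.
#'
#' @param config A named list or path to a JSON file. Required fields:
#'   \code{stage}, \code{out_dir}, \code{seed}; remaining fields mirror
#'   the arguments of the stage's function (e.g. \code{params} and
#'   \code{lattice} sub-lists for \code{simulate}; concentrations may be
#'   given as \code{concentration_nM} or \code{concentration_per_um3}).
#' @return Invisibly, a list of the stage's result objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (field in c("stage", "out_dir", "seed"))
    if (is.null(config[[field]]))
      stop("pipeline config needs a '", field, "' field", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  get_params <- function() do.call(kinetic_params, as.list(config$params))
  get_conc <- function(lat) {
    if (!is.null(lat$concentration_nM))
      list(concentration = lat$concentration_nM, conc_unit = "nM")
    else list(concentration = lat$concentration_per_um3 %||% 0,
              conc_unit = "per_um3")
  }

  out <- switch(
    config$stage,
    simulate = {
      lat <- as.list(config$lattice)
      cu <- get_conc(lat)
      cfg <- lattice_config(
        lattice_length_um = lat$lattice_length_um,
        duration_s = lat$duration_s,
        concentration = cu$concentration, conc_unit = cu$conc_unit,
        boundary = lat$boundary %||% "open",
        langmuir = lat$langmuir %||% TRUE,
        n_motors = lat$n_motors %||% 0L,
        burn_in_s = lat$burn_in_s,
        snapshot_interval_s = lat$snapshot_interval_s %||% Inf,
        seed = derive_seed(seed, 1))
      ts <- simulate_traffic(get_params(), cfg)
      write_runs_csv(ts, file.path(config$out_dir, "runs.csv"))
      if (nrow(ts$snapshots))
        utils::write.csv(ts$snapshots,
                         file.path(config$out_dir, "snapshots.csv"),
                         row.names = FALSE)
      s <- summarize_traffic(ts, min_uncensored =
                               config$min_uncensored %||% 100)
      jsonlite::write_json(unclass(s),
                           file.path(config$out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      list(trajectories = ts, summary = s)
    },
    render = {
      tr <- as.list(config$trajectories)
      ts <- parametric_trajectories(tr$v_um_s, tr$omega_D,
                                    tr$binding_rate_per_um, tr$length_um,
                                    tr$duration_s,
                                    seed = derive_seed(seed, 2))
      oc <- as.list(config$optics)
      oc$seed <- derive_seed(seed, 3)
      stack <- render_stack(ts, do.call(optics_config, oc))
      write_stack_tiff(stack, file.path(config$out_dir, "stack.tif"))
      write_runs_csv(data.frame(lane = 1L,
                                bind_time_s = ts$paths$t0_s,
                                unbind_time_s = ts$paths$t1_s,
                                bind_site = round(ts$paths$x0_um * 1000),
                                unbind_site = round(ts$paths$x1_um * 1000),
                                censored = ts$paths$censored),
                     file.path(config$out_dir, "ground_truth_runs.csv"))
      list(stack = stack, trajectories = ts)
    },
    kymo = {
      stack <- read_stack_tiff(config$stack)
      kymo <- make_kymograph(stack,
                             width_pixels = config$width_pixels %||% 3,
                             background_offset_px =
                               config$background_offset_px %||% 5)
      write_kymograph_csv(kymo, file.path(config$out_dir, "kymograph.csv"))
      list(kymograph = kymo)
    },
    `analyze-corr` = {
      kymo <- read_kymograph_csv(config$kymograph)
      est <- correlation_motility(kymo,
                                  labeled_conc_nM = config$labeled_nM,
                                  total_conc_nM = config$total_nM,
                                  max_lag_s = config$max_lag_s %||% 10)
      surf <- est$surface
      est$surface <- NULL
      jsonlite::write_json(unclass(est),
                           file.path(config$out_dir, "estimates.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      utils::write.csv(surf$fits,
                       file.path(config$out_dir, "correlation_fits.csv"),
                       row.names = FALSE)
      list(estimates = est, surface = surf)
    },
    `analyze-spt` = {
      stack <- read_stack_tiff(config$stack)
      tracks <- detect_and_link(stack,
                                intensity_threshold =
                                  config$intensity_threshold,
                                max_disp_per_frame_um =
                                  config$max_disp_per_frame_um %||% 0.25)
      utils::write.csv(tracks$tracks,
                       file.path(config$out_dir, "tracks.csv"),
                       row.names = FALSE)
      md <- mean_displacement_velocity(tracks)
      rl <- runlength_cdf_fit(tracks, min_observable_um =
                                config$min_observable_um %||% 0)
      est <- list(velocity_um_s = md$velocity_um_s,
                  velocity_se = md$se,
                  run_length_um = rl$run_length_um,
                  run_length_se = rl$se, n_tracks = tracks$n_tracks)
      jsonlite::write_json(est,
                           file.path(config$out_dir, "estimates.json"),
                           auto_unbox = TRUE, digits = NA)
      list(tracks = tracks, estimates = est)
    },
    series = {
      ser <- predict_series(get_params(), config$concentrations_nM,
                            reps = config$reps %||% 3,
                            seed = derive_seed(seed, 4),
                            lattice_length_um =
                              config$lattice_length_um %||% 5,
                            duration_s = config$duration_s %||% 80)
      utils::write.csv(as.data.frame(ser),
                       file.path(config$out_dir, "series.csv"),
                       row.names = FALSE)
      list(series = ser)
    },
    fit = {
      obs <- utils::read.csv(config$observed)
      class(obs) <- c("concentration_series", "data.frame")
      params <- get_params()
      res <- list()
      if (isTRUE(config$low_density)) {
        res$stage1 <- fit_low_density(obs, params)
        jsonlite::write_json(res$stage1,
                             file.path(config$out_dir, "stage1.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      if (!is.null(config$grid)) {
        g <- config$grid
        fr <- grid_search_fit(obs, params,
                              lanes = g$lanes, ranges = g$ranges,
                              ratios = g$ratios,
                              reps = config$reps %||% 3,
                              seed = derive_seed(seed, 6),
                              lattice_length_um =
                                config$lattice_length_um %||% 5,
                              duration_s = config$duration_s %||% 80)
        utils::write.csv(fr$loss_table,
                         file.path(config$out_dir, "loss_table.csv"),
                         row.names = FALSE)
        jsonlite::write_json(list(best = fr$best, loss = fr$loss,
                                  stage1 = fr$stage1),
                             file.path(config$out_dir, "fit_result.json"),
                             auto_unbox = TRUE, digits = NA)
        res$grid_fit <- fr
      }
      res
    },
    demo = {
      params <- get_params()
      ser <- predict_series(params,
                            config$concentrations_nM %||% c(5, 50, 500),
                            reps = config$reps %||% 1,
                            seed = derive_seed(seed, 5),
                            lattice_length_um =
                              config$lattice_length_um %||% 5,
                            duration_s = config$duration_s %||% 60)
      utils::write.csv(as.data.frame(ser),
                       file.path(config$out_dir, "series.csv"),
                       row.names = FALSE)
      list(series = ser)
    },
    stop("unknown pipeline stage: ", config$stage, call. = FALSE))
  write_manifest(config$out_dir, config, seed)
  invisible(out)
}
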