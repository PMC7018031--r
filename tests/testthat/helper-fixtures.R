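# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

table1_params <- function(...) kinetic_params(...)

# brute-force stationary mean stepping fraction of a ring exclusion process
# with single-site motors: enumerate all configurations (uniform stationary
# measure) and average the fraction of motors free to step
ring_step_fraction_enum <- function(L, N) {
  configs <- utils::combn(L, N)
  frac <- apply(configs, 2, function(occ) {
    ahead <- ifelse(occ == L, 1, occ + 1)
    mean(!(ahead %in% occ))
  })
  mean(frac)
}

# low-density rendered stack shared by correlation tests (medium size)
corr_fixture <- function() {
  memo("corr_fixture", {
    ts <- parametric_trajectories(0.3, 0.25, binding_rate_per_um = 0.75,
                                  length_um = 12, duration_s = 100,
                                  seed = 401)
    stack <- render_stack(ts, optics_config(n_frames = 500, seed = 402))
    list(ts = ts, stack = stack,
         kymo = background_subtract(make_kymograph(stack)))
  })
}

# single noiseless motor crossing the field at constant speed
single_motor_stack <- function(v = 0.3, n_frames = 100) {
  paths <- data.frame(id = 1L, t0_s = 0, t1_s = n_frames * 0.2,
                      x0_um = 1, x1_um = 1 + v * n_frames * 0.2,
                      censored = TRUE)
  ts <- structure(list(paths = paths, runs = NULL, stats = NULL,
                       params = list(), burn_in_s = 0, seed = 1L,
                       config = list(lattice_length_um = 10,
                                     duration_s = n_frames * 0.2),
                       site_um = NA_real_, source = "parametric"),
                  class = "trajectory_set")
  render_stack(ts, optics_config(n_frames = n_frames, shot_noise = FALSE,
                                 background_photons = 0, camera_offset = 0,
                                 seed = 7))
}

# a track_set built directly from exact positions (bypassing detection)
make_track_set <- function(xs_list, exposure_s = 0.2) {
  rows <- lapply(seq_along(xs_list), function(i) {
    x <- xs_list[[i]]
    data.frame(track_id = i, frame = seq_along(x),
               t_s = (seq_along(x) - 0.5) * exposure_s,
               x_um = x, y_um = 0, amplitude = 100)
  })
  structure(list(tracks = do.call(rbind, rows),
                 n_detections = sum(lengths(xs_list)),
                 n_tracks = length(xs_list), exposure_s = exposure_s),
            class = "track_set")
}
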