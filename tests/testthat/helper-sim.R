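# Shared fixture builders; all randomness goes through explicit seeds.

DT <- 0.035  # frame interval used throughout the suite (seconds)

pooled_brownian_displacements <- function(D, n_tracks, n_frames, seed,
                                          localization_sd = 0) {
  cfg <- sim_config(n_frames = n_frames, localization_sd = localization_sd,
                    seed = seed)
  sim <- simulate_tracks(cfg, motion_brownian(D), n_tracks)
  collect_displacements(sim$tracks, 1, DT)
}

# Pool displacements from a slow/fast two-population mixture so that a
# fraction A of displacements comes from the slow component.
mixture_displacements <- function(A, D_slow, D_fast, n_tracks, n_frames, seed) {
  n_slow <- round(A * n_tracks)
  slow <- simulate_tracks(sim_config(n_frames = n_frames, seed = seed),
                          motion_brownian(D_slow), max(n_slow, 1))
  fast <- simulate_tracks(sim_config(n_frames = n_frames, seed = seed + 1),
                          motion_brownian(D_fast), max(n_tracks - n_slow, 1))
  tr_slow <- slow$tracks[slow$tracks$track_id <= n_slow, ]
  tr_fast <- fast$tracks[fast$tracks$track_id <= n_tracks - n_slow, ]
  tr_fast$track_id <- tr_fast$track_id + n_slow
  collect_displacements(dplyr::bind_rows(tr_slow, tr_fast), 1, DT)
}

# A deterministic track table built from explicit positions.
toy_track <- function(x, y, id = 1L, channel = "mrna", frame0 = 0L) {
  tibble::tibble(track_id = id, frame = frame0 + seq_along(x) - 1L,
                 x_um = x, y_um = y, channel = channel)
}

# Draw radial displacements exactly from the one-component displacement
# model (Rayleigh with scale sqrt(2 D dt)) -- used as an independent sampling
# oracle for the CDF machinery.
rayleigh_draws <- function(n, D, dt, seed) {
  set.seed(seed)
  sqrt(-4 * D * dt * log(stats::runif(n)))
}

as_displacement_set <- function(r, dt = DT) {
  d <- tibble::tibble(track_id = seq_along(r), frame = 0L, r = r)
  structure(d, lag = dt, frame_interval = dt, lag_frames = 1L,
            class = c("displacement_set", class(d)))
}
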