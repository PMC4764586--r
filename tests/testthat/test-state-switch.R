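test_that("the Rayleigh emission density has the right shape and mass", {
  D <- 0.25; dt <- DT
  # mode at sqrt(2 D dt)
  r <- seq(1e-4, 1, length.out = 5000)
  dens <- step_likelihood(r, D, dt)
  expect_lt(abs(r[which.max(dens)] - sqrt(2 * D * dt)), 2e-3)
  # integrates to 1
  total <- stats::integrate(step_likelihood, 0, Inf, D = D, dt = dt)$value
  expect_lt(abs(total - 1), 1e-6)
  # CDF at r = sqrt(4 D dt) equals 1 - 1/e, consistent with the
  # displacement-CDF model used in the deconvolution fits
  mass <- stats::integrate(step_likelihood, 0, sqrt(4 * D * dt),
                           D = D, dt = dt)$value
  expect_lt(abs(mass - (1 - exp(-1))), 1e-6)
  expect_error(step_likelihood(0.1, -1, dt), "D must be")
})

test_that("a single-state model recovers D from pooled steps", {
  sim <- simulate_tracks(sim_config(n_frames = 101, seed = 1),
                         motion_brownian(0.23), 1000)
  fit <- fit_hmm(sim$tracks, K = 1, frame_interval = DT)
  expect_gte(fit$n_steps, 1e5)
  expect_lt(abs(fit$D - 0.23) / 0.23, 0.02)
  ann <- annotate_states(sim$tracks[sim$tracks$track_id <= 20, ], fit)
  expect_true(all(ann$steps$state == 1L))
})

test_that("EM log-likelihood is non-decreasing and restarts agree", {
  sim <- simulate_tracks(sim_config(n_frames = 60, seed = 2),
                         motion_two_state(0.4, 0.1, 2, 2), 120)
  fit <- fit_hmm(sim$tracks, K = 2, n_restarts = 1, seed = 3,
                 frame_interval = DT)
  expect_true(all(diff(fit$ll_trace) >= -1e-6 * abs(fit$ll_trace[-1])))
  # label-swap invariance: independent initializations give the same model
  # after the fast-first sorting convention
  fit2 <- fit_hmm(sim$tracks, K = 2, n_restarts = 1, seed = 99,
                  frame_interval = DT)
  expect_equal(fit$D, fit2$D, tolerance = 1e-3)
  expect_equal(diag(fit$T), diag(fit2$T), tolerance = 1e-2)
  expect_true(all(diff(fit$D) < 0))  # state 1 fast
})

test_that("BIC selection separates one- from two-state data", {
  for (seed in 1:3) {
    one <- simulate_tracks(sim_config(n_frames = 101, seed = seed),
                           motion_brownian(0.2), 100)
    expect_equal(select_model(one$tracks, c(1, 2), n_restarts = 2,
                              seed = seed, frame_interval = DT)$K, 1L)
    two <- simulate_tracks(sim_config(n_frames = 101, seed = seed + 10),
                           motion_two_state(0.4, 0.1, 2, 2), 100)
    expect_equal(select_model(two$tracks, c(1, 2), n_restarts = 2,
                              seed = seed, frame_interval = DT)$K, 2L)
  }
})

test_that("Viterbi annotation labels steps accurately at 4-fold D contrast", {
  sim <- simulate_tracks(sim_config(n_frames = 80, seed = 4),
                         motion_two_state(0.4, 0.1, 2, 1), 150)
  fit <- fit_hmm(sim$tracks, K = 2, n_restarts = 2, seed = 5,
                 frame_interval = DT)
  ann <- annotate_states(sim$tracks, fit)
  truth <- sim$truth$per_step
  joined <- dplyr::inner_join(ann$steps, truth, by = c("track_id", "frame"),
                              suffix = c("_hat", "_true"))
  expect_equal(nrow(joined), nrow(truth))
  expect_gte(mean(joined$state_hat == joined$state_true), 0.80)
  # tracks that interconvert: multiple visits per state along one track
  multi <- ann$visits |>
    dplyr::group_by(track_id, state) |>
    dplyr::summarise(nv = dplyr::n(), .groups = "drop") |>
    dplyr::filter(nv >= 2)
  expect_gt(nrow(multi), 0)
})

test_that("single-step tracks yield one boundary visit", {
  sim <- simulate_tracks(sim_config(n_frames = 30, seed = 6),
                         motion_brownian(0.2), 60)
  fit <- fit_hmm(sim$tracks, K = 1, frame_interval = DT)
  two_frame <- toy_track(c(0, 0.05), c(0, 0))
  ann <- annotate_states(two_frame, fit)
  expect_equal(nrow(ann$visits), 1)
  expect_true(ann$visits$at_start && ann$visits$at_end)
  expect_equal(ann$visits$duration_s, DT)
})

test_that("visit extraction matches run-length encoding on toy sequences", {
  v <- sptmap:::visits_from_labels(c(1L, 1L, 2L, 2L, 1L, 1L), 0:5, DT)
  expect_equal(v$state, c(1L, 2L, 1L))
  expect_equal(v$n_steps, c(2L, 2L, 2L))
  expect_equal(v$at_start, c(TRUE, FALSE, FALSE))
  expect_equal(v$at_end, c(FALSE, FALSE, TRUE))
  expect_equal(v$start_frame, c(0L, 2L, 4L))
})

test_that("duration histograms pool visits and can exclude boundary visits", {
  sim <- simulate_tracks(sim_config(n_frames = 150, seed = 7),
                         motion_two_state(0.4, 0.1, 1, 0.7), 300)
  fit <- fit_hmm(sim$tracks, K = 2, n_restarts = 2, seed = 8,
                 frame_interval = DT)
  ann <- annotate_states(sim$tracks, fit)
  all_d <- duration_histograms(ann)
  int_d <- duration_histograms(ann, internal_only = TRUE)
  expect_lt(nrow(int_d), nrow(all_d))
  expect_true(all(!int_d$at_start & !int_d$at_end))
  steps <- all_d$duration_s / DT
  expect_true(all(abs(steps - round(steps)) < 1e-9))
  # a track entirely in one state contributes one visit, dropped when
  # internal_only
  whole <- annotate_states(toy_track(seq(0, 0.3, length.out = 8), rep(0, 8)),
                           fit_hmm(sim$tracks, K = 1, frame_interval = DT))
  expect_equal(nrow(duration_histograms(whole)), 1)
  expect_equal(nrow(duration_histograms(whole, internal_only = TRUE)), 0)

  # transition-matrix lifetimes recover the simulated switching kinetics;
  # Viterbi visit durations carry a known upward bias (brief excursions are
  # smoothed away), so their means are compared loosely and by ordering
  expect_lt(abs(fit$lifetimes_s[1] - 1 / 1) / (1 / 1), 0.2)
  expect_lt(abs(fit$lifetimes_s[2] - 1 / 0.7) / (1 / 0.7), 0.2)
  smry <- attr(int_d, "summary")
  truth_int <- sim$truth$per_step |>
    dplyr::group_by(track_id) |>
    dplyr::group_modify(~ sptmap:::visits_from_labels(.x$state, .x$frame, DT)) |>
    dplyr::ungroup() |>
    dplyr::filter(!at_start, !at_end) |>
    dplyr::group_by(state) |>
    dplyr::summarise(m = mean(duration_s))
  expect_gt(smry$mean_duration_s[smry$state == 2],
            smry$mean_duration_s[smry$state == 1])
  for (k in 1:2) {
    est <- smry$mean_duration_s[smry$state == k]
    tru <- truth_int$m[truth_int$state == k]
    expect_gt(est, tru * 0.8)   # not deflated
    expect_lt(est, tru * 1.5)   # inflation bounded
  }
})

test_that("tidy and glance summarise HMM fits", {
  sim <- simulate_tracks(sim_config(n_frames = 50, seed = 9),
                         motion_two_state(0.4, 0.1, 2, 2), 80)
  fit <- fit_hmm(sim$tracks, K = 2, n_restarts = 1, seed = 10,
                 frame_interval = DT)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_named(td, c("state", "D", "occupancy", "stay_prob", "lifetime_s"))
  gl <- glance(fit)
  expect_equal(gl$K, 2L)
  expect_true(jsonlite::validate(fit_to_json(fit)))
})
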