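test_that("degenerate motion produces exactly the expected geometry", {
  cfg <- sim_config(n_frames = 20, localization_sd = 0, seed = 1)
  sim <- simulate_tracks(cfg, motion_brownian(0), 5)
  d <- collect_displacements(sim$tracks, 1, DT)
  expect_true(all(d$r == 0))

  frozen <- simulate_tracks(cfg, motion_two_state(0.4, 0.1, 0, 0), 5)
  expect_true(all(frozen$truth$per_step$state == 1L))

  teth <- simulate_tracks(cfg, motion_tethered(0), 3)
  dt2 <- collect_displacements(teth$tracks, 1, DT)
  expect_true(all(dt2$r == 0))
})

test_that("Brownian displacements match the 4*D*dt closed form", {
  d <- pooled_brownian_displacements(0.19, 400, 51, seed = 2)
  expect_gt(nrow(d), 1.9e4)
  msq <- mean(d$r^2)
  se <- stats::sd(d$r^2) / sqrt(nrow(d))
  expect_lt(abs(msq - 4 * 0.19 * DT), 3 * se)
})

test_that("ensemble MSD of Brownian tracks is linear with slope 4D", {
  cfg <- sim_config(n_frames = 60, seed = 3)
  sim <- simulate_tracks(cfg, motion_brownian(0.12), 300)
  msd <- msd_ensemble(sim$tracks, 8, DT)
  fit <- stats::lm(msd ~ lag, data = msd[1:4, ])
  slope <- unname(stats::coef(fit)[2])
  sem_slope <- max(msd$sem[1:4] / msd$lag[1:4])
  expect_lt(abs(slope - 4 * 0.12), 3 * sem_slope)
})

test_that("two-state occupancy converges to k12/(k12+k21)", {
  k12 <- 2; k21 <- 1
  cfg <- sim_config(n_frames = 80, seed = 4)
  sim <- simulate_tracks(cfg, motion_two_state(0.4, 0.1, k12, k21), 200)
  st <- sim$truth$per_step$state
  frac2 <- mean(st == 2L)
  target <- k12 / (k12 + k21)
  # binomial SE is optimistic (states are autocorrelated); use 3x an
  # effective-sample-size-corrected SE with correlation time ~1/((k12+k21)dt)
  n_eff <- length(st) * (k12 + k21) * DT
  expect_lt(abs(frac2 - target), 3 * sqrt(target * (1 - target) / n_eff))
})

test_that("confined tracks stay inside their corral and reach equilibrium spread", {
  L <- 0.548
  cfg <- sim_config(n_frames = 100, seed = 5)
  sim <- simulate_tracks(cfg, motion_confined(0.4, L), 300)
  spans <- sim$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(sx = diff(range(x_um)), sy = diff(range(y_um)))
  expect_true(all(spans$sx <= L + 1e-12))
  expect_true(all(spans$sy <= L + 1e-12))
  # equilibrium variance of a coordinate inside the corral is L^2/12
  vx <- sim$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(v = stats::var(x_um))
  expect_lt(abs(mean(vx$v) - L^2 / 12) / (L^2 / 12), 0.1)
})

test_that("identical seed gives bit-identical output, different seed differs", {
  cfg <- sim_config(n_frames = 30, localization_sd = 0.02, seed = 42,
                    mean_track_length = 8)
  a <- simulate_tracks(cfg, motion_brownian(0.2), 50)
  b <- simulate_tracks(cfg, motion_brownian(0.2), 50)
  expect_identical(a$tracks, b$tracks)
  cfg$seed <- 43
  c <- simulate_tracks(cfg, motion_brownian(0.2), 50)
  expect_false(identical(a$tracks, c$tracks))
})

test_that("geometric attrition reproduces the configured mean lifetime", {
  cfg <- sim_config(n_frames = 300, mean_track_length = 6.2, seed = 6)
  sim <- simulate_tracks(cfg, motion_brownian(0.2), 3000)
  lt <- track_lifetimes(sim$tracks, DT)
  expect_lt(abs(mean(lt$lifetime_s) - 6.2 * DT) / (6.2 * DT), 0.05)
})

test_that("adhesion field slows tracks inside zones and honours null geometry", {
  cfg <- sim_config(field_size = c(16, 16), n_frames = 40, seed = 7)
  af <- simulate_adhesion_field(cfg, n_adhesions = 6, adhesion_size = 1.3,
                                D_near = 0.1, D_far = 0.4, n_tracks = 600)
  expect_equal(dim(af$mask), c(ceiling(16 / cfg$pixel_size),
                               ceiling(16 / cfg$pixel_size)))
  D <- apparent_D(af$tracks, DT) |>
    dplyr::inner_join(af$truth$per_track, by = "track_id")
  inside <- D$D_app[D$fraction_inside > 0.5]
  outside <- D$D_app[D$fraction_inside == 0]
  expect_gt(length(inside), 20)
  wt <- stats::wilcox.test(inside, outside, alternative = "less")
  expect_lt(wt$p.value, 0.01)

  # null geometry: D_near = D_far makes the two groups indistinguishable
  af0 <- simulate_adhesion_field(cfg, n_adhesions = 6, adhesion_size = 1.3,
                                 D_near = 0.3, D_far = 0.3, n_tracks = 600)
  D0 <- apparent_D(af0$tracks, DT) |>
    dplyr::inner_join(af0$truth$per_track, by = "track_id")
  ks <- suppressWarnings(stats::ks.test(D0$D_app[D0$fraction_inside > 0.5],
                                        D0$D_app[D0$fraction_inside == 0]))
  expect_gt(ks$p.value, 0.01)

  # no adhesions: all-zero mask
  af_none <- simulate_adhesion_field(cfg, n_adhesions = 0, adhesion_size = 1,
                                     D_near = 0.2, D_far = 0.2, n_tracks = 5)
  expect_true(all(af_none$mask == 0))
})

test_that("co-moving channel generator keeps its pairing contract", {
  cfg <- sim_config(field_size = c(30, 30), n_frames = 40,
                    mean_track_length = 10, seed = 8)
  fast <- motion_brownian(0.4)
  slow <- motion_two_state(0.4, 0.1, 2, 2)

  none <- simulate_comoving_channels(cfg, 50, 20, 0, 0.05, slow, fast)
  expect_equal(nrow(none$truth$pairs), 0)

  all_p <- simulate_comoving_channels(cfg, 30, 30, 1, 0, slow, fast)
  expect_equal(nrow(all_p$truth$pairs), 30)
  joined <- dplyr::inner_join(
    all_p$mrna, dplyr::inner_join(all_p$truth$pairs, all_p$ribo,
                                  by = c(ribo_id = "track_id")),
    by = c(track_id = "mrna_id", "frame"))
  expect_true(all(joined$x_um.x == joined$x_um.y))
  expect_true(all(joined$y_um.x == joined$y_um.y))

  frac <- simulate_comoving_channels(cfg, 200, 50, 0.05, 0.05, slow, fast)
  expect_equal(nrow(frac$truth$pairs), round(0.05 * 200))
  expect_equal(expected_comoving_count(9000, 0.05), 450)

  expect_error(simulate_comoving_channels(cfg, 100, 2, 0.5, 0.05, slow, fast),
               "smaller than required")
})

test_that("rendered movies place integrated-Gaussian spots where tracks are", {
  cfg <- sim_config(field_size = c(5, 5), n_frames = 3, seed = 9)
  empty <- render_movie(toy_track(numeric(0), numeric(0))[0, ],
                        psf_sd = 1, photons_per_spot = 100, background = 7,
                        config = cfg, noise = FALSE)
  expect_true(all(empty == 7))

  spot <- toy_track(rep(2.5, 3), rep(1.2, 3))
  mov <- render_movie(spot, psf_sd = 1.2, photons_per_spot = 5000,
                      background = 0, config = cfg, noise = FALSE)
  px <- 2.5 / cfg$pixel_size; py <- 1.2 / cfg$pixel_size
  for (t in 1:3) {
    am <- which(mov[, , t] == max(mov[, , t]), arr.ind = TRUE)
    expect_lt(abs(am[1, 2] - 0.5 - px), 1)
    expect_lt(abs(am[1, 1] - 0.5 - py), 1)
  }
})

test_that("track and movie serialization round-trips", {
  cfg <- sim_config(field_size = c(5, 5), n_frames = 4, seed = 10)
  sim <- simulate_tracks(cfg, motion_brownian(0.1), 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks(sim$tracks, f)
  back <- read_tracks(f)
  expect_equal(as.data.frame(back), as.data.frame(sim$tracks),
               tolerance = 1e-12)

  mov <- suppressWarnings(render_movie(sim$tracks, 1.1, 300, 20, cfg))
  tf <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(mov, tf)
  back_m <- read_movie_tiff(tf)
  expect_equal(back_m, array(as.integer(mov), dim = dim(mov)))

  mask <- matrix(0L, 10, 12); mask[3:5, 4:7] <- 1L
  mf <- withr::local_tempfile(fileext = ".tif")
  write_mask_tiff(mask, mf)
  expect_equal(read_mask_tiff(mf), mask)
})
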