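test_that("frame distances enumerate all cross-channel pairs", {
  a <- toy_track(1, 1, id = 1L, channel = "mrna")
  b <- toy_track(1, 1, id = 2L, channel = "ribosome")
  d <- frame_distances(a, b)
  expect_equal(nrow(d), 1)
  expect_equal(d$d, 0)

  a2 <- dplyr::bind_rows(toy_track(0, 0, id = 1L), toy_track(1, 0, id = 2L))
  b3 <- dplyr::bind_rows(toy_track(0, 1, id = 3L), toy_track(1, 1, id = 4L),
                         toy_track(2, 2, id = 5L))
  expect_equal(nrow(frame_distances(a2, b3)), 6)

  late <- toy_track(1, 1, id = 9L, frame0 = 100L)
  expect_equal(nrow(frame_distances(a, late)), 0)
})

test_that("independent channels give a flat area-normalized distribution", {
  set.seed(1)
  # mRNA restricted to the interior by r_max so every annulus is fully
  # covered by the ribosome support (edge correction)
  mrna <- tibble::tibble(track_id = 1:2000, frame = 0L,
                         x_um = runif(2000, 4, 26), y_um = runif(2000, 4, 26),
                         channel = "mrna")
  ribo <- tibble::tibble(track_id = 10000 + 1:200, frame = 0L,
                         x_um = runif(200, 0, 30), y_um = runif(200, 0, 30),
                         channel = "ribosome")
  dist <- frame_distances(mrna, ribo)
  nd <- normalized_distance_distribution(dist, bin_width = 0.107, r_max = 3)
  expect_gte(sum(nd$count), 1e4)
  expect_equal(sum(nd$count), sum(dist$d < 3))
  # no bin deviates from the median density by more than 4 Poisson sd
  med <- stats::median(nd$density)
  pois_sd <- sqrt(pmax(med * pi * (nd$r_out^2 - nd$r_in^2), 1)) /
    (pi * (nd$r_out^2 - nd$r_in^2))
  expect_true(all(abs(nd$density - med) <= 4 * pois_sd))
  # chi-square flatness on raw counts vs annulus-area-proportional expectation
  areas <- pi * (nd$r_out^2 - nd$r_in^2)
  chi <- stats::chisq.test(nd$count, p = areas / sum(areas))
  expect_gt(chi$p.value, 0.01)
})

test_that("a co-moving subpopulation appears as a short-distance peak", {
  cfg <- sim_config(field_size = c(30, 30), n_frames = 60,
                    mean_track_length = 12, seed = 2)
  sim <- simulate_comoving_channels(cfg, 1500, 150, 0.05, 0.05,
                                    motion_two_state(0.4, 0.1, 2, 2),
                                    motion_brownian(0.4))
  nd <- normalized_distance_distribution(frame_distances(sim$mrna, sim$ribo),
                                         bin_width = 0.107, r_max = 3)
  short <- nd$r_out <= 3 * 0.107
  baseline <- stats::median(nd$density[!short])
  expect_gt(max(nd$density[short]), 3 * baseline)

  # no-translation control: near-flat with at most a modest excess
  sim0 <- simulate_comoving_channels(cfg, 1500, 150, 0, 0.05,
                                     motion_two_state(0.4, 0.1, 2, 2),
                                     motion_brownian(0.4))
  nd0 <- normalized_distance_distribution(frame_distances(sim0$mrna, sim0$ribo),
                                          bin_width = 0.107, r_max = 3)
  baseline0 <- stats::median(nd0$density[!short])
  expect_lt(max(nd0$density[short]), 3 * baseline0)
})

test_that("the run criterion requires min_frames consecutive close frames", {
  mk <- function(frames, x) tibble::tibble(track_id = 1L, frame = frames,
                                           x_um = x, y_um = 0, channel = "mrna")
  ribo0 <- tibble::tibble(track_id = 2L, frame = 0:9, x_um = 0, y_um = 0,
                          channel = "ribosome")
  # close at frames 1,2,4,5 but not 3: no run of 3
  m1 <- mk(0:9, ifelse(0:9 %in% c(1, 2, 4, 5), 0.1, 5))
  expect_equal(nrow(find_comoving(m1, ribo0)), 0)
  # close for exactly 2 consecutive frames
  m2 <- mk(0:9, ifelse(0:9 %in% c(3, 4), 0.1, 5))
  expect_equal(nrow(find_comoving(m2, ribo0)), 0)
  # close for 3 consecutive frames qualifies; maximal window is reported
  m3 <- mk(0:9, ifelse(0:9 %in% c(2, 3, 4), 0.1, 5))
  p3 <- find_comoving(m3, ribo0)
  expect_equal(nrow(p3), 1)
  expect_equal(c(p3$start_frame, p3$end_frame), c(2, 4))
  # brute-force oracle over all windows of length 3 agrees
  close <- abs(m3$x_um - 0) <= 0.320
  brute <- any(vapply(1:(10 - 2), function(i) all(close[i:(i + 2)]), logical(1)))
  expect_true(brute)
})

test_that("pair detection is symmetric, monotone, and sensitive at zero offset", {
  cfg <- sim_config(field_size = c(30, 30), n_frames = 50,
                    mean_track_length = 12, seed = 3)
  sim <- simulate_comoving_channels(cfg, 300, 60, 0.1, 0,
                                    motion_two_state(0.4, 0.1, 2, 2),
                                    motion_brownian(0.4))
  pairs <- find_comoving(sim$mrna, sim$ribo)
  # recall of ground-truth pairs with enough overlap
  lens <- dplyr::count(sim$mrna, track_id)
  truth <- dplyr::inner_join(sim$truth$pairs, lens,
                             by = c(mrna_id = "track_id")) |>
    dplyr::filter(n >= 3)
  found <- paste(pairs$mrna_id, pairs$ribo_id)
  expect_equal(mean(paste(truth$mrna_id, truth$ribo_id) %in% found), 1)

  # symmetry under channel swap
  swapped <- find_comoving(sim$ribo, sim$mrna)
  expect_setequal(paste(swapped$ribo_id, swapped$mrna_id), found)

  # monotonicity in d_max and min_frames
  tighter <- find_comoving(sim$mrna, sim$ribo, d_max = 0.2)
  expect_true(all(paste(tighter$mrna_id, tighter$ribo_id) %in% found))
  longer <- find_comoving(sim$mrna, sim$ribo, min_frames = 5)
  expect_true(all(paste(longer$mrna_id, longer$ribo_id) %in% found))
})

test_that("frame permutation destroys the co-movement signal", {
  interior <- function(tr) dplyr::filter(tr, x_um > 4, x_um < 26,
                                         y_um > 4, y_um < 26)
  short_peak <- function(nd) {
    short <- nd$r_out <= 3 * 0.107
    max(nd$density[short]) / stats::median(nd$density[!short])
  }
  # spatially independent channels stay flat after frame shuffling
  cfg0 <- sim_config(field_size = c(30, 30), n_frames = 60,
                     mean_track_length = 8, seed = 3)
  sim0 <- simulate_comoving_channels(cfg0, 1200, 600, 0, 0.05,
                                     motion_two_state(0.4, 0.1, 2, 2),
                                     motion_brownian(0.4))
  set.seed(3)
  shuf0 <- dplyr::mutate(sim0$ribo, frame = sample(frame))
  nd0 <- normalized_distance_distribution(
    frame_distances(interior(sim0$mrna), shuf0), bin_width = 0.107, r_max = 3)
  areas <- pi * (nd0$r_out^2 - nd0$r_in^2)
  chi <- stats::chisq.test(nd0$count, p = areas / sum(areas))
  expect_gt(chi$p.value, 0.01)

  # with a co-moving subpopulation the sharp sub-3-pixel peak collapses
  # after shuffling (broad territorial overlap of partner tracks remains)
  cfg1 <- sim_config(field_size = c(30, 30), n_frames = 60,
                     mean_track_length = 8, seed = 4)
  sim1 <- simulate_comoving_channels(cfg1, 1200, 600, 0.05, 0.05,
                                     motion_two_state(0.4, 0.1, 2, 2),
                                     motion_brownian(0.4))
  nd_obs <- normalized_distance_distribution(
    frame_distances(interior(sim1$mrna), sim1$ribo),
    bin_width = 0.107, r_max = 3)
  set.seed(4)
  shuf1 <- dplyr::mutate(sim1$ribo, frame = sample(frame))
  nd_shuf <- normalized_distance_distribution(
    frame_distances(interior(sim1$mrna), shuf1), bin_width = 0.107, r_max = 3)
  expect_gt(short_peak(nd_obs), 3)
  expect_lt(short_peak(nd_shuf), short_peak(nd_obs) / 2)
})

test_that("subset analysis separates co-moving from free populations", {
  cfg <- sim_config(field_size = c(30, 30), n_frames = 60,
                    mean_track_length = 15, seed = 5)
  sim <- simulate_comoving_channels(cfg, 1200, 150, 0.08, 0.05,
                                    motion_two_state(0.4, 0.1, 4, 1),
                                    motion_brownian(0.4))
  pairs <- find_comoving(sim$mrna, sim$ribo)
  expect_gt(nrow(pairs), 20)
  rep <- comoving_subset_analysis(pairs, sim$mrna, sim$ribo, DT,
                                  fix_D = c(0.1, 0.4))
  expect_gt(rep$mrna$comoving$cdf2$A, rep$mrna$free$cdf2$A)
  expect_lt(rep$mrna$comoving$cdf1$D_app, rep$mrna$free$cdf1$D_app)

  # empty-pair case degrades gracefully
  none <- find_comoving(sim$mrna[sim$mrna$track_id %in% 1:5, ],
                        sim$ribo[sim$ribo$track_id == max(sim$ribo$track_id), ])
  rep0 <- comoving_subset_analysis(none, sim$mrna, sim$ribo, DT)
  expect_equal(rep0$n_pairs, 0)
  expect_equal(rep0$mrna$comoving$n_tracks, 0)
})

test_that("colocalization percentage arithmetic", {
  # exact ratio is 15.35%; agrees with the reported 15.4% at its printed
  # precision
  expect_equal(colocalization_percent(33, 215), 100 * 33 / 215)
  expect_lt(abs(colocalization_percent(33, 215) - 15.4), 0.06)
  expect_error(colocalization_percent(10, 0))
})
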