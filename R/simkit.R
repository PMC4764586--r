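#' Simulation configuration
#'
#' Physical and acquisition constants shared by all simulators. Defaults match
#' a typical TIRF single-particle-tracking acquisition: 35 ms frame interval
#' and 107 nm pixels.
#'
#' @param frame_interval Frame interval in seconds.
#' @param pixel_size Pixel size in micrometres.
#' @param field_size Numeric length-2, field width and height in micrometres.
#' @param n_frames Number of movie frames.
#' @param localization_sd Localization error (standard deviation per
#'   coordinate, micrometres) added to every reported position.
#' @param mean_track_length Mean track length in frames for geometric
#'   (memoryless photobleaching) attrition, or `NULL` for tracks spanning the
#'   whole acquisition.
#' @param seed Integer seed; identical configuration implies bit-identical
#'   output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(frame_interval = 0.035, pixel_size = 0.107,
                       field_size = c(20, 20), n_frames = 100,
                       localization_sd = 0, mean_track_length = NULL,
                       seed = NULL) {
  stopifnot(frame_interval > 0, pixel_size > 0, localization_sd >= 0,
            length(field_size) == 2, all(field_size > 0), n_frames >= 1)
  if (!is.null(mean_track_length) && mean_track_length < 1)
    stop("mean_track_length must be >= 1 frame", call. = FALSE)
  structure(list(frame_interval = frame_interval, pixel_size = pixel_size,
                 field_size = as.numeric(field_size), n_frames = as.integer(n_frames),
                 localization_sd = localization_sd,
                 mean_track_length = mean_track_length, seed = seed),
            class = "sim_config")
}

#' Motion models for simulated particles
#'
#' Constructors for the motion specifications understood by
#' [simulate_tracks()]: free Brownian diffusion, two-state switching
#' diffusion, confined (corralled) diffusion in a reflecting square, and a
#' tethered (stationary) particle with positional jitter.
#'
#' @param D,D1,D2,D_in Diffusion coefficients in um^2/s. For two-state motion
#'   state 1 is the fast state (`D1 > D2`).
#' @param k12,k21 Switching rates (1/s) from state 1 to 2 and from 2 to 1.
#' @param corral_side Side of the reflecting square corral in micrometres.
#' @param tether_sd Standard deviation of the jitter about the tether point
#'   (micrometres).
#' @return An object of class `motion_spec`.
#' @name motion_spec
NULL

#' @rdname motion_spec
#' @export
motion_brownian <- function(D) {
  stopifnot(is.numeric(D), length(D) == 1, D >= 0)
  structure(list(kind = "brownian", D = D), class = "motion_spec")
}

#' @rdname motion_spec
#' @export
motion_two_state <- function(D1, D2, k12, k21) {
  if (!(D1 > D2)) stop("two-state motion requires D1 > D2 (state 1 fast)", call. = FALSE)
  stopifnot(D1 >= 0, D2 >= 0, k12 >= 0, k21 >= 0)
  structure(list(kind = "two_state", D1 = D1, D2 = D2, k12 = k12, k21 = k21),
            class = "motion_spec")
}

#' @rdname motion_spec
#' @export
motion_confined <- function(D_in, corral_side) {
  stopifnot(D_in >= 0)
  if (!(corral_side > 0)) stop("corral_side must be > 0", call. = FALSE)
  structure(list(kind = "confined", D = D_in, corral_side = corral_side),
            class = "motion_spec")
}

#' @rdname motion_spec
#' @export
motion_tethered <- function(tether_sd) {
  stopifnot(tether_sd >= 0)
  structure(list(kind = "tethered", tether_sd = tether_sd), class = "motion_spec")
}

# Fold a coordinate into [0, L] by repeated reflection (exact for any number
# of wall crossings within one step).
reflect_fold <- function(z, L) {
  m <- z %% (2 * L)
  ifelse(m > L, 2 * L - m, m)
}

# Exact discrete-time transition matrix of a 2-state continuous-time chain
# observed at interval dt; preserves the stationary distribution exactly.
two_state_transition <- function(k12, k21, dt) {
  ktot <- k12 + k21
  if (ktot == 0) return(diag(2))
  e <- exp(-ktot * dt)
  matrix(c((k21 + k12 * e) / ktot, k12 * (1 - e) / ktot,
           k21 * (1 - e) / ktot, (k12 + k21 * e) / ktot),
         nrow = 2, byrow = TRUE)
}

draw_track_lengths <- function(n_tracks, config) {
  if (is.null(config$mean_track_length)) {
    start <- rep(0L, n_tracks)
    len <- rep(config$n_frames, n_tracks)
  } else {
    m <- config$mean_track_length
    start <- sample.int(config$n_frames, n_tracks, replace = TRUE) - 1L
    len <- stats::rgeom(n_tracks, prob = 1 / m) + 1L
    len <- pmin(len, config$n_frames - start)
  }
  list(start = start, len = pmax(len, 1L))
}

simulate_one_track <- function(len, motion, config) {
  dt <- config$frame_interval
  fs <- config$field_size
  n_steps <- len - 1L
  state <- NULL
  switch(motion$kind,
    brownian = {
      p0 <- stats::runif(2) * fs
      sd <- sqrt(2 * motion$D * dt)
      dx <- if (n_steps > 0) stats::rnorm(n_steps, sd = sd) else numeric(0)
      dy <- if (n_steps > 0) stats::rnorm(n_steps, sd = sd) else numeric(0)
      x <- p0[1] + c(0, cumsum(dx)); y <- p0[2] + c(0, cumsum(dy))
    },
    two_state = {
      P <- two_state_transition(motion$k12, motion$k21, dt)
      ktot <- motion$k12 + motion$k21
      p1 <- if (ktot > 0) motion$k21 / ktot else 1
      state <- integer(max(n_steps, 0))
      if (n_steps > 0) {
        state[1] <- ifelse(stats::runif(1) < p1, 1L, 2L)
        if (n_steps > 1) for (i in 2:n_steps) {
          state[i] <- ifelse(stats::runif(1) < P[state[i - 1], 1], 1L, 2L)
        }
      }
      Ds <- c(motion$D1, motion$D2)[state]
      sd <- sqrt(2 * Ds * dt)
      p0 <- stats::runif(2) * fs
      x <- p0[1] + c(0, cumsum(stats::rnorm(n_steps, sd = sd)))
      y <- p0[2] + c(0, cumsum(stats::rnorm(n_steps, sd = sd)))
    },
    confined = {
      L <- motion$corral_side
      corner <- c(stats::runif(1, 0, max(fs[1] - L, 0)),
                  stats::runif(1, 0, max(fs[2] - L, 0)))
      # equilibrium start: uniform inside the corral
      rel0 <- stats::runif(2) * L
      sd <- sqrt(2 * motion$D * dt)
      rx <- reflect_fold(rel0[1] + c(0, cumsum(stats::rnorm(n_steps, sd = sd))), L)
      ry <- reflect_fold(rel0[2] + c(0, cumsum(stats::rnorm(n_steps, sd = sd))), L)
      x <- corner[1] + rx; y <- corner[2] + ry
    },
    tethered = {
      p0 <- stats::runif(2) * fs
      x <- p0[1] + stats::rnorm(len, sd = motion$tether_sd)
      y <- p0[2] + stats::rnorm(len, sd = motion$tether_sd)
    },
    stop("unknown motion kind: ", motion$kind, call. = FALSE)
  )
  list(x = x, y = y, state = state)
}

#' Simulate single-particle trajectories with ground truth
#'
#' Draws trajectories under the given motion model, applies geometric
#' track-length attrition (if configured) and independent Gaussian
#' localization error to every reported position, and retains per-track and
#' per-step ground truth.
#'
#' @param config A [sim_config()].
#' @param motion A [motion_spec] constructor result.
#' @param n_tracks Number of tracks to simulate.
#' @param channel Channel label stored in the track table.
#' @return A list of class `spt_sim` with elements `tracks` (tibble:
#'   `track_id, frame, x_um, y_um, channel`) and `truth` (list with
#'   `per_track` and, for two-state motion, `per_step` state labels keyed by
#'   the frame at which each step starts).
#' @export
simulate_tracks <- function(config, motion, n_tracks, channel = "mrna") {
  stopifnot(inherits(config, "sim_config"), inherits(motion, "motion_spec"),
            n_tracks >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  geom <- draw_track_lengths(n_tracks, config)
  sims <- purrr::map(geom$len, simulate_one_track, motion = motion, config = config)
  tracks <- purrr::imap(sims, function(s, i) {
    n <- length(s$x)
    tibble::tibble(track_id = i, frame = geom$start[i] + seq_len(n) - 1L,
                   x_um = s$x, y_um = s$y, channel = channel)
  }) |> purrr::list_rbind()
  if (config$localization_sd > 0) {
    tracks$x_um <- tracks$x_um + stats::rnorm(nrow(tracks), sd = config$localization_sd)
    tracks$y_um <- tracks$y_um + stats::rnorm(nrow(tracks), sd = config$localization_sd)
  }
  per_track <- tibble::tibble(track_id = seq_len(n_tracks), kind = motion$kind,
                              n_frames = geom$len, start_frame = geom$start)
  for (f in setdiff(names(motion), "kind")) per_track[[f]] <- motion[[f]]
  per_step <- NULL
  if (motion$kind == "two_state") {
    per_step <- purrr::imap(sims, function(s, i) {
      if (length(s$state) == 0) return(NULL)
      tibble::tibble(track_id = i,
                     frame = geom$start[i] + seq_along(s$state) - 1L,
                     state = s$state)
    }) |> purrr::list_rbind()
  }
  structure(list(tracks = tracks,
                 truth = list(per_track = per_track, per_step = per_step),
                 config = config),
            class = "spt_sim")
}

ellipse_inside <- function(x, y, zones, margin = 0) {
  if (nrow(zones) == 0) return(rep(FALSE, length(x)))
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(zones))) {
    dx <- x - zones$cx[i]; dy <- y - zones$cy[i]
    ct <- cos(zones$theta[i]); st <- sin(zones$theta[i])
    u <- (dx * ct + dy * st) / (zones$a[i] + margin)
    v <- (-dx * st + dy * ct) / (zones$b[i] + margin)
    inside <- inside | (u^2 + v^2 <= 1)
  }
  inside
}

#' Simulate a field with slow adhesion-shaped zones
#'
#' Places non-overlapping elliptical zones (emulating focal adhesions) in the
#' field and simulates tracks whose per-step diffusion coefficient is
#' `D_near` inside a zone (plus `margin`) and `D_far` outside. Tracks are
#' reflected at the field border so the population stays comparable against
#' the static mask. The zone geometry is rasterized to a binary pixel mask.
#'
#' @inheritParams simulate_tracks
#' @param n_adhesions Number of elliptical zones.
#' @param adhesion_size Semi-major axis of each zone (um); semi-minor is half.
#' @param D_near,D_far Diffusion coefficients (um^2/s) inside/outside zones;
#'   requires `D_near <= D_far`.
#' @param n_tracks Number of tracks.
#' @param margin Dilation margin (um) added to zones for the motion rule.
#' @return A list of class `spt_sim` with `tracks`, `mask` (binary matrix,
#'   rows = y pixels), and `truth` (`zones` table and per-track fraction of
#'   true positions inside a zone).
#' @export
simulate_adhesion_field <- function(config, n_adhesions, adhesion_size,
                                    D_near, D_far, n_tracks = 500, margin = 0) {
  stopifnot(inherits(config, "sim_config"), D_near <= D_far, n_tracks >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$field_size
  a <- adhesion_size; b <- adhesion_size / 2
  zones <- tibble::tibble(cx = numeric(0), cy = numeric(0), a = numeric(0),
                          b = numeric(0), theta = numeric(0))
  if (n_adhesions > 0) {
    maxit <- 500 * n_adhesions
    it <- 0
    while (nrow(zones) < n_adhesions) {
      it <- it + 1
      if (it > maxit)
        stop("could not place ", n_adhesions,
             " non-overlapping adhesions in the field", call. = FALSE)
      cx <- stats::runif(1, a, fs[1] - a); cy <- stats::runif(1, a, fs[2] - a)
      if (nrow(zones) == 0 || all(sqrt((zones$cx - cx)^2 + (zones$cy - cy)^2) > 2 * a)) {
        zones <- dplyr::bind_rows(zones, tibble::tibble(
          cx = cx, cy = cy, a = a, b = b, theta = stats::runif(1, 0, pi)))
      }
    }
  }
  # rasterized mask, pixel centres at ((j-0.5), (i-0.5)) * pixel_size
  nx <- ceiling(fs[1] / config$pixel_size); ny <- ceiling(fs[2] / config$pixel_size)
  px <- (seq_len(nx) - 0.5) * config$pixel_size
  py <- (seq_len(ny) - 0.5) * config$pixel_size
  gx <- rep(px, each = ny); gy <- rep(py, times = nx)
  mask <- matrix(as.integer(ellipse_inside(gx, gy, zones)), nrow = ny, ncol = nx)

  geom <- draw_track_lengths(n_tracks, config)
  dt <- config$frame_interval
  maxlen <- max(geom$len)
  X <- matrix(NA_real_, n_tracks, maxlen); Y <- matrix(NA_real_, n_tracks, maxlen)
  X[, 1] <- stats::runif(n_tracks) * fs[1]; Y[, 1] <- stats::runif(n_tracks) * fs[2]
  inside_count <- as.integer(ellipse_inside(X[, 1], Y[, 1], zones, margin))
  if (maxlen > 1) for (t in 2:maxlen) {
    act <- which(geom$len >= t)
    if (length(act) == 0) break
    ins <- ellipse_inside(X[act, t - 1], Y[act, t - 1], zones, margin)
    sd <- sqrt(2 * ifelse(ins, D_near, D_far) * dt)
    X[act, t] <- reflect_fold(X[act, t - 1] + stats::rnorm(length(act), sd = sd), fs[1])
    Y[act, t] <- reflect_fold(Y[act, t - 1] + stats::rnorm(length(act), sd = sd), fs[2])
    inside_count[act] <- inside_count[act] +
      as.integer(ellipse_inside(X[act, t], Y[act, t], zones, margin))
  }
  tracks <- purrr::map(seq_len(n_tracks), function(i) {
    n <- geom$len[i]
    tibble::tibble(track_id = i, frame = geom$start[i] + seq_len(n) - 1L,
                   x_um = X[i, seq_len(n)], y_um = Y[i, seq_len(n)],
                   channel = "mrna")
  }) |> purrr::list_rbind()
  if (config$localization_sd > 0) {
    tracks$x_um <- tracks$x_um + stats::rnorm(nrow(tracks), sd = config$localization_sd)
    tracks$y_um <- tracks$y_um + stats::rnorm(nrow(tracks), sd = config$localization_sd)
  }
  per_track <- tibble::tibble(track_id = seq_len(n_tracks), n_frames = geom$len,
                              fraction_inside = inside_count / geom$len)
  structure(list(tracks = tracks, mask = mask,
                 truth = list(zones = zones, per_track = per_track,
                              D_near = D_near, D_far = D_far),
                 config = config),
            class = "spt_sim")
}

#' Simulate dual-channel co-moving particle pairs
#'
#' A chosen fraction of mRNA tracks each receive a ribosome partner that
#' shadows the mRNA's reported path with independent per-frame Gaussian
#' jitter over the full track span; the remaining ribosome tracks diffuse
#' independently. Co-moving mRNA follow `motion_comoving`; free mRNA and
#' free ribosomes follow `motion_free`.
#'
#' @inheritParams simulate_tracks
#' @param n_mrna,n_ribo Track counts per channel.
#' @param comoving_fraction Fraction of mRNA tracks given a partner; the
#'   number of pairs is `round(comoving_fraction * n_mrna)`.
#' @param pair_offset_sd Jitter of the partner about the mRNA path (um).
#' @param motion_comoving,motion_free Motion specs for paired/free tracks.
#' @return A list of class `spt_sim` with `tracks` (both channels; ribosome
#'   ids continue after mRNA ids) and `truth$pairs`
#'   (`mrna_id, ribo_id, start_frame, end_frame`).
#' @export
simulate_comoving_channels <- function(config, n_mrna, n_ribo, comoving_fraction,
                                       pair_offset_sd, motion_comoving, motion_free) {
  stopifnot(inherits(config, "sim_config"),
            comoving_fraction >= 0, comoving_fraction <= 1,
            n_mrna >= 1, n_ribo >= 0)
  n_pairs <- round(comoving_fraction * n_mrna)
  if (n_ribo < n_pairs)
    stop("n_ribo (", n_ribo, ") smaller than required partners (", n_pairs, ")",
         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_inner <- config; cfg_inner$seed <- NULL

  paired_ids <- if (n_pairs > 0) sort(sample.int(n_mrna, n_pairs)) else integer(0)
  free_ids <- setdiff(seq_len(n_mrna), paired_ids)
  mrna_parts <- list()
  if (n_pairs > 0)
    mrna_parts$co <- simulate_tracks(cfg_inner, motion_comoving, n_pairs, channel = "mrna")
  if (length(free_ids) > 0)
    mrna_parts$free <- simulate_tracks(cfg_inner, motion_free, length(free_ids),
                                       channel = "mrna")
  relabel <- function(sim, ids) {
    tr <- sim$tracks
    tr$track_id <- ids[tr$track_id]
    tr
  }
  mrna <- dplyr::bind_rows(
    if (n_pairs > 0) relabel(mrna_parts$co, paired_ids),
    if (length(free_ids) > 0) relabel(mrna_parts$free, free_ids)
  ) |> dplyr::arrange(.data$track_id, .data$frame)

  # partners shadow the reported mRNA path with i.i.d. jitter
  ribo_list <- list()
  pairs <- tibble::tibble(mrna_id = integer(0), ribo_id = integer(0),
                          start_frame = integer(0), end_frame = integer(0))
  next_id <- n_mrna
  if (n_pairs > 0) {
    for (mid in paired_ids) {
      next_id <- next_id + 1L
      src <- mrna[mrna$track_id == mid, ]
      jit_x <- if (pair_offset_sd > 0) stats::rnorm(nrow(src), sd = pair_offset_sd) else 0
      jit_y <- if (pair_offset_sd > 0) stats::rnorm(nrow(src), sd = pair_offset_sd) else 0
      ribo_list[[length(ribo_list) + 1L]] <- tibble::tibble(
        track_id = next_id, frame = src$frame,
        x_um = src$x_um + jit_x, y_um = src$y_um + jit_y, channel = "ribosome")
      pairs <- dplyr::bind_rows(pairs, tibble::tibble(
        mrna_id = mid, ribo_id = next_id,
        start_frame = min(src$frame), end_frame = max(src$frame)))
    }
  }
  n_free_ribo <- n_ribo - n_pairs
  if (n_free_ribo > 0) {
    fr <- simulate_tracks(cfg_inner, motion_free, n_free_ribo, channel = "ribosome")
    fr$tracks$track_id <- fr$tracks$track_id + next_id
    ribo_list[[length(ribo_list) + 1L]] <- fr$tracks
  }
  ribo <- dplyr::bind_rows(ribo_list)
  structure(list(tracks = dplyr::bind_rows(mrna, ribo),
                 mrna = mrna, ribo = ribo,
                 truth = list(pairs = pairs, paired_mrna = paired_ids),
                 config = config),
            class = "spt_sim")
}

#' Render trajectories into a synthetic movie stack
#'
#' Each localization is rendered as an integrated 2-D Gaussian point-spread
#' function on the pixel grid; Poisson shot noise is applied to signal plus
#' background and the result quantized to 16 bits. Pixel `k` (0-based) covers
#' `[k, k+1)` in pixel coordinates; positions are converted from micrometres
#' with `config$pixel_size`.
#'
#' @param tracks Track tibble (`track_id, frame, x_um, y_um`).
#' @param psf_sd PSF standard deviation in pixels.
#' @param photons_per_spot Expected photons per localization.
#' @param background Expected background counts per pixel.
#' @param config A [sim_config()] (field size, pixel size, frame count).
#' @param noise Apply Poisson noise (`TRUE`) or render noiselessly.
#' @return Integer array `[ny, nx, n_frames]` of class `spt_movie` with
#'   attribute `pixel_size`.
#' @export
render_movie <- function(tracks, psf_sd, photons_per_spot, background, config,
                         noise = TRUE) {
  stopifnot(psf_sd > 0, photons_per_spot > 0, background >= 0)
  ps <- config$pixel_size
  nx <- ceiling(config$field_size[1] / ps)
  ny <- ceiling(config$field_size[2] / ps)
  nt <- config$n_frames
  stack <- array(background, dim = c(ny, nx, nt))
  if (nrow(tracks) > 0) {
    px <- tracks$x_um / ps; py <- tracks$y_um / ps
    keep <- px >= 0 & px < nx & py >= 0 & py < ny & tracks$frame < nt
    if (any(!keep)) {
      warning(sum(!keep), " localizations outside the field were clipped")
      px <- px[keep]; py <- py[keep]
    }
    fr <- tracks$frame[keep]
    w <- ceiling(4 * psf_sd)
    for (i in seq_along(px)) {
      cx <- floor(px[i]); cy <- floor(py[i])
      xs <- max(0, cx - w):min(nx - 1, cx + w)
      ys <- max(0, cy - w):min(ny - 1, cy + w)
      wx <- stats::pnorm(xs + 1, px[i], psf_sd) - stats::pnorm(xs, px[i], psf_sd)
      wy <- stats::pnorm(ys + 1, py[i], psf_sd) - stats::pnorm(ys, py[i], psf_sd)
      patch <- photons_per_spot * outer(wy, wx)
      stack[ys + 1, xs + 1, fr[i] + 1] <- stack[ys + 1, xs + 1, fr[i] + 1] + patch
    }
  }
  if (noise) stack[] <- stats::rpois(length(stack), lambda = stack)
  stack[] <- pmin(round(stack), 65535)
  structure(stack, pixel_size = ps, class = "spt_movie")
}

#' Track table input/output
#'
#' Tracks are stored as CSV with header `track_id,frame,x_um,y_um,channel`;
#' frames are 0-based integers and positions are in micrometres relative to
#' the field origin (top-left, x rightward, y downward).
#'
#' @param tracks Track tibble.
#' @param path File path.
#' @return `read_tracks()` returns the track tibble; `write_tracks()` its
#'   input, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(tracks[, c("track_id", "frame", "x_um", "y_um", "channel")], path)
  invisible(tracks)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    track_id = readr::col_integer(), frame = readr::col_integer(),
    x_um = readr::col_double(), y_um = readr::col_double(),
    channel = readr::col_character()))
}

#' Movie and mask TIFF input/output
#'
#' Movies are multi-page 16-bit grayscale TIFF; compartment masks are
#' single-page 8-bit TIFF with values 0/255.
#'
#' @param stack Array `[ny, nx, n_frames]` of counts (0..65535).
#' @param mask Binary matrix.
#' @param path File path.
#' @return Readers return the array/matrix; writers their input, invisibly.
#' @export
write_movie_tiff <- function(stack, path) {
  pages <- purrr::map(seq_len(dim(stack)[3]), ~ stack[, , .x] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(stack)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

#' @rdname write_movie_tiff
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(ifelse(mask > 0, 1, 0), path, bits.per.sample = 8L)
  invisible(mask)
}

#' @rdname write_movie_tiff
#' @export
read_mask_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  matrix(as.integer(img > 0.5), nrow = nrow(img), ncol = ncol(img))
}
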