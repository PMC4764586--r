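#' Pool radial displacements at a fixed lag
#'
#' For every track and every frame with a localization at both `t` and
#' `t + lag_frames` (overlapping windows), one radial displacement
#' `r = ||p(t+lag) - p(t)||` is emitted.
#'
#' @param tracks Track tibble (`track_id, frame, x_um, y_um`).
#' @param lag_frames Lag in frames (>= 1).
#' @param frame_interval Frame interval in seconds.
#' @return Tibble of class `displacement_set` with columns
#'   `track_id, frame, r` and attributes `lag` (seconds) and
#'   `frame_interval`.
#' @export
collect_displacements <- function(tracks, lag_frames = 1, frame_interval = 0.035) {
  stopifnot(lag_frames >= 1)
  a <- tracks[, c("track_id", "frame", "x_um", "y_um")]
  b <- dplyr::mutate(a, frame = .data$frame - as.integer(lag_frames))
  d <- dplyr::inner_join(a, b, by = c("track_id", "frame"),
                         suffix = c("", "_end")) |>
    dplyr::transmute(.data$track_id, .data$frame,
                     r = sqrt((.data$x_um_end - .data$x_um)^2 +
                              (.data$y_um_end - .data$y_um)^2))
  structure(d, lag = lag_frames * frame_interval,
            frame_interval = frame_interval, lag_frames = as.integer(lag_frames),
            class = c("displacement_set", class(d)))
}

#' Empirical CDF of a displacement set
#'
#' @param d A [collect_displacements()] result (or numeric vector of radial
#'   displacements).
#' @return A right-continuous, nondecreasing step function (class `ecdf`).
#' @export
empirical_cdf <- function(d) {
  r <- if (is.data.frame(d)) d$r else d
  if (length(r) == 0) stop("empty displacement set", call. = FALSE)
  stats::ecdf(r)
}

# Model CDFs of radial displacements for 2-D diffusion.
cdf_one_model <- function(r, D, dt) 1 - exp(-r^2 / (4 * D * dt))
cdf_two_model <- function(r, A, D_slow, D_fast, dt) {
  1 - (A * exp(-r^2 / (4 * D_slow * dt)) + (1 - A) * exp(-r^2 / (4 * D_fast * dt)))
}

# Fixed grid of 200 quantile points; the least-squares objective compares the
# model CDF with the empirical probabilities at these points, which makes the
# objective independent of sample size.
cdf_fit_grid <- function(r, n_grid = 200) {
  p <- (seq_len(n_grid) - 0.5) / n_grid
  list(r = as.numeric(stats::quantile(r, probs = p, names = FALSE)), p = p)
}

new_cdf_fit <- function(n_components, params, residual_ss, n, lag, flag = NULL) {
  structure(c(list(n_components = n_components), params,
              list(residual_ss = residual_ss, n = n, lag = lag, flag = flag)),
            class = "cdf_fit")
}

#' One-component CDF fit of the displacement distribution
#'
#' Fits `P(r) = 1 - exp(-r^2 / (4 D dt))` to the empirical displacement CDF
#' by least squares on a fixed grid of 200 quantile points. `D_app` is
#' bounded in `[1e-4, 10]` um^2/s. The coefficient is *apparent*:
#' localization error is not subtracted.
#'
#' @param d A [collect_displacements()] result.
#' @param n_grid Number of quantile grid points.
#' @return A `cdf_fit` object with fields `D_app`, `residual_ss`, `n`.
#' @export
fit_cdf_one <- function(d, n_grid = 200) {
  dt <- attr(d, "lag")
  r <- d$r
  if (length(r) < 100) stop("fit_cdf_one needs >= 100 displacements", call. = FALSE)
  g <- cdf_fit_grid(r, n_grid)
  obj <- function(logD) sum((cdf_one_model(g$r, exp(logD), dt) - g$p)^2)
  opt <- stats::optimize(obj, interval = log(c(1e-4, 10)), tol = 1e-12)
  new_cdf_fit(1L, list(D_app = exp(opt$minimum)), opt$objective, length(r), dt)
}

#' Two-component CDF fit (slow/fast deconvolution)
#'
#' Fits `P(r) = 1 - [A exp(-r^2/(4 D_slow dt)) + (1-A) exp(-r^2/(4 D_fast dt))]`
#' with `D_slow < D_fast` by least squares on the quantile grid. `A` is the
#' slow fraction. With `fix_D = c(D_slow, D_fast)` only `A` is fitted, which
#' supports deconvolving different conditions against one shared pair of
#' coefficients. With `fix_A` the mixture weight is held and only the
#' coefficients are fitted.
#'
#' @inheritParams fit_cdf_one
#' @param fix_D Optional length-2 vector `c(D_slow, D_fast)` held fixed.
#' @param fix_A Optional fixed slow fraction in `[0, 1]`.
#' @return A `cdf_fit` object with fields `A`, `D_slow`, `D_fast`; the fit is
#'   flagged `"boundary_A"` when the fitted mixture weight hits 0 or 1.
#' @export
fit_cdf_two <- function(d, fix_D = NULL, fix_A = NULL, n_grid = 200) {
  dt <- attr(d, "lag")
  r <- d$r
  if (length(r) < 1000 && is.null(fix_D) && is.null(fix_A))
    stop("fit_cdf_two needs >= 1000 displacements", call. = FALSE)
  g <- cdf_fit_grid(r, n_grid)
  sse <- function(A, Ds, Df) sum((cdf_two_model(g$r, A, Ds, Df, dt) - g$p)^2)

  if (!is.null(fix_A) && (fix_A == 0 || fix_A == 1)) {
    # degenerate mixture: one active component, same objective as the
    # one-component fit
    obj <- function(logD) {
      D <- exp(logD)
      if (fix_A == 0) sse(0, 1e-4, D) else sse(1, D, 10)
    }
    opt <- stats::optimize(obj, interval = log(c(1e-4, 10)), tol = 1e-12)
    D <- exp(opt$minimum)
    return(new_cdf_fit(2L, list(A = fix_A,
                                D_slow = if (fix_A == 1) D else 1e-4,
                                D_fast = if (fix_A == 0) D else 10),
                       opt$objective, length(r), dt))
  }
  if (!is.null(fix_D)) {
    stopifnot(length(fix_D) == 2, fix_D[1] < fix_D[2])
    if (!is.null(fix_A)) {
      return(new_cdf_fit(2L, list(A = fix_A, D_slow = fix_D[1], D_fast = fix_D[2]),
                         sse(fix_A, fix_D[1], fix_D[2]), length(r), dt))
    }
    opt <- stats::optimize(function(A) sse(A, fix_D[1], fix_D[2]),
                           interval = c(0, 1), tol = 1e-12)
    A <- opt$minimum
    flag <- if (A < 1e-3 || A > 1 - 1e-3) "boundary_A" else NULL
    return(new_cdf_fit(2L, list(A = A, D_slow = fix_D[1], D_fast = fix_D[2]),
                       opt$objective, length(r), dt, flag))
  }
  # free fit: A = plogis(a), D_slow = exp(b), D_fast = D_slow + exp(c)
  one <- fit_cdf_one(d, n_grid)
  obj <- function(p) {
    A <- stats::plogis(p[1]); Ds <- exp(p[2]); Df <- Ds + exp(p[3])
    if (Ds < 1e-4 || Df > 10) return(1e6)
    sse(A, Ds, Df)
  }
  starts <- list(
    c(0, log(one$D_app / 3), log(one$D_app * 2)),
    c(stats::qlogis(0.3), log(one$D_app / 4), log(one$D_app * 3)),
    c(stats::qlogis(0.7), log(one$D_app / 4), log(one$D_app * 3))
  )
  fits <- purrr::map(starts, ~ stats::optim(.x, obj, method = "Nelder-Mead",
                                            control = list(maxit = 2000,
                                                           reltol = 1e-12)))
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  A <- stats::plogis(best$par[1]); Ds <- exp(best$par[2]); Df <- Ds + exp(best$par[3])
  flag <- if (A < 1e-3 || A > 1 - 1e-3) "boundary_A" else NULL
  new_cdf_fit(2L, list(A = A, D_slow = Ds, D_fast = Df), best$value, length(r),
              dt, flag)
}

#' @export
print.cdf_fit <- function(x, ...) {
  if (x$n_components == 1) {
    cat(sprintf("One-component CDF fit: D_app = %.4f um^2/s (n = %d, SS = %.3g)\n",
                x$D_app, x$n, x$residual_ss))
  } else {
    cat(sprintf(
      "Two-component CDF fit: A(slow) = %.3f, D_slow = %.4f, D_fast = %.4f um^2/s (n = %d, SS = %.3g)\n",
      x$A, x$D_slow, x$D_fast, x$n, x$residual_ss))
  }
  if (!is.null(x$flag)) cat("  flagged:", x$flag, "\n")
  invisible(x)
}

#' Ensemble mean square displacement curve
#'
#' Per lag, the MSD is the mean of squared displacements pooled over all
#' tracks (overlapping windows). The standard error is computed over
#' per-track mean squared displacements, treating tracks as the independent
#' units.
#'
#' @param tracks Track tibble.
#' @param max_lag_frames Largest lag, in frames.
#' @param frame_interval Frame interval in seconds.
#' @return Tibble of class `msd_curve` with columns
#'   `lag` (s), `msd`, `sem` (um^2), `n` (displacements), `n_tracks`.
#' @export
msd_ensemble <- function(tracks, max_lag_frames, frame_interval = 0.035) {
  stopifnot(max_lag_frames >= 1)
  rows <- purrr::map(seq_len(max_lag_frames), function(lag) {
    d <- collect_displacements(tracks, lag, frame_interval)
    if (nrow(d) == 0) return(NULL)
    per_track <- dplyr::summarise(dplyr::group_by(d, .data$track_id),
                                  m = mean(.data$r^2), .groups = "drop")
    sem <- if (nrow(per_track) > 1)
      stats::sd(per_track$m) / sqrt(nrow(per_track)) else NA_real_
    tibble::tibble(lag = lag * frame_interval, msd = mean(d$r^2), sem = sem,
                   n = nrow(d), n_tracks = nrow(per_track))
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  structure(out, frame_interval = frame_interval,
            class = c("msd_curve", class(out)))
}

#' Per-track apparent diffusion coefficient
#'
#' `D_app = mean(r^2 at lag 1) / (4 dt)`, robust down to the 3-frame tracks
#' that dominate single-particle datasets. Tracks with fewer than 2 frames
#' carry no displacement and are dropped.
#'
#' @param tracks Track tibble.
#' @param frame_interval Frame interval in seconds.
#' @return Tibble `track_id, n_frames, D_app`.
#' @export
apparent_D <- function(tracks, frame_interval = 0.035) {
  d <- collect_displacements(tracks, 1, frame_interval)
  if (nrow(d) == 0) stop("no track with >= 2 frames", call. = FALSE)
  n_frames <- dplyr::count(tracks, .data$track_id, name = "n_frames")
  d |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(D_app = mean(.data$r^2) / (4 * frame_interval),
                     .groups = "drop") |>
    dplyr::left_join(n_frames, by = "track_id") |>
    dplyr::relocate("track_id", "n_frames")
}

#' Exploration area from an MSD plateau
#'
#' For corralled motion the long-lag MSD converges to a plateau whose value
#' is reported as the exploration area (for a reflecting square corral of
#' side `L` the equilibrium plateau is `L^2/3`). The plateau is estimated as
#' the mean MSD over the trailing `plateau_window` fraction of lags. If the
#' curve is still rising there (window slope above 10% of the initial
#' slope), the result is flagged `no_plateau`.
#'
#' @param msd A [msd_ensemble()] curve with at least 10 lags.
#' @param plateau_window Trailing fraction of lags used (default last third).
#' @return List of class `exploration_area` with `area` (um^2), `plateau`
#'   (logical; `FALSE` means flagged "no plateau"), and the window used.
#' @export
exploration_area <- function(msd, plateau_window = 1 / 3) {
  if (nrow(msd) < 10) stop("need an MSD curve with >= 10 lags", call. = FALSE)
  n <- nrow(msd)
  win <- seq.int(n - ceiling(plateau_window * n) + 1L, n)
  area <- mean(msd$msd[win])
  slope0 <- msd$msd[1] / msd$lag[1]
  slope_win <- unname(stats::coef(stats::lm(msd ~ lag, data = msd[win, ]))[2])
  structure(list(area = area, plateau = slope_win <= 0.1 * slope0,
                 window_lags = msd$lag[win],
                 window_slope = slope_win, initial_slope = slope0),
            class = "exploration_area")
}

#' @export
print.exploration_area <- function(x, ...) {
  cat(sprintf("Exploration area: %.4f um^2%s\n", x$area,
              if (x$plateau) "" else " [flagged: no plateau]"))
  invisible(x)
}

#' Track lifetimes
#'
#' The lifetime of an n-localization track is reported as `n * dt`, so a
#' 3-frame track at 35 ms frames lives 105 ms.
#'
#' @param tracks Track tibble.
#' @param frame_interval Frame interval in seconds.
#' @return Tibble `track_id, n_frames, lifetime_s`.
#' @export
track_lifetimes <- function(tracks, frame_interval = 0.035) {
  dplyr::count(tracks, .data$track_id, name = "n_frames") |>
    dplyr::mutate(lifetime_s = .data$n_frames * frame_interval)
}
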