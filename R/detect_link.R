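#' Detection and linking configuration
#'
#' Defaults reproduce a documented single-particle tracking recipe: a
#' Gaussian pre-filter with half-width-at-half-maximum 1.3 pixels, a robust
#' detection threshold, a maximum frame-to-frame displacement of 5 pixels and
#' a 3-frame minimum track length for export.
#'
#' @param filter_hwhm Half width at half maximum of the Gaussian pre-filter,
#'   pixels. The filter sd is `hwhm / sqrt(2*log(2))`.
#' @param detect_threshold Detection threshold as a multiple of the robust
#'   (MAD-based) background standard deviation of the filtered image.
#' @param max_disp Maximum frame-to-frame displacement for linking, pixels.
#' @param min_track_len Minimum number of localizations for an exported track.
#' @return An object of class `link_config`.
#' @export
link_config <- function(filter_hwhm = 1.3, detect_threshold = 5,
                        max_disp = 5, min_track_len = 3) {
  stopifnot(filter_hwhm > 0, detect_threshold > 0, max_disp > 0,
            min_track_len >= 1)
  structure(list(filter_hwhm = filter_hwhm, detect_threshold = detect_threshold,
                 max_disp = max_disp, min_track_len = as.integer(min_track_len)),
            class = "link_config")
}

gaussian_kernel <- function(sigma) {
  w <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-w:w, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

# Least-squares 2-D Gaussian refinement in a small window around a candidate
# maximum. Coordinates: pixel (row i, col j) of a matrix has centre
# x = j - 0.5, y = i - 0.5 (0-based continuous pixel coordinates).
fit_gaussian_spot <- function(img, ci, cj, sd0, win = 3L) {
  ny <- nrow(img); nx <- ncol(img)
  ri <- max(1, ci - win):min(ny, ci + win)
  rj <- max(1, cj - win):min(nx, cj + win)
  z <- img[ri, rj]
  ys <- ri - 0.5; xs <- rj - 0.5
  Y <- matrix(ys, length(ys), length(xs))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  bg0 <- min(z)
  amp0 <- max(z) - bg0
  obj <- function(p) {
    # p = (x0, y0, log amp, log sd, bg)
    mu <- exp(p[3]) * exp(-((X - p[1])^2 + (Y - p[2])^2) / (2 * exp(p[4])^2)) + p[5]
    sum((z - mu)^2)
  }
  p0 <- c(cj - 0.5, ci - 0.5, log(max(amp0, 1e-6)), log(sd0), bg0)
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  list(x = fit$par[1], y = fit$par[2], amplitude = exp(fit$par[3]),
       fit_sd = exp(fit$par[4]), background = fit$par[5],
       converged = fit$convergence == 0)
}

#' Detect sub-pixel particle positions in one frame
#'
#' The frame is background-subtracted (median), smoothed with a Gaussian
#' filter, and candidate local maxima above `detect_threshold` robust
#' standard deviations are refined by local least-squares 2-D Gaussian
#' fitting. Detections closer than twice the filter HWHM are merged to the
#' brighter one.
#'
#' @param frame Numeric matrix of counts (rows = y).
#' @param cfg A [link_config()].
#' @return Tibble with columns `x, y` (sub-pixel, 0-based pixel coordinates),
#'   `amplitude`, `fit_sd`, `background`.
#' @export
detect_spots <- function(frame, cfg = link_config()) {
  stopifnot(is.matrix(frame), all(frame >= 0))
  sigma <- cfg$filter_hwhm / sqrt(2 * log(2))
  bs <- frame - stats::median(frame)
  filt <- EBImage::filter2(bs, gaussian_kernel(sigma))
  thr <- cfg$detect_threshold * stats::mad(filt)
  ny <- nrow(filt); nx <- ncol(filt)
  if (ny < 3 || nx < 3 || thr <= 0) return(empty_detections())
  core <- filt[2:(ny - 1), 2:(nx - 1)]
  ismax <- core > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (core >= filt[2:(ny - 1) + di, 2:(nx - 1) + dj])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_detections())
  dets <- purrr::map(seq_len(nrow(idx)), function(k) {
    ci <- idx[k, 1] + 1L; cj <- idx[k, 2] + 1L
    fit <- fit_gaussian_spot(bs, ci, cj, sigma)
    tibble::tibble(x = fit$x, y = fit$y, amplitude = fit$amplitude,
                   fit_sd = fit$fit_sd, background = fit$background)
  }) |> purrr::list_rbind()
  dets <- dets[dets$amplitude > 0 & dets$x >= 0 & dets$x < nx &
                 dets$y >= 0 & dets$y < ny, ]
  merge_close_detections(dets, 2 * cfg$filter_hwhm)
}

empty_detections <- function() {
  tibble::tibble(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                 fit_sd = numeric(0), background = numeric(0))
}

merge_close_detections <- function(dets, min_sep) {
  if (nrow(dets) < 2) return(dets)
  ord <- order(-dets$amplitude)
  keep <- logical(nrow(dets))
  kept_x <- numeric(0); kept_y <- numeric(0)
  for (i in ord) {
    if (length(kept_x) == 0 ||
        all(sqrt((kept_x - dets$x[i])^2 + (kept_y - dets$y[i])^2) >= min_sep)) {
      keep[i] <- TRUE
      kept_x <- c(kept_x, dets$x[i]); kept_y <- c(kept_y, dets$y[i])
    }
  }
  dets[keep, ]
}

#' Detect spots in every frame of a movie stack
#'
#' @param stack Array `[ny, nx, n_frames]`.
#' @param cfg A [link_config()].
#' @return Tibble with a 0-based `frame` column prepended to the
#'   [detect_spots()] columns.
#' @export
detect_movie <- function(stack, cfg = link_config()) {
  purrr::map(seq_len(dim(stack)[3]), function(t) {
    d <- detect_spots(stack[, , t], cfg)
    if (nrow(d) > 0) d$frame <- t - 1L
    d
  }) |> purrr::list_rbind() |>
    (\(d) if (nrow(d) == 0) dplyr::mutate(empty_detections(), frame = integer(0))
          else dplyr::relocate(d, "frame"))()
}

#' Link detections into trajectories
#'
#' Frame-to-frame assignment is globally greedy by distance: all candidate
#' pairs between consecutive frames with distance at most `max_disp` are
#' sorted ascending (ties broken by lower detection index) and accepted when
#' both endpoints are still unused. Unmatched detections start new tracks;
#' there is no gap closing. Tracks shorter than `min_track_len` are dropped
#' on export.
#'
#' @param detections Tibble from [detect_movie()] (needs `frame, x, y`).
#' @param cfg A [link_config()].
#' @param pixel_size Pixel size in micrometres used to convert positions to
#'   `x_um, y_um`; use 1 to keep pixel units.
#' @param channel Channel label for the exported tracks.
#' @return Track tibble (`track_id, frame, x_um, y_um, channel`).
#' @export
link_tracks <- function(detections, cfg = link_config(), pixel_size = 1,
                        channel = "mrna") {
  if (nrow(detections) == 0) {
    return(tibble::tibble(track_id = integer(0), frame = integer(0),
                          x_um = numeric(0), y_um = numeric(0),
                          channel = character(0)))
  }
  detections <- dplyr::arrange(detections, .data$frame)
  detections$det_id <- seq_len(nrow(detections))
  detections$track_id <- NA_integer_
  next_track <- 0L
  frames <- sort(unique(detections$frame))
  by_frame <- split(seq_len(nrow(detections)), detections$frame)
  # first frame: every detection starts a track
  first <- by_frame[[as.character(frames[1])]]
  detections$track_id[first] <- next_track + seq_along(first)
  next_track <- next_track + length(first)
  if (length(frames) > 1) for (fi in 2:length(frames)) {
    prev <- if (frames[fi] - frames[fi - 1] == 1)
      by_frame[[as.character(frames[fi - 1])]] else integer(0)
    cur <- by_frame[[as.character(frames[fi])]]
    if (length(prev) > 0) {
      dx <- outer(detections$x[prev], detections$x[cur], `-`)
      dy <- outer(detections$y[prev], detections$y[cur], `-`)
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= cfg$max_disp, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        d <- dist[cand]
        ord <- order(d, cand[, 1], cand[, 2])
        used_p <- logical(length(prev)); used_c <- logical(length(cur))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_p[i] && !used_c[j]) {
            used_p[i] <- TRUE; used_c[j] <- TRUE
            detections$track_id[cur[j]] <- detections$track_id[prev[i]]
          }
        }
      }
    }
    new <- cur[is.na(detections$track_id[cur])]
    if (length(new) > 0) {
      detections$track_id[new] <- next_track + seq_along(new)
      next_track <- next_track + length(new)
    }
  }
  out <- detections |>
    dplyr::count(.data$track_id, name = "len") |>
    dplyr::filter(.data$len >= cfg$min_track_len) |>
    dplyr::inner_join(detections, by = "track_id") |>
    dplyr::transmute(track_id = dplyr::dense_rank(.data$track_id),
                     frame = as.integer(.data$frame),
                     x_um = .data$x * pixel_size, y_um = .data$y * pixel_size,
                     channel = channel) |>
    dplyr::arrange(.data$track_id, .data$frame)
  out
}
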