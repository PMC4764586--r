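#' All cross-channel pairwise distances per frame
#'
#' For every frame shared by both channels, emits all mRNA-ribosome
#' Euclidean distances.
#'
#' @param mrna,ribo Track/detection tibbles with `track_id, frame, x_um, y_um`.
#' @return Tibble `frame, mrna_id, ribo_id, d` (um).
#' @export
frame_distances <- function(mrna, ribo) {
  a <- dplyr::select(mrna, mrna_id = "track_id", "frame", ax = "x_um", ay = "y_um")
  b <- dplyr::select(ribo, ribo_id = "track_id", "frame", bx = "x_um", by = "y_um")
  dplyr::inner_join(a, b, by = "frame", relationship = "many-to-many") |>
    dplyr::transmute(.data$frame, .data$mrna_id, .data$ribo_id,
                     d = sqrt((.data$bx - .data$ax)^2 + (.data$by - .data$ay)^2))
}

#' Area-normalized distance distribution
#'
#' Histograms pair distances into annular bins and divides each count by the
#' annulus area `pi * (r_out^2 - r_in^2)`. Under spatial independence of the
#' two channels the normalized density is flat in `r` (up to edge effects);
#' a colocalizing subpopulation appears as a short-distance peak above the
#' flat baseline.
#'
#' @param distances Numeric vector of distances, or a [frame_distances()]
#'   tibble (column `d` is used).
#' @param bin_width Bin width, um.
#' @param r_max Largest distance binned, um.
#' @return Tibble of class `distance_distribution` with
#'   `r_in, r_out, r_mid, count, density`.
#' @export
normalized_distance_distribution <- function(distances, bin_width = 0.107,
                                             r_max = 3) {
  stopifnot(bin_width > 0, r_max > bin_width)
  d <- if (is.data.frame(distances)) distances$d else distances
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  idx <- findInterval(d[d >= 0 & d < r_max], edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  out <- tibble::tibble(r_in = edges[-length(edges)], r_out = edges[-1]) |>
    dplyr::mutate(r_mid = (.data$r_in + .data$r_out) / 2, count = counts,
                  density = counts / (pi * (.data$r_out^2 - .data$r_in^2)))
  structure(out, bin_width = bin_width, r_max = r_max, n = sum(counts),
            class = c("distance_distribution", class(out)))
}

max_consecutive_run <- function(frames) {
  # frames sorted unique; returns c(start, length) of the longest run of
  # consecutive integers (earliest wins ties)
  if (length(frames) == 0) return(c(NA_integer_, 0L))
  breaks <- c(0L, which(diff(frames) != 1L), length(frames))
  lens <- diff(breaks)
  k <- which.max(lens)
  c(frames[breaks[k] + 1L], lens[k])
}

#' Find co-moving trajectory pairs
#'
#' A pair of tracks (one per channel) qualifies as co-moving when there are
#' at least `min_frames` *consecutive* common frames in every one of which
#' their distance is at most `d_max` (320 nm and 3 frames = 105 ms by
#' default). The reported window is the maximal such run. A track may appear
#' in multiple pairs. The candidate search bins detections on a grid of cell
#' size `d_max` so complexity stays near-linear in detections.
#'
#' @param mrna,ribo Track tibbles with the same frame interval and
#'   coordinate frame.
#' @param d_max Maximum distance, um.
#' @param min_frames Minimum consecutive frames.
#' @return Tibble of class `comoving_pairs`:
#'   `mrna_id, ribo_id, start_frame, end_frame, n_frames, mean_d`.
#' @export
find_comoving <- function(mrna, ribo, d_max = 0.320, min_frames = 3) {
  stopifnot(d_max > 0, min_frames >= 1)
  empty <- tibble::tibble(mrna_id = integer(0), ribo_id = integer(0),
                          start_frame = integer(0), end_frame = integer(0),
                          n_frames = integer(0), mean_d = numeric(0))
  if (nrow(mrna) == 0 || nrow(ribo) == 0)
    return(structure(empty, class = c("comoving_pairs", class(empty))))
  a <- dplyr::transmute(mrna, mrna_id = .data$track_id, .data$frame,
                        ax = .data$x_um, ay = .data$y_um,
                        cx = floor(.data$x_um / d_max),
                        cy = floor(.data$y_um / d_max))
  b <- dplyr::transmute(ribo, ribo_id = .data$track_id, .data$frame,
                        bx = .data$x_um, by = .data$y_um,
                        cx = floor(.data$x_um / d_max),
                        cy = floor(.data$y_um / d_max))
  # expand ribosome detections into the 3x3 neighbourhood of grid cells
  neigh <- tidyr::expand_grid(dx = -1:1, dy = -1:1)
  b9 <- tidyr::crossing(b, neigh) |>
    dplyr::mutate(cx = .data$cx + .data$dx, cy = .data$cy + .data$dy)
  close <- dplyr::inner_join(a, b9, by = c("frame", "cx", "cy"),
                             relationship = "many-to-many") |>
    dplyr::mutate(d = sqrt((.data$bx - .data$ax)^2 + (.data$by - .data$ay)^2)) |>
    dplyr::filter(.data$d <= d_max) |>
    dplyr::distinct(.data$mrna_id, .data$ribo_id, .data$frame, .data$d)
  if (nrow(close) == 0)
    return(structure(empty, class = c("comoving_pairs", class(empty))))
  out <- close |>
    dplyr::group_by(.data$mrna_id, .data$ribo_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) {
      run <- max_consecutive_run(g$frame)
      if (run[2] < min_frames) return(tibble::tibble())
      win <- g$frame >= run[1] & g$frame < run[1] + run[2]
      tibble::tibble(start_frame = run[1],
                     end_frame = run[1] + run[2] - 1L,
                     n_frames = run[2], mean_d = mean(g$d[win]))
    }) |>
    dplyr::ungroup()
  structure(out, d_max = d_max, min_frames = as.integer(min_frames),
            class = c("comoving_pairs", class(out)))
}

#' Diffusion analysis of co-moving vs free subsets
#'
#' Splits each channel into tracks that participate in at least one
#' co-moving pair and those that do not, and runs the displacement-CDF fits,
#' ensemble MSD and exploration-area analyses on each subset.
#'
#' @param pairs A [find_comoving()] result.
#' @param mrna,ribo Track tibbles.
#' @param frame_interval Frame interval, seconds.
#' @param max_lag_frames Largest MSD lag in frames.
#' @param fix_D Optional shared `c(D_slow, D_fast)` for two-component fits.
#' @return List of class `comoving_report`, one element per channel, each
#'   with `comoving` and `free` sub-analyses (marked underpowered when
#'   displacements are scarce).
#' @export
comoving_subset_analysis <- function(pairs, mrna, ribo, frame_interval = 0.035,
                                     max_lag_frames = 12, fix_D = NULL) {
  analyse <- function(tr) {
    if (nrow(tr) == 0)
      return(list(n_tracks = 0L, n_displacements = 0L, underpowered = TRUE))
    d <- collect_displacements(tr, 1, frame_interval)
    underpowered <- nrow(d) < 100
    msd <- msd_ensemble(tr, max_lag_frames, frame_interval)
    list(n_tracks = length(unique(tr$track_id)), n_displacements = nrow(d),
         underpowered = underpowered,
         cdf1 = if (!underpowered) fit_cdf_one(d) else NULL,
         cdf2 = if (nrow(d) >= 1000 || (!underpowered && !is.null(fix_D)))
           tryCatch(fit_cdf_two(d, fix_D = fix_D), error = function(e) NULL)
           else NULL,
         msd = msd,
         exploration = if (nrow(msd) >= 10)
           tryCatch(exploration_area(msd), error = function(e) NULL) else NULL)
  }
  split_channel <- function(tr, ids) {
    list(comoving = analyse(tr[tr$track_id %in% ids, ]),
         free = analyse(tr[!(tr$track_id %in% ids), ]))
  }
  structure(list(mrna = split_channel(mrna, unique(pairs$mrna_id)),
                 ribosome = split_channel(ribo, unique(pairs$ribo_id)),
                 n_pairs = nrow(pairs)),
            class = "comoving_report")
}

#' Colocalization percentage
#'
#' Share of trajectories that colocalize with a reference structure,
#' in percent: e.g. 33 of 215 trajectories give 15.4%.
#'
#' @param n_colocalized,n_total Trajectory counts.
#' @return Percentage.
#' @export
colocalization_percent <- function(n_colocalized, n_total) {
  stopifnot(n_total > 0, n_colocalized >= 0, n_colocalized <= n_total)
  100 * n_colocalized / n_total
}
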