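#' Gridded local apparent-diffusion heat map
#'
#' Each lag-1 displacement is assigned to every grid node within
#' `capture_radius` of its origin point ("originating within" the capture
#' disc); the node value is `mean(r^2) / (4 dt)` over the assigned
#' displacements. Nodes with fewer than `min_displacements` are left
#' undefined. Because the capture radius (80 nm) exceeds the grid spacing
#' (20 nm), one displacement contributes to several nodes, which acts as
#' implied smoothing.
#'
#' @param tracks Track tibble in micrometres with uniform frame interval.
#' @param grid_spacing Node spacing, um.
#' @param capture_radius Capture radius about each node, um.
#' @param min_displacements Minimum displacements for a defined node.
#' @param frame_interval Frame interval, seconds.
#' @return Tibble of class `diffusion_map` with columns
#'   `node_x, node_y` (um), `D` (um^2/s), `n` (assigned displacements);
#'   undefined nodes are absent.
#' @export
local_diffusion_map <- function(tracks, grid_spacing = 0.020,
                                capture_radius = 0.080, min_displacements = 5,
                                frame_interval = 0.035) {
  stopifnot(grid_spacing > 0, capture_radius > 0, min_displacements >= 1)
  a <- tracks[, c("track_id", "frame", "x_um", "y_um")]
  b <- dplyr::mutate(a, frame = .data$frame - 1L)
  disp <- dplyr::inner_join(a, b, by = c("track_id", "frame"),
                            suffix = c("", "_end")) |>
    dplyr::transmute(x0 = .data$x_um, y0 = .data$y_um,
                     r2 = (.data$x_um_end - .data$x_um)^2 +
                          (.data$y_um_end - .data$y_um)^2)
  if (nrow(disp) == 0) {
    out <- tibble::tibble(node_x = numeric(0), node_y = numeric(0),
                          D = numeric(0), n = integer(0))
    return(structure(out, grid_spacing = grid_spacing,
                     capture_radius = capture_radius,
                     class = c("diffusion_map", class(out))))
  }
  # nodes at integer multiples of grid_spacing; enumerate the fixed offset
  # pattern around each displacement origin and keep nodes inside the disc
  reach <- ceiling(capture_radius / grid_spacing)
  offs <- expand.grid(di = -reach:reach, dj = -reach:reach)
  base_i <- round(disp$x0 / grid_spacing)
  base_j <- round(disp$y0 / grid_spacing)
  hits <- purrr::map(seq_len(nrow(offs)), function(k) {
    ni <- base_i + offs$di[k]; nj <- base_j + offs$dj[k]
    nx <- ni * grid_spacing; ny <- nj * grid_spacing
    ok <- (nx - disp$x0)^2 + (ny - disp$y0)^2 <= capture_radius^2
    if (!any(ok)) return(NULL)
    tibble::tibble(ni = ni[ok], nj = nj[ok], r2 = disp$r2[ok])
  }) |> purrr::list_rbind()
  out <- hits |>
    dplyr::group_by(.data$ni, .data$nj) |>
    dplyr::summarise(D = mean(.data$r2) / (4 * frame_interval),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= min_displacements) |>
    dplyr::transmute(node_x = .data$ni * grid_spacing,
                     node_y = .data$nj * grid_spacing, .data$D, .data$n)
  structure(out, grid_spacing = grid_spacing, capture_radius = capture_radius,
            min_displacements = min_displacements,
            class = c("diffusion_map", class(out)))
}

#' Localization density map
#'
#' 2-D histogram of all localizations (not tracks) on half-open bins
#' `[k*b, (k+1)*b)`, so every localization is counted in exactly one bin and
#' total counts equal the number of input localizations.
#'
#' @param localizations Tibble with `x_um, y_um` (a track table works).
#' @param bin_size Bin side, um.
#' @return Tibble of class `density_map` with `bin_x, bin_y` (bin lower-left
#'   corner, um) and `count`.
#' @export
density_map <- function(localizations, bin_size) {
  stopifnot(bin_size > 0)
  out <- localizations |>
    dplyr::transmute(bx = floor(.data$x_um / bin_size),
                     by = floor(.data$y_um / bin_size)) |>
    dplyr::count(.data$bx, .data$by, name = "count") |>
    dplyr::transmute(bin_x = .data$bx * bin_size, bin_y = .data$by * bin_size,
                     .data$count)
  structure(out, bin_size = bin_size, class = c("density_map", class(out)))
}

#' Write a map to CSV
#'
#' @param map A `diffusion_map` or `density_map` tibble.
#' @param path File path.
#' @return The map, invisibly.
#' @export
write_map_csv <- function(map, path) {
  readr::write_csv(tibble::as_tibble(map), path)
  invisible(map)
}
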