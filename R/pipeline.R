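#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> diffusion analysis -> mapping ->
#' compartments -> co-movement -> HMM, in dependency order, from one
#' declarative configuration list. Identical configuration (including seed)
#' yields identical report artifacts.
#'
#' @param config Named list with elements:
#'   \describe{
#'     \item{seed}{integer seed recorded in the report.}
#'     \item{frame_interval, pixel_size}{physical constants (seconds, um).}
#'     \item{simulate}{optional list: `scenario` one of `"brownian"`,
#'       `"two_state"`, `"confined"`, `"adhesion_field"`, `"comoving"` plus
#'       the matching [simulate_tracks()], [simulate_adhesion_field()] or
#'       [simulate_comoving_channels()] arguments and `sim_config` fields.}
#'     \item{tracks_csv}{optional path to a track CSV ingested instead of
#'       simulating.}
#'     \item{stages}{character vector of analysis stages to run, any of
#'       `"diffuse"`, `"map"`, `"compartments"`, `"comove"`, `"hmm"`.}
#'     \item{diffuse, map, compartments, comove, hmm}{optional per-stage
#'       parameter lists passed to the module functions.}
#'     \item{out_dir}{optional directory; tables and JSON records are
#'       written there.}
#'   }
#' @return List of class `analysis_report` with one element per executed
#'   stage plus `provenance` (config hash, package version, seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  dt <- config$frame_interval %||% 0.035
  ps <- config$pixel_size %||% 0.107
  stages <- config$stages %||% character(0)
  report <- list()
  sim <- NULL
  mask_obj <- NULL

  if (!is.null(config$simulate)) {
    sc <- config$simulate
    cfg <- sim_config(
      frame_interval = dt, pixel_size = ps,
      field_size = sc$field_size %||% c(20, 20),
      n_frames = sc$n_frames %||% 100,
      localization_sd = sc$localization_sd %||% 0,
      mean_track_length = sc$mean_track_length,
      seed = config$seed)
    sim <- switch(sc$scenario %||% "brownian",
      brownian = simulate_tracks(cfg, motion_brownian(sc$D %||% 0.2),
                                 sc$n_tracks %||% 500),
      two_state = simulate_tracks(
        cfg, motion_two_state(sc$D1 %||% 0.4, sc$D2 %||% 0.1,
                              sc$k12 %||% 2, sc$k21 %||% 2),
        sc$n_tracks %||% 500),
      confined = simulate_tracks(
        cfg, motion_confined(sc$D %||% 0.4, sc$corral_side %||% 0.548),
        sc$n_tracks %||% 500),
      adhesion_field = simulate_adhesion_field(
        cfg, sc$n_adhesions %||% 6, sc$adhesion_size %||% 1,
        sc$D_near %||% 0.1, sc$D_far %||% 0.4,
        n_tracks = sc$n_tracks %||% 500),
      comoving = simulate_comoving_channels(
        cfg, sc$n_mrna %||% 400, sc$n_ribo %||% 100,
        sc$comoving_fraction %||% 0.05, sc$pair_offset_sd %||% 0.05,
        motion_two_state(sc$D1 %||% 0.4, sc$D2 %||% 0.1,
                         sc$k12 %||% 2, sc$k21 %||% 2),
        motion_brownian(sc$D_free %||% 0.4)),
      stop("unknown scenario: ", sc$scenario, call. = FALSE))
    tracks <- sim$tracks
    if (!is.null(sim$mask)) mask_obj <- as_compartment_mask(sim$mask, ps)
    report$simulate <- list(n_tracks = length(unique(tracks$track_id)),
                            n_localizations = nrow(tracks),
                            scenario = sc$scenario %||% "brownian")
  } else if (!is.null(config$tracks_csv)) {
    tracks <- read_tracks(config$tracks_csv)
  } else {
    stop("config needs either $simulate or $tracks_csv", call. = FALSE)
  }

  mrna <- tracks[tracks$channel == "mrna", ]
  ribo <- tracks[tracks$channel == "ribosome", ]
  main <- if (nrow(mrna) > 0) mrna else tracks

  if ("diffuse" %in% stages) {
    pars <- config$diffuse %||% list()
    d <- collect_displacements(main, 1, dt)
    msd <- msd_ensemble(main, pars$max_lag_frames %||% 12, dt)
    report$diffuse <- list(
      cdf1 = if (nrow(d) >= 100) fit_cdf_one(d) else NULL,
      cdf2 = if (nrow(d) >= 1000 || !is.null(pars$fix_D))
        tryCatch(fit_cdf_two(d, fix_D = pars$fix_D), error = function(e) NULL)
        else NULL,
      msd = msd,
      exploration = if (nrow(msd) >= 10) exploration_area(msd) else NULL,
      lifetimes = track_lifetimes(main, dt),
      n_displacements = nrow(d))
  }
  if ("map" %in% stages) {
    pars <- config$map %||% list()
    report$map <- list(
      diffusion = local_diffusion_map(
        main, pars$grid_spacing %||% 0.020, pars$capture_radius %||% 0.080,
        pars$min_displacements %||% 5, dt),
      density = density_map(main, pars$bin_size %||% 0.05))
  }
  if ("compartments" %in% stages && !is.null(mask_obj)) {
    pars <- config$compartments %||% list()
    part <- partition_tracks(main, mask_obj,
                             pars$dilation_radius %||% 0.160,
                             pars$min_inside_fraction %||% 0)
    report$compartments <- list(
      partition = part,
      report = if (all(table(part$label) > 0))
        tryCatch(compare_compartments(main, part, dt,
                                      fix_D = pars$fix_D),
                 error = function(e) NULL) else NULL)
  }
  if ("comove" %in% stages && nrow(ribo) > 0) {
    pars <- config$comove %||% list()
    pairs <- find_comoving(mrna, ribo, pars$d_max %||% 0.320,
                           pars$min_frames %||% 3)
    dist <- frame_distances(mrna, ribo)
    report$comove <- list(
      pairs = pairs,
      distance_distribution = normalized_distance_distribution(
        dist, pars$bin_width %||% ps, pars$r_max %||% 3),
      subsets = if (nrow(pairs) > 0)
        comoving_subset_analysis(pairs, mrna, ribo, dt) else NULL)
  }
  if ("hmm" %in% stages) {
    pars <- config$hmm %||% list()
    hmm_tracks <- if (!is.null(pars$channel) && pars$channel == "ribosome")
      ribo else main
    model <- select_model(hmm_tracks, pars$K_candidates %||% c(1, 2),
                          pars$n_restarts %||% 3, config$seed, dt)
    ann <- annotate_states(hmm_tracks, model)
    report$hmm <- list(model = model, annotation = ann,
                       durations = duration_histograms(ann),
                       durations_internal = duration_histograms(ann, TRUE))
  }

  report$provenance <- list(
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("sptmap")),
    seed = config$seed, frame_interval = dt, pixel_size = ps)
  out <- structure(report, class = "analysis_report")
  if (!is.null(config$out_dir)) write_report_files(out, tracks, config$out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report_files <- function(report, tracks, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks(tracks, file.path(out_dir, "tracks.csv"))
  if (!is.null(report$diffuse)) {
    readr::write_csv(tibble::as_tibble(report$diffuse$msd),
                     file.path(out_dir, "msd.csv"))
    if (!is.null(report$diffuse$cdf1))
      fit_to_json(report$diffuse$cdf1, file.path(out_dir, "cdf_fit_one.json"))
    if (!is.null(report$diffuse$cdf2))
      fit_to_json(report$diffuse$cdf2, file.path(out_dir, "cdf_fit_two.json"))
  }
  if (!is.null(report$map))
    write_map_csv(report$map$diffusion, file.path(out_dir, "diffusion_map.csv"))
  if (!is.null(report$comove))
    readr::write_csv(tibble::as_tibble(report$comove$pairs),
                     file.path(out_dir, "comoving_pairs.csv"))
  if (!is.null(report$hmm)) {
    fit_to_json(report$hmm$model, file.path(out_dir, "hmm_model.json"))
    readr::write_csv(report$hmm$annotation$steps,
                     file.path(out_dir, "state_annotation.csv"))
  }
  writeLines(jsonlite::toJSON(report$provenance, auto_unbox = TRUE),
             file.path(out_dir, "provenance.json"))
  invisible(report)
}

#' Render an analysis report as a Markdown document
#'
#' @param report An [run_pipeline()] result.
#' @param path Optional file path to write the document to.
#' @return Character vector of Markdown lines (invisibly when written).
#' @export
make_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  pv <- report$provenance
  lines <- c("# Single-particle tracking analysis report", "",
             sprintf("- config hash: `%s`", pv$config_hash),
             sprintf("- package version: %s; seed: %s", pv$package_version,
                     pv$seed %||% "none"),
             sprintf("- frame interval: %g s; pixel size: %g um",
                     pv$frame_interval, pv$pixel_size), "")
  missing_sections <- character(0)
  if (!is.null(report$simulate)) {
    lines <- c(lines, "## Simulation", "",
               sprintf("- scenario `%s`: %d tracks, %d localizations",
                       report$simulate$scenario, report$simulate$n_tracks,
                       report$simulate$n_localizations), "")
  }
  if (!is.null(report$diffuse)) {
    dd <- report$diffuse
    lines <- c(lines, "## Diffusion", "",
               sprintf("- %d lag-1 displacements", dd$n_displacements))
    if (!is.null(dd$cdf1))
      lines <- c(lines, sprintf("- one-component fit: D_app = %.4f um^2/s",
                                dd$cdf1$D_app))
    if (!is.null(dd$cdf2))
      lines <- c(lines, sprintf(
        "- two-component fit: A(slow) = %.3f, D_slow = %.3f, D_fast = %.3f um^2/s",
        dd$cdf2$A, dd$cdf2$D_slow, dd$cdf2$D_fast))
    if (!is.null(dd$exploration))
      lines <- c(lines, sprintf("- exploration area: %.4f um^2%s",
                                dd$exploration$area,
                                if (dd$exploration$plateau) ""
                                else " (no plateau)"))
    lines <- c(lines, "")
  } else missing_sections <- c(missing_sections, "diffuse")
  if (!is.null(report$compartments) && !is.null(report$compartments$report)) {
    cr <- report$compartments$report
    lines <- c(lines, "## Compartments", "",
               "| class | tracks | D_app (1-comp) | slow fraction |",
               "|---|---|---|---|",
               sprintf("| adhesion | %d | %s | %s |", cr$adhesion$n_tracks,
                       fmt_or_na(cr$adhesion$cdf1$D_app),
                       fmt_or_na(cr$adhesion$cdf2$A)),
               sprintf("| non-adhesion | %d | %s | %s |",
                       cr$non_adhesion$n_tracks,
                       fmt_or_na(cr$non_adhesion$cdf1$D_app),
                       fmt_or_na(cr$non_adhesion$cdf2$A)),
               sprintf("- percent slowdown: %.1f%%", cr$percent_slowdown), "")
  }
  if (!is.null(report$comove)) {
    lines <- c(lines, "## Co-movement", "",
               sprintf("- %d co-moving pairs", nrow(report$comove$pairs)), "")
  }
  if (!is.null(report$hmm)) {
    m <- report$hmm$model
    lines <- c(lines, "## Motion states", "",
               sprintf("- selected K = %d (BIC %.1f)", m$K, m$BIC))
    for (k in seq_len(m$K))
      lines <- c(lines, sprintf(
        "- state %d: D = %.4f um^2/s, occupancy %.2f, lifetime %.2f s",
        k, m$D[k], m$occupancy[k], m$lifetimes_s[k]))
    lines <- c(lines, "")
  }
  if (length(missing_sections) > 0)
    lines <- c(lines, sprintf("*(sections not run: %s)*",
                              paste(missing_sections, collapse = ", ")), "")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

fmt_or_na <- function(x) if (is.null(x)) "NA" else sprintf("%.3f", x)

#' @export
print.analysis_report <- function(x, ...) {
  cat(make_report(x), sep = "\n")
  invisible(x)
}
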