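# End-to-end orchestration: simulate -> detect -> track -> mask -> fit ->
# quantify -> report.

# rolling polynomial hash of a deparsed object (mod 2^31 - 1); keeps
# reports traceable to their configuration without external dependencies
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in s) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

default_pipeline_config <- function() {
  list(
    layout = list(n_rows = 4, n_cols = 4, radius = 1, spacing = 3,
                  pixel_size = 0.16, alternating = TRUE),
    sim = list(),                       # overrides for sim_config()
    detection = list(snr_threshold = 5),
    tracking = list(max_disp = NULL, gap_max = 0),
    fit = list(truncation = 0.005),
    seed = 1L
  )
}

load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- default_pipeline_config()
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && nm %in% names(cfg))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], config[[nm]])
    else cfg[[nm]] <- config[[nm]]
  }
  cfg
}

#' Run a fully simulated experiment through the analysis chain
#'
#' Generates a micropatterned layout and ground-truth binding events,
#' optionally renders and re-detects a TIRF movie, links trajectories,
#' builds corral masks from the (pre- and post-contact) ligand channel,
#' computes per-region dwell-time fits and on-rates, and reports estimates
#' next to the configured ground truth.
#'
#' @param config a configuration list or path to a YAML file. Recognized
#'   sections: \code{layout} (arguments of
#'   \code{\link{make_pattern_layout}}), \code{sim} (overrides for
#'   \code{\link{sim_config}}), \code{detection}, \code{tracking},
#'   \code{fit}, and a top-level \code{seed}.
#' @param render if \code{TRUE} (default) the movie is rendered and spots
#'   are re-detected; if \code{FALSE} the ground-truth per-frame positions
#'   feed the tracker directly (fast path for kinetics-only studies).
#' @param report_path optional path; when set the report is written as JSON.
#' @return a \code{run_report} list: configuration echo and hash, seed,
#'   per-region ground truth and estimates (tau1, tau2, k_on, molecule
#'   counts), detection/tracking diagnostics, and package version.
#' @export
run_simulated_experiment <- function(config = list(), render = TRUE,
                                     report_path = NULL) {
  pc <- load_pipeline_config(config)
  lay <- do.call(make_pattern_layout, pc$layout)
  scfg <- do.call(sim_config, c(pc$sim, list(seed = pc$seed)))
  px <- attr(lay, "pixel_size_um")
  events <- simulate_binding_events(lay, scfg)
  with_seed(pc$seed + 1L, {
    ligand_pre <- render_ligand_channel(lay, scfg$ligand_density,
                                        clustered_fraction = 0)
    ligand_post <- render_ligand_channel(lay, scfg$ligand_density,
                                         clustered_fraction =
                                           scfg$clustered_fraction)
    if (render) {
      movie <- render_movie(events, lay, scfg)
      loc <- detect_movie(movie, scfg$psf_sigma,
                          pc$detection$snr_threshold)
    } else {
      loc <- data.frame(frame = events$positions$frame,
                        x = events$positions$x_um / px,
                        y = events$positions$y_um / px)
    }
    max_disp <- pc$tracking$max_disp
    if (is.null(max_disp)) max_disp <- 2 * scfg$psf_sigma
    tracks <- link_trajectories(loc, max_disp = max_disp,
                                gap_max = pc$tracking$gap_max)
    mask <- segment_corrals(ligand_pre, expected_radius = pc$layout$radius,
                            pixel_size = px)
    if (mask$status == "ok")
      mask <- classify_corral_mobility(ligand_post, mask)
    else
      mask <- layout_to_mask(lay, ligand_pre)
    tracks <- assign_region(tracks, mask)
    samples <- compute_dwell_times(tracks, scfg$dt, scfg$n_frames)
    samples <- samples[names(samples) %in% c("mobile", "immobile")]
    fits <- lapply(samples, function(s) {
      fit_two_exponential(survival_curve(s, pc$fit$truncation))
    })
    kon <- estimate_kon(tracks, mask, duration = scfg$n_frames * scfg$dt)
    regions <- names(fits)
    estimates <- lapply(regions, function(rg) {
      list(tau1_s = fits[[rg]]$tau1, tau2_s = fits[[rg]]$tau2,
           k_off_per_s = 1 / fits[[rg]]$tau2,
           k_on = kon$k_on[kon$region_class == rg],
           n_molecules = sum(!samples[[rg]]$censored))
    })
    names(estimates) <- regions
    truth <- lapply(regions, function(rg) {
      list(tau1_s = scfg$tau1[[rg]], tau2_s = scfg$tau2[[rg]],
           k_on = scfg$k_on[[rg]], f1 = scfg$f1[[rg]], k_b = scfg$k_b)
    })
    names(truth) <- regions
    report <- list(
      config = pc, config_hash = config_hash(pc), seed = pc$seed,
      rendered = render,
      n_events = nrow(events$events), n_localizations = nrow(loc),
      n_tracks = length(unique(tracks$track_id)),
      n_corrals_masked = nrow(mask$info),
      ground_truth = truth, estimates = estimates,
      version = as.character(utils::packageVersion("corralspt")))
    class(report) <- "run_report"
    if (!is.null(report_path)) write_run_report(report, report_path)
    report
  })
}

#' Run the measurement chain on externally supplied data
#'
#' The same chain as \code{\link{run_simulated_experiment}} without
#' simulation: accepts a movie (multi-page TIFF path or
#' \code{frame_stack}), or precomputed localization/trajectory tables to
#' re-enter the pipeline mid-stream, plus a ligand image or a ready-made
#' mask.
#'
#' @param config configuration list or YAML path; must provide
#'   \code{frame_interval} (s) and \code{pixel_size} (µm/px) unless a
#'   \code{frame_stack} with metadata is supplied.
#' @param movie path to a TIFF movie or a \code{frame_stack}.
#' @param localizations optional localization data.frame or CSV path
#'   (columns \code{frame}, \code{x}, \code{y}, pixels).
#' @param trajectories optional linked-track data.frame or CSV path
#'   (adds \code{track_id}).
#' @param ligand_image optional matrix or TIFF path used to build the mask.
#' @param mask optional \code{region_mask}, overrides segmentation.
#' @param report_path optional JSON output path.
#' @return a \code{run_report} with per-region dwell fits and on-rates.
#' @export
run_measurement <- function(config = list(), movie = NULL,
                            localizations = NULL, trajectories = NULL,
                            ligand_image = NULL, mask = NULL,
                            report_path = NULL) {
  pc <- load_pipeline_config(config)
  dt <- pc$frame_interval
  px <- pc$pixel_size
  if (inherits(movie, "frame_stack")) {
    if (is.null(dt)) dt <- attr(movie, "dt")
    if (is.null(px)) px <- attr(movie, "pixel_size_um")
  }
  if (is.null(dt) || is.null(px))
    stop("configuration error: frame_interval and pixel_size are required")
  if (is.character(ligand_image))
    ligand_image <- tiff::readTIFF(ligand_image)
  if (is.null(mask)) {
    if (is.null(ligand_image))
      stop("either a mask or a ligand image must be supplied")
    mask <- segment_corrals(ligand_image, expected_radius = pc$layout$radius,
                            pixel_size = px)
    mask <- classify_corral_mobility(ligand_image, mask)
  }
  if (!is.null(trajectories)) {
    tracks <- if (is.character(trajectories))
      utils::read.csv(trajectories) else trajectories
  } else {
    if (is.null(localizations)) {
      if (is.null(movie)) stop("no movie, localizations or trajectories given")
      if (is.character(movie))
        movie <- read_frame_stack(movie, dt = dt, pixel_size = px)
      psf_sigma <- if (!is.null(pc$sim$psf_sigma)) pc$sim$psf_sigma else 0.8
      localizations <- detect_movie(movie, psf_sigma,
                                    pc$detection$snr_threshold)
    } else if (is.character(localizations)) {
      localizations <- utils::read.csv(localizations)
    }
    psf_sigma <- if (!is.null(pc$sim$psf_sigma)) pc$sim$psf_sigma else 0.8
    max_disp <- pc$tracking$max_disp
    if (is.null(max_disp)) max_disp <- 2 * psf_sigma
    tracks <- link_trajectories(localizations, max_disp = max_disp,
                                gap_max = pc$tracking$gap_max)
  }
  n_frames <- if (!is.null(pc$n_frames)) pc$n_frames else max(tracks$frame) + 1L
  if (!"region_class" %in% names(tracks))
    tracks <- assign_region(tracks, mask)
  samples <- compute_dwell_times(tracks, dt, n_frames)
  samples <- samples[names(samples) %in% c("mobile", "immobile")]
  fits <- lapply(samples, function(s)
    fit_two_exponential(survival_curve(s, pc$fit$truncation)))
  kon <- estimate_kon(tracks, mask, duration = n_frames * dt)
  estimates <- lapply(names(fits), function(rg) {
    list(tau1_s = fits[[rg]]$tau1, tau2_s = fits[[rg]]$tau2,
         k_off_per_s = 1 / fits[[rg]]$tau2,
         k_on = kon$k_on[kon$region_class == rg],
         n_molecules = sum(!samples[[rg]]$censored))
  })
  names(estimates) <- names(fits)
  report <- list(config = pc, config_hash = config_hash(pc),
                 seed = pc$seed, rendered = !is.null(movie),
                 n_tracks = length(unique(tracks$track_id)),
                 n_corrals_masked = nrow(mask$info),
                 estimates = estimates,
                 version = as.character(utils::packageVersion("corralspt")))
  class(report) <- "run_report"
  if (!is.null(report_path)) write_run_report(report, report_path)
  report
}

#' Write a run report as JSON
#'
#' @param report a \code{run_report}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
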