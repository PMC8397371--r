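#' Build a grid layout of micropatterned ligand corrals
#'
#' Constructs the geometric ground truth of a micropatterned substrate:
#' circular corrals of a single radius placed on a regular grid, each
#' classified as \code{"mobile"} (ligand on a fluid supported membrane,
#' can be clustered by the cell) or \code{"immobile"} (ligand grafted to a
#' polymer). In the alternating configuration classes follow a checkerboard
#' starting with \code{"mobile"} at row 1, column 1.
#'
#' @param n_rows,n_cols number of grid rows and columns.
#' @param radius corral radius in µm.
#' @param spacing center-to-center distance in µm; must exceed
#'   \code{2 * radius} so that disks are disjoint.
#' @param pixel_size camera pixel size in µm/pixel (stored for rendering).
#' @param alternating logical; if \code{TRUE} region classes alternate in
#'   checkerboard order, otherwise every corral is mobile.
#'
#' @return A \code{data.frame} of class \code{"pattern_layout"} with columns
#'   \code{corral_id}, \code{cx_um}, \code{cy_um}, \code{radius_um},
#'   \code{region_class}, and attributes \code{field_um} (width, height of
#'   the field in µm) and \code{pixel_size_um}.
#' @examples
#' lay <- make_pattern_layout(2, 2, radius = 2.5, spacing = 10)
#' table(lay$region_class)
#' @export
make_pattern_layout <- function(n_rows, n_cols, radius, spacing,
                                pixel_size = 0.16, alternating = TRUE) {
  stopifnot(n_rows >= 1, n_cols >= 1, radius > 0, pixel_size > 0)
  if (spacing <= 2 * radius)
    stop("corral disks would overlap: spacing (", spacing,
         ") must exceed 2 * radius (", 2 * radius, ")")
  ij <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  ij <- ij[order(ij$row, ij$col), , drop = FALSE]
  cx <- (ij$col - 0.5) * spacing
  cy <- (ij$row - 0.5) * spacing
  cls <- if (alternating) {
    ifelse((ij$row + ij$col) %% 2 == 0, "mobile", "immobile")
  } else rep("mobile", nrow(ij))
  layout <- data.frame(
    corral_id = seq_len(nrow(ij)),
    cx_um = cx, cy_um = cy,
    radius_um = radius,
    region_class = cls,
    stringsAsFactors = FALSE
  )
  attr(layout, "field_um") <- c(n_cols * spacing, n_rows * spacing)
  attr(layout, "pixel_size_um") <- pixel_size
  class(layout) <- c("pattern_layout", "data.frame")
  validate_pattern_layout(layout)
  layout
}

#' Validate a pattern layout
#'
#' Checks the layout invariants: positive radii, disks pairwise disjoint,
#' every disk fully inside the field, and region classes restricted to
#' \code{"mobile"}/\code{"immobile"}.
#'
#' @param layout a \code{pattern_layout}.
#' @return the layout, invisibly; errors if an invariant is violated.
#' @export
validate_pattern_layout <- function(layout) {
  stopifnot(inherits(layout, "pattern_layout"))
  if (any(layout$radius_um <= 0)) stop("corral radius must be positive")
  if (!all(layout$region_class %in% c("mobile", "immobile")))
    stop("region_class must be 'mobile' or 'immobile'")
  field <- attr(layout, "field_um")
  if (any(layout$cx_um - layout$radius_um < 0) ||
      any(layout$cy_um - layout$radius_um < 0) ||
      any(layout$cx_um + layout$radius_um > field[1]) ||
      any(layout$cy_um + layout$radius_um > field[2]))
    stop("every corral must lie fully inside the field")
  n <- nrow(layout)
  if (n > 1) {
    d <- as.matrix(stats::dist(cbind(layout$cx_um, layout$cy_um)))
    rsum <- outer(layout$radius_um, layout$radius_um, "+")
    diag(d) <- Inf
    if (any(d <= rsum)) stop("corral disks must be pairwise disjoint")
  }
  invisible(layout)
}

#' Simulation configuration for a synthetic single-molecule experiment
#'
#' Bundles the acquisition and generative parameters of a synthetic
#' sptPALM-style experiment. Defaults reproduce the acquisition used
#' throughout: 20 frames/s (\code{dt = 0.05} s), 1000 frames per movie, and
#' single-molecule appearance rates tuned so the active density inside
#' corrals is about 0.5 molecules/µm².
#'
#' Per-region parameters (\code{k_on}, \code{f1}, \code{tau1}, \code{tau2},
#' \code{D}, \code{ligand_density}) are length-2 named numeric vectors with
#' names \code{mobile} and \code{immobile}.
#'
#' @param dt frame interval in s.
#' @param n_frames number of frames in a movie.
#' @param k_on true per-region arrival rate, events/µm²/s.
#' @param f1 fraction of the fast dwell component per region.
#' @param tau1,tau2 fast and slow dwell time constants per region, s.
#' @param k_b photobleach rate, 1/s (0 disables bleaching).
#' @param D per-region diffusion coefficient, µm²/s (immobile default 0).
#' @param confine_radius confinement disk radius for mobile molecules, µm.
#' @param loc_jitter localization jitter standard deviation, µm, applied to
#'   every ground-truth position (models finite localization precision).
#' @param psf_sigma point-spread-function sigma in pixels.
#' @param photons expected photons per molecule per frame.
#' @param background camera background offset, counts/pixel.
#' @param read_noise camera read noise standard deviation, counts.
#' @param excess_noise logical; if \code{TRUE} shot-noise variance is doubled
#'   to approximate EMCCD excess noise (off by default).
#' @param ligand_density per-region ligand density, molecules/µm².
#' @param clustered_fraction fraction of mobile-corral ligand gathered into a
#'   single rim punctum after cell contact.
#' @param seed integer RNG seed recorded with the configuration; used by the
#'   simulators when set.
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(dt = 0.05, n_frames = 1000,
                       k_on = c(mobile = 2, immobile = 2),
                       f1 = c(mobile = 0.55, immobile = 0.55),
                       tau1 = c(mobile = 0.08, immobile = 0.08),
                       tau2 = c(mobile = 0.508, immobile = 0.451),
                       k_b = 0.2,
                       D = c(mobile = 0.05, immobile = 0),
                       confine_radius = 0.3,
                       loc_jitter = 0.03,
                       psf_sigma = 0.8,
                       photons = 500,
                       background = 100,
                       read_noise = 2,
                       excess_noise = FALSE,
                       ligand_density = c(mobile = 100, immobile = 100),
                       clustered_fraction = 0.95,
                       seed = NULL) {
  reg <- function(x) {
    if (length(x) == 1) x <- c(mobile = unname(x), immobile = unname(x))
    stopifnot(all(c("mobile", "immobile") %in% names(x)))
    x[c("mobile", "immobile")]
  }
  cfg <- list(dt = dt, n_frames = n_frames, k_on = reg(k_on), f1 = reg(f1),
              tau1 = reg(tau1), tau2 = reg(tau2), k_b = k_b, D = reg(D),
              confine_radius = confine_radius, loc_jitter = loc_jitter,
              psf_sigma = psf_sigma, photons = photons,
              background = background, read_noise = read_noise,
              excess_noise = excess_noise,
              ligand_density = reg(ligand_density),
              clustered_fraction = clustered_fraction, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg a \code{sim_config}.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (dt <= 0) stop("dt must be positive")
    if (n_frames < 1) stop("n_frames must be at least 1")
    if (any(f1 < 0 | f1 > 1)) stop("f1 must lie in [0, 1]")
    if (any(tau1 <= 0) || any(tau2 < tau1))
      stop("dwell constants must satisfy 0 < tau1 <= tau2")
    if (any(k_on < 0) || k_b < 0 || any(D < 0))
      stop("rates must be non-negative")
    if (photons <= 0 || psf_sigma <= 0) stop("photons and psf_sigma must be positive")
    if (clustered_fraction < 0 || clustered_fraction > 1)
      stop("clustered_fraction must lie in [0, 1]")
  })
  invisible(cfg)
}
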