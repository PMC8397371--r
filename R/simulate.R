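# Synthetic-data generators: binding events, dwell samples, movie rendering,
# ligand-channel images and corral intensity tables.

# run expr with a locally seeded RNG when seed is non-NULL, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Draw dwell times from a two-component exponential mixture
#'
#' Generates continuous true dwell times from
#' \code{f1 * Exp(mean tau1) + (1 - f1) * Exp(mean tau2)}, optionally
#' truncated by an independent exponential photobleach time with rate
#' \code{k_b}.
#'
#' @param n number of molecules.
#' @param f1 fraction of the fast component.
#' @param tau1,tau2 fast and slow mean dwell times, s.
#' @param k_b photobleach rate, 1/s; 0 disables bleaching.
#' @return numeric vector of dwell times in s.
#' @export
simulate_dwell_times <- function(n, f1, tau1, tau2, k_b = 0) {
  stopifnot(n >= 0, f1 >= 0, f1 <= 1, tau1 > 0, tau2 >= tau1, k_b >= 0)
  fast <- stats::runif(n) < f1
  tt <- stats::rexp(n, rate = 1 / ifelse(fast, tau1, tau2))
  if (k_b > 0) tt <- pmin(tt, stats::rexp(n, rate = k_b))
  tt
}

#' Quantize continuous dwell times to the acquisition frame grid
#'
#' A molecule arriving at a uniformly random phase within the frame interval
#' is observed in \code{ceil((T - u) / dt)} frames, where \code{u ~ U(0, dt)}
#' is the wait until its first frame; molecules never caught by a frame
#' (\code{T <= u}) are dropped. The observed dwell is the number of observed
#' frames times \code{dt}, so the smallest observable dwell is one frame.
#'
#' @param dwell numeric vector of continuous dwell times, s.
#' @param dt frame interval, s.
#' @param random_phase if \code{FALSE}, use \code{ceil(T / dt)} frames
#'   (molecule assumed to arrive exactly on a frame).
#' @return numeric vector of frame-quantized dwells (multiples of \code{dt}),
#'   one per observed molecule.
#' @export
quantize_dwells <- function(dwell, dt, random_phase = TRUE) {
  stopifnot(dt > 0, all(dwell >= 0))
  if (random_phase) {
    u <- stats::runif(length(dwell), 0, dt)
    k <- ceiling(pmax(dwell - u, 0) / dt)
  } else {
    k <- ceiling(dwell / dt)
  }
  k[k > 0] * dt
}

#' Construct a dwell-time sample
#'
#' Frame-quantized residence times for one (cell, region, species) group.
#'
#' @param times dwell times in s; each must be a positive multiple of
#'   \code{dt} (within numerical tolerance).
#' @param dt frame interval, s.
#' @param censored logical vector marking dwells truncated by the movie
#'   boundaries (excluded from fitting by default downstream).
#' @param cell_id,region_class,species optional labels.
#' @return a \code{data.frame} of class \code{"dwell_sample"} with columns
#'   \code{dwell_s} and \code{censored}; \code{dt} and the labels are stored
#'   as attributes.
#' @export
dwell_sample <- function(times, dt, censored = rep(FALSE, length(times)),
                         cell_id = NA, region_class = NA, species = NA) {
  stopifnot(dt > 0, length(censored) == length(times))
  k <- times / dt
  if (any(times <= 0) || any(abs(k - round(k)) > 1e-6))
    stop("dwell times must be positive integer multiples of dt")
  out <- data.frame(dwell_s = times, censored = censored)
  attr(out, "dt") <- dt
  attr(out, "cell_id") <- cell_id
  attr(out, "region_class") <- region_class
  attr(out, "species") <- species
  class(out) <- c("dwell_sample", "data.frame")
  out
}

# reflect positions into a disk of radius r centred at the origin
reflect_into_disk <- function(x, y, r) {
  d <- sqrt(x^2 + y^2)
  bad <- which(d > r)
  for (i in bad) {
    di <- sqrt(x[i]^2 + y[i]^2)
    while (di > r) {
      # radial reflection: d -> 2r - d
      s <- (2 * r - di) / di
      x[i] <- x[i] * s
      y[i] <- y[i] * s
      di <- abs(2 * r - di)
    }
  }
  list(x = x, y = y)
}

#' Attach ligand-cluster sites to mobile corrals
#'
#' Draws one cluster (punctum) position per mobile corral at a uniformly
#' random rim angle, 0.7 radius from the center (clusters are trapped at
#' the corral periphery). When present, \code{\link{render_ligand_channel}}
#' places the clustered intensity there and
#' \code{\link{simulate_binding_events}} centers mobile binding sites on the
#' cluster, emulating receptor recruitment into the ligand cluster. Without
#' cluster sites, binding positions are uniform over the corral.
#'
#' @param layout a \code{pattern_layout}.
#' @param seed optional RNG seed.
#' @return the layout with \code{punctum_x_um}/\code{punctum_y_um} columns
#'   (\code{NA} for immobile corrals).
#' @export
add_cluster_sites <- function(layout, seed = NULL) {
  validate_pattern_layout(layout)
  with_seed(seed, {
    ang <- stats::runif(nrow(layout), 0, 2 * pi)
    mob <- layout$region_class == "mobile"
    layout$punctum_x_um <- ifelse(mob, layout$cx_um +
                                    0.7 * layout$radius_um * cos(ang), NA)
    layout$punctum_y_um <- ifelse(mob, layout$cy_um +
                                    0.7 * layout$radius_um * sin(ang), NA)
    layout
  })
}

#' Simulate ground-truth binding events on a corral layout
#'
#' Per corral, molecular arrivals follow a Poisson process with rate
#' \code{k_on * corral_area} over the movie duration. Each molecule draws a
#' true dwell from the region's two-exponential mixture and an independent
#' photobleach time; the observed dwell is the minimum of true dwell, bleach
#' time and remaining movie time. Mobile-region molecules perform reflected
#' Brownian motion inside a confinement disk contained in the corral;
#' immobile-region molecules stay at their binding site. Localization jitter
#' is added to every per-frame position.
#'
#' @param layout a \code{pattern_layout}.
#' @param cfg a \code{sim_config}.
#' @param include_positions if \code{FALSE}, skip per-frame positions (faster
#'   when only event statistics are needed).
#' @return list of class \code{"binding_events"} with elements
#'   \code{events} (one row per molecule: \code{event_id}, \code{corral_id},
#'   \code{region_class}, \code{arrival_s}, \code{true_dwell_s},
#'   \code{bleach_s}, \code{observed_dwell_s}, \code{first_frame},
#'   \code{n_frames_obs}, \code{x0_um}, \code{y0_um}) and \code{positions}
#'   (per-frame ground truth: \code{event_id}, \code{frame}, \code{x_um},
#'   \code{y_um}); frames are 0-based.
#' @export
simulate_binding_events <- function(layout, cfg, include_positions = TRUE) {
  validate_pattern_layout(layout)
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    t_end <- cfg$n_frames * cfg$dt
    ev_list <- list()
    pos_list <- list()
    eid <- 0L
    for (i in seq_len(nrow(layout))) {
      reg <- layout$region_class[i]
      area <- pi * layout$radius_um[i]^2
      n_arr <- stats::rpois(1, cfg$k_on[[reg]] * area * t_end)
      if (n_arr == 0) next
      arrival <- sort(stats::runif(n_arr, 0, t_end))
      true_dwell <- simulate_dwell_times(n_arr, cfg$f1[[reg]],
                                         cfg$tau1[[reg]], cfg$tau2[[reg]])
      bleach <- if (cfg$k_b > 0) stats::rexp(n_arr, cfg$k_b) else rep(Inf, n_arr)
      observed <- pmin(true_dwell, bleach, t_end - arrival)
      # binding sites: uniform in the disk that keeps the confinement disk
      # inside the corral, or gathered around the ligand cluster when the
      # layout carries cluster sites (mobile corrals only)
      rmax <- max(layout$radius_um[i] - cfg$confine_radius, 0)
      has_punctum <- reg == "mobile" &&
        "punctum_x_um" %in% names(layout) && !is.na(layout$punctum_x_um[i])
      if (has_punctum) {
        x0 <- layout$punctum_x_um[i] + stats::rnorm(n_arr, 0, 0.15)
        y0 <- layout$punctum_y_um[i] + stats::rnorm(n_arr, 0, 0.15)
        dxy <- sqrt((x0 - layout$cx_um[i])^2 + (y0 - layout$cy_um[i])^2)
        far <- dxy > rmax
        if (any(far)) {  # clamp radially so the confinement disk stays inside
          sc <- rmax / dxy[far]
          x0[far] <- layout$cx_um[i] + (x0[far] - layout$cx_um[i]) * sc
          y0[far] <- layout$cy_um[i] + (y0[far] - layout$cy_um[i]) * sc
        }
      } else {
        rr <- rmax * sqrt(stats::runif(n_arr))
        th <- stats::runif(n_arr, 0, 2 * pi)
        x0 <- layout$cx_um[i] + rr * cos(th)
        y0 <- layout$cy_um[i] + rr * sin(th)
      }
      first_frame <- ceiling(arrival / cfg$dt)
      last_frame <- pmin(ceiling((arrival + observed) / cfg$dt) - 1L,
                         cfg$n_frames - 1L)
      n_obs <- pmax(last_frame - first_frame + 1L, 0L)
      ids <- eid + seq_len(n_arr)
      eid <- eid + n_arr
      ev_list[[length(ev_list) + 1L]] <- data.frame(
        event_id = ids, corral_id = layout$corral_id[i], region_class = reg,
        arrival_s = arrival, true_dwell_s = true_dwell, bleach_s = bleach,
        observed_dwell_s = observed, first_frame = as.integer(first_frame),
        n_frames_obs = as.integer(n_obs), x0_um = x0, y0_um = y0,
        stringsAsFactors = FALSE)
      if (include_positions) {
        Dreg <- cfg$D[[reg]]
        for (j in seq_len(n_arr)) {
          if (n_obs[j] < 1) next
          nf <- n_obs[j]
          if (Dreg > 0 && nf > 1) {
            sd_step <- sqrt(2 * Dreg * cfg$dt)
            dx <- cumsum(c(0, stats::rnorm(nf - 1, 0, sd_step)))
            dy <- cumsum(c(0, stats::rnorm(nf - 1, 0, sd_step)))
            refl <- reflect_into_disk(dx, dy, cfg$confine_radius)
            px <- x0[j] + refl$x
            py <- y0[j] + refl$y
          } else {
            px <- rep(x0[j], nf)
            py <- rep(y0[j], nf)
          }
          px <- px + stats::rnorm(nf, 0, cfg$loc_jitter)
          py <- py + stats::rnorm(nf, 0, cfg$loc_jitter)
          pos_list[[length(pos_list) + 1L]] <- data.frame(
            event_id = ids[j],
            frame = seq.int(first_frame[j], length.out = nf),
            x_um = px, y_um = py)
        }
      }
    }
    events <- if (length(ev_list)) do.call(rbind, ev_list) else
      data.frame(event_id = integer(), corral_id = integer(),
                 region_class = character(), arrival_s = numeric(),
                 true_dwell_s = numeric(), bleach_s = numeric(),
                 observed_dwell_s = numeric(), first_frame = integer(),
                 n_frames_obs = integer(), x0_um = numeric(),
                 y0_um = numeric(), stringsAsFactors = FALSE)
    positions <- if (length(pos_list)) do.call(rbind, pos_list) else
      data.frame(event_id = integer(), frame = integer(),
                 x_um = numeric(), y_um = numeric())
    out <- list(events = events, positions = positions,
                layout = layout, cfg = cfg)
    class(out) <- "binding_events"
    out
  })
}

# integrated 2-D Gaussian mass on unit pixels around (x, y) (pixel units)
gauss_patch <- function(x, y, sigma, half) {
  cx <- floor(x)
  cy <- floor(y)
  xs <- (cx - half):(cx + half)
  ys <- (cy - half):(cy + half)
  fx <- stats::pnorm(xs + 1, mean = x, sd = sigma) -
        stats::pnorm(xs, mean = x, sd = sigma)
  fy <- stats::pnorm(ys + 1, mean = y, sd = sigma) -
        stats::pnorm(ys, mean = y, sd = sigma)
  list(rows = ys, cols = xs, mass = outer(fy, fx))
}

#' Render a synthetic TIRF movie from binding events
#'
#' Each active molecule contributes an integrated 2-D Gaussian of width
#' \code{psf_sigma} carrying \code{photons} expected photons per frame;
#' photon shot noise is Poisson, the camera adds a constant background and
#' Gaussian read noise, and pixel values are clipped at zero.
#'
#' @param events a \code{binding_events} object (with positions).
#' @param layout the \code{pattern_layout} used to generate the events.
#' @param cfg the \code{sim_config}.
#' @return a 3-D array (rows x cols x frames) of class \code{"frame_stack"}
#'   with attributes \code{dt} and \code{pixel_size_um}.
#' @export
render_movie <- function(events, layout, cfg) {
  stopifnot(inherits(events, "binding_events"))
  validate_sim_config(cfg)
  px <- attr(layout, "pixel_size_um")
  field <- attr(layout, "field_um")
  w <- round(field[1] / px)
  h <- round(field[2] / px)
  pos <- events$positions
  if (nrow(pos) > 0 &&
      (any(pos$x_um < 0) || any(pos$x_um > field[1]) ||
       any(pos$y_um < 0) || any(pos$y_um > field[2])))
    stop("events contain positions outside the field")
  half <- ceiling(4 * cfg$psf_sigma)
  signal <- array(0, dim = c(h, w, cfg$n_frames))
  if (nrow(pos) > 0) {
    xs_px <- pos$x_um / px
    ys_px <- pos$y_um / px
    for (k in seq_len(nrow(pos))) {
      p <- gauss_patch(xs_px[k], ys_px[k], cfg$psf_sigma, half)
      rkeep <- p$rows >= 0 & p$rows < h
      ckeep <- p$cols >= 0 & p$cols < w
      if (!any(rkeep) || !any(ckeep)) next
      fr <- pos$frame[k] + 1L
      signal[p$rows[rkeep] + 1L, p$cols[ckeep] + 1L, fr] <-
        signal[p$rows[rkeep] + 1L, p$cols[ckeep] + 1L, fr] +
        cfg$photons * p$mass[rkeep, ckeep, drop = FALSE]
    }
  }
  noisy <- stats::rpois(length(signal), signal)
  if (cfg$excess_noise)  # EMCCD excess noise: variance doubled
    noisy <- noisy + stats::rpois(length(signal), signal) - signal
  stack <- noisy + cfg$background +
    stats::rnorm(length(signal), 0, cfg$read_noise)
  stack <- array(pmax(stack, 0), dim = dim(signal))
  attr(stack, "dt") <- cfg$dt
  attr(stack, "pixel_size_um") <- px
  class(stack) <- "frame_stack"
  stack
}

#' Render the ligand reference channel for a corral layout
#'
#' Immobile corrals are uniformly filled. Mobile corrals place
#' \code{clustered_fraction} of their total intensity into a single Gaussian
#' punctum at a uniformly random rim angle, 0.7 radius from the center
#' (clusters are trapped at the corral periphery), with the remainder
#' uniform. Total intensity per corral equals \code{density * area} in
#' calibrated units (1 count per molecule) regardless of class.
#'
#' @param layout a \code{pattern_layout}.
#' @param densities per-region ligand densities, molecules/µm² (named vector
#'   with \code{mobile} and \code{immobile}).
#' @param clustered_fraction fraction of mobile-corral intensity in the
#'   punctum; 0 renders the pre-contact (unclustered) channel.
#' @param punctum_sigma punctum width, µm.
#' @param noise_sd additive Gaussian noise sd, counts.
#' @return image matrix (rows x cols) with attribute \code{pixel_size_um}.
#' @export
render_ligand_channel <- function(layout,
                                  densities = c(mobile = 100, immobile = 100),
                                  clustered_fraction = 0,
                                  punctum_sigma = 0.25, noise_sd = 0) {
  validate_pattern_layout(layout)
  if (length(densities) == 1)
    densities <- c(mobile = unname(densities), immobile = unname(densities))
  stopifnot(all(densities >= 0))
  if (clustered_fraction < 0 || clustered_fraction > 1)
    stop("clustered_fraction must lie in [0, 1]")
  px <- attr(layout, "pixel_size_um")
  field <- attr(layout, "field_um")
  w <- round(field[1] / px)
  h <- round(field[2] / px)
  img <- matrix(0, nrow = h, ncol = w)
  # pixel centers in µm
  xc <- (seq_len(w) - 0.5) * px
  yc <- (seq_len(h) - 0.5) * px
  for (i in seq_len(nrow(layout))) {
    r <- layout$radius_um[i]
    total <- densities[[layout$region_class[i]]] * pi * r^2
    if (total == 0) next
    dx2 <- outer(rep(1, h), (xc - layout$cx_um[i])^2)
    dy2 <- outer((yc - layout$cy_um[i])^2, rep(1, w))
    inside <- (dx2 + dy2) <= r^2
    n_in <- sum(inside)
    if (n_in == 0) next
    cf <- if (layout$region_class[i] == "mobile") clustered_fraction else 0
    img[inside] <- img[inside] + (1 - cf) * total / n_in
    if (cf > 0) {
      if ("punctum_x_um" %in% names(layout) && !is.na(layout$punctum_x_um[i])) {
        pxum <- layout$punctum_x_um[i]
        pyum <- layout$punctum_y_um[i]
      } else {
        ang <- stats::runif(1, 0, 2 * pi)
        pxum <- layout$cx_um[i] + 0.7 * r * cos(ang)
        pyum <- layout$cy_um[i] + 0.7 * r * sin(ang)
      }
      gx <- stats::dnorm(xc, pxum, punctum_sigma)
      gy <- stats::dnorm(yc, pyum, punctum_sigma)
      punct <- outer(gy, gx) * px^2
      punct[!inside] <- 0              # clusters stay within the corral
      s <- sum(punct)
      if (s > 0) img <- img + cf * total * punct / s
    }
  }
  if (noise_sd > 0) img <- pmax(img + stats::rnorm(length(img), 0, noise_sd), 0)
  attr(img, "pixel_size_um") <- px
  img
}

#' Simulate a per-corral two-channel intensity table with a known fold-change
#'
#' Generates numerator/denominator intensity pairs for mobile and immobile
#' corrals. Denominator (ligand) intensities are lognormal around a common
#' mean; numerator (signal) intensities are lognormal around region means
#' whose ratio is \code{fold_change}, each with coefficient of variation
#' \code{cv}. Lognormal location parameters are set so arithmetic means hit
#' the targets exactly.
#'
#' @param n_mobile,n_immobile corral counts per region.
#' @param fold_change mobile/immobile ratio of numerator means.
#' @param cv lognormal coefficient of variation of both channels.
#' @param cell_id label attached to all rows.
#' @param base_num,base_den immobile-region mean numerator and denominator
#'   intensities, counts.
#' @param rng_seed optional integer seed.
#' @return \code{data.frame} with columns \code{cell_id}, \code{corral_id},
#'   \code{region_class}, \code{net_num}, \code{net_den}.
#' @export
simulate_corral_ratio_dataset <- function(n_mobile, n_immobile, fold_change,
                                          cv, cell_id = 1,
                                          base_num = 200, base_den = 100,
                                          rng_seed = NULL) {
  if (n_mobile < 1 || n_immobile < 1) stop("corral counts must be positive")
  stopifnot(fold_change > 0, cv >= 0)
  with_seed(rng_seed, {
    n <- n_mobile + n_immobile
    cls <- rep(c("mobile", "immobile"), c(n_mobile, n_immobile))
    mean_num <- ifelse(cls == "mobile", base_num * fold_change, base_num)
    rl <- function(m, cv, n) {
      if (cv == 0) return(rep(m, n))
      s2 <- log(1 + cv^2)
      stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
    }
    data.frame(cell_id = cell_id, corral_id = seq_len(n), region_class = cls,
               net_num = rl(1, cv, n) * mean_num,
               net_den = rl(base_den, cv, n),
               stringsAsFactors = FALSE)
  })
}

#' Simulate corral recruitment time series with a known fold-change
#'
#' Generates per-corral net-intensity time courses of adaptor recruitment
#' after cell contact: a saturating rise \code{plateau * (1 - exp(-t/tau))}
#' sampled on a regular grid (defaults: 30 min at 30 s/frame). Each corral
#' draws a lognormal ligand intensity around a common mean and a lognormal
#' plateau-per-ligand around its region mean; mobile and immobile region
#' means differ by \code{fold_change}.
#'
#' @param n_mobile,n_immobile corrals per region.
#' @param fold_change mobile/immobile ratio of plateau recruitment per
#'   ligand.
#' @param cv lognormal coefficient of variation of plateau-per-ligand and
#'   ligand intensity.
#' @param duration total duration, s.
#' @param dt_sample sampling interval, s.
#' @param tau_rise rise time constant, s.
#' @param base_per_ligand immobile-region mean plateau per ligand unit.
#' @param ligand_mean mean ligand intensity per corral.
#' @param cell_id label attached to all rows.
#' @param rng_seed optional integer seed.
#' @return list with \code{series} (corral intensity table rows:
#'   \code{cell_id}, \code{corral_id}, \code{region_class},
#'   \code{timepoint_s}, \code{net}) and \code{ligand} (named vector of
#'   per-corral ligand intensities for \code{\link{max_and_cumulative}}).
#' @export
simulate_recruitment_series <- function(n_mobile, n_immobile,
                                        fold_change, cv,
                                        duration = 1800, dt_sample = 30,
                                        tau_rise = 300,
                                        base_per_ligand = 2,
                                        ligand_mean = 50,
                                        cell_id = 1, rng_seed = NULL) {
  if (n_mobile < 1 || n_immobile < 1) stop("corral counts must be positive")
  stopifnot(fold_change > 0, cv >= 0, duration > 0, dt_sample > 0)
  with_seed(rng_seed, {
    n <- n_mobile + n_immobile
    cls <- rep(c("mobile", "immobile"), c(n_mobile, n_immobile))
    rl <- function(m, n) {
      if (cv == 0) return(rep(m, n))
      s2 <- log(1 + cv^2)
      stats::rlnorm(n, log(m) - s2 / 2, sqrt(s2))
    }
    ligand <- rl(ligand_mean, n)
    per_lig <- rl(1, n) * base_per_ligand *
      ifelse(cls == "mobile", fold_change, 1)
    plateau <- per_lig * ligand
    tp <- seq(0, duration, by = dt_sample)
    series <- do.call(rbind, lapply(seq_len(n), function(k) {
      data.frame(cell_id = cell_id, corral_id = k, region_class = cls[k],
                 timepoint_s = tp,
                 net = plateau[k] * (1 - exp(-tp / tau_rise)),
                 stringsAsFactors = FALSE)
    }))
    list(series = series,
         ligand = stats::setNames(ligand, as.character(seq_len(n))))
  })
}

#' Write a frame stack as a multi-page TIFF
#'
#' @param stack a \code{frame_stack} (rows x cols x frames).
#' @param path output file path.
#' @param scale divisor applied before writing (TIFF stores [0,1] floats).
#' @return the path, invisibly.
#' @export
write_frame_stack <- function(stack, path, scale = 65535) {
  frames <- lapply(seq_len(dim(stack)[3]),
                   function(i) pmin(stack[, , i] / scale, 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path TIFF file.
#' @param dt frame interval, s.
#' @param pixel_size pixel size, µm/px.
#' @param scale multiplier restoring counts from the stored [0,1] floats.
#' @return a \code{frame_stack}.
#' @export
read_frame_stack <- function(path, dt, pixel_size, scale = 65535) {
  frames <- tiff::readTIFF(path, all = TRUE)
  stack <- array(unlist(frames) * scale,
                 dim = c(dim(frames[[1]])[1], dim(frames[[1]])[2],
                         length(frames)))
  attr(stack, "dt") <- dt
  attr(stack, "pixel_size_um") <- pixel_size
  class(stack) <- "frame_stack"
  stack
}
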