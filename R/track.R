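# Nearest-neighbor trajectory linking, dwell times, localization images and
# MSD diagnostics.

#' Link per-frame localizations into trajectories (nearest neighbor)
#'
#' Frame-to-frame assignment is greedy over candidate (track, localization)
#' pairs sorted by ascending distance: a pair is accepted when its distance
#' is at most \code{max_disp} and neither member is already assigned. Ties
#' in distance are broken by the lower localization index. Unmatched
#' localizations start new tracks; a track unmatched for \code{gap_max + 1}
#' consecutive frames is terminated. The default \code{gap_max = 0} performs
#' plain nearest-neighbor linking with no gap closing.
#'
#' @param localizations data.frame with columns \code{frame} (0-based
#'   integer), \code{x}, \code{y}; additional columns are carried through.
#' @param max_disp maximum frame-to-frame displacement (same units as
#'   \code{x}/\code{y}).
#' @param gap_max number of consecutive missed frames tolerated.
#' @return the input rows with a \code{track_id} column, ordered by
#'   \code{track_id} then \code{frame}.
#' @export
link_trajectories <- function(localizations, max_disp, gap_max = 0) {
  stopifnot(max_disp > 0, gap_max >= 0)
  loc <- localizations
  if (nrow(loc) == 0) return(cbind(loc, track_id = integer(0)))
  loc$track_id <- NA_integer_
  ord <- order(loc$frame)
  loc <- loc[ord, , drop = FALSE]
  next_id <- 1L
  # active track state
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_last <- integer(0)
  frames <- min(loc$frame):max(loc$frame)
  idx_by_frame <- split(seq_len(nrow(loc)), factor(loc$frame, levels = frames))
  for (f in frames) {
    rows <- idx_by_frame[[as.character(f)]]
    # retire tracks that have been dark too long
    keep <- act_last >= f - 1L - gap_max
    act_id <- act_id[keep]; act_x <- act_x[keep]; act_y <- act_y[keep]
    act_last <- act_last[keep]
    if (length(rows)) {
      nl <- length(rows)
      if (length(act_id)) {
        d <- sqrt(outer(act_x, loc$x[rows], "-")^2 +
                  outer(act_y, loc$y[rows], "-")^2)
        cand <- which(d <= max_disp, arr.ind = TRUE)
        if (nrow(cand)) {
          # sort by distance, then by localization index for tie-breaks
          o <- order(d[cand], cand[, 2], cand[, 1])
          cand <- cand[o, , drop = FALSE]
          t_used <- logical(length(act_id))
          l_used <- logical(nl)
          for (i in seq_len(nrow(cand))) {
            ti <- cand[i, 1]; li <- cand[i, 2]
            if (t_used[ti] || l_used[li]) next
            t_used[ti] <- TRUE; l_used[li] <- TRUE
            loc$track_id[rows[li]] <- act_id[ti]
            act_x[ti] <- loc$x[rows[li]]
            act_y[ti] <- loc$y[rows[li]]
            act_last[ti] <- f
          }
        }
      }
      new <- rows[is.na(loc$track_id[rows])]
      if (length(new)) {
        ids <- next_id + seq_along(new) - 1L
        next_id <- next_id + length(new)
        loc$track_id[new] <- ids
        act_id <- c(act_id, ids)
        act_x <- c(act_x, loc$x[new])
        act_y <- c(act_y, loc$y[new])
        act_last <- c(act_last, rep(f, length(new)))
      }
    }
  }
  loc[order(loc$track_id, loc$frame), , drop = FALSE]
}

#' Summarize linked trajectories
#'
#' @param tracks linked localizations (output of
#'   \code{\link{link_trajectories}}).
#' @param n_frames total number of movie frames; tracks touching frame 0 or
#'   frame \code{n_frames - 1} are flagged as censored.
#' @return data.frame with one row per track: \code{track_id},
#'   \code{start_frame}, \code{end_frame}, \code{n_obs}, \code{x0},
#'   \code{y0} (first-appearance position), \code{censored_start},
#'   \code{censored_end}.
#' @export
summarize_tracks <- function(tracks, n_frames) {
  if (nrow(tracks) == 0)
    return(data.frame(track_id = integer(), start_frame = integer(),
                      end_frame = integer(), n_obs = integer(),
                      x0 = numeric(), y0 = numeric(),
                      censored_start = logical(), censored_end = logical()))
  sp <- split(seq_len(nrow(tracks)), tracks$track_id)
  first <- vapply(sp, function(i) i[which.min(tracks$frame[i])], integer(1))
  res <- data.frame(
    track_id = as.integer(names(sp)),
    start_frame = vapply(sp, function(i) min(tracks$frame[i]), numeric(1)),
    end_frame = vapply(sp, function(i) max(tracks$frame[i]), numeric(1)),
    n_obs = lengths(sp),
    x0 = tracks$x[first], y0 = tracks$y[first])
  res$censored_start <- res$start_frame == 0
  res$censored_end <- res$end_frame == n_frames - 1
  res[order(res$track_id), , drop = FALSE]
}

#' Frame-quantized dwell times of linked trajectories
#'
#' The dwell of a track is the number of frames spanned from its first to
#' its last appearance (gap frames count as observed) times the frame
#' interval, so a single-frame appearance has dwell \code{dt}. Tracks
#' touching the first or last movie frame are flagged as censored; fitting
#' functions exclude them by default.
#'
#' @param tracks linked localizations or a \code{\link{summarize_tracks}}
#'   result.
#' @param dt frame interval in s.
#' @param n_frames total number of movie frames.
#' @param cell_id,region_class,species labels stored on the sample; when
#'   \code{region_class} is \code{NULL} and the tracks carry a
#'   \code{region_class} column, one sample per region is returned as a list.
#' @return a \code{\link{dwell_sample}} (or a named list of them, one per
#'   region class present).
#' @export
compute_dwell_times <- function(tracks, dt, n_frames, cell_id = NA,
                                region_class = NULL, species = NA) {
  stopifnot(dt > 0)
  if (!"n_obs" %in% names(tracks)) {
    has_region <- "region_class" %in% names(tracks)
    reg_by_track <- if (has_region)
      tracks$region_class[match(unique(tracks$track_id), tracks$track_id)]
    tracks_sm <- summarize_tracks(tracks, n_frames)
    if (has_region)
      tracks_sm$region_class <- reg_by_track[match(tracks_sm$track_id,
                                                   unique(tracks$track_id))]
    if (is.null(region_class) && has_region) {
      return(lapply(split(tracks_sm, tracks_sm$region_class), function(s)
        dwell_from_summary(s, dt, cell_id, s$region_class[1], species)))
    }
    tracks <- tracks_sm
  }
  dwell_from_summary(tracks, dt, cell_id, region_class, species)
}

dwell_from_summary <- function(sm, dt, cell_id, region_class, species) {
  n_span <- sm$end_frame - sm$start_frame + 1
  dwell_sample(n_span * dt, dt,
               censored = sm$censored_start | sm$censored_end,
               cell_id = cell_id,
               region_class = if (is.null(region_class)) NA else region_class,
               species = species)
}

#' Assemble first-appearance positions into a localization image
#'
#' Builds the sptPALM-style super-resolved image: a 2-D histogram of the
#' first position of every trajectory on a rendering grid.
#'
#' @param tracks linked localizations or a track summary (needs \code{x0},
#'   \code{y0} or per-point \code{x}, \code{y} with \code{frame}).
#' @param render_pixel rendering pixel size, in the same units as the
#'   coordinates.
#' @param field field extent \code{c(width, height)} in coordinate units.
#' @return integer matrix (rows x cols); the sum equals the number of
#'   tracks. Positions outside the field are clamped to the edge bins.
#' @export
localization_image <- function(tracks, render_pixel, field) {
  stopifnot(render_pixel > 0, length(field) == 2)
  if (!"x0" %in% names(tracks)) {
    if (nrow(tracks) == 0) {
      x0 <- numeric(0); y0 <- numeric(0)
    } else {
      sp <- split(seq_len(nrow(tracks)), tracks$track_id)
      first <- vapply(sp, function(i) i[which.min(tracks$frame[i])], integer(1))
      x0 <- tracks$x[first]; y0 <- tracks$y[first]
    }
  } else {
    x0 <- tracks$x0; y0 <- tracks$y0
  }
  w <- max(1L, ceiling(field[1] / render_pixel))
  h <- max(1L, ceiling(field[2] / render_pixel))
  img <- matrix(0L, nrow = h, ncol = w)
  if (length(x0)) {
    cx <- pmin(pmax(floor(x0 / render_pixel) + 1L, 1L), w)
    cy <- pmin(pmax(floor(y0 / render_pixel) + 1L, 1L), h)
    tab <- table(factor(cy, levels = seq_len(h)), factor(cx, levels = seq_len(w)))
    img <- matrix(as.integer(tab), nrow = h, ncol = w)
  }
  img
}

#' Agreement of links with ground-truth molecule identities
#'
#' A link (two consecutive localizations in a track) agrees with the ground
#' truth when some simulated molecule lies within \code{radius} of both
#' endpoints in their respective frames. Identity at sub-diffraction
#' separations is not physically resolvable, so agreement is defined by
#' consistency within the matching radius rather than by exclusive
#' assignment.
#'
#' @param tracks linked localizations (\code{track_id}, \code{frame},
#'   \code{x}, \code{y}).
#' @param truth ground-truth per-frame positions (\code{event_id},
#'   \code{frame}, \code{x}, \code{y}) in the same units as the tracks.
#' @param radius matching radius.
#' @return fraction of links consistent with a common ground-truth molecule
#'   (\code{NA} when there are no links).
#' @export
link_identity <- function(tracks, truth, radius = 2) {
  by_frame <- split(truth, truth$frame)
  near <- function(x, y, f) {
    tf <- by_frame[[as.character(f)]]
    if (is.null(tf)) return(integer(0))
    tf$event_id[(tf$x - x)^2 + (tf$y - y)^2 <= radius^2]
  }
  ok <- unlist(lapply(split(seq_len(nrow(tracks)), tracks$track_id),
    function(i) {
      if (length(i) < 2) return(NULL)
      vapply(2:length(i), function(j) {
        a <- near(tracks$x[i[j - 1]], tracks$y[i[j - 1]],
                  tracks$frame[i[j - 1]])
        b <- near(tracks$x[i[j]], tracks$y[i[j]], tracks$frame[i[j]])
        length(intersect(a, b)) > 0
      }, logical(1))
    }))
  if (!length(ok)) return(NA_real_)
  mean(ok)
}

#' Mean squared displacement and confinement ratio of one trajectory
#'
#' Time-averaged MSD over lags 1..\code{max_lag}. The confinement ratio
#' \code{MSD(max_lag) / (max_lag * MSD(1))} is about 1 for free diffusion
#' and well below 1 for confined motion.
#'
#' @param track data.frame with columns \code{frame}, \code{x}, \code{y}
#'   for a single track (no gaps assumed).
#' @param max_lag maximum lag in frames.
#' @return list with \code{lag} (frames), \code{msd} and
#'   \code{confinement_ratio}.
#' @export
compute_msd <- function(track, max_lag = 20) {
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  if (n < max_lag + 1) stop("track shorter than max_lag + 1 positions")
  msd <- vapply(seq_len(max_lag), function(L) {
    dx <- track$x[(1 + L):n] - track$x[1:(n - L)]
    dy <- track$y[(1 + L):n] - track$y[1:(n - L)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  list(lag = seq_len(max_lag), msd = msd,
       confinement_ratio = msd[max_lag] / (max_lag * msd[1]))
}
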