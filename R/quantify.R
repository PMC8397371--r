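# Corral-wise and nuclear intensity quantification: background subtraction,
# channel ratios, time-lapse heatmaps, max/cumulative recruitment.

#' Background-subtracted mean intensity per corral
#'
#' Per-corral mean pixel intensity with background subtraction. Background
#' is the median of off-pattern pixels (\code{"global"}, default) or the
#' median of a 3-pixel annulus around each corral (\code{"local"}). Net
#' intensities are floored at zero.
#'
#' @param image numeric matrix, one channel.
#' @param mask a \code{region_mask} congruent with the image.
#' @param background_mode \code{"global"} or \code{"local"}.
#' @param cell_id,channel,timepoint labels attached to the rows.
#' @return data.frame rows of a corral intensity table: \code{cell_id},
#'   \code{corral_id}, \code{region_class}, \code{timepoint_s},
#'   \code{channel}, \code{mean_intensity}, \code{background}, \code{net}.
#' @export
corral_mean_intensity <- function(image, mask,
                                  background_mode = c("global", "local"),
                                  cell_id = 1, channel = "ch1",
                                  timepoint = 0) {
  stopifnot(inherits(mask, "region_mask"),
            all(dim(image) == dim(mask$labels)))
  background_mode <- match.arg(background_mode)
  ids <- mask$info$corral_id
  ids <- ids[vapply(ids, function(k) any(mask$labels == k), logical(1))]
  if (background_mode == "global") {
    bg_global <- stats::median(image[mask$labels == 0])
  }
  rows <- lapply(ids, function(k) {
    sel <- mask$labels == k
    m <- mean(image[sel])
    bg <- if (background_mode == "global") bg_global else {
      ring <- annulus_pixels(sel, width = 3) & mask$labels == 0
      if (!any(ring)) stats::median(image[mask$labels == 0])
      else stats::median(image[ring])
    }
    data.frame(cell_id = cell_id, corral_id = k,
               region_class = mask$info$region_class[mask$info$corral_id == k],
               timepoint_s = timepoint, channel = channel,
               mean_intensity = m, background = bg,
               net = max(m - bg, 0), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# pixels within `width` of a region but outside it
annulus_pixels <- function(sel, width = 3) {
  out <- sel
  for (i in seq_len(width)) out <- dilate_labels(out * 1L) > 0
  out & !sel
}

#' Per-cell channel ratios by region
#'
#' Per-corral ratio \code{netA / netB} between two matched corral intensity
#' tables, then the mean of corral ratios per cell and region. Corrals whose
#' denominator net intensity is non-positive are excluded (their count is
#' reported in the \code{n_excluded} attribute).
#'
#' @param tableA,tableB corral intensity tables (same corral ids), e.g. the
#'   signal and the ligand channel.
#' @return list with \code{per_corral} (adds a \code{ratio} column) and
#'   \code{per_cell} (mean ratio by \code{cell_id} x \code{region_class},
#'   suitable for \code{\link{paired_region_comparison}} after reshaping).
#' @export
channel_ratio_per_cell <- function(tableA, tableB) {
  key <- function(d) paste(d$cell_id, d$corral_id, sep = "/")
  m <- match(key(tableA), key(tableB))
  if (any(is.na(m))) stop("corral ids of the two tables do not match")
  den <- tableB$net[m]
  excl <- den <= 0
  per_corral <- tableA[!excl, c("cell_id", "corral_id", "region_class")]
  per_corral$ratio <- tableA$net[!excl] / den[!excl]
  agg <- stats::aggregate(ratio ~ cell_id + region_class, data = per_corral,
                          FUN = mean)
  attr(agg, "n_excluded") <- sum(excl)
  list(per_corral = per_corral, per_cell = agg)
}

#' Reshape per-cell region means to paired wide format
#'
#' @param per_cell data.frame with \code{cell_id}, \code{region_class},
#'   \code{ratio} (or another value column).
#' @param value name of the value column.
#' @return data.frame with columns \code{cell_id}, \code{mobile},
#'   \code{immobile}.
#' @export
pair_by_cell <- function(per_cell, value = "ratio") {
  wide <- stats::reshape(per_cell[, c("cell_id", "region_class", value)],
                         idvar = "cell_id", timevar = "region_class",
                         direction = "wide")
  names(wide) <- sub(paste0("^", value, "\\."), "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Normalized corral-by-time heatmap matrix
#'
#' All net intensities of one cell are divided by the single maximum over
#' all corrals and all timepoints, so the hottest block is exactly 1.
#'
#' @param series corral intensity table for one cell (columns
#'   \code{corral_id}, \code{timepoint_s}, \code{net}).
#' @return numeric matrix (corral x time) in [0, 1] with an
#'   \code{all_zero} attribute; rows named by corral id, columns by time.
#' @export
timelapse_heatmap <- function(series) {
  stopifnot(nrow(series) >= 1)
  ids <- sort(unique(series$corral_id))
  tps <- sort(unique(series$timepoint_s))
  m <- matrix(0, length(ids), length(tps),
              dimnames = list(ids, tps))
  m[cbind(match(series$corral_id, ids), match(series$timepoint_s, tps))] <-
    series$net
  mx <- max(m)
  if (mx > 0) m <- m / mx
  attr(m, "all_zero") <- mx <= 0
  m
}

#' Maximum and cumulative recruitment per corral, ligand-normalized
#'
#' For each corral: the maximal net intensity within the window and the
#' trapezoid time-integral of net intensity over the window, both divided by
#' the corral's ligand intensity. Defaults match a 30-min acquisition at
#' 30 s/frame.
#'
#' @param series corral intensity table (one cell, one channel).
#' @param window analysis window, s (from the first timepoint).
#' @param ligand named numeric vector: ligand intensity per corral id.
#'   Corrals without a ligand value are excluded.
#' @return data.frame with \code{corral_id}, \code{region_class},
#'   \code{max_per_ligand}, \code{cumulative_per_ligand}.
#' @export
max_and_cumulative <- function(series, window = 1800, ligand) {
  stopifnot(window > 0)
  rows <- lapply(sort(unique(series$corral_id)), function(k) {
    lg <- ligand[as.character(k)]
    if (is.na(lg) || length(lg) == 0) return(NULL)
    if (lg <= 0) stop("ligand intensity must be positive")
    s <- series[series$corral_id == k, , drop = FALSE]
    s <- s[order(s$timepoint_s), , drop = FALSE]
    t0 <- s$timepoint_s[1]
    s <- s[s$timepoint_s <= t0 + window, , drop = FALSE]
    if (max(s$timepoint_s) - t0 > window)
      stop("window exceeds series duration")
    cum <- if (nrow(s) > 1)
      sum(diff(s$timepoint_s) * (utils::head(s$net, -1) + utils::tail(s$net, -1)) / 2)
    else 0
    data.frame(corral_id = k, region_class = s$region_class[1],
               max_per_ligand = max(s$net) / lg,
               cumulative_per_ligand = cum / lg, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Nuclear signal per ligand for one cell
#'
#' Mean background-subtracted signal inside a supplied nuclear mask, divided
#' by the substrate ligand intensity for that cell. Used when the readout
#' (e.g. nuclear phospho-Erk immunostaining) cannot be separated by corral
#' within one cell, so whole cells on mobile-only vs immobile-only
#' substrates are compared with an unpaired test.
#'
#' @param signal_image numeric matrix.
#' @param nuclear_mask logical or 0/1 matrix marking nuclear pixels
#'   (segmentation is supplied, not computed).
#' @param ligand_reference substrate ligand intensity for this cell (> 0).
#' @param background background level; default the median of non-nuclear
#'   pixels.
#' @return nuclear net intensity / ligand_reference (a scalar).
#' @export
nuclear_ratio <- function(signal_image, nuclear_mask, ligand_reference,
                          background = NULL) {
  stopifnot(all(dim(signal_image) == dim(nuclear_mask)),
            ligand_reference > 0)
  sel <- nuclear_mask > 0
  if (!any(sel)) stop("nuclear mask is empty")
  if (is.null(background)) background <- stats::median(signal_image[!sel])
  max(mean(signal_image[sel]) - background, 0) / ligand_reference
}
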