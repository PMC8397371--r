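# Corral masks from the ligand channel: segmentation, mobility
# classification, and region assignment of trajectories.

#' Segment corrals from a ligand reference image
#'
#' Global Otsu threshold, connected-component labelling, then a shape
#' filter: components are kept when their area lies within
#' \code{[0.5, 2]} times the expected disk area and their circularity
#' (\code{4 * pi * area / perimeter^2}) is at least 0.6. Kept components are
#' dilated by 1 pixel so rim-trapped ligand clusters straddling the
#' threshold edge stay inside their corral.
#'
#' Automated segmentation reconstructs the manually outlined masks of the
#' original workflow; a user-supplied mask (see \code{\link{layout_to_mask}})
#' can be used instead anywhere a mask is accepted.
#'
#' @param ligand_image numeric matrix (ligand channel).
#' @param expected_radius expected corral radius, µm.
#' @param pixel_size µm per pixel.
#' @return a \code{region_mask}: list with \code{labels} (integer matrix,
#'   0 = background), \code{info} (per corral: \code{corral_id},
#'   \code{region_class} [\code{NA} until classified], \code{area_um2},
#'   \code{mean_ligand}, \code{cx_px}, \code{cy_px}), \code{pixel_size_um},
#'   and a \code{status} flag (\code{"ok"} or \code{"empty"}).
#' @export
segment_corrals <- function(ligand_image, expected_radius, pixel_size) {
  stopifnot(expected_radius > 0, pixel_size > 0)
  img <- ligand_image
  rng <- range(img)
  empty <- function() {
    warning("no corral-like components found; returning empty mask")
    structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                   info = data.frame(corral_id = integer(),
                                     region_class = character(),
                                     area_um2 = numeric(),
                                     mean_ligand = numeric(),
                                     cx_px = numeric(), cy_px = numeric()),
                   pixel_size_um = pixel_size, status = "empty"),
              class = "region_mask")
  }
  if (rng[2] <= rng[1]) return(empty())
  norm <- (img - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  nobj <- max(lab)
  if (nobj == 0) return(empty())
  shp <- EBImage::computeFeatures.shape(lab)
  area_px <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1)
  circ <- 4 * pi * area_px / perim^2
  exp_area <- pi * (expected_radius / pixel_size)^2
  keep <- which(area_px >= 0.5 * exp_area & area_px <= 2 * exp_area &
                circ >= 0.6)
  if (!length(keep)) return(empty())
  labm <- matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(img))
  relab <- matrix(0L, nrow(img), ncol(img))
  for (k in seq_along(keep)) relab[labm == keep[k]] <- k
  # areas and ligand intensities reflect the thresholded corral itself;
  # the 1-px dilation below only widens the assignment footprint so that
  # rim-trapped clusters straddling the threshold edge stay inside
  info <- mask_info(relab, img, pixel_size)
  relab <- dilate_labels(relab)
  structure(list(labels = relab, info = info, pixel_size_um = pixel_size,
                 status = "ok"),
            class = "region_mask")
}

# grayscale-style dilation of a label image by one pixel (4+diagonal
# neighborhood); background pixels take any adjacent label
dilate_labels <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  out <- lab
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- matrix(0L, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    s[rs, cs] <- lab[rs - dr, cs - dc]
    fill <- out == 0L & s > 0L
    out[fill] <- s[fill]
  }
  out
}

mask_info <- function(labels, img, pixel_size) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids))
    return(data.frame(corral_id = integer(), region_class = character(),
                      area_um2 = numeric(), mean_ligand = numeric(),
                      cx_px = numeric(), cy_px = numeric()))
  area <- tabulate(labels, nbins = max(ids))[ids]
  mean_lig <- vapply(ids, function(k) mean(img[labels == k]), numeric(1))
  cx <- vapply(ids, function(k) mean(col(labels)[labels == k]), numeric(1))
  cy <- vapply(ids, function(k) mean(row(labels)[labels == k]), numeric(1))
  data.frame(corral_id = as.integer(ids), region_class = NA_character_,
             area_um2 = area * pixel_size^2, mean_ligand = mean_lig,
             cx_px = cx, cy_px = cy, stringsAsFactors = FALSE)
}

#' Build a region mask directly from a known layout
#'
#' Rasterizes the ground-truth corral disks; the user-supplied override for
#' automated segmentation.
#'
#' @param layout a \code{pattern_layout}.
#' @param ligand_image optional image used to fill \code{mean_ligand}.
#' @return a \code{region_mask} with \code{region_class} taken from the
#'   layout.
#' @export
layout_to_mask <- function(layout, ligand_image = NULL) {
  validate_pattern_layout(layout)
  px <- attr(layout, "pixel_size_um")
  field <- attr(layout, "field_um")
  w <- round(field[1] / px); h <- round(field[2] / px)
  labels <- matrix(0L, h, w)
  xc <- (seq_len(w) - 0.5) * px
  yc <- (seq_len(h) - 0.5) * px
  for (i in seq_len(nrow(layout))) {
    dx2 <- outer(rep(1, h), (xc - layout$cx_um[i])^2)
    dy2 <- outer((yc - layout$cy_um[i])^2, rep(1, w))
    labels[dx2 + dy2 <= layout$radius_um[i]^2] <- layout$corral_id[i]
  }
  img <- if (is.null(ligand_image)) matrix(0, h, w) else ligand_image
  info <- mask_info(labels, img, px)
  m <- match(info$corral_id, layout$corral_id)
  info$region_class <- layout$region_class[m]
  # the ground-truth mask knows the exact disk geometry
  info$area_um2 <- pi * layout$radius_um[m]^2
  info$cx_px <- layout$cx_um[m] / px
  info$cy_px <- layout$cy_um[m] / px
  structure(list(labels = labels, info = info, pixel_size_um = px,
                 status = "ok"),
            class = "region_mask")
}

#' Classify corrals as mobile or immobile from ligand clustering
#'
#' Mobile-corral ligand is gathered by the cell into a dense cluster, so the
#' intensity distribution inside the corral becomes strongly peaked. The
#' clustering index of a corral is its 99th-percentile intensity divided by
#' its mean intensity; corrals with index above \code{threshold} are called
#' mobile, the rest immobile. A known layout can override the data-driven
#' call.
#'
#' @param ligand_image post-contact ligand channel.
#' @param mask a \code{region_mask}.
#' @param threshold clustering-index cutoff (default 3).
#' @param layout optional \code{pattern_layout}; when supplied, classes are
#'   copied from the layout by nearest corral center instead.
#' @return the mask with \code{info$region_class} filled in; the index is
#'   stored in \code{info$cluster_index}.
#' @export
classify_corral_mobility <- function(ligand_image, mask, threshold = 3,
                                     layout = NULL) {
  stopifnot(inherits(mask, "region_mask"))
  if (nrow(mask$info) == 0) stop("mask is empty")
  idx <- vapply(mask$info$corral_id, function(k) {
    v <- ligand_image[mask$labels == k]
    stats::quantile(v, 0.99, names = FALSE) / mean(v)
  }, numeric(1))
  mask$info$cluster_index <- idx
  if (is.null(layout)) {
    mask$info$region_class <- ifelse(idx > threshold, "mobile", "immobile")
  } else {
    px <- mask$pixel_size_um
    d <- outer(mask$info$cx_px * px, layout$cx_um, "-")^2 +
         outer(mask$info$cy_px * px, layout$cy_um, "-")^2
    mask$info$region_class <- layout$region_class[apply(d, 1, which.min)]
  }
  mask
}

#' Assign trajectories to corral regions by first-appearance position
#'
#' The region of a track is decided by the mask label under its first
#' localization (the binding position defines the signaling region); tracks
#' starting on background are labeled \code{"unassigned"} and are excluded
#' from region kinetics downstream.
#'
#' @param tracks linked localizations with \code{track_id}, \code{frame},
#'   \code{x}, \code{y} in pixels (same grid as the mask).
#' @param mask a classified \code{region_mask}.
#' @return \code{tracks} with \code{corral_id} and \code{region_class}
#'   columns added (constant within each track).
#' @export
assign_region <- function(tracks, mask) {
  stopifnot(inherits(mask, "region_mask"))
  if (nrow(tracks) == 0) {
    tracks$corral_id <- integer(0)
    tracks$region_class <- character(0)
    return(tracks)
  }
  sp <- split(seq_len(nrow(tracks)), tracks$track_id)
  first <- vapply(sp, function(i) i[which.min(tracks$frame[i])], integer(1))
  h <- nrow(mask$labels); w <- ncol(mask$labels)
  cx <- pmin(pmax(floor(tracks$x[first]) + 1L, 1L), w)
  cy <- pmin(pmax(floor(tracks$y[first]) + 1L, 1L), h)
  lab <- mask$labels[cbind(cy, cx)]
  cls <- rep("unassigned", length(lab))
  m <- match(lab, mask$info$corral_id)
  ok <- !is.na(m) & !is.na(mask$info$region_class[m])
  cls[ok] <- mask$info$region_class[m[ok]]
  track_ids <- as.integer(names(sp))
  pos <- match(tracks$track_id, track_ids)
  tracks$corral_id <- ifelse(is.na(m[pos]), NA_integer_,
                             mask$info$corral_id[m[pos]])
  tracks$region_class <- cls[pos]
  tracks
}
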