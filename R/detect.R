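# Single-molecule spot detection and validation diagnostics.

gauss_kernel <- function(sigma) {
  half <- ceiling(2 * sigma)
  x <- -half:half
  k <- outer(stats::dnorm(x, sd = sigma), stats::dnorm(x, sd = sigma))
  k <- k - mean(k)            # zero-sum: response invariant to offsets
  k / sqrt(sum(k^2))          # unit norm
}

# local maxima of a matrix in the 8-neighborhood, strict against ties to
# the right/bottom so plateaus yield a single candidate
local_maxima <- function(m) {
  h <- nrow(m); w <- ncol(m)
  res <- matrix(TRUE, h, w)
  shift <- function(dr, dc) {
    s <- matrix(-Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    s[rs, cs] <- m[rs - dr, cs - dc]
    s
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    cmp <- shift(dr, dc)
    if (dr > 0 || (dr == 0 && dc > 0)) res <- res & (m >= cmp)
    else res <- res & (m > cmp)
  }
  res
}

# least-squares 2-D Gaussian + constant background on a square window.
# xs, ys are 0-based pixel-center coordinates; returns NULL when the fit is
# rejected (sigma at a bound, center outside window, non-positive amplitude)
fit_gaussian_spot <- function(win, xs, ys, psf_sigma) {
  z <- as.vector(win)
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  b0 <- stats::median(z)
  a0 <- max(z) - b0
  if (a0 <= 0) return(NULL)
  imax <- which.max(z)
  lo <- c(a0 * 1e-3, min(xs), min(ys), 0.5 * psf_sigma, -Inf)
  hi <- c(Inf, max(xs), max(ys), 2 * psf_sigma, Inf)
  start <- c(A = a0, x = gx[imax], y = gy[imax], s = psf_sigma, b = b0)
  resid_fn <- function(p) {
    p["A"] * exp(-((gx - p["x"])^2 + (gy - p["y"])^2) / (2 * p["s"]^2)) +
      p["b"] - z
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = start, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 60))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  out <- list(A = unname(p["A"]), x = unname(p["x"]), y = unname(p["y"]),
              s = unname(p["s"]), b = unname(p["b"]), rss = fit$deviance,
              status = "ok")
  # sigma pinned at a bound flags an unresolved pair or aggregate
  if (p["s"] >= 2 * psf_sigma * 0.999) { out$status <- "wide"; return(out) }
  if (p["s"] <= 0.5 * psf_sigma * 1.001) return(NULL)
  if (p["A"] <= 0) return(NULL)
  if (p["x"] <= min(xs) || p["x"] >= max(xs) ||
      p["y"] <= min(ys) || p["y"] >= max(ys)) return(NULL)
  out
}

# two-emitter refit for unresolved pairs: two Gaussians of fixed width
# psf_sigma with a shared constant background. Returns NULL unless the
# doublet model at least halves the single-emitter RSS with a credible
# separation.
fit_gaussian_doublet <- function(win, xs, ys, psf_sigma, rss_single) {
  z <- as.vector(win)
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  b0 <- stats::median(z)
  # init at the two brightest pixels at least 2 px apart
  o <- order(z, decreasing = TRUE)
  i1 <- o[1]
  i2 <- o[which((gx[o] - gx[i1])^2 + (gy[o] - gy[i1])^2 >= 4)[1]]
  if (is.na(i2)) return(NULL)
  a0 <- max(z[i1] - b0, 1e-3)
  start <- c(A1 = a0, x1 = gx[i1], y1 = gy[i1],
             A2 = max(z[i2] - b0, a0 / 4), x2 = gx[i2], y2 = gy[i2], b = b0)
  lo <- c(a0 * 1e-3, min(xs), min(ys), a0 * 1e-3, min(xs), min(ys), -Inf)
  hi <- c(Inf, max(xs), max(ys), Inf, max(xs), max(ys), Inf)
  s2 <- 2 * psf_sigma^2
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(par = start, lower = lo, upper = hi,
      fn = function(p) {
        p[["A1"]] * exp(-((gx - p[["x1"]])^2 + (gy - p[["y1"]])^2) / s2) +
        p[["A2"]] * exp(-((gx - p[["x2"]])^2 + (gy - p[["y2"]])^2) / s2) +
        p[["b"]] - z
      },
      control = minpack.lm::nls.lm.control(maxiter = 80))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  sep <- sqrt((p[["x1"]] - p[["x2"]])^2 + (p[["y1"]] - p[["y2"]])^2)
  if (fit$deviance > 0.5 * rss_single || sep < 1 ||
      p[["A1"]] <= 0 || p[["A2"]] <= 0) return(NULL)
  amp <- c(p[["A1"]], p[["A2"]])
  if (min(amp) < 0.15 * max(amp)) return(NULL)  # implausible faint partner
  list(x = c(p[["x1"]], p[["x2"]]), y = c(p[["y1"]], p[["y2"]]),
       A = amp, b = p[["b"]])
}

#' Detect and localize single molecules in one frame
#'
#' Candidate pixels are local maxima of the cross-correlation of the frame
#' with a zero-mean, unit-norm Gaussian kernel of width \code{psf_sigma}
#' (a matched filter). Candidates whose response falls below
#' \code{snr_threshold} times a robust noise scale (median absolute
#' deviation of the response) are discarded; survivors are refined to
#' subpixel precision by least-squares fitting of a 2-D Gaussian with
#' constant background in a window of side \code{4 * psf_sigma + 1} pixels.
#' Fits that come out substantially wider than the PSF are re-fitted with a
#' two-emitter model and split when the doublet clearly explains the data
#' (unresolved molecule pairs are common at the working density); remaining
#' fits pinned at the width bounds \code{[0.5, 2] * psf_sigma} are discarded
#' as likely aggregates or noise.
#'
#' Coordinates are continuous and zero-based: a molecule centered on pixel
#' (row r, col c) has \code{x = c - 0.5}, \code{y = r - 0.5}; multiply by the
#' pixel size to obtain µm.
#'
#' @param frame numeric matrix (one movie frame, counts).
#' @param psf_sigma PSF sigma in pixels.
#' @param snr_threshold detection threshold in robust-noise units.
#' @return \code{data.frame} with columns \code{x}, \code{y} (pixels),
#'   \code{amplitude}, \code{background}, \code{sigma}, \code{response}.
#' @export
detect_spots <- function(frame, psf_sigma, snr_threshold = 5) {
  stopifnot(is.matrix(frame), psf_sigma > 0)
  half <- ceiling(2 * psf_sigma)
  if (nrow(frame) < 2 * half + 1 || ncol(frame) < 2 * half + 1)
    stop("frame smaller than the fit window")
  k <- gauss_kernel(psf_sigma)
  resp <- EBImage::filter2(frame, k, boundary = "replicate")
  noise_sd <- stats::mad(resp)
  thr <- snr_threshold * noise_sd
  cand <- which(local_maxima(resp) & resp > thr, arr.ind = TRUE)
  out <- list()
  h <- nrow(frame); w <- ncol(frame)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    if (r - half < 1 || r + half > h || c - half < 1 || c + half > w) next
    win <- frame[(r - half):(r + half), (c - half):(c + half)]
    xs <- (c - half):(c + half) - 0.5
    ys <- (r - half):(r + half) - 0.5
    f <- fit_gaussian_spot(win, xs, ys, psf_sigma)
    if (is.null(f)) next
    # wide fits are candidate unresolved pairs: attempt a two-emitter refit
    if (f$status == "wide" || f$s > 1.4 * psf_sigma) {
      dbl <- fit_gaussian_doublet(win, xs, ys, psf_sigma, f$rss)
      if (!is.null(dbl)) {
        out[[length(out) + 1L]] <- data.frame(
          x = dbl$x, y = dbl$y, amplitude = dbl$A, background = dbl$b,
          sigma = psf_sigma, response = resp[r, c])
        next
      }
    }
    if (f$status != "ok") next
    out[[length(out) + 1L]] <- data.frame(
      x = f$x, y = f$y, amplitude = f$A, background = f$b, sigma = f$s,
      response = resp[r, c])
  }
  if (!length(out))
    return(data.frame(x = numeric(), y = numeric(), amplitude = numeric(),
                      background = numeric(), sigma = numeric(),
                      response = numeric()))
  res <- do.call(rbind, out)
  # adjacent candidates can both claim a member of an unresolved pair;
  # keep the brighter of any detections closer than one pixel
  if (nrow(res) > 1) {
    o <- order(res$amplitude, decreasing = TRUE)
    keep <- logical(nrow(res))
    for (i in o) {
      if (any(keep & (res$x - res$x[i])^2 + (res$y - res$y[i])^2 < 1)) next
      keep[i] <- TRUE
    }
    res <- res[keep, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Detect molecules in every frame of a movie
#'
#' Applies \code{\link{detect_spots}} frame by frame.
#'
#' @param stack a \code{frame_stack} or 3-D array (rows x cols x frames).
#' @inheritParams detect_spots
#' @return \code{data.frame} of localizations with a 0-based \code{frame}
#'   column prepended.
#' @export
detect_movie <- function(stack, psf_sigma, snr_threshold = 5) {
  n <- dim(stack)[3]
  res <- vector("list", n)
  for (f in seq_len(n)) {
    loc <- detect_spots(stack[, , f], psf_sigma, snr_threshold)
    if (nrow(loc)) res[[f]] <- cbind(frame = f - 1L, loc)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(frame = integer(), x = numeric(), y = numeric(),
                      amplitude = numeric(), background = numeric(),
                      sigma = numeric(), response = numeric()))
  do.call(rbind, res)
}

#' Match detections to ground-truth positions
#'
#' A ground-truth molecule counts as recalled when any detection lies within
#' \code{radius} of its true position; a detection is a true positive when
#' any ground-truth molecule lies within \code{radius}. Matching is not
#' one-to-one: a single detection covering an unresolved (sub-diffraction)
#' pair is attributed to both molecules.
#'
#' @param truth,detected data.frames with columns \code{x}, \code{y}
#'   (pixels) for one frame.
#' @param radius matching radius in pixels.
#' @return list with \code{recall}, \code{precision}, \code{n_truth},
#'   \code{n_detected}.
#' @export
match_localizations <- function(truth, detected, radius = 2) {
  nt <- nrow(truth); nd <- nrow(detected)
  if (nt == 0 || nd == 0)
    return(list(recall = ifelse(nt == 0, NA_real_, 0),
                precision = ifelse(nd == 0, NA_real_, 0),
                n_truth = nt, n_detected = nd))
  d2 <- outer(truth$x, detected$x, "-")^2 + outer(truth$y, detected$y, "-")^2
  hit_t <- apply(d2, 1, min) <= radius^2
  hit_d <- apply(d2, 2, min) <= radius^2
  list(recall = mean(hit_t), precision = mean(hit_d),
       n_truth = nt, n_detected = nd)
}

#' Check that single-molecule intensities are unimodal
#'
#' Counts the modes of a kernel-density estimate of log10 amplitudes
#' (Silverman's rule-of-thumb bandwidth). Single fluorophores give one mode;
#' a second mode at roughly double or triple intensity indicates unresolved
#' multimers.
#'
#' @param localizations data.frame with an \code{amplitude} column, or a
#'   numeric vector of amplitudes.
#' @param min_n minimum sample size; smaller inputs are flagged underpowered
#'   rather than rejected.
#' @return list with \code{mode_count}, \code{quartiles} (25/50/75% of
#'   amplitude), \code{underpowered}.
#' @export
check_intensity_unimodality <- function(localizations, min_n = 50) {
  amp <- if (is.data.frame(localizations)) localizations$amplitude
         else as.numeric(localizations)
  amp <- amp[is.finite(amp) & amp > 0]
  if (length(amp) < min_n)
    return(list(mode_count = NA_integer_,
                quartiles = if (length(amp)) stats::quantile(amp, c(.25, .5, .75))
                            else c(NA, NA, NA),
                underpowered = TRUE))
  d <- stats::density(log10(amp), bw = "nrd0")
  y <- d$y
  is_mode <- y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf)
  # ignore shoulder wiggles below 5% of the highest mode
  modes <- sum(is_mode & y > 0.05 * max(y))
  list(mode_count = as.integer(modes),
       quartiles = stats::quantile(amp, c(.25, .5, .75)),
       underpowered = FALSE)
}

#' Count photobleaching steps in an intensity trace
#'
#' Selects among 0-, 1- and 2-step piecewise-constant models of the trace by
#' penalized residual sum of squares. Each step adds two parameters (a level
#' and a change-point location), so the BIC-style penalty is
#' \code{2 * log(n) * sigma^2} per parameter, i.e. \code{4 * log(n) * sigma^2}
#' per step, where \code{sigma} is a robust noise scale from the first
#' differences. Genuine single fluorophores bleach in one step; two steps
#' indicate a dimer.
#'
#' @param trace numeric vector, intensity per frame (length >= 4).
#' @return list with \code{step_count} and \code{change_points} (1-based
#'   index of the last frame before each drop).
#' @export
count_photobleach_steps <- function(trace) {
  n <- length(trace)
  if (n < 4) stop("trace must contain at least 4 frames")
  sigma2 <- (stats::mad(diff(trace)) / sqrt(2))^2
  penalty <- 4 * log(n) * sigma2  # 2 log(n) sigma^2 per parameter, 2 per step
  css <- cumsum(trace)
  css2 <- cumsum(trace^2)
  seg_rss <- function(i, j) { # RSS of constant fit on trace[i..j]
    s <- css[j] - if (i > 1) css[i - 1] else 0
    s2 <- css2[j] - if (i > 1) css2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  rss0 <- seg_rss(1, n)
  best1 <- list(rss = Inf, cp = NA)
  for (t in 1:(n - 1)) {
    r <- seg_rss(1, t) + seg_rss(t + 1, n)
    if (r < best1$rss) best1 <- list(rss = r, cp = t)
  }
  best2 <- list(rss = Inf, cp = c(NA, NA))
  if (n >= 6) {
    for (t1 in 1:(n - 2)) {
      r1 <- seg_rss(1, t1)
      for (t2 in (t1 + 1):(n - 1)) {
        r <- r1 + seg_rss(t1 + 1, t2) + seg_rss(t2 + 1, n)
        if (r < best2$rss) best2 <- list(rss = r, cp = c(t1, t2))
      }
    }
  }
  cost <- c(rss0, best1$rss + penalty, best2$rss + 2 * penalty)
  k <- which.min(cost) - 1L
  cps <- switch(k + 1L, integer(0), best1$cp, best2$cp)
  list(step_count = k, change_points = as.integer(cps))
}
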