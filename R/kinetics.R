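# Dwell-time survival curves, two-order exponential decay fitting,
# photobleach control, on-rate estimation and paired per-cell comparisons.

#' Empirical survival curve of a dwell-time sample
#'
#' Computes \code{S(t_k)}, the fraction of molecules with dwell time at
#' least \code{t_k = k * dt}, for \code{k = 1 .. k_max}. Since every
#' observed dwell is at least one frame, \code{S(t_1) = 1} by construction.
#' The curve is truncated where fewer than a fraction \code{truncation} of
#' the molecules remain (default 0.5%): the long-dwell tail is noisy but
#' represents less than 0.5% of the total molecules, and the model is fitted
#' to the vast majority of the data.
#'
#' @param sample a \code{\link{dwell_sample}}.
#' @param truncation survival fraction below which points are dropped.
#' @param include_censored if \code{FALSE} (default) dwells censored by the
#'   movie boundaries are excluded.
#' @return data.frame with columns \code{t} (s) and \code{S}; attributes
#'   \code{dt}, \code{n} (dwells used) and \code{truncation_time} (first
#'   excluded time, \code{Inf} when nothing was truncated).
#' @export
survival_curve <- function(sample, truncation = 0.005,
                           include_censored = FALSE) {
  dt <- attr(sample, "dt")
  tt <- if (include_censored) sample$dwell_s
        else sample$dwell_s[!sample$censored]
  if (length(tt) < 1) stop("no uncensored dwell times in sample")
  k <- round(tt / dt)
  kmax_all <- max(k)
  S <- vapply(seq_len(kmax_all), function(j) mean(k >= j), numeric(1))
  keep <- S >= truncation
  kmax <- if (any(keep)) max(which(keep)) else 1L
  out <- data.frame(t = seq_len(kmax) * dt, S = S[seq_len(kmax)])
  attr(out, "dt") <- dt
  attr(out, "n") <- length(tt)
  attr(out, "truncation_time") <- if (kmax < kmax_all) (kmax + 1) * dt else Inf
  out
}

exp2_model <- function(p, t) {
  p[["y0"]] + p[["A1"]] * exp(-t / p[["tau1"]]) +
    p[["A2"]] * exp(-t / p[["tau2"]])
}

#' Fit a two-order exponential decay to a survival curve
#'
#' Unweighted nonlinear least squares of
#' \deqn{y = y_0 + A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}}
#' with all parameters bounded below by zero, Levenberg-Marquardt
#' optimization, and five jittered restarts around the default
#' initialization (\code{tau1 = dt}, \code{tau2} twice the mean dwell,
#' \code{A1 = A2 = 0.5}, \code{y0 = 0}); the lowest-RSS converged fit wins.
#' Components are reordered after convergence so that \code{tau2 >= tau1}:
#' the slower constant \code{tau2} is the dwell-time statistic used for
#' pairwise comparisons.
#'
#' @param curve a survival curve from \code{\link{survival_curve}}, or any
#'   data.frame with columns \code{t} and \code{S} (or \code{y}).
#' @param n_starts number of jittered initializations.
#' @param weights optional per-point weights (default unweighted).
#' @return object of class \code{"exp2_fit"}: list with \code{y0},
#'   \code{A1}, \code{tau1}, \code{A2}, \code{tau2}, \code{rss}, \code{se}
#'   (named parameter standard errors), \code{n_points},
#'   \code{truncation_time}, \code{converged}.
#' @export
fit_two_exponential <- function(curve, n_starts = 5, weights = NULL) {
  t <- curve$t
  y <- if ("S" %in% names(curve)) curve$S else curve$y
  if (length(t) < 6) stop("need at least 6 points to fit 5 parameters")
  dt <- attr(curve, "dt")
  if (is.null(dt)) dt <- min(diff(sort(unique(t))))
  w <- if (is.null(weights)) rep(1, length(t)) else sqrt(weights)
  # mean dwell from the curve itself: E[T] ~ dt * sum(S) / S(t_1); the
  # amplitude start scales with the curve so fits are invariant to
  # rescaling (0.5 for a unit-normalized survival curve)
  scale0 <- max(y[1], .Machine$double.eps)
  mean_dwell <- dt * sum(y) / scale0
  start0 <- c(y0 = 0, A1 = 0.5 * scale0, tau1 = dt, A2 = 0.5 * scale0,
              tau2 = max(2 * mean_dwell, 2 * dt))
  lower <- c(0, 0, dt * 1e-3, 0, dt * 1e-3)
  best <- NULL
  set_jitter <- function(i) {
    if (i == 1) return(start0)
    f <- exp(stats::runif(5, -0.7, 0.7))
    s <- start0 * f
    s[["y0"]] <- 0
    s
  }
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = set_jitter(i), lower = lower,
        fn = function(p) w * (exp2_model(p, t) - y),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(y0 = NA, A1 = NA, tau1 = NA, A2 = NA, tau2 = NA,
                          rss = NA, se = NULL, n_points = length(t),
                          truncation_time = attr(curve, "truncation_time"),
                          converged = FALSE),
                     class = "exp2_fit"))
  p <- best$par
  se <- tryCatch(sqrt(diag(solve(best$hessian)) *
                        best$deviance / max(length(t) - 5, 1)),
                 error = function(e) rep(NA_real_, 5))
  names(se) <- names(p)
  if (p[["tau1"]] > p[["tau2"]]) {   # canonical order: tau2 is the slower
    p[c("A1", "tau1", "A2", "tau2")] <- p[c("A2", "tau2", "A1", "tau1")]
    se[c("A1", "tau1", "A2", "tau2")] <- se[c("A2", "tau2", "A1", "tau1")]
  }
  structure(list(y0 = p[["y0"]], A1 = p[["A1"]], tau1 = p[["tau1"]],
                 A2 = p[["A2"]], tau2 = p[["tau2"]],
                 rss = best$deviance, se = se, n_points = length(t),
                 truncation_time = attr(curve, "truncation_time"),
                 converged = TRUE),
            class = "exp2_fit")
}

#' @export
print.exp2_fit <- function(x, ...) {
  cat("Two-order exponential decay fit\n")
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  y0 = %.4g, A1 = %.4g, tau1 = %.4g s, A2 = %.4g, tau2 = %.4g s\n",
              x$y0, x$A1, x$tau1, x$A2, x$tau2))
  cat(sprintf("  RSS = %.4g on %d points (truncated at %s)\n",
              x$rss, x$n_points,
              if (is.finite(x$truncation_time))
                sprintf("%.3g s", x$truncation_time) else "none"))
  invisible(x)
}

#' Photobleach rate from a membrane-anchored control
#'
#' The dwell-time distribution of a membrane-anchored fluorophore (CAAX
#' construct) reflects photobleaching alone. A single-exponential decay is
#' fitted to its survival curve; the bleach rate is \code{k_b = 1/tau}.
#' The rate is reported alongside species off-rates, never silently
#' subtracted: apparent dwell times are the comparison statistic because an
#' absolute bleach deconvolution is not reliable at these photon budgets.
#'
#' @param caax_sample a \code{\link{dwell_sample}} from the control.
#' @param truncation tail truncation fraction as in
#'   \code{\link{survival_curve}}.
#' @return list with \code{k_b} (1/s), \code{tau} (s), \code{rss},
#'   \code{n_points}.
#' @export
fit_photobleach_control <- function(caax_sample, truncation = 0.005) {
  curve <- survival_curve(caax_sample, truncation = truncation)
  t <- curve$t; y <- curve$S
  mean_dwell <- attr(curve, "dt") * sum(y)
  fit <- minpack.lm::nls.lm(
    par = c(A = 1, tau = max(mean_dwell, attr(curve, "dt"))),
    lower = c(0, attr(curve, "dt") * 1e-3),
    fn = function(p) p[["A"]] * exp(-t / p[["tau"]]) - y,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  tau <- fit$par[["tau"]]
  list(k_b = 1 / tau, tau = tau, rss = fit$deviance, n_points = length(t))
}

#' Photobleach-corrected off-rate
#'
#' \code{1/tau2 - k_b}, reported for reference only; negative values are
#' floored at zero (bleaching slower than the species decay is required for
#' the correction to make sense).
#'
#' @param tau2 slow dwell constant, s.
#' @param k_b photobleach rate, 1/s.
#' @return corrected off-rate, 1/s.
#' @export
corrected_koff <- function(tau2, k_b) pmax(1 / tau2 - k_b, 0)

#' Appearance-based association rate per region
#'
#' \code{K_on(region) = appearances / (region area * duration)}, counting
#' the first appearance of every track whose start is observed (tracks
#' already present in frame 0 are not appearances). With
#' \code{normalize_by_ligand} the rate is additionally divided by the
#' region's mean ligand intensity.
#'
#' @param tracks region-assigned linked localizations (see
#'   \code{\link{assign_region}}), or a track summary with
#'   \code{region_class} and \code{censored_start} columns.
#' @param mask a classified \code{region_mask} (provides areas and mean
#'   ligand intensities).
#' @param duration movie duration, s.
#' @param normalize_by_ligand divide by mean ligand intensity per region.
#' @return data.frame with one row per region class: \code{region_class},
#'   \code{n_appearances}, \code{area_um2}, \code{k_on}
#'   (appearances/µm²/s, optionally per intensity unit).
#' @export
estimate_kon <- function(tracks, mask, duration, normalize_by_ligand = FALSE) {
  stopifnot(duration > 0, inherits(mask, "region_mask"))
  if (!"censored_start" %in% names(tracks)) {
    n_frames_guess <- max(tracks$frame) + 1L
    sm <- summarize_tracks(tracks, n_frames_guess)
    sm$region_class <- tracks$region_class[match(sm$track_id, tracks$track_id)]
    tracks <- sm
  }
  info <- mask$info[!is.na(mask$info$region_class), , drop = FALSE]
  zero_area <- info$area_um2 <= 0
  if (any(zero_area)) {
    warning("excluding ", sum(zero_area), " zero-area corral(s)")
    info <- info[!zero_area, , drop = FALSE]
  }
  regions <- unique(info$region_class)
  res <- lapply(regions, function(rg) {
    area <- sum(info$area_um2[info$region_class == rg])
    n_app <- sum(tracks$region_class == rg & !tracks$censored_start,
                 na.rm = TRUE)
    kon <- n_app / (area * duration)
    if (normalize_by_ligand) {
      mlig <- stats::weighted.mean(info$mean_ligand[info$region_class == rg],
                                   info$area_um2[info$region_class == rg])
      kon <- kon / mlig
    }
    data.frame(region_class = rg, n_appearances = n_app, area_um2 = area,
               k_on = kon, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Paired per-cell comparison of mobile vs immobile values
#'
#' Classical paired Student's t-test on per-cell (mobile - immobile)
#' differences with \code{n - 1} degrees of freedom. Cell-to-cell variation
#' of kinetic parameters is of the same order as the mobile-immobile
#' difference, so only this side-by-side pairing within each cell resolves
#' the clustering effect. Per-cell differences are returned so the pairing
#' can be inspected.
#'
#' @param values data.frame with columns \code{cell_id}, \code{mobile},
#'   \code{immobile}; rows with a missing member are dropped with a warning.
#' @return list with \code{statistic} (t), \code{p_value}, \code{df},
#'   \code{differences} (named by cell), \code{mean_difference},
#'   \code{zero_variance} flag.
#' @export
paired_region_comparison <- function(values) {
  stopifnot(all(c("mobile", "immobile") %in% names(values)))
  ok <- stats::complete.cases(values[, c("mobile", "immobile")])
  if (any(!ok)) warning("dropping ", sum(!ok), " incomplete pair(s)")
  values <- values[ok, , drop = FALSE]
  n <- nrow(values)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- values$mobile - values$immobile
  names(d) <- if ("cell_id" %in% names(values)) values$cell_id else seq_len(n)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0) {
      out <- list(statistic = 0, p_value = 1, df = n - 1)
    } else {
      # all differences identical and non-zero: degenerate, report as
      # significant beyond machine precision
      out <- list(statistic = sign(mean(d)) * Inf,
                  p_value = .Machine$double.xmin, df = n - 1)
    }
    zero_var <- TRUE
  } else {
    tt <- stats::t.test(values$mobile, values$immobile, paired = TRUE)
    out <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                df = unname(tt$parameter))
    zero_var <- FALSE
  }
  c(out, list(differences = d, mean_difference = mean(d),
              zero_variance = zero_var))
}
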