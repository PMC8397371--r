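# Independent oracles used to cross-check the package's estimators.

# Maximum-likelihood fit of the frame-quantized two-exponential mixture.
# Observed frame counts k (dwell / dt) follow, conditional on k >= 1,
#   P(K >= k) = [B1 r1^(k-1) + B2 r2^(k-1)] / (B1 + B2),  r_i = exp(-dt/tau_i)
# with B_i the phase-averaged component weights. This likelihood route is
# independent of the survival-curve least-squares path it checks.
mle_quantized_mixture <- function(dwell_s, dt) {
  k <- round(dwell_s / dt)
  tab <- table(k)
  kv <- as.integer(names(tab))
  nv <- as.integer(tab)
  nll <- function(par) {
    f <- stats::plogis(par[1])
    tau1 <- exp(par[2]); tau2 <- exp(par[3])
    g <- function(tau) (tau / dt) * (1 - exp(-dt / tau))
    B1 <- f * g(tau1); B2 <- (1 - f) * g(tau2)
    r1 <- exp(-dt / tau1); r2 <- exp(-dt / tau2)
    pk <- (B1 * r1^(kv - 1) * (1 - r1) + B2 * r2^(kv - 1) * (1 - r2)) /
      (B1 + B2)
    -sum(nv * log(pmax(pk, 1e-300)))
  }
  m <- mean(dwell_s)
  fit <- stats::optim(c(0, log(dt), log(2 * m)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  taus <- sort(exp(fit$par[2:3]))
  list(tau1 = taus[1], tau2 = taus[2],
       f1 = if (exp(fit$par[2]) <= exp(fit$par[3]))
         stats::plogis(fit$par[1]) else 1 - stats::plogis(fit$par[1]))
}

# Brute-force optimal one-to-one frame linking: enumerates all injective
# partial assignments between <=6 tracks and <=6 localizations, keeping
# pairs within max_disp, maximizing matches then minimizing total distance.
brute_force_assignment <- function(prev, cur, max_disp) {
  np <- nrow(prev); nc <- nrow(cur)
  if (np == 0 || nc == 0) return(cbind(integer(0), integer(0)))
  d <- sqrt(outer(prev$x, cur$x, "-")^2 + outer(prev$y, cur$y, "-")^2)
  best <- NULL
  best_key <- c(-1, Inf)
  rec <- function(i, used, pairs) {
    if (i > np) {
      if (nrow(pairs)) {
        tot <- sum(d[pairs])
        key <- c(nrow(pairs), tot)
      } else key <- c(0, 0)
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2])) {
        best_key <<- key
        best <<- pairs
      }
      return(invisible())
    }
    rec(i + 1, used, pairs)                       # leave track i unmatched
    for (j in seq_len(nc)) {
      if (!used[j] && d[i, j] <= max_disp) {
        used[j] <- TRUE
        rec(i + 1, used, rbind(pairs, c(i, j)))
        used[j] <- FALSE
      }
    }
  }
  rec(1, rep(FALSE, nc), matrix(integer(0), 0, 2))
  best
}

# closed-form mean observed dwell under exponential competition
mixture_mean_dwell <- function(f1, tau1, tau2, k_b = 0) {
  f1 / (1 / tau1 + k_b) + (1 - f1) / (1 / tau2 + k_b)
}

# render a single emitter at (x, y) px on a blank frame (pixel units,
# integrated Gaussian, Poisson photon noise + background + read noise)
render_single_emitter <- function(h, w, x, y, photons, sigma,
                                  background = 100, read_noise = 2) {
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  fx <- stats::pnorm(xs + 1, x, sigma) - stats::pnorm(xs, x, sigma)
  fy <- stats::pnorm(ys + 1, y, sigma) - stats::pnorm(ys, y, sigma)
  signal <- photons * outer(fy, fx)
  frame <- matrix(stats::rpois(h * w, signal), h, w) + background +
    matrix(stats::rnorm(h * w, 0, read_noise), h, w)
  pmax(frame, 0)
}

reported_tau2_conditions <- function() {
  data.frame(
    species = c("Grb2", "Grb2", "SOS", "SOS", "NCK", "NCK", "NWASP", "NWASP",
                "Grb2_COS7", "Grb2_COS7", "NWASP_COS7", "NWASP_COS7"),
    region = rep(c("mobile", "immobile"), 6),
    tau2_ms = c(508, 451, 207, 150, 165, 143, 156, 140, 310, 241, 235, 214),
    tau1_ms = c(80, 80, 60, 60, 60, 60, 60, 60, 80, 80, 60, 60),
    stringsAsFactors = FALSE)
}
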