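test_that("survival curves count dwell fractions exactly", {
  s <- dwell_sample(c(0.05, 0.1, 0.1, 0.15), dt = 0.05)
  cv <- survival_curve(s)
  expect_equal(cv$t, c(0.05, 0.10, 0.15))
  expect_equal(cv$S, c(1, 0.75, 0.25))
  # all dwells equal: survival 1 over the whole observed range
  s2 <- dwell_sample(rep(0.2, 10), dt = 0.05)
  cv2 <- survival_curve(s2)
  expect_true(all(cv2$S == 1))
  expect_equal(max(cv2$t), 0.2)
  expect_error(survival_curve(dwell_sample(numeric(0), dt = 0.05)), "no ")
})

test_that("survival curves are non-increasing, start at 1, and match the analytic mixture", {
  set.seed(51)
  for (i in 1:5) {
    f1 <- stats::runif(1, 0.3, 0.7)
    tau2 <- stats::runif(1, 0.2, 0.6)
    n <- 5000
    tt <- simulate_dwell_times(n, f1, 0.08, tau2)
    s <- dwell_sample(quantize_dwells(tt, 0.05, random_phase = FALSE), 0.05)
    cv <- survival_curve(s)
    expect_equal(cv$S[1], 1)
    expect_true(all(diff(cv$S) <= 0))
    # analytic survival of the quantized mixture (ceil(T/dt) >= k <=> T > (k-1) dt)
    Sa <- (f1 * exp(-(cv$t - 0.05) / 0.08) +
           (1 - f1) * exp(-(cv$t - 0.05) / tau2))
    se <- sqrt(Sa * (1 - Sa) / n)
    expect_true(all(abs(cv$S - Sa) <= 3 * se + 1e-9))
  }
})

test_that("the two-exponential fit is exact on noiseless curves", {
  tg <- (1:40) * 0.05
  curve <- data.frame(t = tg, S = 0.6 * exp(-tg / 0.1) + 0.4 * exp(-tg / 0.5))
  f <- fit_two_exponential(curve)
  expect_equal(f$tau1, 0.1, tolerance = 1e-4)
  expect_equal(f$tau2, 0.5, tolerance = 1e-4)
  expect_equal(f$y0, 0, tolerance = 1e-6)
  expect_equal(f$A1, 0.6, tolerance = 1e-3)
  # too few points rejected
  expect_error(fit_two_exponential(curve[1:4, ]), "6 points")
})

test_that("fitting is invariant to curve rescaling and component order", {
  tg <- (1:30) * 0.05
  y <- 0.55 * exp(-tg / 0.08) + 0.45 * exp(-tg / 0.45)
  f1 <- fit_two_exponential(data.frame(t = tg, S = y))
  f2 <- fit_two_exponential(data.frame(t = tg, S = 13.7 * y))
  expect_equal(f2$tau1, f1$tau1, tolerance = 1e-4)
  expect_equal(f2$tau2, f1$tau2, tolerance = 1e-4)
  expect_equal(f2$A2 / f1$A2, 13.7, tolerance = 1e-3)
  # swapping the components before fitting leaves (tau1, tau2) unchanged
  yswap <- 0.45 * exp(-tg / 0.45) + 0.55 * exp(-tg / 0.08)
  f3 <- fit_two_exponential(data.frame(t = tg, S = yswap))
  expect_equal(f3$tau1, f1$tau1, tolerance = 1e-4)
  expect_equal(f3$tau2, f1$tau2, tolerance = 1e-4)
  expect_lte(f1$tau1, f1$tau2)
})

test_that("tau2 recovery agrees with the censored-mixture likelihood oracle", {
  set.seed(52)
  for (tau2 in c(0.150, 0.451)) {
    tau1 <- if (tau2 > 0.3) 0.08 else 0.06
    rel_ls <- rel_ml <- numeric(10)
    for (i in 1:10) {
      tt <- simulate_dwell_times(10000, 0.55, tau1, tau2)
      q <- quantize_dwells(tt, 0.05)
      fit <- fit_two_exponential(survival_curve(dwell_sample(q, 0.05)))
      ora <- mle_quantized_mixture(q, 0.05)
      rel_ls[i] <- fit$tau2 / tau2 - 1
      rel_ml[i] <- ora$tau2 / tau2 - 1
    }
    expect_lt(abs(median(rel_ls)), 0.05)
    expect_lt(abs(median(rel_ml)), 0.05)
    # the two routes agree with each other
    expect_lt(median(abs(rel_ls - rel_ml)), 0.08)
  }
})

test_that("photobleach control recovers the bleach rate and orders below species decay", {
  set.seed(53)
  kb <- 0.5
  tt <- stats::rexp(20000, kb)
  s <- dwell_sample(quantize_dwells(tt, 0.05), 0.05)
  fit <- fit_photobleach_control(s)
  expect_equal(fit$k_b, kb, tolerance = 0.05)
  # control survival decays more slowly than the species curve at every t
  sp <- dwell_sample(quantize_dwells(
    simulate_dwell_times(20000, 0.55, 0.08, 0.5), 0.05), 0.05)
  cs <- survival_curve(s); cp <- survival_curve(sp)
  kk <- seq_len(min(nrow(cs), nrow(cp)))[-1]
  expect_true(all(cs$S[kk] >= cp$S[kk]))
  # corrected off-rate algebra
  expect_gte(corrected_koff(0.5, 0.5), 0)
  expect_equal(corrected_koff(0.5, 0.5), 1 / 0.5 - 0.5)
  expect_equal(corrected_koff(10, 0.5), 0)  # floored when tau2 > 1/k_b
})

test_that("appearance-based Kon recovers the configured rate", {
  lay <- make_pattern_layout(2, 2, radius = 1.5, spacing = 4,
                             pixel_size = 0.16)
  mask <- layout_to_mask(lay)
  # zero appearances
  tr0 <- data.frame(track_id = integer(), frame = integer(),
                    x = numeric(), y = numeric(),
                    region_class = character(),
                    censored_start = logical())
  k0 <- estimate_kon(tr0, mask, duration = 10)
  expect_true(all(k0$k_on == 0))
  # simulated: long dwells so virtually every arrival is observed
  cfg <- sim_config(k_on = 0.05, tau1 = 5, tau2 = 5, k_b = 0,
                    n_frames = 2000, seed = 54)
  ev <- simulate_binding_events(lay, cfg, include_positions = FALSE)
  sm <- data.frame(track_id = ev$events$event_id,
                   region_class = ev$events$region_class,
                   censored_start = ev$events$first_frame == 0,
                   n_obs = ev$events$n_frames_obs)
  sm <- sm[ev$events$n_frames_obs >= 1, ]
  kon <- estimate_kon(sm, mask, duration = 2000 * 0.05)
  for (rg in c("mobile", "immobile")) {
    est <- kon$k_on[kon$region_class == rg]
    n <- kon$n_appearances[kon$region_class == rg]
    se <- 0.05 * 3 / sqrt(n)   # 3 Poisson SE on the rate
    expect_lt(abs(est - 0.05), se)
  }
})

test_that("the Kon estimator is unbiased over many seeds", {
  lay <- make_pattern_layout(1, 2, radius = 1.5, spacing = 4,
                             pixel_size = 0.16)
  mask <- layout_to_mask(lay)
  ests <- vapply(1:100, function(s) {
    cfg <- sim_config(k_on = 3, tau1 = 20, tau2 = 20, k_b = 0,
                      n_frames = 500, seed = 600 + s)
    ev <- simulate_binding_events(lay, cfg, include_positions = FALSE)
    keep <- ev$events$n_frames_obs >= 1
    sm <- data.frame(track_id = ev$events$event_id[keep],
                     region_class = ev$events$region_class[keep],
                     censored_start = ev$events$first_frame[keep] == 0,
                     n_obs = ev$events$n_frames_obs[keep])
    # appearances register at frames 1..n-1, an arrival window of (n-1) dt
    kon <- estimate_kon(sm, mask, duration = 499 * 0.05)
    mean(kon$k_on)
  }, numeric(1))
  # dwells are ~400x the frame interval, so the zero-frame loss is ~0.1%
  expect_lt(abs(mean(ests) - 3) / 3, 0.01)
})

test_that("paired comparisons handle trivial and degenerate inputs", {
  idn <- data.frame(cell_id = 1:4, mobile = c(2, 3, 4, 5),
                    immobile = c(2, 3, 4, 5))
  r <- paired_region_comparison(idn)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # constant non-zero differences: degenerate, flagged
  deg <- data.frame(cell_id = 1:3, mobile = c(2, 3, 4), immobile = c(1, 2, 3))
  rd <- paired_region_comparison(deg)
  expect_true(rd$zero_variance)
  expect_lt(rd$p_value, 1e-300)
  expect_equal(unname(rd$differences), rep(1, 3))
  # incomplete pairs dropped with warning
  inc <- data.frame(cell_id = 1:3, mobile = c(1, 2, NA),
                    immobile = c(0.5, 1, 2))
  expect_warning(ri <- paired_region_comparison(inc), "incomplete")
  expect_equal(ri$df, 1)
  # agreement with the standard implementation on regular data
  set.seed(55)
  reg <- data.frame(cell_id = 1:8, mobile = stats::rnorm(8, 0.5, 0.1),
                    immobile = stats::rnorm(8, 0.45, 0.1))
  rr <- paired_region_comparison(reg)
  tt <- stats::t.test(reg$mobile, reg$immobile, paired = TRUE)
  expect_equal(rr$statistic, unname(tt$statistic))
  expect_equal(rr$p_value, tt$p.value)
  # hand-computed t as an independent check
  d <- reg$mobile - reg$immobile
  expect_equal(rr$statistic, mean(d) / (sd(d) / sqrt(8)))
})

test_that("paired test power matches a Monte-Carlo oracle at the study design", {
  # 5 cells, true difference 57 ms, cell-to-cell sd 60 ms
  set.seed(56)
  n <- 5; delta <- 0.057; sdc <- 0.060
  rejections <- vapply(seq_len(1500), function(i) {
    d <- stats::rnorm(n, delta, sdc)
    vals <- data.frame(cell_id = seq_len(n), mobile = d, immobile = 0)
    paired_region_comparison(vals)$p_value < 0.05
  }, logical(1))
  power_mc <- mean(rejections)
  power_ref <- stats::power.t.test(n = n, delta = delta, sd = sdc,
                                   type = "one.sample")$power
  expect_lt(abs(power_mc - power_ref), 3 * sqrt(power_ref * (1 - power_ref) / 1500))
})
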