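test_that("corrected FRET handles the defining cases", {
  p <- fret_model_params(background_donor = 10, background_acceptor = 20,
                         leakage_fraction = 0, read_noise_sd = 0)
  mk_trace <- function(donor, acceptor) {
    structure(data.frame(frame_index = seq_along(donor) - 1L,
                         time_s = (seq_along(donor) - 1) * 0.033,
                         donor = donor, acceptor = acceptor),
              frame_interval = 0.033,
              class = c("fluorescence_trace", "data.frame"))
  }
  # equal corrected channels -> E = 0.5
  fs <- compute_fret(mk_trace(510, 520), p)
  expect_equal(fs$fret[1], 0.5)
  # zero corrected acceptor -> E = 0
  fs <- compute_fret(mk_trace(510, 20), p)
  expect_equal(fs$fret[1], 0)
  # all-masked trace is flagged
  fs <- compute_fret(mk_trace(c(10, 10), c(20, 20)), p, intensity_floor = 5)
  expect_true(fs$all_masked)
})

test_that("noiseless rendered traces round-trip to the ground-truth FRET", {
  p <- fret_params_effective(112, read_noise_sd = 0)
  cfg <- sim_config(n_frames = 4000, rng_seed = 5)
  tr <- simulate_trajectory(cfg)
  trace <- render_intensities(tr, p)
  fs <- compute_fret(trace, p)
  bound <- tr$bound
  e_true <- position_to_fret(tr$position[bound], p)
  expect_lt(max(abs(fs$fret[bound] - e_true)), 1e-12)
  expect_true(all(fs$fret[!bound] == 0))
})

test_that("event segmentation applies threshold, min length and abortive cutoff", {
  e <- c(rep(0.05, 30), rep(0.7, 91), rep(0.05, 30))
  fs <- structure(list(fret = e, valid = rep(TRUE, length(e)),
                       frame_interval = 0.033, all_masked = FALSE),
                  class = "fret_series")
  ev <- segment_events(fs, on_threshold = 0.6, min_frames = 3)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$start_frame, 30L)
  expect_identical(ev$end_frame, 121L)
  # 45 frames at 33 ms = 1.485 s < 2 s -> abortive
  e2 <- c(rep(0.05, 10), rep(0.8, 45), rep(0.05, 10))
  fs2 <- structure(list(fret = e2, valid = rep(TRUE, length(e2)),
                        frame_interval = 0.033, all_masked = FALSE),
                   class = "fret_series")
  ev2 <- segment_events(fs2)
  expect_equal(ev2$duration_s, 45 * 0.033)
  expect_identical(ev2$classification, "abortive")
  # nothing above threshold -> no events
  fs3 <- structure(list(fret = rep(0.5, 100), valid = rep(TRUE, 100),
                        frame_interval = 0.033, all_masked = FALSE),
                   class = "fret_series")
  expect_identical(nrow(segment_events(fs3, on_threshold = 0.6)), 0L)
})

test_that("anticorrelation score is exact for constructed channels and tight under the null", {
  mk_trace <- function(donor, acceptor) {
    structure(data.frame(frame_index = seq_along(donor) - 1L,
                         time_s = (seq_along(donor) - 1) * 0.033,
                         donor = donor, acceptor = acceptor),
              frame_interval = 0.033,
              class = c("fluorescence_trace", "data.frame"))
  }
  ev <- list(start_frame = 0L, end_frame = 50L)
  set.seed(1)
  d <- cumsum(rnorm(50))
  expect_equal(anticorrelation_score(mk_trace(d, 100 - d), ev), -1)
  expect_equal(anticorrelation_score(mk_trace(d, d), ev), 1)
  expect_warning(anticorrelation_score(mk_trace(rep(1, 50), d), ev),
                 "zero-variance")
  # independent white noise: |score| < 0.1 in at least 19/20 seeds
  ok <- 0L
  ev2 <- list(start_frame = 0L, end_frame = 1000L)
  for (s in 1:20) {
    set.seed(s)
    sc <- anticorrelation_score(mk_trace(rnorm(1000), rnorm(1000)), ev2)
    ok <- ok + (abs(sc) < 0.1)
  }
  expect_gte(ok, 19L)
})

test_that("event autocorrelation matches the O(n^2) oracle and handles degenerate input", {
  set.seed(7)
  fx <- events_from_series(list(0.5 + 0.1 * ar1_series(300, 0.8)))
  ac <- autocorrelate_events(fx$events, fx$fret, max_lag = 1)
  e <- fx$fret$fret[(fx$events$start_frame[1] + 1):fx$events$end_frame[1]]
  oracle <- autocorr_oracle(e, length(ac$G) - 1)
  expect_lt(max(abs(ac$G - oracle)), 1e-10)
  expect_equal(ac$G[1], 1)
  # white noise: G(lag >= 1) consistent with zero
  set.seed(8)
  fxw <- events_from_series(list(0.5 + 0.05 * rnorm(3000)))
  acw <- autocorrelate_events(fxw$events, fxw$fret, max_lag = 0.5)
  expect_true(all(abs(acw$G[-1]) < 3 / sqrt(acw$npairs[-1])))
  # constant FRET in all events is an error
  fxc <- events_from_series(list(rep(0.7, 200)))
  expect_error(autocorrelate_events(fxc$events, fxc$fret), "variance")
})

test_that("abortive events are excluded from the pooled autocorrelation", {
  set.seed(9)
  long_ev <- 0.5 + 0.1 * ar1_series(300, 0.8)   # ~10 s, kept
  short_ev <- 0.5 + 0.1 * ar1_series(30, 0.8)   # ~1 s, abortive
  fx <- events_from_series(list(long_ev, short_ev))
  expect_identical(fx$events$classification, c("on", "abortive"))
  ac <- autocorrelate_events(fx$events, fx$fret)
  expect_identical(ac$n_events, 1L)
})

test_that("single-exponential fit recovers a noiseless decay exactly", {
  lag <- (0:30) * 0.033
  res <- structure(list(lag_s = lag, G = exp(-lag / 0.165),
                        npairs = rep(1000, 31), n_events = 10L,
                        sliding_time = NA_real_, sliding_time_se = NA_real_,
                        amplitude = NA_real_, offset = NA_real_,
                        fit_failed = NA),
                   class = "autocorrelation_result")
  fit <- fit_sliding_time(res)
  expect_false(fit$fit_failed)
  expect_equal(fit$sliding_time, 0.165, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
})

test_that("AR(1) FRET yields the closed-form sliding time", {
  set.seed(42)
  phi <- exp(-1 / 5)  # 5-frame correlation time -> tau = 0.165 s at 33 ms
  evs <- lapply(1:250, function(i) 0.5 + 0.1 * ar1_series(400, phi))
  fx <- events_from_series(evs)
  ac <- fit_sliding_time(autocorrelate_events(fx$events, fx$fret, max_lag = 1))
  expect_false(ac$fit_failed)
  expect_equal(ac$sliding_time, 0.165, tolerance = 0.15)
})

test_that("pure-noise autocorrelation does not produce a spurious sliding time", {
  set.seed(10)
  fx <- events_from_series(list(0.5 + 0.05 * rnorm(2000)))
  ac <- fit_sliding_time(autocorrelate_events(fx$events, fx$fret))
  # either the fit fails or tau is consistent with zero signal:
  # no slower than a single frame within 3 SE
  if (!isTRUE(ac$fit_failed)) {
    expect_lt(ac$sliding_time - 3 * ac$sliding_time_se, 0.033)
  } else {
    expect_true(ac$fit_failed)
  }
})

test_that("residence statistics report means and a two-sample comparison", {
  fi <- 0.033
  st <- residence_stats(list(a = c(10, 20, 30) * fi))
  expect_equal(st$summary$mean_s, 0.66)
  st2 <- residence_stats(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(st2$t_statistic, 0)
  expect_equal(st2$p_value, 1)
  st3 <- residence_stats(list(a = c(5, 6, 7, 8), b = c(1, 1.5, 2, 2.5)))
  expect_lt(st3$p_value, 0.05)
  expect_equal(st3$test, "Welch two-sample t-test")
})

test_that("eviction shortens residence times significantly", {
  res0 <- c()
  res1 <- c()
  for (s in 1:25) {
    t0 <- simulate_trajectory(obstacle_config(s, FALSE))
    c1 <- obstacle_config(s, TRUE)
    c1$eviction_prob_on_contact <- 0.5
    t1 <- simulate_with_obstacle(c1)
    res0 <- c(res0, (t0$events$end_frame - t0$events$start_frame) * 0.033)
    res1 <- c(res1, (t1$events$end_frame - t1$events$start_frame) * 0.033)
  }
  st <- residence_stats(list(no_obstacle = res0, obstacle = res1))
  expect_lt(st$summary$mean_s[2], st$summary$mean_s[1])
  expect_lt(st$p_value, 0.05)
})

test_that("gated histograms conserve frames and gate per trace", {
  fi <- 0.033
  mk <- function(e) {
    structure(list(fret = e, valid = rep(TRUE, length(e)),
                   frame_interval = fi, all_masked = FALSE),
              class = "fret_series")
  }
  # one trace at constant E = 0.85 (one 100-frame event, > 2 s)
  e1 <- c(rep(0, 5), rep(0.84, 100))
  f1 <- mk(e1)
  ev1 <- segment_events(f1, min_frames = 3)
  h <- gated_fret_histogram(list(f1), list(ev1))
  expect_identical(sum(h$counts), 100L)
  bin <- findInterval(0.84, h$breaks, rightmost.closed = TRUE)
  expect_identical(h$counts[bin], 100L)
  # a trace never exceeding the gate contributes nothing
  e2 <- c(rep(0, 5), rep(0.7, 100))
  f2 <- mk(e2)
  ev2 <- segment_events(f2, min_frames = 3)
  h2 <- gated_fret_histogram(list(f2), list(ev2), high_fret_gate = 0.8)
  expect_true(h2$empty)
  expect_identical(sum(h2$counts), 0L)
  # mixed: only the qualifying trace is counted
  h3 <- gated_fret_histogram(list(f1, f2), list(ev1, ev2))
  expect_identical(sum(h3$counts), 100L)
  expect_identical(h3$n_traces_used, 1L)
})
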