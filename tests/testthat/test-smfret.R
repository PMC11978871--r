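test_that("position_to_fret follows the Forster relation", {
  p <- fret_model_params(forster_radius = 5.4, helical_rise = 0.28,
                         dye_offset = 1.5)
  # r = R0 -> E = 0.5
  pos_mid <- (5.4 - 1.5) / 0.28
  expect_equal(position_to_fret(pos_mid, p), 0.5)
  # direct evaluation at position 0
  expect_equal(position_to_fret(0, p), 1 / (1 + (1.5 / 5.4)^6),
               tolerance = 1e-12)
  # strictly decreasing, vanishing at large separation
  e <- position_to_fret(seq(0, 500, by = 5), p)
  expect_true(all(diff(e) < 0))
  expect_lt(position_to_fret(1e4, p), 1e-10)
})

test_that("frozen diffusion keeps position constant within bound events", {
  cfg <- sim_config(diffusion_coeff = 0, n_frames = 5000, rng_seed = 11)
  tr <- simulate_trajectory(cfg)
  expect_gt(nrow(tr$events), 0)
  for (i in seq_len(nrow(tr$events))) {
    pos <- tr$position[(tr$events$start_frame[i] + 1):tr$events$end_frame[i]]
    expect_equal(max(pos) - min(pos), 0)
  }
})

test_that("long-run bound fraction matches the two-state equilibrium", {
  # k_on*c = 0.1 /s, k_off = 0.5 /s -> occupancy 1/6; pooled over 10 seeds
  kon_c <- 0.1
  koff <- 0.5
  p_eq <- kon_c / (kon_c + koff)
  fracs <- vapply(1:10, function(s) {
    cfg <- sim_config(k_on = 0.002, protein_conc = 50, k_off = koff,
                      n_frames = 20000, diffusion_coeff = 0, rng_seed = s)
    mean(simulate_trajectory(cfg)$bound)
  }, numeric(1))
  # effective number of independent sojourns sets the Monte-Carlo error
  t_total <- 10 * 20000 * 0.033
  n_cycles <- t_total / (1 / kon_c + 1 / koff)
  se <- sqrt(p_eq * (1 - p_eq) / n_cycles)
  expect_lt(abs(mean(fracs) - p_eq), 3 * se)
})

test_that("short-lag MSD of bound positions matches free diffusion", {
  # huge box, no unbinding, 1 substep per frame (no camera blur)
  cfg <- sim_config(duplex_length = 1e5, n_frames = 50000,
                    substeps_per_frame = 1, k_on = 2, protein_conc = 50,
                    k_off = 0, diffusion_coeff = 1000, rng_seed = 3)
  x <- simulate_trajectory(cfg)$position
  v <- stats::var(diff(x), na.rm = TRUE)
  expect_equal(v, 2 * 1000 * 0.033, tolerance = 0.05)
})

test_that("bound-position autocovariance relaxes on the diffusion-in-a-box time", {
  # tau1 = L_eff^2 / (pi^2 D), within 20%
  cfg <- sim_config(duplex_length = 112, n_frames = 60000, k_on = 1,
                    protein_conc = 50, k_off = 0.01, diffusion_coeff = 1000,
                    rng_seed = 3)
  x <- simulate_trajectory(cfg)$position
  xc <- x[!is.na(x)] - mean(x, na.rm = TRUE)
  g <- vapply(0:60, function(k) {
    mean(xc[1:(length(xc) - k)] * xc[(1 + k):length(xc)])
  }, numeric(1))
  g <- g / g[1]
  fit <- minpack.lm::nlsLM(g ~ A * exp(-(0:60) * 0.033 / tau),
                           start = list(A = 1, tau = 0.5))
  tau1 <- (112 - 15)^2 / (pi^2 * 1000)
  expect_equal(unname(coef(fit)["tau"]), tau1, tolerance = 0.2)
})

test_that("trajectories and rendered traces are reproducible from the seed", {
  cfg <- sim_config(n_frames = 2000, rng_seed = 9)
  t1 <- simulate_trajectory(cfg)
  t2 <- simulate_trajectory(cfg)
  expect_identical(t1, t2)
  p <- fret_model_params()
  expect_identical(render_intensities(t1, p, seed = 4),
                   render_intensities(t2, p, seed = 4))
})

test_that("rendered intensities follow the camera model", {
  p0 <- fret_model_params(read_noise_sd = 0, leakage_fraction = 0,
                          background_donor = 0, background_acceptor = 0,
                          donor_total_intensity = 1000)
  # one bound frame at E = 0.5 and one unbound frame
  pos_mid <- (p0$forster_radius - p0$dye_offset) / p0$helical_rise
  truth <- structure(list(
    config = sim_config(n_frames = 2),
    bound = c(TRUE, FALSE), position = c(pos_mid, NA),
    events = data.frame(start_frame = 0L, end_frame = 1L)),
    class = "ground_truth_trajectory")
  tr <- render_intensities(truth, p0)
  expect_equal(tr$donor[1], 500)
  expect_equal(tr$acceptor[1], 500)
  expect_equal(tr$acceptor[2], 0)    # unbound: acceptor at background
  expect_equal(tr$donor[2], 1000)    # unbound: full donor
})

test_that("a pinned obstacle excludes the scanning protein from its footprint", {
  cfg <- sim_config(n_frames = 5000, rng_seed = 4, pact_present = TRUE,
                    n_pact = 1, pact_k_on = 0, pact_k_off = 0,
                    pact_diffusion_coeff = 0, eviction_prob_on_contact = 0,
                    pact_initial_position = 50, pact_footprint = 20)
  tr <- simulate_with_obstacle(cfg)
  pos <- tr$position[!is.na(tr$position)]
  # obstacle occupies [50, 70); a 15 bp footprint must not overlap it
  expect_true(all(pos <= 35 + 1e-9 | pos >= 70 - 1e-9))
  expect_true(all(tr$pact_bound[, 1]))
})

test_that("obstacle and protein footprints never overlap in any frame", {
  # 1 substep/frame so recorded positions are exact states, not averages
  cfg <- sim_config(n_frames = 20000, substeps_per_frame = 1, rng_seed = 12,
                    pact_present = TRUE)
  tr <- simulate_with_obstacle(cfg)
  violations <- 0L
  for (f in which(tr$bound)) {
    x <- tr$position[f]
    for (j in seq_len(ncol(tr$pact_bound))) {
      if (tr$pact_bound[f, j]) {
        y <- tr$pact_position[f, j]
        if (x < y + cfg$pact_footprint - 1e-9 &&
              y < x + cfg$footprint - 1e-9) {
          violations <- violations + 1L
        }
      }
    }
  }
  expect_identical(violations, 0L)
  expect_gt(sum(tr$pact_bound), 0)
})

test_that("an obstacle restricts per-event movement and eviction shortens residence", {
  fp <- fret_params_effective(112)
  span_of <- function(tr) {
    ev <- tr$events
    ev <- ev[ev$end_frame - ev$start_frame >= 20, , drop = FALSE]
    spans <- vapply(seq_len(nrow(ev)), function(i) {
      p <- tr$position[(ev$start_frame[i] + 1):ev$end_frame[i]]
      unname(diff(stats::quantile(p, c(0.05, 0.95))))
    }, numeric(1))
    spans
  }
  spans_free <- c()
  spans_obst <- c()
  res_free <- c()
  res_obst <- c()
  for (s in 1:150) {
    c0 <- obstacle_config(s, FALSE)
    c1 <- obstacle_config(s, TRUE)
    t0 <- simulate_trajectory(c0)
    t1 <- simulate_with_obstacle(c1)
    spans_free <- c(spans_free, span_of(t0))
    spans_obst <- c(spans_obst, span_of(t1))
    d0 <- (t0$events$end_frame - t0$events$start_frame) * 0.033
    d1 <- (t1$events$end_frame - t1$events$start_frame) * 0.033
    res_free <- c(res_free, d0)
    res_obst <- c(res_obst, d1)
  }
  expect_gte(length(spans_obst), 200)
  expect_lt(mean(spans_obst), mean(spans_free))
  expect_lt(mean(res_obst), mean(res_free))
})

test_that("simulation with zero obstacles is bit-identical to the plain simulator", {
  c1 <- sim_config(n_frames = 3000, rng_seed = 21)
  c2 <- c1
  c2$pact_present <- TRUE
  c2$n_pact <- 0L
  t1 <- simulate_trajectory(c1)
  t2 <- simulate_with_obstacle(c2)
  expect_identical(t1$bound, t2$bound)
  expect_identical(t1$position, t2$position)
  expect_identical(t1$events, t2$events)
})

test_that("configs shorter than the footprint are rejected", {
  expect_error(sim_config(duplex_length = 10, footprint = 15), "footprint")
})
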