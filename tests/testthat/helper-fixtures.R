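# Shared fixture builders: everything is generated in code at test time.

# AR(1) series with lag-1 correlation phi and unit marginal variance
ar1_series <- function(n, phi) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1, 0, sqrt(1 - phi^2))
  x
}

# Build a fret_series + binding_events table from a list of per-event FRET
# vectors (events separated by 5 unbound frames).
events_from_series <- function(series_list, frame_interval = 0.033) {
  fret <- c()
  rows <- list()
  pos <- 0L
  for (e in series_list) {
    fret <- c(fret, rep(0, 5), e)
    pos <- pos + 5L
    rows[[length(rows) + 1]] <- data.frame(
      start_frame = pos, end_frame = pos + length(e),
      duration_s = length(e) * frame_interval,
      classification = if (length(e) * frame_interval < 2) "abortive" else "on",
      mean_fret = mean(e))
    pos <- pos + length(e)
  }
  fs <- structure(list(fret = fret, valid = rep(TRUE, length(fret)),
                       frame_interval = frame_interval, all_masked = FALSE),
                  class = "fret_series")
  ev <- do.call(rbind, rows)
  attr(ev, "frame_interval") <- frame_interval
  class(ev) <- c("binding_events", "data.frame")
  list(fret = fs, events = ev)
}

# Direct O(n^2) double-loop normalized autocovariance oracle for one event
autocorr_oracle <- function(e, kmax) {
  n <- length(e)
  x <- e - mean(e)
  v <- sum(x^2) / n
  vapply(0:kmax, function(k) {
    s <- 0
    for (t in 1:(n - k)) s <- s + x[t] * x[t + k]
    s / n / v
  }, numeric(1))
}

# PACT-restriction study conditions used across tests: 50 s observation
# windows per molecule at 33 ms, 50 nM protein, D = 1000 bp^2/s on 112 bp.
obstacle_config <- function(seed, pact) {
  sim_config(duplex_length = 112, n_frames = 1500, rng_seed = seed,
             diffusion_coeff = 1000, k_on = 0.002, protein_conc = 50,
             k_off = 0.1, pact_present = pact)
}

run_obstacle_analysis <- function(seed, pact, n_molecules) {
  fp <- fret_params_effective(112)
  sim <- simulate_traces(obstacle_config(seed, pact), fp, n_molecules)
  analyze_traces(sim$traces, fp, on_threshold = 0.1, max_lag = 1.5)
}
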