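#' Compute a corrected FRET efficiency series from a two-channel trace
#'
#' Ratiometric FRET with background subtraction and donor leakage
#' correction:
#' \deqn{E = \frac{I_A - b_A - l (I_D - b_D)}{(I_A - b_A - l (I_D - b_D)) + (I_D - b_D)}}
#' clamped to [0, 1]. Frames whose corrected total intensity falls below
#' \code{intensity_floor} are masked and excluded from all downstream
#' statistics.
#'
#' @param trace A \code{fluorescence_trace} (columns \code{donor},
#'   \code{acceptor}) or any data frame with those columns plus a
#'   \code{frame_interval} attribute.
#' @param corrections A \code{\link{fret_model_params}} supplying the
#'   backgrounds and leakage fraction.
#' @param intensity_floor Minimum corrected total intensity for a frame to be
#'   considered valid (default 0: no masking).
#' @return A \code{fret_series}: list with \code{fret} (per-frame E),
#'   \code{valid} (mask), \code{frame_interval}, \code{all_masked} flag.
#' @export
compute_fret <- function(trace, corrections, intensity_floor = 0) {
  stopifnot(is.data.frame(trace), all(c("donor", "acceptor") %in% names(trace)),
            inherits(corrections, "fret_model_params"))
  fi <- attr(trace, "frame_interval")
  if (is.null(fi)) {
    if (nrow(trace) >= 2 && "time_s" %in% names(trace)) {
      fi <- diff(trace$time_s[1:2])
    } else {
      stop("trace carries no frame_interval attribute")
    }
  }
  fd <- trace$donor - corrections$background_donor
  fa <- trace$acceptor - corrections$background_acceptor -
    corrections$leakage_fraction * fd
  total <- fa + fd
  valid <- is.finite(total) & total >= intensity_floor & total > 0
  e <- ifelse(valid, pmin(pmax(fa / total, 0), 1), NA_real_)
  structure(list(fret = e, valid = valid, frame_interval = fi,
                 all_masked = !any(valid)),
            class = "fret_series")
}

#' Segment a FRET series into binding events
#'
#' Maximal runs of consecutive valid frames with \code{E > on_threshold}, at
#' least \code{min_frames} long, become binding events (half-open frame
#' intervals). Events with duration below \code{abortive_cutoff} are
#' classified abortive; they are retained in the table but excluded from
#' autocorrelation aggregation downstream.
#'
#' @param fret A \code{fret_series}.
#' @param on_threshold FRET threshold defining the bound ("On") state,
#'   default 0.6.
#' @param min_frames Minimum event length in frames, default 3.
#' @param abortive_cutoff Duration (s) below which an event is abortive,
#'   default 2.
#' @return A data frame of class \code{binding_events} with columns
#'   \code{start_frame}, \code{end_frame} (0-based, half-open),
#'   \code{duration_s}, \code{classification} ("on" or "abortive"),
#'   \code{mean_fret}.
#' @export
segment_events <- function(fret, on_threshold = 0.6, min_frames = 3,
                           abortive_cutoff = 2.0) {
  stopifnot(inherits(fret, "fret_series"),
            on_threshold > 0, on_threshold < 1, min_frames >= 1)
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0),
                      classification = character(0), mean_fret = numeric(0))
  if (length(fret$fret) == 0 || fret$all_masked) {
    return(structure(empty, frame_interval = fret$frame_interval,
                     class = c("binding_events", "data.frame")))
  }
  on <- fret$valid & !is.na(fret$fret) & fret$fret > on_threshold
  ev <- frame_runs(on)
  ev <- ev[ev$end_frame - ev$start_frame >= min_frames, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(structure(empty, frame_interval = fret$frame_interval,
                     class = c("binding_events", "data.frame")))
  }
  ev$duration_s <- (ev$end_frame - ev$start_frame) * fret$frame_interval
  ev$classification <- ifelse(ev$duration_s < abortive_cutoff, "abortive", "on")
  ev$mean_fret <- vapply(seq_len(nrow(ev)), function(i) {
    mean(fret$fret[(ev$start_frame[i] + 1):ev$end_frame[i]])
  }, numeric(1))
  rownames(ev) <- NULL
  structure(ev, frame_interval = fret$frame_interval,
            class = c("binding_events", "data.frame"))
}

#' Donor/acceptor anticorrelation score of a binding event
#'
#' Pearson correlation of the frame-to-frame intensity changes of the two
#' channels within the event. Genuine scanning events show strongly negative
#' scores (the acceptor gains what the donor loses); a non-negative score can
#' be used to flag an event for exclusion.
#'
#' @param trace The source \code{fluorescence_trace}.
#' @param event One row of a \code{binding_events} table (or a list with
#'   \code{start_frame}, \code{end_frame}).
#' @return Correlation in [-1, 1], or \code{NA} (with a warning) if a channel
#'   has zero variance within the event.
#' @export
anticorrelation_score <- function(trace, event) {
  i0 <- event$start_frame + 1
  i1 <- event$end_frame
  if (i1 - i0 + 1 < 3) stop("event must span at least 3 frames")
  dd <- diff(trace$donor[i0:i1])
  da <- diff(trace$acceptor[i0:i1])
  if (stats::sd(dd) == 0 || stats::sd(da) == 0) {
    warning("zero-variance channel within event; score undefined")
    return(NA_real_)
  }
  stats::cor(dd, da)
}

# Biased (1/n) mean-subtracted autocovariance of one event, normalized to
# G(0) = 1. Returns NULL for zero-variance segments.
event_autocorr <- function(e, max_lag_frames) {
  n <- length(e)
  x <- e - mean(e)
  v <- sum(x^2) / n
  if (v <= 0) return(NULL)
  kmax <- min(max_lag_frames, n - 1)
  g <- vapply(0:kmax, function(k) {
    sum(x[1:(n - k)] * x[(1 + k):n]) / n / v
  }, numeric(1))
  list(g = g, npairs = n - (0:kmax))
}

#' Pooled FRET autocorrelation over binding events
#'
#' For each non-abortive event, computes the mean-subtracted,
#' variance-normalized sample autocovariance of E within the event (biased
#' 1/n estimator, per-event mean subtraction). Events are pooled by averaging
#' G(lag) weighted by the number of contributing frame pairs; events shorter
#' than the lag window contribute only the lags they support. G(0) = 1 by
#' construction.
#'
#' This is the operational form of the FRET autocorrelation used for sliding
#' (scanning) time estimation: fit its decay with
#' \code{\link{fit_sliding_time}}.
#'
#' @param events A \code{binding_events} table.
#' @param fret The \code{fret_series} the events were segmented from.
#' @param max_lag Maximum lag in seconds (default 1).
#' @param include_abortive Include abortive events (default FALSE, matching
#'   the exclusion of transient events from the analysis).
#' @return An \code{autocorrelation_result}: \code{lag_s}, \code{G},
#'   \code{npairs}, \code{n_events}; fit fields are filled in by
#'   \code{\link{fit_sliding_time}}.
#' @export
autocorrelate_events <- function(events, fret, max_lag = 1.0,
                                 include_abortive = FALSE) {
  stopifnot(inherits(fret, "fret_series"), max_lag > 0)
  ev <- events
  if (!include_abortive && nrow(ev) > 0) {
    ev <- ev[ev$classification == "on", , drop = FALSE]
  }
  if (nrow(ev) == 0) stop("no usable (non-abortive) events")
  kmax <- max(1L, floor(max_lag / fret$frame_interval))
  gsum <- numeric(kmax + 1)
  wsum <- numeric(kmax + 1)
  n_used <- 0L
  for (i in seq_len(nrow(ev))) {
    e <- fret$fret[(ev$start_frame[i] + 1):ev$end_frame[i]]
    ac <- event_autocorr(e, kmax)
    if (is.null(ac)) next
    idx <- seq_along(ac$g)
    gsum[idx] <- gsum[idx] + ac$g * ac$npairs
    wsum[idx] <- wsum[idx] + ac$npairs
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    stop("all events have zero FRET variance; autocorrelation undefined")
  }
  keep <- wsum > 0
  structure(list(lag_s = (0:kmax)[keep] * fret$frame_interval,
                 G = (gsum / pmax(wsum, 1))[keep],
                 npairs = wsum[keep], n_events = n_used,
                 sliding_time = NA_real_, sliding_time_se = NA_real_,
                 amplitude = NA_real_, offset = NA_real_,
                 fit_failed = NA),
            class = "autocorrelation_result")
}

#' Fit a single-exponential decay to a pooled autocorrelation
#'
#' Least-squares fit of \code{G(lag) = A * exp(-lag / tau) + C} over
#' \code{fit_range}; by default the offset C is fixed at 0 and the range runs
#' from lag 0 to the first lag where G drops below \code{g_floor}. The fitted
#' tau is the average sliding time.
#'
#' @param result An \code{autocorrelation_result}.
#' @param fit_range Optional numeric length-2 lag window in seconds.
#' @param fit_offset Fit a free offset C (default FALSE).
#' @param g_floor Default fit-range cutoff on G (default 0.05).
#' @return The updated \code{autocorrelation_result} with
#'   \code{sliding_time} (s), \code{sliding_time_se}, \code{amplitude},
#'   \code{offset}, and \code{fit_failed}. On non-convergence or a
#'   non-positive tau, \code{fit_failed} is TRUE and no tau is reported.
#' @export
fit_sliding_time <- function(result, fit_range = NULL, fit_offset = FALSE,
                             g_floor = 0.05) {
  stopifnot(inherits(result, "autocorrelation_result"))
  lag <- result$lag_s
  g <- result$G
  if (is.null(fit_range)) {
    below <- which(g < g_floor)
    hi <- if (length(below)) lag[below[1]] else max(lag)
    fit_range <- c(0, hi)
  }
  sel <- lag >= fit_range[1] & lag <= fit_range[2]
  if (sum(sel) < 4) sel <- seq_along(lag) <= max(4, sum(sel))
  lags <- lag[sel]
  gs <- g[sel]
  tau0 <- {
    pos <- gs > 0.05 & lags > 0
    if (any(pos)) max(stats::median(-lags[pos] / log(gs[pos])), result$lag_s[2]) else result$lag_s[2]
  }
  fit <- tryCatch({
    if (fit_offset) {
      minpack.lm::nlsLM(gs ~ A * exp(-lags / tau) + C,
                        start = list(A = 1, tau = tau0, C = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(gs ~ A * exp(-lags / tau),
                        start = list(A = 1, tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    result$fit_failed <- TRUE
    return(result)
  }
  co <- summary(fit)$coefficients
  tau <- co["tau", "Estimate"]
  if (!is.finite(tau) || tau <= 0) {
    result$fit_failed <- TRUE
    return(result)
  }
  result$sliding_time <- tau
  result$sliding_time_se <- co["tau", "Std. Error"]
  result$amplitude <- co["A", "Estimate"]
  result$offset <- if (fit_offset) co["C", "Estimate"] else 0
  result$fit_failed <- FALSE
  result
}

#' Residence-time statistics, optionally compared across conditions
#'
#' Per-condition residence ("on") time lists with mean and SD, and for two
#' conditions a two-tailed two-sample t-test (Welch by default; set
#' \code{paired = TRUE} when events are matched by a pairing key).
#'
#' @param events_by_condition Named list of \code{binding_events} tables (or
#'   numeric vectors of durations in seconds), one per condition.
#' @param paired Use a paired t-test (requires equal lengths).
#' @return A \code{dwell_stats} list: per-condition \code{times},
#'   \code{summary} data frame (n, mean, sd), and for two conditions
#'   \code{t_statistic}, \code{p_value}, \code{test}.
#' @export
residence_stats <- function(events_by_condition, paired = FALSE) {
  times <- lapply(events_by_condition, function(x) {
    if (is.data.frame(x)) x$duration_s else as.numeric(x)
  })
  if (is.null(names(times)) || any(names(times) == "")) {
    names(times) <- paste0("condition", seq_along(times))
  }
  stopifnot(all(vapply(times, function(t) all(t > 0), logical(1))))
  summ <- data.frame(condition = names(times),
                     n = vapply(times, length, integer(1)),
                     mean_s = vapply(times, mean, numeric(1)),
                     sd_s = vapply(times, stats::sd, numeric(1)),
                     row.names = NULL)
  out <- list(times = times, summary = summ, t_statistic = NA_real_,
              p_value = NA_real_, test = NA_character_)
  if (length(times) == 2) {
    a <- times[[1]]
    b <- times[[2]]
    if (identical(a, b)) {
      # degenerate identical samples: no difference by construction
      out$t_statistic <- 0
      out$p_value <- 1
      out$test <- "identical samples"
    } else {
      tt <- stats::t.test(a, b, paired = paired, var.equal = FALSE)
      out$t_statistic <- unname(tt$statistic)
      out$p_value <- tt$p.value
      out$test <- if (paired) "paired two-tailed t-test" else "Welch two-sample t-test"
    }
  }
  class(out) <- "dwell_stats"
  out
}

#' High-FRET-gated histogram of On-state FRET values
#'
#' Only traces containing at least one On-state frame with
#' \code{E > high_fret_gate} contribute; the histogram is then built from all
#' On-state frames of the qualifying traces, so that a restricted scanner
#' (confined near the labeled end) yields a narrower distribution than a free
#' one. Frame count is conserved: the counts sum to the number of On-state
#' frames in gated traces.
#'
#' @param fret_list List of \code{fret_series}, one per trace.
#' @param events_list Matching list of \code{binding_events} tables.
#' @param high_fret_gate Gate threshold, default 0.8.
#' @param bins Number of bins over [0, 1], default 40.
#' @param include_abortive Count frames of abortive events too (default
#'   FALSE).
#' @return A \code{fret_histogram}: \code{breaks}, \code{counts},
#'   \code{n_traces_used}, \code{gate}, \code{empty} flag.
#' @export
gated_fret_histogram <- function(fret_list, events_list, high_fret_gate = 0.8,
                                 bins = 40, include_abortive = FALSE) {
  stopifnot(high_fret_gate > 0, high_fret_gate < 1,
            length(fret_list) == length(events_list))
  breaks <- seq(0, 1, length.out = bins + 1)
  pooled <- numeric(0)
  used <- 0L
  for (i in seq_along(fret_list)) {
    ev <- events_list[[i]]
    if (nrow(ev) == 0) next
    if (!include_abortive) ev <- ev[ev$classification == "on", , drop = FALSE]
    if (nrow(ev) == 0) next
    frames <- unlist(lapply(seq_len(nrow(ev)), function(j) {
      (ev$start_frame[j] + 1):ev$end_frame[j]
    }))
    e <- fret_list[[i]]$fret[frames]
    e <- e[!is.na(e)]
    if (!any(e > high_fret_gate)) next
    pooled <- c(pooled, e)
    used <- used + 1L
  }
  if (used == 0L) {
    return(structure(list(breaks = breaks, counts = integer(bins),
                          n_traces_used = 0L, gate = high_fret_gate,
                          empty = TRUE),
                     class = "fret_histogram"))
  }
  counts <- graphics::hist(pooled, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  structure(list(breaks = breaks, counts = counts, n_traces_used = used,
                 gate = high_fret_gate, empty = FALSE,
                 values = pooled),
            class = "fret_histogram")
}

#' Interdecile span of a gated FRET histogram
#'
#' The 10th-90th percentile span of the pooled gated FRET values; used to
#' compare scanning ranges between conditions.
#'
#' @param h A \code{fret_histogram}.
#' @return Numeric span (0 if the histogram is empty).
#' @export
interdecile_span <- function(h) {
  stopifnot(inherits(h, "fret_histogram"))
  if (h$empty) return(0)
  unname(diff(stats::quantile(h$values, c(0.1, 0.9))))
}

#' End-to-end analysis of a set of traces
#'
#' Runs the full single-molecule pipeline: FRET computation, event
#' segmentation, pooled autocorrelation with sliding-time fit, residence
#' times, and the high-FRET-gated histogram.
#'
#' @param traces List of \code{fluorescence_trace} objects.
#' @param corrections A \code{\link{fret_model_params}}.
#' @param on_threshold,abortive_cutoff,max_lag,high_fret_gate,bins Pipeline
#'   parameters (see the individual operations).
#' @param min_frames Minimum event length in frames.
#' @return A list: \code{fret_list}, \code{events_list}, \code{events}
#'   (pooled table), \code{autocorrelation}, \code{histogram},
#'   \code{residence_s} (vector of non-abortive durations).
#' @export
analyze_traces <- function(traces, corrections, on_threshold = 0.6,
                           min_frames = 3, abortive_cutoff = 2.0,
                           max_lag = 1.0, high_fret_gate = 0.8, bins = 40) {
  fret_list <- lapply(traces, compute_fret, corrections = corrections)
  events_list <- lapply(fret_list, segment_events, on_threshold = on_threshold,
                        min_frames = min_frames,
                        abortive_cutoff = abortive_cutoff)
  pooled <- do.call(rbind, lapply(seq_along(events_list), function(i) {
    ev <- events_list[[i]]
    if (nrow(ev) == 0) return(NULL)
    cbind(trace = i, as.data.frame(ev))
  }))
  ac <- NULL
  n_on <- sum(vapply(events_list, function(ev) sum(ev$classification == "on"),
                     integer(1)))
  if (n_on > 0) {
    # pool per-trace autocorrelations with pair-count weighting
    kmax <- max(1L, floor(max_lag / fret_list[[1]]$frame_interval))
    gsum <- numeric(kmax + 1)
    wsum <- numeric(kmax + 1)
    n_events <- 0L
    for (i in seq_along(fret_list)) {
      ev <- events_list[[i]]
      ev <- ev[ev$classification == "on", , drop = FALSE]
      if (nrow(ev) == 0) next
      for (j in seq_len(nrow(ev))) {
        e <- fret_list[[i]]$fret[(ev$start_frame[j] + 1):ev$end_frame[j]]
        acj <- event_autocorr(e, kmax)
        if (is.null(acj)) next
        idx <- seq_along(acj$g)
        gsum[idx] <- gsum[idx] + acj$g * acj$npairs
        wsum[idx] <- wsum[idx] + acj$npairs
        n_events <- n_events + 1L
      }
    }
    if (n_events > 0) {
      keep <- wsum > 0
      ac <- structure(list(lag_s = (0:kmax)[keep] * fret_list[[1]]$frame_interval,
                           G = (gsum / pmax(wsum, 1))[keep],
                           npairs = wsum[keep], n_events = n_events,
                           sliding_time = NA_real_, sliding_time_se = NA_real_,
                           amplitude = NA_real_, offset = NA_real_,
                           fit_failed = NA),
                      class = "autocorrelation_result")
      ac <- fit_sliding_time(ac)
    }
  }
  hist <- gated_fret_histogram(fret_list, events_list,
                               high_fret_gate = high_fret_gate, bins = bins)
  res <- if (!is.null(pooled)) pooled$duration_s[pooled$classification == "on"] else numeric(0)
  list(fret_list = fret_list, events_list = events_list, events = pooled,
       autocorrelation = ac, histogram = hist, residence_s = res)
}
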