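# Windowed mean of dff_pct over [from, to); errors if the window is not
# fully sampled.
window_mean <- function(d, from, to) {
  idx <- window_idx(d$time, from, to, d$dt)
  expected <- round((to - from) / d$dt)
  if (length(idx) < expected) {
    stop(sprintf("window [%g, %g) extends past the trace", from, to),
         call. = FALSE)
  }
  mean(d$dff_pct[idx])
}

#' ON response of a dF/F trace
#'
#' Mean dF/F (%) over the ON window after stimulus onset minus the mean
#' over the 10-s window before onset.
#'
#' @param d A [dff()] trace.
#' @param windows A [response_windows()]; defaults to the neuron class's
#'   standard windows ([default_windows()]).
#' @return ON response in percentage points of dF/F.
#' @export
on_response <- function(d, windows = NULL) {
  stopifnot(inherits(d, "dff_trace"))
  if (is.null(windows)) windows <- default_windows(d$neuron_class)
  pre <- window_mean(d, d$t_onset - windows$pre_duration, d$t_onset)
  post <- window_mean(d, d$t_onset + windows$on_offset,
                      d$t_onset + windows$on_offset + windows$on_duration)
  post - pre
}

#' OFF response of a dF/F trace
#'
#' Mean dF/F (%) over the OFF window after stimulus removal minus the mean
#' over the 10-s window before removal.
#'
#' @inheritParams on_response
#' @return OFF response in percentage points of dF/F.
#' @export
off_response <- function(d, windows = NULL) {
  stopifnot(inherits(d, "dff_trace"))
  if (is.null(windows)) windows <- default_windows(d$neuron_class)
  pre <- window_mean(d, d$t_removal - windows$pre_duration, d$t_removal)
  post <- window_mean(d, d$t_removal + windows$off_offset,
                      d$t_removal + windows$off_offset + windows$off_duration)
  post - pre
}

#' OFF-response latency by threshold crossing
#'
#' Time after stimulus removal for the calcium signal to first reach the
#' mean of the 10-s pre-removal window plus `k_sd` standard deviations
#' (sample SD, n-1). The removal frame itself is the first candidate. If
#' the signal never reaches the threshold before the end of the recording,
#' the latency is reported as `cap` (default 40 s) with
#' `threshold_crossed = FALSE`.
#'
#' @param d A [dff()] trace.
#' @param k_sd Threshold multiplier (default 3).
#' @param cap Latency assigned when the threshold is never crossed (s).
#' @return A list: `latency` (s), `threshold_crossed` (logical),
#'   `threshold` (dF/F %).
#' @export
off_latency <- function(d, k_sd = 3, cap = 40) {
  stopifnot(inherits(d, "dff_trace"))
  pre_idx <- window_idx(d$time, d$t_removal - 10, d$t_removal, d$dt)
  if (length(pre_idx) < round(10 / d$dt)) {
    stop("insufficient pre-removal window: need 10 s of samples",
         call. = FALSE)
  }
  post_idx <- which(d$time >= d$t_removal - d$dt * 1e-6)
  if (length(post_idx) < 1) {
    stop("no samples at or after stimulus removal", call. = FALSE)
  }
  thr <- mean(d$dff_pct[pre_idx]) + k_sd * stats::sd(d$dff_pct[pre_idx])
  hit <- post_idx[d$dff_pct[post_idx] >= thr]
  if (length(hit) == 0) {
    list(latency = cap, threshold_crossed = FALSE, threshold = thr)
  } else {
    list(latency = d$time[hit[1]] - d$t_removal, threshold_crossed = TRUE,
         threshold = thr)
  }
}

#' Full response metrics for one trace
#'
#' Convenience wrapper computing the ON response, OFF response and OFF
#' latency of a raw trace in one call.
#'
#' @param trace A [fluorescence_trace()].
#' @param windows Optional [response_windows()] (default: neuron class's).
#' @param k_sd,cap Passed to [off_latency()].
#' @return One-row tibble: `trace_id`, `neuron_class`, `genotype`,
#'   `stimulus`, `on_response`, `off_response`, `off_latency`,
#'   `threshold_crossed`.
#' @export
response_metrics <- function(trace, windows = NULL, k_sd = 3, cap = 40) {
  d <- if (inherits(trace, "dff_trace")) trace else dff(trace)
  lat <- off_latency(d, k_sd = k_sd, cap = cap)
  tibble::tibble(
    trace_id = d$trace_id,
    neuron_class = d$neuron_class,
    genotype = d$genotype,
    stimulus = d$stimulus,
    on_response = on_response(d, windows),
    off_response = off_response(d, windows),
    off_latency = lat$latency,
    threshold_crossed = lat$threshold_crossed
  )
}

#' Group mean and SEM time series
#'
#' Aligns dF/F traces to stimulus onset and returns the per-frame mean and
#' SEM (SD/sqrt(n)) across traces, the summary drawn as solid line and
#' shaded ribbon in imaging figures. Traces whose grids differ from the
#' first trace's by less than half a frame are resampled to it by nearest
#' frame; larger mismatches are an error.
#'
#' @param traces List of [dff()] traces.
#' @return Tibble: `time` (s, relative to onset), `mean_dff`, `sem_dff`,
#'   `n`.
#' @export
summarize_traces <- function(traces) {
  stopifnot(length(traces) >= 1)
  lapply(traces, function(d) stopifnot(inherits(d, "dff_trace")))
  ref <- traces[[1]]
  ref_rel <- ref$time - ref$t_onset
  mat <- vapply(traces, function(d) {
    if (abs(d$dt - ref$dt) > ref$dt / 2) {
      stop("trace '", d$trace_id, "' has an incompatible frame interval",
           call. = FALSE)
    }
    rel <- d$time - d$t_onset
    idx <- vapply(ref_rel, function(t) {
      j <- which.min(abs(rel - t))
      if (abs(rel[j] - t) > d$dt / 2) {
        stop("trace '", d$trace_id,
             "' cannot be aligned to the reference grid", call. = FALSE)
      }
      j
    }, integer(1))
    d$dff_pct[idx]
  }, numeric(length(ref_rel)))
  mat <- matrix(mat, nrow = length(ref_rel))
  n <- ncol(mat)
  mean_dff <- rowMeans(mat)
  sem_dff <- if (n > 1) apply(mat, 1, stats::sd) / sqrt(n) else
    rep(0, nrow(mat))
  tibble::tibble(time = ref_rel, mean_dff = mean_dff, sem_dff = sem_dff,
                 n = n)
}
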