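# Independent brute-force oracles used to cross-check the implementation.

# Choice index by per-worm tally: build one entry per worm (+1 toward,
# -1 away, 0 middle) and average.
tally_choice_index <- function(n_toward, n_away, n_middle) {
  worms <- c(rep(1, n_toward), rep(-1, n_away), rep(0, n_middle))
  sum(worms) / length(worms)
}

# OFF latency by exhaustive frame scan over a dff trace.
frame_scan_latency <- function(d, k_sd = 3, cap = 40) {
  pre <- d$dff_pct[d$time >= d$t_removal - 10 - d$dt * 1e-6 &
                     d$time < d$t_removal - d$dt * 1e-6]
  thr <- mean(pre) + k_sd * sd(pre)
  for (i in seq_along(d$time)) {
    if (d$time[i] >= d$t_removal - d$dt * 1e-6 && d$dff_pct[i] >= thr) {
      return(list(latency = d$time[i] - d$t_removal, crossed = TRUE))
    }
  }
  list(latency = cap, crossed = FALSE)
}

# A fluorescence trace with dff following a supplied function of time
# (percent), f0 = 100, 5-Hz grid, onset 10 s, removal 40 s, 40 s post.
trace_from_dff <- function(dff_fun, neuron_class = "AWB", dt = 0.2,
                           t_onset = 10, t_removal = 40, t_end = 80) {
  tt <- seq(0, t_end - dt / 2, by = dt)
  f <- 100 * (1 + vapply(tt, dff_fun, numeric(1)) / 100)
  fluorescence_trace(tt, f, t_onset, t_removal,
                     neuron_class = neuron_class)
}

# Random valid plate counts (total >= 1 guaranteed).
random_plate_counts <- function(n) {
  df <- data.frame(
    n_toward = sample(0:80, n, replace = TRUE),
    n_away = sample(0:80, n, replace = TRUE),
    n_middle = sample(0:80, n, replace = TRUE)
  )
  empty <- rowSums(df) == 0
  df$n_middle[empty] <- 1
  df
}
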