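test_that("trace_baseline averages the 10-s pre-onset window", {
  tr <- trace_from_dff(function(t) 0)
  expect_equal(trace_baseline(tr), 100)

  # alternating 90/110 raw baseline
  tt <- seq(0, 79.9, by = 0.2)
  f <- rep(c(90, 110), length.out = length(tt))
  tr2 <- fluorescence_trace(tt, f, 10, 40)
  expect_equal(trace_baseline(tr2), 100)

  # ramp 100 -> 110 over the baseline: frozen by brute-force frame sum
  f3 <- ifelse(tt < 10, 100 + tt, 110)
  tr3 <- fluorescence_trace(tt, f3, 10, 40)
  expect_equal(trace_baseline(tr3), mean(100 + seq(0, 9.8, by = 0.2)))

  expect_error(fluorescence_trace(seq(0, 50, 0.2), rep(1, 251),
                                  t_onset = 5, t_removal = 20),
               "baseline")
})

test_that("dff normalises to percent of baseline and rejects F_base <= 0", {
  tr <- trace_from_dff(function(t) 0)
  d <- dff(tr)
  expect_equal(d$f_base, 100)
  expect_true(all(d$dff_pct == 0))

  step <- trace_from_dff(function(t) if (t >= 10) 50 else 0)
  expect_equal(dff(step)$dff_pct[dff(step)$time >= 10][1], 50)
  drop <- trace_from_dff(function(t) if (t >= 10) -20 else 0)
  expect_equal(dff(drop)$dff_pct[dff(drop)$time >= 10][1], -20)

  tt <- seq(0, 50 - 0.2, by = 0.2)
  bad <- fluorescence_trace(tt, rep(-5, length(tt)), 10, 40)
  expect_error(dff(bad), "F_base")
})

test_that("dff over the baseline window has mean zero", {
  set.seed(11)
  tr <- simulate_trace(trace_sim_config(noise_sd = 2, on_amplitude = 30,
                                        seed = 3))
  d <- dff(tr)
  base <- d$dff_pct[d$time < d$t_onset - d$dt * 1e-6]
  expect_equal(mean(base), 0, tolerance = 1e-10)
})

test_that("on/off responses are windowed mean differences", {
  zero <- dff(trace_from_dff(function(t) 0))
  expect_identical(on_response(zero), 0)
  expect_identical(off_response(zero), 0)

  # +50% step at onset held through the stimulus
  step <- dff(trace_from_dff(function(t) if (t >= 10) 50 else 0))
  expect_equal(on_response(step, response_windows(0, 10, 0, 10)), 50)
  # AVA's late window sees the same constant segment
  expect_equal(on_response(step, response_windows(10, 10, 0, 5)), 50)

  # -20% during stimulus jumping to +30% at removal (ASH windows)
  jump <- dff(trace_from_dff(function(t) {
    if (t >= 40) 30 else if (t >= 10) -20 else 0
  }, neuron_class = "ASH"))
  expect_equal(off_response(jump), 50)

  # +50% during stimulus decaying to 0 at removal
  decay <- dff(trace_from_dff(function(t) {
    if (t >= 40) 0 else if (t >= 10) 50 else 0
  }))
  expect_equal(off_response(decay, response_windows(0, 10, 0, 10)), -50)

  short <- dff(trace_from_dff(function(t) 0, t_end = 42))
  expect_error(off_response(short, response_windows(0, 10, 0, 10)),
               "past the trace")
})

test_that("dff-based metrics are invariant to multiplicative scaling", {
  set.seed(21)
  cfg <- trace_sim_config(on_amplitude = -30, off_amplitude = 35,
                          noise_sd = 1, seed = 9)
  tr <- simulate_trace(cfg, neuron_class = "AWB")
  for (c_scale in c(0.5, 3)) {
    tr2 <- tr
    tr2$F <- tr$F * c_scale
    m1 <- response_metrics(tr)
    m2 <- response_metrics(tr2)
    expect_equal(m2$on_response, m1$on_response, tolerance = 1e-9)
    expect_equal(m2$off_response, m1$off_response, tolerance = 1e-9)
    expect_equal(m2$off_latency, m1$off_latency)
  }
})

test_that("off_latency detects threshold crossings and caps at 40 s", {
  # pre-removal noise, post-removal flat at the pre-removal mean: no cross
  set.seed(31)
  tt <- seq(0, 79.9, by = 0.2)
  dffv <- ifelse(tt < 40, ifelse(tt >= 30, rep(c(-1, 1), 25), 0), 0)
  f <- 100 * (1 + dffv / 100)
  d <- dff(fluorescence_trace(tt, f, 10, 40))
  lat <- off_latency(d)
  expect_equal(lat$latency, 40)
  expect_false(lat$threshold_crossed)

  # already above threshold at the removal frame
  d2 <- dff(trace_from_dff(function(t) {
    if (t >= 40) 60 else if (t >= 30) sin(t * 7) else 0
  }))
  lat2 <- off_latency(d2)
  expect_equal(lat2$latency, 0)
  expect_true(lat2$threshold_crossed)

  # pre-removal mean 0, SD 1 (alternating +-1), ramp crossing 3.0 at 2.4 s
  pre_pat <- rep(c(-1, 1), length.out = 50)
  dff3 <- function(t) {
    if (t < 30) 0
    else if (t < 40) pre_pat[round((t - 30) / 0.2) + 1]
    else 1.25 * (t - 40)  # reaches 3.0 at t = 42.4
  }
  d3 <- dff(trace_from_dff(dff3))
  sd_pre <- sd(pre_pat)  # 1.0101... (n-1); threshold just above 3
  lat3 <- off_latency(d3)
  oracle3 <- frame_scan_latency(d3)
  expect_equal(lat3$latency, oracle3$latency)
  expect_equal(lat3$latency, 2.6)  # first frame at/above mean + 3*SD
  expect_true(lat3$threshold_crossed)
})

test_that("off_latency never decreases when k_sd is raised", {
  set.seed(41)
  for (i in 1:20) {
    cfg <- trace_sim_config(on_amplitude = runif(1, -30, 0),
                            off_amplitude = runif(1, 10, 40),
                            off_latency_true = runif(1, 1, 6),
                            noise_sd = 1.5, seed = 100 + i)
    d <- dff(simulate_trace(cfg))
    lats <- vapply(c(1, 2, 3, 4), function(k) off_latency(d, k_sd = k)$latency,
                   numeric(1))
    expect_true(all(diff(lats) >= 0))
  }
})

test_that("off_latency agrees with the frame-scan oracle on random traces", {
  set.seed(51)
  for (i in 1:60) {
    cfg <- trace_sim_config(on_amplitude = runif(1, -40, 40),
                            off_amplitude = runif(1, -20, 40),
                            off_latency_true = runif(1, 0, 10),
                            noise_sd = runif(1, 0, 3), seed = 2000 + i)
    d <- dff(simulate_trace(cfg))
    got <- off_latency(d)
    want <- frame_scan_latency(d)
    expect_equal(got$latency, want$latency)
    expect_equal(got$threshold_crossed, want$crossed)
  }
})

test_that("summarize_traces returns per-frame mean and SEM", {
  t0 <- dff(trace_from_dff(function(t) 0))
  expect_equal(summarize_traces(list(t0))$sem_dff, rep(0, length(t0$time)))
  t10 <- dff(trace_from_dff(function(t) if (t >= 10) 10 else 0))
  # constant 0 and constant 10 after onset: mean 5, SEM 5 there
  s <- summarize_traces(list(t0, t10))
  post <- s$time >= 0
  expect_true(all(abs(s$mean_dff[post] - 5) < 1e-9))
  expect_true(all(abs(s$sem_dff[post] - 5) < 1e-9))
  s3 <- summarize_traces(list(t0, t0, t0))
  expect_true(all(s3$sem_dff == 0))

  coarse <- dff(fluorescence_trace(seq(0, 79.5, 0.5), rep(100, 160), 10, 40))
  expect_error(summarize_traces(list(t0, coarse)), "incompatible")
})

test_that("default_windows encode the neuron-class conventions", {
  expect_equal(default_windows("AWB")$on_duration, 10)
  expect_equal(default_windows("ASH")$off_duration, 10)
  for (nc in c("AVA", "AIB", "RIM")) {
    w <- default_windows(nc)
    expect_equal(w$on_duration, 5)
    expect_equal(w$off_duration, 5)
  }
  late <- default_windows("AVA", "ava_late")
  expect_equal(late$on_offset, 10)
  expect_equal(late$on_duration, 10)
  expect_error(default_windows("other"), "no default windows")
  expect_error(default_windows("AWB", "ava_late"), "AVA")
})
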