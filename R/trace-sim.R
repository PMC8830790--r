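#' Trace simulator configuration
#'
#' Parameters of the GCaMP-like trace synthesizer. The deterministic
#' kernel is: baseline `f0`; during the stimulus a saturating-exponential
#' ON component toward `on_amplitude` (% of `f0`, signed) with time
#' constant `on_tau`; after removal the signal briefly deflects by
#' `off_undershoot` opposite to the upcoming OFF transient (the small dip
#' commonly seen at stimulus transitions), holds, and then — starting
#' `off_latency_true` seconds after removal — relaxes toward
#' `plateau + off_amplitude` with time constant `off_tau`. When
#' `off_amplitude <= 0` no undershoot is applied and the post-removal
#' signal moves away from (or stays at) the pre-removal level, so the
#' threshold-crossing latency is never reached. I.i.d. Gaussian noise of
#' SD `noise_sd` (% of `f0`) is added to every frame.
#'
#' @param f0 Baseline intensity (arbitrary units).
#' @param dt Frame interval (s). Default 0.2 (5 frames/s).
#' @param pre_duration Baseline epoch before onset (s), >= 10.
#' @param stim_duration Stimulus epoch (s).
#' @param post_duration Epoch after removal (s), >= `off_latency_true`.
#' @param on_amplitude Signed ON plateau (% of f0).
#' @param on_tau ON rise time constant (s).
#' @param off_amplitude Signed OFF transient amplitude (% of f0).
#' @param off_latency_true Delay from removal to the start of the OFF
#'   transient (s).
#' @param off_tau OFF rise time constant (s).
#' @param off_undershoot Size of the post-removal deflection opposite to a
#'   positive OFF transient (% of f0).
#' @param noise_sd Gaussian noise SD (% of f0).
#' @param seed Integer RNG seed.
#' @return A list of class `trace_sim_config`.
#' @export
trace_sim_config <- function(f0 = 100, dt = 0.2, pre_duration = 10,
                             stim_duration = 30, post_duration = 40,
                             on_amplitude = 0, on_tau = 0.3,
                             off_amplitude = 0, off_latency_true = 2,
                             off_tau = 0.4, off_undershoot = 2,
                             noise_sd = 0, seed = 1L) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (pre_duration < 10) {
    stop("pre_duration must be >= 10 s (baseline window)", call. = FALSE)
  }
  if (stim_duration <= 0 || post_duration <= 0) {
    stop("stimulus and post-removal epochs must be positive", call. = FALSE)
  }
  if (post_duration < off_latency_true) {
    stop("post_duration must cover off_latency_true", call. = FALSE)
  }
  if (f0 <= 0) stop("f0 must be positive", call. = FALSE)
  structure(
    list(f0 = f0, dt = dt, pre_duration = pre_duration,
         stim_duration = stim_duration, post_duration = post_duration,
         on_amplitude = on_amplitude, on_tau = on_tau,
         off_amplitude = off_amplitude,
         off_latency_true = off_latency_true, off_tau = off_tau,
         off_undershoot = off_undershoot, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "trace_sim_config"
  )
}

# Noise-free dF/F kernel (% of f0) at times t (s, absolute grid with
# onset at pre_duration). Each frame reports the exponential accumulated
# by the END of its frame interval (camera integration convention), so a
# transition frame already carries dt of rise and in the fast-kinetics
# limit the kernel is a clean step at the transition frame.
trace_kernel <- function(t, cfg) {
  t_on <- cfg$pre_duration
  t_off <- cfg$pre_duration + cfg$stim_duration
  dt <- cfg$dt
  k <- numeric(length(t))
  stim <- t >= t_on & t < t_off
  k[stim] <- cfg$on_amplitude *
    (1 - exp(-(t[stim] - t_on + dt) / cfg$on_tau))
  plateau <- cfg$on_amplitude * (1 - exp(-cfg$stim_duration / cfg$on_tau))
  post <- t >= t_off
  tp <- t[post] - t_off
  base_post <- rep(plateau, length(tp))
  if (cfg$off_amplitude > 0 && cfg$off_undershoot != 0) {
    base_post <- base_post -
      cfg$off_undershoot * (1 - exp(-(tp + dt) / 0.5))
  }
  risen <- tp >= cfg$off_latency_true - dt * 1e-6
  base_post[risen] <- base_post[risen] + cfg$off_amplitude *
    (1 - exp(-(tp[risen] - cfg$off_latency_true + dt) / cfg$off_tau))
  k[post] <- base_post
  k
}

#' Simulate a GCaMP-like fluorescence trace
#'
#' Evaluates the deterministic kernel described in [trace_sim_config()] on
#' a uniform 5-Hz (by default) grid, adds i.i.d. Gaussian noise, and
#' returns a raw-intensity [fluorescence_trace()] with its onset and
#' removal marks set.
#'
#' @param config A [trace_sim_config()].
#' @param trace_id,neuron_class,genotype,stimulus Labels for the trace.
#' @return A [fluorescence_trace()].
#' @export
simulate_trace <- function(config, trace_id = "sim",
                           neuron_class = "other",
                           genotype = "wild_type", stimulus = "odor") {
  stopifnot(inherits(config, "trace_sim_config"))
  total <- config$pre_duration + config$stim_duration + config$post_duration
  t <- seq(0, total - config$dt / 2, by = config$dt)
  dff_true <- trace_kernel(t, config)
  f_clean <- config$f0 * (1 + dff_true / 100)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  noise <- if (config$noise_sd > 0)
    stats::rnorm(length(t), 0, config$noise_sd * config$f0 / 100)
  else 0
  fluorescence_trace(
    time = t, F = f_clean + noise,
    t_onset = config$pre_duration,
    t_removal = config$pre_duration + config$stim_duration,
    trace_id = trace_id, neuron_class = neuron_class,
    genotype = genotype, stimulus = stimulus
  )
}

#' Library of neuron/stimulus/genotype trace presets
#'
#' Encodes the qualitative ON/OFF sign patterns of the imaging panels for
#' the sensory neurons AWB and ASH and the interneurons AVA, AIB and RIM
#' under isoamyl alcohol (IAA), 2-nonanone and their mixture: AWB is
#' activated by IAA but suppressed by 2-nonanone and by the mixture (with
#' a rebound OFF response on removal); ASH is activated by 2-nonanone but
#' does not respond to IAA; AVA is suppressed by IAA and flat to
#' 2-nonanone; AIB is suppressed by all three; RIM is suppressed by IAA
#' and the mixture but flat to 2-nonanone. `osm5_like` variants shrink
#' response amplitudes and, where a positive OFF transient exists, lengthen
#' its latency. Amplitudes encode signs and orderings, not figure-read
#' magnitudes.
#'
#' @return Tibble with one row per preset: `neuron_class`, `stimulus`,
#'   `genotype` and the kernel parameters.
#' @export
preset_library <- function() {
  p <- function(neuron, stim, geno, on_amp, off_amp, lat) {
    tibble::tibble(neuron_class = neuron, stimulus = stim, genotype = geno,
                   on_amplitude = on_amp, off_amplitude = off_amp,
                   off_latency_true = lat)
  }
  dplyr::bind_rows(
    # AWB: activated by IAA; suppressed by nonanone and the mixture with
    # a rebound OFF transient on removal
    p("AWB", "iaa", "wild_type", 40, -20, 2),
    p("AWB", "nonanone", "wild_type", -30, 35, 2),
    p("AWB", "mixture", "wild_type", -30, 35, 2),
    # ASH: nociceptive; responds to nonanone, not IAA
    p("ASH", "nonanone", "wild_type", 35, -15, 2),
    p("ASH", "iaa", "wild_type", 0, 0, 2),
    # interneurons (5-s windows)
    p("AVA", "iaa", "wild_type", -25, 20, 2),
    p("AVA", "nonanone", "wild_type", 0, 0, 2),
    p("AIB", "iaa", "wild_type", -25, 18, 2),
    p("AIB", "nonanone", "wild_type", -25, 18, 2),
    p("AIB", "mixture", "wild_type", -25, 18, 2),
    p("RIM", "iaa", "wild_type", -25, 18, 2),
    p("RIM", "mixture", "wild_type", -25, 18, 2),
    p("RIM", "nonanone", "wild_type", 0, 0, 2),
    # osm-5-like: shrunken amplitudes; slower OFF where one exists
    p("AWB", "iaa", "osm5_like", 15, -8, 2),
    p("AWB", "nonanone", "osm5_like", -12, 15, 6),
    p("AWB", "mixture", "osm5_like", -12, 15, 6),
    p("ASH", "nonanone", "osm5_like", 14, -6, 2)
  )
}

#' Look up one trace preset
#'
#' @param neuron_class,stimulus,genotype Preset key, e.g.
#'   `"AWB"`, `"nonanone"`, `"wild_type"`.
#' @param noise_sd,seed Overrides applied to the resulting config.
#' @return A [trace_sim_config()].
#' @export
trace_preset <- function(neuron_class, stimulus, genotype = "wild_type",
                         noise_sd = 1, seed = 1L) {
  lib <- preset_library()
  row <- lib[lib$neuron_class == neuron_class & lib$stimulus == stimulus &
               lib$genotype == genotype, ]
  if (nrow(row) != 1) {
    stop("no preset for ", neuron_class, "/", stimulus, "/", genotype,
         call. = FALSE)
  }
  trace_sim_config(on_amplitude = row$on_amplitude,
                   off_amplitude = row$off_amplitude,
                   off_latency_true = row$off_latency_true,
                   noise_sd = noise_sd, seed = seed)
}

#' Simulate a batch of preset traces
#'
#' @param n Number of traces.
#' @param neuron_class,stimulus,genotype Preset key (see
#'   [preset_library()]).
#' @param noise_sd Noise SD (% of f0).
#' @param seed Integer base seed; trace `i` uses `seed + i`.
#' @return List of [fluorescence_trace()] objects.
#' @export
simulate_traces <- function(n, neuron_class, stimulus,
                            genotype = "wild_type", noise_sd = 1,
                            seed = 1L) {
  lapply(seq_len(n), function(i) {
    cfg <- trace_preset(neuron_class, stimulus, genotype,
                        noise_sd = noise_sd, seed = as.integer(seed + i))
    simulate_trace(cfg,
                   trace_id = sprintf("%s_%s_%s_%03d", neuron_class,
                                      stimulus, genotype, i),
                   neuron_class = neuron_class, genotype = genotype,
                   stimulus = stimulus)
  })
}
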