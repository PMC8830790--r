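#' Plate simulator configuration
#'
#' Parameters of the agent-based chemotaxis plate simulation. Geometry
#' follows the standard 10-cm assay plate: odorant spot 3.33 cm from the
#' plate center, control spot on the opposite side, sodium-azide
#' immobilization zones at both spots, worms started at the center, 1-h
#' assay. Navigation is a biased run-and-tumble walk: the instantaneous
#' tumble rate is `base_tumble_rate * exp(-tumble_gain * dS/dt)`, clamped
#' to `[0, lambda_max]`, where `S` is the perceived odor signal, so worms
#' lengthen runs up-gradient and cut them short down-gradient.
#'
#' @param plate_radius Plate radius (cm). Default 5 (10-cm plate).
#' @param source_offset Distance of odorant/control spots from the center
#'   (cm). Default 3.33.
#' @param trap_radius Radius of the azide immobilization disks (cm).
#' @param duration Assay duration (s). Default 3600 (1 h).
#' @param dt Simulation time step (s).
#' @param n_worms Worms per plate. Default 60 (assays use > 50 worms).
#' @param speed Crawl speed (cm/s).
#' @param base_tumble_rate Baseline tumble rate (1/s).
#' @param tumble_gain Sensitivity of the tumble rate to dS/dt
#'   (dimensionless).
#' @param lambda_max Upper clamp on the tumble rate (1/s).
#' @param field_sigma Width of the Gaussian odor kernels (cm).
#' @param attractant_amplitude,repellent_amplitude Odor-field amplitudes,
#'   proportional to the volume of odorant spotted (1 = the reference
#'   1-uL dose).
#' @param g_att,g_rep Genotype sensory gains for the attractive and
#'   repulsive pathways; see [genotype_presets()].
#' @param source_att,source_rep Source coordinates `(x, y)` in cm.
#'   Defaults place the tested odorant at `(+source_offset, 0)`; assay
#'   presets reposition them (see [simulate_plate()]).
#' @param seed Integer RNG seed for the plate.
#'
#' @return A list of class `plate_sim_config`.
#' @export
plate_sim_config <- function(plate_radius = 5, source_offset = 3.33,
                             trap_radius = 0.5, duration = 3600, dt = 1,
                             n_worms = 60, speed = 0.015,
                             base_tumble_rate = 0.25, tumble_gain = 10,
                             lambda_max = 2, field_sigma = 2,
                             attractant_amplitude = 1,
                             repellent_amplitude = 1,
                             g_att = 45, g_rep = 180,
                             source_att = c(source_offset, 0),
                             source_rep = c(-source_offset, 0),
                             seed = 1L) {
  if (source_offset >= plate_radius) {
    stop("source_offset must be smaller than plate_radius", call. = FALSE)
  }
  if (dt <= 0 || duration <= 0) stop("dt and duration must be positive",
                                     call. = FALSE)
  if (base_tumble_rate < 0 || lambda_max < 0 || speed < 0 ||
      attractant_amplitude < 0 || repellent_amplitude < 0) {
    stop("rates, speed and amplitudes must be nonnegative", call. = FALSE)
  }
  structure(
    list(plate_radius = plate_radius, source_offset = source_offset,
         trap_radius = trap_radius, duration = duration, dt = dt,
         n_worms = as.integer(n_worms), speed = speed,
         base_tumble_rate = base_tumble_rate, tumble_gain = tumble_gain,
         lambda_max = lambda_max, field_sigma = field_sigma,
         attractant_amplitude = attractant_amplitude,
         repellent_amplitude = repellent_amplitude,
         g_att = g_att, g_rep = g_rep,
         source_att = source_att, source_rep = source_rep,
         seed = as.integer(seed)),
    class = "plate_sim_config"
  )
}

#' Genotype sensory-gain presets
#'
#' Gain settings for the two sensory pathways of the simulator.
#' `wild_type` carries the full attractive and (dominant) repulsive gains,
#' calibrated so that single-odorant assays give |CI| well above 0.8 and
#' the pairing assay is repelled nearly as strongly as the repellent alone
#' (integration index near 100%). `osm5_like` models a ciliary-structure
#' mutant: the attractive gain is mildly reduced while the repulsive gain
#' is strongly reduced, so single-odorant chemotaxis keeps its sign but the
#' pairing response collapses toward attraction and the integration index
#' drops far below wild type.
#'
#' @param name `"wild_type"` or `"osm5_like"`.
#' @return List with elements `g_att` and `g_rep`.
#' @export
genotype_presets <- function(name = c("wild_type", "osm5_like")) {
  name <- match.arg(name)
  switch(name,
         wild_type = list(g_att = 45, g_rep = 180),
         osm5_like = list(g_att = 10, g_rep = 5))
}

#' Attractant amplitude presets
#'
#' Field amplitudes for the attractants used in the assays, on the scale
#' where the reference 1-uL isoamyl-alcohol dose is 1. The benzaldehyde
#' dose used in pairing experiments (0.02 uL) is highly attractive,
#' slightly below the IAA reference.
#'
#' @param name `"iaa"` or `"benzaldehyde"`.
#' @return Attractant amplitude (dimensionless).
#' @export
attractant_presets <- function(name = c("iaa", "benzaldehyde")) {
  name <- match.arg(name)
  switch(name, iaa = 1, benzaldehyde = 0.8)
}

#' Perceived odor signal at plate positions
#'
#' The static odor landscape: a difference of isotropic Gaussian kernels,
#' `S = g_att * A_att * G(p; source_att) - g_rep * A_rep * G(p; source_rep)`
#' with `G(p; s) = exp(-|p - s|^2 / (2 field_sigma^2))` (so `G = 1` at the
#' source center).
#'
#' @param x,y Position coordinates (cm), vectorised.
#' @param config A [plate_sim_config()].
#' @return Perceived signal S (dimensionless).
#' @export
odor_field <- function(x, y, config) {
  two_s2 <- 2 * config$field_sigma^2
  g_at <- exp(-((x - config$source_att[1])^2 +
                  (y - config$source_att[2])^2) / two_s2)
  g_rp <- exp(-((x - config$source_rep[1])^2 +
                  (y - config$source_rep[2])^2) / two_s2)
  config$g_att * config$attractant_amplitude * g_at -
    config$g_rep * config$repellent_amplitude * g_rp
}

# Instantaneous tumble rate given the temporal signal derivative.
tumble_rate <- function(dsdt, config) {
  pmin(pmax(config$base_tumble_rate * exp(-config$tumble_gain * dsdt), 0),
       config$lambda_max)
}

# Specialise a config for one assay type: the tested odorant(s) sit at
# (+source_offset, 0); unused pathways get zero amplitude. In the pairing
# assay both odorants are co-located at the odor spot.
assay_config <- function(config, assay_type) {
  assay_type <- match.arg(assay_type, assay_types())
  off <- config$source_offset
  if (assay_type == "attractant") {
    config$source_att <- c(off, 0)
    config$repellent_amplitude <- 0
  } else if (assay_type == "repellent") {
    config$source_rep <- c(off, 0)
    config$attractant_amplitude <- 0
  } else {
    config$source_att <- c(off, 0)
    config$source_rep <- c(off, 0)
  }
  config
}

# One vectorised run-and-tumble step for a block of worms.
# state: list(x, y, theta, immobilized, dsdt, s_prev)
step_worms <- function(state, config) {
  n <- length(state$x)
  u_tumble <- stats::runif(n)
  u_theta <- stats::runif(n)
  active <- !state$immobilized

  lambda <- tumble_rate(state$dsdt, config)
  p_tumble <- 1 - exp(-lambda * config$dt)
  tumble <- active & (u_tumble < p_tumble)
  run <- active & !tumble

  # tumblers reorient in place; their signal derivative resets
  state$theta[tumble] <- 2 * pi * u_theta[tumble]
  state$dsdt[tumble] <- 0

  if (any(run)) {
    nx <- state$x[run] + config$speed * config$dt * cos(state$theta[run])
    ny <- state$y[run] + config$speed * config$dt * sin(state$theta[run])
    r <- sqrt(nx^2 + ny^2)
    out <- r > config$plate_radius
    if (any(out)) {
      # reflect the overshoot back inside and mirror the heading across
      # the tangent at the wall
      phi <- atan2(ny[out], nx[out])
      r_ref <- pmax(2 * config$plate_radius - r[out], 0)
      nx[out] <- r_ref * cos(phi)
      ny[out] <- r_ref * sin(phi)
      th <- state$theta[run][out]
      vx <- cos(th); vy <- sin(th)
      dot <- vx * cos(phi) + vy * sin(phi)
      vx <- vx - 2 * dot * cos(phi)
      vy <- vy - 2 * dot * sin(phi)
      theta_run <- state$theta[run]
      theta_run[out] <- atan2(vy, vx)
      state$theta[run] <- theta_run
    }
    s_new <- odor_field(nx, ny, config)
    state$dsdt[run] <- (s_new - state$s_prev[run]) / config$dt
    state$s_prev[run] <- s_new
    state$x[run] <- nx
    state$y[run] <- ny
  }

  # azide traps at the odor and control spots immobilize on entry
  off <- config$source_offset
  d_odor <- sqrt((state$x - off)^2 + state$y^2)
  d_ctrl <- sqrt((state$x + off)^2 + state$y^2)
  newly <- active & (d_odor <= config$trap_radius |
                       d_ctrl <= config$trap_radius)
  state$immobilized <- state$immobilized | newly
  state
}

#' Simulate one assay plate
#'
#' Runs `n_worms` worms from the plate center for `duration` seconds under
#' the assay's odor field, then partitions final positions into the three
#' scoring areas — odor-side, middle and control-side strips bounded by
#' the lines `x = +plate_radius/3` and `x = -plate_radius/3` — and returns
#' the worm counts as a [plate_count()] row.
#'
#' @param config A [plate_sim_config()].
#' @param assay_type `"attractant"`, `"repellent"` or `"pairing"`.
#' @param genotype Genotype label recorded on the plate (the gains in
#'   `config` define the behavior; see [genotype_presets()]).
#' @param plate_id Identifier recorded on the plate.
#' @return A [plate_count()] row.
#' @export
simulate_plate <- function(config, assay_type, genotype = "wild_type",
                           plate_id = "sim") {
  stopifnot(inherits(config, "plate_sim_config"))
  cfg <- assay_config(config, assay_type)
  n <- cfg$n_worms
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)
  state <- list(
    x = rep(0, n), y = rep(0, n),
    theta = 2 * pi * stats::runif(n),
    immobilized = rep(FALSE, n),
    dsdt = rep(0, n),
    s_prev = rep(odor_field(0, 0, cfg), n)
  )
  n_steps <- ceiling(cfg$duration / cfg$dt)
  for (i in seq_len(n_steps)) {
    state <- step_worms(state, cfg)
  }
  bound <- cfg$plate_radius / 3
  n_toward <- sum(state$x > bound)
  n_away <- sum(state$x < -bound)
  plate_count(plate_id, genotype, assay_type,
              n_toward = n_toward, n_away = n_away,
              n_middle = n - n_toward - n_away)
}

#' Simulate a batch of assay plates
#'
#' Runs `n_plates` independent plates (each with its own deterministic
#' sub-seed `seed + plate number`) and returns a plate-count table ready
#' for [score_plates()].
#'
#' @param n_plates Number of plates.
#' @param assay_type Assay type for all plates.
#' @param genotype `"wild_type"` or `"osm5_like"`; sets the sensory gains
#'   via [genotype_presets()] unless gains are given explicitly in
#'   `config`.
#' @param config Base [plate_sim_config()]; its `seed` is ignored in favor
#'   of `seed`.
#' @param seed Integer base seed.
#' @param use_preset_gains If `TRUE` (default) overwrite `config`'s gains
#'   with the genotype preset.
#' @return Tibble of plate counts, one row per plate.
#' @export
simulate_plates <- function(n_plates, assay_type, genotype = "wild_type",
                            config = plate_sim_config(), seed = 1L,
                            use_preset_gains = TRUE) {
  if (use_preset_gains) {
    gains <- genotype_presets(genotype)
    config$g_att <- gains$g_att
    config$g_rep <- gains$g_rep
  }
  rows <- lapply(seq_len(n_plates), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    simulate_plate(cfg, assay_type, genotype = genotype,
                   plate_id = sprintf("%s_%s_%03d", genotype, assay_type, i))
  })
  dplyr::bind_rows(rows)
}
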