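# Seeded synthetic MEA plates. The generative model is the simplest one that
# makes every scored feature controllable: per-electrode background firing as
# a gamma-renewal process (shape 1 = Poisson), plus network bursts as a
# common Poisson event train; at each event every electrode emits a packet of
# spikes around the event time with Gaussian jitter. Treated phases apply an
# effect profile; vehicle variability enters as per-well and per-phase
# lognormal rate factors so vehicle effect-size distributions are
# non-degenerate for tolerance-interval calibration.

#' Drug-effect profile for the simulator
#'
#' All-default arguments give a vehicle-like profile.
#'
#' @param rate_multiplier Multiplies background rate and burst spike counts.
#' @param burst_duration_multiplier Multiplies the network-burst packet
#'   duration.
#' @param synchrony_jitter_ms Per-electrode jitter of burst packets (ms);
#'   `NULL` keeps the design value.
#' @param decouple_network Replace the common burst driver by independent
#'   per-electrode drivers (rates preserved, synchrony destroyed).
#' @param silence Near-total silencing of the treated phase.
#' @param isi_regularization In `[0, 1)`: 0 keeps exponential background
#'   ISIs; larger values raise the gamma shape, pushing median/mean ISI
#'   toward 1.
#' @return An `effect_profile` list.
#' @export
effect_profile <- function(rate_multiplier = 1, burst_duration_multiplier = 1,
                           synchrony_jitter_ms = NULL,
                           decouple_network = FALSE, silence = FALSE,
                           isi_regularization = 0) {
  stopifnot(rate_multiplier > 0, burst_duration_multiplier > 0,
            isi_regularization >= 0, isi_regularization < 1)
  structure(list(rate_multiplier = rate_multiplier,
                 burst_duration_multiplier = burst_duration_multiplier,
                 synchrony_jitter_ms = synchrony_jitter_ms,
                 decouple_network = decouple_network, silence = silence,
                 isi_regularization = isi_regularization),
            class = "effect_profile")
}

#' Simulation design for one 48-well plate
#'
#' Defaults emulate the screening setup: 48 wells of 16 electrodes, 30-min
#' baseline and treated phases, 8 vehicle wells and five conditions of 8
#' replicate wells each (inhibitory and excitatory positive controls, a mild
#' inhibitory test compound, a silencing test compound, and a negative
#' control).
#'
#' @param n_wells,electrodes_per_well,duration_s Plate geometry and phase
#'   length.
#' @param background_rate_hz Background (tonic) firing rate per electrode.
#' @param network_burst_rate_hz Rate of common network-burst events.
#' @param network_burst_shape Gamma shape of the inter-event intervals:
#'   1 = Poisson; the default 4 (ISI CV 0.5) reproduces the quasi-rhythmic
#'   network bursting of mature cortical cultures.
#' @param burst_spikes Mean spikes per electrode per network burst.
#' @param burst_duration_s Burst packet duration (s).
#' @param synchrony_jitter_ms Gaussian jitter of packet centers across
#'   electrodes (ms).
#' @param vehicle_rate_sdlog Lognormal sd of the per-well rate factor.
#' @param phase_drift_sdlog Lognormal sd of the per-phase drift factor
#'   (makes vehicle percent changes non-degenerate).
#' @param n_vehicle Number of vehicle wells.
#' @param conditions List of conditions, each
#'   `list(compound=, role=, concentration_um=, n_wells=, profile=)`.
#' @param seed Root seed; identical designs give identical plates.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_wells = 48L, electrodes_per_well = 16L,
                              duration_s = 1800, background_rate_hz = 0.8,
                              network_burst_rate_hz = 0.15,
                              network_burst_shape = 4, burst_spikes = 12,
                              burst_duration_s = 0.2,
                              synchrony_jitter_ms = 10,
                              vehicle_rate_sdlog = 0.10,
                              phase_drift_sdlog = 0.08, n_vehicle = 8L,
                              conditions = default_conditions(), seed = 1L) {
  design <- structure(as.list(environment()), class = "simulation_design")
  n_cond <- sum(vapply(conditions, function(cd) cd$n_wells, numeric(1)))
  if (n_vehicle + n_cond > n_wells)
    stop("design is over-full: ", n_vehicle + n_cond, " wells requested on a ",
         n_wells, "-well plate")
  design
}

#' @rdname simulation_design
#' @export
default_conditions <- function() {
  list(
    list(compound = "pos_inhibitory", role = "positive_control",
         concentration_um = 10, n_wells = 8L,
         profile = effect_profile(rate_multiplier = 0.25,
                                  burst_duration_multiplier = 0.6,
                                  synchrony_jitter_ms = 30)),
    list(compound = "pos_excitatory", role = "positive_control",
         concentration_um = 10, n_wells = 8L,
         profile = effect_profile(rate_multiplier = 2.5,
                                  burst_duration_multiplier = 2,
                                  synchrony_jitter_ms = 4)),
    list(compound = "mild_inhibitory", role = "test",
         concentration_um = 1, n_wells = 8L,
         profile = effect_profile(rate_multiplier = 0.6,
                                  synchrony_jitter_ms = 16)),
    list(compound = "silencer", role = "test",
         concentration_um = 10, n_wells = 8L,
         profile = effect_profile(silence = TRUE)),
    list(compound = "neg_control", role = "negative_control",
         concentration_um = 10, n_wells = 8L, profile = effect_profile())
  )
}

# Gamma-renewal spike train on [0, duration]: shape 1 = Poisson; larger
# shapes regularize the ISIs while keeping the mean rate.
.renewal_train <- function(rate, duration, shape = 1) {
  if (rate <= 0) return(numeric(0))
  n_exp <- rate * duration
  isi <- rgamma(ceiling(n_exp + 6 * sqrt(n_exp) + 10),
                shape = shape, rate = shape * rate)
  ts <- cumsum(isi)
  while (length(ts) && ts[length(ts)] < duration) {
    more <- cumsum(rgamma(50, shape = shape, rate = shape * rate)) +
      ts[length(ts)]
    ts <- c(ts, more)
  }
  ts[ts < duration]
}

#' Simulate one well recording
#'
#' @param design A [simulation_design()].
#' @param profile An [effect_profile()] (applied only when
#'   `phase = "treated"`); `NULL` means vehicle.
#' @param phase `"baseline"` or `"treated"`.
#' @param seed Integer seed for this well/phase.
#' @param well_id,plate_id Identifiers for the recording.
#' @param well_rate_factor Per-well lognormal rate factor shared by the two
#'   phases of the same well.
#' @return A [well_recording()].
#' @export
simulate_well <- function(design, profile = NULL, phase = "baseline",
                          seed = 1L, well_id = "A1", plate_id = "simplate",
                          well_rate_factor = 1) {
  set.seed(seed)
  if (is.null(profile)) profile <- effect_profile()
  treated <- identical(phase, "treated")
  drift <- rlnorm(1, 0, design$phase_drift_sdlog)
  base_rate <- design$background_rate_hz * well_rate_factor * drift
  nb_rate <- design$network_burst_rate_hz
  burst_n <- design$burst_spikes
  burst_dur <- design$burst_duration_s
  jitter_s <- design$synchrony_jitter_ms / 1000
  shape <- 1
  rate <- base_rate
  decouple <- FALSE
  if (treated) {
    if (profile$silence) {
      rate <- base_rate * 0.002
      nb_rate <- 0
    } else {
      rate <- base_rate * profile$rate_multiplier
      burst_n <- burst_n * profile$rate_multiplier
      burst_dur <- burst_dur * profile$burst_duration_multiplier
      if (!is.null(profile$synchrony_jitter_ms))
        jitter_s <- profile$synchrony_jitter_ms / 1000
      shape <- 1 / (1 - profile$isi_regularization)
      decouple <- profile$decouple_network
    }
  }
  dur <- design$duration_s
  nb_shape <- design$network_burst_shape %||% 4
  events <- if (nb_rate > 0) .renewal_train(nb_rate, dur, nb_shape)
            else numeric(0)
  trains <- lapply(seq_len(design$electrodes_per_well), function(e) {
    bg <- .renewal_train(rate, dur, shape)
    ev <- if (decouple && nb_rate > 0)
      .renewal_train(nb_rate, dur, nb_shape) else events
    burst_ts <- unlist(lapply(ev, function(t0) {
      center <- t0 + rnorm(1, 0, jitter_s)
      n <- rpois(1, burst_n)
      if (n == 0) return(numeric(0))
      center + runif(n, 0, burst_dur)
    }))
    ts <- sort(c(bg, burst_ts))
    ts <- ts[ts >= 0 & ts < dur]
    # strictly increasing timestamps: nudge exact duplicates apart
    if (length(ts) > 1) {
      dup <- which(diff(ts) <= 0)
      while (length(dup)) {
        ts[dup + 1] <- ts[dup] + 1e-6
        ts <- sort(ts)
        dup <- which(diff(ts) <= 0)
      }
    }
    spike_train(sprintf("e%02d", e), ts)
  })
  well_recording(well_id, phase, trains, dur, plate_id)
}

#' Simulate a full plate (both phases) and its plate map
#'
#' Vehicle wells receive vehicle-noise-only treated phases. Every well/phase
#' derives its own substream seed from the design seed, so identical designs
#' reproduce identical plates.
#'
#' @param design A [simulation_design()].
#' @param plate_id Plate identifier.
#' @return `list(recordings=, map=)` with one baseline and one treated
#'   [well_recording()] per well.
#' @export
simulate_plate <- function(design = simulation_design(),
                           plate_id = "simplate") {
  rows <- LETTERS[1:6]
  wells <- as.vector(t(outer(rows, 1:8, paste0)))[seq_len(design$n_wells)]
  roles <- c(rep("vehicle", design$n_vehicle),
             unlist(lapply(design$conditions, function(cd)
               rep(cd$role, cd$n_wells))))
  compounds <- c(rep("", design$n_vehicle),
                 unlist(lapply(design$conditions, function(cd)
                   rep(cd$compound, cd$n_wells))))
  concs <- c(rep(0, design$n_vehicle),
             unlist(lapply(design$conditions, function(cd)
               rep(cd$concentration_um, cd$n_wells))))
  profiles <- c(rep(list(NULL), design$n_vehicle),
                unlist(lapply(design$conditions, function(cd)
                  rep(list(cd$profile), cd$n_wells)), recursive = FALSE))
  n_used <- length(roles)
  map <- plate_map(well = wells[seq_len(n_used)], role = roles,
                   compound = compounds, concentration_um = concs)
  recordings <- list()
  for (i in seq_len(n_used)) {
    set.seed(derive_seed(design$seed, plate_id, wells[i], "factor"))
    wf <- rlnorm(1, 0, design$vehicle_rate_sdlog)
    for (phase in c("baseline", "treated")) {
      rec <- simulate_well(design, profiles[[i]], phase,
                           seed = derive_seed(design$seed, plate_id,
                                              wells[i], phase),
                           well_id = wells[i], plate_id = plate_id,
                           well_rate_factor = wf)
      recordings[[paste(wells[i], phase, sep = ".")]] <- rec
    }
  }
  list(recordings = recordings, map = map)
}
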