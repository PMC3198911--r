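#' Cohort generator configuration
#'
#' Study-scale defaults: 33,520 samples per recording at 1 kHz, eight
#' channels, 5% antagonist co-activation (15% in the unfamiliar supinated
#' posture), 0.5%-of-range torque sensor noise, and the session/posture
#' perturbation magnitudes. Cross-session change combines per-muscle source
#' amplitude drift with a per-muscle amplitude nonlinearity (an exponent on
#' the excitation-to-EMG amplitude map, emulating fatigue and electrode
#' impedance change, which per-session normalization cannot cancel); the
#' 24-hour session additionally perturbs the cross-talk matrix (new
#' electrode placement). The supinated posture blends the cross-talk matrix
#' with a neighbor-shifted copy, rescales per-muscle moment arms (forearm
#' rotation changes leverage) and reverses the torque sensor sign.
#'
#' @param n_samples Samples per recording.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param coactivation Antagonist co-activation fraction (pronated).
#' @param coactivation_supinated Antagonist co-activation fraction in the
#'   supinated posture.
#' @param torque_noise_frac Torque sensor noise SD as a fraction of the
#'   noiseless torque range.
#' @param participation_primary,participation_secondary Ranges of per-muscle
#'   participation weights for primary wrist movers and secondary (finger /
#'   deep-representative) muscles.
#' @param segment_jitter Range of per-segment load-sharing variability.
#' @param gain_drift_range Source amplitude drift bounds (sessions 2, 3).
#' @param amp_exponent_s2,amp_exponent_s3 Per-muscle amplitude-nonlinearity
#'   exponent ranges for sessions 2 and 3.
#' @param drive_noise SD of the per-muscle multiplicative neural-drive
#'   noise on the EMG side (low-pass filtered at `drive_noise_hz`): EMG
#'   amplitude fluctuates around the true drive even at constant force.
#' @param drive_noise_hz Bandwidth of the drive-noise fluctuations, Hz.
#' @param fatigue_drift Range of the within-session growth of each muscle's
#'   EMG amplitude at constant force (fatigue / electrode-gel settling; EMG
#'   side only). The growth is concave (fast early, plateauing), with time
#'   constant `fatigue_tau` as a fraction of the session.
#' @param fatigue_tau Time constant of the within-session amplitude
#'   transient, as a fraction of the session length.
#' @param electrode_shift_max Maximum additive off-diagonal cross-talk
#'   perturbation (session 3).
#' @param posture_blend Weight of the shifted mixing in the supinated
#'   posture remap (0 = no change, 1 = fully shifted).
#' @param ma_scale_supinated Range of per-muscle moment-arm scaling in the
#'   supinated posture.
#' @param tab Physiological muscle table.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 33520, sample_rate_hz = 1000,
                          coactivation = 0.05,
                          coactivation_supinated = 0.15,
                          torque_noise_frac = 0.005,
                          participation_primary = c(0.7, 1),
                          participation_secondary = c(0.55, 0.95),
                          segment_jitter = c(0.7, 1.3),
                          gain_drift_range = c(0.7, 1.3),
                          amp_exponent_s2 = c(0.7, 1.35),
                          amp_exponent_s3 = c(0.6, 1.5),
                          drive_noise = 0.15,
                          drive_noise_hz = 2,
                          fatigue_drift = c(0.3, 0.8),
                          fatigue_tau = 0.15,
                          electrode_shift_max = 0.15,
                          posture_blend = 0.5,
                          ma_scale_supinated = c(0.55, 0.85),
                          tab = muscle_table()) {
  structure(list(n_samples = as.integer(n_samples),
                 sample_rate_hz = sample_rate_hz,
                 coactivation = coactivation,
                 coactivation_supinated = coactivation_supinated,
                 torque_noise_frac = torque_noise_frac,
                 participation_primary = participation_primary,
                 participation_secondary = participation_secondary,
                 segment_jitter = segment_jitter,
                 gain_drift_range = gain_drift_range,
                 amp_exponent_s2 = amp_exponent_s2,
                 amp_exponent_s3 = amp_exponent_s3,
                 drive_noise = drive_noise,
                 drive_noise_hz = drive_noise_hz,
                 fatigue_drift = fatigue_drift,
                 fatigue_tau = fatigue_tau,
                 electrode_shift_max = electrode_shift_max,
                 posture_blend = posture_blend,
                 ma_scale_supinated = ma_scale_supinated,
                 tab = tab),
            class = "cohort_config")
}

#' Draw a synthetic subject with known ground truth
#'
#' Ground-truth activation dynamics and per-muscle physiology are drawn
#' within the same bounds the calibration searches (activation parameters in
#' their stability/physiology boxes; Fmax and moment arms within mean ± 1 SD
#' of the table). The cross-talk matrix is diagonally dominant with
#' neighbor decay; channel gains, DC offsets, motion-artefact drift
#' amplitudes and measurement noise define the raw-signal model.
#'
#' @param config A [cohort_config()].
#' @param seed Subject seed; everything about the subject derives from it.
#' @param subject_id Label.
#' @return A list of class `synthetic_subject` with `ground_truth`
#'   ([pbm_parameters()]), `crosstalk`, `channel_gains`, `noise`, `seed`.
#' @export
synthetic_subject <- function(config = cohort_config(), seed = 1,
                              subject_id = sprintf("sub%02d", seed)) {
  tab <- config$tab
  m <- nrow(tab)
  with_seed(seed, {
    act <- activation_params(A = runif(1, -1.5, -0.2),
                             C1 = runif(1, -0.6, 0.8),
                             C2 = runif(1, -0.6, 0.6),
                             d_ms = runif(1, 15, 90))
    muscles <- lapply(seq_len(m), function(j) {
      r <- tab[j, ]
      muscle_physiology(r$muscle,
                        runif(1, max(r$fmax_mean_N - r$fmax_sd_N, 1),
                              r$fmax_mean_N + r$fmax_sd_N),
                        r$ma_mean_m + runif(1, -r$ma_sd_m, r$ma_sd_m) *
                          0.999,
                        r$pcsa_cm2, r$sigma_pcsa_cm2, r$role)
    })
    cross <- outer(seq_len(m), seq_len(m),
                   function(i, j) 0.15 * exp(-abs(i - j) / 1.2))
    diag(cross) <- 1
    gains <- runif(m, 5e-4, 2e-3)
    noise <- list(carrier_band_hz = c(20, 450),
                  dc_offset_V = runif(m, -0.4, 0.4),
                  drift_amp_V = runif(m, 1, 3) * 3e-4,
                  measurement_sd_V = 5e-6)
    structure(list(ground_truth = pbm_parameters(act, muscles),
                   crosstalk = cross, channel_gains = gains,
                   noise = noise, seed = as.integer(seed),
                   subject_id = subject_id, config = config),
              class = "synthetic_subject")
  })
}

#' Per-muscle excitation schedule for the torque-tracking protocol
#'
#' Builds the 14-segment protocol: one maximum-effort flexion and one
#' maximum-effort extension, then three gradual flexions to 50% MVC and back
#' to zero, three gradual extensions to 50%, three flexions to 25% and three
#' extensions to 25%. Segment durations carry small seeded jitter. Agonist
#' muscles follow the ramp profile, weighted by per-muscle participation
#' (primary wrist movers high, secondary muscles low — the fingers are
#' braced against the plate) and per-segment load-sharing jitter (motor
#' redundancy: repetitions of the same torque ramp share load differently
#' across synergists); antagonists co-activate at a low fraction of the
#' profile.
#'
#' @param config A [cohort_config()] (sample count, rate, co-activation).
#' @param seed Schedule seed.
#' @param coactivation Co-activation fraction override (default from
#'   `config`).
#' @return An `n_samples` x 8 matrix of excitations in \[0, 1\] (columns in
#'   canonical channel order), with attributes `segments` (action table) and
#'   `profile` (the signed target-torque fraction series).
#' @export
generate_excitation_schedule <- function(config = cohort_config(), seed = 1,
                                         coactivation = config$coactivation) {
  n <- config$n_samples
  actions <- data.frame(
    direction = c("flex", "ext", rep("flex", 3), rep("ext", 3),
                  rep("flex", 3), rep("ext", 3)),
    level = c(1, 1, rep(0.5, 3), rep(0.5, 3), rep(0.25, 3), rep(0.25, 3)))
  ns <- nrow(actions)
  primary <- semg_channels %in% primary_channels()
  with_seed(seed, {
    dur <- runif(ns, 0.9, 1.1)
    dur <- floor(dur / sum(dur) * n)
    dur[ns] <- dur[ns] + (n - sum(dur))
    pp <- config$participation_primary
    ps <- config$participation_secondary
    base_w <- ifelse(primary, runif(8, pp[1], pp[2]),
                     runif(8, ps[1], ps[2]))
    sj <- config$segment_jitter
    seg_jit <- matrix(runif(ns * 8, sj[1], sj[2]), ns, 8)
  })
  profile <- numeric(n)
  exc <- matrix(0, n, 8, dimnames = list(NULL, semg_channels))
  tab_roles <- c(rep("ext", 4), rep("flex", 4)) # canonical channel order
  pos <- 0L
  segments <- actions
  segments$start <- NA_integer_
  segments$end <- NA_integer_
  for (s in seq_len(ns)) {
    len <- dur[s]
    idx <- (pos + 1L):(pos + len)
    # ramp up, brief hold, ramp down, short rest
    up <- floor(0.40 * len)
    hold <- floor(0.12 * len)
    down <- floor(0.40 * len)
    rest <- len - up - hold - down
    prof <- c(seq(0, 1, length.out = up), rep(1, hold),
              seq(1, 0, length.out = down), rep(0, rest)) * actions$level[s]
    profile[idx] <- prof * if (actions$direction[s] == "flex") 1 else -1
    agonist <- tab_roles == actions$direction[s]
    for (j in 1:8) {
      w <- if (agonist[j]) base_w[j] * seg_jit[s, j] else coactivation
      exc[idx, j] <- pmin(prof * w, 1)
    }
    segments$start[s] <- pos + 1L
    segments$end[s] <- pos + len
    pos <- pos + len
  }
  attr(exc, "segments") <- segments
  attr(exc, "profile") <- profile
  exc
}

#' Ground-truth torque for a set of muscle excitations
#'
#' Runs the forward physiological model with the subject's ground-truth
#' parameters on the noiseless excitations and adds seeded Gaussian
#' measurement noise. Flexion positive, extension negative.
#'
#' @param excitations Excitation matrix (samples x muscles, \[0, 1\]).
#' @param subject A [synthetic_subject()].
#' @param noise_sd Measurement noise SD in N·m (0 = noiseless).
#' @param seed Noise seed.
#' @param ma_scale Optional per-muscle moment-arm scaling (posture change).
#' @return Torque series, N·m.
#' @export
synthesize_torque <- function(excitations, subject, noise_sd = 0, seed = 1,
                              ma_scale = NULL) {
  stopifnot(inherits(subject, "synthetic_subject"))
  fs <- subject$config$sample_rate_hz
  gt <- subject$ground_truth
  if (!is.null(ma_scale)) {
    stopifnot(length(ma_scale) == length(gt$muscles), all(ma_scale > 0))
    for (j in seq_along(gt$muscles))
      gt$muscles[[j]]$ma_m <- gt$muscles[[j]]$ma_m * ma_scale[j]
  }
  tau <- forward_pbm(list(envelopes = excitations, sample_rate_hz = fs), gt)
  if (noise_sd > 0)
    tau <- tau + with_seed(seed, rnorm(length(tau), 0, noise_sd))
  tau
}

# Band-limited (band_hz) unit-variance Gaussian carrier.
emg_carrier <- function(n, fs, band_hz) {
  x <- rnorm(n)
  bt <- signal::butter(4, band_hz / (fs / 2), type = "pass")
  y <- filtfilt_reflect(bt$b, bt$a, x, pad = 12)
  y / sd(y)
}

#' Synthesize raw SEMG channels from muscle excitations
#'
#' Each channel is amplitude-modulated band-limited Gaussian noise: the
#' cross-talk-mixed excitation modulates a 20–450 Hz carrier, scaled by the
#' channel gain, plus a DC offset, a sub-5 Hz motion-artefact drift, and
#' white measurement noise. An optional per-muscle amplitude exponent
#' distorts the excitation-to-EMG amplitude map before mixing (fatigue /
#' impedance drift between sessions). Fully deterministic given `seed`.
#'
#' @param excitations Excitation matrix (samples x muscles).
#' @param subject A [synthetic_subject()].
#' @param seed Carrier/noise seed.
#' @param mixing Optional effective mixing matrix (channels x muscles);
#'   defaults to the subject's cross-talk matrix.
#' @param amp_exponent Optional per-muscle exponents applied to the
#'   excitations on the recorded-EMG side only.
#' @return SEMG matrix, samples x channels, volts.
#' @export
synthesize_raw_semg <- function(excitations, subject, seed = 1,
                                mixing = subject$crosstalk,
                                amp_exponent = NULL) {
  stopifnot(inherits(subject, "synthetic_subject"))
  n <- nrow(excitations)
  m <- ncol(excitations)
  fs <- subject$config$sample_rate_hz
  if (!is.null(amp_exponent)) {
    stopifnot(length(amp_exponent) == m, all(amp_exponent > 0))
    excitations <- sweep(excitations, 2, amp_exponent, "^")
  }
  mixed <- excitations %*% t(mixing)
  nz <- subject$noise
  with_seed(seed, {
    semg <- matrix(0, n, m, dimnames = list(NULL, semg_channels[seq_len(m)]))
    for (i in seq_len(m)) {
      carrier <- emg_carrier(n, fs, nz$carrier_band_hz)
      drift_raw <- rnorm(n)
      bt <- signal::butter(2, 2 / (fs / 2), type = "low")
      drift <- filtfilt_reflect(bt$b, bt$a, drift_raw, pad = 6)
      drift <- drift / max(sd(drift), 1e-12) * nz$drift_amp_V[i]
      semg[, i] <- subject$channel_gains[i] * mixed[, i] * carrier +
        nz$dc_offset_V[i] + drift + rnorm(n, 0, nz$measurement_sd_V)
    }
    semg
  })
}

#' Session-to-session perturbation specification
#'
#' @param gain_drift Per-muscle multiplicative source amplitude factors
#'   (NULL = none). Applied to the mixing matrix columns, so the relative
#'   channel mix changes across sessions.
#' @param amplitude_exponent Per-muscle exponents on the excitation-to-EMG
#'   amplitude map (NULL = none): values below/above 1 emulate the
#'   fatigue- and impedance-driven change of the amplitude-force relation,
#'   which per-session normalization cannot cancel.
#' @param electrode_shift Additive perturbation to the cross-talk matrix
#'   (NULL = none); typically off-diagonal, emulating re-attached electrodes.
#' @param posture_remap Replacement mixing matrix for a posture change
#'   (NULL = none).
#' @param ma_scale Per-muscle moment-arm scaling on the torque side
#'   (NULL = none); forearm rotation changes muscle leverage.
#' @param flip_torque Flip the recorded torque sign (supinated sensor
#'   orientation).
#' @return A list of class `drift_spec`.
#' @export
drift_spec <- function(gain_drift = NULL, amplitude_exponent = NULL,
                       electrode_shift = NULL, posture_remap = NULL,
                       ma_scale = NULL, flip_torque = FALSE) {
  structure(list(gain_drift = gain_drift,
                 amplitude_exponent = amplitude_exponent,
                 electrode_shift = electrode_shift,
                 posture_remap = posture_remap, ma_scale = ma_scale,
                 flip_torque = isTRUE(flip_torque)),
            class = "drift_spec")
}

# Effective mixing matrix after a drift specification.
apply_drift_mixing <- function(base, drift) {
  mix <- if (!is.null(drift$posture_remap)) drift$posture_remap else base
  if (!is.null(drift$electrode_shift)) mix <- mix + drift$electrode_shift
  if (!is.null(drift$gain_drift)) mix <- mix %*% diag(drift$gain_drift)
  if (any(mix < 0)) stop("drifted mixing matrix has negative entries")
  if (any(diag(mix) <= 0)) stop("drifted mixing matrix lost its diagonal")
  mix
}

# Assemble a full synthetic recording for one protocol run.
generate_session <- function(subject, schedule_seed, synth_seed,
                             drift = drift_spec(), session_id = "s1",
                             posture = "pronated",
                             coactivation = subject$config$coactivation) {
  cfg <- subject$config
  exc <- generate_excitation_schedule(cfg, schedule_seed, coactivation)
  synthesize_drifted(subject, exc, drift, synth_seed, session_id, posture)
}

# Shared synthesis path: deterministic given (subject, excitations, drift,
# seed).
synthesize_drifted <- function(subject, exc, drift, synth_seed, session_id,
                               posture) {
  cfg <- subject$config
  mix <- apply_drift_mixing(subject$crosstalk, drift)
  tau0 <- synthesize_torque(exc, subject, noise_sd = 0,
                            ma_scale = drift$ma_scale)
  noise_sd <- cfg$torque_noise_frac * diff(range(tau0))
  tau <- tau0 + with_seed(derive_seed(synth_seed, 2),
                          rnorm(length(tau0), 0, noise_sd))
  if (drift$flip_torque) {
    tau <- -tau
    tau0 <- -tau0
  }
  # within-session amplitude transient (electrode-gel settling, early
  # fatigue): EMG amplitude per unit force rises quickly after attachment
  # and plateaus; the torque side is untouched
  fr <- cfg$fatigue_drift
  fat <- with_seed(derive_seed(synth_seed, 3),
                   runif(ncol(exc), fr[1], fr[2]))
  tt <- seq(0, 1, length.out = nrow(exc))
  settle <- 1 - exp(-tt / cfg$fatigue_tau)
  exc_emg <- exc * (1 + outer(settle, fat))
  # multiplicative neural-drive noise: EMG amplitude fluctuates around the
  # true drive even at constant force (motor unit rotation)
  if (cfg$drive_noise > 0) {
    bt <- signal::butter(2, cfg$drive_noise_hz / (cfg$sample_rate_hz / 2),
                         type = "low")
    dn <- with_seed(derive_seed(synth_seed, 4), {
      sapply(seq_len(ncol(exc)), function(j) {
        z <- filtfilt_reflect(bt$b, bt$a, rnorm(nrow(exc)), pad = 6)
        1 + z / sd(z) * cfg$drive_noise
      })
    })
    exc_emg <- exc_emg * pmax(dn, 0)
  }
  exc_emg[exc_emg > 1] <- 1
  semg <- synthesize_raw_semg(exc_emg, subject, derive_seed(synth_seed, 1),
                              mix, drift$amplitude_exponent)
  rec <- recording(semg, tau, cfg$sample_rate_hz, semg_channels,
                   session_id, posture, subject$subject_id)
  attr(rec, "synthesis") <- list(excitations = exc, subject = subject,
                                 mixing = mix, seed = synth_seed,
                                 noiseless_torque = tau0)
  rec
}

#' Re-synthesize a recording under a session/posture perturbation
#'
#' Takes a synthetic recording (which carries its excitations and subject as
#' provenance) and re-synthesizes it under the drift specification. With an
#' identity drift and the recording's own seed, the output equals the input.
#'
#' @param rec A synthetic `semg_recording` (from the generator).
#' @param drift A [drift_spec()].
#' @param seed Synthesis seed for the new carriers/noise (default: the
#'   recording's own).
#' @param session_id,posture Metadata for the perturbed recording.
#' @return A `semg_recording`.
#' @export
apply_drift <- function(rec, drift, seed = NULL, session_id = rec$session_id,
                        posture = rec$posture) {
  syn <- attr(rec, "synthesis")
  if (is.null(syn))
    stop("recording carries no synthesis provenance; apply_drift only ",
         "operates on generator output")
  if (is.null(seed)) seed <- syn$seed
  synthesize_drifted(syn$subject, syn$excitations, drift, seed,
                     session_id, posture)
}

# Default posture remap: blend of the subject's mixing with a
# neighbor-shifted copy (each channel partially picks up the next muscle's
# sources), emulating the SEMG signal-space shift under forearm supination.
posture_remap_matrix <- function(cross, blend) {
  m <- ncol(cross)
  shifted <- cross[, c(2:m, 1)]
  (1 - blend) * cross + blend * shifted
}

#' Generate a synthetic cohort with ground-truth manifest
#'
#' Per subject: a session-1 pronated and a session-1 supinated recording
#' (posture remap, moment-arm rescaling, higher co-activation, reversed
#' torque sensor), a session-2 recording (one hour later: source amplitude
#' drift and amplitude nonlinearity) and a session-3 recording (24 hours
#' later: fresh, stronger drift plus electrode-shift cross-talk
#' perturbation). Each protocol run uses a fresh excitation schedule. All
#' seeds derive from `master_seed`; the manifest records ground-truth
#' parameters and seeds.
#'
#' @param n_subjects Number of subjects (default 11).
#' @param config A [cohort_config()].
#' @param master_seed Master seed.
#' @return A list of class `synthetic_cohort`: `subjects` (each with
#'   `recordings` list `s1_pronated`, `s1_supinated`, `s2`, `s3` and
#'   `subject`), plus `config` and `manifest`.
#' @export
generate_cohort <- function(n_subjects = 11, config = cohort_config(),
                            master_seed = 1) {
  stopifnot(n_subjects >= 1)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sseed <- derive_seed(master_seed, i)
    subject <- synthetic_subject(config, sseed, sprintf("sub%02d", i))
    m <- nrow(config$tab)
    drifts <- with_seed(derive_seed(sseed, 99), {
      g2 <- runif(m, config$gain_drift_range[1], config$gain_drift_range[2])
      g3 <- runif(m, config$gain_drift_range[1], config$gain_drift_range[2])
      p2 <- runif(m, config$amp_exponent_s2[1], config$amp_exponent_s2[2])
      p3 <- runif(m, config$amp_exponent_s3[1], config$amp_exponent_s3[2])
      shift <- matrix(runif(m * m, 0, config$electrode_shift_max), m, m)
      diag(shift) <- 0
      ma_s <- runif(m, config$ma_scale_supinated[1],
                    config$ma_scale_supinated[2])
      list(g2 = g2, g3 = g3, p2 = p2, p3 = p3, shift = shift, ma_s = ma_s)
    })
    remap <- posture_remap_matrix(subject$crosstalk, config$posture_blend)
    recs <- list(
      s1_pronated = generate_session(subject, derive_seed(sseed, 1),
                                     derive_seed(sseed, 2)),
      s1_supinated = generate_session(subject, derive_seed(sseed, 3),
                                      derive_seed(sseed, 4),
                                      drift_spec(posture_remap = remap,
                                                 ma_scale = drifts$ma_s,
                                                 flip_torque = TRUE),
                                      session_id = "s1",
                                      posture = "supinated",
                                      coactivation =
                                        config$coactivation_supinated),
      s2 = generate_session(subject, derive_seed(sseed, 5),
                            derive_seed(sseed, 6),
                            drift_spec(gain_drift = drifts$g2,
                                       amplitude_exponent = drifts$p2),
                            session_id = "s2"),
      s3 = generate_session(subject, derive_seed(sseed, 7),
                            derive_seed(sseed, 8),
                            drift_spec(gain_drift = drifts$g3,
                                       amplitude_exponent = drifts$p3,
                                       electrode_shift = drifts$shift),
                            session_id = "s3"))
    subjects[[i]] <- list(subject = subject, recordings = recs,
                          drifts = drifts, seed = sseed)
  }
  manifest <- lapply(subjects, function(s) {
    gt <- s$subject$ground_truth
    list(subject_id = s$subject$subject_id, seed = s$seed,
         activation = unclass(gt$activation)[c("A", "C1", "C2", "d_ms")],
         fmax_N = vapply(gt$muscles, `[[`, numeric(1), "fmax_N"),
         ma_m = vapply(gt$muscles, `[[`, numeric(1), "ma_m"))
  })
  structure(list(subjects = subjects, config = config,
                 master_seed = master_seed, manifest = manifest),
            class = "synthetic_cohort")
}

#' Write a cohort's ground-truth manifest to JSON
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(cohort, path) {
  jsonlite::write_json(list(master_seed = cohort$master_seed,
                            subjects = cohort$manifest),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
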