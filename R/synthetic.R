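# Surrogate multi-subject sEMG generator.
#
# Signal model per channel c:
#   s_c(t) = gain_c * env_c(t - onset) * n_c(t) + noise_c(t) + m * sin(2*pi*50*t + phi)
# with n_c a unit-variance bandlimited Gaussian carrier (the standard
# interference-pattern surrogate for sEMG), env_c a class-specific
# activation envelope, and a common-mode 50 Hz mains component so the
# notch stage is exercised.

#' Acquisition paradigm specification
#'
#' Timing of one cued movement trial: a 12 s trial sampled at 1500 Hz with
#' the go-cue ("beep") at 4 s and 3 s of movement, matching a standard
#' cued lower-limb acquisition protocol. A session comprises `n_groups`
#' blocks of `moves_per_group` trials.
#'
#' @param n_groups number of trial blocks per subject session.
#' @param moves_per_group trials per block.
#' @param cue_onset_s go-cue time (s).
#' @param move_duration_s movement duration (s).
#' @param trial_duration_s total trial duration (s).
#' @param fs_hz sampling rate (Hz).
#' @return object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(n_groups = 3L, moves_per_group = 10L,
                          cue_onset_s = 4.0, move_duration_s = 3.0,
                          trial_duration_s = 12.0, fs_hz = 1500L) {
  if (cue_onset_s + move_duration_s > trial_duration_s)
    stopf("cue_onset_s + move_duration_s must be <= trial_duration_s")
  assert_scalar_number(fs_hz, "fs_hz", min = 1)
  structure(list(n_groups = as.integer(n_groups),
                 moves_per_group = as.integer(moves_per_group),
                 cue_onset_s = cue_onset_s, move_duration_s = move_duration_s,
                 trial_duration_s = trial_duration_s, fs_hz = as.integer(fs_hz)),
            class = "paradigm_spec")
}

#' Class-specific activation-envelope templates
#'
#' Builds the three movement templates for a 5-muscle montage (rectus
#' femoris, vastus lateralis, tibialis anterior, biceps femoris, lateral
#' gastrocnemius). Each template is a C x K nonnegative envelope matrix
#' sampled at `env_fs_hz` over the movement duration plus a carrier band:
#' * standing: ramp-then-hold, weighted toward the knee extensors;
#' * sitting: high initial activation decaying through the descent,
#'   weighted toward the posterior chain;
#' * walking: ~1 Hz alternating bursts between antagonist channel groups.
#'
#' The distinct per-channel weighting patterns give the classes distinct
#' amplitude synergies, and walking's burst periodicity adds a temporal
#' signature; all three share the 20-450 Hz sEMG carrier band by default.
#'
#' @param move_duration_s envelope support in seconds.
#' @param env_fs_hz envelope sampling rate (Hz); envelopes vary slowly,
#'   50 Hz is ample.
#' @param carrier_band_hz length-2 numeric, carrier band edges in Hz.
#' @param n_channels number of sEMG channels (default 5, one leg).
#' @return named list of `movement_template` objects
#'   (`standing`, `sitting`, `walking`).
#' @export
movement_templates <- function(move_duration_s = 3.0, env_fs_hz = 50,
                               carrier_band_hz = c(20, 450),
                               n_channels = 5L) {
  K <- round(move_duration_s * env_fs_hz)
  tt <- (seq_len(K) - 1L) / env_fs_hz
  C <- as.integer(n_channels)
  # per-channel synergy weights, recycled if C != 5
  w_ext  <- rep_len(c(1.0, 0.9, 0.5, 0.3, 0.2), C)  # extensor-dominant
  w_post <- rep_len(c(0.3, 0.25, 0.4, 1.0, 0.8), C) # posterior-dominant
  w_odd  <- rep_len(c(1.0, 0.0, 0.9, 0.0, 0.6), C)
  w_even <- rep_len(c(0.0, 0.8, 0.0, 0.7, 0.0), C)

  ramp_hold <- pmin(tt / 0.4, 1)                    # 0.4 s rise, hold
  decay <- pmax(1 - 0.3 * tt, 0.1)                  # descent: high -> low
  burst <- function(phase) {                        # 1 Hz raised-cosine bursts
    ph <- (tt - phase) %% 1.0
    ifelse(ph < 0.5, 0.5 * (1 - cos(2 * pi * ph / 0.5)), 0)
  }
  env <- function(w, profile) outer(w, profile)
  tmpl <- function(label, em) {
    stopifnot(all(em >= 0))
    structure(list(label = label, envelope_matrix = em,
                   env_fs_hz = env_fs_hz, carrier_band_hz = carrier_band_hz),
              class = "movement_template")
  }
  list(
    standing = tmpl("standing", env(w_ext, ramp_hold)),
    sitting  = tmpl("sitting",  env(w_post, decay)),
    walking  = tmpl("walking",  env(w_odd, burst(0)) + env(w_even, burst(0.5)))
  )
}

#' Create a synthetic subject profile
#'
#' Encodes inter-subject variability: per-channel multiplicative gains
#' (log-normal around 1), a timing jitter of movement onset relative to
#' the cue, and subject-specific baseline-noise and mains-interference
#' levels. `variability = 0` yields the reference subject exactly (unit
#' gains, zero jitter, baseline noise).
#'
#' @param subject_id subject identifier string.
#' @param seed integer seed; the profile is a pure function of
#'   `(seed, variability)`.
#' @param variability nonnegative scalar; log-sd of the gain distribution
#'   and scale of the timing/noise variation.
#' @param n_channels number of sEMG channels.
#' @param base_noise_std baseline additive-noise standard deviation
#'   (signal units).
#' @param base_mains_amplitude baseline 50 Hz mains amplitude (signal
#'   units); nonzero by default so the notch stage has work to do.
#' @return object of class `subject_profile`.
#' @export
make_subject_profile <- function(subject_id, seed, variability,
                                 n_channels = 5L,
                                 base_noise_std = 0.05,
                                 base_mains_amplitude = 0.2) {
  assert_scalar_number(variability, "variability", min = 0)
  C <- as.integer(n_channels)
  with_seed(seed, {
    gains <- exp(rnorm(C, 0, variability))
    jitter <- rnorm(1, 0, 0.1 * variability)
    noise_std <- base_noise_std * exp(rnorm(1, 0, variability))
    mains <- base_mains_amplitude * exp(rnorm(1, 0, variability))
    structure(list(subject_id = as.character(subject_id),
                   channel_gains = gains, onset_jitter_s = jitter,
                   noise_std = noise_std, mains_amplitude = mains,
                   seed = as.integer(seed)),
              class = "subject_profile")
  })
}

# unit-variance Gaussian noise bandlimited to `band` (zero-phase Butterworth)
#' @noRd
bandlimited_carrier <- function(n, fs, band) {
  x <- rnorm(n)
  bf <- signal::butter(4, band * 2 / fs, type = "pass")
  y <- signal::filtfilt(bf, x)
  y / stats::sd(y)
}

#' Simulate one cued movement trial
#'
#' Generates a C x T recording following the amplitude-modulated
#' bandlimited-noise signal model: before the cue only baseline noise and
#' mains interference are present; from `cue_onset_s + onset_jitter_s`
#' the class-specific envelope modulates each channel's carrier, scaled
#' by the subject's channel gains.
#'
#' @param profile a [make_subject_profile()] object.
#' @param template a `movement_template` from [movement_templates()].
#' @param paradigm a [paradigm_spec()].
#' @param trial_seed integer seed; the trial is a pure function of
#'   profile, template, paradigm and this seed.
#' @param trial_index trial number recorded in the output metadata.
#' @return a [raw_recording()] of shape C x round(trial_duration_s * fs).
#' @export
simulate_trial <- function(profile, template, paradigm, trial_seed,
                           trial_index = 1L) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(template, "movement_template"),
            inherits(paradigm, "paradigm_spec"))
  fs <- paradigm$fs_hz
  if (fs <= 2 * max(template$carrier_band_hz))
    stopf("sampling rate %d Hz cannot represent carrier band up to %g Hz",
          fs, max(template$carrier_band_hz))
  T <- round(paradigm$trial_duration_s * fs)
  C <- nrow(template$envelope_matrix)
  if (length(profile$channel_gains) != C)
    stopf("profile has %d channel gains but template has %d channels",
          length(profile$channel_gains), C)
  t <- (seq_len(T) - 1L) / fs
  onset <- paradigm$cue_onset_s + profile$onset_jitter_s
  K <- ncol(template$envelope_matrix)
  env_t <- (seq_len(K) - 1L) / template$env_fs_hz

  with_seed(trial_seed, {
    phi <- runif(1, 0, 2 * pi)
    mains <- profile$mains_amplitude * sin(2 * pi * 50 * t + phi)
    sig <- matrix(0, C, T)
    for (c in seq_len(C)) {
      env <- stats::approx(env_t + onset, template$envelope_matrix[c, ],
                           xout = t, yleft = 0, yright = 0, rule = 1)$y
      env[is.na(env)] <- 0
      carrier <- if (any(env > 0)) bandlimited_carrier(T, fs, template$carrier_band_hz)
                 else numeric(T)
      noise <- if (profile$noise_std > 0) rnorm(T, 0, profile$noise_std) else numeric(T)
      sig[c, ] <- profile$channel_gains[c] * env * carrier + noise + mains
    }
    raw_recording(sig, fs, profile$subject_id, template$label,
                  channel_names = paste0("ch", seq_len(C)),
                  trial_index = trial_index)
  })
}

#' Simulate a full multi-subject dataset
#'
#' Each subject performs one session of `n_groups x moves_per_group`
#' trials (default 30) with balanced classes: standing and walking trials
#' are randomly interleaved over the first two thirds of the session and
#' all sitting trials come last (the subject must be standing before a
#' stand or sit trial can begin). With defaults, 10 subjects yield 300
#' recordings, 10 per class per subject.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param paradigm a [paradigm_spec()].
#' @param variability inter-subject variability passed to
#'   [make_subject_profile()].
#' @param seed master seed; all profiles, orderings and trials derive
#'   from it deterministically.
#' @param out_dir optional directory; when given, every recording is
#'   written via [write_recording()] and a `manifest.tsv` is produced.
#' @param templates movement templates; default [movement_templates()]
#'   sized to the paradigm.
#' @return list with `recordings` (list of [raw_recording()]),
#'   `manifest` (data.frame: path, subject_id, label, trial_index, fs_hz),
#'   and `profiles`.
#' @export
simulate_dataset <- function(n_subjects, paradigm = paradigm_spec(),
                             variability = 0.1, seed = 1L,
                             out_dir = NULL, templates = NULL) {
  if (n_subjects < 1L) stopf("n_subjects must be >= 1")
  if (is.null(templates))
    templates <- movement_templates(move_duration_s = paradigm$move_duration_s)
  n_trials <- paradigm$n_groups * paradigm$moves_per_group
  n_per_class <- n_trials / length(MOVEMENT_CLASSES)
  if (n_per_class != round(n_per_class))
    stopf("session length %d is not divisible by %d classes",
          n_trials, length(MOVEMENT_CLASSES))
  subj_seeds <- derive_seeds(seed, n_subjects)

  recordings <- list(); profiles <- list(); rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    prof <- make_subject_profile(sid, subj_seeds[s], variability)
    profiles[[sid]] <- prof
    streams <- derive_seeds(subj_seeds[s] + 1L, n_trials + 1L)
    # session ordering: standing/walking interleaved first, sitting last
    labels <- with_seed(streams[1L], {
      first <- sample(rep(c("standing", "walking"), n_per_class))
      c(first, rep("sitting", n_per_class))
    })
    for (k in seq_len(n_trials)) {
      rec <- simulate_trial(prof, templates[[labels[k]]], paradigm,
                            trial_seed = streams[k + 1L], trial_index = k)
      path <- sprintf("%s_trial%02d.csv", sid, k)
      recordings[[length(recordings) + 1L]] <- rec
      rows[[length(rows) + 1L]] <- data.frame(
        path = path, subject_id = sid, label = labels[k],
        trial_index = k, fs_hz = paradigm$fs_hz,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(recordings))
      write_recording(recordings[[i]], file.path(out_dir, manifest$path[i]))
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  }
  list(recordings = recordings, manifest = manifest, profiles = profiles)
}
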