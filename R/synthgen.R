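#' Standard eight-channel bipolar montage
#'
#' Bipolar derivations over frontal, central, parietal and occipital sites on
#' both hemispheres (10-20 system). Odd electrode numbers sit over the left
#' hemisphere, even numbers over the right.
#'
#' @return A tibble with columns `channel`, `region` (`F`, `C`, `P`, `O`) and
#'   `side` (`left`, `right`).
#' @export
eeg_montage <- function() {
  tibble::tibble(
    channel = c("F3-Fz", "F4-Fz", "C3-Cz", "C4-Cz",
                "P3-Pz", "P4-Pz", "O1-A2", "O2-A1"),
    region  = rep(c("F", "C", "P", "O"), each = 2),
    side    = rep(c("left", "right"), 4)
  )
}

#' Condition effect sizes for the synthetic cohort
#'
#' The knobs that make the four behavioral conditions differ. Setting
#' `alpha_closed_gain = 1`, `beta_cycling_atten = 1` and `pedal_amp = 0`
#' (see [null_effects()]) makes all four conditions draws from one process,
#' which is the null configuration used for type-I-error calibration.
#'
#' @param alpha_closed_gain Multiplier on alpha-band (8-12 Hz) amplitude when
#'   the eyes are closed. Values above 1 emulate occipital alpha
#'   synchronisation, which lowers signal complexity.
#' @param beta_cycling_atten Multiplier on beta-band (20-30 Hz) amplitude
#'   during cycling; values below 1 emulate movement-related beta suppression.
#' @param pedal_amp Amplitude (uV) of the deterministic pedaling-locked
#'   periodic component added during cycling. This is the single knob that
#'   controls the expected entropy drop under movement, so the injected
#'   effect size is tunable and recoverable.
#' @param pedal_hz Nominal pedaling cadence (Hz); the per-recording cadence is
#'   jittered by +/- 10 percent.
#' @param n_harmonics Number of harmonics of the cadence included (amplitudes
#'   decay as `1/sqrt(k)`). Harmonics at and above 3 Hz survive the 3-35 Hz
#'   cycling band-pass.
#' @return A named list of effect sizes.
#' @export
effect_sizes <- function(alpha_closed_gain = 2.5, beta_cycling_atten = 0.5,
                         pedal_amp = 6, pedal_hz = 1, n_harmonics = 8) {
  stopifnot(alpha_closed_gain >= 0, beta_cycling_atten >= 0, pedal_amp >= 0,
            pedal_hz > 0, n_harmonics >= 1)
  list(alpha_closed_gain = alpha_closed_gain,
       beta_cycling_atten = beta_cycling_atten,
       pedal_amp = pedal_amp, pedal_hz = pedal_hz, n_harmonics = n_harmonics)
}

#' @rdname effect_sizes
#' @export
null_effects <- function() {
  effect_sizes(alpha_closed_gain = 1, beta_cycling_atten = 1, pedal_amp = 0)
}

#' Specification of a synthetic EEG cohort
#'
#' Describes a cohort of subjects each recorded in the four behavioral
#' conditions (rest/cycling crossed with eyes open/closed) on the standard
#' eight-channel montage. Identical specifications (including `seed`) produce
#' bit-identical cohorts.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param fs Sampling rate in Hz.
#' @param duration Recording length per condition in seconds.
#' @param channels Montage tibble (`channel`, `region`, `side`); defaults to
#'   [eeg_montage()]. Override to generate a channel subset.
#' @param seed Integer root seed; all randomness derives from it.
#' @param effects Condition effect sizes, see [effect_sizes()].
#' @param subject_sd Standard deviation of the per-subject log-normal
#'   multiplier on the regularity (periodic-component) amplitude. The
#'   multiplier is shared by all of a subject's recordings, giving median
#'   entropy a per-subject random intercept.
#' @param artifact_rate Probability that a recording contains injected step
#'   (electrode-pop) artifacts. The default, together with subject-level
#'   exclusion, removes about a quarter of subjects in expectation.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 24, fs = 1000, duration = 120,
                        channels = eeg_montage(), seed = 1,
                        effects = effect_sizes(), subject_sd = 0.1,
                        artifact_rate = 0.07) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort_config("n_subjects must be >= 2")
  }
  if (!is.numeric(fs) || fs <= 0) abort_config("fs must be positive")
  if (!is.numeric(duration) || duration <= 0) {
    abort_config("duration must be positive")
  }
  channels <- tibble::as_tibble(channels)
  need <- c("channel", "region", "side")
  if (!all(need %in% names(channels)) || nrow(channels) < 1) {
    abort_config("channels must have columns channel, region, side")
  }
  if (!all(channels$region %in% c("F", "C", "P", "O"))) {
    abort_config("unknown region label in channels (use F, C, P, O)")
  }
  if (!all(channels$side %in% c("left", "right"))) {
    abort_config("unknown side label in channels (use left, right)")
  }
  if (!all(channels$channel %in% eeg_montage()$channel)) {
    abort_config(paste0("unknown channel label: ",
                        paste(setdiff(channels$channel, eeg_montage()$channel),
                              collapse = ", ")))
  }
  stopifnot(subject_sd >= 0, artifact_rate >= 0, artifact_rate <= 1)
  structure(
    list(n_subjects = as.integer(n_subjects), fs = fs, duration = duration,
         channels = channels, seed = as.integer(seed), effects = effects,
         subject_sd = subject_sd, artifact_rate = artifact_rate),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_subjects, " subjects x 4 conditions, ",
      nrow(x$channels), " channels, ", x$duration, " s @ ", x$fs, " Hz, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# ---- signal components ------------------------------------------------------

# 1/f^gamma-shaped Gaussian noise via spectral shaping, unit variance
pink_noise <- function(n, gamma = 1) {
  w <- stats::rnorm(n)
  f <- pmin(0:(n - 1), n - (0:(n - 1)))           # two-sided bin index
  scale <- ifelse(f < 1, 0, f^(-gamma / 2))       # zero out DC
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Gaussian noise restricted to [lo, hi] Hz via FFT masking, unit variance
band_noise <- function(n, fs, lo, hi) {
  w <- stats::rnorm(n)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  mask <- as.numeric(f >= lo & f <= hi)
  x <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x / s
}

# baseline component amplitudes (uV); occipital-dominant alpha
.alpha_base <- c(F = 2, C = 3, P = 5, O = 8)
.beta_base <- 3
.broadband_sd <- 10

# deterministic pedaling-locked component (cadence fundamental + harmonics)
pedal_component <- function(n, fs, amp, cadence, n_harmonics, phases) {
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  w <- (seq_len(n_harmonics))^(-0.5)
  w <- w / sqrt(sum(w^2) / 2)                     # unit-RMS mixture
  for (k in seq_len(n_harmonics)) {
    x <- x + w[k] * sin(2 * pi * k * cadence * t + phases[k])
  }
  amp * x
}

# per-subject log-normal regularity multiplier, shared across conditions
subject_multiplier <- function(spec, subject_id) {
  withr::with_seed(
    derive_seed(spec$seed, subject_id, "regularity"),
    exp(stats::rnorm(1, 0, spec$subject_sd))
  )
}

#' Generate one synthetic EEG recording
#'
#' Builds the channel signals for one (subject, state, eyes) condition as a
#' sum of 1/f background noise, an occipital-dominant alpha (8-12 Hz)
#' component amplified with eyes closed, a beta (20-30 Hz) component
#' attenuated during cycling, and -- during cycling -- a deterministic
#' pedaling-locked periodic component that raises signal regularity. The
#' random substream is derived from `(seed, subject_id, state, eyes)`, so the
#' same arguments always return identical samples.
#'
#' @param spec A [cohort_spec()].
#' @param subject_id Subject identifier (character or integer).
#' @param state `"rest"` or `"cycling"`.
#' @param eyes `"open"` or `"closed"`.
#' @return A tibble with one row per channel and columns `subject`, `state`,
#'   `eyes`, `channel`, `region`, `side`, `fs` and the list-column `signal`
#'   (microvolts).
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 2, duration = 2)
#' rec <- generate_recording(spec, "S01", "rest", "closed")
#' rec
generate_recording <- function(spec, subject_id, state, eyes) {
  stopifnot(inherits(spec, "cohort_spec"))
  state <- match.arg(state, c("rest", "cycling"))
  eyes <- match.arg(eyes, c("open", "closed"))
  n <- round(spec$fs * spec$duration)
  ef <- spec$effects
  s_mult <- subject_multiplier(spec, subject_id)
  alpha_gain <- if (eyes == "closed") ef$alpha_closed_gain else 1
  beta_gain <- if (state == "cycling") ef$beta_cycling_atten else 1

  signals <- withr::with_seed(
    derive_seed(spec$seed, subject_id, state, eyes),
    {
      cadence <- ef$pedal_hz * stats::runif(1, 0.9, 1.1)
      phases <- stats::runif(ef$n_harmonics, 0, 2 * pi)
      lapply(seq_len(nrow(spec$channels)), function(i) {
        region <- spec$channels$region[i]
        bb <- .broadband_sd * pink_noise(n)
        a_amp <- .alpha_base[[region]] * alpha_gain * s_mult
        tone_f <- stats::runif(1, 9, 11)
        tone_ph <- stats::runif(1, 0, 2 * pi)
        alpha <- a_amp * (0.6 * band_noise(n, spec$fs, 8, 12) +
                          0.4 * sqrt(2) *
                            sin(2 * pi * tone_f * (seq_len(n) - 1) / spec$fs +
                                tone_ph))
        beta <- .beta_base * beta_gain * band_noise(n, spec$fs, 20, 30)
        x <- bb + alpha + beta
        if (state == "cycling" && ef$pedal_amp > 0) {
          x <- x + pedal_component(n, spec$fs, ef$pedal_amp * s_mult,
                                   cadence, ef$n_harmonics, phases)
        }
        x
      })
    }
  )
  out <- spec$channels
  out$subject <- as.character(subject_id)
  out$state <- state
  out$eyes <- eyes
  out$fs <- spec$fs
  out$signal <- signals
  dplyr::select(out, "subject", "state", "eyes", "channel", "region", "side",
                "fs", "signal")
}

# inject step (electrode-pop) artifacts into one recording's signals
inject_steps <- function(signals, spec, subject_id, state, eyes) {
  withr::with_seed(
    derive_seed(spec$seed, subject_id, state, eyes, "artifact"),
    {
      n_ch <- length(signals)
      ch <- sample.int(n_ch, 1)
      x <- signals[[ch]]
      n_steps <- sample(1:3, 1)
      pos <- sort(sample(seq(floor(0.1 * length(x)), floor(0.9 * length(x))),
                         n_steps))
      amp <- 30 * stats::sd(x)
      for (p in pos) {
        x[(p + 1):length(x)] <- x[(p + 1):length(x)] +
          amp * sample(c(-1, 1), 1)
      }
      signals[[ch]] <- x
      signals
    }
  )
}

#' Generate a full synthetic cohort
#'
#' Produces `n_subjects` x 4 condition-recordings on the montage in
#' `spec$channels`, plus a manifest of recordings with artifact flags. Step
#' artifacts (amplitude far above the signal's standard deviation, as from a
#' failing electrode contact) are injected into a random subset of recordings
#' at rate `spec$artifact_rate`.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `eeg_cohort`: a list with elements
#'   \describe{
#'     \item{signals}{tibble, one row per (subject, state, eyes, channel),
#'       with list-column `signal`}
#'     \item{manifest}{tibble, one row per recording: `subject`, `state`,
#'       `eyes`, `artifact`}
#'     \item{spec}{the generating specification}
#'   }
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 2, duration = 1))
#' coh$manifest
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  manifest <- tidyr::expand_grid(
    subject = subjects,
    state = c("rest", "cycling"),
    eyes = c("open", "closed")
  )
  manifest$artifact <- withr::with_seed(
    derive_seed(spec$seed, "artifact-flags"),
    stats::runif(nrow(manifest)) < spec$artifact_rate
  )
  signals <- purrr::pmap(manifest, function(subject, state, eyes, artifact) {
    rec <- generate_recording(spec, subject, state, eyes)
    if (artifact) {
      rec$signal <- inject_steps(rec$signal, spec, subject, state, eyes)
    }
    rec
  })
  structure(
    list(signals = dplyr::bind_rows(signals), manifest = manifest,
         spec = spec),
    class = "eeg_cohort"
  )
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat("<eeg_cohort> ", length(unique(x$manifest$subject)), " subjects, ",
      nrow(x$manifest), " recordings, ",
      nrow(x$signals) / nrow(x$manifest), " channels each, ",
      sum(x$manifest$artifact), " artifact-flagged\n", sep = "")
  invisible(x)
}
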