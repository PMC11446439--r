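#' Filter specification
#'
#' A Butterworth band-pass or band-stop filter. The default realization is a
#' 4th-order design applied forward-backward (zero phase), standard practice
#' for offline EEG conditioning.
#'
#' @param kind `"bandpass"` or `"bandstop"`.
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @param order Filter order (per pass).
#' @param zero_phase Apply forward-backward (`filtfilt`) so the filter has no
#'   group delay; `FALSE` uses a single causal pass.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "bandstop"), low_hz, high_hz,
                        order = 4, zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz) {
    abort_config("need 0 < low_hz < high_hz")
  }
  stopifnot(order >= 1)
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s %g-%g Hz, order %d%s\n", x$kind, x$low_hz,
              x$high_hz, x$order, if (x$zero_phase) ", zero-phase" else ""))
  invisible(x)
}

#' The default conditioning chain
#'
#' Acquisition band-pass 1-100 Hz, mains band-stop 59-61 Hz, and a 3-35 Hz
#' band-pass reserved for cycling recordings.
#'
#' @return Named list of [filter_spec()] objects
#'   (`acquisition`, `mains`, `cycling`).
#' @export
default_filters <- function() {
  list(acquisition = filter_spec("bandpass", 1, 100),
       mains = filter_spec("bandstop", 59, 61),
       cycling = filter_spec("bandpass", 3, 35))
}

#' Apply a filter to a signal
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param filt A [filter_spec()].
#' @return Filtered signal of identical length.
#' @export
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 60 * seq(0, 2, by = 1 / fs))
#' y <- apply_filter(x, fs, filter_spec("bandstop", 59, 61))
#' sqrt(mean(y^2)) # mains tone almost entirely removed
apply_filter <- function(x, fs, filt) {
  stopifnot(inherits(filt, "filter_spec"))
  assert_signal(x)
  if (filt$high_hz >= fs / 2) {
    abort_config(sprintf("filter cutoff %g Hz is at or above Nyquist (%g Hz)",
                         filt$high_hz, fs / 2))
  }
  settle <- 3 * (2 * filt$order + 1)
  if (length(x) <= 3 * settle) {
    abort_config(sprintf(
      "signal too short to filter (%d samples; need > %d for settling)",
      length(x), 3 * settle))
  }
  w <- c(filt$low_hz, filt$high_hz) / (fs / 2)
  bu <- signal::butter(filt$order,
                       w,
                       type = if (filt$kind == "bandpass") "pass" else "stop")
  if (filt$zero_phase) {
    as.numeric(signal::filtfilt(bu, x))
  } else {
    as.numeric(signal::filter(bu, x))
  }
}

#' Condition one channel signal according to its behavioral state
#'
#' Applies, in order: the 1-100 Hz acquisition band-pass, the 59-61 Hz mains
#' band-stop, and -- if the recording was made during cycling (or
#' `apply_335_to_all` is set) -- the 3-35 Hz band-pass. The names of the
#' applied filters are attached as attribute `"filters"`.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param state `"rest"` or `"cycling"`.
#' @param apply_335_to_all Apply the 3-35 Hz band-pass to every state,
#'   for symmetric-preprocessing sensitivity analyses.
#' @param filters Filter chain as produced by [default_filters()].
#' @return Filtered vector with attribute `"filters"` (character).
#' @export
condition_signal <- function(x, fs, state, apply_335_to_all = FALSE,
                             filters = default_filters()) {
  state <- match.arg(state, c("rest", "cycling"))
  y <- apply_filter(x, fs, filters$acquisition)
  y <- apply_filter(y, fs, filters$mains)
  applied <- c("acquisition", "mains")
  if (state == "cycling" || isTRUE(apply_335_to_all)) {
    y <- apply_filter(y, fs, filters$cycling)
    applied <- c(applied, "cycling")
  }
  attr(y, "filters") <- applied
  y
}

#' Condition every recording of a cohort
#'
#' @param cohort An `eeg_cohort` (see [generate_cohort()]) or its `signals`
#'   tibble.
#' @inheritParams condition_signal
#' @return The same structure with filtered signals and an added
#'   `n_filters` column counting the filters applied to each channel.
#' @export
condition_recordings <- function(cohort, apply_335_to_all = FALSE,
                                 filters = default_filters()) {
  tbl <- if (inherits(cohort, "eeg_cohort")) cohort$signals else cohort
  out <- tbl
  res <- purrr::pmap(list(tbl$signal, tbl$state, tbl$fs), function(x, st, fs) {
    y <- condition_signal(x, fs, st, apply_335_to_all, filters)
    list(y = as.numeric(y), k = length(attr(y, "filters")))
  })
  out$signal <- purrr::map(res, "y")
  out$n_filters <- purrr::map_int(res, "k")
  if (inherits(cohort, "eeg_cohort")) {
    cohort$signals <- out
    cohort
  } else {
    out
  }
}

#' Detect step ("erratic jump") artifacts in a channel
#'
#' Flags samples whose absolute first difference exceeds `z_thresh` robust
#' standard deviations (median-absolute-deviation scaled) of the channel's
#' first differences -- the signature of a step discontinuity from poor
#' skin-electrode contact. Screening is meant to run on raw signals, before
#' filtering smears steps into pulses.
#'
#' @param x Numeric sample vector.
#' @param window Minimum separation (samples) between distinct flagged
#'   events; flags closer than this are merged onto the largest jump.
#' @param z_thresh Robust z-score threshold on first differences.
#' @return Integer vector of flagged sample indices (positions `i` such that
#'   the jump occurs between samples `i` and `i + 1`); empty when clean.
#' @export
detect_jump_artifacts <- function(x, window = 100, z_thresh = 8) {
  assert_signal(x)
  if (window < 2) abort_config("window must be >= 2")
  d <- diff(x)
  s <- stats::mad(d)
  if (s == 0) {
    message("constant or quantised signal (MAD of differences is 0); ",
            "no artifact screening possible")
    return(integer(0))
  }
  idx <- which(abs(d) > z_thresh * s)
  if (length(idx) < 2) return(idx)
  # merge flags within `window` samples onto the largest jump of the cluster
  grp <- cumsum(c(1, diff(idx) > window))
  as.integer(vapply(split(idx, grp), function(ii) {
    ii[which.max(abs(d[ii]))]
  }, numeric(1)))
}

#' Screen a cohort for artifacts and apply the exclusion rule
#'
#' Mirrors the study design: a subject is excluded whenever any channel of
#' any of their recordings shows step artifacts (`level = "subject"`), or
#' only the offending recordings are dropped (`level = "recording"`).
#'
#' @param cohort An `eeg_cohort`.
#' @inheritParams detect_jump_artifacts
#' @param level `"subject"` (default) or `"recording"`.
#' @return The cohort with flagged rows removed; the exclusion table (one row
#'   per flagged recording-channel) is attached as attribute `"excluded"` and
#'   the manifest gains a `flagged` column.
#' @export
screen_artifacts <- function(cohort, z_thresh = 8, window = 100,
                             level = c("subject", "recording")) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  level <- match.arg(level)
  tbl <- cohort$signals
  nflag <- purrr::map_int(tbl$signal, function(x) {
    length(detect_jump_artifacts(x, window = window, z_thresh = z_thresh))
  })
  excluded <- dplyr::filter(
    dplyr::select(dplyr::mutate(tbl, n_jumps = nflag), -"signal"),
    .data$n_jumps > 0
  )
  flagged_rec <- dplyr::distinct(excluded, .data$subject, .data$state,
                                 .data$eyes)
  cohort$manifest$flagged <- purrr::pmap_lgl(
    cohort$manifest[c("subject", "state", "eyes")],
    function(subject, state, eyes) {
      any(flagged_rec$subject == subject & flagged_rec$state == state &
            flagged_rec$eyes == eyes)
    })
  keep <- if (level == "subject") {
    !(tbl$subject %in% excluded$subject)
  } else {
    !(paste(tbl$subject, tbl$state, tbl$eyes) %in%
        paste(flagged_rec$subject, flagged_rec$state, flagged_rec$eyes))
  }
  cohort$signals <- tbl[keep, ]
  attr(cohort, "excluded") <- excluded
  cohort
}

#' Split a signal into equal contiguous segments
#'
#' Cuts the signal into `n_pieces` contiguous, non-overlapping segments of
#' length `floor(length(x) / n_pieces)`; any remainder at the end is
#' discarded.
#'
#' @param x Numeric sample vector.
#' @param n_pieces Number of segments.
#' @return A tibble with columns `index` (0-based) and list-column `samples`;
#'   the number of discarded trailing samples is attached as attribute
#'   `"discarded"`.
#' @export
#' @examples
#' seg <- segment_signal(rnorm(1005), n_pieces = 100)
#' nrow(seg)                  # 100
#' attr(seg, "discarded")     # 5
segment_signal <- function(x, n_pieces = 100) {
  assert_signal(x)
  n_pieces <- as.integer(n_pieces)
  if (n_pieces < 1) abort_config("n_pieces must be >= 1")
  if (length(x) < n_pieces) {
    abort_config(sprintf("signal (%d samples) shorter than n_pieces (%d)",
                         length(x), n_pieces))
  }
  seg_len <- length(x) %/% n_pieces
  used <- seg_len * n_pieces
  out <- tibble::tibble(
    index = 0:(n_pieces - 1),
    samples = lapply(0:(n_pieces - 1), function(i) {
      x[(i * seg_len + 1):((i + 1) * seg_len)]
    })
  )
  attr(out, "discarded") <- length(x) - used
  out
}
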