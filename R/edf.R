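# Minimal EDF (European Data Format) writer/reader for continuous
# multichannel recordings: 16-bit samples, one-second data records, one file
# per recording. Covers exactly what the pipeline needs for interchange; it
# is not a general EDF+ implementation (no annotations, no discontinuous
# records).

.edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

.edf_num <- function(v, width = 8) {
  for (digits in 6:1) {
    s <- sprintf("%.*g", digits, v)
    if (nchar(s) <= width) return(.edf_pad(s, width))
  }
  .edf_pad(sprintf("%.0e", v), width)
}

#' Write one recording to an EDF file
#'
#' Signals are scaled per channel to the 16-bit digital range; the physical
#' range is symmetric around zero. The start date/time fields are fixed
#' placeholders so identical recordings yield byte-identical files.
#'
#' @param rec A tibble with one row per channel (columns `subject`, `state`,
#'   `eyes`, `channel`, `fs`, list-column `signal`), e.g. one recording of an
#'   `eeg_cohort`'s `signals` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(is.data.frame(rec), nrow(rec) >= 1,
            all(c("channel", "fs", "signal") %in% names(rec)))
  fs <- rec$fs[1]
  if (fs != round(fs)) abort_config("write_edf needs an integer sampling rate")
  ns <- nrow(rec)
  len <- unique(lengths(rec$signal))
  if (length(len) != 1) abort_config("all channels must have equal length")
  n_rec <- len %/% fs
  if (n_rec < 1) abort_config("recording shorter than one data record (1 s)")
  if (n_rec * fs != len) {
    warning(sprintf("discarding %d trailing samples (partial EDF record)",
                    len - n_rec * fs), call. = FALSE)
  }
  pmaxs <- vapply(rec$signal, function(x) max(abs(x), 1e-6), numeric(1))
  pmaxs <- signif(pmaxs * 1.001, 6)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  subj <- if ("subject" %in% names(rec)) rec$subject[1] else "X"
  meta <- if (all(c("state", "eyes") %in% names(rec))) {
    paste0("state=", rec$state[1], " eyes=", rec$eyes[1])
  } else {
    ""
  }
  wr(.edf_pad("0", 8))
  wr(.edf_pad(subj, 80))
  wr(.edf_pad(meta, 80))
  wr(.edf_pad("01.01.20", 8))
  wr(.edf_pad("00.00.00", 8))
  wr(.edf_pad(sprintf("%d", 256 * (1 + ns)), 8))
  wr(.edf_pad("", 44))
  wr(.edf_pad(sprintf("%d", n_rec), 8))
  wr(.edf_pad("1", 8))
  wr(.edf_pad(sprintf("%d", ns), 4))
  for (lab in rec$channel) wr(.edf_pad(lab, 16))
  for (i in seq_len(ns)) wr(.edf_pad("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wr(.edf_pad("uV", 8))
  for (p in pmaxs) wr(.edf_num(-p))
  for (p in pmaxs) wr(.edf_num(p))
  for (i in seq_len(ns)) wr(.edf_pad("-32768", 8))
  for (i in seq_len(ns)) wr(.edf_pad("32767", 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_pad(sprintf("%d", fs), 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 32))

  dig <- lapply(seq_len(ns), function(i) {
    x <- rec$signal[[i]][seq_len(n_rec * fs)]
    p <- as.numeric(.edf_num(pmaxs[i]))  # round-trip through the header text
    as.integer(pmin(pmax(round(x / p * 32767.5 - 0.5), -32768), 32767))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      writeBin(dig[[i]][((r - 1) * fs + 1):(r * fs)], con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any simple continuous EDF)
#'
#' @param path File path.
#' @return A list: `labels`, `fs` (per signal), `signals` (list of numeric
#'   vectors in physical units), `patient`, `recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(n) as.numeric(trimws(rd(n)))
  rd(8)
  patient <- trimws(rd(80))
  recording <- trimws(rd(80))
  rd(16)
  num(8)
  rd(44)
  n_rec <- num(8)
  rec_dur <- num(8)
  ns <- as.integer(num(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  for (i in seq_len(ns)) rd(32)
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little")
  if (length(raw) < n_rec * sum(spr)) {
    stop("truncated EDF file: ", path, call. = FALSE)
  }
  signals <- vector("list", ns)
  for (i in seq_len(ns)) signals[[i]] <- numeric(n_rec * spr[i])
  off <- 0
  pos <- integer(ns)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- raw[(off + 1):(off + spr[i])]
      signals[[i]][(pos[i] + 1):(pos[i] + spr[i])] <-
        (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
      off <- off + spr[i]
      pos[i] <- pos[i] + spr[i]
    }
  }
  list(labels = labels, fs = spr / rec_dur, signals = signals,
       patient = patient, recording = recording)
}

#' Export a cohort as EDF files plus a manifest CSV
#'
#' Writes one EDF file per (subject, state, eyes) and a `manifest.csv`
#' mapping each file to its condition and artifact flag.
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with a `file` column), invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$file <- sprintf("%s_%s_%s.edf", man$subject, man$state, man$eyes)
  for (i in seq_len(nrow(man))) {
    rec <- dplyr::filter(cohort$signals, .data$subject == man$subject[i],
                         .data$state == man$state[i],
                         .data$eyes == man$eyes[i])
    write_edf(rec, file.path(dir, man$file[i]))
  }
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  invisible(man)
}

#' Ingest a directory of EDF recordings
#'
#' Validates each manifest entry (file present, expected channel labels,
#' uniform sampling rate, equal duration) and assembles an `eeg_cohort`.
#' Files that fail validation are excluded with a per-file reason and the
#' run continues.
#'
#' @param dir Directory containing the EDF files.
#' @param manifest Manifest data frame or path to a manifest CSV with
#'   columns `subject`, `state`, `eyes`, `file` (and optionally `artifact`).
#' @param channels Expected montage (defaults to [eeg_montage()]).
#' @return An `eeg_cohort`; rejected files are recorded in the attribute
#'   `"ingest_errors"` (tibble `file`, `reason`).
#' @export
ingest_edf <- function(dir, manifest, channels = eeg_montage()) {
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  stopifnot(all(c("subject", "state", "eyes", "file") %in% names(manifest)))
  errors <- list()
  rows <- list()
  kept <- logical(nrow(manifest))
  fs_seen <- NULL
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    reason <- NULL
    if (!file.exists(f)) {
      reason <- "file missing"
    } else {
      e <- tryCatch(read_edf(f), error = function(err) conditionMessage(err))
      if (is.character(e)) {
        reason <- e
      } else if (!setequal(e$labels, channels$channel) ||
                 length(e$labels) != nrow(channels)) {
        miss <- setdiff(channels$channel, e$labels)
        reason <- if (length(miss)) {
          paste("missing channel:", paste(miss, collapse = ", "))
        } else {
          "unexpected channel labels"
        }
      } else if (length(unique(e$fs)) != 1) {
        reason <- "mixed sampling rates within file"
      } else {
        if (is.null(fs_seen)) fs_seen <- e$fs[1]
        if (e$fs[1] != fs_seen) reason <- "sampling rate differs from cohort"
      }
    }
    if (!is.null(reason)) {
      errors[[length(errors) + 1]] <-
        tibble::tibble(file = manifest$file[i], reason = reason)
      next
    }
    ord <- match(channels$channel, e$labels)
    rows[[length(rows) + 1]] <- tibble::tibble(
      subject = manifest$subject[i], state = manifest$state[i],
      eyes = manifest$eyes[i], channel = channels$channel,
      region = channels$region, side = channels$side, fs = e$fs[1],
      signal = e$signals[ord]
    )
    kept[i] <- TRUE
  }
  errors <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(file = character(), reason = character())
  if (nrow(errors) > 0) {
    message("ingest_edf: excluded ", nrow(errors), " file(s): ",
            paste(errors$file, errors$reason, sep = " (", collapse = "), "),
            ")")
  }
  man <- manifest[kept, c("subject", "state", "eyes")]
  man$artifact <- if ("artifact" %in% names(manifest)) {
    as.logical(manifest$artifact[kept])
  } else {
    FALSE
  }
  out <- structure(
    list(signals = dplyr::bind_rows(rows), manifest = man, spec = NULL),
    class = "eeg_cohort"
  )
  attr(out, "ingest_errors") <- errors
  out
}
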