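#' Configuration of the recurrence-microstate entropy estimator
#'
#' The estimator samples `K` random pairs of length-`N` windows from a
#' segment, encodes each pair's N-by-N block of the (never materialised)
#' recurrence matrix as a binary microstate, and takes the Shannon entropy of
#' the microstate distribution, maximised over a grid of recurrence
#' thresholds. The threshold grid is expressed in quantiles of the segment's
#' pairwise-distance distribution, which makes the statistic invariant to
#' affine amplitude rescaling and hence comparable across subjects and
#' channels.
#'
#' @param N Microstate block edge length; blocks are N x N, so there are at
#'   most `2^(N^2)` distinct microstates (N <= 4).
#' @param K Number of sampled anchor pairs per segment.
#' @param n_eps Number of candidate thresholds.
#' @param q_range Quantile range of the pairwise-distance distribution
#'   spanned by the threshold grid (end points excluded from 0 and 1).
#' @param eps_grid Optional explicit ascending grid of thresholds in signal
#'   units, overriding the quantile rule.
#' @param n_dist_pairs Size of the random subsample of pairwise distances
#'   used to estimate the quantile grid.
#' @param seed Integer seed for microstate sampling. Each segment of each
#'   recording gets its own substream derived from this seed, so results are
#'   reproducible and independent of evaluation order.
#' @return An object of class `entropy_config`.
#' @export
entropy_config <- function(N = 4, K = 10000, n_eps = 20,
                           q_range = c(0.05, 0.95), eps_grid = NULL,
                           n_dist_pairs = 2000, seed = 1) {
  stopifnot(N >= 1, N <= 4, K >= 1, n_eps >= 1, n_dist_pairs >= 2)
  stopifnot(length(q_range) == 2, q_range[1] > 0, q_range[2] < 1,
            q_range[1] <= q_range[2])
  if (!is.null(eps_grid)) {
    if (any(eps_grid <= 0) || is.unsorted(eps_grid)) {
      abort_config("eps_grid must be ascending and strictly positive")
    }
  }
  structure(list(N = as.integer(N), K = as.integer(K),
                 n_eps = as.integer(n_eps), q_range = q_range,
                 eps_grid = eps_grid, n_dist_pairs = as.integer(n_dist_pairs),
                 seed = as.integer(seed)),
            class = "entropy_config")
}

#' Recurrence matrix of a time series
#'
#' `R[i, j] = 1` when `|x[i] - x[j]| <= eps` (embedding dimension 1). Mostly
#' useful for inspection and for small oracle computations; the entropy
#' estimator itself never builds this matrix.
#'
#' @param x Numeric sample vector.
#' @param eps Recurrence threshold (>= 0), in signal units.
#' @return A symmetric 0/1 integer matrix with unit diagonal.
#' @export
#' @examples
#' recurrence_matrix(c(0, 0.5, 10), eps = 1)
recurrence_matrix <- function(x, eps) {
  assert_signal(x)
  if (eps < 0) abort_config("eps must be >= 0")
  m <- outer(x, x, function(a, b) as.integer(abs(a - b) <= eps))
  dimnames(m) <- NULL
  m
}

#' Sampled microstate distribution of a segment
#'
#' Draws `K` independent uniform anchor pairs `(i, j)` and encodes, for each,
#' the N x N recurrence block starting at `(i, j)` as an integer (row-major,
#' bit set where the pair of samples recurs). Frequencies sum to one.
#'
#' @inheritParams recurrence_matrix
#' @param N Microstate edge length.
#' @param K Number of sampled anchors (ignored when `exhaustive`).
#' @param seed Integer seed for the sampling stream.
#' @param exhaustive Enumerate all `(len(x) - N + 1)^2` anchors instead of
#'   sampling; exact, and feasible for segments up to a few thousand samples.
#' @return A tibble with columns `code` (integer microstate code in
#'   `[0, 2^(N^2) - 1]`) and `prob`, sorted by code.
#' @export
microstate_distribution <- function(x, eps, N = 4, K = 10000, seed = 1,
                                    exhaustive = FALSE) {
  assert_signal(x)
  if (length(x) < N) abort_config("need length(x) >= N")
  if (eps < 0) abort_config("eps must be >= 0")
  r <- cpp_microstate_counts(x, eps, as.integer(N), as.integer(K),
                             as.double(seed), isTRUE(exhaustive))
  out <- tibble::tibble(code = as.integer(r$code), prob = r$prob)
  dplyr::arrange(out, .data$code)
}

#' Shannon entropy of a probability distribution
#'
#' `S = -sum(p * log(p))` in nats, with the convention `0 * log(0) = 0`.
#'
#' @param p Numeric vector of probabilities (non-negative, summing to 1
#'   within 1e-9), or a data frame with a `prob` column such as the output of
#'   [microstate_distribution()].
#' @return Entropy in nats.
#' @export
#' @examples
#' shannon_entropy(c(0.5, 0.5)) # log(2)
shannon_entropy <- function(p) {
  if (is.data.frame(p)) p <- p$prob
  if (!is.numeric(p) || length(p) == 0) abort_config("p must be numeric")
  if (any(p < 0)) abort_config("negative probability")
  if (abs(sum(p) - 1) > 1e-9) abort_config("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Maximum recurrence-microstate entropy of one segment
#'
#' Evaluates the sampled microstate entropy over the realized threshold grid
#' and returns the maximum; ties break toward the smaller threshold. A
#' constant segment (all pairwise distances zero) returns `S_max = 0` at
#' `eps = 0`.
#'
#' @param x Numeric sample vector (one segment).
#' @param cfg An [entropy_config()].
#' @param seed Optional integer seed overriding `cfg$seed` (used internally
#'   to give each segment its own substream).
#' @return A list with `S_max` (nats), `eps_star`, and the profile tibble
#'   `profile` (`eps`, `S`).
#' @export
max_entropy <- function(x, cfg = entropy_config(), seed = NULL) {
  stopifnot(inherits(cfg, "entropy_config"))
  assert_signal(x)
  if (length(x) < cfg$N) abort_config("segment shorter than N")
  seed <- seed %||% cfg$seed
  if (is.null(cfg$eps_grid)) {
    r <- cpp_segment_max_entropy(x, cfg$N, cfg$K, cfg$n_eps, cfg$q_range[1],
                                 cfg$q_range[2], cfg$n_dist_pairs,
                                 as.double(seed))
    if (isTRUE(r$constant)) {
      message("constant segment: S_max = 0 at eps = 0")
    }
    list(S_max = r$S_max, eps_star = r$eps_star,
         profile = tibble::tibble(eps = r$eps_grid, S = r$S))
  } else {
    S <- cpp_entropy_over_grid(x, cfg$N, cfg$K, cfg$eps_grid,
                               as.double(seed))
    best <- which.max(S) # which.max keeps the first (smallest eps) on ties
    list(S_max = S[best], eps_star = cfg$eps_grid[best],
         profile = tibble::tibble(eps = cfg$eps_grid, S = S))
  }
}

#' Median entropy of a conditioned channel recording
#'
#' Splits the channel signal into `n_pieces` equal segments, computes the
#' maximum microstate entropy of each, and summarises the recording by the
#' median over segments (the response variable of the downstream models).
#'
#' @param x Conditioned channel signal.
#' @param cfg An [entropy_config()].
#' @param n_pieces Number of segments.
#' @param id Recording identifier mixed into the per-segment seeds, so that
#'   every recording of a cohort has an independent, reproducible sampling
#'   stream.
#' @return An object of class `rme_entropy`: list with `median_S`,
#'   `eps_median`, `n_segments`, `seg_len` and the per-segment tibble
#'   `segments` (`index`, `S`, `eps_star`).
#' @export
median_entropy <- function(x, cfg = entropy_config(), n_pieces = 100,
                           id = "") {
  stopifnot(inherits(cfg, "entropy_config"))
  assert_signal(x)
  n_pieces <- as.integer(n_pieces)
  if (length(x) %/% n_pieces < cfg$N) {
    abort_config("segments would be shorter than the microstate size N")
  }
  base <- derive_seed(cfg$seed, id)
  seeds <- segment_seeds(base, n_pieces)
  if (is.null(cfg$eps_grid)) {
    r <- cpp_channel_entropy(x, n_pieces, cfg$N, cfg$K, cfg$n_eps,
                             cfg$q_range[1], cfg$q_range[2],
                             cfg$n_dist_pairs, as.double(seeds))
    segs <- tibble::tibble(index = 0:(n_pieces - 1), S = r$S_max,
                           eps_star = r$eps_star)
    seg_len <- r$seg_len
  } else {
    seg_len <- length(x) %/% n_pieces
    res <- lapply(seq_len(n_pieces), function(i) {
      seg <- x[((i - 1) * seg_len + 1):(i * seg_len)]
      S <- cpp_entropy_over_grid(seg, cfg$N, cfg$K, cfg$eps_grid,
                                 as.double(seeds[i]))
      best <- which.max(S)
      c(S[best], cfg$eps_grid[best])
    })
    segs <- tibble::tibble(index = 0:(n_pieces - 1),
                           S = vapply(res, `[`, numeric(1), 1),
                           eps_star = vapply(res, `[`, numeric(1), 2))
  }
  structure(list(median_S = stats::median(segs$S),
                 eps_median = stats::median(segs$eps_star),
                 n_segments = n_pieces, seg_len = as.integer(seg_len),
                 segments = segs),
            class = "rme_entropy")
}

#' @export
print.rme_entropy <- function(x, ...) {
  cat(sprintf("<rme_entropy> median S = %.4f nats over %d segments of %d samples (median eps %.3g)\n",
              x$median_S, x$n_segments, x$seg_len, x$eps_median))
  invisible(x)
}

#' Entropy table for a whole cohort
#'
#' Computes [median_entropy()] for every channel of every (conditioned)
#' recording and returns the long-format table consumed by the statistical
#' models.
#'
#' @param cohort An `eeg_cohort` (ideally after [condition_recordings()]) or
#'   its `signals` tibble.
#' @param cfg An [entropy_config()].
#' @param n_pieces Number of segments per recording.
#' @return A tibble of class `entropy_tbl` with one row per (subject, region,
#'   side, state, eyes): `median_entropy` (nats), `n_segments`, `eps_median`.
#' @export
entropy_table <- function(cohort, cfg = entropy_config(), n_pieces = 100) {
  tbl <- if (inherits(cohort, "eeg_cohort")) cohort$signals else cohort
  res <- purrr::pmap(
    list(tbl$signal, tbl$subject, tbl$state, tbl$eyes, tbl$channel),
    function(x, subject, state, eyes, channel) {
      me <- median_entropy(x, cfg, n_pieces,
                           id = paste(subject, state, eyes, channel,
                                      sep = "|"))
      c(me$median_S, me$eps_median)
    })
  out <- tibble::tibble(
    subject = tbl$subject, region = tbl$region, side = tbl$side,
    state = tbl$state, eyes = tbl$eyes,
    median_entropy = vapply(res, `[`, numeric(1), 1),
    n_segments = as.integer(n_pieces),
    eps_median = vapply(res, `[`, numeric(1), 2)
  )
  class(out) <- c("entropy_tbl", class(out))
  out
}
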