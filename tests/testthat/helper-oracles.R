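# Independent oracles used across the suite. These deliberately avoid the
# package's C++ code paths: the microstate oracle enumerates every anchor via
# plain matrix algebra on the full recurrence matrix, and the paired-t oracle
# is the textbook within-subject t on subject cell means.

oracle_microstates <- function(x, eps, N) {
  R <- outer(x, x, function(a, b) as.numeric(abs(a - b) <= eps))
  M <- length(x) - N + 1
  code <- matrix(0, M, M)
  for (a in 0:(N - 1)) {
    for (b in 0:(N - 1)) {
      code <- code + R[(1:M) + a, (1:M) + b, drop = FALSE] * 2^(a * N + b)
    }
  }
  tab <- table(code)
  data.frame(code = as.integer(names(tab)),
             prob = as.numeric(tab) / (M * M))
}

oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# paired t on per-subject differences d_i = y_i(level2) - y_i(level1)
oracle_paired_t <- function(d) {
  mean(d) / (sd(d) / sqrt(length(d)))
}

# Welch-style band power: mean periodogram power in [lo, hi] Hz over
# half-overlapping segments
band_power <- function(x, fs, lo, hi, seg = 2048) {
  starts <- seq(1, length(x) - seg + 1, by = seg %/% 2)
  pw <- vapply(starts, function(s) {
    y <- x[s:(s + seg - 1)] * 0.5 * (1 - cos(2 * pi * seq_len(seg) / seg))
    sp <- Mod(fft(y))^2
    f <- (seq_len(seg) - 1) * fs / seg
    sum(sp[f >= lo & f <= hi])
  }, numeric(1))
  mean(pw)
}

# dominant frequency of the periodogram within [lo, hi] Hz
peak_frequency <- function(x, fs, lo = 2, hi = 45) {
  n <- length(x)
  sp <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= lo & f <= hi
  # light smoothing so a single noisy bin cannot win
  p <- stats::filter(sp[keep], rep(1 / 11, 11), sides = 2)
  f[keep][which.max(replace(p, is.na(p), 0))]
}

# small balanced entropy-like table for the stats tests
make_entropy_table <- function(n = 10, seed = 1, sd_subject = 0.3,
                               sd_noise = 0.15, state_effect = 0,
                               eyes_effect = 0, interaction = 0,
                               region = "O", side = "right") {
  withr::with_seed(seed, {
    tbl <- tidyr::expand_grid(
      subject = sprintf("S%02d", seq_len(n)),
      region = region, side = side,
      state = c("rest", "cycling"), eyes = c("open", "closed")
    )
    b <- rnorm(n, 0, sd_subject)[match(tbl$subject, unique(tbl$subject))]
    tbl$median_entropy <- 3 + b +
      state_effect * (tbl$state == "cycling") +
      eyes_effect * (tbl$eyes == "closed") +
      interaction * (tbl$state == "cycling") * (tbl$eyes == "closed") +
      rnorm(nrow(tbl), 0, sd_noise)
    tbl
  })
}
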