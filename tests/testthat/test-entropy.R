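test_that("recurrence matrix matches direct evaluation", {
  expect_equal(recurrence_matrix(c(5, 5, 5), 0), matrix(1L, 3, 3))
  expect_equal(recurrence_matrix(c(0, 10), 1), diag(2) * 1L)
  m <- recurrence_matrix(c(0, 0.5, 10), 1)
  expect_equal(m, matrix(c(1L, 1L, 0L,
                           1L, 1L, 0L,
                           0L, 0L, 1L), 3, 3))
  expect_true(isSymmetric(m))
  expect_error(recurrence_matrix(numeric(0), 1), "non-empty")
})

test_that("microstate distribution reduces to known closed forms", {
  # constant series: the all-ones block with probability 1
  d <- microstate_distribution(rep(2, 50), 0, N = 3, exhaustive = TRUE)
  expect_equal(d$code, 2^9 - 1)
  expect_equal(d$prob, 1)

  # alternating two-level series, even anchor count: exactly the two
  # checkerboard blocks at probability 1/2
  x <- rep(c(0, 1), length.out = 401)
  d2 <- microstate_distribution(x, 0.5, N = 2, exhaustive = TRUE)
  expect_equal(d2$code, c(6L, 9L))
  expect_equal(d2$prob, c(0.5, 0.5))

  # probabilities always sum to one
  withr::with_seed(3, {
    for (rep in 1:5) {
      y <- rnorm(300)
      ds <- microstate_distribution(y, runif(1, 0.1, 2), N = 4, K = 5000,
                                    seed = rep)
      expect_equal(sum(ds$prob), 1, tolerance = 1e-12)
    }
  })
})

test_that("exhaustive enumeration agrees with the independent matrix oracle", {
  withr::with_seed(14, {
    for (N in 2:4) {
      y <- rnorm(120)
      eps <- runif(1, 0.3, 1.5)
      got <- microstate_distribution(y, eps, N = N, exhaustive = TRUE)
      want <- oracle_microstates(y, eps, N)
      expect_equal(got$code, want$code)
      expect_equal(got$prob, want$prob, tolerance = 1e-12)
    }
  })
})

test_that("sampled distributions converge to the exhaustive one", {
  withr::with_seed(5, {
    tv <- vapply(1:10, function(i) {
      y <- rnorm(400)
      eps <- runif(1, 0.5, 1.5)
      s <- microstate_distribution(y, eps, N = 2, K = 10000, seed = i)
      e <- microstate_distribution(y, eps, N = 2, exhaustive = TRUE)
      all_codes <- union(s$code, e$code)
      ps <- s$prob[match(all_codes, s$code)]
      pe <- e$prob[match(all_codes, e$code)]
      sum(abs(replace(ps, is.na(ps), 0) - replace(pe, is.na(pe), 0))) / 2
    }, numeric(1))
    expect_true(all(tv < 3 * sqrt(2^4 / 10000)))
  })
})

test_that("shannon entropy has its closed-form values and guards", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  expect_equal(shannon_entropy(rep(1 / 16, 16)), 4 * log(2))
  expect_equal(shannon_entropy(c(0.5, 0.5, 0)), log(2))  # 0 log 0 = 0
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")
  expect_error(shannon_entropy(c(0.4, 0.4)), "sum to 1")
})

test_that("max_entropy handles degenerate and analytic segments", {
  expect_message(r0 <- max_entropy(rep(1, 500)), "constant")
  expect_equal(r0$S_max, 0)
  expect_equal(r0$eps_star, 0)

  # strictly periodic two-level series: S_max = ln 2 (exact under exhaustive
  # anchors; the sampled estimate sits within its own sampling error)
  x <- rep(c(0, 1), length.out = 401)
  S_exh <- shannon_entropy(microstate_distribution(x, 0.25, N = 2,
                                                   exhaustive = TRUE))
  expect_equal(S_exh, log(2), tolerance = 1e-12)
  r <- max_entropy(x, entropy_config(N = 2, seed = 2))
  expect_equal(r$S_max, log(2), tolerance = 1e-3)
  expect_lte(r$S_max, log(2) + 1e-12)
})

test_that("sampled S_max tracks the exhaustive-anchor value on noise", {
  withr::with_seed(77, {
    x <- rnorm(1200)
    grid <- as.numeric(quantile(abs(outer(x[1:200], x[1:200], "-")),
                                seq(0.05, 0.95, length.out = 10)))
    cfg <- entropy_config(N = 2, K = 10000, eps_grid = grid, seed = 4)
    r <- max_entropy(x, cfg)
    S_exh <- vapply(grid, function(e) {
      oracle_entropy(oracle_microstates(x, e, 2)$prob)
    }, numeric(1))
    # sampling standard error of the plug-in entropy is below ~ B/sqrt(K)
    expect_lt(abs(max(S_exh) - r$S_max), 3 * 16 / sqrt(10000))
  })
})

test_that("entropy is invariant under affine amplitude transforms", {
  withr::with_seed(6, {
    x <- rnorm(1000)
    cfg <- entropy_config(seed = 8)
    base <- max_entropy(x, cfg)$S_max
    expect_equal(max_entropy(2.5 * x + 7, cfg)$S_max, base)
    expect_equal(max_entropy(-0.3 * x + 1, cfg)$S_max, base)
  })
})

test_that("entropy respects the 0 <= S <= N^2 ln 2 bound", {
  withr::with_seed(9, {
    for (N in c(2, 4)) {
      for (rep in 1:5) {
        x <- switch(sample(3, 1),
                    rnorm(600),
                    sin(2 * pi * 3 * seq_len(600) / 250) + 0.1 * rnorm(600),
                    cumsum(rnorm(600)))
        r <- max_entropy(x, entropy_config(N = N, K = 3000, seed = rep))
        expect_gte(r$S_max, 0)
        expect_lte(r$S_max, N^2 * log(2))
      }
    }
  })
})

test_that("S_max decreases as the periodic component grows", {
  # 5-point amplitude ladder, 20 replicate segments per rung
  amps <- c(0, 0.5, 1, 2, 4)
  mean_S <- vapply(amps, function(a) {
    mean(vapply(1:20, function(r) {
      x <- withr::with_seed(1000 + r, rnorm(800))
      x <- x + a * sin(2 * pi * 5 * seq_len(800) / 1000)
      max_entropy(x, entropy_config(K = 3000, seed = r))$S_max
    }, numeric(1)))
  }, numeric(1))
  expect_identical(order(mean_S, decreasing = TRUE), seq_along(amps))
})

test_that("median_entropy summarises the per-segment values", {
  x <- rep(rep(c(0, 1), length.out = 120), 50)  # 50 identical periodic pieces
  me <- median_entropy(x, entropy_config(N = 2, K = 2000), n_pieces = 50,
                       id = "periodic")
  expect_equal(nrow(me$segments), 50)
  expect_equal(me$median_S, median(me$segments$S))
  expect_equal(me$median_S, log(2), tolerance = 2e-3)

  # channel kernel and single-segment path agree exactly for shared seeds
  y <- withr::with_seed(12, rnorm(600))
  cfg <- entropy_config(K = 2000)
  me2 <- median_entropy(y, cfg, n_pieces = 3, id = "probe")
  seeds <- recmicro:::segment_seeds(derive_seed(cfg$seed, "probe"), 3)
  for (i in 1:3) {
    seg <- y[((i - 1) * 200 + 1):(i * 200)]
    expect_identical(me2$segments$S[i],
                     max_entropy(seg, cfg, seed = seeds[i])$S_max)
  }

  expect_error(median_entropy(rnorm(300), entropy_config(), n_pieces = 100),
               "shorter")
})

test_that("entropy_table is deterministic and well-shaped", {
  spec <- cohort_spec(n_subjects = 2, duration = 1, seed = 13,
                      artifact_rate = 0)
  coh <- condition_recordings(generate_cohort(spec))
  cfg <- entropy_config(K = 500, n_eps = 5, seed = 3)
  e1 <- entropy_table(coh, cfg, n_pieces = 10)
  e2 <- entropy_table(coh, cfg, n_pieces = 10)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 2 * 4 * 8)
  expect_true(all(c("subject", "region", "side", "state", "eyes",
                    "median_entropy", "n_segments", "eps_median")
                  %in% names(e1)))
  expect_true(all(e1$median_entropy >= 0 & e1$median_entropy <= 16 * log(2)))
})
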