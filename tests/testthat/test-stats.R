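test_that("balanced closed-form t statistics reproduce the REML mixed fit", {
  for (seed in 1:3) {
    tbl <- make_entropy_table(n = 12, seed = seed, state_effect = -0.15,
                              eyes_effect = -0.05, interaction = 0.03)
    f <- fit_mixed(tbl, "GLMM2", region = "O", side = "right")
    expect_false(f$singular)
    co <- summary(f$fit)$coefficients
    for (term in f$terms$term) {
      expect_equal(f$terms$t_value[f$terms$term == term],
                   unname(co[term, "t value"]), tolerance = 1e-4)
      expect_equal(f$terms$estimate[f$terms$term == term],
                   unname(co[term, "Estimate"]), tolerance = 1e-6)
    }
  }
})

test_that("GLM1 eyes t equals the paired t on subject cell means", {
  tbl <- make_entropy_table(n = 18, seed = 4, eyes_effect = -0.1)
  f <- fit_mixed(tbl, "GLM1")
  rest <- dplyr::filter(tbl, state == "rest")
  d <- with(rest, tapply(median_entropy, list(subject, eyes), mean))
  t_oracle <- oracle_paired_t(d[, "closed"] - d[, "open"])
  expect_equal(f$terms$t_value, t_oracle, tolerance = 1e-9)
  expect_equal(f$terms$df, 17)
  # and equals the lme4 t as well
  expect_equal(f$terms$t_value,
               unname(summary(f$fit)$coefficients["eyesclosed", "t value"]),
               tolerance = 1e-6)
})

test_that("degenerate tables give zero effects and p = 1", {
  tbl <- make_entropy_table(n = 6, seed = 1, sd_subject = 0, sd_noise = 0)
  expect_message(f <- fit_mixed(tbl, "GLMM2", region = "O", side = "right"),
                 "singular")
  expect_equal(f$terms$estimate, rep(0, 3))
  expect_equal(f$terms$t_value, rep(0, 3))
  p <- permutation_test(tbl, "GLMM2", "statecycling", region = "O",
                        side = "right", n_perm = 200, seed = 1)
  expect_equal(p$p_perm, 1)
})

test_that("a constant within-subject difference is recovered exactly", {
  tbl <- make_entropy_table(n = 2, seed = 2, sd_noise = 0, eyes_effect = -0.3)
  f <- suppressMessages(fit_mixed(tbl, "GLM1"))
  expect_equal(f$terms$estimate, -0.3, tolerance = 1e-12)
})

test_that("unbalanced tables fail with the offending subjects named", {
  tbl <- make_entropy_table(n = 5, seed = 3)
  tbl <- tbl[!(tbl$subject == "S02" & tbl$state == "cycling" &
                 tbl$eyes == "open"), ]
  expect_error(fit_mixed(tbl, "GLMM2", region = "O", side = "right"), "S02")
})

test_that("permutation p-values are reproducible, seed-sensitive and bounded", {
  tbl <- make_entropy_table(n = 10, seed = 6, state_effect = -0.12)
  p1 <- permutation_test(tbl, "GLMM2", "statecycling", region = "O",
                         side = "right", n_perm = 500, seed = 11)
  p2 <- permutation_test(tbl, "GLMM2", "statecycling", region = "O",
                         side = "right", n_perm = 500, seed = 11)
  expect_identical(p1$p_perm, p2$p_perm)
  expect_gte(p1$p_perm, 1 / 501)
  expect_lte(p1$p_perm, 1)
  expect_error(permutation_test(tbl, "GLMM2", "statecycling", region = "O",
                                side = "right", n_perm = 0), "n_perm")
})

test_that("p_perm is invariant to affine rescaling of the response", {
  tbl <- make_entropy_table(n = 10, seed = 7, state_effect = -0.1)
  tbl2 <- dplyr::mutate(tbl, median_entropy = 3.7 * median_entropy + 12)
  for (term in c("statecycling", "statecycling:eyesclosed")) {
    a <- permutation_test(tbl, "GLMM2", term, region = "O", side = "right",
                          n_perm = 300, seed = 5)
    b <- permutation_test(tbl2, "GLMM2", term, region = "O", side = "right",
                          n_perm = 300, seed = 5)
    expect_equal(a$p_perm, b$p_perm)
    expect_equal(a$t_value, b$t_value, tolerance = 1e-9)
  }
})

test_that("exchanging the state labels flips the estimate and keeps |t|", {
  tbl <- make_entropy_table(n = 10, seed = 9, state_effect = -0.2)
  swapped <- dplyr::mutate(tbl, state = ifelse(state == "rest", "cycling",
                                               "rest"))
  f1 <- fit_mixed(tbl, "GLMM2", region = "O", side = "right")
  f2 <- fit_mixed(swapped, "GLMM2", region = "O", side = "right")
  st1 <- f1$terms[f1$terms$term == "statecycling", ]
  st2 <- f2$terms[f2$terms$term == "statecycling", ]
  expect_equal(st1$estimate, -st2$estimate, tolerance = 1e-10)
  expect_equal(abs(st1$t_value), abs(st2$t_value), tolerance = 1e-10)
})

test_that("tiny designs fall back to exact enumeration with a warning", {
  tbl <- make_entropy_table(n = 3, seed = 10, eyes_effect = -0.4)
  expect_warning(
    p <- permutation_test(tbl, "GLM1", "eyesclosed", n_perm = 100, seed = 1),
    "exact enumeration")
  # oracle: enumerate all 2^3 within-subject eye swaps directly
  rest <- dplyr::filter(tbl, state == "rest")
  d <- with(rest, tapply(median_entropy, list(subject, eyes), mean))
  d <- d[, "closed"] - d[, "open"]
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  ts <- apply(signs, 1, function(s) oracle_paired_t(s * d))
  t_obs <- oracle_paired_t(d)
  expect_equal(p$p_perm, mean(abs(ts) >= abs(t_obs) - 1e-12))
  expect_equal(p$n_perm, 8L)
})

test_that("run_inference returns the full 17-row result set deterministically", {
  tbl <- dplyr::bind_rows(lapply(c("F", "C", "P", "O"), function(rg) {
    dplyr::bind_rows(
      make_entropy_table(n = 8, seed = match(rg, c("F", "C", "P", "O")),
                         state_effect = -0.1, region = rg, side = "left"),
      make_entropy_table(n = 8, seed = 10 + match(rg, c("F", "C", "P", "O")),
                         state_effect = -0.1, region = rg, side = "right")
    )
  }))
  r1 <- run_inference(tbl, n_perm = 200, seed = 3)
  expect_equal(nrow(r1), 17)
  expect_equal(sum(r1$model == "GLM1"), 1)
  expect_equal(sum(r1$model == "GLMM2" & r1$term == "statecycling"), 8)
  expect_equal(sum(r1$model == "GLMM2" &
                     r1$term == "statecycling:eyesclosed"), 8)
  r2 <- run_inference(tbl, n_perm = 200, seed = 3)
  expect_identical(r1$p_perm, r2$p_perm)

  rh <- run_inference(tbl, n_perm = 100, seed = 3, holm = TRUE)
  st <- rh[rh$model == "GLMM2" & rh$term == "statecycling", ]
  expect_equal(st$p_holm, p.adjust(st$p_perm, "holm"))

  rp <- run_inference(tbl, n_perm = 100, seed = 3, pool_sides = TRUE)
  expect_equal(sum(rp$side == "both"), 8)
})

test_that("tidy and glance provide broom-style summaries", {
  tbl <- make_entropy_table(n = 8, seed = 5, state_effect = -0.1)
  f <- fit_mixed(tbl, "GLMM2", region = "O", side = "right")
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("model", "region", "side", "term", "estimate",
                     "statistic", "df"))
  gl <- glance(f)
  expect_equal(gl$n_obs, 32)
  expect_equal(gl$n_subjects, 8)
})
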