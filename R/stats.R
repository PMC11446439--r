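# cell orderings used throughout: state and eyes are treatment-coded with
# reference levels rest and open, so "statecycling" is the cycling - rest
# contrast and negative t values mean lower entropy under movement.
.cells_glmm2 <- c("rest.open", "cycling.open", "rest.closed", "cycling.closed")
.cells_glm1 <- c("open", "closed")

.contrasts_glmm2 <- list(
  "statecycling" = c(-1, 1, 0, 0),
  "eyesclosed" = c(-1, 0, 1, 0),
  "statecycling:eyesclosed" = c(1, -1, -1, 1)
)
.contrasts_glm1 <- list("eyesclosed" = c(-1, 1))

# subjects x cells response matrix from a balanced long table
.cell_matrix <- function(tbl, cells) {
  key <- if (length(cells) == 4) {
    paste(tbl$state, tbl$eyes, sep = ".")
  } else {
    tbl$eyes
  }
  subjects <- sort(unique(as.character(tbl$subject)))
  bad <- character(0)
  Y <- matrix(NA_real_, length(subjects), length(cells),
              dimnames = list(subjects, cells))
  for (s in seq_along(subjects)) {
    rows <- tbl$subject == subjects[s]
    k <- key[rows]
    if (length(k) != length(cells) || anyDuplicated(k) ||
        !setequal(k, cells)) {
      bad <- c(bad, subjects[s])
      next
    }
    Y[s, k] <- tbl$median_entropy[rows]
  }
  if (length(bad) > 0) {
    stop("unbalanced or missing cells for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(Y)) stop("missing median_entropy values", call. = FALSE)
  Y
}

# closed-form balanced random-intercept fit: treatment-coded cell-mean
# contrasts with the within-subject (subject x cell interaction) mean square.
# On balanced data this reproduces lme4's REML t statistics exactly (including
# the boundary case, where it matches the subject-as-fixed-factor fallback);
# it is what the permutation loops refit.
.term_est_t <- function(Y, a) {
  n <- nrow(Y)
  m <- ncol(Y)
  mu <- .colMeans(Y, n, m)
  res <- Y - .rowMeans(Y, n, m) - rep(mu, each = n) + sum(mu) / m
  MSw <- sum(res * res) / ((n - 1) * (m - 1))
  est <- sum(a * mu)
  se <- sqrt(MSw * sum(a * a) / n)
  t <- if (se == 0) {
    if (est == 0) 0 else sign(est) * Inf
  } else {
    est / se
  }
  c(est, t)
}

.balanced_terms <- function(Y, contrasts) {
  n <- nrow(Y)
  m <- ncol(Y)
  out <- vapply(contrasts, function(a) .term_est_t(Y, a), numeric(2))
  tibble::tibble(term = names(contrasts), estimate = unname(out[1, ]),
                 t_value = unname(out[2, ]), df = (n - 1) * (m - 1))
}

.prep_table <- function(table, model, region = NULL, side = NULL) {
  stopifnot(is.data.frame(table))
  need <- c("subject", "region", "side", "state", "eyes", "median_entropy")
  if (!all(need %in% names(table))) {
    stop("entropy table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tbl <- table
  if (model == "GLM1") {
    region <- region %||% "O"
    side <- side %||% "right"
    tbl <- dplyr::filter(tbl, .data$region == !!region, .data$side == !!side,
                         .data$state == "rest")
  } else {
    if (is.null(region) || is.null(side)) {
      stop("GLMM2 needs one (region, side)", call. = FALSE)
    }
    tbl <- dplyr::filter(tbl, .data$region == !!region, .data$side == !!side)
  }
  if (dplyr::n_distinct(tbl$subject) < 2) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  tbl$state <- factor(tbl$state, levels = c("rest", "cycling"))
  tbl$eyes <- factor(tbl$eyes, levels = c("open", "closed"))
  tbl$subject <- factor(tbl$subject)
  attr(tbl, "region") <- region
  attr(tbl, "side") <- side
  tbl
}

#' Fit the random-intercept model for one channel or region-side
#'
#' `GLM1` regresses median entropy on eyes (open/closed) with a per-subject
#' random intercept, on resting-state data of one channel (by default the
#' right occipital validation channel). `GLMM2` adds the movement factor:
#' `median_entropy ~ state * eyes + (1 | subject)` on the four conditions of
#' one (region, side). Both use treatment coding with reference levels rest
#' and open and are fitted by REML via \pkg{lme4}; when the random-intercept
#' variance collapses to zero (singular fit) the model falls back to a
#' fixed-effects fit with subject as a factor, which leaves the
#' within-subject contrasts and their t statistics unchanged.
#'
#' @param table Long-format entropy table (see [entropy_table()]).
#' @param model `"GLM1"` or `"GLMM2"`.
#' @param region,side Region (`F`, `C`, `P`, `O`) and side (`left`, `right`)
#'   selecting the data subset. Defaults to occipital-right for `GLM1`.
#' @return An object of class `rme_fit` with the fitted model, the term table
#'   (`term`, `estimate`, `t_value`, `df`) and bookkeeping fields. The
#'   reported degrees of freedom are the within-subject error degrees of
#'   freedom `(n_subjects - 1) * (n_cells - 1)`.
#' @export
fit_mixed <- function(table, model = c("GLM1", "GLMM2"), region = NULL,
                      side = NULL) {
  model <- match.arg(model)
  tbl <- .prep_table(table, model, region, side)
  cells <- if (model == "GLM1") .cells_glm1 else .cells_glmm2
  contrasts <- if (model == "GLM1") .contrasts_glm1 else .contrasts_glmm2
  Y <- .cell_matrix(tbl, cells)
  terms <- .balanced_terms(Y, contrasts)

  form <- if (model == "GLM1") {
    median_entropy ~ eyes + (1 | subject)
  } else {
    median_entropy ~ state * eyes + (1 | subject)
  }
  n <- nrow(Y)
  m <- ncol(Y)
  resid_w <- Y - rowMeans(Y) - rep(colMeans(Y), each = n) + mean(Y)
  degenerate <- sum(resid_w^2) <= 1e-20 * (1 + max(abs(Y)))^2
  if (degenerate) {
    # zero within-subject variance: REML is on the boundary and lme4 only
    # emits spurious convergence noise, so go straight to the fallback
    singular <- TRUE
  } else {
    fit <- suppressMessages(
      lme4::lmer(form, data = tbl, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )
    singular <- lme4::isSingular(fit, tol = 1e-6)
  }
  if (singular) {
    message(model, " (", attr(tbl, "region"), ", ", attr(tbl, "side"),
            "): singular random-intercept variance; ",
            "falling back to fixed-effects fit with subject as a factor")
    fit <- stats::lm(
      if (model == "GLM1") median_entropy ~ subject + eyes
      else median_entropy ~ subject + state * eyes,
      data = tbl)
  }
  structure(
    list(model = model, region = attr(tbl, "region"),
         side = attr(tbl, "side"), terms = terms, fit = fit,
         singular = singular, n_subjects = nrow(Y), cell_matrix = Y,
         data = tbl),
    class = "rme_fit"
  )
}

#' @export
print.rme_fit <- function(x, ...) {
  cat(sprintf("<rme_fit> %s, region %s (%s), %d subjects%s\n", x$model,
              x$region, x$side, x$n_subjects,
              if (x$singular) ", singular (fixed-effects fallback)" else ""))
  print(x$terms)
  invisible(x)
}

#' @export
tidy.rme_fit <- function(x, ...) {
  tibble::tibble(model = x$model, region = x$region, side = x$side,
                 term = x$terms$term, estimate = x$terms$estimate,
                 statistic = x$terms$t_value, df = x$terms$df)
}

#' @export
glance.rme_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_subjects = x$n_subjects,
                 n_obs = nrow(x$data), singular = x$singular,
                 sigma = stats::sigma(x$fit))
}

# ---- permutation machinery --------------------------------------------------

.perm_scheme <- function(model, term) {
  if (model == "GLM1") {
    if (term != "eyesclosed") stop("GLM1 has only the eyes term",
                                   call. = FALSE)
    return(list(type = "swap", pairs = list(c(1, 2)), per_subject = 2))
  }
  switch(term,
    "statecycling" = list(type = "swap", pairs = list(c(1, 2), c(3, 4)),
                          per_subject = 4),
    "eyesclosed" = list(type = "swap", pairs = list(c(1, 3), c(2, 4)),
                        per_subject = 4),
    "statecycling:eyesclosed" = list(type = "cells", per_subject = 24),
    stop("unknown term: ", term, call. = FALSE)
  )
}

.all_perms4 <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 4), ])
  dimnames(p) <- NULL
  p
}

.permute_Y <- function(Y, scheme, perms4 = NULL) {
  n <- nrow(Y)
  if (scheme$type == "swap") {
    for (pr in scheme$pairs) {
      fl <- stats::runif(n) < 0.5
      if (any(fl)) Y[fl, pr] <- Y[fl, rev(pr)]
    }
    Y
  } else {
    idx <- perms4[sample.int(24, n, replace = TRUE), , drop = FALSE]
    matrix(Y[cbind(rep(seq_len(n), 4), as.vector(idx))], n, 4)
  }
}

# enumerate all within-subject label assignments for swap-type schemes
.enumerate_swaps <- function(Y, scheme, contrast) {
  n <- nrow(Y)
  np <- length(scheme$pairs)
  bits <- expand.grid(rep(list(c(FALSE, TRUE)), n * np))
  ts <- apply(as.matrix(bits), 1, function(b) {
    Yp <- Y
    bm <- matrix(b, n, np)
    for (p in seq_len(np)) {
      fl <- bm[, p]
      if (any(fl)) Yp[fl, scheme$pairs[[p]]] <- Yp[fl, rev(scheme$pairs[[p]])]
    }
    .term_est_t(Yp, contrast)[2]
  })
  ts
}

#' Within-subject permutation test for one model term
#'
#' Builds the null distribution of the term's t statistic by permuting,
#' independently within each subject, the condition labels that are
#' exchangeable under that term's null: eyes labels for the eyes term, state
#' labels within each eyes stratum for the state term, and the joint
#' (state, eyes) cell labels for the interaction. Each permutation refits the
#' balanced random-intercept model; the two-sided p-value uses the add-one
#' rule `p = (1 + #{|t*| >= |t_obs|}) / (1 + n_perm)`, which cannot reach
#' zero at finite `n_perm`.
#'
#' When the design admits fewer distinct within-subject label assignments
#' than `1 / alpha`, the test warns and enumerates all assignments exactly
#' instead of sampling.
#'
#' @inheritParams fit_mixed
#' @param term Coefficient to test (`"eyesclosed"`, `"statecycling"` or
#'   `"statecycling:eyesclosed"`).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @param alpha Significance level used only to decide when exact
#'   enumeration replaces sampling.
#' @return A one-row tibble: `model`, `region`, `side`, `term`, `estimate`,
#'   `t_value`, `df`, `p_perm`, `n_perm`, `seed`.
#' @export
permutation_test <- function(table, model = c("GLM1", "GLMM2"), term,
                             region = NULL, side = NULL, n_perm = 10000,
                             seed = 1, alpha = 0.05) {
  model <- match.arg(model)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  tbl <- .prep_table(table, model, region, side)
  cells <- if (model == "GLM1") .cells_glm1 else .cells_glmm2
  contrasts <- if (model == "GLM1") .contrasts_glm1 else .contrasts_glmm2
  if (!term %in% names(contrasts)) {
    stop("term ", term, " not in ", model, call. = FALSE)
  }
  Y <- .cell_matrix(tbl, cells)
  n <- nrow(Y)
  obs <- .balanced_terms(Y, contrasts[term])
  t_obs <- obs$t_value
  scheme <- .perm_scheme(model, term)
  n_distinct <- scheme$per_subject^n

  if (scheme$type == "swap" && n_distinct < 1 / alpha) {
    warning(sprintf(
      "only %d distinct within-subject permutations (< 1/alpha = %g); using exact enumeration",
      n_distinct, 1 / alpha), call. = FALSE)
    ts <- .enumerate_swaps(Y, scheme, contrasts[[term]])
    p <- mean(abs(ts) >= abs(t_obs) - 1e-12)
    n_used <- length(ts)
  } else {
    perms4 <- if (scheme$type == "cells") .all_perms4() else NULL
    contrast <- contrasts[[term]]
    ts <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        .term_est_t(.permute_Y(Y, scheme, perms4), contrast)[2]
      }, numeric(1))
    })
    p <- (1 + sum(abs(ts) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  tibble::tibble(model = model, region = attr(tbl, "region"),
                 side = attr(tbl, "side"), term = term,
                 estimate = obs$estimate, t_value = t_obs, df = obs$df,
                 p_perm = p, n_perm = as.integer(n_used),
                 seed = as.integer(seed))
}

#' Full inference layer over the entropy table
#'
#' Runs the validation model (`GLM1`: eyes effect on the right occipital
#' channel at rest) and, for every (region, side), the movement model
#' (`GLMM2`) with permutation tests of the state term and the state-by-eyes
#' interaction: 1 + 8 + 8 = 17 results. Per-region p-values are reported
#' uncorrected, matching common practice for confirmatory per-electrode
#' contrasts; `holm = TRUE` adds a Holm-adjusted column within each term
#' family.
#'
#' @inheritParams permutation_test
#' @param holm Add Holm-corrected p-values across the 8 region-side tests of
#'   each GLMM2 term.
#' @param pool_sides Also run a sensitivity variant in which the two sides of
#'   each region are averaged subject-wise before fitting (rows with
#'   `side = "both"`).
#' @return A tibble of results, one row per (model, region, side, term). Each
#'   row records the seed of its permutation stream, so any single test can
#'   be re-run exactly.
#' @export
run_inference <- function(table, n_perm = 10000, seed = 1, holm = FALSE,
                          pool_sides = FALSE) {
  res <- list(
    permutation_test(table, "GLM1", "eyesclosed",
                     n_perm = n_perm,
                     seed = derive_seed(seed, "GLM1", "O", "right"))
  )
  grid <- dplyr::distinct(dplyr::as_tibble(table[c("region", "side")]))
  grid <- dplyr::arrange(grid, .data$region, .data$side)
  for (i in seq_len(nrow(grid))) {
    for (term in c("statecycling", "statecycling:eyesclosed")) {
      res[[length(res) + 1]] <- permutation_test(
        table, "GLMM2", term, region = grid$region[i], side = grid$side[i],
        n_perm = n_perm,
        seed = derive_seed(seed, "GLMM2", grid$region[i], grid$side[i], term))
    }
  }
  out <- dplyr::bind_rows(res)
  if (pool_sides) {
    pooled <- table |>
      dplyr::summarise(median_entropy = mean(.data$median_entropy),
                       .by = c("subject", "region", "state", "eyes")) |>
      dplyr::mutate(side = "both")
    for (rg in unique(grid$region)) {
      for (term in c("statecycling", "statecycling:eyesclosed")) {
        row <- permutation_test(
          pooled, "GLMM2", term, region = rg, side = "both",
          n_perm = n_perm, seed = derive_seed(seed, "GLMM2", rg, "both", term))
        out <- dplyr::bind_rows(out, row)
      }
    }
  }
  if (holm) {
    out <- out |>
      dplyr::mutate(p_holm = ifelse(.data$model == "GLMM2" &
                                      .data$side != "both",
                                    NA_real_, NA_real_))
    for (term in unique(out$term[out$model == "GLMM2"])) {
      sel <- out$model == "GLMM2" & out$term == term & out$side != "both"
      out$p_holm[sel] <- stats::p.adjust(out$p_perm[sel], method = "holm")
    }
  }
  class(out) <- c("rme_inference", class(out))
  out
}
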