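# Brute-force oracles implemented from first principles, kept independent of
# the code paths they check.

oracle_paired_t <- function(a, b) {
  d <- b - a
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

oracle_chisq_2x2 <- function(tab) {
  # Yates-corrected Pearson chi-square, the default for 2x2 tables
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((abs(tab - e) - 0.5)^2 / e)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

test_that("paired t contrasts match the closed-form oracle on a 5-pair sample", {
  t0 <- c(52, 44, 60, 38, 70)
  t3 <- c(30, 28, 44, 30, 52)
  long <- tibble::tibble(
    subject_id = rep(paste0("S", 1:5), 2),
    arm = "DFCRS",
    day = rep(c(0, 90), each = 5),
    timepoint = rep(c("T0", "T3"), each = 5),
    thi = c(t0, t3))
  coh <- structure(list(subjects = tibble::tibble(
    subject_id = paste0("S", 1:5), arm = "DFCRS"),
    longitudinal = long), class = "cohort")
  res <- timepoint_contrasts(coh, "thi")
  ref <- oracle_paired_t(t0, t3)
  expect_equal(res$t, ref$t, tolerance = 1e-10)
  expect_equal(res$df, ref$df)
  expect_equal(res$p_value, ref$p, tolerance = 1e-10)
  expect_equal(res$mean_diff, mean(t3 - t0), tolerance = 1e-12)
})

test_that("identical scores at two timepoints give t = 0, p = 1", {
  long <- tibble::tibble(
    subject_id = rep(paste0("S", 1:4), 2),
    arm = "DFCRS",
    day = rep(c(0, 30), each = 4),
    timepoint = rep(c("T0", "T1"), each = 4),
    thi = rep(c(40, 50, 60, 70), 2))
  coh <- structure(list(longitudinal = long), class = "cohort")
  res <- timepoint_contrasts(coh, "thi")
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
})

test_that("categorical baseline test matches a hand-computed 2x2 chi-square", {
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:20),
    arm = rep(c("DFCRS", "UM"), each = 10),
    gender = c(rep("male", 7), rep("female", 3),
               rep("male", 3), rep("female", 7)))
  long <- tibble::tibble(subject_id = subjects$subject_id,
                         arm = subjects$arm, timepoint = "T0",
                         thi = 50)
  coh <- structure(list(subjects = subjects, longitudinal = long),
                   class = "cohort")
  res <- baseline_tests(coh, covariates = "gender")
  ref <- oracle_chisq_2x2(table(subjects$gender, subjects$arm))
  expect_equal(res$test, "chi-square")
  expect_equal(res$statistic, ref$stat, tolerance = 1e-10)
  expect_equal(res$p_value, ref$p, tolerance = 1e-10)
})

test_that("the normality gate routes covariates to ANOVA or Kruskal-Wallis", {
  set.seed(4)
  n <- 60
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:n),
    arm = rep(c("DFCRS", "UM"), each = n / 2),
    age = round(stats::rnorm(n, 45, 8)),                   # normal-ish
    course_months = round(stats::rlnorm(n, 2, 1.2), 1))    # heavy-tailed
  long <- tibble::tibble(subject_id = subjects$subject_id,
                         arm = subjects$arm, timepoint = "T0", thi = 50)
  coh <- structure(list(subjects = subjects, longitudinal = long),
                   class = "cohort")
  res <- baseline_tests(coh, covariates = c("age", "course_months"))
  expect_equal(res$test[res$covariate == "age"], "anova")
  expect_equal(res$test[res$covariate == "course_months"], "kruskal-wallis")
})

test_that("a large location shift is detected by Kruskal-Wallis", {
  set.seed(6)
  n <- 50
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:n),
    arm = rep(c("DFCRS", "UM"), each = n / 2),
    course_months = c(stats::rlnorm(n / 2, 3.5, 0.6),
                      stats::rlnorm(n / 2, 1.5, 0.6)))
  long <- tibble::tibble(subject_id = subjects$subject_id,
                         arm = subjects$arm, timepoint = "T0", thi = 50)
  coh <- structure(list(subjects = subjects, longitudinal = long),
                   class = "cohort")
  res <- baseline_tests(coh, covariates = "course_months")
  expect_lt(res$p_value, 0.001)
})

test_that("constant covariates yield a degenerate-test row, not an error", {
  coh <- small_cohort(n_dfcrs = 10, n_um = 10)
  coh$subjects$site <- "A"
  res <- baseline_tests(coh, covariates = "site")
  expect_equal(res$test, "degenerate")
  expect_true(is.na(res$p_value))
})

test_that("LMM recovers the generating coefficients in the noise-free limit", {
  cfg <- sim_config(n_dfcrs = 40, n_um = 30, sd_intercept = 1e-4,
                    sd_resid = 1e-4, round_scores = FALSE)
  coh <- generate_cohort(cfg, seed = 17)
  fit <- fit_thi_lmm(coh, fixed = c("day", "arm"))
  est <- fit$fixed_effects
  expect_equal(est$estimate[est$term == "day"], -0.119, tolerance = 1e-3)
  expect_equal(est$estimate[est$term == "armDFCRS"], -16.6469,
               tolerance = 1e-3)
  expect_equal(est$estimate[est$term == "(Intercept)"], 56.13335,
               tolerance = 1e-3)
})

test_that("LMM output carries SEs, Satterthwaite df and variance components", {
  coh <- small_cohort()
  fit <- fit_thi_lmm(coh)
  expect_equal(fit$df_method, "satterthwaite")
  expect_true(all(fit$fixed_effects$se > 0))
  expect_true(all(fit$fixed_effects$p_value >= 0 &
                    fit$fixed_effects$p_value <= 1))
  expect_gt(fit$variance_components$random_intercept_var, 0)
  expect_gt(fit$variance_components$residual_var, 0)
  # treatment benefit appears as negative estimates (UM is reference)
  expect_lt(fit$fixed_effects$estimate[fit$fixed_effects$term == "armDFCRS"],
            0)
  expect_lt(fit$fixed_effects$estimate[fit$fixed_effects$term == "day"], 0)
})

test_that("permuting arm labels removes the group effect", {
  set.seed(23)
  hits <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    coh <- generate_cohort(sim_config(n_dfcrs = 30, n_um = 25),
                           seed = 500 + i)
    perm <- sample(coh$subjects$arm)
    coh$subjects$arm <- perm
    coh$longitudinal$arm <-
      perm[match(coh$longitudinal$subject_id, coh$subjects$subject_id)]
    fit <- fit_thi_lmm(coh, fixed = c("day", "arm"))
    p <- fit$fixed_effects$p_value[fit$fixed_effects$term == "armDFCRS"]
    if (p >= 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("multinomial fit matches direct likelihood maximization on 10 subjects", {
  # 10-subject fixture, one continuous covariate, all three outcome levels
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:10),
    arm = "DFCRS",
    daily_listen_hours = c(0.5, 0.8, 1.0, 1.6, 2.0, 2.2, 2.5, 3.0, 3.5, 4.0),
    # classes overlap in x, so the likelihood has a finite interior optimum
    outcome = c("worsened", "relief", "worsened", "relief", "worsened",
                "relief", "relief", "disappeared", "disappeared", "relief"))
  coh <- structure(list(subjects = subjects), class = "cohort")
  res <- fit_outcome_multinomial(coh,
                                 candidate_covariates = "daily_listen_hours",
                                 criterion = "AIC")
  expect_equal(res$selected_covariates, "daily_listen_hours")

  # independent oracle: maximize the multinomial log-likelihood directly,
  # coarse grid then Nelder-Mead polish, never calling nnet
  x <- subjects$daily_listen_hours
  y <- match(subjects$outcome, c("worsened", "relief", "disappeared"))
  negll <- function(par) {
    eta1 <- par[1] + par[2] * x    # relief vs worsened
    eta2 <- par[3] + par[4] * x    # disappeared vs worsened
    denom <- log1p(exp(eta1) + exp(eta2))
    ll <- sum(ifelse(y == 1, 0, ifelse(y == 2, eta1, eta2)) - denom)
    -ll
  }
  grid <- expand.grid(a1 = seq(-10, 5, by = 1), b1 = seq(-1, 6, by = 0.5),
                      a2 = seq(-20, 0, by = 2), b2 = seq(-1, 8, by = 0.5))
  vals <- apply(grid, 1, negll)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  opt <- stats::optim(opt$par, negll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))

  ors <- res$odds_ratios
  got <- log(c(
    ors$or[ors$category == "relief" & ors$term == "(Intercept)"],
    ors$or[ors$category == "relief" & ors$term == "daily_listen_hours"],
    ors$or[ors$category == "disappeared" & ors$term == "(Intercept)"],
    ors$or[ors$category == "disappeared" & ors$term == "daily_listen_hours"]))
  expect_equal(got, opt$par, tolerance = 1e-4)
  expect_equal(-negll(got), -opt$value, tolerance = 1e-6)
})

test_that("stepwise keeps the real dose effect and drops pure noise", {
  set.seed(37)
  kept_noise <- 0
  kept_dose <- 0
  n_rep <- 10
  for (i in seq_len(n_rep)) {
    coh <- generate_cohort(sim_config(), seed = 700 + i)
    coh$subjects$noise_cov <- stats::rnorm(nrow(coh$subjects))
    res <- fit_outcome_multinomial(
      coh, candidate_covariates = c("daily_listen_hours", "noise_cov"))
    if ("noise_cov" %in% res$selected_covariates) kept_noise <- kept_noise + 1
    if ("daily_listen_hours" %in% res$selected_covariates)
      kept_dose <- kept_dose + 1
  }
  expect_lt(kept_noise / n_rep, 0.5)   # noise excluded in the majority
  expect_gt(kept_dose / n_rep, 0.9)    # the true dose effect always kept
})

test_that("refitting the selected covariate set reproduces the coefficients", {
  coh <- generate_cohort(sim_config(), seed = 41)
  res <- fit_outcome_multinomial(coh)
  refit <- fit_outcome_multinomial(
    coh, candidate_covariates = res$selected_covariates)
  expect_equal(refit$selected_covariates, res$selected_covariates)
  expect_equal(refit$odds_ratios$or, res$odds_ratios$or, tolerance = 1e-6)
})

test_that("two observed outcome levels raise an explicit error", {
  coh <- small_cohort()
  coh$subjects$outcome[coh$subjects$outcome == "disappeared"] <- "relief"
  expect_error(fit_outcome_multinomial(coh), "level")
})

test_that("outcome percentages reproduce the trial's reported rates", {
  res <- outcome_proportions(
    c(relief = 93, disappeared = 6, worsened = 8),
    combine = list(improved = c("relief", "disappeared")))
  expect_equal(res$percent[res$category == "relief"], 86.9)
  expect_equal(res$percent[res$category == "disappeared"], 5.6)
  expect_equal(res$percent[res$category == "worsened"], 7.5)
  expect_equal(res$percent[res$category == "improved"], 92.5)
  expect_equal(outcome_proportions(c(a = 12))$percent, 100)
  expect_error(outcome_proportions(c(a = 0, b = 0)), "zero")
  expect_error(outcome_proportions(c(5, 3)), "named")
})

test_that("rounded percentages sum to 100 within 0.2", {
  set.seed(19)
  for (i in 1:25) {
    counts <- stats::setNames(stats::rpois(3, 40) + 1, c("a", "b", "c"))
    res <- outcome_proportions(counts)
    expect_lt(abs(sum(res$percent) - 100), 0.2)
  }
})
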