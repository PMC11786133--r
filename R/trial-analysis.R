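# Analysis pipeline for two-arm longitudinal cohorts: baseline group
# comparisons, random-intercept LMM for the THI trajectory, stepwise
# multinomial logistic regression for the 3-category treatment outcome, and
# paired timepoint contrasts.

#' Baseline group comparisons
#'
#' Tests each baseline covariate for differences between arms: chi-square for
#' categorical covariates; for continuous covariates, one-way ANOVA when every
#' group passes a Shapiro-Wilk normality check (at `normality_alpha`),
#' otherwise Kruskal-Wallis. The normality gate used for each covariate is
#' reported in the output.
#'
#' @param cohort A `cohort` (see [generate_cohort()] / [read_cohort_csv()]).
#' @param covariates Character vector of covariate names to test; defaults to
#'   the standard baseline set.
#' @param normality_alpha Significance level of the Shapiro-Wilk gate.
#' @return A tibble with `covariate`, `test` (`"chi-square"`, `"anova"`,
#'   `"kruskal-wallis"` or `"degenerate"`), `statistic`, `p_value`,
#'   `normality_p_min`.
#' @export
baseline_tests <- function(cohort,
                           covariates = c("gender", "location", "status",
                                          "severity_grade", "age",
                                          "course_months", "pitch_hz", "thi"),
                           normality_alpha = 0.05) {
  subjects <- cohort$subjects
  arms <- unique(subjects$arm)
  if (length(arms) < 2 || any(table(subjects$arm) == 0)) {
    stop("Need at least two nonempty groups.", call. = FALSE)
  }
  t0 <- dplyr::filter(cohort$longitudinal, .data$timepoint == "T0")
  base <- dplyr::left_join(subjects, t0, by = c("subject_id", "arm"))

  test_one <- function(v) {
    x <- base[[v]]
    if (is.null(x)) stop("Unknown covariate: ", v, call. = FALSE)
    grp <- factor(base$arm)
    if (length(unique(x[!is.na(x)])) < 2) {
      return(tibble::tibble(covariate = v, test = "degenerate",
                            statistic = NA_real_, p_value = NA_real_,
                            normality_p_min = NA_real_))
    }
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      tab <- table(x, grp)
      res <- suppressWarnings(stats::chisq.test(tab))
      tibble::tibble(covariate = v, test = "chi-square",
                     statistic = unname(res$statistic),
                     p_value = res$p.value, normality_p_min = NA_real_)
    } else {
      sw <- vapply(split(x, grp), function(g) {
        g <- g[!is.na(g)]
        if (length(g) < 3 || length(unique(g)) < 2) return(0)
        stats::shapiro.test(g)$p.value
      }, 0)
      if (min(sw) >= normality_alpha) {
        res <- stats::aov(x ~ grp)
        s <- summary(res)[[1]]
        tibble::tibble(covariate = v, test = "anova",
                       statistic = s[["F value"]][1],
                       p_value = s[["Pr(>F)"]][1],
                       normality_p_min = min(sw))
      } else {
        res <- stats::kruskal.test(x ~ grp)
        tibble::tibble(covariate = v, test = "kruskal-wallis",
                       statistic = unname(res$statistic),
                       p_value = res$p.value, normality_p_min = min(sw))
      }
    }
  }
  dplyr::bind_rows(lapply(covariates, test_one))
}

#' Fit the random-intercept linear mixed model for the THI trajectory
#'
#' Fits `thi ~ day + arm + gender + age + location + course_months +
#' (1 | subject_id)` (fixed effects configurable) with REML, reporting each
#' fixed effect with its standard error, t statistic, degrees of freedom
#' (Satterthwaite approximation via \pkg{lmerTest}; falls back to residual df
#' with a flag if the approximation fails) and p value, plus the variance
#' components. Arm is coded with "UM" as reference so that treatment benefit
#' appears as a negative estimate, matching the convention that lower THI is
#' better.
#'
#' @param cohort A `cohort`.
#' @param fixed Character vector of fixed-effect terms (the time variable
#'   `day` is always included first).
#' @return An object of class `lmm_result`: list with `fixed_effects` tibble
#'   (`term`, `estimate`, `se`, `t`, `df`, `p_value`), `variance_components`
#'   (`random_intercept_var`, `residual_var`), `df_method`, `singular`
#'   (logical flag), and the underlying `fit`.
#' @export
fit_thi_lmm <- function(cohort,
                        fixed = c("day", "arm", "gender", "age", "location",
                                  "course_months")) {
  long <- cohort$longitudinal
  subj_cols <- setdiff(intersect(fixed, names(cohort$subjects)), names(long))
  if (length(subj_cols)) {
    long <- dplyr::left_join(
      long,
      dplyr::select(cohort$subjects, "subject_id",
                    dplyr::all_of(subj_cols)),
      by = "subject_id")
  }
  if (!"day" %in% fixed) fixed <- c("day", fixed)
  long$arm <- stats::relevel(factor(long$arm), ref = "UM")
  form <- stats::as.formula(
    paste("thi ~", paste(fixed, collapse = " + "), "+ (1 | subject_id)"))
  fit <- lmerTest::lmer(form, data = long)
  singular <- lme4::isSingular(fit)
  coefs <- tryCatch(
    {
      cc <- summary(fit)$coefficients  # Satterthwaite df
      list(tab = cc, method = "satterthwaite")
    },
    error = function(e) {
      cc <- summary(fit, ddf = "lme4")$coefficients
      n <- stats::nobs(fit)
      df_resid <- n - nrow(cc)
      cc <- cbind(cc, df = df_resid,
                  `Pr(>|t|)` = 2 * stats::pt(-abs(cc[, "t value"]), df_resid))
      list(tab = cc, method = "residual")
    })
  tab <- coefs$tab
  fixed_effects <- tibble::tibble(
    term = rownames(tab),
    estimate = unname(tab[, "Estimate"]),
    se = unname(tab[, "Std. Error"]),
    t = unname(tab[, "t value"]),
    df = unname(tab[, "df"]),
    p_value = unname(tab[, "Pr(>|t|)"])
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(fixed_effects = fixed_effects,
         variance_components = list(
           random_intercept_var = vc$vcov[vc$grp == "subject_id"],
           residual_var = vc$vcov[vc$grp == "Residual"]),
         df_method = coefs$method,
         singular = singular,
         reference_levels = c(arm = "UM"),
         fit = fit),
    class = "lmm_result"
  )
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Random-intercept linear mixed model for THI",
      if (x$singular) "(singular fit)" else "", "\n")
  print(as.data.frame(x$fixed_effects), digits = 4)
  cat(sprintf("Random intercept var %.2f, residual var %.2f (%s df)\n",
              x$variance_components$random_intercept_var,
              x$variance_components$residual_var, x$df_method))
  invisible(x)
}

# Information criteria for a multinom fit. AICc uses the standard small-sample
# correction with k = number of estimated parameters.
multinom_criterion <- function(fit, criterion) {
  k <- length(stats::coef(fit))
  n <- nrow(fit$residuals)
  ll <- -fit$value  # multinom minimizes the negative log-likelihood
  switch(criterion,
         AIC = 2 * k - 2 * ll,
         BIC = log(n) * k - 2 * ll,
         AICc = {
           pen <- if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
           2 * k - 2 * ll + pen
         })
}

fit_multinom_quiet <- function(formula, data) {
  # do.call embeds the evaluated formula and data in the stored call, so that
  # summary()/vcov(), which re-evaluate it, work outside this frame
  do.call(nnet::multinom,
          list(formula, data = data, trace = FALSE, maxit = 500))
}

#' Fit the 3-category outcome model with stepwise covariate selection
#'
#' Models the subjective treatment outcome (worsened / relief / disappeared,
#' reference "worsened") as multinomial logistic in the candidate covariates,
#' choosing the covariate set by bidirectional stepwise search from the
#' intercept-only model, scored by AICc (default), AIC or BIC. Odds ratios are
#' exponentiated coefficients with Wald 95% CIs on the log scale. The selected
#' covariate set is refit without selection, which yields identical
#' coefficients: selection only chooses the set.
#'
#' @param cohort A `cohort`; only subjects with a non-missing outcome enter
#'   (the treated arm in the synthetic design).
#' @param candidate_covariates Covariates available to the stepwise search.
#' @param criterion `"AICc"`, `"AIC"` or `"BIC"`.
#' @return An object of class `multinomial_result`: list with `odds_ratios`
#'   tibble (`category`, `term`, `or`, `ci_lower`, `ci_upper`, `p_value`),
#'   `selected_covariates`, `criterion`, `reference_category`, `separation`
#'   flag, and the underlying `fit`.
#' @export
fit_outcome_multinomial <- function(cohort,
                                    candidate_covariates =
                                      c("daily_listen_hours", "gender", "age",
                                        "course_months", "status",
                                        "severity_grade"),
                                    criterion = c("AICc", "AIC", "BIC")) {
  criterion <- match.arg(criterion)
  d <- dplyr::filter(cohort$subjects, !is.na(.data$outcome))
  lv <- c("worsened", "relief", "disappeared")
  present <- intersect(lv, unique(d$outcome))
  if (length(present) < 3) {
    stop("Outcome has only ", length(present),
         " observed level(s); need all of worsened/relief/disappeared.",
         call. = FALSE)
  }
  d$outcome <- factor(d$outcome, levels = lv)
  if ("severity_grade" %in% names(d)) {
    d$severity_grade <- factor(d$severity_grade,
                               levels = c("I", "II", "III", "IV"))
  }

  # bidirectional stepwise from the intercept-only model
  selected <- character()
  repeat {
    current_form <- stats::as.formula(paste(
      "outcome ~", if (length(selected)) paste(selected, collapse = " + ")
      else "1"))
    current_score <- multinom_criterion(fit_multinom_quiet(current_form, d),
                                        criterion)
    moves <- list()
    for (v in setdiff(candidate_covariates, selected)) {
      moves[[paste0("+", v)]] <- c(selected, v)
    }
    for (v in selected) {
      moves[[paste0("-", v)]] <- setdiff(selected, v)
    }
    if (!length(moves)) break
    scores <- vapply(moves, function(set) {
      f <- stats::as.formula(paste(
        "outcome ~", if (length(set)) paste(set, collapse = " + ") else "1"))
      tryCatch(multinom_criterion(fit_multinom_quiet(f, d), criterion),
               error = function(e) Inf)
    }, 0)
    if (min(scores) >= current_score - 1e-8) break
    selected <- moves[[names(which.min(scores))]]
  }

  final_form <- stats::as.formula(paste(
    "outcome ~", if (length(selected)) paste(selected, collapse = " + ")
    else "1"))
  fit <- fit_multinom_quiet(final_form, d)

  cf <- stats::coef(fit)
  se <- summary(fit)$standard.errors
  if (is.null(dim(cf))) {  # single non-reference category edge case
    cf <- matrix(cf, nrow = 1, dimnames = list(lv[2], names(cf)))
    se <- matrix(se, nrow = 1, dimnames = dimnames(cf))
  }
  z <- cf / se
  p <- 2 * stats::pnorm(-abs(z))
  # crude separation diagnostic: implausibly large |coef| or tiny gradient SEs
  separation <- any(abs(cf) > 15) || any(!is.finite(se))
  rows <- list()
  for (cat_i in rownames(cf)) {
    for (term in colnames(cf)) {
      rows[[paste(cat_i, term)]] <- tibble::tibble(
        category = cat_i, term = term,
        or = exp(cf[cat_i, term]),
        ci_lower = exp(cf[cat_i, term] - 1.96 * se[cat_i, term]),
        ci_upper = exp(cf[cat_i, term] + 1.96 * se[cat_i, term]),
        p_value = p[cat_i, term])
    }
  }
  structure(
    list(odds_ratios = dplyr::bind_rows(rows),
         selected_covariates = selected,
         criterion = criterion,
         reference_category = "worsened",
         separation = separation,
         fit = fit),
    class = "multinomial_result"
  )
}

#' @export
print.multinomial_result <- function(x, ...) {
  cat("Multinomial logistic outcome model (reference:",
      x$reference_category, ")\n")
  cat("Selected by", x$criterion, ":",
      if (length(x$selected_covariates))
        paste(x$selected_covariates, collapse = ", ") else "(intercept only)",
      "\n")
  if (x$separation) cat("WARNING: possible separation detected\n")
  print(as.data.frame(x$odds_ratios), digits = 3)
  invisible(x)
}

#' Pairwise paired t tests between timepoints
#'
#' Two-tailed paired t tests of a scale score between every pair of the four
#' visits, optionally within one arm. Subjects missing either visit of a pair
#' are dropped listwise and counted in `n_dropped`.
#'
#' @param cohort A `cohort`.
#' @param scale Longitudinal score column, e.g. `"thi"`.
#' @param arm Optional arm filter (`"DFCRS"` or `"UM"`).
#' @return A tibble with `timepoint_a`, `timepoint_b`, `n_pairs`, `n_dropped`,
#'   `mean_diff` (b minus a), `t`, `df`, `p_value`.
#' @export
timepoint_contrasts <- function(cohort, scale = "thi", arm = NULL) {
  long <- cohort$longitudinal
  if (!is.null(arm)) long <- dplyr::filter(long, .data$arm == !!arm)
  if (!scale %in% names(long)) {
    stop("Unknown scale column: ", scale, call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(long, "subject_id", "timepoint",
                  dplyr::all_of(scale)),
    names_from = "timepoint", values_from = dplyr::all_of(scale))
  tps <- intersect(paste0("T", 0:3), names(wide))
  pairs <- utils::combn(tps, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- wide[[pr[1]]]
    b <- wide[[pr[2]]]
    ok <- !is.na(a) & !is.na(b)
    diffs <- b[ok] - a[ok]
    if (sum(ok) < 2 || stats::sd(diffs) == 0) {
      # all differences identical: t test degenerate; report t = 0 / p = 1
      # for the no-change case, NA otherwise
      no_change <- all(diffs == 0)
      return(tibble::tibble(
        timepoint_a = pr[1], timepoint_b = pr[2],
        n_pairs = sum(ok), n_dropped = sum(!ok),
        mean_diff = if (sum(ok)) mean(diffs) else NA_real_,
        t = if (no_change) 0 else NA_real_,
        df = sum(ok) - 1,
        p_value = if (no_change) 1 else NA_real_))
    }
    res <- stats::t.test(b[ok], a[ok], paired = TRUE)
    tibble::tibble(
      timepoint_a = pr[1], timepoint_b = pr[2],
      n_pairs = sum(ok), n_dropped = sum(!ok),
      mean_diff = unname(res$estimate),
      t = unname(res$statistic), df = unname(res$parameter),
      p_value = res$p.value)
  })
  dplyr::bind_rows(rows)
}

#' Outcome percentages from category counts
#'
#' Converts outcome counts into percentages of the total, rounded to one
#' decimal place. `combine` reports additional percentages for pooled
#' categories (e.g. relief + disappeared).
#'
#' @param counts Named nonnegative counts, e.g.
#'   `c(worsened = 8, relief = 93, disappeared = 6)`.
#' @param combine Optional named list of character vectors of categories to
#'   pool.
#' @return A tibble with `category`, `count`, `percent`.
#' @export
#' @examples
#' outcome_proportions(c(worsened = 8, relief = 93, disappeared = 6),
#'                     combine = list(improved = c("relief", "disappeared")))
outcome_proportions <- function(counts, combine = NULL) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("`counts` must be named.", call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("Counts must be nonnegative.", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("Total count is zero.", call. = FALSE)
  out <- tibble::tibble(
    category = names(counts),
    count = as.numeric(counts),
    percent = unname(round(100 * counts / total, 1)))
  if (!is.null(combine)) {
    extra <- lapply(names(combine), function(nm) {
      cats <- combine[[nm]]
      missing_c <- setdiff(cats, names(counts))
      if (length(missing_c)) {
        stop("Unknown categories in `combine`: ",
             paste(missing_c, collapse = ", "), call. = FALSE)
      }
      cnt <- sum(counts[cats])
      tibble::tibble(category = nm, count = as.numeric(cnt),
                     percent = round(100 * cnt / total, 1))
    })
    out <- dplyr::bind_rows(out, extra)
  }
  out
}
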