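#' Binarize a score within cancer types
#'
#' Splits samples into high/low groups at a within-cancer-type empirical
#' percentile: a sample is high when its value is strictly above the
#' percentile of its own cancer type (ties at the threshold go to low, so
#' identical values never produce a spurious high group). Cancer types with
#' fewer than 2 samples are excluded (`NA` label) with a warning.
#'
#' @param df A data frame with a `cancer_type` column.
#' @param value_col Name of the numeric column to binarize.
#' @param percentile Percentile in (0, 100) defining the split.
#' @param out_col Name of the new logical column; default
#'   `paste0(value_col, "_high")`.
#' @return `df` with the added logical column.
#' @export
#' @examples
#' df <- tibble::tibble(cancer_type = "A", score = 1:10)
#' binarize_within_type(df, "score", 60)$score_high  # top 4 TRUE
binarize_within_type <- function(df, value_col, percentile, out_col = NULL) {
  stopifnot(percentile > 0, percentile < 100)
  assert_columns(df, c("cancer_type", value_col), "cohort")
  out_col <- out_col %||% paste0(value_col, "_high")
  small <- df |>
    dplyr::count(.data$cancer_type) |>
    dplyr::filter(.data$n < 2)
  if (nrow(small) > 0) {
    rlang::warn(sprintf(
      "binarize_within_type: cancer type(s) with < 2 samples excluded: %s",
      paste(small$cancer_type, collapse = ", ")))
  }
  df |>
    dplyr::mutate(
      !!out_col := if (dplyr::n() < 2) NA else
        .data[[value_col]] > quantile(.data[[value_col]], percentile / 100,
                                      na.rm = TRUE, names = FALSE),
      .by = "cancer_type")
}

#' Build a binned cohort for survival stratification
#'
#' Joins per-sample scores to the clinical table and adds the two binary
#' stratification covariates the survival models use: `tmb_high` (TMB
#' strictly above the within-cancer-type `tmb_percentile`, default 80, i.e.
#' the top 20%) and `score_high` (score above the within-cancer-type
#' `score_percentile`), plus the four-group label
#' `TMB-{H,L}/Score-{H,L}`.
#'
#' @param clinical A validated clinical table ([read_clinical()]).
#' @param scores A data frame with `sample_id` and the score column, e.g. a
#'   [compute_scores()] result.
#' @param score_col Name of the score column in `scores` (default
#'   `"fga"`).
#' @param score_percentile Within-type percentile binarizing the score.
#' @param tmb_percentile Within-type percentile binarizing TMB (default 80).
#' @return A tibble of class `cna_binned`: the joined cohort with
#'   `score_high`, `tmb_high` and `group4`.
#' @export
bin_cohort <- function(clinical, scores, score_col = "fga",
                       score_percentile = 50, tmb_percentile = 80) {
  assert_columns(scores, c("sample_id", score_col), "score table")
  clinical <- tibble::as_tibble(clinical)
  # the score may already sit in the clinical table; the `scores` copy wins
  clinical <- clinical[, setdiff(names(clinical),
                                 setdiff(score_col, "sample_id"))]
  df <- dplyr::inner_join(clinical, scores[, c("sample_id", score_col)],
                          by = "sample_id")
  df <- binarize_within_type(df, "tmb", tmb_percentile, out_col = "tmb_high")
  df <- binarize_within_type(df, score_col, score_percentile,
                             out_col = "score_high")
  df$group4 <- factor(
    paste0("TMB-", ifelse(df$tmb_high, "H", "L"),
           "/Score-", ifelse(df$score_high, "H", "L")),
    levels = c("TMB-H/Score-L", "TMB-H/Score-H",
               "TMB-L/Score-L", "TMB-L/Score-H"))
  class(df) <- c("cna_binned", class(tibble::tibble()))
  df
}

drug_class_factor <- function(x) {
  lev <- unique(as.character(x))
  ref <- if ("PD-1/PD-L1" %in% lev) "PD-1/PD-L1" else sort(lev)[1]
  factor(as.character(x), levels = c(ref, sort(setdiff(lev, ref))))
}

#' Multivariable Cox proportional-hazards fit
#'
#' Fits a partial-likelihood proportional-hazards model of overall survival
#' on a subset of the stratification covariates (`score_high`, `tmb_high`,
#' `drug_class`), with Efron handling of tied event times. `drug_class` is
#' entered as indicator contrasts against a fixed reference level
#' (`"PD-1/PD-L1"` when present, else the alphabetically first class).
#' Optionally the baseline hazard is stratified by cancer type.
#'
#' @param cohort A [bin_cohort()] result (needs `os_time`, `os_event` and
#'   the requested covariates).
#' @param covariates Character subset of
#'   `c("score_high", "tmb_high", "drug_class")`.
#' @param stratify_by_type Stratify the baseline hazard by `cancer_type`?
#'   Default `FALSE`.
#' @return An object of class `cna_cox` with [tidy()] (per-term hazard
#'   ratios, Wald confidence intervals and P values) and [glance()] methods.
#'   Non-convergence is flagged in `glance()$converged`, never silent.
#' @export
fit_cox <- function(cohort,
                    covariates = c("score_high", "tmb_high", "drug_class"),
                    stratify_by_type = FALSE) {
  covariates <- match.arg(covariates, several.ok = TRUE)
  assert_columns(cohort, c("os_time", "os_event", covariates), "cohort")
  df <- tibble::as_tibble(cohort)
  df <- df[complete.cases(df[, c("os_time", "os_event", covariates)]), ]
  if (sum(df$os_event) < 1) {
    abort_cnasurv("no events in cohort: Cox model is undefined",
                  class = "cnasurv_no_events")
  }
  for (v in covariates) {
    if (length(unique(df[[v]])) < 2) {
      abort_cnasurv(sprintf("covariate '%s' is constant in the cohort", v),
                    class = "cnasurv_validation_error")
    }
  }
  if ("drug_class" %in% covariates) {
    df$drug_class <- drug_class_factor(df$drug_class)
  }
  rhs <- paste(covariates, collapse = " + ")
  if (stratify_by_type) rhs <- paste(rhs, "+ strata(cancer_type)")
  fml <- as.formula(paste("survival::Surv(os_time, os_event) ~", rhs))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w))) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  if (any(is.na(fit$coefficients))) converged <- FALSE
  s <- summary(fit)
  terms_tbl <- tibble::tibble(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    std.error = s$coefficients[, "se(coef)"],
    conf.low = s$conf.int[, "lower .95"],
    conf.high = s$conf.int[, "upper .95"],
    p.value = s$coefficients[, "Pr(>|z|)"])
  structure(
    list(fit = fit, terms = terms_tbl, n = nrow(df),
         n_events = sum(df$os_event), converged = converged,
         covariates = covariates, stratified = stratify_by_type),
    class = "cna_cox")
}

#' @export
print.cna_cox <- function(x, ...) {
  cat(sprintf("<cna_cox> n = %d, events = %d%s%s\n", x$n, x$n_events,
              if (x$stratified) ", stratified by cancer type" else "",
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$terms)
  invisible(x)
}

#' Kaplan-Meier comparison of patient groups
#'
#' Computes the product-limit survival estimate per group, the median
#' survival per group, and for every pair of groups the hazard ratio from a
#' univariable proportional-hazards fit (with Wald confidence interval and
#' P value) together with the log-rank P value. Pairs involving a group
#' with zero events get a missing hazard ratio.
#'
#' @param cohort A data frame with `os_time`, `os_event` and the grouping
#'   column.
#' @param group_col Name of the grouping column (default `"group4"`, the
#'   four-group TMB-by-score label from [bin_cohort()]).
#' @return An object of class `cna_km`: a list with tibbles `curves`
#'   (group, time, n_risk, n_event, surv, conf.low, conf.high), `medians`
#'   (group, n, n_events, median) and `pairwise` (group_1, group_2, hr,
#'   conf.low, conf.high, p.value, logrank_p, converged). Has an
#'   [autoplot()] method.
#' @export
km_compare <- function(cohort, group_col = "group4") {
  assert_columns(cohort, c("os_time", "os_event", group_col), "cohort")
  df <- tibble::as_tibble(cohort)
  df$.group <- droplevels(factor(df[[group_col]]))
  df <- df[!is.na(df$.group), ]
  groups <- levels(df$.group)
  if (length(groups) < 2) {
    abort_cnasurv("km_compare needs at least 2 groups",
                  class = "cnasurv_validation_error")
  }
  sf <- survival::survfit(survival::Surv(os_time, os_event) ~ .group,
                          data = df)
  strata_grp <- rep(sub("^\\.group=", "", names(sf$strata)), sf$strata)
  curves <- tibble::tibble(
    group = strata_grp, time = sf$time, n_risk = sf$n.risk,
    n_event = sf$n.event, surv = sf$surv,
    conf.low = sf$lower, conf.high = sf$upper)
  st <- summary(sf)$table
  medians <- tibble::tibble(
    group = sub("^\\.group=", "", rownames(st)),
    n = unname(st[, "records"]), n_events = unname(st[, "events"]),
    median = unname(st[, "median"]))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    sub <- df[df$.group %in% pr, ]
    sub$.group <- factor(sub$.group, levels = pr)
    ev <- tapply(sub$os_event, sub$.group, sum)
    lr <- survival::survdiff(survival::Surv(os_time, os_event) ~ .group,
                             data = sub)
    logrank_p <- pchisq(lr$chisq, df = 1, lower.tail = FALSE)
    if (any(ev == 0)) {
      return(tibble::tibble(group_1 = pr[1], group_2 = pr[2], hr = NA_real_,
                            conf.low = NA_real_, conf.high = NA_real_,
                            p.value = NA_real_, logrank_p = logrank_p,
                            converged = NA))
    }
    converged <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(os_time, os_event) ~ .group,
                      data = sub, ties = "efron"),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    tibble::tibble(group_1 = pr[1], group_2 = pr[2],
                   hr = s$conf.int[1, "exp(coef)"],
                   conf.low = s$conf.int[1, "lower .95"],
                   conf.high = s$conf.int[1, "upper .95"],
                   p.value = s$coefficients[1, "Pr(>|z|)"],
                   logrank_p = logrank_p, converged = converged)
  })
  structure(list(curves = curves, medians = medians, pairwise = pairwise,
                 group_col = group_col),
            class = "cna_km")
}

#' @export
print.cna_km <- function(x, ...) {
  cat(sprintf("<cna_km> %d group(s) on '%s'\n", nrow(x$medians), x$group_col))
  print(x$medians)
  cat("pairwise comparisons:\n")
  print(x$pairwise)
  invisible(x)
}

#' Search the optimal score-binarization percentile
#'
#' For each candidate percentile, binarizes the score within cancer types,
#' fits the multivariable proportional-hazards model
#' `score_high + tmb_high + drug_class` (TMB binned at the
#' `tmb_percentile`), and records the score hazard ratio with its Wald P
#' value, Bonferroni-corrected over the number of candidates. The chosen
#' percentile is the candidate with the highest hazard ratio among those
#' with corrected P below `alpha`; when none passes, the result carries an
#' explicit "none chosen" state. Optionally a leave-one-out refit per
#' patient provides a stability diagnostic (the spread of hazard ratios when
#' any single patient is dropped); selection always uses the full-cohort
#' fit.
#'
#' @param cohort Clinical table joined with the score column.
#' @param score_col Name of the score column.
#' @param candidates Candidate percentiles (default `seq(20, 80, 10)`).
#' @param alpha Significance level on the Bonferroni-corrected P (default
#'   0.05).
#' @param tmb_percentile TMB binarization percentile (default 80).
#' @param stratify_by_type Passed to [fit_cox()].
#' @param loo Run the leave-one-out stability diagnostic? Default `FALSE`
#'   (it refits the model once per patient and candidate).
#' @return An object of class `cna_search`: a tibble with one row per
#'   candidate (`percentile`, `hr`, `conf.low`, `conf.high`, `p.value`,
#'   `p_bonferroni`, `chosen`, and with `loo` the leave-one-out `loo_hr_sd`,
#'   `loo_hr_min`, `loo_hr_max`), with the chosen percentile (or `NA`) in
#'   `attr(, "chosen")`.
#' @export
search_binarization <- function(cohort, score_col,
                                candidates = seq(20, 80, 10), alpha = 0.05,
                                tmb_percentile = 80, stratify_by_type = FALSE,
                                loo = FALSE) {
  assert_columns(cohort, c("sample_id", "cancer_type", "tmb", "os_time",
                           "os_event", "drug_class", score_col), "cohort")
  stopifnot(length(candidates) >= 1, all(candidates > 0 & candidates < 100))
  covars <- c("score_high", "tmb_high")
  if (length(unique(cohort$drug_class)) > 1) {
    covars <- c(covars, "drug_class")
  } else {
    rlang::inform("search_binarization: drug_class is constant, dropped from the model")
  }
  one_fit <- function(df, pct) {
    binned <- bin_cohort(df, df[, c("sample_id", score_col)],
                         score_col = score_col, score_percentile = pct,
                         tmb_percentile = tmb_percentile)
    fit <- fit_cox(binned, covariates = covars,
                   stratify_by_type = stratify_by_type)
    fit$terms[fit$terms$term == "score_highTRUE", ]
  }
  res <- purrr::map_dfr(candidates, function(pct) {
    row <- one_fit(cohort, pct)
    out <- tibble::tibble(percentile = pct, hr = row$hr,
                          conf.low = row$conf.low, conf.high = row$conf.high,
                          p.value = row$p.value)
    if (loo) {
      loo_hr <- vapply(seq_len(nrow(cohort)), function(i) {
        one_fit(cohort[-i, ], pct)$hr
      }, numeric(1))
      out$loo_hr_sd <- stats::sd(loo_hr)
      out$loo_hr_min <- min(loo_hr)
      out$loo_hr_max <- max(loo_hr)
    }
    out
  })
  res$p_bonferroni <- pmin(1, res$p.value * length(candidates))
  eligible <- which(res$p_bonferroni < alpha)
  chosen <- if (length(eligible) == 0) NA_real_ else
    res$percentile[eligible[which.max(res$hr[eligible])]]
  res$chosen <- !is.na(chosen) & res$percentile == chosen
  attr(res, "chosen") <- chosen
  attr(res, "alpha") <- alpha
  class(res) <- c("cna_search", class(tibble::tibble()))
  res
}

#' Paired comparison of per-cancer-type hazard ratios
#'
#' Two-sided Wilcoxon signed-rank test on hazard ratios computed per cancer
#' type under two scoring schemes (e.g. two CNA-calling cutoffs), paired by
#' cancer type, plus the difference of mean hazard ratios
#' (`mean(b) - mean(a)`). Zero differences are dropped per the standard
#' signed-rank convention; if every pair is tied the P value is 1 with a
#' zero-variance warning.
#'
#' @param hrs_a,hrs_b Data frames with columns `cancer_type` and `hr`, the
#'   same cancer types in both (at least 5 in common).
#' @return A one-row tibble: `n_pairs`, `n_zero_diff`, `statistic`,
#'   `p.value`, `delta_mean_hr`.
#' @export
compare_hrs_paired <- function(hrs_a, hrs_b) {
  assert_columns(hrs_a, c("cancer_type", "hr"), "hrs_a")
  assert_columns(hrs_b, c("cancer_type", "hr"), "hrs_b")
  j <- dplyr::inner_join(hrs_a, hrs_b, by = "cancer_type",
                         suffix = c("_a", "_b"))
  if (nrow(j) < 5) {
    abort_cnasurv("compare_hrs_paired needs at least 5 shared cancer types",
                  class = "cnasurv_validation_error")
  }
  d <- j$hr_b - j$hr_a
  delta <- mean(j$hr_b) - mean(j$hr_a)
  n_zero <- sum(d == 0)
  if (all(d == 0)) {
    rlang::warn("all paired differences are zero: P = 1 (zero variance)")
    return(tibble::tibble(n_pairs = nrow(j), n_zero_diff = n_zero,
                          statistic = NA_real_, p.value = 1,
                          delta_mean_hr = 0))
  }
  wt <- suppressWarnings(wilcox.test(j$hr_b, j$hr_a, paired = TRUE,
                                     alternative = "two.sided"))
  tibble::tibble(n_pairs = nrow(j), n_zero_diff = n_zero,
                 statistic = unname(wt$statistic), p.value = wt$p.value,
                 delta_mean_hr = delta)
}

#' Required sample size for a two-group survival comparison
#'
#' Schoenfeld's formula for the number of events needed to detect a hazard
#' ratio `hr` between two groups at two-sided level `alpha` with the given
#' power:
#' \deqn{d = \frac{(z_{1-\alpha/2} + z_{power})^2}{p(1-p)(\ln hr)^2}}
#' where `p` is the fraction allocated to one group. The required total
#' sample size is `ceiling(d / psi)` with `psi` the overall probability of
#' observing an event. The sample size grows without bound as `hr`
#' approaches 1 and scales as `1/psi`.
#'
#' @param hr Target hazard ratio (> 0, != 1).
#' @param p Group-allocation fraction in (0, 1); 0.5 for balanced groups.
#' @param psi Overall event probability in (0, 1].
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.8).
#' @return A one-row tibble: the inputs plus `d_events` (required events,
#'   unrounded) and `n_required` (required total sample size).
#' @export
#' @examples
#' power_sample_size(hr = 2, p = 0.5, psi = 1)$n_required  # 66
power_sample_size <- function(hr, p = 0.5, psi = 1, alpha = 0.05,
                              power = 0.8) {
  stopifnot(p > 0, p < 1, psi > 0, psi <= 1, alpha > 0, alpha < 1,
            power > 0, power < 1)
  if (hr <= 0 || hr == 1) {
    abort_cnasurv("hr must be positive and different from 1",
                  class = "cnasurv_infeasible")
  }
  d <- (qnorm(1 - alpha / 2) + qnorm(power))^2 / (p * (1 - p) * log(hr)^2)
  tibble::tibble(hr = hr, p = p, psi = psi, alpha = alpha, power = power,
                 d_events = d, n_required = ceiling(d / psi))
}

#' Differential gene-mutation frequency between score groups
#'
#' For every gene, compares the mutation frequency between score-high and
#' score-low patients with a 2x2 chi-squared test (no continuity
#' correction) and applies Bonferroni correction across the genes actually
#' tested. Genes mutated in no patient of either group are untestable and
#' skipped (flagged, not silently dropped).
#'
#' @param mutations A validated mutation matrix ([read_mutations()]).
#' @param groups A data frame with `sample_id` and a logical/0-1 column
#'   named by `group_col` splitting patients into the two groups.
#' @param group_col Name of the grouping column (default `"score_high"`).
#' @return A tibble with one row per gene: `gene`, `n_high`, `n_low`,
#'   `freq_high`, `freq_low`, `statistic`, `p.value`, `p_bonferroni`,
#'   `testable`.
#' @export
mutation_frequency_diff <- function(mutations, groups,
                                    group_col = "score_high") {
  assert_columns(groups, c("sample_id", group_col), "group table")
  mut <- tibble::as_tibble(mutations)
  df <- dplyr::inner_join(mut, groups[, c("sample_id", group_col)],
                          by = "sample_id")
  g <- as.logical(df[[group_col]])
  if (sum(g) == 0 || sum(!g) == 0) {
    abort_cnasurv("both score groups must be non-empty",
                  class = "cnasurv_validation_error")
  }
  genes <- setdiff(names(mut), "sample_id")
  res <- purrr::map_dfr(genes, function(gene) {
    x <- df[[gene]]
    a <- sum(x[g]); b <- sum(g) - a       # high: mutated / wild type
    c_ <- sum(x[!g]); d <- sum(!g) - c_   # low
    testable <- (a + c_) > 0 && (b + d) > 0
    if (!testable) {
      return(tibble::tibble(gene = gene, n_high = sum(g), n_low = sum(!g),
                            freq_high = a / sum(g), freq_low = c_ / sum(!g),
                            statistic = NA_real_, p.value = NA_real_,
                            testable = FALSE))
    }
    ct <- suppressWarnings(
      chisq.test(matrix(c(a, b, c_, d), nrow = 2), correct = FALSE))
    tibble::tibble(gene = gene, n_high = sum(g), n_low = sum(!g),
                   freq_high = a / sum(g), freq_low = c_ / sum(!g),
                   statistic = unname(ct$statistic),
                   p.value = ct$p.value, testable = TRUE)
  })
  n_tested <- sum(res$testable)
  res$p_bonferroni <- pmin(1, res$p.value * n_tested)
  if (any(!res$testable)) {
    rlang::inform(sprintf(
      "mutation_frequency_diff: %d gene(s) with no mutations were untestable",
      sum(!res$testable)))
  }
  res
}
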