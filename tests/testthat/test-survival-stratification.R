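test_that("binarization splits within each cancer type at the percentile", {
  df <- tibble::tibble(cancer_type = "A", v = 1:10)
  out <- binarize_within_type(df, "v", 60)
  expect_equal(sum(out$v_high), 4)
  expect_equal(out$v_high, df$v > 6)

  # all values identical: everyone low
  same <- tibble::tibble(cancer_type = "A", v = rep(2, 8))
  expect_true(all(!binarize_within_type(same, "v", 50)$v_high))

  # disjoint ranges are binarized per type, not globally
  two <- tibble::tibble(cancer_type = rep(c("A", "B"), each = 10),
                        v = c(1:10, 101:110))
  out2 <- binarize_within_type(two, "v", 50)
  expect_equal(sum(out2$v_high[two$cancer_type == "A"]), 5)
  expect_equal(sum(out2$v_high[two$cancer_type == "B"]), 5)

  tiny <- tibble::tibble(cancer_type = c("A", "A", "B"), v = c(1, 2, 3))
  expect_warning(out3 <- binarize_within_type(tiny, "v", 50), "B")
  expect_true(is.na(out3$v_high[3]))
})

test_that("binarization is idempotent", {
  df <- tibble::tibble(cancer_type = rep(c("A", "B"), each = 20),
                       v = withr::with_seed(1, runif(40)))
  for (pct in c(20, 50, 80)) {
    once <- binarize_within_type(df, "v", pct)$v_high
    again <- binarize_within_type(
      dplyr::mutate(df, v = as.numeric(once)), "v", pct)$v_high
    expect_equal(again, once)
  }
})

test_that("tmb_high marks the top 20% within each cancer type", {
  df <- tibble::tibble(
    sample_id = as.character(1:200),
    cancer_type = rep(c("A", "B"), each = 100),
    tmb = withr::with_seed(3, rlnorm(200, log(5), 1)),
    os_time = 1, os_event = 1, drug_class = "PD-1/PD-L1")
  scores <- tibble::tibble(sample_id = df$sample_id,
                           fga = withr::with_seed(4, runif(200)))
  bc <- bin_cohort(df, scores, score_percentile = 50)
  prop <- tapply(bc$tmb_high, bc$cancer_type, mean)
  expect_true(all(abs(prop - 0.2) < 0.02))
  expect_true(all(levels(bc$group4) == c("TMB-H/Score-L", "TMB-H/Score-H",
                                         "TMB-L/Score-L", "TMB-L/Score-H")))
})

test_that("Cox fit matches an independent partial-likelihood maximiser", {
  df <- withr::with_seed(17, {
    d <- sim_two_group_surv(300, beta = 0.4)
    # no ties, no censoring for the oracle
    d$os_time <- d$os_time + seq_len(300) * 1e-9
    d$os_event <- 1
    d
  })
  fit <- fit_cox(df, covariates = "score_high")
  beta_hat <- tidy(fit)$estimate
  beta_oracle <- oracle_cox_binary(df$os_time, df$score_high)
  expect_lt(abs(beta_hat - beta_oracle), 1e-6)
})

test_that("Cox recovery: CI coverage near nominal, null P near uniform", {
  n_rep <- 60
  covered <- withr::with_seed(23, vapply(seq_len(n_rep), function(i) {
    df <- sim_two_group_surv(800, beta = log(1.35), censor = 60)
    t <- tidy(fit_cox(df, covariates = "score_high"))
    t$conf.low <= 1.35 && 1.35 <= t$conf.high
  }, logical(1)))
  expect_gte(mean(covered), 0.85)

  null_p <- withr::with_seed(29, vapply(seq_len(n_rep), function(i) {
    df <- sim_two_group_surv(400, beta = 0, censor = 60)
    tidy(fit_cox(df, covariates = "score_high"))$p.value
  }, numeric(1)))
  expect_gt(mean(null_p), 0.35)
  expect_lt(mean(null_p), 0.65)
  expect_gt(suppressWarnings(stats::ks.test(null_p, "punif")$p.value), 0.01)
})

test_that("Cox preconditions: events and non-constant covariates", {
  df <- sim_two_group_surv(50, beta = 0)
  none <- df; none$os_event <- 0
  expect_error(fit_cox(none, covariates = "score_high"),
               class = "cnasurv_no_events")
  const <- df; const$score_high <- TRUE
  expect_error(fit_cox(const, covariates = "score_high"),
               class = "cnasurv_validation_error")
})

test_that("KM product-limit estimates drop by 1/n at each death", {
  df <- tibble::tibble(
    os_time = c(1, 2, 3, 4, 5, 6), os_event = 1,
    grp = rep(c("g1", "g2"), each = 3))
  km <- km_compare(df, group_col = "grp")
  g1 <- km$curves[km$curves$group == "g1", ]
  expect_equal(g1$surv, c(2 / 3, 1 / 3, 0))
  # group 2 (deaths at 4,5,6) dominates group 1 (deaths at 1,2,3)
  expect_equal(glance(km)$median[glance(km)$group == "g2"], 5)
  expect_equal(glance(km)$median[glance(km)$group == "g1"], 2)

  # identical groups: HR = 1
  same <- tibble::tibble(os_time = rep(c(1, 2, 3, 4), 2), os_event = 1,
                         grp = rep(c("a", "b"), each = 4))
  expect_equal(tidy(km_compare(same, "grp"))$hr, 1, tolerance = 1e-9)

  # zero-event group: HR reported missing, log-rank still defined
  zero <- tibble::tibble(os_time = c(1, 2, 3, 10, 10, 10),
                         os_event = c(1, 1, 1, 0, 0, 0),
                         grp = rep(c("a", "b"), each = 3))
  pw <- tidy(km_compare(zero, "grp"))
  expect_true(is.na(pw$hr))
  expect_false(is.na(pw$logrank_p))
})

test_that("percentile search finds a constructed 60th-percentile effect", {
  cfg <- sim_config(n_samples = 400, cancer_types = c("a", "b"),
                    score_percentile = 60, beta_score = log(1.6),
                    beta_tmb = 0, beta_drug = c("CTLA-4" = 0, "Combo" = 0))
  truth <- tibble::tibble(
    sample_id = as.character(1:800),
    cancer_type = rep(c("a", "b"), each = 400),
    true_as = withr::with_seed(31, runif(800)))
  clin <- simulate_survival(truth, cfg, seed = 33)
  clin$score <- truth$true_as
  clin$score_high <- NULL
  res <- search_binarization(clin, "score")
  expect_s3_class(res, "cna_search")
  expect_equal(nrow(res), 7)
  expect_equal(attr(res, "chosen"), 60)
  expect_equal(res$percentile[res$chosen], 60)
  expect_true(all(res$p_bonferroni >= res$p.value - 1e-15))
})

test_that("null cohorts usually yield an explicit none-chosen state", {
  cfg <- sim_config(n_samples = 150, cancer_types = "a", beta_score = 0,
                    beta_tmb = 0, beta_drug = c("CTLA-4" = 0, "Combo" = 0))
  none <- withr::with_seed(41, vapply(1:15, function(i) {
    truth <- tibble::tibble(sample_id = as.character(1:150),
                            cancer_type = "a", true_as = runif(150))
    clin <- simulate_survival(truth, cfg, seed = 1000 + i)
    clin$score <- truth$true_as
    clin$score_high <- NULL
    is.na(attr(search_binarization(clin, "score"), "chosen"))
  }, logical(1)))
  expect_gte(mean(none), 0.8)
})

test_that("leave-one-out diagnostic reports a tight HR spread", {
  cfg <- sim_config(n_samples = 80, cancer_types = "a",
                    beta_score = log(2), beta_tmb = 0,
                    beta_drug = c("CTLA-4" = 0, "Combo" = 0))
  truth <- tibble::tibble(sample_id = as.character(1:80), cancer_type = "a",
                          true_as = withr::with_seed(43, runif(80)))
  clin <- simulate_survival(truth, cfg, seed = 44)
  clin$score <- truth$true_as
  clin$score_high <- NULL
  res <- search_binarization(clin, "score", candidates = 50, loo = TRUE)
  expect_true(all(c("loo_hr_sd", "loo_hr_min", "loo_hr_max") %in% names(res)))
  expect_lte(res$loo_hr_min, res$hr)
  expect_gte(res$loo_hr_max, res$hr)
  # dropping one of 80 patients cannot move the HR wildly
  expect_lt(res$loo_hr_sd / res$hr, 0.25)
})

test_that("paired HR comparison matches the exact signed-rank tail", {
  hrs_a <- tibble::tibble(cancer_type = letters[1:10],
                          hr = seq(0.8, 1.7, 0.1))
  hrs_b <- dplyr::mutate(hrs_a, hr = hr + seq(0.05, 0.5, 0.05))
  res <- compare_hrs_paired(hrs_a, hrs_b)
  expect_equal(res$statistic, 55)  # all ranks on one side
  expect_equal(res$p.value, 2 * oracle_signed_rank_tail(10, 55))
  expect_equal(res$delta_mean_hr, mean(hrs_b$hr) - mean(hrs_a$hr))

  # identity: P = 1, delta = 0, zero-variance warning
  expect_warning(same <- compare_hrs_paired(hrs_a, hrs_a), "zero")
  expect_equal(same$p.value, 1)
  expect_equal(same$delta_mean_hr, 0)

  # a tied pair is dropped per signed-rank convention
  hrs_c <- hrs_b; hrs_c$hr[1] <- hrs_a$hr[1]
  res2 <- compare_hrs_paired(hrs_a, hrs_c)
  expect_equal(res2$n_zero_diff, 1)
  expect_equal(res2$statistic, 45)  # ranks 1..9 on one side

  expect_error(compare_hrs_paired(hrs_a[1:3, ], hrs_b[1:3, ]),
               class = "cnasurv_validation_error")
})

test_that("Schoenfeld sample size matches an independent power calculation", {
  expect_equal(power_sample_size(hr = 2, p = 0.5, psi = 1)$n_required, 66)
  for (hr in c(1.35, 1.5, 2, 3)) {
    for (psi in c(0.5, 1)) {
      got <- power_sample_size(hr, p = 0.5, psi = psi)$n_required
      expect_equal(got, oracle_power_n(hr, 0.5, psi))
    }
  }
  # monotone in hr towards 1
  hr_grid <- c(3, 2, 1.5, 1.25, 1.1, 1.05)
  ns <- vapply(hr_grid, function(h) power_sample_size(h)$n_required,
               numeric(1))
  expect_true(all(diff(ns) > 0))
  # 1/psi scaling (up to the ceiling)
  n1 <- power_sample_size(1.5, psi = 1)
  n2 <- power_sample_size(1.5, psi = 0.5)
  expect_equal(n2$d_events, n1$d_events)
  expect_equal(n2$n_required, ceiling(n1$d_events / 0.5))
  expect_error(power_sample_size(1), class = "cnasurv_infeasible")
})

test_that("mutation frequency chi-squared matches the closed form", {
  groups <- tibble::tibble(sample_id = as.character(1:200),
                           score_high = rep(c(TRUE, FALSE), each = 100))
  mut <- tibble::tibble(
    sample_id = groups$sample_id,
    GENE_DIFF = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)),
    GENE_SAME = rep(c(1, 0, 0, 0), 50),
    GENE_NONE = 0)
  expect_message(res <- mutation_frequency_diff(mut, groups), "untestable")
  diff_row <- res[res$gene == "GENE_DIFF", ]
  expect_equal(diff_row$statistic, oracle_chisq_2x2(30, 70, 10, 90))
  expect_equal(diff_row$statistic, 12.5)
  expect_equal(diff_row$freq_high, 0.3)
  expect_equal(diff_row$freq_low, 0.1)
  same_row <- res[res$gene == "GENE_SAME", ]
  expect_equal(same_row$statistic, 0)
  expect_equal(same_row$p.value, 1)
  expect_false(res$testable[res$gene == "GENE_NONE"])
  # Bonferroni over the 2 testable genes only
  expect_equal(diff_row$p_bonferroni, min(1, diff_row$p.value * 2))
})
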