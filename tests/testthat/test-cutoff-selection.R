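grid_default <- seq(0.01, 0.5, by = 0.01)

test_that("elbow of a piecewise-linear curve sits at the slope break", {
  y <- ifelse(grid_default <= 0.2, 1 - 4 * (grid_default - 0.01),
              (1 - 4 * (0.2 - 0.01)) - 0.1 * (grid_default - 0.2))
  curve <- tibble::tibble(cutoff = grid_default, value = y)
  expect_equal(find_elbow(curve), 0.2)
  expect_equal(find_elbow(curve), oracle_elbow(grid_default, y))
})

test_that("elbow of an exponential decay matches the brute-force oracle", {
  y <- exp(-grid_default / 0.1)
  curve <- tibble::tibble(cutoff = grid_default, value = y)
  expect_equal(find_elbow(curve), oracle_elbow(grid_default, y))
  # a slower decay moves the elbow right
  y2 <- exp(-grid_default / 0.2)
  expect_gt(find_elbow(tibble::tibble(cutoff = grid_default, value = y2)),
            find_elbow(curve))
})

test_that("degenerate curves are rejected", {
  line <- tibble::tibble(cutoff = grid_default, value = 1 - grid_default)
  expect_error(find_elbow(line), class = "cnasurv_no_knee")
  flat <- tibble::tibble(cutoff = grid_default, value = 0.5)
  expect_error(find_elbow(flat), class = "cnasurv_no_knee")
  rising <- tibble::tibble(cutoff = grid_default, value = grid_default)
  expect_error(find_elbow(rising), class = "cnasurv_validation_error")
  short <- tibble::tibble(cutoff = 1:4 / 10, value = c(1, 0.5, 0.4, 0.39))
  expect_error(find_elbow(short), class = "cnasurv_validation_error")
})

test_that("elbow is invariant to shift and positive rescaling of the curve", {
  y <- exp(-grid_default / 0.08)
  base <- find_elbow(tibble::tibble(cutoff = grid_default, value = y))
  for (tr in list(function(v) v + 3, function(v) 7 * v,
                  function(v) 0.2 * v - 5)) {
    expect_equal(
      find_elbow(tibble::tibble(cutoff = grid_default, value = tr(y))),
      base)
  }
})

test_that("bootstrap elbow recovers a constructed knee with a sane CI", {
  kc <- make_knee_cohort(knee_location = 0.2, n_samples = 120, seed = 11)
  res <- bootstrap_elbow(kc, score = "value", n_bootstrap = 300, seed = 3)
  expect_s3_class(res, "cna_elbow")
  expect_lte(abs(res$elbow_point - 0.2), 0.01)
  expect_lte(res$ci_low, res$elbow_point)
  expect_gte(res$ci_high, res$elbow_point)
  expect_equal(res$n_noknee, 0)
})

test_that("bootstrap of identical samples is degenerate and deterministic", {
  one <- make_knee_cohort(0.2, n_samples = 1, seed = 1,
                          scale_sd = 0, shift_sd = 0, noise_sd = 0)
  many <- dplyr::bind_rows(lapply(1:10, function(i) {
    d <- one; d$sample_id <- paste0("C", i); d
  }))
  res <- bootstrap_elbow(many, score = "value", n_bootstrap = 100, seed = 9)
  expect_equal(res$ci_low, res$elbow_point)
  expect_equal(res$ci_high, res$elbow_point)
  expect_equal(res$elbow_point, 0.2)
  # identical seed, identical result
  res2 <- bootstrap_elbow(many, score = "value", n_bootstrap = 100, seed = 9)
  expect_identical(res, res2)
  # different seed still the same point estimate (it ignores the RNG)
  res3 <- bootstrap_elbow(many, score = "value", n_bootstrap = 100, seed = 10)
  expect_equal(res3$elbow_point, res$elbow_point)
})

test_that("bootstrap CI narrows as the cohort grows", {
  width <- vapply(c(40, 400), function(n) {
    kc <- make_knee_cohort(0.2, n_samples = n, seed = 21,
                           scale_sd = 0.3, noise_sd = 0.05)
    r <- bootstrap_elbow(kc, score = "value", n_bootstrap = 300, seed = 5)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_lte(width[2], width[1] + 0.01)  # one grid step of slack
})

test_that("gmm_cutoff recovers the equal-posterior boundary of a known mixture", {
  vals <- withr::with_seed(101, {
    comp <- rbinom(10000, 1, 0.5)
    abs(rnorm(10000, ifelse(comp == 1, 0.4, 0.05),
              ifelse(comp == 1, 0.05, 0.02)))
  })
  res <- gmm_cutoff(vals, seed = 7)
  truth <- oracle_gmm_boundary(0.05, 0.02, 0.5, 0.4, 0.05, 0.5)
  expect_lt(abs(res$cutoff - truth), 0.02)
  expect_gt(res$cutoff, res$mean_1)
  expect_lt(res$cutoff, res$mean_2)
  # determinism
  expect_identical(res, gmm_cutoff(vals, seed = 7))
})

test_that("gmm_cutoff rejects unimodal and degenerate inputs", {
  vals <- withr::with_seed(5, abs(rnorm(2000, 0.1, 0.05)))
  expect_error(gmm_cutoff(vals, seed = 1),
               class = "cnasurv_degenerate_mixture")
  expect_error(gmm_cutoff(rep(0.1, 30), seed = 1),
               class = "cnasurv_degenerate_mixture")
  expect_error(gmm_cutoff(runif(10), seed = 1),
               class = "cnasurv_validation_error")
  expect_error(gmm_cutoff(c(-0.1, runif(30)), seed = 1),
               class = "cnasurv_validation_error")
})

test_that("a high-purity subset drags the mixture cutoff above the elbow and zeroes AS", {
  # low-purity majority: events sit just above the noise floor; pure-tumor
  # minority: events at log2(1.5)/1.0 push the altered component high
  lo <- simulate_segments(sim_config(cancer_types = "lo", n_samples = 150,
                                     noise_sd = 0.08, purity_fixed = 0.2),
                          seed = 5)
  hi <- simulate_segments(sim_config(cancer_types = "hi", n_samples = 50,
                                     noise_sd = 0.08, purity_fixed = 1),
                          seed = 6)
  seg <- dplyr::bind_rows(lo$segments, hi$segments)
  g <- gmm_cutoff(abs(seg$log2_ratio), seed = 7)
  sweep <- score_sweep(seg)
  mc <- suppressMessages(cohort_mean_curve(sweep, "as"))
  elb <- find_elbow(mc[, c("cutoff", "value")])
  expect_gt(g$cutoff, elb)
  zero_gmm <- mean(compute_scores(seg, cutoff = g$cutoff)$as_score == 0,
                   na.rm = TRUE)
  zero_elb <- mean(compute_scores(seg, cutoff = elb)$as_score == 0,
                   na.rm = TRUE)
  expect_gt(zero_gmm, 0.3)   # a large share of samples lose all events
  expect_lt(zero_elb, 0.1)   # the elbow cutoff keeps them
})

test_that("two point masses give a boundary strictly between them", {
  vals <- c(rep(0.1, 60), rep(0.4, 40))
  res <- gmm_cutoff(vals, seed = 2)
  expect_gt(res$cutoff, 0.1)
  expect_lt(res$cutoff, 0.4)
})
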