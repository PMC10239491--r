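test_that("FGA matches the closed-form length-weighted fraction", {
  seg <- toy_seg(c(1, 40e6, 0.5), c(40e6 + 1, 100e6, 0.0))
  expect_equal(compute_fga(seg, cutoff = 0.2)$fga, 0.4)
  # nothing qualifies below the cutoff
  seg2 <- toy_seg(c(1, 50e6, 0.1), c(50e6 + 1, 100e6, -0.19))
  expect_equal(compute_fga(seg2, cutoff = 0.2)$fga, 0)
  # whole genome altered
  seg3 <- toy_seg(c(1, 100e6, 1.0))
  expect_equal(compute_fga(seg3, cutoff = 0.2)$fga, 1)
  expect_error(compute_fga(seg[0, ], cutoff = 0.2),
               class = "cnasurv_undefined_score")
})

test_that("FGA boundary rule only matters for segments exactly at the cutoff", {
  seg <- toy_seg(c(1, 10e6, 0.2), c(10e6 + 1, 100e6, 0.0))
  expect_equal(compute_fga(seg, 0.2, boundary = ">=")$fga, 0.1)
  expect_equal(compute_fga(seg, 0.2, boundary = ">")$fga, 0)
  # no segment at the boundary: rules agree
  seg2 <- toy_seg(c(1, 10e6, 0.25), c(10e6 + 1, 100e6, 0.05))
  expect_equal(compute_fga(seg2, 0.2, boundary = ">=")$fga,
               compute_fga(seg2, 0.2, boundary = ">")$fga)
})

test_that("arm calls follow coverage and dominance rules", {
  # full-coverage gain
  seg <- toy_seg(c(1, 100e6, 0.5))
  calls <- call_arm_events(seg, toy_arms, cutoff = 0.2)
  expect_equal(nrow(calls), 4)  # one row per sample x arm
  expect_equal(calls$call[calls$arm == "1p"], "GAIN")
  expect_equal(sum(calls$call == "NOT_EVALUABLE"), 3)

  # 60% gain / 40% neutral on a fully measured arm -> below 0.7 dominance
  seg2 <- toy_seg(c(1, 60e6, 0.5), c(60e6 + 1, 100e6, 0.0))
  calls2 <- call_arm_events(seg2, toy_arms, cutoff = 0.2)
  expect_equal(calls2$call[calls2$arm == "1p"], "NO_CALL")

  # 30% of the arm measured -> coverage gate
  seg3 <- toy_seg(c(1, 30e6, 0.5))
  calls3 <- call_arm_events(seg3, toy_arms, cutoff = 0.2)
  expect_equal(calls3$call[calls3$arm == "1p"], "NOT_EVALUABLE")
  expect_equal(calls3$coverage[calls3$arm == "1p"], 0.3)

  # 80% loss of measured length -> LOSS
  seg4 <- toy_seg(c(1, 80e6, -0.5), c(80e6 + 1, 100e6, 0.0))
  calls4 <- call_arm_events(seg4, toy_arms, cutoff = 0.2)
  expect_equal(calls4$call[calls4$arm == "1p"], "LOSS")

  expect_error(call_arm_events(seg, toy_arms[0, ], cutoff = 0.2),
               class = "cnasurv_validation_error")
})

test_that("centromere-spanning segments are split between arms", {
  # one segment covering all of 1p and 40% of 1q at gain level
  seg <- toy_seg(c(1, 101e6 + 0.4 * 120e6 - 1, 0.5),
                 c(101e6 + 0.4 * 120e6, 220e6, 0.0))
  calls <- call_arm_events(seg, toy_arms, cutoff = 0.2)
  expect_equal(calls$call[calls$arm == "1p"], "GAIN")
  expect_equal(calls$call[calls$arm == "1q"], "NO_CALL")  # 40/60 split
})

test_that("AS is altered over evaluable arms", {
  calls <- tibble::tibble(
    sample_id = "S1",
    arm = paste0("a", 1:39),
    call = c(rep("GAIN", 3), rep("LOSS", 2), rep("NOT_EVALUABLE", 10),
             rep("NEUTRAL", 20), rep("NO_CALL", 4)))
  as_tbl <- compute_as(calls)
  expect_equal(as_tbl$as_score, 5 / 29)
  expect_equal(as_tbl$n_evaluable_arms, 29)

  none <- calls; none$call <- "NEUTRAL"
  expect_equal(compute_as(none)$as_score, 0)

  thirteen <- calls
  thirteen$call <- c(rep("GAIN", 13), rep("NEUTRAL", 26))
  expect_equal(compute_as(thirteen)$as_score, 13 / 39)

  lost <- calls; lost$call <- "NOT_EVALUABLE"
  expect_message(res <- compute_as(lost), "zero evaluable")
  expect_true(is.na(res$as_score))
})

test_that("arm caller and AS agree with the synthetic golden files", {
  golden_dir <- system.file("extdata", "golden", package = "cnasurv")
  seg <- read_seg(file.path(golden_dir, "toy_cohort.seg"))
  arms <- read_arm_coordinates()
  exp_calls <- readr::read_tsv(
    file.path(golden_dir, "golden_arm_calls_synthetic.tsv"),
    show_col_types = FALSE)
  exp_as <- readr::read_tsv(
    file.path(golden_dir, "golden_as_synthetic.tsv"),
    show_col_types = FALSE)
  for (t in c(0.1, 0.2)) {
    calls <- call_arm_events(seg, arms, cutoff = t)
    got <- dplyr::inner_join(
      exp_calls[exp_calls$cutoff == t, ],
      calls[, c("sample_id", "arm", "call")],
      by = c("sample_id", "arm"), suffix = c("_exp", "_got"))
    expect_equal(nrow(got), sum(exp_calls$cutoff == t))
    expect_equal(got$call_got, got$call_exp)

    as_got <- compute_as(calls)
    cmp <- dplyr::inner_join(exp_as[exp_as$cutoff == t, ], as_got,
                             by = "sample_id")
    expect_equal(cmp$as_score.y, cmp$as_score.x, tolerance = 1e-12)
    expect_equal(cmp$n_evaluable_arms, cmp$n_evaluable)
  }
})

test_that("score sweep is monotone, bounded, and averages correctly", {
  cfg <- sim_config(n_samples = 10, cancer_types = c("a", "b"))
  sim <- simulate_segments(cfg, seed = 42)
  sweep <- score_sweep(sim$segments, grid = seq(0.05, 0.5, by = 0.05))
  expect_true(all(sweep$fga >= 0 & sweep$fga <= 1))
  expect_true(all(sweep$as_score >= 0 & sweep$as_score <= 1, na.rm = TRUE))
  by_sample <- split(sweep, sweep$sample_id)
  for (d in by_sample) {
    d <- d[order(d$cutoff), ]
    expect_true(all(diff(d$fga) <= 1e-12))
    expect_true(all(diff(d$as_score) <= 1e-12))
  }
  # flat fully-gained genome: FGA = 1 at every cutoff up to the gain level
  arms <- read_arm_coordinates()
  flat <- tibble::tibble(sample_id = "F", chromosome = arms$chromosome,
                         start_bp = arms$start_bp, end_bp = arms$end_bp,
                         log2_ratio = 1.0)
  sw <- score_sweep(flat, grid = seq(0.1, 0.5, 0.1))
  expect_true(all(sw$fga == 1))
  expect_true(all(sw$as_score == 1))
  # cohort mean is the arithmetic mean
  two <- dplyr::bind_rows(
    tibble::tibble(sample_id = "A", cutoff = 0.1, fga = 0.2, as_score = 0.1),
    tibble::tibble(sample_id = "B", cutoff = 0.1, fga = 0.4, as_score = 0.3))
  mc <- cohort_mean_curve(two, score = "fga")
  expect_equal(mc$value, 0.3)
})

test_that("sweep rejects a malformed grid", {
  seg <- toy_seg(c(1, 100, 0.5))
  expect_error(score_sweep(seg, toy_arms, grid = c(0.2, 0.1)),
               class = "cnasurv_validation_error")
  expect_error(score_sweep(seg, toy_arms, grid = numeric(0)),
               class = "cnasurv_validation_error")
})
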