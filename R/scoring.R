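#' Fraction of genome altered (FGA)
#'
#' FGA at a CNA-calling cutoff `x` is the length-weighted fraction of the
#' measured genome lying in segments whose absolute log2 copy ratio reaches
#' the cutoff:
#' \deqn{FGA = \frac{\sum \mathrm{length}(|log2\ ratio| \ge x)}{\sum \mathrm{length}(\mathrm{all\ segments})}}
#' The boundary rule defaults to `">="` (segments sitting exactly at the
#' cutoff count as altered); `">"` is available because both conventions
#' circulate, and they differ only for samples with a segment exactly at the
#' cutoff.
#'
#' @param seg A validated segment table ([read_seg()]); may contain many
#'   samples.
#' @param cutoff Positive CNA-calling cutoff on the absolute log2 copy
#'   ratio.
#' @param boundary `">="` (default) or `">"`: whether a segment exactly at
#'   the cutoff counts as altered.
#' @param include_sex Include X/Y segments? Default `FALSE`, matching the
#'   autosomal convention of arm-level scoring.
#' @return A tibble with one row per sample: `sample_id`, `cutoff`, `fga`.
#' @export
#' @examples
#' seg <- tibble::tibble(
#'   sample_id = "S1", chromosome = "1",
#'   start_bp = c(1, 40e6 + 1), end_bp = c(40e6, 100e6),
#'   log2_ratio = c(0.5, 0))
#' compute_fga(seg, cutoff = 0.2)$fga  # 0.4
compute_fga <- function(seg, cutoff = 0.2, boundary = c(">=", ">"),
                        include_sex = FALSE) {
  boundary <- match.arg(boundary)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  seg <- validate_segments(seg)
  if (!include_sex) seg <- seg[is_autosome(seg$chromosome), ]
  if (nrow(seg) == 0) {
    abort_cnasurv("no segments to score: FGA is undefined",
                  class = "cnasurv_undefined_score")
  }
  len <- seg$end_bp - seg$start_bp + 1
  alr <- abs(seg$log2_ratio)
  hit <- if (boundary == ">=") alr >= cutoff else alr > cutoff
  seg |>
    dplyr::mutate(.len = len, .hit = hit) |>
    dplyr::summarise(fga = sum(.data$.len[.data$.hit]) / sum(.data$.len),
                     .by = "sample_id") |>
    dplyr::mutate(cutoff = cutoff, .after = "sample_id")
}

# clip segments to arm intervals; segments spanning the centromere contribute
# their within-arm portion to each arm separately
clip_to_arms <- function(seg, arms) {
  clipped <- dplyr::inner_join(
    seg[, c("sample_id", "chromosome", "start_bp", "end_bp", "log2_ratio")],
    arms[, c("arm", "chromosome", "start_bp", "end_bp", "arm_length")],
    by = "chromosome", suffix = c("", ".arm"), relationship = "many-to-many")
  clipped$clip_start <- pmax(clipped$start_bp, clipped$start_bp.arm)
  clipped$clip_end <- pmin(clipped$end_bp, clipped$end_bp.arm)
  clipped <- clipped[clipped$clip_end >= clipped$clip_start, ]
  clipped$len <- clipped$clip_end - clipped$clip_start + 1
  clipped[, c("sample_id", "arm", "arm_length", "len", "log2_ratio")]
}

# shared worker: per (sample, arm) category coverage at one or many cutoffs.
# Returns a list with the per-group measured lengths (cutoff-independent) and
# a function giving gain/loss lengths per group at a cutoff.
arm_coverage_engine <- function(seg, arms, include_sex = FALSE) {
  seg <- validate_segments(seg)
  arms <- if (inherits(arms, "cna_arms")) arms else
    validate_arms_df(arms)
  if (nrow(arms) == 0) {
    abort_cnasurv("empty arm table", class = "cnasurv_validation_error")
  }
  if (!include_sex) seg <- seg[is_autosome(seg$chromosome), ]
  samples <- unique(seg$sample_id)
  clipped <- clip_to_arms(seg, arms)
  # index every (sample, arm) pair, including unmeasured ones
  full <- tidyr::expand_grid(sample_id = samples, arm = arms$arm)
  key <- paste(clipped$sample_id, clipped$arm, sep = "\r")
  full_key <- paste(full$sample_id, full$arm, sep = "\r")
  grp <- match(key, full_key)
  measured <- numeric(nrow(full))
  ms <- rowsum(clipped$len, grp)
  measured[as.integer(rownames(ms))] <- ms[, 1]
  arm_len <- arms$arm_length[match(full$arm, arms$arm)]
  list(
    full = full, measured = measured, arm_length = arm_len,
    coverage = measured / arm_len,
    category_lengths = function(cutoff) {
      gain <- clipped$log2_ratio >= cutoff
      loss <- clipped$log2_ratio <= -cutoff
      g <- l <- numeric(nrow(full))
      if (any(gain)) {
        gs <- rowsum(clipped$len[gain], grp[gain])
        g[as.integer(rownames(gs))] <- gs[, 1]
      }
      if (any(loss)) {
        ls <- rowsum(clipped$len[loss], grp[loss])
        l[as.integer(rownames(ls))] <- ls[, 1]
      }
      list(gain = g, loss = l)
    }
  )
}

# internal: accept a plain arms data.frame (already-validated tables pass
# through read_arm_coordinates)
validate_arms_df <- function(arms) {
  assert_columns(arms, c("arm", "chromosome", "start_bp", "end_bp"),
                 "arm table")
  arms <- tibble::as_tibble(arms)
  if (!"arm_length" %in% names(arms)) {
    arms$arm_length <- arms$end_bp - arms$start_bp + 1
  }
  class(arms) <- c("cna_arms", class(tibble::tibble()))
  arms
}

arm_calls_from_lengths <- function(eng, cat, arm_call_fraction,
                                   min_arm_coverage) {
  measured <- eng$measured
  neutral <- measured - cat$gain - cat$loss
  call <- rep("NO_CALL", length(measured))
  with_m <- measured > 0
  frac <- function(x) ifelse(with_m, x / pmax(measured, 1), 0)
  fg <- frac(cat$gain); fl <- frac(cat$loss); fn <- frac(neutral)
  top <- pmax(fg, fl, fn)
  dominant <- ifelse(top < arm_call_fraction, "NO_CALL",
              ifelse(fg == top, "GAIN",
              ifelse(fl == top, "LOSS", "NEUTRAL")))
  call[with_m] <- dominant[with_m]
  call[eng$coverage < min_arm_coverage] <- "NOT_EVALUABLE"
  call
}

#' Call arm-level copy-number events
#'
#' Classifies every chromosome arm of every sample as `GAIN`, `LOSS`,
#' `NEUTRAL`, `NO_CALL` (evaluable, but no dominant category) or
#' `NOT_EVALUABLE` (insufficient measured coverage). Segments are clipped to
#' arm intervals (a segment spanning the centromere contributes its
#' within-arm portion to each arm separately); per arm, the length-weighted
#' coverage of the categories gain (log2 ratio >= cutoff), loss (<= -cutoff)
#' and neutral is computed. An arm is evaluable when at least
#' `min_arm_coverage` of its length is measured; an evaluable arm receives a
#' category call when that category covers at least `arm_call_fraction` of
#' the measured length. The defaults (0.7 and 0.5, 39 autosomal arms) are
#' the published defaults of the standard arm-calling tool for targeted
#' panels.
#'
#' @inheritParams compute_fga
#' @param arms Arm coordinate table ([read_arm_coordinates()]); default the
#'   bundled hg19 autosomal table.
#' @param arm_call_fraction Fraction of the measured arm length a dominant
#'   category must cover for a call (default 0.7).
#' @param min_arm_coverage Minimum measured fraction of the arm length for
#'   the arm to be evaluable (default 0.5).
#' @return A tibble of class `cna_arm_calls`, exactly one row per
#'   (sample, arm): `sample_id`, `arm`, `call`, `coverage`, plus the cutoff
#'   as an attribute.
#' @export
call_arm_events <- function(seg, arms = read_arm_coordinates(), cutoff = 0.2,
                            arm_call_fraction = 0.7, min_arm_coverage = 0.5,
                            include_sex = FALSE) {
  stopifnot(cutoff > 0, arm_call_fraction > 0, arm_call_fraction <= 1,
            min_arm_coverage > 0, min_arm_coverage <= 1)
  eng <- arm_coverage_engine(seg, arms, include_sex)
  call <- arm_calls_from_lengths(eng, eng$category_lengths(cutoff),
                                 arm_call_fraction, min_arm_coverage)
  out <- eng$full
  out$call <- call
  out$coverage <- pmin(eng$coverage, 1)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("cna_arm_calls", class(tibble::tibble()))
  out
}

#' Aneuploidy score (AS) from arm-level calls
#'
#' AS is the fraction of evaluable chromosome arms carrying an arm-level
#' copy-number alteration:
#' \deqn{AS = \frac{\#GAIN + \#LOSS}{\#\mathrm{arms\ not\ NOT\_EVALUABLE}}}
#' Arms with insufficient measured coverage are excluded from the
#' denominator (counting unmeasured arms as unaltered would bias AS downward
#' on targeted panels). A sample with zero evaluable arms gets `NA` with a
#' message.
#'
#' @param arm_calls Output of [call_arm_events()].
#' @return A tibble: `sample_id`, `as_score`, `n_altered`,
#'   `n_evaluable_arms`.
#' @export
compute_as <- function(arm_calls) {
  assert_columns(arm_calls, c("sample_id", "arm", "call"), "arm-call table")
  out <- arm_calls |>
    dplyr::summarise(
      n_altered = sum(.data$call %in% c("GAIN", "LOSS")),
      n_evaluable_arms = sum(.data$call != "NOT_EVALUABLE"),
      .by = "sample_id") |>
    dplyr::mutate(as_score = ifelse(.data$n_evaluable_arms > 0,
                                    .data$n_altered / .data$n_evaluable_arms,
                                    NA_real_)) |>
    dplyr::select("sample_id", "as_score", "n_altered", "n_evaluable_arms")
  n_na <- sum(is.na(out$as_score))
  if (n_na > 0) {
    rlang::inform(sprintf(
      "compute_as: %d sample(s) with zero evaluable arms reported as missing AS",
      n_na))
  }
  out
}

#' Per-sample AS and FGA at one cutoff
#'
#' Convenience wrapper combining [compute_fga()], [call_arm_events()] and
#' [compute_as()].
#'
#' @inheritParams call_arm_events
#' @inheritParams compute_fga
#' @return A tibble: `sample_id`, `cutoff`, `as_score`, `fga`,
#'   `n_evaluable_arms`.
#' @export
compute_scores <- function(seg, arms = read_arm_coordinates(), cutoff = 0.2,
                           boundary = ">=", arm_call_fraction = 0.7,
                           min_arm_coverage = 0.5, include_sex = FALSE) {
  fga <- compute_fga(seg, cutoff, boundary, include_sex)
  as_tbl <- compute_as(call_arm_events(seg, arms, cutoff, arm_call_fraction,
                                       min_arm_coverage, include_sex))
  dplyr::full_join(fga, as_tbl, by = "sample_id")[
    , c("sample_id", "cutoff", "as_score", "fga", "n_evaluable_arms")]
}

#' Sweep AS and FGA across a grid of CNA-calling cutoffs
#'
#' Computes per-sample AS and FGA at every cutoff of the grid (default 0.01
#' to 0.50 in steps of 0.01). Both scores are non-increasing in the cutoff
#' by construction; the resulting score-versus-cutoff curves are the input
#' to elbow-point cutoff selection.
#'
#' @inheritParams call_arm_events
#' @inheritParams compute_fga
#' @param grid Strictly increasing vector of positive cutoffs.
#' @return A long tibble of class `cna_score_curve`: `sample_id`, `cutoff`,
#'   `as_score`, `fga`.
#' @export
score_sweep <- function(seg, arms = read_arm_coordinates(),
                        grid = seq(0.01, 0.5, by = 0.01), boundary = ">=",
                        arm_call_fraction = 0.7, min_arm_coverage = 0.5,
                        include_sex = FALSE) {
  if (length(grid) == 0 || any(diff(grid) <= 0) || any(grid <= 0)) {
    abort_cnasurv("cutoff grid must be non-empty, positive and strictly increasing",
                  class = "cnasurv_validation_error")
  }
  seg <- validate_segments(seg)
  if (!include_sex) seg <- seg[is_autosome(seg$chromosome), ]
  if (nrow(seg) == 0) {
    abort_cnasurv("no segments to score", class = "cnasurv_undefined_score")
  }

  # FGA: per sample, vectorised over the grid
  len <- seg$end_bp - seg$start_bp + 1
  alr <- abs(seg$log2_ratio)
  fga_tbl <- seg |>
    dplyr::mutate(.len = len, .alr = alr) |>
    dplyr::reframe({
      tot <- sum(.data$.len)
      hits <- vapply(grid, function(x) {
        q <- if (boundary == ">=") .data$.alr >= x else .data$.alr > x
        sum(.data$.len[q])
      }, numeric(1))
      tibble::tibble(cutoff = grid, fga = hits / tot)
    }, .by = "sample_id")

  # AS: clip once, re-call per cutoff
  eng <- arm_coverage_engine(seg, arms, include_sex = TRUE)  # already filtered
  as_list <- lapply(grid, function(x) {
    call <- arm_calls_from_lengths(eng, eng$category_lengths(x),
                                   arm_call_fraction, min_arm_coverage)
    altered <- call %in% c("GAIN", "LOSS")
    evaluable <- call != "NOT_EVALUABLE"
    n_alt <- rowsum(as.numeric(altered), eng$full$sample_id)
    n_eval <- rowsum(as.numeric(evaluable), eng$full$sample_id)
    tibble::tibble(sample_id = rownames(n_alt), cutoff = x,
                   as_score = ifelse(n_eval[, 1] > 0,
                                     n_alt[, 1] / n_eval[, 1], NA_real_))
  })
  as_tbl <- dplyr::bind_rows(as_list)

  out <- dplyr::left_join(fga_tbl, as_tbl, by = c("sample_id", "cutoff"))
  out <- out[order(out$sample_id, out$cutoff),
             c("sample_id", "cutoff", "as_score", "fga")]
  class(out) <- c("cna_score_curve", class(tibble::tibble()))
  out
}

#' Cohort-mean score curve
#'
#' Averages per-sample score-versus-cutoff curves over samples, optionally
#' within cancer types (join on a clinical table). Samples with an undefined
#' score at a cutoff are excluded from that mean with a message.
#'
#' @param sweep A [score_sweep()] result.
#' @param score `"as"` or `"fga"`: which score to average.
#' @param clinical Optional clinical table; when given, means are computed
#'   per `cancer_type`.
#' @return A tibble of class `cna_mean_curve`: (`cancer_type`,) `cutoff`,
#'   `value`, `n`.
#' @export
cohort_mean_curve <- function(sweep, score = c("as", "fga"), clinical = NULL) {
  score <- match.arg(score)
  col <- if (score == "as") "as_score" else "fga"
  assert_columns(sweep, c("sample_id", "cutoff", col), "score sweep")
  df <- sweep
  by <- "cutoff"
  if (!is.null(clinical)) {
    df <- dplyr::inner_join(df,
                            clinical[, c("sample_id", "cancer_type")],
                            by = "sample_id")
    by <- c("cancer_type", "cutoff")
  }
  n_na <- sum(is.na(df[[col]]))
  if (n_na > 0) {
    rlang::inform(sprintf(
      "cohort_mean_curve: %d missing score value(s) excluded from means", n_na))
  }
  out <- df |>
    dplyr::summarise(value = mean(.data[[col]], na.rm = TRUE),
                     n = sum(!is.na(.data[[col]])),
                     .by = dplyr::all_of(by)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
  attr(out, "score") <- score
  class(out) <- c("cna_mean_curve", class(tibble::tibble()))
  out
}
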