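#' Configuration of the synthetic cohort generator
#'
#' Bundles and validates the parameters of the synthetic-cohort generator.
#' The defaults describe a mid-sized immune-checkpoint-blockade cohort
#' profiled on a targeted panel: three cancer types of 200 samples, tumor
#' purity Beta(4, 4) (median ~0.5, the typical range of clinical specimens),
#' arm-level events at probability 0.15 per arm (a handful of altered arms
#' per tumor), occasional focal events of a few megabases, log2-ratio
#' measurement noise of sd 0.1 (which places cohort elbow points in the
#' 0.14-0.22 range reported for targeted-panel ICB cohorts), log-normal TMB
#' around 5 mutations/Mb, and
#' exponential survival with a baseline median of 15 months, a protective
#' high-TMB effect (hazard ratio 0.6) and a harmful high-CNA-score effect
#' (hazard ratio 1.35), administratively censored within a 60-month window.
#'
#' @param cancer_types Character vector of cancer-type labels.
#' @param n_samples Samples per cancer type (scalar or one per type).
#' @param purity_shape1,purity_shape2 Beta parameters of the per-sample
#'   tumor purity.
#' @param purity_fixed Optional fixed purity in (0, 1] for every sample,
#'   overriding the Beta draw (useful for controlled experiments on the
#'   purity-cutoff interplay).
#' @param arm_event_prob Probability that an arm carries a true arm-level
#'   event.
#' @param p_loss Probability an arm event is a loss (copy number 1) rather
#'   than a gain (copy number 3).
#' @param focal_rate Poisson mean number of focal events per sample.
#' @param focal_meanlog,focal_sdlog Log-normal parameters of the focal
#'   event length in bp (default ~3 Mb).
#' @param noise_sd Gaussian sd of the log2-ratio measurement noise.
#' @param max_segs_per_arm Arms are emitted as 1..`max_segs_per_arm`
#'   segments.
#' @param tmb_meanlog,tmb_sdlog Log-normal parameters of TMB
#'   (mutations/Mb).
#' @param drug_classes,drug_probs ICB drug classes and their sampling
#'   probabilities.
#' @param score_percentile,tmb_percentile Within-type percentiles defining
#'   the score-high and TMB-high groups the hazard acts on.
#' @param beta_score,beta_tmb Log hazard ratios of the score-high and
#'   TMB-high indicators.
#' @param beta_drug Named log hazard ratios for non-reference drug classes
#'   (reference is the first element of `drug_classes`).
#' @param baseline_rate Exponential baseline hazard per month.
#' @param censor_window Administrative censoring: censoring times are
#'   uniform on `[0, censor_window]` months.
#' @return A validated list of class `cna_sim_config`.
#' @export
sim_config <- function(cancer_types = c("melanoma", "nsclc", "rcc"),
                       n_samples = 200,
                       purity_shape1 = 4, purity_shape2 = 4,
                       purity_fixed = NULL,
                       arm_event_prob = 0.15, p_loss = 0.5,
                       focal_rate = 3,
                       focal_meanlog = log(3e6), focal_sdlog = 0.5,
                       noise_sd = 0.1, max_segs_per_arm = 3,
                       tmb_meanlog = log(5), tmb_sdlog = 1,
                       drug_classes = c("PD-1/PD-L1", "CTLA-4", "Combo"),
                       drug_probs = c(0.6, 0.15, 0.25),
                       score_percentile = 60, tmb_percentile = 80,
                       beta_score = log(1.35), beta_tmb = log(0.6),
                       beta_drug = c("CTLA-4" = log(1.1), "Combo" = log(0.9)),
                       baseline_rate = log(2) / 15,
                       censor_window = 60) {
  n_samples <- rep(n_samples, length.out = length(cancer_types))
  stopifnot(
    length(cancer_types) >= 1, all(n_samples >= 0),
    purity_shape1 > 0, purity_shape2 > 0,
    arm_event_prob >= 0, arm_event_prob <= 1, p_loss >= 0, p_loss <= 1,
    focal_rate >= 0, noise_sd >= 0, max_segs_per_arm >= 1,
    length(drug_probs) == length(drug_classes),
    abs(sum(drug_probs) - 1) < 1e-8,
    score_percentile > 0, score_percentile < 100,
    tmb_percentile > 0, tmb_percentile < 100,
    baseline_rate > 0, censor_window >= 0)
  structure(
    list(cancer_types = cancer_types, n_samples = n_samples,
         purity_shape1 = purity_shape1, purity_shape2 = purity_shape2,
         purity_fixed = purity_fixed,
         arm_event_prob = arm_event_prob, p_loss = p_loss,
         focal_rate = focal_rate, focal_meanlog = focal_meanlog,
         focal_sdlog = focal_sdlog, noise_sd = noise_sd,
         max_segs_per_arm = max_segs_per_arm,
         tmb_meanlog = tmb_meanlog, tmb_sdlog = tmb_sdlog,
         drug_classes = drug_classes, drug_probs = drug_probs,
         score_percentile = score_percentile, tmb_percentile = tmb_percentile,
         beta_score = beta_score, beta_tmb = beta_tmb, beta_drug = beta_drug,
         baseline_rate = baseline_rate, censor_window = censor_window),
    class = "cna_sim_config")
}

# observed log2 copy ratio of a region with tumor copy number cn at purity rho
purity_log2 <- function(cn, rho) {
  log2((rho * cn + (1 - rho) * 2) / 2)
}

#' Simulate segmented copy-number profiles with known ground truth
#'
#' Draws, for every sample, a tumor purity and a true integer copy state per
#' chromosome arm (2 = neutral, 3 = single-copy gain, 1 = single-copy
#' loss); emits each arm as one or more SEG segments whose observed log2
#' ratio is the purity-mixing value
#' `log2((rho * CN + (1 - rho) * 2) / 2)` plus Gaussian measurement noise;
#' and injects short focal events (copy state one step up or down from the
#' arm background) as extra segments. The returned truth table carries the
#' per-arm states, the true aneuploidy score (fraction of the 39 arms with
#' an arm-level event), the true fraction of genome altered (length-weighted
#' over all emitted segments with truly altered copy state) and the purity,
#' so recovery of the truth by the scoring pipeline can be tested exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical (config, seed) give identical
#'   output.
#' @param arms Arm coordinate table (default the bundled hg19 table).
#' @return A list with elements `segments` (a validated `cna_segments`
#'   tibble) and `truth` (one row per sample: `sample_id`, `cancer_type`,
#'   `purity`, `true_as`, `true_fga`, `n_altered_arms` and the per-arm
#'   states as a list column `arm_states`).
#' @export
simulate_segments <- function(config = sim_config(), seed = 1,
                              arms = read_arm_coordinates()) {
  stopifnot(inherits(config, "cna_sim_config"))
  n_arm <- nrow(arms)
  with_seed(seed, {
    samples <- purrr::imap(config$cancer_types, function(ct, k) {
      n <- config$n_samples[k]
      if (n == 0) return(NULL)
      ids <- sprintf("%s%d_%03d", toupper(substr(ct, 1, 3)), k, seq_len(n))
      purrr::map2(ids, seq_len(n), function(id, i) {
        rho <- if (!is.null(config$purity_fixed)) config$purity_fixed else
          min(max(rbeta(1, config$purity_shape1, config$purity_shape2),
                  0.05), 1)
        event <- runif(n_arm) < config$arm_event_prob
        state <- rep(2L, n_arm)
        state[event] <- ifelse(runif(sum(event)) < config$p_loss, 1L, 3L)
        # focal events: at most one per arm, copy state +/- 1 from background
        n_focal <- min(rpois(1, config$focal_rate), n_arm)
        focal_arms <- if (n_focal > 0) sample.int(n_arm, n_focal) else integer(0)
        seg_rows <- purrr::map(seq_len(n_arm), function(a) {
          a_start <- arms$start_bp[a]; a_end <- arms$end_bp[a]
          a_len <- a_end - a_start + 1
          cuts <- sort(unique(c(a_start - 1, a_end,
            if (config$max_segs_per_arm > 1) {
              k_extra <- sample.int(config$max_segs_per_arm, 1) - 1L
              if (k_extra > 0)
                floor(a_start - 1 + runif(k_extra, 0.1, 0.9) * a_len)
            })))
          pieces <- tibble::tibble(start_bp = head(cuts, -1) + 1,
                                   end_bp = cuts[-1], cn = state[a])
          if (a %in% focal_arms) {
            # cap at a quarter of the arm so a focal event can never overturn
            # the dominant arm-level category (0.75 measured > 0.7 threshold)
            f_len <- min(round(rlnorm(1, config$focal_meanlog,
                                      config$focal_sdlog)), floor(a_len / 4))
            f_len <- max(f_len, 1)
            f_start <- floor(a_start + runif(1) * (a_len - f_len))
            f_end <- f_start + f_len - 1
            f_cn <- max(0L, state[a] + sample(c(-1L, 1L), 1))
            # re-cut background pieces around the focal interval
            bounds <- sort(unique(c(cuts, f_start - 1, f_end)))
            bounds <- bounds[bounds >= a_start - 1 & bounds <= a_end]
            pieces <- tibble::tibble(start_bp = head(bounds, -1) + 1,
                                     end_bp = bounds[-1], cn = state[a])
            inside <- pieces$start_bp >= f_start & pieces$end_bp <= f_end
            pieces$cn[inside] <- f_cn
          }
          pieces$chromosome <- arms$chromosome[a]
          pieces
        })
        seg <- dplyr::bind_rows(seg_rows)
        # clamp to +/-3, the practical dynamic range of panel log2 ratios
        # (a homozygous deletion at purity 1 is otherwise -Inf)
        seg$log2_ratio <- pmin(pmax(
          purity_log2(seg$cn, rho) + rnorm(nrow(seg), 0, config$noise_sd),
          -3), 3)
        len <- seg$end_bp - seg$start_bp + 1
        truth <- tibble::tibble(
          sample_id = id, cancer_type = ct, purity = rho,
          true_as = mean(state != 2L),
          true_fga = sum(len[seg$cn != 2L]) / sum(len),
          n_altered_arms = sum(state != 2L),
          arm_states = list(setNames(state, arms$arm)))
        seg$sample_id <- id
        list(seg = seg[, c("sample_id", "chromosome", "start_bp", "end_bp",
                           "log2_ratio", "cn")],
             truth = truth)
      })
    })
    samples <- unlist(samples, recursive = FALSE)
    if (length(samples) == 0) {
      empty <- validate_segments(tibble::tibble(
        sample_id = character(), chromosome = character(),
        start_bp = numeric(), end_bp = numeric(), log2_ratio = numeric()))
      return(list(segments = empty,
                  truth = tibble::tibble(sample_id = character(),
                                         cancer_type = character(),
                                         purity = numeric(),
                                         true_as = numeric(),
                                         true_fga = numeric(),
                                         n_altered_arms = integer(),
                                         arm_states = list())))
    }
    seg <- dplyr::bind_rows(purrr::map(samples, "seg"))
    seg$cn <- NULL
    list(segments = validate_segments(seg),
         truth = dplyr::bind_rows(purrr::map(samples, "truth")))
  })
}

#' Simulate clinical records from a proportional-hazards model
#'
#' Generates TMB, ICB drug class and overall survival for the samples of a
#' truth table. The hazard is exponential:
#' `rate = baseline * exp(beta_score * score_high + beta_tmb * tmb_high +
#' beta_drug[drug])`, where `score_high`/`tmb_high` are within-cancer-type
#' binarizations of the true score and the simulated TMB at the configured
#' percentiles (if `truth` already carries logical `score_high`/`tmb_high`
#' columns they are used as-is). Administrative censoring is uniform on the
#' configured window; times are months.
#'
#' @param truth A truth table from [simulate_segments()] (needs
#'   `sample_id`, `cancer_type` and `score_col`), or any cohort skeleton.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param score_col Column of `truth` binarized into the score groups
#'   (default `"true_as"`).
#' @return A validated `cna_clinical` tibble with the extra truth columns
#'   `score_high`, `tmb_high` and `true_rate`.
#' @export
simulate_survival <- function(truth, config = sim_config(), seed = 1,
                              score_col = "true_as") {
  stopifnot(inherits(config, "cna_sim_config"))
  assert_columns(truth, c("sample_id", "cancer_type"), "truth table")
  df <- tibble::as_tibble(truth)
  with_seed(seed, {
    n <- nrow(df)
    df$tmb <- rlnorm(n, config$tmb_meanlog, config$tmb_sdlog)
    df$drug_class <- sample(config$drug_classes, n, replace = TRUE,
                            prob = config$drug_probs)
    if (!"tmb_high" %in% names(df)) {
      df <- binarize_within_type(df, "tmb", config$tmb_percentile,
                                 out_col = "tmb_high")
    }
    if (!"score_high" %in% names(df)) {
      assert_columns(df, score_col, "truth table")
      df <- binarize_within_type(df, score_col, config$score_percentile,
                                 out_col = "score_high")
    }
    bd <- rep(0, n)
    for (cls in names(config$beta_drug)) {
      bd[df$drug_class == cls] <- config$beta_drug[[cls]]
    }
    df$true_rate <- config$baseline_rate *
      exp(config$beta_score * df$score_high +
            config$beta_tmb * df$tmb_high + bd)
    t_event <- rexp(n, rate = df$true_rate)
    t_cens <- runif(n, 0, max(config$censor_window, 1e-12))
    df$os_time <- pmin(t_event, t_cens)
    df$os_event <- as.numeric(t_event <= t_cens)
    if (!"purity" %in% names(df)) df$purity <- NA_real_
    validate_clinical(df)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: [simulate_segments()] then [simulate_survival()]
#' (and optionally a null mutation matrix), with seeds derived from `seed`.
#'
#' @inheritParams simulate_segments
#' @param n_genes Number of genes for the mutation matrix; 0 skips it.
#' @return A list: `segments`, `clinical`, `truth`, and `mutations` (or
#'   `NULL`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1,
                            arms = read_arm_coordinates(), n_genes = 0) {
  sim <- simulate_segments(config, seed = seed, arms = arms)
  clinical <- simulate_survival(sim$truth, config, seed = seed + 1)
  mutations <- if (n_genes > 0) {
    simulate_mutations(clinical$sample_id, n_genes = n_genes,
                       seed = seed + 2)
  }
  list(segments = sim$segments, clinical = clinical, truth = sim$truth,
       mutations = mutations)
}

#' Simulate a null binary mutation matrix
#'
#' Every gene is mutated independently of everything else at a gene-specific
#' background frequency, so any downstream group comparison is a true null.
#'
#' @param sample_ids Character vector of sample ids.
#' @param n_genes Number of genes (default 500).
#' @param freq_range Range of per-gene background mutation frequencies.
#' @param seed Integer seed.
#' @return A validated `cna_mutations` tibble.
#' @export
simulate_mutations <- function(sample_ids, n_genes = 500,
                               freq_range = c(0.02, 0.3), seed = 1) {
  with_seed(seed, {
    freq <- runif(n_genes, freq_range[1], freq_range[2])
    m <- vapply(freq, function(f) rbinom(length(sample_ids), 1, f),
                numeric(length(sample_ids)))
    colnames(m) <- sprintf("GENE%03d", seq_len(n_genes))
    validate_mutations(
      dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                       tibble::as_tibble(m)))
  })
}

#' Synthetic per-sample score curves with a constructed knee
#'
#' Builds noisy per-sample score-versus-cutoff curves whose cohort mean is
#' piecewise linear with a knee at a known location, for elbow-recovery
#' tests. The template curve falls from `y_range[2]` to `y_range[1]` over
#' the grid, spending `drop_fraction` of the total drop before the knee
#' (steep phase) and the rest after it (shallow phase). Each sample's curve
#' is the template scaled by a log-normal positive factor and shifted by a
#' small Gaussian offset — transformations under which the Kneedle elbow is
#' invariant — plus independent Gaussian noise per grid point, then made
#' non-increasing (running minimum) and clamped to [0, 1]. With one sample
#' and zero noise the curve is exactly the template and the elbow is exactly
#' the construction knee.
#'
#' @param knee_location Construction knee, a grid point strictly inside the
#'   grid.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param grid Cutoff grid (default 0.01..0.50 step 0.01).
#' @param y_range Range of the template curve values.
#' @param drop_fraction Fraction of the total drop occurring before the
#'   knee (default 0.9; must be large enough that the normalised pre-knee
#'   slope exceeds 1 and the post-knee slope stays below 1).
#' @param scale_sd Log-sd of the per-sample positive scale factor.
#' @param shift_sd Sd of the per-sample offset.
#' @param noise_sd Sd of the per-grid-point noise.
#' @return A long tibble: `sample_id`, `cutoff`, `value`; the construction
#'   knee in `attr(, "knee")`.
#' @export
make_knee_cohort <- function(knee_location = 0.2, n_samples = 200, seed = 1,
                             grid = seq(0.01, 0.5, by = 0.01),
                             y_range = c(0.15, 0.75), drop_fraction = 0.9,
                             scale_sd = 0.1, shift_sd = 0.02,
                             noise_sd = 0.02) {
  stopifnot(knee_location > min(grid), knee_location < max(grid),
            drop_fraction > 0, drop_fraction < 1)
  drop_total <- y_range[2] - y_range[1]
  template <- ifelse(
    grid <= knee_location,
    y_range[2] - drop_fraction * drop_total *
      (grid - grid[1]) / (knee_location - grid[1]),
    y_range[2] - drop_fraction * drop_total -
      (1 - drop_fraction) * drop_total *
      (grid - knee_location) / (max(grid) - knee_location))
  out <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_samples), function(i) {
      a <- exp(rnorm(1, 0, scale_sd))
      b <- rnorm(1, 0, shift_sd)
      y <- a * template + b + rnorm(length(grid), 0, noise_sd)
      y <- cummin(pmin(pmax(y, 0), 1))
      tibble::tibble(sample_id = sprintf("K%04d", i), cutoff = grid,
                     value = y)
    })
  })
  attr(out, "knee") <- knee_location
  out
}
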