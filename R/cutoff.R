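# Kneedle knee detection on a decreasing curve, shared by find_elbow and the
# bootstrap loop. xn must be min-max normalised and strictly increasing;
# returns the knee index or NA when no knee satisfies the sensitivity
# criterion.
kneedle_index <- function(xn, y, sensitivity = 1) {
  rng <- range(y)
  if (rng[2] - rng[1] <= 0) return(NA_integer_)
  yn <- (y - rng[1]) / (rng[2] - rng[1])
  d <- (1 - yn) - xn  # flip the decreasing curve, then difference from the diagonal
  n <- length(d)
  mean_dx <- mean(diff(xn))
  # interior local maxima of the difference curve (ties allowed)
  lm <- which(d[2:(n - 1)] >= d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  if (length(lm) == 0) return(NA_integer_)
  # collapse runs of tied neighbours to their first index
  lm <- lm[c(TRUE, diff(lm) > 1 | d[lm[-1]] != d[lm[-length(lm)]])]
  for (k in seq_along(lm)) {
    i <- lm[k]
    thr <- d[i] - sensitivity * mean_dx
    stop_at <- if (k < length(lm)) lm[k + 1] else n
    j <- i + 1L
    while (j <= stop_at) {
      if (d[j] < thr) return(i)  # knee confirmed
      j <- j + 1L
    }
  }
  NA_integer_
}

#' Elbow point of a score-versus-cutoff curve
#'
#' Implements the Kneedle procedure for a decreasing curve: both axes are
#' min-max normalised, the curve is flipped to increasing, and the
#' difference between the flipped curve and the unit diagonal is formed; the
#' elbow is the grid cutoff at the first local maximum of that difference
#' curve that the sensitivity criterion confirms (the difference must fall
#' more than `sensitivity` times the mean normalised grid step below the
#' maximum before the next candidate). The elbow is reported on the grid,
#' not interpolated, because downstream CNA calling is grid-based. The
#' result is invariant to shifting the curve by a constant or rescaling the
#' y axis by a positive factor.
#'
#' @param curve A data frame with columns `cutoff` and `value` (e.g. a
#'   [cohort_mean_curve()] for one cancer type), values non-increasing in
#'   the cutoff.
#' @param sensitivity Positive Kneedle sensitivity; 1 (the package default
#'   of the original implementation) declares a knee as soon as the
#'   difference curve drops one mean grid step below a local maximum.
#' @return The elbow cutoff, a length-1 numeric on the input grid.
#' @export
#' @examples
#' grid <- seq(0.01, 0.5, by = 0.01)
#' y <- ifelse(grid <= 0.2, 1 - 4 * (grid - 0.01), 0.24 - 0.1 * (grid - 0.2))
#' find_elbow(tibble::tibble(cutoff = grid, value = y))  # 0.2
find_elbow <- function(curve, sensitivity = 1) {
  assert_columns(curve, c("cutoff", "value"), "score curve")
  stopifnot(sensitivity > 0)
  curve <- curve[order(curve$cutoff), ]
  x <- curve$cutoff
  y <- curve$value
  if (length(x) < 5) {
    abort_cnasurv("elbow detection needs at least 5 grid points",
                  class = "cnasurv_validation_error")
  }
  if (any(diff(y) > 1e-9 * max(abs(y), 1))) {
    abort_cnasurv("curve must be non-increasing in the cutoff",
                  class = "cnasurv_validation_error")
  }
  xn <- (x - x[1]) / (x[length(x)] - x[1])
  i <- kneedle_index(xn, y, sensitivity)
  if (is.na(i)) {
    abort_cnasurv("no knee found: curve has no elbow at this sensitivity",
                  class = "cnasurv_no_knee")
  }
  x[i]
}

#' Bootstrap elbow point with percentile confidence interval
#'
#' Resamples samples with replacement, recomputes the cohort-mean
#' score-versus-cutoff curve in each replicate and finds its elbow. The
#' point estimate is the elbow of the full-cohort mean curve; the 95%
#' confidence interval is the 2.5th/97.5th percentile of the replicate
#' elbows. Replicates in which no knee is found are dropped and counted; if
#' more than half of the replicates have no knee the elbow is deemed
#' unstable and an error is raised.
#'
#' @param curves Per-sample score curves for one cohort (one cancer type): a
#'   long data frame with columns `sample_id`, `cutoff` and the score column
#'   selected by `score` (a [score_sweep()] result, or any table with a
#'   `value` column).
#' @param score `"as"`, `"fga"` or `"value"`: which column holds the score.
#' @param n_bootstrap Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; fixed seed gives an identical result.
#' @param sensitivity Kneedle sensitivity, see [find_elbow()].
#' @param conf_level Confidence level of the percentile interval.
#' @return A one-row tibble of class `cna_elbow`: `score_kind`,
#'   `elbow_point`, `ci_low`, `ci_high`, `n_bootstrap`, `n_noknee`, `n_samples`,
#'   `seed`.
#' @export
bootstrap_elbow <- function(curves, score = c("as", "fga", "value"),
                            n_bootstrap = 1000, seed = 1, sensitivity = 1,
                            conf_level = 0.95) {
  score <- match.arg(score)
  col <- switch(score, as = "as_score", fga = "fga", value = "value")
  if (!col %in% names(curves) && "value" %in% names(curves)) col <- "value"
  assert_columns(curves, c("sample_id", "cutoff", col), "per-sample curves")
  wide <- tidyr::pivot_wider(curves[, c("sample_id", "cutoff", col)],
                             names_from = "cutoff", values_from = dplyr::all_of(col))
  m <- as.matrix(wide[, -1])
  grid <- as.numeric(colnames(m))
  ord <- order(grid)
  grid <- grid[ord]
  m <- m[, ord, drop = FALSE]
  keep <- complete.cases(m)
  if (sum(keep) < nrow(m)) {
    rlang::inform(sprintf("bootstrap_elbow: dropped %d sample(s) with missing curve values",
                          sum(!keep)))
  }
  m <- m[keep, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) {
    abort_cnasurv("bootstrap_elbow needs at least 2 samples",
                  class = "cnasurv_validation_error")
  }
  xn <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  point <- find_elbow(tibble::tibble(cutoff = grid, value = colMeans(m)),
                      sensitivity)
  reps <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      i <- kneedle_index(xn, colMeans(m[idx, , drop = FALSE]), sensitivity)
      if (is.na(i)) NA_real_ else grid[i]
    }, numeric(1))
  })
  n_noknee <- sum(is.na(reps))
  if (n_noknee > n_bootstrap / 2) {
    abort_cnasurv(sprintf(
      "unstable elbow: %d of %d bootstrap replicates found no knee",
      n_noknee, n_bootstrap), class = "cnasurv_unstable_elbow")
  }
  alpha <- (1 - conf_level) / 2
  ci <- quantile(reps[!is.na(reps)], c(alpha, 1 - alpha), type = 1,
                 names = FALSE)
  out <- tibble::tibble(
    score_kind = toupper(score), elbow_point = point,
    ci_low = ci[1], ci_high = ci[2],
    n_bootstrap = n_bootstrap, n_noknee = n_noknee,
    n_samples = n, seed = seed)
  class(out) <- c("cna_elbow", class(tibble::tibble()))
  out
}

#' Two-component Gaussian-mixture cutoff
#'
#' Fits a two-component Gaussian mixture (unequal variances,
#' expectation-maximisation) to the absolute log2 copy-ratio values of a
#' cohort's segments, and returns the decision boundary between the two
#' component means at which the posterior membership probabilities are
#' equal. The fit is rejected as degenerate when a single Gaussian explains
#' the data better (by BIC), when a component weight falls below 0.01, or
#' when the component means are closer than 1e-3 — all situations in which a
#' two-state "neutral versus altered" reading of the mixture is
#' meaningless.
#'
#' @param values Non-negative numeric vector of absolute log2 copy ratios
#'   (one value per segment); at least 20 values.
#' @param seed Integer seed for the mixture initialisation.
#' @return A one-row tibble of class `cna_gmm`: `mean_1`, `sd_1`,
#'   `weight_1`, `mean_2`, `sd_2`, `weight_2` (components ordered by mean)
#'   and `cutoff`, the equal-posterior boundary, strictly between the two
#'   means.
#' @export
gmm_cutoff <- function(values, seed = 1) {
  values <- as.numeric(values)
  if (length(values) < 20) {
    abort_cnasurv("gmm_cutoff needs at least 20 values",
                  class = "cnasurv_validation_error")
  }
  if (any(values < 0) || any(!is.finite(values))) {
    abort_cnasurv("values must be finite and >= 0 (absolute log2 ratios)",
                  class = "cnasurv_validation_error")
  }
  if (length(unique(values)) < 2 || stats::sd(values) < 1e-10) {
    abort_cnasurv("degenerate input: values are (nearly) constant",
                  class = "cnasurv_degenerate_mixture")
  }
  # Mclust() resolves mclustBIC in the calling frame; alias it locally so the
  # package need not be attached
  mclustBIC <- mclust::mclustBIC
  fit2 <- with_seed(seed, suppressWarnings(
    mclust::Mclust(values, G = 2, modelNames = "V", verbose = FALSE)))
  if (is.null(fit2)) {
    # zero-variance clusters (e.g. repeated values) break the unconstrained
    # fit; retry with mclust's conjugate prior as a variance regulariser
    fit2 <- with_seed(seed, suppressWarnings(
      mclust::Mclust(values, G = 2, modelNames = "V",
                     prior = mclust::priorControl(), verbose = FALSE)))
  }
  fit1 <- with_seed(seed, suppressWarnings(
    mclust::Mclust(values, G = 1, verbose = FALSE)))
  if (is.null(fit2)) {
    abort_cnasurv("two-component mixture fit failed",
                  class = "cnasurv_degenerate_mixture")
  }
  if (!is.null(fit1) && fit1$bic >= fit2$bic) {
    abort_cnasurv("degenerate mixture: one component is preferred by BIC",
                  class = "cnasurv_degenerate_mixture")
  }
  mu <- as.numeric(fit2$parameters$mean)
  sd_ <- sqrt(as.numeric(fit2$parameters$variance$sigmasq))
  if (length(sd_) == 1) sd_ <- rep(sd_, 2)
  w <- as.numeric(fit2$parameters$pro)
  o <- order(mu)
  mu <- mu[o]; sd_ <- pmax(sd_[o], 1e-8); w <- w[o]
  if (min(w) < 0.01 || diff(mu) < 1e-3) {
    abort_cnasurv("degenerate mixture: vanishing weight or indistinct means",
                  class = "cnasurv_degenerate_mixture")
  }
  cutoff <- equal_posterior_boundary(mu, sd_, w)
  out <- tibble::tibble(mean_1 = mu[1], sd_1 = sd_[1], weight_1 = w[1],
                        mean_2 = mu[2], sd_2 = sd_[2], weight_2 = w[2],
                        cutoff = cutoff, seed = seed)
  class(out) <- c("cna_gmm", class(tibble::tibble()))
  out
}

# point between the two component means where posterior membership
# probabilities are equal: w1 N(x; m1, s1) = w2 N(x; m2, s2)
equal_posterior_boundary <- function(mu, sd_, w) {
  g <- function(x) {
    (log(w[1]) + dnorm(x, mu[1], sd_[1], log = TRUE)) -
      (log(w[2]) + dnorm(x, mu[2], sd_[2], log = TRUE))
  }
  eps <- diff(mu) * 1e-6
  lo <- mu[1] + eps
  hi <- mu[2] - eps
  if (g(lo) > 0 && g(hi) < 0) {
    return(uniroot(g, c(lo, hi), tol = 1e-10)$root)
  }
  # no sign change between the means (extreme weight imbalance): take the
  # interior minimiser of the absolute log posterior odds
  xs <- seq(lo, hi, length.out = 512)
  xs[which.min(abs(vapply(xs, g, numeric(1))))]
}
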