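#' Read a SEG file of segmented copy-number data
#'
#' Parses the tab-separated SEG format (one row per genomic segment with a
#' log2 copy-ratio mean) into a validated segment table, the substrate of all
#' downstream scoring. Column names are matched case-insensitively against
#' the common dialects (`ID`/`Sample`, `chrom`/`chr`, `loc.start`/`start`,
#' `loc.end`/`end`, `seg.mean`/`seg_mean`, optional `num.mark`). `"chr"`
#' prefixes are stripped from chromosome labels. Rows with a missing segment
#' mean are dropped with a message giving the count.
#'
#' @param path Path to a tab-separated SEG file with a header row.
#' @param dialect Optional named character vector overriding column-name
#'   detection; names are the canonical fields `sample`, `chromosome`,
#'   `start`, `end`, `seg_mean`, `n_probes`, values the column names in the
#'   file.
#'
#' @return A tibble of class `cna_segments` with columns `sample_id`,
#'   `chromosome`, `start_bp`, `end_bp` (1-based, inclusive), `log2_ratio`
#'   and `n_probes` (`NA` when absent).
#' @seealso [validate_segments()], [write_seg()], [compute_fga()]
#' @export
#' @examples
#' seg <- file.path(tempdir(), "toy.seg")
#' writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
#'              "S1\tchr1\t1\t1000000\t50\t0.31",
#'              "S1\tchr1\t1000001\t2000000\t40\t-0.02"), seg)
#' read_seg(seg)
read_seg <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort_cnasurv(sprintf("SEG file not found: %s", path),
                  class = "cnasurv_format_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    abort_cnasurv("SEG file is empty", class = "cnasurv_format_error")
  }
  aliases <- list(
    sample     = c("id", "sample", "sample_id", "samplename"),
    chromosome = c("chrom", "chr", "chromosome"),
    start      = c("loc.start", "start", "start_bp", "loc_start"),
    end        = c("loc.end", "end", "end_bp", "loc_end"),
    seg_mean   = c("seg.mean", "seg_mean", "segmean", "log2_ratio", "log2ratio"),
    n_probes   = c("num.mark", "num_mark", "n_probes", "nummark")
  )
  pick <- function(field, required = TRUE) {
    if (!is.null(dialect) && field %in% names(dialect)) {
      hit <- match(tolower(dialect[[field]]), tolower(names(raw)))
    } else {
      hit <- match(aliases[[field]], tolower(names(raw)))
      hit <- hit[!is.na(hit)][1]
    }
    if (is.na(hit) || length(hit) == 0) {
      if (required) {
        abort_cnasurv(
          sprintf("SEG file is missing a '%s' column (accepted names: %s)",
                  field, paste(aliases[[field]], collapse = ", ")),
          class = "cnasurv_format_error")
      }
      return(NA_integer_)
    }
    hit
  }
  idx <- c(sample = pick("sample"), chromosome = pick("chromosome"),
           start = pick("start"), end = pick("end"), seg_mean = pick("seg_mean"))
  np <- pick("n_probes", required = FALSE)

  seg <- tibble::tibble(
    sample_id  = as.character(raw[[idx["sample"]]]),
    chromosome = norm_chrom(raw[[idx["chromosome"]]]),
    start_bp   = as.numeric(raw[[idx["start"]]]),
    end_bp     = as.numeric(raw[[idx["end"]]]),
    log2_ratio = as.numeric(raw[[idx["seg_mean"]]]),
    n_probes   = if (is.na(np)) NA_real_ else as.numeric(raw[[np]])
  )
  n_missing <- sum(is.na(seg$log2_ratio))
  if (n_missing > 0) {
    rlang::inform(sprintf("read_seg: dropped %d segment(s) with missing log2 ratio",
                          n_missing))
    seg <- seg[!is.na(seg$log2_ratio), ]
  }
  validate_segments(seg)
}

#' Validate a segment table
#'
#' Checks the invariants every segment table must satisfy: positions are
#' 1-based with `end_bp >= start_bp >= 1`, chromosome labels are in
#' 1..22/X/Y, and segments within one sample and chromosome do not overlap
#' (overlaps would corrupt every length-weighted score downstream, so they
#' are a hard error rather than a silent merge).
#'
#' @param seg A data frame with columns `sample_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `log2_ratio` (optionally `n_probes`).
#' @return The input as a `cna_segments` tibble, invisibly validated.
#' @export
validate_segments <- function(seg) {
  assert_columns(seg, c("sample_id", "chromosome", "start_bp", "end_bp",
                        "log2_ratio"), "segment table")
  seg <- tibble::as_tibble(seg)
  if (!"n_probes" %in% names(seg)) seg$n_probes <- NA_real_
  seg$chromosome <- norm_chrom(seg$chromosome)
  bad_chrom <- setdiff(unique(seg$chromosome), chrom_levels)
  if (length(bad_chrom) > 0) {
    abort_cnasurv(sprintf("unrecognised chromosome label(s): %s",
                          paste(bad_chrom, collapse = ", ")),
                  class = "cnasurv_validation_error")
  }
  if (nrow(seg) > 0) {
    if (any(seg$start_bp < 1) || any(seg$end_bp < seg$start_bp)) {
      abort_cnasurv("segments must satisfy 1 <= start_bp <= end_bp",
                    class = "cnasurv_validation_error")
    }
    ord <- order(seg$sample_id, seg$chromosome, seg$start_bp)
    s <- seg[ord, ]
    same <- s$sample_id[-1] == s$sample_id[-nrow(s)] &
      s$chromosome[-1] == s$chromosome[-nrow(s)]
    ovl <- which(same & s$start_bp[-1] <= s$end_bp[-nrow(s)])
    if (length(ovl) > 0) {
      i <- ovl[1]
      abort_cnasurv(
        sprintf("overlapping segments in sample %s chromosome %s: [%d, %d] and [%d, %d]",
                s$sample_id[i], s$chromosome[i],
                as.integer(s$start_bp[i]), as.integer(s$end_bp[i]),
                as.integer(s$start_bp[i + 1]), as.integer(s$end_bp[i + 1])),
        class = "cnasurv_validation_error")
    }
  }
  seg <- seg[, c("sample_id", "chromosome", "start_bp", "end_bp",
                 "log2_ratio", "n_probes")]
  class(seg) <- c("cna_segments", class(tibble::tibble()))
  seg
}

#' Write a segment table to SEG format
#'
#' Inverse of [read_seg()]: writes the standard six-column tab-separated SEG
#' layout (`ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`, `seg.mean`).
#' A write/read round trip reproduces all fields.
#'
#' @param seg A validated segment table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(seg, path) {
  seg <- validate_segments(seg)
  out <- data.frame(ID = seg$sample_id, chrom = seg$chromosome,
                    loc.start = seg$start_bp, loc.end = seg$end_bp,
                    num.mark = seg$n_probes, seg.mean = seg$log2_ratio,
                    check.names = FALSE)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read (or load the bundled) chromosome-arm coordinate table
#'
#' Arm-level calls are made over fixed arm intervals. With `path = NULL` the
#' bundled hg19 table is used: 39 autosomal arms, i.e. 22 autosomes times two
#' arms minus the five acrocentric p arms (13p, 14p, 15p, 21p, 22p) whose
#' short arms carry no unique sequence. A user table is a 4-column
#' tab-separated file (`arm`, `chrom`, `start`, `end`, 1-based inclusive).
#'
#' @param path Path to an arm-coordinate TSV, or `NULL` for the bundled hg19
#'   autosomal table.
#' @param flag_acrocentric When `TRUE` (default), warn if the table contains
#'   an acrocentric p arm — accepted, but outside the 39-arm convention.
#' @return A tibble of class `cna_arms` with columns `arm`, `chromosome`,
#'   `start_bp`, `end_bp`, `arm_length`.
#' @export
#' @examples
#' arms <- read_arm_coordinates()
#' nrow(arms)  # 39
read_arm_coordinates <- function(path = NULL, flag_acrocentric = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "arm_coordinates_hg19.tsv",
                        package = "cnasurv", mustWork = TRUE)
    flag_acrocentric <- FALSE  # bundled table is known-good
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    abort_cnasurv("arm coordinate file is empty", class = "cnasurv_format_error")
  }
  names(raw) <- tolower(names(raw))
  cols <- names(raw)
  pick <- function(opts) {
    hit <- match(opts, cols); hit <- hit[!is.na(hit)][1]
    if (is.na(hit)) abort_cnasurv(
      sprintf("arm coordinate table is missing a column (accepted: %s)",
              paste(opts, collapse = ", ")), class = "cnasurv_format_error")
    hit
  }
  arms <- tibble::tibble(
    arm        = as.character(raw[[pick(c("arm", "arm_label"))]]),
    chromosome = norm_chrom(raw[[pick(c("chrom", "chr", "chromosome"))]]),
    start_bp   = as.numeric(raw[[pick(c("start", "start_bp"))]]),
    end_bp     = as.numeric(raw[[pick(c("end", "end_bp"))]])
  )
  if (any(arms$end_bp < arms$start_bp) || any(arms$start_bp < 1)) {
    abort_cnasurv("arm intervals must satisfy 1 <= start <= end",
                  class = "cnasurv_validation_error")
  }
  ord <- order(arms$chromosome, arms$start_bp)
  a <- arms[ord, ]
  if (nrow(a) > 1) {
    same <- a$chromosome[-1] == a$chromosome[-nrow(a)]
    if (any(same & a$start_bp[-1] <= a$end_bp[-nrow(a)])) {
      abort_cnasurv("arm intervals overlap within a chromosome",
                    class = "cnasurv_validation_error")
    }
  }
  acro <- c("13p", "14p", "15p", "21p", "22p")
  if (flag_acrocentric && any(arms$arm %in% acro)) {
    rlang::warn(sprintf(
      "arm table contains acrocentric p arm(s) outside the 39-arm convention: %s",
      paste(intersect(arms$arm, acro), collapse = ", ")))
  }
  arms$arm_length <- arms$end_bp - arms$start_bp + 1
  class(arms) <- c("cna_arms", class(tibble::tibble()))
  arms
}

#' Read a clinical table
#'
#' Loads the per-sample clinical covariates used by the survival analyses:
#' cancer type, tumor mutational burden (TMB, mutations per megabase),
#' overall-survival time in months with an event indicator, the immune
#' checkpoint blockade (ICB) drug class, and optionally tumor purity.
#'
#' @param path Path to a tab-separated file with header columns `sample_id`,
#'   `cancer_type`, `tmb`, `os_time`, `os_event`, `drug_class` and optional
#'   `purity`.
#' @return A tibble of class `cna_clinical`.
#' @export
read_clinical <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_clinical(raw)
}

#' Validate a clinical table
#'
#' @param clin A data frame with the columns documented in [read_clinical()].
#' @return The validated `cna_clinical` tibble.
#' @export
validate_clinical <- function(clin) {
  assert_columns(clin, c("sample_id", "cancer_type", "tmb", "os_time",
                         "os_event", "drug_class"), "clinical table")
  clin <- tibble::as_tibble(clin)
  clin$sample_id <- as.character(clin$sample_id)
  if (any(clin$os_time < 0, na.rm = TRUE)) {
    abort_cnasurv("os_time must be >= 0 (months)",
                  class = "cnasurv_validation_error")
  }
  if (!all(clin$os_event %in% c(0, 1))) {
    abort_cnasurv("os_event must be 0 (censored) or 1 (death observed)",
                  class = "cnasurv_validation_error")
  }
  if (any(clin$tmb < 0, na.rm = TRUE)) {
    abort_cnasurv("tmb must be >= 0 (mutations per megabase)",
                  class = "cnasurv_validation_error")
  }
  if ("purity" %in% names(clin) &&
      any(clin$purity < 0 | clin$purity > 1, na.rm = TRUE)) {
    abort_cnasurv("purity must lie in [0, 1]",
                  class = "cnasurv_validation_error")
  }
  if (anyDuplicated(clin$sample_id)) {
    abort_cnasurv("duplicated sample_id in clinical table",
                  class = "cnasurv_validation_error")
  }
  class(clin) <- c("cna_clinical", class(tibble::tibble()))
  clin
}

#' Read a binary gene-mutation matrix
#'
#' @param path Tab-separated file: first column `sample_id`, remaining
#'   columns one gene each with entries 0/1 (1 = gene mutated in sample).
#' @param clinical Optional clinical table; when given, sample ids must be a
#'   subset of the clinical table's.
#' @return A tibble of class `cna_mutations` (sample_id + one 0/1 column per
#'   gene).
#' @export
read_mutations <- function(path, clinical = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_mutations(raw, clinical)
}

#' Validate a mutation matrix
#' @inheritParams read_mutations
#' @param mut A data frame: `sample_id` plus one 0/1 column per gene.
#' @return The validated `cna_mutations` tibble.
#' @export
validate_mutations <- function(mut, clinical = NULL) {
  assert_columns(mut, "sample_id", "mutation matrix")
  mut <- tibble::as_tibble(mut)
  mut$sample_id <- as.character(mut$sample_id)
  genes <- setdiff(names(mut), "sample_id")
  if (length(genes) == 0) {
    abort_cnasurv("mutation matrix has no gene columns",
                  class = "cnasurv_format_error")
  }
  vals <- unlist(mut[genes], use.names = FALSE)
  if (!all(vals %in% c(0, 1))) {
    abort_cnasurv("mutation matrix entries must be 0 or 1",
                  class = "cnasurv_validation_error")
  }
  if (!is.null(clinical) && !all(mut$sample_id %in% clinical$sample_id)) {
    abort_cnasurv("mutation matrix contains sample ids absent from the clinical table",
                  class = "cnasurv_validation_error")
  }
  class(mut) <- c("cna_mutations", class(tibble::tibble()))
  mut
}
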