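# internal helpers shared across modules

# run `code` under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister")
}

# normalise chromosome labels: strip "chr" prefix, uppercase X/Y
norm_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  toupper(x)
}

chrom_levels <- c(as.character(1:22), "X", "Y")

is_autosome <- function(chrom) chrom %in% as.character(1:22)

# stop with a classed condition so callers/tests can catch specific failures
abort_cnasurv <- function(message, class) {
  rlang::abort(message, class = c(class, "cnasurv_error"))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_cnasurv(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "cnasurv_format_error"
    )
  }
  invisible(df)
}
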