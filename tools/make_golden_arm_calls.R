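# Builds the synthetic golden files for the arm-caller agreement test.
#
# The reference arm-calling tool itself is not redistributable here, so these
# expected values are computed by an INDEPENDENT brute-force oracle written in
# this script (plain loops over segments and arms, no package code), using the
# tool's published defaults: categories gain (log2 >= t), loss (log2 <= -t),
# neutral; an arm is evaluable when measured coverage >= 0.5 of its length;
# an evaluable arm is called when a category covers >= 0.7 of the measured
# length; AS = altered / evaluable over the 39 autosomal arms.
# Files are labelled *_synthetic_* because they are a constructed stand-in,
# not output of the reference tool.
#
# Run from the repository root:  Rscript tools/make_golden_arm_calls.R

arms <- read.delim("inst/extdata/arm_coordinates_hg19.tsv")

seg_rows <- list()
add <- function(id, chrom, start, end, lr) {
  seg_rows[[length(seg_rows) + 1]] <<- data.frame(
    ID = id, chrom = chrom, loc.start = start, loc.end = end,
    num.mark = NA, seg.mean = lr)
}

a <- function(arm) arms[arms$arm == arm, ]
p1 <- a("1p"); q1 <- a("1q"); p2 <- a("2p"); q2 <- a("2q"); p3 <- a("3p")

# S1: whole-arm gain on 1p, whole-arm loss on 1q, neutral 2p
add("S1", 1, p1$start, p1$end, 0.45)
add("S1", 1, q1$start, q1$end, -0.38)
add("S1", 2, p2$start, p2$end, 0.02)
# S2: 60% gain / 40% neutral on 1p (NO_CALL at fraction 0.7); 1q fully gained
cut60 <- p1$start + round(0.6 * (p1$end - p1$start + 1)) - 1
add("S2", 1, p1$start, cut60, 0.5)
add("S2", 1, cut60 + 1, p1$end, 0.0)
add("S2", 1, q1$start, q1$end, 0.3)
# S3: only 30% of 1p measured (NOT_EVALUABLE); 75% of 2p measured, all lost
cut30 <- p1$start + round(0.3 * (p1$end - p1$start + 1)) - 1
add("S3", 1, p1$start, cut30, 0.6)
cut75 <- p2$start + round(0.75 * (p2$end - p2$start + 1)) - 1
add("S3", 2, p2$start, cut75, -0.5)
# S4: centromere-spanning segment on chr1 (gain); covers all of 1p and 40% of 1q
cut40q <- q1$start + round(0.4 * (q1$end - q1$start + 1)) - 1
add("S4", 1, p1$start, cut40q, 0.35)
add("S4", 1, cut40q + 1, q1$end, 0.0)
# S5: values exactly at the cutoffs (gain counts at >= t)
add("S5", 1, p1$start, p1$end, 0.2)
add("S5", 1, q1$start, q1$end, -0.1)
add("S5", 2, p2$start, p2$end, 0.15)
# S6: mixed gain+loss on 3p, neither dominant; 2q 80% loss / 20% gain -> LOSS at 0.2? (0.8 >= 0.7 yes)
half3 <- p3$start + round(0.5 * (p3$end - p3$start + 1)) - 1
add("S6", 3, p3$start, half3, 0.4)
add("S6", 3, half3 + 1, p3$end, -0.4)
cut80 <- q2$start + round(0.8 * (q2$end - q2$start + 1)) - 1
add("S6", 2, q2$start, cut80, -0.25)
add("S6", 2, cut80 + 1, q2$end, 0.25)
# S7: everything neutral at 0.2 but altered at 0.1 (lr = 0.15 genome-wide on chr1/2)
for (ar in c("1p", "1q", "2p", "2q")) {
  r <- a(ar); add("S7", r$chrom, r$start, r$end, 0.15)
}
# S8: many small segments tiling 1p, 80% at gain level
n_tile <- 10
bnd <- round(seq(p1$start - 1, p1$end, length.out = n_tile + 1))
for (i in seq_len(n_tile)) {
  add("S8", 1, bnd[i] + 1, bnd[i + 1], ifelse(i <= 8, 0.3, 0.0))
}

seg <- do.call(rbind, seg_rows)
write.table(seg, "inst/extdata/golden/toy_cohort.seg", sep = "\t",
            quote = FALSE, row.names = FALSE)

# ---- independent oracle -----------------------------------------------------
oracle_calls <- function(seg, arms, t) {
  out <- list()
  for (id in unique(seg$ID)) {
    s_all <- seg[seg$ID == id, ]
    for (j in seq_len(nrow(arms))) {
      arm <- arms[j, ]
      gain <- loss <- neut <- 0
      s <- s_all[s_all$chrom == arm$chrom, ]
      if (nrow(s) > 0) for (i in seq_len(nrow(s))) {
        lo <- max(s$loc.start[i], arm$start)
        hi <- min(s$loc.end[i], arm$end)
        if (hi < lo) next
        w <- hi - lo + 1
        if (s$seg.mean[i] >= t) gain <- gain + w
        else if (s$seg.mean[i] <= -t) loss <- loss + w
        else neut <- neut + w
      }
      measured <- gain + loss + neut
      arm_len <- arm$end - arm$start + 1
      call <- if (measured / arm_len < 0.5) "NOT_EVALUABLE"
      else {
        fr <- c(GAIN = gain, LOSS = loss, NEUTRAL = neut) / measured
        top <- names(fr)[which.max(fr)]
        if (max(fr) >= 0.7) top else "NO_CALL"
      }
      out[[length(out) + 1]] <- data.frame(
        sample_id = id, arm = arm$arm, cutoff = t, call = call)
    }
  }
  do.call(rbind, out)
}

calls <- rbind(oracle_calls(seg, arms, 0.1), oracle_calls(seg, arms, 0.2))
as_tbl <- do.call(rbind, lapply(split(calls, list(calls$sample_id, calls$cutoff)),
  function(d) data.frame(
    sample_id = d$sample_id[1], cutoff = d$cutoff[1],
    n_altered = sum(d$call %in% c("GAIN", "LOSS")),
    n_evaluable = sum(d$call != "NOT_EVALUABLE"),
    as_score = sum(d$call %in% c("GAIN", "LOSS")) /
      sum(d$call != "NOT_EVALUABLE"))))
as_tbl <- as_tbl[order(as_tbl$cutoff, as_tbl$sample_id), ]

# only keep informative rows of the call table (non-NOT_EVALUABLE)
calls_keep <- calls[calls$call != "NOT_EVALUABLE", ]
write.table(calls_keep, "inst/extdata/golden/golden_arm_calls_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(as_tbl, "inst/extdata/golden/golden_as_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(calls_keep), "calls;", nrow(as_tbl), "AS rows\n")
print(as_tbl, row.names = FALSE)
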