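# Promoter (TA)n repeat genotyping from spanning reads.
#
# Automates the manual procedure used for UGT1A1*28: each read whose
# sequence contains left anchor + (TA)^k + right anchor contiguously
# contributes its repeat-unit count k, the per-sample percentage of
# spanning reads with the reference 6 units (pct_ta6) is computed, and a
# three-cluster rule assigns *1/*1, *1/*28 or *28/*28.

#' Describe a promoter repeat locus
#' @param chrom chromosome.
#' @param repeat_start 1-based position of the first repeat base.
#' @param unit repeat unit (length >= 2).
#' @param ref_units,var_units reference and variant unit counts.
#' @param left_anchor,right_anchor unique flanking sequences (>= 6 bases,
#'   not containing the unit twice in a row).
#' @return a `RepeatLocus` list.
#' @export
repeat_locus <- function(chrom, repeat_start, unit = "TA", ref_units = 6L,
                         var_units = 7L, left_anchor, right_anchor) {
  if (nchar(unit) < 2) stop("repeat unit must be at least 2 bases")
  for (a in c(left_anchor, right_anchor)) {
    if (nchar(a) < 6) stop("anchors must be at least 6 bases")
    if (grepl(strrep(unit, 2), a, fixed = TRUE)) {
      stop("anchor contains the repeat unit twice: ", a)
    }
  }
  structure(list(chrom = chrom, repeat_start = as.integer(repeat_start),
                 unit = unit, ref_units = as.integer(ref_units),
                 var_units = as.integer(var_units),
                 left_anchor = left_anchor, right_anchor = right_anchor),
            class = "RepeatLocus")
}

count_repeat_units <- function(seqs, locus) {
  pat <- paste0(locus$left_anchor, "((?:", locus$unit, ")+)",
                locus$right_anchor)
  m <- regmatches(seqs, regexpr(pat, seqs))
  k <- rep(NA_integer_, length(seqs))
  hit <- regexpr(pat, seqs) > 0
  if (any(hit)) {
    inner <- sub(paste0("^", locus$left_anchor), "",
                 sub(paste0(locus$right_anchor, "$"), "", m))
    k[hit] <- nchar(inner) / nchar(locus$unit)
  }
  # strand robustness: try the reverse complement where unmatched
  miss <- which(!hit)
  if (length(miss)) {
    rc <- revcomp(seqs[miss])
    hit2 <- regexpr(pat, rc) > 0
    if (any(hit2)) {
      m2 <- regmatches(rc, regexpr(pat, rc))
      inner2 <- sub(paste0("^", locus$left_anchor), "",
                    sub(paste0(locus$right_anchor, "$"), "", m2))
      k[miss[hit2]] <- nchar(inner2) / nchar(locus$unit)
    }
  }
  k
}

#' Profile repeat-unit counts in spanning reads
#'
#' A read contributes iff its sequence contains the full
#' anchor-(unit)^k-anchor motif (the count is taken on the read, not the
#' reference); reads merely overlapping but ending inside the repeat are
#' excluded, as are duplicates and secondary alignments.
#'
#' @param reads read tibble or SAM/BAM path.
#' @param locus a `RepeatLocus`.
#' @param sample_id optional label.
#' @param common_range unit counts treated as genuine alleles for the
#'   pct_ta6 denominator; counts outside it are kept in the histogram and
#'   flagged when they exceed `rare_flag_frac` of spanning reads.
#' @param rare_flag_frac see `common_range`.
#' @return a `RepeatReadProfile`: list with `sample_id`,
#'   `spanning_read_count`, `hist` (named counts per k), `pct_ta6`,
#'   `rare_allele_flag`.
#' @export
profile_repeat_reads <- function(reads, locus, sample_id = NULL,
                                 common_range = 5:8,
                                 rare_flag_frac = 0.01) {
  if (is.character(reads)) reads <- read_sam(reads)
  sample_id <- sample_id %||% attr(reads, "sample_id") %||% NA_character_
  if (nrow(reads)) {
    keep <- !flag_has(reads$flag, SAM_DUPLICATE) &
      !flag_has(reads$flag, SAM_SECONDARY) &
      !flag_has(reads$flag, SAM_SUPPLEMENTARY) &
      !flag_has(reads$flag, SAM_UNMAPPED)
    reads <- reads[keep, ]
  }
  # restrict to reads aligned near the locus
  if (nrow(reads)) {
    window <- 2L * max(nchar(reads$seq), 0L) + 100L
    near <- reads$rname == locus$chrom &
      abs(reads$pos - locus$repeat_start) <= window
    reads <- reads[near, ]
  }
  k <- if (nrow(reads)) count_repeat_units(reads$seq, locus) else integer(0)
  k <- k[!is.na(k)]
  hist <- table(factor(k, levels = sort(unique(k))))
  spanning <- length(k)
  common <- k[k %in% common_range]
  odd <- spanning - length(common)
  pct_ta6 <- if (length(common)) {
    100 * sum(common == locus$ref_units) / length(common)
  } else NA_real_
  structure(list(sample_id = sample_id,
                 spanning_read_count = spanning,
                 hist = hist,
                 pct_ta6 = pct_ta6,
                 rare_allele_flag = spanning > 0 &&
                   odd / spanning >= rare_flag_frac),
            class = "RepeatReadProfile")
}

#' @export
print.RepeatReadProfile <- function(x, ...) {
  cat(sprintf("RepeatReadProfile %s: %d spanning reads, pct_ta6 = %.1f\n",
              x$sample_id, x$spanning_read_count, x$pct_ta6))
  invisible(x)
}

#' Assign the three-cluster (TA)n genotype
#'
#' pct_ta6 at or above `upper` is homozygous reference (*1/*1), at or
#' below `lower` homozygous expanded (*28/*28), in between heterozygous
#' (*1/*28); fewer than `min_spanning` spanning reads gives no_call.
#'
#' @param profile a `RepeatReadProfile`.
#' @param lower,upper percentage cut points.
#' @param min_spanning minimum spanning reads for a call.
#' @return one-row tibble: `sample_id`, `genotype`, `pct_ta6`,
#'   `spanning_read_count`.
#' @export
genotype_ta <- function(profile, lower = 25, upper = 75, min_spanning = 20) {
  g <- if (profile$spanning_read_count < min_spanning) {
    "no_call"
  } else if (profile$pct_ta6 >= upper) {
    "*1/*1"
  } else if (profile$pct_ta6 <= lower) {
    "*28/*28"
  } else "*1/*28"
  tibble(sample_id = profile$sample_id, genotype = g,
         pct_ta6 = profile$pct_ta6,
         spanning_read_count = profile$spanning_read_count)
}

#' Cohort pct_ta6 histogram and cluster diagnostics
#'
#' One-dimensional gap clustering of per-sample pct_ta6 values: sorted
#' values are split wherever consecutive values differ by more than `gap`
#' percentage points.  With all three genotypes present the expected
#' pattern is three clusters with means near 100, 50 and 0.
#'
#' @param profiles list of `RepeatReadProfile`.
#' @param binwidth histogram bin width in percentage points.
#' @param gap minimum separation defining a new cluster.
#' @return list: `values` tibble (sample_id, pct_ta6), `hist` tibble
#'   (bin midpoint, count), `n_clusters`, `cluster_means` (ascending).
#' @export
cohort_ta_histogram <- function(profiles, binwidth = 5, gap = 20) {
  if (length(profiles) < 3) stop("cohort histogram needs >= 3 samples")
  vals <- tibble(
    sample_id = vapply(profiles, function(p) p$sample_id, character(1)),
    pct_ta6 = vapply(profiles, function(p) p$pct_ta6, numeric(1)))
  v <- sort(vals$pct_ta6[!is.na(vals$pct_ta6)])
  if (!length(v)) stop("no callable profiles")
  cl <- cumsum(c(1, diff(v) > gap))
  means <- as.numeric(tapply(v, cl, mean))
  breaks <- seq(0, 100 + binwidth, by = binwidth)
  cnt <- table(cut(v, breaks, right = FALSE, include.lowest = TRUE))
  list(values = vals,
       hist = tibble(bin_mid = breaks[-length(breaks)] + binwidth / 2,
                     count = as.integer(cnt)),
       n_clusters = max(cl),
       cluster_means = means)
}
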