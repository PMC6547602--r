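# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (per-base loops, per-read products) so they share no
# code path with the implementation they check.

# Interval-stabbing depth oracle: counts, for every base of every region,
# the reads that qualify under the depth rules (primary, mapped, paired
# with mapped mate, non-duplicate, MAPQ >= 1), using raw flag arithmetic.
oracle_depth <- function(reads, regions) {
  qual <- rep(TRUE, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    f <- reads$flag[i]
    bit <- function(b) bitwAnd(f, b) != 0
    if (bit(0x4) || !bit(0x1) || bit(0x8) || bit(0x400) || bit(0x100) ||
        bit(0x800) || reads$mapq[i] < 1) {
      qual[i] <- FALSE
    }
  }
  ends <- reads$pos + as.integer(sub("M.*", "", reads$cigar)) - 1L
  lapply(seq_along(regions), function(ri) {
    rs <- GenomicRanges::start(regions)[ri]
    re <- GenomicRanges::end(regions)[ri]
    ch <- as.character(GenomicRanges::seqnames(regions))[ri]
    vapply(rs:re, function(b) {
      sum(qual & reads$rname == ch & reads$pos <= b & ends >= b)
    }, numeric(1))
  })
}

# Exhaustive three-genotype likelihood oracle: per-read probability
# products (the binomial coefficient cancels in the normalization).
oracle_posteriors <- function(is_alt, eps) {
  lik <- function(p_alt) prod(ifelse(is_alt, p_alt, 1 - p_alt))
  l <- c(hom_ref = lik(eps), het = lik(0.5), hom_alt = lik(1 - eps))
  l / sum(l)
}

# GC content by naive base counting.
oracle_gc <- function(seqs) {
  chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  sum(chars %in% c("G", "C")) / length(chars)
}

# Chi-squared statistic and p-value for a 2x2 table by the textbook
# formula (no continuity correction).
oracle_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Wilson interval by direct formula (cross-checked elsewhere against
# prop.test, which implements the same interval without correction).
oracle_wilson <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n),
    (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n))
}
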