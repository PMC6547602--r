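# Coverage and read-level QC: FastQC-style read summaries, depth-of-
# coverage over the evaluation footprint with read exclusions, threshold
# summaries, sample-exclusion decisions and GST-null flags.

#' Read-level QC summary
#'
#' @param x a read tibble, a `DNAStringSet` (qualities unavailable), or a
#'   FASTQ path.
#' @param sample_id optional label.
#' @return one-row tibble: `sample_id`, `total_reads`,
#'   `mean_base_quality` (Phred), `gc_percent` (mean per-read GC %),
#'   `gc_sd`.
#' @export
read_qc <- function(x, sample_id = NA_character_) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    # the reader warns about dropping FASTQ description metadata; harmless
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(x))
  }
  if (is.data.frame(x)) {
    if (!nrow(x)) stop("no reads to summarize")
    seqs <- Biostrings::DNAStringSet(x$seq)
    quals <- unlist(lapply(x$qual, string_to_phred))
    sample_id <- if (is.na(sample_id)) attr(x, "sample_id") %||% NA_character_ else sample_id
  } else if (methods::is(x, "QualityScaledDNAStringSet")) {
    if (!length(x)) stop("no reads to summarize")
    seqs <- Biostrings::DNAStringSet(as.character(x))
    quals <- unlist(lapply(as.character(Biostrings::quality(x)),
                           string_to_phred))
  } else if (methods::is(x, "DNAStringSet")) {
    if (!length(x)) stop("no reads to summarize")
    seqs <- x
    quals <- NA_real_
  } else stop("unsupported input to read_qc()")
  gc <- as.numeric(Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE)) * 100
  tibble(sample_id = sample_id,
         total_reads = length(seqs),
         mean_base_quality = mean(quals),
         gc_percent = mean(gc),
         gc_sd = stats::sd(gc))
}

#' Depth-of-coverage over evaluation regions
#'
#' Depth at a base is the number of qualifying reads covering it: primary,
#' mapped, paired with a mapped mate, non-duplicate, and mapping quality
#' at or above `min_mapq` (non-specific matches excluded).  Bases outside
#' the evaluation regions are ignored.
#'
#' @param reads a read tibble or SAM/BAM path.
#' @param regions evaluation `GRanges` (see [evaluation_regions()]).
#' @param sample_id optional label (taken from the tibble attribute when
#'   absent).
#' @param min_mapq minimum mapping quality for inclusion.
#' @param detect_duplicates mark duplicates from identical fragment
#'   endpoints when no record carries a duplicate flag (see
#'   [qualifying_reads()]).
#' @return a `CoverageTrack`: list with `sample_id`, `regions`, `depth`
#'   (per-region integer vectors) and `batch`.
#' @export
depth_of_coverage <- function(reads, regions, sample_id = NULL,
                              min_mapq = 1L, detect_duplicates = TRUE) {
  if (is.character(reads)) reads <- read_sam(reads)
  sample_id <- sample_id %||% attr(reads, "sample_id") %||% NA_character_
  batch <- attr(reads, "batch") %||% NA_character_
  q <- qualifying_reads(reads, min_mapq = min_mapq,
                        detect_duplicates = detect_duplicates)
  rs <- GenomicRanges::start(regions)
  re <- GenomicRanges::end(regions)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  depth <- vector("list", length(regions))
  if (nrow(q)) {
    gr <- GenomicRanges::GRanges(q$rname, IRanges::IRanges(q$pos, read_end(q)))
    cov <- GenomicRanges::coverage(gr)
    flat <- lapply(as.list(cov), as.integer)
    for (i in seq_along(regions)) {
      ch <- chroms[i]
      if (!ch %in% names(flat)) {
        depth[[i]] <- integer(re[i] - rs[i] + 1L)
        next
      }
      v <- flat[[ch]]
      want <- rs[i]:re[i]
      d <- integer(length(want))
      avail <- want <= length(v)
      d[avail] <- v[want[avail]]
      depth[[i]] <- d
    }
  } else {
    depth <- lapply(seq_along(regions), function(i) integer(re[i] - rs[i] + 1L))
  }
  structure(list(sample_id = sample_id, regions = regions, depth = depth,
                 batch = batch),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack %s: %d regions, %d bases, mean DOC %.1f\n",
              x$sample_id, length(x$regions),
              sum(lengths(x$depth)), mean(unlist(x$depth))))
  invisible(x)
}

#' Coverage summary with threshold fractions
#'
#' @param track a `CoverageTrack`.
#' @param panel optional `PanelDefinition` (unused beyond validation; the
#'   track's regions carry the gene assignment).
#' @return a `CoverageSummary`: list with a one-row `stats` tibble
#'   (`mean_doc`, `median_doc`, `pct_ge_1x` ... `pct_ge_30x`) and a
#'   `gene_doc` tibble of per-gene median DOC (shared regions are carried
#'   by their canonical gene, so each base counts once).
#' @export
coverage_summary <- function(track, panel = NULL) {
  d <- unlist(track$depth)
  pct <- function(t) 100 * mean(d >= t)
  genes <- track$regions$gene
  gene_doc <- tibble(
    gene = unique(genes),
    median_doc = vapply(unique(genes), function(g) {
      stats::median(as.numeric(unlist(track$depth[genes == g])))
    }, numeric(1)))
  structure(list(
    sample_id = track$sample_id,
    batch = track$batch,
    stats = tibble(sample_id = track$sample_id,
                   mean_doc = mean(d), median_doc = stats::median(as.numeric(d)),
                   pct_ge_1x = pct(1), pct_ge_10x = pct(10),
                   pct_ge_20x = pct(20), pct_ge_30x = pct(30)),
    gene_doc = gene_doc),
    class = "CoverageSummary")
}

#' @export
print.CoverageSummary <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("CoverageSummary %s: mean %.1fx median %.0fx; ",
                     ">=1x %.1f%% >=10x %.1f%% >=20x %.1f%% >=30x %.1f%%\n"),
              x$sample_id, s$mean_doc, s$median_doc, s$pct_ge_1x,
              s$pct_ge_10x, s$pct_ge_20x, s$pct_ge_30x))
  invisible(x)
}

#' Sample exclusion decision
#'
#' A sample is excluded from variant analysis when more than
#' `max_pct_below_10x` percent of its target bases are below 10x (strict
#' "more than"), when its read count falls below `min_reads`, or when its
#' mean read GC deviates from the cohort median by more than
#' `gc_k` robust standard deviations (1.4826 * MAD, floored at
#' `gc_mad_floor` percentage points to keep degenerate cohorts sane).
#'
#' @param summary a `CoverageSummary`.
#' @param read_summary a [read_qc()] row for the same sample.
#' @param cohort_gc numeric vector of per-sample mean GC percentages for
#'   the cohort (>= 3 samples).
#' @param min_reads,max_pct_below_10x,gc_k,gc_mad_floor thresholds.
#' @return one-row tibble: `sample_id`, `excluded`, `reasons`
#'   (`;`-separated subset of low_reads / high_gc_deviation /
#'   low_coverage_fraction).
#' @export
sample_exclusion <- function(summary, read_summary, cohort_gc,
                             min_reads = 1000, max_pct_below_10x = 20,
                             gc_k = 3, gc_mad_floor = 0.25) {
  if (length(cohort_gc) < 3) stop("cohort GC distribution needs >= 3 samples")
  reasons <- character(0)
  if ((100 - summary$stats$pct_ge_10x) > max_pct_below_10x) {
    reasons <- c(reasons, "low_coverage_fraction")
  }
  if (read_summary$total_reads < min_reads) reasons <- c(reasons, "low_reads")
  rsd <- max(stats::mad(cohort_gc), gc_mad_floor)
  if (abs(read_summary$gc_percent - stats::median(cohort_gc)) > gc_k * rsd) {
    reasons <- c(reasons, "high_gc_deviation")
  }
  tibble(sample_id = summary$sample_id,
         excluded = length(reasons) > 0,
         reasons = paste(reasons, collapse = ";"))
}

#' Flag putative homozygous whole-gene deletions (GST-style)
#'
#' A gene is flagged when its median DOC is below `fraction` of the
#' sample's overall median DOC (near-zero coverage).
#'
#' @param summary a `CoverageSummary`.
#' @param genes genes to assess.
#' @param fraction flagging threshold relative to the sample median.
#' @return tibble: `gene`, `median_doc`, `relative_doc`, `flagged`.
#' @export
gst_null_flag <- function(summary, genes = c("GSTM1", "GSTT1"),
                          fraction = 0.05) {
  overall <- summary$stats$median_doc
  if (overall == 0) {
    stop("sample overall median DOC is zero; sample should be excluded")
  }
  gd <- summary$gene_doc[summary$gene_doc$gene %in% genes, ]
  missing <- setdiff(genes, gd$gene)
  if (length(missing)) stop("genes absent from track: ",
                            paste(missing, collapse = ", "))
  tibble(sample_id = summary$sample_id, gene = gd$gene,
         median_doc = gd$median_doc,
         relative_doc = gd$median_doc / overall,
         flagged = gd$median_doc < fraction * overall)
}

#' Write per-sample coverage reports
#'
#' Emits a one-line coverage summary report and a base-by-base coverage
#' table (tab-separated text).
#' @param summary a `CoverageSummary`.
#' @param track the matching `CoverageTrack`.
#' @param dir output directory.
#' @export
write_coverage_report <- function(summary, track, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- summary$sample_id
  write.table(cbind(summary$stats, batch = summary$batch),
              file.path(dir, paste0(id, "_coverage_summary.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rs <- GenomicRanges::start(track$regions)
  base_tab <- data.frame(
    chrom = rep(as.character(GenomicRanges::seqnames(track$regions)),
                lengths(track$depth)),
    pos = unlist(lapply(seq_along(track$depth), function(i) {
      rs[i] + seq_along(track$depth[[i]]) - 1L
    })),
    gene = rep(track$regions$gene, lengths(track$depth)),
    depth = unlist(track$depth))
  write.table(base_tab, file.path(dir, paste0(id, "_coverage_table.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
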