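# Shared fixtures: a cached simulated cohort (built once per test run)
# and small constructors for hand-made reads, tracks and profiles.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Mid-size cohort exercising QC exclusions: 12 samples at 80x, one with a
# crashed read count and one with shifted GC.
mini_cohort <- function() {
  fixture("mini_cohort", {
    cfg <- sim_config(seed = 42, n_samples = 12, mean_depth = 80,
                      n_excluded_low_reads = 1, n_excluded_high_gc = 1)
    cohort <- simulate_cohort(cfg)
    cohort$eval <- evaluation_regions(cohort$ref$panel)
    cohort$tracks <- lapply(cohort$reads, depth_of_coverage,
                            regions = cohort$eval)
    cohort
  })
}

make_reads <- function(pos, len = 10L, flag = 99L, rname = "chr1",
                       mapq = 60L, seq = NULL, qual_char = "I",
                       pnext = NULL) {
  n <- length(pos)
  flag <- rep_len(as.integer(flag), n)
  len <- rep_len(as.integer(len), n)
  seq <- seq %||% vapply(len, function(l) strrep("A", l), character(1))
  tibble::tibble(
    qname = sprintf("r%03d", seq_len(n)), flag = flag, rname = rname,
    pos = as.integer(pos), mapq = rep_len(as.integer(mapq), n),
    cigar = paste0(nchar(seq), "M"), rnext = "=",
    pnext = as.integer(pnext %||% (pos + len)), tlen = 2L * len,
    seq = seq,
    qual = vapply(nchar(seq), function(l) strrep(qual_char, l), character(1)))
}

make_track <- function(depth_list, genes = NULL, sample_id = "T1",
                       batch = "plex24", chrom = "chr1") {
  genes <- genes %||% sprintf("G%d", seq_along(depth_list))
  starts <- cumsum(c(1L, head(lengths(depth_list), -1) + 50L))
  regions <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(starts, starts + lengths(depth_list) - 1L),
    gene = genes, kind = "exon")
  structure(list(sample_id = sample_id, regions = regions,
                 depth = lapply(depth_list, as.integer), batch = batch),
            class = "CoverageTrack")
}

make_profile <- function(pct, sample_id = "P1", spanning = 100L) {
  structure(list(sample_id = sample_id, spanning_read_count = spanning,
                 hist = table(integer(0)), pct_ta6 = pct,
                 rare_allele_flag = FALSE),
            class = "RepeatReadProfile")
}

# Annotation set mirroring a published cohort composition: 1093 unique
# variants in the printed class counts, with exonic MAF categories of
# 284 common / 153 low frequency / 536 rare / 105 novel.
cohort_annotations <- function() {
  classes <- c(rep("non_synonymous", 605), rep("synonymous", 417),
               rep("frameshift_indel", 18), rep("nonframeshift_indel", 17),
               rep("splicing", 7), rep("stopgain_or_loss", 14),
               rep("known_noncoding", 15))
  n <- length(classes)
  ann <- tibble::tibble(
    variant_id = sprintf("v%04d", seq_len(n)),
    gene = rep(sprintf("G%02d", 1:20), length.out = n),
    class = classes)
  exonic <- which(ann$class != "known_noncoding")
  maf <- rep(NA_real_, n)
  rsid <- rep(NA_character_, n)
  maf[exonic[1:284]] <- 0.2
  maf[exonic[285:437]] <- 0.03
  maf[exonic[438:973]] <- 0.004
  rsid[exonic[1:973]] <- sprintf("rs%d", exonic[1:973])
  ann$maf_exac <- maf
  ann$rsid <- rsid   # remaining 105 exonic variants are novel
  ann
}

make_summary <- function(pct_ge_10x, sample_id = "S1", median_doc = 50,
                         gene_doc = NULL) {
  structure(list(sample_id = sample_id, batch = "plex24",
                 stats = tibble::tibble(sample_id = sample_id,
                                        mean_doc = 50, median_doc = median_doc,
                                        pct_ge_1x = 100, pct_ge_10x = pct_ge_10x,
                                        pct_ge_20x = 90, pct_ge_30x = 85),
                 gene_doc = gene_doc %||%
                   tibble::tibble(gene = character(), median_doc = numeric())),
            class = "CoverageSummary")
}
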