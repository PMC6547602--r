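# Read QC, depth-of-coverage with read exclusions, coverage summaries,
# sample exclusion and GST-null flags.

test_that("read_qc computes per-read GC and mean base quality", {
  reads <- make_reads(c(1, 1), seq = c("ATGC", "GGCC"),
                      qual_char = rawToChar(as.raw(30 + 33)))
  qc <- read_qc(reads)
  expect_equal(qc$gc_percent, 75)          # (50 + 100) / 2
  expect_equal(qc$mean_base_quality, 30)
  expect_equal(qc$total_reads, 2)
  expect_error(read_qc(reads[0, ]), "no reads")
})

test_that("simulated read GC agrees with a brute-force base count", {
  co <- mini_cohort()
  rd <- co$reads[["S003"]]
  qc <- read_qc(rd)
  expect_equal(qc$gc_percent, 100 * oracle_gc(rd$seq), tolerance = 0.01)
})

test_that("read_qc works from FASTQ files", {
  co <- mini_cohort()
  rd <- co$reads[["S004"]]
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rd, path)
  qc <- read_qc(path)
  primary <- sum(!bitwAnd(rd$flag, 0x100) & !bitwAnd(rd$flag, 0x800))
  expect_equal(qc$total_reads, primary)
  expect_equal(qc$gc_percent, read_qc(rd)$gc_percent, tolerance = 0.01)
})

test_that("overlapping qualifying reads stack to the expected depth", {
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 60),
                                    gene = "G1", kind = "exon")
  # 10 staggered qualifying reads all covering base 25
  reads <- make_reads(16:25, len = 10)
  trk <- depth_of_coverage(reads, regions)
  expect_equal(trk$depth[[1]][25], 10)
  expect_equal(trk$depth[[1]][15], 0)
  expect_equal(trk$depth[[1]][35], 0)
})

test_that("duplicate-flagged copies are excluded from depth", {
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 40),
                                    gene = "G1", kind = "exon")
  # 5 reads over one span, 3 of them duplicate-flagged copies
  reads <- make_reads(rep(10, 5), len = 10,
                      flag = c(99L, 99L, 99L + 1024L, 99L + 1024L,
                               99L + 1024L))
  reads$qname <- c("a", "b", "a:d1", "a:d2", "a:d3")
  trk <- depth_of_coverage(reads, regions)
  expect_equal(trk$depth[[1]][15], 2)
})

test_that("unpaired, mate-unmapped, secondary and MAPQ-0 reads are excluded", {
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 40),
                                    gene = "G1", kind = "exon")
  flags <- c(99L,          # qualifying
             0L,           # unpaired
             99L + 8L,     # mate unmapped
             99L + 256L,   # secondary
             99L)          # MAPQ 0 (below)
  reads <- make_reads(rep(10, 5), len = 10, flag = flags,
                      mapq = c(60L, 60L, 60L, 60L, 0L))
  trk <- depth_of_coverage(reads, regions, detect_duplicates = FALSE)
  expect_equal(trk$depth[[1]][12], 1)
})

test_that("duplicate marking by identical endpoints keeps the best copy", {
  reads <- make_reads(c(10, 10, 30), len = 10)
  reads$qual <- c(strrep("I", 10), strrep("5", 10), strrep("I", 10))
  marked <- mark_duplicates(reads)
  dup <- bitwAnd(marked$flag, 1024L) != 0
  expect_equal(sum(dup), 1)
  expect_equal(marked$qname[dup], "r002")  # the lower-quality copy
})

test_that("depth equals the brute-force interval oracle on fuzzed inputs", {
  withr::local_seed(404)
  for (rep in 1:15) {
    n <- sample(5:40, 1)
    flags <- sample(c(99L, 147L, 99L + 1024L, 99L + 256L, 0L, 99L + 8L),
                    n, replace = TRUE)
    reads <- make_reads(sample(1:80, n, replace = TRUE),
                        len = sample(5:20, n, replace = TRUE),
                        flag = flags,
                        mapq = sample(c(0L, 30L, 60L), n, replace = TRUE))
    regions <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(1, 61), c(50, 120)),
      gene = c("G1", "G2"), kind = "exon")
    trk <- depth_of_coverage(reads, regions, detect_duplicates = FALSE)
    expect_equal(lapply(trk$depth, as.numeric), oracle_depth(reads, regions))
  }
})

test_that("excluding duplicates never increases depth anywhere", {
  co <- mini_cohort()
  rd <- co$reads[["S005"]]
  regions <- co$eval[co$eval$gene == "CYP2C19"]
  with_excl <- depth_of_coverage(rd, regions)
  no_flags <- rd
  no_flags$flag <- bitwAnd(no_flags$flag, bitwNot(1024L))
  without_excl <- depth_of_coverage(no_flags, regions,
                                    detect_duplicates = FALSE)
  d1 <- unlist(with_excl$depth)
  d2 <- unlist(without_excl$depth)
  expect_true(all(d1 <= d2))
})

test_that("coverage summary thresholds are exact on constructed tracks", {
  trk <- make_track(list(rep(50L, 200)))
  s <- coverage_summary(trk)
  expect_equal(s$stats$pct_ge_1x, 100)
  expect_equal(s$stats$pct_ge_30x, 100)
  expect_equal(s$stats$median_doc, 50)

  trk2 <- make_track(list(c(rep(5L, 120), rep(40L, 880))))
  s2 <- coverage_summary(trk2)
  expect_equal(s2$stats$pct_ge_10x, 88)
  expect_equal(s2$stats$pct_ge_1x, 100)
})

test_that("threshold percentages are monotone on random tracks", {
  withr::local_seed(11)
  for (rep in 1:25) {
    trk <- make_track(list(as.integer(rnbinom(300, mu = runif(1, 1, 60),
                                              size = 2))))
    s <- coverage_summary(trk)$stats
    expect_true(s$pct_ge_1x >= s$pct_ge_10x)
    expect_true(s$pct_ge_10x >= s$pct_ge_20x)
    expect_true(s$pct_ge_20x >= s$pct_ge_30x)
    expect_true(s$pct_ge_30x >= 0 && s$pct_ge_1x <= 100)
  }
})

test_that("the 20%-below-10x exclusion rule is strict", {
  rq <- tibble::tibble(sample_id = "S1", total_reads = 1e6,
                       mean_base_quality = 35, gc_percent = 45.6, gc_sd = 5)
  cohort_gc <- c(45, 45.5, 46, 45.8)
  dec <- sample_exclusion(make_summary(79), rq, cohort_gc)
  expect_true(dec$excluded)
  expect_match(dec$reasons, "low_coverage_fraction")
  dec2 <- sample_exclusion(make_summary(80), rq, cohort_gc)
  expect_false(dec2$excluded)
  expect_equal(dec2$reasons, "")
})

test_that("low read count and GC deviation trigger exclusion", {
  rq_low <- tibble::tibble(sample_id = "S1", total_reads = 900,
                           mean_base_quality = 35, gc_percent = 45.6,
                           gc_sd = 5)
  cohort_gc <- c(44, 45.6, 46.2, 45.1, 45.9)
  expect_match(sample_exclusion(make_summary(95), rq_low, cohort_gc)$reasons,
               "low_reads")
  rq_gc <- rq_low; rq_gc$total_reads <- 1e6; rq_gc$gc_percent <- 56
  dec <- sample_exclusion(make_summary(95), rq_gc, cohort_gc)
  expect_true(dec$excluded)
  expect_equal(dec$reasons, "high_gc_deviation")
  expect_error(sample_exclusion(make_summary(95), rq_gc, c(45, 46)),
               ">= 3 samples")
})

test_that("simulated QC-failure samples are excluded and clean ones kept", {
  co <- mini_cohort()
  qcs <- lapply(co$reads, read_qc)
  cohort_gc <- vapply(qcs, function(q) q$gc_percent, numeric(1))
  decisions <- lapply(co$truth$samples$sample_id, function(s) {
    sample_exclusion(coverage_summary(co$tracks[[s]]), qcs[[s]], cohort_gc)
  })
  dec <- do.call(rbind, decisions)
  truth <- co$truth$samples
  expect_true(all(dec$excluded[truth$exclude_low_reads]))
  expect_match(dec$reasons[truth$exclude_low_reads], "low_reads")
  expect_true(all(dec$excluded[truth$exclude_high_gc]))
  expect_match(dec$reasons[truth$exclude_high_gc], "high_gc_deviation")
  clean <- !truth$exclude_low_reads & !truth$exclude_high_gc
  expect_true(all(!dec$excluded[clean]))
})

test_that("GST-null flags fire on zero-coverage genes only", {
  gd <- tibble::tibble(gene = c("GSTM1", "GSTT1"), median_doc = c(0, 100))
  s <- make_summary(95, median_doc = 100, gene_doc = gd)
  flags <- gst_null_flag(s)
  expect_equal(flags$flagged, c(TRUE, FALSE))
  s0 <- make_summary(95, median_doc = 0, gene_doc = gd)
  expect_error(gst_null_flag(s0), "zero")
})

test_that("simulated GST deletion status is recovered across the cohort", {
  co <- mini_cohort()
  truth <- co$truth
  keep <- !truth$samples$exclude_low_reads & !truth$samples$exclude_high_gc
  ok <- 0L; n <- 0L
  for (s in truth$samples$sample_id[keep]) {
    flags <- gst_null_flag(coverage_summary(co$tracks[[s]]))
    for (g in c("GSTM1", "GSTT1")) {
      want <- truth$cnv$copies[truth$cnv$sample_id == s &
                                 truth$cnv$gene == g] == 0
      got <- flags$flagged[flags$gene == g]
      n <- n + 1L
      ok <- ok + as.integer(got == want)
    }
  }
  expect_gte(ok / n, 0.95)
})

test_that("coverage reports are written as parseable TSV", {
  co <- mini_cohort()
  trk <- co$tracks[["S006"]]
  s <- coverage_summary(trk)
  dir <- withr::local_tempdir()
  write_coverage_report(s, trk, dir)
  sm <- read.delim(file.path(dir, "S006_coverage_summary.tsv"))
  expect_equal(sm$pct_ge_10x, s$stats$pct_ge_10x)
  bt <- read.delim(file.path(dir, "S006_coverage_table.tsv"))
  expect_equal(nrow(bt), sum(lengths(trk$depth)))
})
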