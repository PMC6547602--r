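# Functional/frequency/deleteriousness classification and cohort
# summaries.

# Two-exon toy gene: CDS "ATG GCT CGA TAA" split as ATGGCT | CGATAA with a
# 100-bp intron.
toy_model <- function() {
  genome <- c(chrZ = paste0(strrep("C", 100), "ATGGCT", strrep("G", 100),
                            "CGATAA", strrep("C", 100)))
  exons <- GenomicRanges::GRanges("chrZ",
                                  IRanges::IRanges(c(101, 207), c(106, 212)))
  list(model = transcript_model("TOY", exons, genome), genome = genome)
}

test_that("coding SNVs classify by codon translation", {
  m <- toy_model()$model
  # GCT -> GTT: Ala -> Val
  expect_equal(classify_function("chrZ", 105, "C", "T", m), "non_synonymous")
  # GCT -> GCA: synonymous
  expect_equal(classify_function("chrZ", 106, "T", "A", m), "synonymous")
  # CGA -> TGA: stop gained
  expect_equal(classify_function("chrZ", 207, "C", "T", m),
               "stopgain_or_loss")
  # TAA -> CAA: stop lost
  expect_equal(classify_function("chrZ", 210, "T", "C", m),
               "stopgain_or_loss")
})

test_that("positions within 2 bases of an exon boundary are splicing", {
  m <- toy_model()$model
  expect_equal(classify_function("chrZ", 107, "G", "A", m), "splicing")
  expect_equal(classify_function("chrZ", 108, "G", "A", m), "splicing")
  expect_error(classify_function("chrZ", 109, "G", "A", m),
               "outside the gene model")
  expect_equal(classify_function("chrZ", 205, "G", "A", m), "splicing")
})

test_that("indel length modulo 3 separates frameshift from in-frame", {
  m <- toy_model()$model
  expect_equal(classify_function("chrZ", 103, "GG", "G", m),
               "frameshift_indel")
  expect_equal(classify_function("chrZ", 103, "GGCT", "G", m),
               "nonframeshift_indel")
})

test_that("known non-coding regions take precedence", {
  m <- toy_model()$model
  nc <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 50))
  expect_equal(classify_function("chrZ", 25, "C", "T", m,
                                 noncoding_regions = nc),
               "known_noncoding")
})

test_that("minus-strand transcripts translate through the complement", {
  # reverse-complement of ATGGCTTAA embedded on the forward strand
  genome <- c(chrW = paste0(strrep("A", 300), revcomp("ATGGCTTAA"),
                            strrep("A", 100)))
  exons <- GenomicRanges::GRanges("chrW", IRanges::IRanges(301, 309))
  m <- transcript_model("TOYM", exons, genome, strand = "-")
  # cds position 5 (middle of GCT) corresponds to genome position 305;
  # G -> A on the genome is C -> T on the transcript: Ala -> Val
  expect_equal(classify_function("chrW", 305, "G", "A", m),
               "non_synonymous")
})

test_that("reference mismatches against the model are caught", {
  m <- toy_model()$model
  expect_error(classify_function("chrZ", 105, "A", "T", m),
               "does not match")
})

test_that("MAF categories follow the stated bands and fold the minor allele", {
  expect_equal(classify_maf(0.25, TRUE), "common")
  expect_equal(classify_maf(0.05, TRUE), "common")
  expect_equal(classify_maf(0.03, TRUE), "low_frequency")
  expect_equal(classify_maf(0.01, TRUE), "low_frequency")
  expect_equal(classify_maf(0.005, TRUE), "rare")
  expect_equal(classify_maf(NA, TRUE), "rare")    # known rsid, no MAF
  expect_equal(classify_maf(NA, FALSE), "novel")
  expect_equal(classify_maf(0.93, TRUE), "common")  # folded to 0.07
  expect_error(classify_maf(1.2, TRUE), "outside")
})

test_that("deleteriousness cutoffs are strict in the stated directions", {
  f <- flag_deleterious(cadd = c(25, 20, NA), sift = c(0.04, 0.05, NA),
                        polyphen = c(0.9, 0.85, NA))
  expect_equal(f$by_cadd, c(TRUE, FALSE, NA))
  expect_equal(f$by_sift, c(TRUE, FALSE, NA))
  expect_equal(f$by_polyphen, c(TRUE, FALSE, NA))
  expect_error(flag_deleterious(sift = 1.5), "SIFT")
  # monotone in each score's direction
  withr::local_seed(5)
  cadd <- sort(runif(20, 0, 40))
  expect_true(!is.unsorted(flag_deleterious(cadd = cadd)$by_cadd))
  sift <- sort(runif(20))
  expect_true(!is.unsorted(rev(flag_deleterious(sift = sift)$by_sift)))
})

test_that("cohort class counts and percentages match the printed totals", {
  s <- summarize_cohort(cohort_annotations())
  expect_equal(s$n_variants, 1093)
  cc <- s$class_counts
  expect_equal(cc$n[cc$class == "non_synonymous"], 605)
  expect_equal(cc$pct[cc$class == "non_synonymous"], 55.4)
  expect_equal(cc$pct[cc$class == "synonymous"], 38.2)  # 417/1093
  expect_equal(sum(cc$n), 1093)
  expect_equal(s$exonic_denominator, 1078)
  expect_equal(s$pct_rare_or_novel, 59.5)
  mc <- s$maf_counts
  expect_equal(mc$pct[mc$category == "common"], 26.3)
  expect_equal(mc$pct[mc$category == "low_frequency"], 14.2)
})

test_that("a single variant is 100% of its class", {
  s <- summarize_cohort(tibble::tibble(variant_id = "v1", gene = "G",
                                       class = "non_synonymous",
                                       maf_exac = NA, rsid = NA))
  expect_equal(s$class_counts$pct[s$class_counts$class == "non_synonymous"],
               100)
})

test_that("random annotation sets match a brute-force tally and partition", {
  withr::local_seed(21)
  for (rep in 1:10) {
    n <- sample(50:300, 1)
    ann <- tibble::tibble(
      variant_id = sprintf("v%d", seq_len(n)),
      gene = sample(LETTERS[1:6], n, replace = TRUE),
      class = sample(c("non_synonymous", "synonymous", "splicing",
                       "known_noncoding"), n, replace = TRUE),
      maf_exac = ifelse(runif(n) < 0.3, NA, runif(n, 0, 0.5)),
      rsid = ifelse(runif(n) < 0.2, NA, "rs1"))
    s <- summarize_cohort(ann)
    for (cl in unique(ann$class)) {
      expect_equal(s$class_counts$n[s$class_counts$class == cl],
                   sum(ann$class == cl))
    }
    # every variant gets exactly one class and one MAF category
    expect_equal(sum(s$class_counts$n), n)
    expect_equal(sum(s$maf_counts$n), s$exonic_denominator)
    # percentages sum to 100 up to 1-decimal rounding
    expect_lt(abs(sum(s$class_counts$pct) - 100), 0.35)
  }
})

test_that("the 2x2 proportion test matches the textbook chi-squared", {
  tab <- matrix(c(30, 70, 10, 90), nrow = 2, byrow = TRUE)
  res <- deleterious_proportion_test(tab)
  expect_equal(res$test, "chisq")
  expect_equal(unname(res$prop), c(0.30, 0.10))
  expect_equal(res$p, oracle_chisq_2x2(tab), tolerance = 1e-12)
  even <- matrix(c(20, 80, 20, 80), nrow = 2, byrow = TRUE)
  expect_equal(deleterious_proportion_test(even)$p, 1, tolerance = 1e-12)
  sparse <- matrix(c(2, 8, 1, 20), nrow = 2, byrow = TRUE)
  expect_equal(deleterious_proportion_test(sparse)$test, "fisher")
})

test_that("simulated rare-variant enrichment is detected as rare > common", {
  withr::local_seed(31)
  hits <- 0
  for (rep in 1:20) {
    n <- 400
    rare <- runif(n) < 0.6
    cadd <- ifelse(rare, ifelse(runif(n) < 0.45, 30, 5),
                   ifelse(runif(n) < 0.15, 30, 5))
    ann <- tibble::tibble(
      variant_id = sprintf("v%d", 1:n), gene = "G",
      class = "non_synonymous",
      maf_exac = ifelse(rare, 0.001, 0.2),
      rsid = "rs1", cadd = cadd, sift = NA_real_, polyphen = NA_real_)
    ann$sift <- ifelse(cadd > 20, 0.01, 0.6)
    ann$polyphen <- ifelse(cadd > 20, 0.95, 0.2)
    s <- summarize_cohort(ann)
    cmp <- compare_rare_vs_common_deleterious(s)
    hits <- hits + as.integer(all(cmp$direction == "rare > common" &
                                    cmp$p < 0.05))
  }
  expect_gte(hits / 20, 0.95)
})

test_that("per-subject deleterious and homozygous level-1 counts tally", {
  ann <- tibble::tibble(
    variant_id = c("v1", "v2", "v3"), gene = "G",
    class = "non_synonymous",
    maf_exac = c(0.2, 0.001, NA), rsid = c("rs1", "rs2", NA),
    cadd = c(25, 30, 5))
  g <- tibble::tibble(
    sample_id = c("A", "A", "A", "B"),
    variant_id = c("v1", "v2", "v3", "v1"),
    genotype = c("het", "hom_alt", "hom_alt", "het"))
  ks <- tibble::tibble(variant_id = c("v1", "v2"),
                       pharmgkb_level = c("1A", "3"))
  s <- summarize_cohort(ann, genotypes = g, known_sites = ks)
  ps <- s$per_subject
  expect_equal(ps$n_deleterious_het[ps$sample_id == "A"], 1)
  expect_equal(ps$n_deleterious_hom[ps$sample_id == "A"], 1)
  expect_equal(ps$n_hom_level1[ps$sample_id == "A"], 0)  # v1 only het
  expect_equal(ps$n_deleterious_het[ps$sample_id == "B"], 1)
})
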