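# Phenotype prediction, actionable reporting, concordance statistics.

test_that("activity scores map canonical diplotypes to their phenotypes", {
  cases <- list(list("*4", "*5", NA, 1L, "PM"),
                list("*3", "*5", NA, 1L, "PM"),
                list("*1", "*5", NA, 1L, "IM"),
                list("*1", "*1", "*1", 3L, "UM"),
                list("*1", "*4", "*4", 3L, "IM"),
                list("*41", "*4", "*4", 3L, "IM"),
                list("*1", "*1", NA, 2L, "NM"),
                list("*1", "*41", NA, 2L, "NM"))
  for (cs in cases) {
    dip <- diplotype(cs[[1]], cs[[2]],
                     duplicated_allele = cs[[3]], copies = cs[[4]])
    expect_equal(predict_phenotype(dip)$phenotype, cs[[5]])
  }
})

test_that("every bundled CNV-carrier row reproduces its reported phenotype", {
  tab <- cyp2d6_cnv_validation()
  expect_equal(nrow(tab), 15)
  for (i in seq_len(nrow(tab))) {
    alleles <- strsplit(tab$genotype[i], "/", fixed = TRUE)[[1]]
    copies <- if (tab$taqman_copy_number[i] == "more_than_2") 3L else
      as.integer(tab$taqman_copy_number[i])
    dip <- diplotype(alleles[1], alleles[2],
                     duplicated_allele = tab$duplicated_allele[i],
                     copies = copies)
    expect_equal(predict_phenotype(dip)$phenotype,
                 tab$phenotype_reported[i])
  }
})

test_that("unknown alleles error and invalid diplotypes are rejected", {
  expect_error(predict_phenotype(diplotype("*1", "*99")), "\\*99")
  expect_error(diplotype("*1", "*4", copies = 1L), "\\*5")
  expect_error(diplotype("*1", "*4", duplicated_allele = "*41",
                         copies = 3L), "carried")
  expect_error(diplotype("*1", "*4", duplicated_allele = "*4",
                         copies = 2L), "more than 2")
})

test_that("an unknown duplicated allele reports both candidate phenotypes", {
  dip <- diplotype("*1", "*4", copies = 3L)
  p <- predict_phenotype(dip)
  expect_true(p$ambiguous)
  expect_equal(p$phenotype, "NM/IM")
})

test_that("removing a functional allele never raises the phenotype band", {
  band <- c(PM = 1, IM = 2, NM = 3, UM = 4)
  for (alleles2 in list(c("*1", "*1"), c("*1", "*41"), c("*1", "*4"))) {
    base <- band[predict_phenotype(diplotype(alleles2[1],
                                             alleles2[2]))$phenotype]
    worse <- band[predict_phenotype(diplotype("*4", alleles2[2],
                                              copies = 2L))$phenotype]
    expect_lte(worse, base)
  }
})

test_that("homozygous level 1A/1B sites flag subjects, heterozygous do not", {
  sites <- tibble::tibble(rsid = c("rs1", "rs2", "rs3"),
                          pharmgkb_level = c("1A", "3", "1B"))
  calls <- tibble::tibble(
    sample_id = c("A", "A", "B", "B", "C"),
    rsid = c("rs1", "rs2", "rs1", "rs3", "rs2"),
    genotype = c("hom_alt", "het", "het", "het", "hom_alt"))
  rpt <- actionable_report(calls, sites)
  s <- rpt$subjects
  expect_true(s$flagged[s$sample_id == "A"])
  expect_equal(s$sites[s$sample_id == "A"], "rs1")
  expect_false(s$flagged[s$sample_id == "B"])   # only heterozygous
  expect_false(s$flagged[s$sample_id == "C"])   # level 3 site
  expect_equal(rpt$n_flagged, 1)
})

test_that("the cohort actionable percentage uses whole-percent rounding", {
  calls <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:235),
    rsid = "rs1",
    genotype = c(rep("hom_alt", 183), rep("het", 52)))
  sites <- tibble::tibble(rsid = "rs1", pharmgkb_level = "1A")
  rpt <- actionable_report(calls, sites)
  expect_equal(rpt$n_flagged, 183)
  expect_equal(rpt$pct_flagged, 78)
})

test_that("perfect agreement gives 100% concordance with tight intervals", {
  cmp <- tibble::tibble(sample_id = rep("S", 40), rsid = sprintf("r%d", 1:40),
                        ngs = rep(c("hom_ref", "het", "hom_alt"),
                                  length.out = 40),
                        ortho = rep(c("hom_ref", "het", "hom_alt"),
                                    length.out = 40))
  st <- concordance_stats(cmp)$stats
  expect_equal(st$pct, c(100, 100, 100))
  expect_true(all(st$ci_hi == 100))
})

test_that("zygosity mismatches are discordant but neither FP nor FN", {
  cmp <- tibble::tibble(sample_id = "S", rsid = c("r1", "r2", "r3"),
                        ngs = c("het", "hom_alt", "hom_ref"),
                        ortho = c("hom_alt", "hom_alt", "hom_ref"))
  cs <- concordance_stats(cmp)
  expect_equal(cs$confusion$other_discordant, 1)
  expect_equal(cs$confusion$fp, 0)
  expect_equal(cs$confusion$fn, 0)
  # sensitivity counts the mismatched carrier as detected
  expect_equal(cs$stats$pct[cs$stats$metric == "sensitivity"], 100)
})

test_that("dosage-coded genotypes are accepted", {
  cmp <- tibble::tibble(sample_id = "S", rsid = c("r1", "r2"),
                        ngs = c(0L, 1L), ortho = c(0L, 1L))
  expect_equal(concordance_stats(cmp)$stats$pct[1], 100)
  expect_error(concordance_stats(cmp[0, ]), "no comparisons")
})

test_that("confusion statistics match closed-form formulas on random inputs", {
  withr::local_seed(61)
  gts <- c("hom_ref", "het", "hom_alt")
  for (rep in 1:15) {
    n <- sample(50:400, 1)
    ortho <- sample(gts, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
    ngs <- ifelse(runif(n) < 0.9, ortho, sample(gts, n, replace = TRUE))
    cmp <- tibble::tibble(sample_id = "S", rsid = seq_len(n),
                          ngs = ngs, ortho = ortho)
    cs <- concordance_stats(cmp)
    conc <- sum(ngs == ortho)
    carriers <- sum(ortho != "hom_ref")
    fn <- sum(ortho != "hom_ref" & ngs == "hom_ref")
    fp <- sum(ortho == "hom_ref" & ngs != "hom_ref")
    wt <- n - carriers
    expect_equal(cs$confusion$concordant, conc)
    expect_equal(cs$stats$pct[1], round(100 * conc / n, 1))
    expect_equal(cs$stats$pct[2], round(100 * (carriers - fn) / carriers, 1))
    expect_equal(cs$stats$pct[3], round(100 * (wt - fp) / wt, 1))
    w <- oracle_wilson(conc, n)
    expect_equal(cs$stats$ci_lo[1], round(100 * w[1], 1))
    expect_equal(cs$stats$ci_hi[1], round(100 * w[2], 1))
    # permutation invariance
    perm <- sample.int(n)
    cs2 <- concordance_stats(cmp[perm, ])
    expect_equal(cs2$stats, cs$stats)
  }
})

test_that("wilson_ci agrees with prop.test's uncorrected interval", {
  for (case in list(c(95, 100), c(1933, 1935), c(3, 10))) {
    got <- wilson_ci(case[1], case[2])
    want <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(got, as.numeric(want), tolerance = 1e-9)
  }
})

test_that("the published worked example yields 99.9% concordance", {
  # 215 subjects x 9 genotype comparisons on average, 2 false negatives
  n <- 215 * 9
  ortho <- rep(c("het", "hom_alt", "hom_ref"), c(600, 67, n - 667))
  ngs <- ortho
  ngs[1:2] <- "hom_ref"   # two missed heterozygous carriers
  cmp <- tibble::tibble(sample_id = rep(sprintf("S%03d", 1:215),
                                        length.out = n),
                        rsid = sprintf("site%d", seq_len(n)),
                        ngs = ngs, ortho = ortho)
  cs <- concordance_stats(cmp)
  expect_equal(cs$confusion$total, 1935)
  expect_equal(cs$confusion$fn, 2)
  expect_equal(cs$confusion$fp, 0)
  expect_equal(cs$stats$pct[cs$stats$metric == "concordance"], 99.9)
  expect_equal(cs$stats$pct[cs$stats$metric == "sensitivity"], 99.7)
  expect_equal(cs$stats$pct[cs$stats$metric == "specificity"], 100)
})
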