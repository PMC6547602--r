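# CYP2D6 diplotype + copy-number phenotype prediction, actionable
# homozygote reporting, and concordance statistics against orthogonal
# genotyping.

#' CYP2D6 activity-score model
#'
#' Default activities: fully functional *1 and *2 score 1.0, the
#' reduced-function *41 scores 0.5, the null alleles *3, *4 and *5
#' (whole-gene deletion) score 0.  Phenotype bands: score 0 is a poor
#' metabolizer (PM), (0, 1] intermediate (IM), (1, 2] normal (NM), above
#' 2 ultrarapid (UM).  This banding reproduces diplotype-with-CNV
#' phenotype assignments such as *1/*5 -> IM and *1/*4 with a duplicated
#' *4 -> IM; it is intentionally simple and is not a current CPIC table.
#'
#' @param activity named numeric vector of per-allele activity values.
#' @return an `ActivityModel`.
#' @export
cyp2d6_activity_model <- function(activity = c("*1" = 1, "*2" = 1,
                                               "*41" = 0.5, "*3" = 0,
                                               "*4" = 0, "*5" = 0)) {
  if (any(activity < 0)) stop("activity values must be >= 0")
  structure(list(activity = activity), class = "ActivityModel")
}

score_to_phenotype <- function(score) {
  ifelse(score == 0, "PM",
         ifelse(score <= 1, "IM",
                ifelse(score <= 2, "NM", "UM")))
}

#' Construct a diplotype
#'
#' @param allele1,allele2 star-allele labels.
#' @param duplicated_allele label of the duplicated allele when total
#'   copies exceed 2 (NA when unknown).
#' @param copies total gene copies: 1 (one allele must be the deleted
#'   *5), 2, or 3 for "more than 2".
#' @param gene gene symbol.
#' @return a `Diplotype`.
#' @export
diplotype <- function(allele1, allele2, duplicated_allele = NA_character_,
                      copies = 2L, gene = "CYP2D6") {
  copies <- as.integer(copies)
  if (copies == 1L && !("*5" %in% c(allele1, allele2))) {
    stop("a one-copy diplotype must carry the *5 deletion allele")
  }
  if (!is.na(duplicated_allele)) {
    if (copies < 3L) stop("a duplicated allele implies more than 2 copies")
    if (!duplicated_allele %in% c(allele1, allele2)) {
      stop("duplicated allele must be one of the carried alleles")
    }
  }
  structure(list(gene = gene, allele1 = allele1, allele2 = allele2,
                 duplicated_allele = duplicated_allele, copies = copies),
            class = "Diplotype")
}

#' Predict metabolizer phenotype from a diplotype
#'
#' The activity score is the sum of per-allele activities over all
#' carried copies (a duplicated allele counts twice).  When copies exceed
#' 2 but the duplicated allele is unknown, both candidate phenotypes are
#' reported joined by "/" with `ambiguous = TRUE`.
#'
#' @param dip a `Diplotype`.
#' @param model an `ActivityModel`.
#' @return one-row tibble: `gene`, `diplotype`, `copies`, `score`,
#'   `phenotype`, `ambiguous`.
#' @export
predict_phenotype <- function(dip, model = cyp2d6_activity_model()) {
  act <- model$activity
  lookup <- function(a) {
    if (!a %in% names(act)) stop("unknown star allele: ", a)
    unname(act[a])
  }
  base <- lookup(dip$allele1) + lookup(dip$allele2)
  label <- paste0(dip$allele1, "/", dip$allele2)
  if (dip$copies >= 3L) {
    if (!is.na(dip$duplicated_allele)) {
      score <- base + lookup(dip$duplicated_allele)
      return(tibble(gene = dip$gene, diplotype = label, copies = dip$copies,
                    score = score, phenotype = score_to_phenotype(score),
                    ambiguous = FALSE))
    }
    scores <- base + c(lookup(dip$allele1), lookup(dip$allele2))
    phen <- unique(score_to_phenotype(scores))
    return(tibble(gene = dip$gene, diplotype = label, copies = dip$copies,
                  score = NA_real_, phenotype = paste(phen, collapse = "/"),
                  ambiguous = length(phen) > 1))
  }
  tibble(gene = dip$gene, diplotype = label, copies = dip$copies,
         score = base, phenotype = score_to_phenotype(base),
         ambiguous = FALSE)
}

#' Actionable-variant report: homozygous level 1A/1B carriers
#'
#' A subject is flagged when homozygous for the variant allele at one or
#' more PharmGKB level 1A/1B sites (homozygous states include UGT1A1
#' *28/*28 and CYP2D6 copy number 0 when encoded as hom_alt rows).
#'
#' @param genotype_calls tibble: `sample_id`, `rsid`, `genotype`
#'   (hom_ref/het/hom_alt or dosage 0/1/2).
#' @param known_sites known-site tibble with `rsid` and
#'   `pharmgkb_level`.
#' @param n_subjects cohort denominator (defaults to the number of
#'   distinct subjects in `genotype_calls`).
#' @return list: `subjects` tibble (sample_id, n_hom_level1, flagged,
#'   sites), `n_flagged`, `pct_flagged` (0 decimals).
#' @export
actionable_report <- function(genotype_calls, known_sites,
                              n_subjects = NULL) {
  g <- as_tibble(genotype_calls)
  g$genotype <- normalize_genotype(g$genotype)
  lvl <- known_sites$rsid[known_sites$pharmgkb_level %in% c("1A", "1B")]
  subj <- unique(g$sample_id)
  n_subjects <- n_subjects %||% length(subj)
  hom <- g[g$genotype == "hom_alt" & g$rsid %in% lvl, ]
  subjects <- tibble(
    sample_id = subj,
    n_hom_level1 = vapply(subj, function(s) sum(hom$sample_id == s),
                          integer(1), USE.NAMES = FALSE),
    sites = vapply(subj, function(s) {
      paste(hom$rsid[hom$sample_id == s], collapse = ";")
    }, character(1), USE.NAMES = FALSE))
  subjects$flagged <- subjects$n_hom_level1 >= 1L
  list(subjects = subjects,
       n_flagged = sum(subjects$flagged),
       pct_flagged = round(100 * sum(subjects$flagged) / n_subjects))
}

normalize_genotype <- function(g) {
  if (is.numeric(g)) {
    return(c("hom_ref", "het", "hom_alt")[as.integer(g) + 1L])
  }
  g
}

#' Wilson score confidence interval for a proportion
#' @param x successes, `n` trials, `conf` confidence level.
#' @param n,conf see above.
#' @return c(lower, upper) on the proportion scale.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Concordance of NGS calls with orthogonal genotypes
#'
#' Comparisons are matched on (sample, site).  A comparison is concordant
#' when the zygosity matches exactly.  A false positive is an orthogonal
#' homozygous wildtype called as a variant carrier by NGS; a false
#' negative is an orthogonal variant carrier called homozygous wildtype.
#' Sensitivity is 1 - FN / (orthogonal carriers), specificity
#' 1 - FP / (orthogonal wildtypes); intervals are Wilson score (or exact
#' binomial) 95% CIs and percentages are reported at 1 decimal.
#'
#' @param comparisons tibble: `sample_id`, `rsid`, `ngs`, `ortho`
#'   (genotypes as hom_ref/het/hom_alt or dosage 0/1/2).
#' @param ci_method "wilson" or "exact".
#' @return a `ConcordanceStats`: list with `confusion` (concordant, fp,
#'   fn, other_discordant, total, carriers, wildtypes) and `stats` tibble
#'   (metric, pct, ci_lo, ci_hi).
#' @export
concordance_stats <- function(comparisons, ci_method = c("wilson", "exact")) {
  ci_method <- match.arg(ci_method)
  cmp <- as_tibble(comparisons)
  if (!nrow(cmp)) stop("no comparisons")
  ngs <- normalize_genotype(cmp$ngs)
  ort <- normalize_genotype(cmp$ortho)
  concord <- ngs == ort
  carrier <- ort != "hom_ref"
  fp <- sum(!carrier & ngs != "hom_ref")
  fn <- sum(carrier & ngs == "hom_ref")
  total <- nrow(cmp)
  n_car <- sum(carrier); n_wt <- sum(!carrier)
  ci <- function(x, n) {
    if (ci_method == "wilson") wilson_ci(x, n) else {
      if (n == 0) c(NA_real_, NA_real_) else
        as.numeric(stats::binom.test(x, n)$conf.int)
    }
  }
  mk <- function(metric, x, n) {
    b <- ci(x, n)
    tibble(metric = metric, pct = round1(100 * x / n),
           ci_lo = round1(100 * b[1]), ci_hi = round1(100 * b[2]))
  }
  stats <- rbind(mk("concordance", sum(concord), total),
                 mk("sensitivity", n_car - fn, n_car),
                 mk("specificity", n_wt - fp, n_wt))
  structure(list(confusion = list(concordant = sum(concord), fp = fp,
                                  fn = fn,
                                  other_discordant = total - sum(concord) -
                                    fp - fn,
                                  total = total, carriers = n_car,
                                  wildtypes = n_wt),
                 stats = stats),
            class = "ConcordanceStats")
}

#' @export
print.ConcordanceStats <- function(x, ...) {
  cf <- x$confusion
  cat(sprintf("ConcordanceStats: %d comparisons, %d concordant, %d FP, %d FN\n",
              cf$total, cf$concordant, cf$fp, cf$fn))
  print(x$stats)
  invisible(x)
}

#' Load the bundled CYP2D6 CNV validation summary
#'
#' Per-subject published coverage metrics (normalized ratio and z-score),
#' orthogonal assay ratio and copy number, diplotype, duplicated allele
#' (where applicable) and reported phenotype, for the 15 CNV carriers of
#' a 183-subject screened cohort.
#' @return a tibble.
#' @export
cyp2d6_cnv_validation <- function() {
  path <- system.file("extdata", "cyp2d6_cnv_validation.tsv",
                      package = "pgxpanel")
  as_tibble(read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                       na.strings = c("NA", "")))
}
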