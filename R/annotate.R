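# Variant classification: functional consequence from a transcript model,
# population-frequency category from reference MAFs, deleteriousness flags
# from external in-silico scores (CADD/SIFT/PolyPhen-2 arrive as an
# annotation table; the package never computes them), cohort summaries and
# the rare-versus-common deleterious-proportion comparison.

FUNCTIONAL_CLASSES <- c("non_synonymous", "synonymous", "frameshift_indel",
                        "nonframeshift_indel", "splicing",
                        "stopgain_or_loss", "known_noncoding")
MAF_CATEGORIES <- c("common", "low_frequency", "rare", "novel")

#' Build a transcript model for consequence classification
#' @param gene gene symbol.
#' @param exons `GRanges` of coding exons in transcription order.
#' @param genome named character vector (or `DNAStringSet`) of reference
#'   sequences.
#' @param strand "+" or "-".
#' @return a `TranscriptModel`.
#' @export
transcript_model <- function(gene, exons, genome, strand = "+") {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  chrom <- as.character(GenomicRanges::seqnames(exons))[1]
  seqs <- substring(genome[[chrom]], GenomicRanges::start(exons),
                    GenomicRanges::end(exons))
  structure(list(gene = gene, chrom = chrom, exons = exons,
                 exon_seqs = seqs, strand = strand),
            class = "TranscriptModel")
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify the functional consequence of a variant
#'
#' Coding SNVs are classified by codon translation (synonymous /
#' non-synonymous / stop gain-or-loss); coding indels by length modulo 3;
#' intronic positions within 2 nucleotides of an intron-exon boundary are
#' splicing; positions inside a supplied known non-coding region are
#' known_noncoding.  Anything else is outside the model and errors.
#'
#' @param chrom,pos,ref,alt the variant (1-based VCF convention; indels
#'   as atomic allele strings).
#' @param model a `TranscriptModel` covering the variant's gene.
#' @param noncoding_regions optional `GRanges` of known non-coding
#'   targets (promoters, functional intronic sites).
#' @return one of `r paste(FUNCTIONAL_CLASSES, collapse = ", ")`.
#' @export
classify_function <- function(chrom, pos, ref, alt, model,
                              noncoding_regions = NULL) {
  if (!is.null(noncoding_regions) && length(noncoding_regions)) {
    v <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    if (any(IRanges::overlapsAny(v, noncoding_regions,
                                 ignore.strand = TRUE))) {
      return("known_noncoding")
    }
  }
  if (chrom != model$chrom) stop("variant outside the gene model")
  ex <- model$exons
  es <- GenomicRanges::start(ex); ee <- GenomicRanges::end(ex)
  in_exon <- which(pos >= es & pos <= ee)

  if (nchar(ref) != nchar(alt)) {            # indel
    if (length(in_exon)) {
      shift <- abs(nchar(ref) - nchar(alt))
      return(if (shift %% 3 == 0) "nonframeshift_indel" else
        "frameshift_indel")
    }
    if (splice_distance(pos, es, ee) <= 2) return("splicing")
    stop("variant outside the gene model")
  }
  if (!length(in_exon)) {
    if (splice_distance(pos, es, ee) <= 2) return("splicing")
    stop("variant outside the gene model")
  }

  ei <- in_exon[1]
  offset_in_exon <- pos - es[ei] + 1L
  cds_pos <- sum(nchar(model$exon_seqs[seq_len(ei - 1L)])) + offset_in_exon
  cds <- paste(model$exon_seqs, collapse = "")
  ref_base <- ref; alt_base <- alt
  if (model$strand == "-") {
    cds <- revcomp(cds)
    cds_pos <- nchar(cds) - cds_pos + 1L
    ref_base <- revcomp(ref); alt_base <- revcomp(alt)
  }
  if (substr(cds, cds_pos, cds_pos) != ref_base) {
    stop("reference allele does not match the transcript model at pos ", pos)
  }
  codon_i <- (cds_pos - 1L) %/% 3L
  codon_start <- codon_i * 3L + 1L
  if (codon_start + 2L > nchar(cds)) {
    # trailing partial codon: treat as non-coding tail
    stop("variant falls in a partial trailing codon of the model")
  }
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, cds_pos - codon_start + 1L,
         cds_pos - codon_start + 1L) <- alt_base
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (ref_aa == alt_aa) return("synonymous")
  if (ref_aa == "*" || alt_aa == "*") return("stopgain_or_loss")
  "non_synonymous"
}

splice_distance <- function(pos, exon_starts, exon_ends) {
  d <- suppressWarnings(min(c(exon_starts[exon_starts > pos] - pos,
                              pos - exon_ends[exon_ends < pos])))
  if (!is.finite(d)) Inf else d
}

#' Categorize a variant by reference minor allele frequency
#'
#' MAF at or above 5% is common, 1% to below 5% low frequency, below 1%
#' rare; a missing MAF is rare when the variant has a known rsid and
#' novel when it is absent from the reference databases entirely.
#' Frequencies above 0.5 are folded to the minor allele.
#'
#' @param maf numeric vector of reference MAFs (NA = not reported).
#' @param rsid_known logical vector: known database identifier present.
#' @return character vector of categories.
#' @export
classify_maf <- function(maf, rsid_known) {
  n <- max(length(maf), length(rsid_known))
  maf <- rep_len(maf, n); rsid_known <- rep_len(rsid_known, n)
  bad <- !is.na(maf) & (maf < 0 | maf > 1)
  if (any(bad)) stop("MAF outside [0, 1]: ", paste(maf[bad], collapse = ", "))
  maf <- ifelse(!is.na(maf) & maf > 0.5, 1 - maf, maf)
  ifelse(is.na(maf),
         ifelse(rsid_known, "rare", "novel"),
         ifelse(maf >= 0.05, "common",
                ifelse(maf >= 0.01, "low_frequency", "rare")))
}

#' Deleteriousness flags from in-silico scores
#'
#' A variant is potentially functional when scaled CADD exceeds 20
#' (strict), SIFT is below 0.05, or PolyPhen-2 exceeds 0.85.  Flags are
#' NA exactly where the score is missing.
#'
#' @param cadd,sift,polyphen numeric score vectors (NA = missing).
#' @return tibble with logical columns `by_cadd`, `by_sift`,
#'   `by_polyphen`.
#' @export
flag_deleterious <- function(cadd = NA_real_, sift = NA_real_,
                             polyphen = NA_real_) {
  n <- max(length(cadd), length(sift), length(polyphen))
  cadd <- rep_len(cadd, n); sift <- rep_len(sift, n)
  polyphen <- rep_len(polyphen, n)
  if (any(cadd < 0, na.rm = TRUE)) stop("CADD scores must be >= 0")
  if (any(sift < 0 | sift > 1, na.rm = TRUE)) stop("SIFT scores in [0, 1]")
  if (any(polyphen < 0 | polyphen > 1, na.rm = TRUE)) {
    stop("PolyPhen-2 scores in [0, 1]")
  }
  tibble(by_cadd = cadd > 20, by_sift = sift < 0.05,
         by_polyphen = polyphen > 0.85)
}

#' Cohort variant summary
#'
#' @param annotations tibble of unique variants with columns `variant_id`,
#'   `gene`, `class` (functional class), `maf_exac`, `rsid` (NA when
#'   absent from databases) and optionally `cadd`, `sift`, `polyphen`.
#' @param genotypes optional per-subject genotype tibble (`sample_id`,
#'   `variant_id`, `genotype` in het/hom_alt) for zygosity breakdowns.
#' @param known_sites optional known-site tibble with `pharmgkb_level`
#'   and `variant_id` for the per-subject homozygous 1A/1B count.
#' @return a `CohortVariantSummary`: list with `n_variants`,
#'   `class_counts` (n and percentage at 1 decimal), `exonic_denominator`
#'   (variants outside known_noncoding), `maf_counts` over exonic
#'   variants (with `pct`), `pct_rare_or_novel`, `gene_counts`, and when
#'   genotypes are given `per_subject` (deleterious counts by zygosity,
#'   homozygous 1A/1B count).
#' @export
summarize_cohort <- function(annotations, genotypes = NULL,
                             known_sites = NULL) {
  ann <- as_tibble(annotations)
  if (!all(ann$class %in% FUNCTIONAL_CLASSES)) {
    stop("unknown functional class in annotations")
  }
  total <- nrow(ann)
  tab <- table(factor(ann$class, levels = FUNCTIONAL_CLASSES))
  class_counts <- tibble(class = names(tab), n = as.integer(tab),
                         pct = round1(100 * as.integer(tab) / total))
  exonic <- ann[ann$class != "known_noncoding", ]
  mcat <- classify_maf(exonic$maf_exac, !is.na(exonic$rsid))
  mtab <- table(factor(mcat, levels = MAF_CATEGORIES))
  maf_counts <- tibble(category = names(mtab), n = as.integer(mtab),
                       pct = round1(100 * as.integer(mtab) / nrow(exonic)))
  pct_rare_or_novel <- round1(100 * sum(mcat %in% c("rare", "novel")) /
                                nrow(exonic))
  gene_counts <- as_tibble(as.data.frame(table(gene = ann$gene),
                                         stringsAsFactors = FALSE))
  names(gene_counts) <- c("gene", "n")

  per_subject <- NULL
  if (!is.null(genotypes) && nrow(genotypes)) {
    del_ids <- ann$variant_id[!is.na(ann$cadd) & ann$cadd > 20]
    g <- as_tibble(genotypes)
    subj <- unique(g$sample_id)
    per_subject <- tibble(
      sample_id = subj,
      n_deleterious_het = vapply(subj, function(s) {
        sum(g$sample_id == s & g$variant_id %in% del_ids &
              g$genotype == "het")
      }, integer(1), USE.NAMES = FALSE),
      n_deleterious_hom = vapply(subj, function(s) {
        sum(g$sample_id == s & g$variant_id %in% del_ids &
              g$genotype == "hom_alt")
      }, integer(1), USE.NAMES = FALSE))
    if (!is.null(known_sites) && nrow(known_sites)) {
      lvl_ids <- known_sites$variant_id[known_sites$pharmgkb_level %in%
                                          c("1A", "1B")]
      per_subject$n_hom_level1 <- vapply(subj, function(s) {
        sum(g$sample_id == s & g$variant_id %in% lvl_ids &
              g$genotype == "hom_alt")
      }, integer(1), USE.NAMES = FALSE)
    }
  }
  structure(list(n_variants = total, class_counts = class_counts,
                 exonic_denominator = nrow(exonic), maf_counts = maf_counts,
                 pct_rare_or_novel = pct_rare_or_novel,
                 gene_counts = gene_counts, per_subject = per_subject,
                 annotations = ann),
            class = "CohortVariantSummary")
}

#' @export
print.CohortVariantSummary <- function(x, ...) {
  cat(sprintf("CohortVariantSummary: %d unique variants (%d exonic)\n",
              x$n_variants, x$exonic_denominator))
  print(x$class_counts)
  invisible(x)
}

#' Test a 2x2 deleterious-by-frequency contingency table
#'
#' Chi-squared without continuity correction, switching to Fisher's exact
#' test when any expected cell is below 5.
#' @param tab 2x2 matrix: rows rare_or_novel / common_or_low, columns
#'   deleterious / not.
#' @return list: `p`, `prop` (per-row deleterious proportions), `test`.
#' @export
deleterious_proportion_test <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ht <- fisher.test(tab)
    test <- "fisher"
  } else {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    test <- "chisq"
  }
  list(p = ht$p.value, prop = tab[, 1] / rowSums(tab), test = test)
}

#' Compare deleterious proportions: rare-or-novel versus common-or-low
#'
#' For each in-silico score, exonic protein-coding variants with a
#' non-missing score are cross-tabulated as (rare_or_novel vs
#' common_or_low) x (deleterious vs not) and tested.
#'
#' @param summary a `CohortVariantSummary` (its stored annotations are
#'   used).
#' @return tibble: `score`, `n`, `prop_rare`, `prop_common`, `direction`,
#'   `p`, `test`.
#' @export
compare_rare_vs_common_deleterious <- function(summary) {
  ann <- summary$annotations
  ann <- ann[ann$class %in% c("non_synonymous", "stopgain_or_loss"), ]
  mcat <- classify_maf(ann$maf_exac, !is.na(ann$rsid))
  rare_grp <- mcat %in% c("rare", "novel")
  flags <- flag_deleterious(ann$cadd %||% NA_real_,
                            ann$sift %||% NA_real_,
                            ann$polyphen %||% NA_real_)
  out <- lapply(names(flags), function(col) {
    f <- flags[[col]]
    use <- !is.na(f)
    if (!sum(use & rare_grp) || !sum(use & !rare_grp)) {
      stop("empty MAF group for score ", col)
    }
    tab <- matrix(c(sum(f[use] & rare_grp[use]),
                    sum(!f[use] & rare_grp[use]),
                    sum(f[use] & !rare_grp[use]),
                    sum(!f[use] & !rare_grp[use])),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("rare_or_novel", "common_or_low"),
                                  c("deleterious", "benign")))
    res <- deleterious_proportion_test(tab)
    dir <- if (res$prop[1] > res$prop[2]) "rare > common"
           else if (res$prop[1] < res$prop[2]) "common > rare" else "none"
    tibble(score = sub("^by_", "", col), n = sum(use),
           prop_rare = unname(res$prop[1]), prop_common = unname(res$prop[2]),
           direction = dir, p = res$p, test = res$test)
  })
  do.call(rbind, out)
}
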