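# Read simulation: negative-binomial fragment counts per capture region
# scaled by copy number, GC weight and sequencing-cluster size; paired-end
# reads with per-read quality and per-base substitution errors; flagged
# duplicate, secondary and mate-unmapped records.

empty_reads <- function() {
  tibble(qname = character(), flag = integer(), rname = character(),
         pos = integer(), mapq = integer(), cigar = character(),
         rnext = character(), pnext = integer(), tlen = integer(),
         seq = character(), qual = character())
}

apply_base_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  rl <- nchar(seqs)
  nerr <- rbinom(length(seqs), rl, rate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    ppos <- sample.int(rl[i], nerr[i])
    for (p in ppos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  seqs
}

#' Simulate aligned reads for one sample
#'
#' Per capture region, the expected fragment count is
#' `mean_depth * (width + fragment) / (2 * read_length)` scaled by
#' `copies/2` for the region's gene, `24/cluster_size`, and a logistic
#' GC weight; counts are negative-binomial.  Paired 100M reads are drawn
#' from the sample's two haplotypes (known-site SNVs and the promoter
#' (TA)n allele applied); reads fully containing the repeat motif on a
#' (TA)7 haplotype get the expanded repeat spliced into their sequence.
#' Duplicate fragments, secondary (multimapped) alignments and
#' mate-unmapped fragments are injected at the configured rates and
#' flagged.
#'
#' @param config a `SimConfig`.
#' @param ref a `SimReference`.
#' @param truth a `SimTruth`.
#' @param sample_id one of `truth$samples$sample_id`.
#' @param genes optional character vector restricting simulation to a gene
#'   subset (used for narrow, fast simulations).
#' @return a tibble of SAM-style records, sorted by position, with
#'   attributes `sample_id` and `batch`.
#' @export
simulate_sample <- function(config, ref, truth, sample_id, genes = NULL) {
  si <- match(sample_id, truth$samples$sample_id)
  if (is.na(si)) stop("unknown sample: ", sample_id)
  srow <- truth$samples[si, ]
  if (!config$cnv_gene %in% ref$panel$genes$gene &&
      config$cnv_gene %in% truth$cnv$gene) {
    stop("truth/panel mismatch: CNV gene absent from panel")
  }
  withr::with_seed(derive_seed(config$seed, 100L + si), {
    genome <- ref$genome[["chrT"]]
    rl <- config$read_length

    # haplotype sequences: SNV dosage 1 -> alt on hap1; dosage 2 -> both
    hap <- c(genome, genome)
    gts <- truth$genotypes[truth$genotypes$sample_id == sample_id, ]
    sites <- ref$panel$known_sites
    if (nrow(gts)) {
      for (i in seq_len(nrow(gts))) {
        if (gts$dosage[i] == 0L) next
        srec <- sites[sites$rsid == gts$rsid[i], ]
        if (!nrow(srec)) stop("truth/panel mismatch: unknown site ",
                              gts$rsid[i])
        substr(hap[1], srec$pos, srec$pos) <- srec$alt
        if (gts$dosage[i] == 2L) substr(hap[2], srec$pos, srec$pos) <- srec$alt
      }
    }
    ta_alleles <- as.integer(strsplit(srow$ta_genotype, "/")[[1]])

    copies <- setNames(rep(2L, nrow(ref$panel$genes)), ref$panel$genes$gene)
    cnv <- truth$cnv[truth$cnv$sample_id == sample_id, ]
    if (nrow(cnv)) copies[cnv$gene] <- cnv$copies

    regions <- ref$panel$regions
    if (!is.null(genes)) regions <- regions[regions$gene %in% genes]
    w <- GenomicRanges::width(regions)
    rstart <- GenomicRanges::start(regions)
    rend <- GenomicRanges::end(regions)
    rgc <- regions$gc

    frag_mean <- 2 * rl + (config$insert_mean - rl)
    cluster_factor <- 24 / config$cluster_size
    depth_scale <- if (srow$exclude_low_reads) 0.002 else 1
    gshift <- if (srow$exclude_high_gc) exp(4 * (rgc - 0.45)) else 1

    # fragment midpoints are uniform within the region, so the expected
    # interior read-base density is exactly mean_depth for a 2-copy gene
    mu <- config$mean_depth * w / (2 * rl) *
      (copies[regions$gene] / 2) * cluster_factor *
      gc_weight(rgc, config$gc_bias_strength) * depth_scale * gshift
    nfrag <- ifelse(mu <= 0, 0L,
                    rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion))
    total <- sum(nfrag)
    if (total == 0) {
      out <- empty_reads()
      attr(out, "sample_id") <- sample_id
      attr(out, "batch") <- srow$batch
      return(out)
    }

    ridx <- rep(seq_along(nfrag), nfrag)
    fl <- pmax(rl + 2L, round(rnorm(total, frag_mean, config$insert_sd)))
    mid <- runif(total, rstart[ridx] - 0.5, rend[ridx] + 0.5)
    fs <- as.integer(round(mid - fl / 2))
    fs <- pmax(1L, pmin(fs, nchar(genome) - fl))
    fe <- fs + fl - 1L
    h <- sample(1:2, total, replace = TRUE)

    seq1 <- substring(hap[1], fs, fs + rl - 1L)
    seq2 <- substring(hap[2], fs, fs + rl - 1L)
    r1 <- ifelse(h == 1L, seq1, seq2)
    p2 <- fe - rl + 1L
    seq1b <- substring(hap[1], p2, fe)
    seq2b <- substring(hap[2], p2, fe)
    r2 <- ifelse(h == 1L, seq1b, seq2b)

    # expanded-repeat haplotypes: splice (TA)7 into reads containing the
    # full reference motif (positions never shift; trailing bases trimmed)
    loc <- ref$repeat_locus
    if (!is.na(loc$repeat_start) && any(ta_alleles > loc$ref_units)) {
      motif6 <- paste0(loc$left_anchor, strrep(loc$unit, loc$ref_units),
                       loc$right_anchor)
      motif7 <- paste0(loc$left_anchor, strrep(loc$unit, loc$var_units),
                       loc$right_anchor)
      expand <- function(s, hap_idx) {
        carry <- ta_alleles[hap_idx] > loc$ref_units
        hit <- carry[h] & grepl(motif6, s, fixed = TRUE)
        s[hit] <- substr(sub(motif6, motif7, s[hit], fixed = TRUE), 1L, rl)
        s
      }
      r1 <- expand(r1, 1:2)
      r2 <- expand(r2, 1:2)
    }

    r1 <- apply_base_errors(r1, config$base_error_rate)
    r2 <- apply_base_errors(r2, config$base_error_rate)

    q <- pmin(40, pmax(2, round(rnorm(2L * total, 36, 2))))
    quals <- phred_to_string(q)
    qual1 <- vapply(quals[seq_len(total)], function(ch) strrep(ch, rl),
                    character(1), USE.NAMES = FALSE)
    qual2 <- vapply(quals[total + seq_len(total)], function(ch) strrep(ch, rl),
                    character(1), USE.NAMES = FALSE)

    qname <- sprintf("%s_frag%06d", sample_id, seq_len(total))
    unpaired <- runif(total) < config$unpaired_rate

    f1 <- ifelse(unpaired,
                 SAM_PAIRED + SAM_MATE_UNMAPPED + SAM_FIRST_IN_PAIR,
                 SAM_PAIRED + SAM_PROPER_PAIR + SAM_MATE_REVERSE +
                   SAM_FIRST_IN_PAIR)
    reads1 <- tibble(qname = qname, flag = as.integer(f1), rname = "chrT",
                     pos = fs, mapq = 60L, cigar = paste0(rl, "M"),
                     rnext = "=", pnext = ifelse(unpaired, fs, p2),
                     tlen = as.integer(fl), seq = r1, qual = qual1)
    keep2 <- !unpaired
    reads2 <- tibble(qname = qname[keep2],
                     flag = as.integer(SAM_PAIRED + SAM_PROPER_PAIR +
                                         SAM_REVERSE + SAM_SECOND_IN_PAIR),
                     rname = "chrT", pos = p2[keep2], mapq = 60L,
                     cigar = paste0(rl, "M"), rnext = "=",
                     pnext = fs[keep2], tlen = -as.integer(fl[keep2]),
                     seq = r2[keep2], qual = qual2[keep2])
    reads <- rbind(reads1, reads2)

    # exact-copy PCR duplicates
    ndup <- rbinom(1, total, config$dup_rate)
    if (ndup > 0) {
      didx <- sample.int(total, ndup)
      dups <- reads[reads$qname %in% qname[didx], ]
      dups$flag <- dups$flag + SAM_DUPLICATE
      dups$qname <- paste0(dups$qname, ":dup")
      reads <- rbind(reads, dups)
    }
    # multimapping: secondary alignment copies with MAPQ 0
    nmm <- rbinom(1, nrow(reads), config$multimap_rate)
    if (nmm > 0) {
      midx <- sample.int(nrow(reads), nmm)
      mm <- reads[midx, ]
      mm$flag <- mm$flag + SAM_SECONDARY
      mm$mapq <- 0L
      reads <- rbind(reads, mm)
    }

    reads <- reads[order(reads$pos, reads$qname, reads$flag), ]
    attr(reads, "sample_id") <- sample_id
    attr(reads, "batch") <- srow$batch
    reads
  })
}

#' Simulate a whole cohort
#'
#' @param config a `SimConfig`.
#' @param genes optional gene subset passed to [simulate_sample()].
#' @param write_dir if non-NULL, FASTA/BED/truth/SAM/FASTQ files are
#'   written there.
#' @return a `SimCohort` list: `config`, `ref`, `truth`, `reads` (named
#'   list of read tibbles).
#' @export
simulate_cohort <- function(config, genes = NULL, write_dir = NULL) {
  ref <- make_reference(config)
  truth <- make_truth(config, ref)
  reads <- lapply(truth$samples$sample_id, function(s) {
    simulate_sample(config, ref, truth, s, genes = genes)
  })
  names(reads) <- truth$samples$sample_id
  out <- structure(list(config = config, ref = ref, truth = truth,
                        reads = reads), class = "SimCohort")
  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(ref$genome_set,
                                file.path(write_dir, "reference.fa"))
    write_panel_bed(ref$panel$regions, file.path(write_dir, "panel.bed"))
    write.table(ref$panel$genes, file.path(write_dir, "genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ref$panel$known_sites, file.path(write_dir, "known_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_truth(truth, write_dir)
    for (s in names(reads)) {
      write_sam(reads[[s]], setNames(nchar(ref$genome), names(ref$genome)),
                file.path(write_dir, paste0(s, ".sam")))
      write_fastq(reads[[s]], file.path(write_dir, paste0(s, ".fastq")))
    }
  }
  out
}
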