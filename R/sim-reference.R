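# Synthetic data: miniature reference genome + panel with embedded features
# (a CNV target gene, a promoter TA-repeat locus, deletable GST-like genes)
# and a ground-truth generator.  All randomness flows from config$seed via
# derived per-task streams; a fixed config is byte-reproducible.

TA_LEFT_ANCHOR  <- "GGACCTCAGC"
TA_RIGHT_ANCHOR <- "GCCTGGATCG"

MINI_GENES <- data.frame(
  gene   = c("CYP2D6", "CYP2C19", "UGT1A1", "SLCO1B1", "ABCB1",
             "TPMT", "DPYD", "GSTM1", "GSTT1", "VKORC1"),
  family = c("CYP", "CYP", "UGT", "SLC", "ABC",
             "other", "other", "GST", "GST", "other"),
  stringsAsFactors = FALSE)

# Known clinically relevant sites of the miniature panel: synthetic
# positions (exon index + offset) with field-style star-allele labels,
# PharmGKB-style evidence levels and population allele frequencies.
MINI_SITES <- data.frame(
  gene   = c("CYP2C19", "CYP2D6", "CYP2D6", "SLCO1B1", "DPYD",
             "TPMT", "ABCB1", "VKORC1"),
  exon   = c(2L, 1L, 3L, 2L, 2L, 3L, 2L, 1L),
  offset = c(40L, 60L, 25L, 50L, 30L, 45L, 70L, 30L),
  star   = c("*2", "*4", "*10", "*5", "c.2846A>T",
             "*3", "c.3435C>T", "-1639G>A"),
  level  = c("1A", "1A", "1A", "1A", "1A", "1A", "2A", "1B"),
  maf    = c(0.15, 0.18, 0.20, 0.16, 0.02, 0.04, 0.45, 0.40),
  stringsAsFactors = FALSE)

#' Simulation configuration
#'
#' Study-condition defaults: 24 barcoded samples per sequencing cluster
#' (`cluster_size` 12 or 24; 24-plex roughly halves per-sample depth),
#' 100-fold nominal coverage, 100-bp paired reads, a logistic GC-coverage
#' anticorrelation, negative-binomial region counts (dispersion 0.01, i.e.
#' per-region coefficient of variation about 0.1 as seen for stable capture
#' probes), per-base error 1e-3, 5% PCR-duplicate and 2% multimapping
#' read rates, a CYP2D6 copy-number gene (states 1/2/3), a promoter (TA)6/7
#' repeat with (TA)7 allele frequency 0.3, and GST-like genes homozygously
#' deleted in 57% (GSTM1) / 17% (GSTT1) of subjects.
#'
#' @param seed integer master seed; everything downstream derives from it.
#' @param n_samples samples in the simulated cohort.
#' @param cluster_size sequencing-cluster (plex) size, 12 or 24.
#' @param mean_depth nominal per-base fold coverage at 2 copies.
#' @param read_length read length in bases.
#' @param insert_mean,insert_sd fragment length is
#'   `2*read_length + N(insert_mean - read_length, insert_sd)` like spread.
#' @param gc_bias_strength >= 0; 0 disables GC bias.
#' @param base_error_rate per-base substitution error probability (< 0.5).
#' @param nb_dispersion negative-binomial dispersion of region fragment
#'   counts (variance = mu + dispersion * mu^2).
#' @param dup_rate,multimap_rate,unpaired_rate rates of duplicate
#'   fragments, secondary alignments and mate-unmapped fragments.
#' @param n_genes genes in the miniature genome (first 10 are named).
#' @param cnv_gene gene carrying simulated copy-number states.
#' @param cnv_state_probs probabilities of copy states 1/2/3.
#' @param ta7_allele_freq allele frequency of the (TA)7 promoter allele.
#' @param gst_null_freq named homozygous-deletion frequencies for GST genes.
#' @param n_excluded_low_reads,n_excluded_high_gc samples simulated to fail
#'   read-count / GC QC (exclusion truth).
#' @return a `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, n_samples = 24L, cluster_size = 24L,
                       mean_depth = 100, read_length = 100L,
                       insert_mean = 160, insert_sd = 15,
                       gc_bias_strength = 1, base_error_rate = 0.001,
                       nb_dispersion = 0.01, dup_rate = 0.05,
                       multimap_rate = 0.02, unpaired_rate = 0.01,
                       n_genes = 10L, cnv_gene = "CYP2D6",
                       cnv_state_probs = c(`1` = 0.08, `2` = 0.84, `3` = 0.08),
                       ta7_allele_freq = 0.3,
                       gst_null_freq = c(GSTM1 = 0.57, GSTT1 = 0.17),
                       n_excluded_low_reads = 0L, n_excluded_high_gc = 0L) {
  stopifnot(mean_depth > 0, base_error_rate >= 0, base_error_rate < 0.5,
            cluster_size %in% c(12L, 24L), n_genes >= 1)
  structure(as.list(environment()), class = "SimConfig")
}

gc_weight <- function(gc, strength) {
  if (strength <= 0) return(rep(1, length(gc)))
  2 * stats::plogis(-strength * (gc - 0.45) * 10)
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Build the miniature reference genome and panel
#'
#' Lays out `config$n_genes` genes on a single chromosome `chrT`: four
#' 160-bp exons with 200-bp introns (captured whole), 120-bp UTRs, a 60-bp
#' promoter region for UGT1A1 embedding unique anchors around a (TA)6
#' repeat, and gene-specific GC content spanning 0.35-0.60 so GC bias is
#' visible.  Known clinically relevant sites are placed inside exons.
#'
#' @param config a `SimConfig`.
#' @return a `SimReference`: list with `genome` (named character),
#'   `genome_set` (`DNAStringSet`), `panel` (`PanelDefinition`),
#'   `repeat_locus`, `gene_gc` (declared per-gene GC of the full gene
#'   block) and `transcripts` (exon `GRanges` per gene).
#' @export
make_reference <- function(config) {
  withr::with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_genes
    genes <- if (n <= nrow(MINI_GENES)) MINI_GENES[seq_len(n), ] else {
      extra <- data.frame(gene = sprintf("GENE%02d", seq_len(n - nrow(MINI_GENES))),
                          family = "other")
      rbind(MINI_GENES, extra)
    }
    gc_targets <- seq(0.35, 0.60, length.out = n)

    exon_w <- 160L; intron_w <- 200L; utr_w <- 120L; gap <- 10L
    flank <- 300L  # capture flank; introns (200bp) are captured whole
    spacer <- 400L
    n_exons <- 4L

    pieces <- character(0)
    cursor <- 1L
    reg <- list(); ri <- 0L
    add_region <- function(s, e, g, k) {
      ri <<- ri + 1L
      reg[[ri]] <<- data.frame(start = s, end = e, gene = g, kind = k)
    }
    emit <- function(seq_str) {
      pieces <<- c(pieces, seq_str)
      cursor <<- cursor + nchar(seq_str)
    }
    exon_starts <- list()
    ta_start <- NA_integer_

    for (gi in seq_len(n)) {
      g <- genes$gene[gi]; gc <- gc_targets[gi]
      emit(random_dna(spacer, 0.45))
      # outer 5' capture flank
      add_region(cursor - 1L, cursor - 1L + flank, g, "intron_flank")
      emit(random_dna(flank, gc))
      if (g == "UGT1A1") {
        # promoter repeat region: pad + left anchor + (TA)6 + right anchor + pad
        motif <- paste0(TA_LEFT_ANCHOR, strrep("TA", 6L), TA_RIGHT_ANCHOR)
        pad_l <- random_dna(18L, gc); pad_r <- random_dna(10L, gc)
        add_region(cursor - 1L, cursor - 1L + 18L + nchar(motif) + 10L,
                   g, "known_noncoding")
        ta_start <- cursor + 18L + nchar(TA_LEFT_ANCHOR)
        emit(paste0(pad_l, motif, pad_r))
        emit(random_dna(gap, gc))
      }
      add_region(cursor - 1L, cursor - 1L + utr_w, g, "utr_flank")
      emit(random_dna(utr_w, gc))
      emit(random_dna(gap, gc))
      ex <- integer(n_exons)
      for (ei in seq_len(n_exons)) {
        ex[ei] <- cursor
        add_region(cursor - 1L, cursor - 1L + exon_w, g, "exon")
        emit(random_dna(exon_w, gc))
        if (ei < n_exons) {
          add_region(cursor - 1L, cursor - 1L + intron_w, g, "intron_flank")
          emit(random_dna(intron_w, gc))
        }
      }
      exon_starts[[g]] <- ex
      emit(random_dna(gap, gc))
      add_region(cursor - 1L, cursor - 1L + utr_w, g, "utr_flank")
      emit(random_dna(utr_w, gc))
      add_region(cursor - 1L, cursor - 1L + flank, g, "intron_flank")
      emit(random_dna(flank, gc))
    }
    emit(random_dna(spacer, 0.45))
    genome <- paste(pieces, collapse = "")

    df <- do.call(rbind, reg)
    regions <- target_regions("chrT", df$start, df$end, df$gene, df$kind)

    # realized per-gene GC over the gene's own target regions
    gene_gc <- vapply(genes$gene, function(g) {
      rr <- regions[regions$gene == g]
      seqs <- substring(genome, GenomicRanges::start(rr), GenomicRanges::end(rr))
      s <- paste(seqs, collapse = "")
      sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
    }, numeric(1))

    # known sites: fix ref from the genome, alt by transition
    mk <- MINI_SITES[MINI_SITES$gene %in% genes$gene, ]
    sites <- empty_known_sites()
    if (nrow(mk)) {
      pos <- integer(nrow(mk)); refb <- altb <- character(nrow(mk))
      trans <- c(A = "G", G = "A", C = "T", T = "C")
      for (i in seq_len(nrow(mk))) {
        pos[i] <- exon_starts[[mk$gene[i]]][mk$exon[i]] + mk$offset[i]
        refb[i] <- substr(genome, pos[i], pos[i])
        altb[i] <- trans[[refb[i]]]
      }
      sites <- tibble(chrom = "chrT", pos = pos, ref = refb, alt = altb,
                      rsid = sprintf("sim%04d", seq_len(nrow(mk))),
                      gene = mk$gene, star_allele = mk$star,
                      pharmgkb_level = mk$level, maf = mk$maf)
    }

    # per-region GC for the depth model
    rgc <- vapply(seq_along(regions), function(i) {
      s <- substr(genome, GenomicRanges::start(regions)[i],
                  GenomicRanges::end(regions)[i])
      sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
    }, numeric(1))
    regions$gc <- rgc

    panel <- new_panel(regions, as_tibble(genes), sites)
    locus <- repeat_locus("chrT", ta_start, unit = "TA", ref_units = 6L,
                          var_units = 7L, left_anchor = TA_LEFT_ANCHOR,
                          right_anchor = TA_RIGHT_ANCHOR)
    transcripts <- lapply(exon_starts, function(ex) {
      GenomicRanges::GRanges("chrT", IRanges::IRanges(ex, ex + exon_w - 1L))
    })
    structure(list(genome = c(chrT = genome),
                   genome_set = Biostrings::DNAStringSet(c(chrT = genome)),
                   panel = panel, repeat_locus = locus,
                   gene_gc = setNames(gene_gc, genes$gene),
                   transcripts = transcripts),
              class = "SimReference")
  })
}

#' Draw cohort ground truth
#'
#' Per sample: genotype dosages at every known site (Hardy-Weinberg draws
#' at the site's allele frequency), a copy-number state for the CNV gene,
#' homozygous-deletion status for GST genes, a (TA)n promoter genotype, a
#' batch label, and intended QC-exclusion flags.
#'
#' @param config a `SimConfig`.
#' @param ref a `SimReference` from [make_reference()].
#' @return a `SimTruth`: list of tibbles `samples`, `cnv`, `genotypes`.
#' @export
make_truth <- function(config, ref) {
  withr::with_seed(derive_seed(config$seed, 2L), {
    n <- config$n_samples
    ids <- sprintf("S%03d", seq_len(n))
    batch <- sprintf("plex%d", config$cluster_size)

    ta_allele <- function() sample(c(7L, 6L), 1,
                                   prob = c(config$ta7_allele_freq,
                                            1 - config$ta7_allele_freq))
    ta <- vapply(ids, function(s) {
      a <- sort(c(ta_allele(), ta_allele()))
      paste(a, collapse = "/")
    }, character(1))

    low <- seq_len(n) <= config$n_excluded_low_reads
    hig <- !low & seq_len(n) <= (config$n_excluded_low_reads +
                                   config$n_excluded_high_gc)
    samples <- tibble(sample_id = ids, batch = batch, ta_genotype = ta,
                      exclude_low_reads = low, exclude_high_gc = hig)

    genes <- ref$panel$genes$gene
    cnv <- list()
    if (config$cnv_gene %in% genes) {
      vals <- as.integer(names(config$cnv_state_probs))
      states <- vals[sample.int(length(vals), n, replace = TRUE,
                                prob = config$cnv_state_probs)]
      cnv[[length(cnv) + 1L]] <- tibble(sample_id = ids,
                                        gene = config$cnv_gene,
                                        copies = states)
    }
    for (g in names(config$gst_null_freq)) {
      if (!g %in% genes) next
      nulls <- rbinom(n, 1, config$gst_null_freq[[g]]) == 1
      cnv[[length(cnv) + 1L]] <- tibble(sample_id = ids, gene = g,
                                        copies = ifelse(nulls, 0L, 2L))
    }
    cnv <- if (length(cnv)) do.call(rbind, cnv) else
      tibble(sample_id = character(), gene = character(), copies = integer())

    sites <- ref$panel$known_sites
    genotypes <- if (nrow(sites)) {
      dos <- vapply(sites$maf, function(m) rbinom(n, 2, m), integer(n))
      if (n == 1) dos <- matrix(dos, nrow = 1)
      tibble(sample_id = rep(ids, times = nrow(sites)),
             rsid = rep(sites$rsid, each = n),
             gene = rep(sites$gene, each = n),
             star_allele = rep(sites$star_allele, each = n),
             chrom = rep(sites$chrom, each = n),
             pos = rep(sites$pos, each = n),
             dosage = as.integer(dos))
    } else {
      tibble(sample_id = character(), rsid = character(), gene = character(),
             star_allele = character(), chrom = character(), pos = integer(),
             dosage = integer())
    }
    structure(list(samples = samples, cnv = cnv, genotypes = genotypes),
              class = "SimTruth")
  })
}

#' Serialize / read ground truth as tab-separated text
#' @param truth a `SimTruth`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("samples", "cnv", "genotypes")) {
    write.table(truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  out <- lapply(c("samples", "cnv", "genotypes"), function(nm) {
    as_tibble(read.delim(file.path(dir, paste0("truth_", nm, ".tsv")),
                         stringsAsFactors = FALSE))
  })
  names(out) <- c("samples", "cnv", "genotypes")
  structure(out, class = "SimTruth")
}
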