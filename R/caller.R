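# Quality-threshold diploid genotype calling from pileup observations.
#
# Detection parameters mirror a quality-based caller for a diploid
# organism: non-reference posterior >= 0.95 (versus sequencing error),
# depth >= 10x after base-quality filtering, alternate read frequency
# >= 20%, and per-base quality >= 30 at the variant position.  The
# genotype model is a flat-prior three-genotype binomial: alternate-allele
# probabilities {eps, 0.5, 1 - eps} for hom-ref / het / hom-alt with eps
# derived from the mean retained base quality.

#' Caller parameters
#' @param min_doc minimum depth after base-quality filtering.
#' @param min_alt_fraction minimum alternate read frequency.
#' @param min_base_quality minimum Phred base quality for a read to count.
#' @param min_nonref_posterior posterior threshold for emitting a variant
#'   (ties at the threshold are calls).
#' @param ploidy diploid only; kept explicit for the record.
#' @return a `CallerParams` list.
#' @export
caller_params <- function(min_doc = 10, min_alt_fraction = 0.20,
                          min_base_quality = 30,
                          min_nonref_posterior = 0.95, ploidy = 2L) {
  stopifnot(min_doc >= 0, min_alt_fraction >= 0, min_base_quality >= 0,
            min_nonref_posterior > 0.5, min_nonref_posterior < 1,
            ploidy == 2L)
  structure(list(min_doc = min_doc, min_alt_fraction = min_alt_fraction,
                 min_base_quality = min_base_quality,
                 min_nonref_posterior = min_nonref_posterior,
                 ploidy = ploidy), class = "CallerParams")
}

#' Pileup observation at one site
#' @param chrom,pos site coordinates (`pos` 1-based).
#' @param ref reference allele (atomic; indel alleles allowed).
#' @param alleles per-read observed alleles.
#' @param quals per-read Phred base qualities (same length as `alleles`).
#' @return a `SiteObservation` list.
#' @export
site_observation <- function(chrom, pos, ref, alleles, quals) {
  if (length(alleles) != length(quals)) {
    stop("alleles and quals must have equal length")
  }
  if (any(quals < 0)) stop("negative base quality")
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref,
                 alleles = as.character(alleles), quals = as.numeric(quals)),
            class = "SiteObservation")
}

#' Three-genotype posterior from allele counts
#'
#' Flat prior over {hom_ref, het, hom_alt}; binomial likelihoods with
#' alternate-allele probabilities {eps, 1/2, 1 - eps}.
#' @param n_alt,n_total alternate and total (filtered) read counts.
#' @param eps per-read error probability.
#' @return named numeric vector of posteriors summing to one.
#' @export
genotype_posteriors <- function(n_alt, n_total, eps) {
  p <- c(hom_ref = eps, het = 0.5, hom_alt = 1 - eps)
  ll <- dbinom(n_alt, n_total, p, log = TRUE)
  post <- exp(ll - max(ll))
  post / sum(post)
}

#' Call a diploid genotype at one site
#'
#' @param obs a `SiteObservation`.
#' @param params a `CallerParams`.
#' @return one-row tibble: `chrom, pos, ref, alt, genotype`
#'   (`hom_ref`/`het`/`hom_alt`/`no_call`), `posterior` (non-reference
#'   posterior), `depth`, `alt_count`, `alt_frac`, `filter`.
#' @export
call_site <- function(obs, params = caller_params()) {
  if (is.null(obs$ref) || is.na(obs$ref) || !nzchar(obs$ref)) {
    stop("reference allele absent from observation")
  }
  keep <- obs$quals >= params$min_base_quality
  alleles <- obs$alleles[keep]
  quals <- obs$quals[keep]
  depth <- length(alleles)
  row <- function(genotype, alt = NA_character_, posterior = NA_real_,
                  alt_count = NA_integer_, filter = "PASS") {
    tibble(chrom = obs$chrom, pos = obs$pos, ref = obs$ref, alt = alt,
           genotype = genotype, posterior = posterior,
           depth = depth, alt_count = alt_count,
           alt_frac = if (depth > 0 && !is.na(alt_count)) alt_count / depth
                      else NA_real_,
           filter = filter)
  }
  if (depth < params$min_doc) {
    return(row("no_call", filter = "low_depth"))
  }
  tab <- sort(table(alleles), decreasing = TRUE)
  nonref <- tab[names(tab) != obs$ref]
  if (!length(nonref) || nonref[1] == 0) {
    post <- genotype_posteriors(0L, depth, qual_to_eps(quals))
    return(row("hom_ref", posterior = unname(post["het"] + post["hom_alt"]),
               alt_count = 0L))
  }
  nonref <- nonref[order(-nonref, names(nonref))]
  alt <- names(nonref)[1]
  extra <- length(nonref) > 1
  n_alt <- as.integer(nonref[1])
  eps <- qual_to_eps(quals)
  post <- genotype_posteriors(n_alt, depth, eps)
  p_nonref <- unname(post["het"] + post["hom_alt"])
  filt <- if (extra) "multiallelic_minor_dropped" else "PASS"
  if (n_alt / depth < params$min_alt_fraction) {
    return(row("hom_ref", alt = alt, posterior = p_nonref, alt_count = n_alt,
               filter = paste_filters("low_alt_fraction", extra)))
  }
  if (p_nonref >= params$min_nonref_posterior) {
    g <- if (post["hom_alt"] > post["het"]) "hom_alt" else "het"
    return(row(g, alt = alt, posterior = p_nonref, alt_count = n_alt,
               filter = filt))
  }
  row("hom_ref", alt = alt, posterior = p_nonref, alt_count = n_alt,
      filter = paste_filters("low_posterior", extra))
}

qual_to_eps <- function(quals) {
  # eps capped away from 0.5 so the hom-ref/het likelihoods stay ordered
  min(10^(-mean(quals) / 10), 0.49)
}

paste_filters <- function(base, extra) {
  if (extra) paste(base, "multiallelic_minor_dropped", sep = ";") else base
}

#' Pileup observations at known sites
#'
#' Collects the per-read base (and its quality) overlapping each site from
#' qualifying reads, walking CIGARs; reads whose alignment deletes the
#' site contribute a `"<del>"` allele.
#' @param reads read tibble (or SAM/BAM path).
#' @param sites known-site tibble (chrom, pos, ref, alt, rsid, ...).
#' @param min_mapq mapping-quality floor for included reads.
#' @return list of `SiteObservation`, named by rsid.
#' @export
pileup_sites <- function(reads, sites, min_mapq = 1L) {
  if (is.character(reads)) reads <- read_sam(reads)
  q <- qualifying_reads(reads, min_mapq = min_mapq)
  ends <- if (nrow(q)) read_end(q) else integer(0)
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    pos <- sites$pos[i]
    sel <- which(q$rname == sites$chrom[i] & q$pos <= pos & ends >= pos)
    alleles <- character(0); quals <- numeric(0)
    for (j in sel) {
      off <- cigar_query_offset(q$cigar[j], q$pos[j], pos)
      if (is.na(off$qpos)) {
        if (off$op == "D") {
          alleles <- c(alleles, "<del>")
          quals <- c(quals, mean_string_qual(q$qual[j]))
        }
        next
      }
      alleles <- c(alleles, substr(q$seq[j], off$qpos, off$qpos))
      quals <- c(quals, string_to_phred(q$qual[j])[off$qpos])
    }
    out[[i]] <- site_observation(sites$chrom[i], pos, sites$ref[i],
                                 alleles, quals)
  }
  names(out) <- sites$rsid
  out
}

#' Call genotypes at all panel known sites for one sample
#'
#' @param reads read tibble or SAM/BAM path.
#' @param panel a `PanelDefinition` with known sites.
#' @param params a `CallerParams`.
#' @param sample_id optional label.
#' @param vcf_path if non-NULL, variant records (het/hom_alt) are written
#'   as VCF 4.2.
#' @return tibble of per-site calls (all sites, including hom_ref and
#'   no_call rows) with columns `rsid`, `gene`, `star_allele` joined in.
#' @export
call_sample <- function(reads, panel, params = caller_params(),
                        sample_id = NULL, vcf_path = NULL) {
  if (is.character(reads)) reads <- read_sam(reads)
  sample_id <- sample_id %||% attr(reads, "sample_id") %||% "sample"
  sites <- panel$known_sites
  obs <- pileup_sites(reads, sites)
  calls <- do.call(rbind, lapply(obs, call_site, params = params))
  calls <- cbind(tibble(sample_id = sample_id, rsid = sites$rsid,
                        gene = sites$gene, star_allele = sites$star_allele),
                 calls)
  calls <- as_tibble(calls)
  if (!is.null(vcf_path)) write_vcf(calls, vcf_path, sample_id)
  calls
}

#' Write variant calls as VCF 4.2
#'
#' Homozygous-reference and no-call sites are omitted from the VCF body
#' (they remain in the call set).
#' @param calls a [call_sample()] tibble.
#' @param path output path.
#' @param sample_id sample column name.
#' @export
write_vcf <- function(calls, path, sample_id = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pgxpanel",
           "##INFO=<ID=PP,Number=1,Type=Float,Description=\"Posterior probability of a non-reference genotype\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Filtered read depth\">",
           "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_id))
  v <- calls[calls$genotype %in% c("het", "hom_alt"), ]
  body <- if (nrow(v)) {
    gt <- ifelse(v$genotype == "het", "0/1", "1/1")
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\tPP=%.6g\t%s\t%s",
            v$chrom, v$pos, ifelse(is.na(v$rsid), ".", v$rsid),
            v$ref, v$alt, ifelse(v$filter == "PASS", "PASS", v$filter),
            v$posterior, "GT:DP:AF",
            sprintf("%s:%d:%.4g", gt, v$depth, v$alt_frac))
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
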