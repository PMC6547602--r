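# SAM/FASTQ I/O and read-record filtering.  Reads are held as a tibble of
# SAM columns; files are read back through Rsamtools (SAM -> BAM -> scan).

#' Write read records as SAM
#' @param reads read tibble (see [simulate_sample()]).
#' @param seqlengths named integer vector of reference lengths.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sam <- function(reads, seqlengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  reads <- reads[order(match(reads$rname, names(seqlengths)), reads$pos), ]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  reads$qname, reads$flag, reads$rname, reads$pos,
                  reads$mapq, reads$cigar, reads$rnext, reads$pnext,
                  reads$tlen, reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM/BAM file into a read tibble
#' @param path SAM or BAM path (SAM requires an @SQ header).
#' @return a read tibble.
#' @export
read_sam <- function(path) {
  bam <- if (grepl("\\.bam$", path)) path else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize", "seq", "qual")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  tibble(qname = res$qname, flag = as.integer(res$flag),
         rname = as.character(res$rname), pos = res$pos,
         mapq = as.integer(res$mapq), cigar = res$cigar,
         rnext = ifelse(is.na(as.character(res$mrnm)), "*",
                        as.character(res$mrnm)),
         pnext = ifelse(is.na(res$mpos), 0L, res$mpos),
         tlen = ifelse(is.na(res$isize), 0L, res$isize),
         seq = as.character(res$seq), qual = as.character(res$qual))
}

#' Write read records as FASTQ
#'
#' Sequences of reverse-strand records are reverse-complemented back to
#' read orientation; secondary/supplementary records are skipped.
#' @param reads read tibble.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  keep <- !flag_has(reads$flag, SAM_SECONDARY) &
    !flag_has(reads$flag, SAM_SUPPLEMENTARY)
  reads <- reads[keep, ]
  seqs <- reads$seq
  quals <- reads$qual
  rev <- flag_has(reads$flag, SAM_REVERSE)
  if (any(rev)) {
    seqs[rev] <- revcomp(seqs[rev])
    quals[rev] <- vapply(quals[rev], function(q) {
      paste(rev(strsplit(q, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  mate <- ifelse(flag_has(reads$flag, SAM_SECOND_IN_PAIR), "/2", "/1")
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$qname, mate)
  out[seq(2, length(out), 4)] <- seqs
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- quals
  writeLines(out, path)
  invisible(path)
}

#' Read end positions (1-based inclusive) from CIGAR
#' @param reads read tibble.
#' @export
read_end <- function(reads) {
  reads$pos + cigar_ref_width(reads$cigar) - 1L
}

#' Mark PCR duplicates by identical fragment endpoints
#'
#' Records sharing (chromosome, start, CIGAR-end, mate start) are treated
#' as one fragment; the copy with the highest mean base quality is kept,
#' the rest receive the SAM duplicate flag.
#' @param reads read tibble.
#' @return the tibble with duplicate flags set.
#' @export
mark_duplicates <- function(reads) {
  if (!nrow(reads)) return(reads)
  key <- paste(reads$rname, reads$pos, read_end(reads), reads$pnext,
               bitwAnd(reads$flag, SAM_FIRST_IN_PAIR + SAM_SECOND_IN_PAIR),
               sep = ":")
  mq <- vapply(reads$qual, mean_string_qual, numeric(1), USE.NAMES = FALSE)
  ord <- order(key, -mq)
  dupvec <- duplicated(key[ord])
  dup <- logical(nrow(reads))
  dup[ord] <- dupvec
  set <- dup & !flag_has(reads$flag, SAM_DUPLICATE)
  reads$flag[set] <- reads$flag[set] + SAM_DUPLICATE
  reads
}

#' Filter to depth-qualifying reads
#'
#' Keeps primary, mapped, paired records whose mate is mapped, excluding
#' duplicates and non-specific matches (secondary/supplementary or
#' MAPQ below `min_mapq`).  When no record carries a duplicate flag and
#' `detect_duplicates` is TRUE, duplicates are first marked from identical
#' fragment endpoints.
#' @param reads read tibble.
#' @param min_mapq minimum mapping quality (default 1, i.e. MAPQ 0 is
#'   treated as multimapped).
#' @param detect_duplicates mark duplicates when no flags are present.
#' @return the filtered tibble.
#' @export
qualifying_reads <- function(reads, min_mapq = 1L, detect_duplicates = TRUE) {
  if (!nrow(reads)) return(reads)
  if (detect_duplicates && !any(flag_has(reads$flag, SAM_DUPLICATE))) {
    reads <- mark_duplicates(reads)
  }
  keep <- !flag_has(reads$flag, SAM_UNMAPPED) &
    flag_has(reads$flag, SAM_PAIRED) &
    !flag_has(reads$flag, SAM_MATE_UNMAPPED) &
    !flag_has(reads$flag, SAM_DUPLICATE) &
    !flag_has(reads$flag, SAM_SECONDARY) &
    !flag_has(reads$flag, SAM_SUPPLEMENTARY) &
    reads$mapq >= min_mapq
  reads[keep, ]
}
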