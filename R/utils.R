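# Shared low-level helpers: SAM flag bits, Phred encoding, seed derivation.

SAM_PAIRED        <- 0x1L
SAM_PROPER_PAIR   <- 0x2L
SAM_UNMAPPED      <- 0x4L
SAM_MATE_UNMAPPED <- 0x8L
SAM_REVERSE       <- 0x10L
SAM_MATE_REVERSE  <- 0x20L
SAM_FIRST_IN_PAIR <- 0x40L
SAM_SECOND_IN_PAIR<- 0x80L
SAM_SECONDARY     <- 0x100L
SAM_QCFAIL        <- 0x200L
SAM_DUPLICATE     <- 0x400L
SAM_SUPPLEMENTARY <- 0x800L

flag_has <- function(flag, bit) bitwAnd(as.integer(flag), as.integer(bit)) != 0L

#' Reverse-complement DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 encoding used throughout (SAM/FASTQ convention).
PHRED_CHARS <- strsplit(rawToChar(as.raw(33:126)), "", fixed = TRUE)[[1]]

phred_to_string <- function(q) {
  PHRED_CHARS[pmin(pmax(as.integer(round(q)), 0L), 93L) + 1L]
}

string_to_phred <- function(s) utf8ToInt(s) - 33L

mean_string_qual <- function(s) {
  if (!nzchar(s)) return(NA_real_)
  mean(string_to_phred(s))
}

# All randomness derives from a single user seed; per-task streams are
# spawned deterministically and kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

round1 <- function(x) round(x, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

ref_consumed_ops <- c("M", "D", "N", "=", "X")

parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(m)) stop("malformed CIGAR: ", cigar)
  list(len = as.integer(sub("[MIDNSHP=X]$", "", m)),
       op  = sub("^\\d+", "", m))
}

cigar_ref_width <- function(cigar) {
  # reads typically share a handful of CIGAR strings; compute per unique
  u <- unique(cigar)
  w <- vapply(u, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% ref_consumed_ops])
  }, integer(1), USE.NAMES = FALSE)
  w[match(cigar, u)]
}

# Map a 1-based reference position to the 1-based query offset of a read.
# Returns a list(qpos, op): qpos is NA when the position falls in a deletion
# or reference skip (op then says which), or outside the alignment.
cigar_query_offset <- function(cigar, read_pos, target_pos) {
  p <- parse_cigar(cigar)
  rpos <- read_pos
  qpos <- 1L
  for (i in seq_along(p$op)) {
    op <- p$op[i]; len <- p$len[i]
    if (op %in% c("M", "=", "X")) {
      if (target_pos < rpos + len) {
        if (target_pos >= rpos) {
          return(list(qpos = qpos + (target_pos - rpos), op = op))
        }
        return(list(qpos = NA_integer_, op = "outside"))
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (target_pos < rpos + len) return(list(qpos = NA_integer_, op = op))
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    }
    # H and P consume nothing we track
  }
  list(qpos = NA_integer_, op = "outside")
}
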