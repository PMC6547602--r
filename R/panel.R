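# Panel model: capture/evaluation target intervals, gene metadata and the
# table of known clinically relevant sites.
#
# Coordinate conventions: BED files are 0-based half-open; everything held
# in memory is a 1-based GRanges; variant positions are 1-based (VCF).
# Conversions happen only at the I/O boundary (rtracklayer does them).

REGION_KINDS <- c("exon", "utr_flank", "intron_flank", "known_noncoding")
PHARMGKB_LEVELS <- c("1A", "1B", "2A", "2B", "3", "other")

#' Construct panel target regions
#'
#' @param chrom,gene,kind character vectors (recycled).
#' @param start,end 0-based half-open interval bounds (BED convention).
#' @return a sorted `GRanges` with metadata columns `gene` and `kind`.
#' @export
target_regions <- function(chrom, start, end, gene, kind = "exon") {
  if (any(start >= end)) stop("target regions must satisfy start < end")
  kind <- rep_len(kind, length(start))
  if (!all(kind %in% REGION_KINDS)) {
    stop("region kind must be one of: ", paste(REGION_KINDS, collapse = ", "))
  }
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(as.integer(start) + 1L, as.integer(end)),
    gene = rep_len(gene, length(start)), kind = kind)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

new_panel <- function(regions, genes, known_sites) {
  structure(list(regions = regions, genes = genes, known_sites = known_sites),
            class = "PanelDefinition")
}

#' @export
print.PanelDefinition <- function(x, ...) {
  cat(sprintf(
    "PanelDefinition: %d genes, %d regions, %s target bases, %d known sites\n",
    nrow(x$genes), length(x$regions),
    format(panel_target_length(x), big.mark = ","), nrow(x$known_sites)))
  invisible(x)
}

empty_known_sites <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), rsid = character(), gene = character(),
         star_allele = character(), pharmgkb_level = character(),
         maf = numeric())
}

merge_panel_regions <- function(gr) {
  key <- paste(gr$gene, gr$kind, sep = "\r")
  parts <- lapply(split(seq_along(gr), key), function(idx) {
    red <- GenomicRanges::reduce(gr[idx], ignore.strand = TRUE)
    red$gene <- gr$gene[idx][1]
    red$kind <- gr$kind[idx][1]
    red
  })
  GenomicRanges::sort(do.call(c, unname(parts)), ignore.strand = TRUE)
}

#' Load a panel definition from BED + gene table + known-site table
#'
#' The BED `name` column encodes `gene|kind` with `kind` one of
#' `exon`, `utr_flank`, `intron_flank`, `known_noncoding` (a bare gene name
#' implies `exon`).  Overlapping regions of a single gene (same kind) are
#' merged; overlaps between different genes are rejected.  Every known site
#' must fall inside some region.
#'
#' @param bed_source path to a BED file (>= 4 columns) or a `GRanges` with
#'   metadata columns `gene` and `kind` (or `name`).
#' @param gene_table path to a tab-separated table, or a data frame, with
#'   columns `gene` and `family` (e.g. CYP/UGT/SLC/ABC/GST/other).
#' @param known_site_table optional path or data frame with columns
#'   `chrom, pos, ref, alt, rsid, gene, star_allele, pharmgkb_level`
#'   (`pos` 1-based, VCF convention) and optionally `maf`.
#' @return a `PanelDefinition`.
#' @export
load_panel <- function(bed_source, gene_table, known_site_table = NULL) {
  gr <- if (is.character(bed_source)) {
    rtracklayer::import(bed_source, format = "BED")
  } else bed_source
  if (is.null(gr$gene)) {
    nm <- gr$name
    if (is.null(nm) || anyNA(nm)) stop("BED source needs a 4th (name) column")
    parts <- strsplit(nm, "|", fixed = TRUE)
    gr$gene <- vapply(parts, `[`, character(1), 1)
    gr$kind <- vapply(parts, function(p) if (length(p) > 1) p[2] else "exon",
                      character(1))
  }
  if (!all(gr$kind %in% REGION_KINDS)) {
    bad <- unique(gr$kind[!gr$kind %in% REGION_KINDS])
    stop("unknown region kind(s): ", paste(bad, collapse = ", "))
  }
  GenomicRanges::strand(gr) <- "*"
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)

  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE,
                                      ignore.strand = TRUE)
  if (length(hits)) {
    gq <- gr$gene[S4Vectors::queryHits(hits)]
    gs <- gr$gene[S4Vectors::subjectHits(hits)]
    if (any(gq != gs)) {
      pair <- which(gq != gs)[1]
      stop(sprintf("overlapping regions belong to different genes: %s / %s",
                   gq[pair], gs[pair]))
    }
  }
  gr <- merge_panel_regions(gr)

  genes <- if (is.character(gene_table)) {
    as_tibble(read.delim(gene_table, stringsAsFactors = FALSE))
  } else as_tibble(gene_table)
  if (!all(c("gene", "family") %in% names(genes))) {
    stop("gene table needs columns 'gene' and 'family'")
  }
  missing_genes <- setdiff(unique(gr$gene), genes$gene)
  if (length(missing_genes)) {
    stop("regions refer to genes absent from the gene table: ",
         paste(missing_genes, collapse = ", "))
  }

  sites <- if (is.null(known_site_table)) {
    empty_known_sites()
  } else if (is.character(known_site_table)) {
    as_tibble(read.delim(known_site_table, stringsAsFactors = FALSE))
  } else as_tibble(known_site_table)
  if (nrow(sites)) {
    needed <- c("chrom", "pos", "ref", "alt", "rsid", "gene",
                "star_allele", "pharmgkb_level")
    if (!all(needed %in% names(sites))) {
      stop("known-site table needs columns: ", paste(needed, collapse = ", "))
    }
    if (any(sites$ref == sites$alt)) stop("known site with ref == alt")
    if (!all(sites$pharmgkb_level %in% PHARMGKB_LEVELS)) {
      stop("pharmgkb_level must be one of: ",
           paste(PHARMGKB_LEVELS, collapse = ", "))
    }
    site_gr <- GenomicRanges::GRanges(sites$chrom,
                                      IRanges::IRanges(sites$pos, sites$pos))
    inside <- IRanges::overlapsAny(site_gr, gr, ignore.strand = TRUE)
    if (!all(inside)) {
      stop("known site(s) outside all panel regions: ",
           paste(sites$rsid[!inside], collapse = ", "))
    }
  }
  new_panel(gr, genes, sites)
}

#' Total (merged) panel target length in bases
#' @param panel a `PanelDefinition` or `GRanges`.
#' @export
panel_target_length <- function(panel) {
  gr <- if (inherits(panel, "PanelDefinition")) panel$regions else panel
  sum(GenomicRanges::width(GenomicRanges::reduce(gr, ignore.strand = TRUE)))
}

#' Write panel regions to BED
#' @param regions `GRanges` with `gene` and `kind` metadata columns.
#' @param path output path.
#' @export
write_panel_bed <- function(regions, path) {
  gr <- regions
  gr$name <- paste(gr$gene, gr$kind, sep = "|")
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, "name", drop = FALSE]
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Evaluation footprint of a panel
#'
#' Coverage and variant analysis are restricted to the coding regions plus
#' a short flank on each exon side (default 10 bp) and at most `utr_extent`
#' bases (default 250) of each UTR; separately targeted known non-coding
#' regions are retained and deep intronic capture flanks are dropped.  The
#' result is merged per gene.  Applied to an already-evaluated `GRanges`
#' the function only re-merges, so it is idempotent.
#'
#' @param panel a `PanelDefinition` (or a `GRanges` from a previous call).
#' @param exon_flank bases added on each side of every exon (>= 0).
#' @param utr_extent maximum UTR bases kept, measured from the gene-body
#'   side (>= 0).
#' @return a sorted `GRanges` with `gene` and `kind` metadata columns.
#' @export
evaluation_regions <- function(panel, exon_flank = 10, utr_extent = 250) {
  if (exon_flank < 0 || utr_extent < 0) stop("flank parameters must be >= 0")
  if (!inherits(panel, "PanelDefinition")) {
    return(reduce_by_gene(panel))
  }
  gr <- panel$regions
  ex <- gr[gr$kind == "exon"]
  if (length(ex)) {
    GenomicRanges::start(ex) <- pmax(1L, GenomicRanges::start(ex) - as.integer(exon_flank))
    GenomicRanges::end(ex) <- GenomicRanges::end(ex) + as.integer(exon_flank)
  }
  utr <- gr[gr$kind == "utr_flank"]
  if (length(utr) && utr_extent > 0) {
    keep <- vector("list", length(utr))
    for (i in seq_along(utr)) {
      u <- utr[i]
      if (GenomicRanges::width(u) > utr_extent) {
        gx <- ex[ex$gene == u$gene &
                   as.character(GenomicRanges::seqnames(ex)) ==
                     as.character(GenomicRanges::seqnames(u))]
        upstream <- length(gx) > 0 &&
          GenomicRanges::end(u) <= min(GenomicRanges::start(gx))
        if (upstream) {
          GenomicRanges::start(u) <- GenomicRanges::end(u) - as.integer(utr_extent) + 1L
        } else {
          GenomicRanges::end(u) <- GenomicRanges::start(u) + as.integer(utr_extent) - 1L
        }
      }
      keep[[i]] <- u
    }
    utr <- do.call(c, keep)
  } else if (utr_extent == 0) {
    utr <- utr[0]
  }
  noncoding <- gr[gr$kind == "known_noncoding"]
  reduce_by_gene(c(ex, utr, noncoding))
}

# Merge per gene, keeping a representative kind (exon wins on mixtures).
reduce_by_gene <- function(gr) {
  parts <- lapply(split(seq_along(gr), gr$gene), function(idx) {
    red <- GenomicRanges::reduce(gr[idx], ignore.strand = TRUE,
                                 with.revmap = TRUE)
    kinds <- lapply(red$revmap, function(m) unique(gr$kind[idx][m]))
    red$gene <- gr$gene[idx][1]
    red$kind <- vapply(kinds, function(k) {
      if ("exon" %in% k) "exon" else k[1]
    }, character(1))
    red$revmap <- NULL
    red
  })
  GenomicRanges::sort(do.call(c, unname(parts)), ignore.strand = TRUE)
}

#' Generate a full-scale panel layout
#'
#' Deterministic coordinate generator reproducing the geometry of a
#' 100-gene pharmacogene capture design: per gene, six 600-bp exons with
#' 300-bp intronic capture flanks (short introns captured whole), 250 bp of
#' UTR on each side, and two of five introns short enough that their flanks
#' merge.  At `n_genes = 100` the merged capture footprint is 722 kb and
#' the evaluation footprint (10-bp exon flanks, 250-bp UTRs) is 422 kb.
#'
#' @param n_genes number of genes to lay out.
#' @return a `PanelDefinition` (no known sites).
#' @export
make_scaled_panel <- function(n_genes = 100) {
  exon_w <- 600L; flank <- 300L; utr_w <- 250L; gap <- 10L
  introns <- c(1000L, 360L, 1000L, 360L, 1000L)
  stride <- 300L + utr_w + gap + 6L * exon_w + sum(introns) + gap + utr_w + 300L + 500L
  rows <- vector("list", n_genes)
  for (gi in seq_len(n_genes)) {
    g <- sprintf("GENE%03d", gi)
    cur <- 1000L + (gi - 1L) * stride
    s <- integer(0); e <- integer(0); k <- character(0)
    add <- function(len, kind) {
      s <<- c(s, cur); e <<- c(e, cur + len); k <<- c(k, kind)
      cur <<- cur + len
    }
    add(flank, "intron_flank")          # outer 5' flank
    add(utr_w, "utr_flank")             # 5' UTR
    cur <- cur + gap
    for (ei in 1:6) {
      add(exon_w, "exon")
      if (ei < 6) {
        L <- introns[ei]
        if (L <= 2L * flank) {
          add(L, "intron_flank")
        } else {
          add(flank, "intron_flank")
          cur <- cur + (L - 2L * flank)
          add(flank, "intron_flank")
        }
      }
    }
    cur <- cur + gap
    add(utr_w, "utr_flank")             # 3' UTR
    add(flank, "intron_flank")          # outer 3' flank
    rows[[gi]] <- data.frame(start = s, end = e, gene = g, kind = k)
  }
  df <- do.call(rbind, rows)
  regions <- target_regions("chrP", df$start, df$end, df$gene, df$kind)
  fams <- c("CYP", "UGT", "SLC", "ABC", "other")
  genes <- tibble(gene = sprintf("GENE%03d", seq_len(n_genes)),
                  family = fams[(seq_len(n_genes) - 1L) %% length(fams) + 1L])
  new_panel(merge_panel_regions(regions), genes, empty_known_sites())
}
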