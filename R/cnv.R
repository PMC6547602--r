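# Read-depth CNV calling for a target gene versus a two-copy reference
# control panel.  Each track's per-region mean coverage over the CNV
# gene's probe target regions is divided by that sample's own mean
# coverage over the rest of the evaluation target (library-size
# normalization, excluding the CNV gene to avoid self-bias); per-region
# ratio and z-score metrics against the control mean/SD are combined into
# a whole-gene copy-number state by majority vote.

region_ids <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr), GenomicRanges::end(gr))
}

normalized_region_coverage <- function(track, cnv_gene) {
  idx <- track$regions$gene == cnv_gene
  if (!any(idx)) stop("track has no regions for gene ", cnv_gene)
  other <- unlist(track$depth[!idx])
  denom <- mean(other)
  if (!is.finite(denom) || denom == 0) {
    stop("zero overall coverage for sample ", track$sample_id)
  }
  means <- vapply(track$depth[idx], mean, numeric(1))
  setNames(means / denom, region_ids(track$regions[idx]))
}

#' Build a two-copy CNV reference panel from control tracks
#'
#' Controls must pass coverage QC and, unless `allow_mixed_batch`, come
#' from a single sequencing-cluster batch (coverage profiles differ
#' between plex sizes, so mixing batches confounds the normalization).
#'
#' @param control_tracks list of `CoverageTrack` for 2-copy controls.
#' @param cnv_gene the CNV target gene.
#' @param sd_floor lower clamp on per-region SD of normalized coverage.
#' @param min_controls required number of controls (configurable floor;
#'   fewer than 2 is always an error).
#' @param allow_mixed_batch override the single-batch precondition.
#' @return a `CnvReference`: list with `gene`, `regions`, `mean`, `sd`,
#'   `n_controls`, `batch`.
#' @export
build_cnv_reference <- function(control_tracks, cnv_gene, sd_floor = 0.02,
                                min_controls = 10,
                                allow_mixed_batch = FALSE) {
  n <- length(control_tracks)
  if (n < 2) stop("a CNV reference needs at least 2 controls")
  if (n < min_controls) {
    stop(sprintf("only %d controls; %d required (min_controls)", n,
                 min_controls))
  }
  batches <- unique(vapply(control_tracks, function(t) {
    as.character(t$batch %||% NA_character_)
  }, character(1)))
  if (length(batches) > 1 && !allow_mixed_batch) {
    stop("controls span multiple sequencing-cluster batches: ",
         paste(batches, collapse = ", "))
  }
  mat <- do.call(rbind, lapply(control_tracks, normalized_region_coverage,
                               cnv_gene = cnv_gene))
  zero_frac <- colMeans(mat == 0)
  if (any(zero_frac > 0.5)) {
    stop("region(s) with zero coverage in most controls: ",
         paste(colnames(mat)[zero_frac > 0.5], collapse = ", "))
  }
  idx <- control_tracks[[1]]$regions$gene == cnv_gene
  structure(list(gene = cnv_gene,
                 regions = control_tracks[[1]]$regions[idx],
                 mean = colMeans(mat),
                 sd = pmax(apply(mat, 2, stats::sd), sd_floor),
                 n_controls = n,
                 batch = batches[1],
                 sd_floor = sd_floor),
            class = "CnvReference")
}

#' Score a sample against a CNV reference panel
#' @param track the sample's `CoverageTrack` (normalized identically to
#'   the controls).
#' @param reference a `CnvReference`.
#' @return a `CnvMetrics`: per-region `normalized`, `ratio`
#'   (normalized / control mean, ~ copies/2) and `z`
#'   ((normalized - mean) / SD), plus gene-level medians.
#' @export
score_cnv_sample <- function(track, reference) {
  norm <- normalized_region_coverage(track, reference$gene)
  if (!identical(names(norm), names(reference$mean))) {
    stop("sample regions do not match the reference panel")
  }
  ratio <- norm / reference$mean
  z <- (norm - reference$mean) / reference$sd
  structure(list(sample_id = track$sample_id, gene = reference$gene,
                 region = names(norm), normalized = norm,
                 ratio = unname(ratio), z = unname(z),
                 median_ratio = stats::median(ratio),
                 median_z = stats::median(z)),
            class = "CnvMetrics")
}

#' Construct CNV metrics from precomputed ratio / z values
#'
#' Used when the per-region metrics come from elsewhere (e.g. a published
#' per-subject summary) rather than from [score_cnv_sample()].
#' @param sample_id,gene labels.
#' @param ratio,z numeric vectors (one value per probe region; a single
#'   gene-level pair is allowed).
#' @export
cnv_metrics <- function(sample_id, gene, ratio, z) {
  stopifnot(length(ratio) == length(z), all(ratio >= 0), all(is.finite(z)))
  structure(list(sample_id = sample_id, gene = gene,
                 region = sprintf("region%02d", seq_along(ratio)),
                 normalized = NA_real_, ratio = ratio, z = z,
                 median_ratio = stats::median(ratio),
                 median_z = stats::median(z)),
            class = "CnvMetrics")
}

#' CNV calling thresholds
#'
#' Conjunctive ratio-and-z rule: a region supports heterozygous deletion
#' when ratio <= `del_ratio` and z <= `del_z`, duplication when ratio >=
#' `dup_ratio` and z >= `dup_z`; ratio <= `homdel_ratio` marks a
#' homozygous deletion regardless of z.  Defaults bracket published
#' deletion metrics (ratios 0.43-0.55, z <= -2.74) and duplication
#' metrics (ratios 1.29-1.62, z >= 1.91).
#' @param del_ratio,del_z,dup_ratio,dup_z,homdel_ratio region thresholds.
#' @param majority fraction of regions that must agree for a gene call.
#' @export
cnv_thresholds <- function(del_ratio = 0.65, del_z = -2.5,
                           dup_ratio = 1.25, dup_z = 1.9,
                           homdel_ratio = 0.1, majority = 0.6) {
  structure(list(del_ratio = del_ratio, del_z = del_z,
                 dup_ratio = dup_ratio, dup_z = dup_z,
                 homdel_ratio = homdel_ratio, majority = majority),
            class = "CnvThresholds")
}

#' Whole-gene copy-number call
#'
#' Per-region states (0 / 1 / 2 / more_than_2) are combined by majority
#' vote; when no state reaches the majority fraction the gene is no_call.
#' Regions whose ratio passes a CNV threshold while the z-score does not
#' (or vice versa) stay state 2 and raise a high-variance note, since
#' both criteria are required.
#'
#' @param metrics a `CnvMetrics`.
#' @param thresholds a `CnvThresholds`.
#' @return one-row tibble: `sample_id`, `gene`, `state`
#'   (`"0"`, `"1"`, `"2"`, `"more_than_2"`, `"no_call"`),
#'   `support_frac`, `median_ratio`, `median_z`, `note`.
#' @export
call_cnv_gene <- function(metrics, thresholds = cnv_thresholds()) {
  th <- thresholds
  r <- metrics$ratio; z <- metrics$z
  state <- ifelse(r <= th$homdel_ratio, "0",
           ifelse(r <= th$del_ratio & z <= th$del_z, "1",
           ifelse(r >= th$dup_ratio & z >= th$dup_z, "more_than_2", "2")))
  conflicted <- (r <= th$del_ratio & z > th$del_z & r > th$homdel_ratio) |
    (r >= th$dup_ratio & z < th$dup_z)
  tab <- table(state)
  top <- names(tab)[which.max(tab)]
  frac <- max(tab) / length(state)
  call <- if (frac >= th$majority) top else "no_call"
  note <- if (any(conflicted & state == "2")) "high_variance" else ""
  tibble(sample_id = metrics$sample_id, gene = metrics$gene,
         state = call, support_frac = frac,
         median_ratio = metrics$median_ratio, median_z = metrics$median_z,
         note = note)
}

#' Cohort CNV state frequencies
#'
#' Subject-level percentages per state (1 decimal) plus allele-level
#' deletion/duplication frequencies (a heterozygous deletion is one
#' deleted allele of 2N; a homozygous deletion is two).
#' @param calls tibble of [call_cnv_gene()] rows.
#' @param n_subjects cohort denominator (defaults to `nrow(calls)`).
#' @return list: `states` tibble (state, n, pct_subjects) and `alleles`
#'   tibble (event, n_alleles, pct_alleles).
#' @export
cohort_cnv_frequency <- function(calls, n_subjects = nrow(calls)) {
  lev <- c("0", "1", "2", "more_than_2", "no_call")
  tab <- table(factor(calls$state, levels = lev))
  states <- tibble(state = lev, n = as.integer(tab),
                   pct_subjects = round1(100 * as.integer(tab) / n_subjects))
  del_alleles <- 2L * tab[["0"]] + tab[["1"]]
  dup_alleles <- tab[["more_than_2"]]
  alleles <- tibble(event = c("deletion", "duplication"),
                    n_alleles = c(del_alleles, dup_alleles),
                    pct_alleles = round1(100 * c(del_alleles, dup_alleles) /
                                           (2L * n_subjects)))
  list(states = states, alleles = alleles)
}

#' Serialize / read a CNV reference panel as tab-separated text
#' @param reference a `CnvReference`.
#' @param path file path.
#' @export
write_cnv_reference <- function(reference, path) {
  df <- data.frame(region = names(reference$mean),
                   gene = reference$gene,
                   mean = reference$mean, sd = reference$sd,
                   n = reference$n_controls, batch = reference$batch)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cnv_reference
#' @export
read_cnv_reference <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(list(gene = df$gene[1], regions = NULL,
                 mean = setNames(df$mean, df$region),
                 sd = setNames(df$sd, df$region),
                 n_controls = df$n[1], batch = df$batch[1],
                 sd_floor = min(df$sd)),
            class = "CnvReference")
}
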