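---
title: "Methods: models and design choices in pgxpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in pgxpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pgxpanel implements the computational stages of a targeted pharmacogene
capture panel: coverage quality control, quality-threshold diploid
genotype calling at known clinically relevant sites, promoter (TA)n
repeat genotyping of the UGT1A1*28 type, read-depth copy-number (CNV)
calling for CYP2D6 against a two-copy reference control group, variant
classification, activity-score phenotype prediction, and concordance
assessment against orthogonal genotyping.  This vignette records the
models behind each stage, the tunable parameters and their defaults, and
the design choices made where the underlying procedure was open.

## Coordinates and the two panel footprints

BED input/output is 0-based half-open; everything in memory is a 1-based
`GRanges`; variant positions follow the 1-based VCF convention.
Conversions happen only at the I/O boundary (rtracklayer performs them),
so the formats round-trip bit-exactly.

A panel has two footprints.  The *capture* footprint is everything
probes were designed against: exons, 300-bp intronic flanks, 250-bp
UTRs, and separately targeted known non-coding sites.  The *evaluation*
footprint, over which coverage and variants are assessed, restricts this
to exons plus a 10-bp flank on each side, at most 250 bp of each UTR,
and the known non-coding regions; deep intronic capture flank is
dropped.  `evaluation_regions()` implements the restriction and merges
per gene; applied to its own output it only re-merges, so the operation
is idempotent.  UTR regions longer than the cap are clipped from the
gene-body side (the retained bases are the ones adjacent to the coding
sequence), and known non-coding regions carry no extra flank — they are
point targets by construction, so widening them has no biological
justification.

`make_scaled_panel()` reproduces the geometry of the full-scale design
(six 600-bp exons per gene, two of five introns short enough that their
flanks merge, 250-bp UTRs): at 100 genes the merged capture footprint is
722 kb and the evaluation footprint 422 kb, which the test suite checks
by summing merged interval widths.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream claim is verified.

*Reference and panel.*  `make_reference()` lays out (by default) ten
genes on one miniature chromosome — a CNV target (CYP2D6), a promoter
(TA)6 repeat with unique 10-bp anchors (UGT1A1), two deletable GST-like
genes, and six further genes carrying known sites — with per-gene GC
content spanning 0.35–0.60 so that GC-coverage anticorrelation is
visible.  Known sites receive Hardy–Weinberg genotypes at per-site
allele frequencies.

*Depth model.*  Per capture region, fragment counts are negative
binomial with mean

    mu = mean_depth * width / (2 * read_length) * copies/2
         * (24 / cluster_size) * w(GC)

and dispersion 0.01 (variance mu + 0.01 mu^2).  Fragment midpoints are
uniform within the region, so the expected interior read-base density of
a two-copy gene equals `mean_depth` exactly; paired 100-bp reads are cut
from the two ends of each fragment.  The dispersion default gives
per-region coefficients of variation near 0.1 for well-behaved capture
probes, which in turn yields CNV z-scores of magnitude 3–6 for true
single-copy changes — the magnitude published per-subject summaries show
for validated deletions and duplications.  The GC weight
`w(GC) = 2 * plogis(-s * (GC - 0.45) * 10)` (strength `s`, default 1)
reproduces the qualitative GC/coverage anticorrelation; no quantitative
GC curve is published for the assay, so the strength is calibrated only
to make the bias visible, not to match a measured curve.

*Batch structure.*  The sequencing-cluster (plex) factor `24 /
cluster_size` makes 12-plex samples roughly twice as deep as 24-plex
samples at a fixed flow-cell budget, mirroring the direction of the
published per-cluster summary.

*Haplotypes and reads.*  Each sample has two haplotype sequences; a
heterozygous site puts the alternate allele on one of them, and reads
inherit a haplotype per fragment.  A (TA)7 haplotype is realised by
splicing the expanded repeat into any read that fully contains the
reference motif, trimming the read back to length — coordinates never
shift, which keeps the depth machinery exact.  Per-read quality is
drawn from N(36, 2) and applied uniformly across the read; substitution
errors occur at `base_error_rate` (default 1e-3) independent of the
quality string.  Exact-copy PCR duplicates, MAPQ-0 secondary alignments
and mate-unmapped fragments are injected at configurable rates and
flagged, so the exclusion rules downstream have something to exclude.

*Ground truth.*  Copy-number states for the CNV gene default to
1/2/3 with probabilities 0.08/0.84/0.08; GST-like genes are homozygously
deleted in 57% (GSTM1) and 17% (GSTT1) of subjects, matching the
near-zero-coverage carrier rates reported for those genes; the (TA)7
allele frequency defaults to 0.3.  Intended QC failures (a sample with a
collapsed read count, a sample with shifted GC) can be planted and are
recorded in the truth tables.

*What the generator does not emulate:* instrument-specific error
profiles, indel alignment artifacts, pseudogene homology beyond
well-separated genes, stutter noise in the repeat, and partial-gene
CNVs.  Passing tests therefore demonstrate correctness of the
*computational* stages under a clean generative model, not robustness to
every artifact of real capture data.

## Coverage QC

Depth of coverage at a base counts primary, mapped, paired reads whose
mate is mapped, excluding duplicates and non-specific matches.
"Non-specific" is implemented as secondary/supplementary flags or
mapping quality below 1 (configurable); duplicate flags are honoured
when present, otherwise duplicates are detected as identical
(chromosome, start, end, mate-start) fragments keeping the
highest-mean-quality copy.

A sample is excluded from variant analysis when

* more than 20% of its evaluation bases are below 10x (strictly more
  than — a sample at exactly 80% `pct_ge_10x` is retained),
* its read count falls below 1,000, or
* its mean read GC deviates from the cohort median by more than
  3 robust standard deviations (1.4826·MAD, floored at 0.25 percentage
  points so a degenerate cohort cannot flag everything).

The GC rule is a design choice: the underlying procedure flagged
samples whose GC distribution "deviated greatly" without a stated
cutoff, so the robust rule is exposed with `gc_k` configurable.

GST-style whole-gene deletions are flagged when a gene's median DOC is
below 5% of the sample's overall median; a zero overall median is an
error because such a sample should already have been excluded.

## Genotype calling

The caller keeps the four stated detection thresholds explicit: bases
below Q30 are dropped first; fewer than 10 remaining reads is a
`no_call` (this is what makes low-coverage heterozygotes designed false
negatives); an alternate fraction below 20% stays homozygous reference;
otherwise a flat-prior three-genotype binomial model is evaluated with
alternate-allele probabilities {eps, 1/2, 1 − eps} for
hom-ref/het/hom-alt, eps = 10^(−Q̄/10) from the mean retained base
quality (capped at 0.49 to keep the likelihoods ordered).  A variant is
emitted when the posterior probability of a non-reference genotype is at
least 0.95, ties counting as calls.  The model is the simplest one
consistent with a "non-reference probability versus sequencing error"
criterion; the commercial caller's internal model is unpublished, so
equivalence is claimed for the thresholds, not for numeric posteriors.
Raising the depth, fraction or posterior thresholds can only remove
calls; the base-quality threshold is *not* logically monotone (removing
low-quality reference reads can raise the alternate fraction), which is
why the monotonicity property is asserted for the former three.

Indel alleles are supported as atomic observation alleles; pileup from
reads additionally recognises deletions spanning a site via the CIGAR D
operation.  Multi-allelic sites keep the highest-count alternate and
flag the rest.  Homozygous-reference and no-call records stay in the
call set but are omitted from the VCF body.

## (TA)n repeat genotyping

A read contributes if its sequence contains left anchor + (TA)^k +
right anchor contiguously — the unit count is taken on the read, not the
reference, so expanded alleles are counted correctly; reads ending
inside the repeat are excluded, and unmatched reads are retried as
reverse complements.  The per-sample statistic is the percentage of
spanning reads with exactly 6 units.  Genotypes use fixed cut points
(>= 75% — *1/*1, <= 25% — *28/*28, between — *1/*28) with a 20-read
minimum; the published procedure genotyped by clustering a cohort
histogram, which `cohort_ta_histogram()` reproduces (gap-based
one-dimensional clustering, three modes near 100/50/0 when all three
genotypes are present), but a tool must also call single samples, hence
the fixed thresholds.  `min_spanning = 20` keeps the binomial 95%
confidence interval on the (TA)6 fraction narrower than the distance to
the nearest cut point.  Unit counts outside 5–8 stay in the histogram
and are excluded from the percentage denominator; if they exceed 1% of
spanning reads the profile carries a rare-allele flag (possible (TA)5 or
(TA)8 alleles) rather than a call.

## CNV calling

Each track's per-region mean coverage over the CNV gene is divided by
the sample's own mean coverage over the rest of the evaluation target —
library-size normalization that excludes the CNV gene itself to avoid
self-bias (the published tool does not document its formula; this is the
standard read-depth construction and is invariant under global scaling,
a property the suite asserts exactly).  A reference panel of two-copy
controls (>= 10 by default, always >= 2) from a single
sequencing-cluster batch supplies per-region means and SDs; SDs are
floored at 0.02 so degenerate panels cannot produce infinite z-scores,
and regions with zero coverage in most controls are rejected.  The
batch restriction mirrors the published analysis (CNV calling was
restricted to one plex size to avoid confounding by sample preparation)
and can be overridden.

Per region, ratio = normalized/mean (≈ copies/2) and z =
(normalized − mean)/SD.  The calling rule is conjunctive: deletion
requires ratio <= 0.65 *and* z <= −2.5, duplication ratio >= 1.25 *and*
z >= 1.9; ratio <= 0.1 marks a homozygous deletion.  The thresholds
bracket the published per-subject deletion metrics (ratios 0.43–0.55
with z <= −2.74) and duplication metrics (ratios 1.29–1.62 with
z >= 1.91).  Regions where one criterion passes and the other fails stay
two-copy and raise a high-variance note.  Gene state is a majority vote
(fraction >= 0.6) across probe regions, `no_call` otherwise.

Cohort frequencies are reported both per subject and per allele: nine
heterozygous deletions among 183 subjects are 4.9% of subjects but 2.5%
of alleles, and published frequency statements mix the two conventions,
so the tool prints both rather than choosing.

## Variant classification

Functional classes are assigned deterministically: codon translation
for coding SNVs (synonymous / non-synonymous / stop gain-or-loss),
indel length modulo 3 for frameshift versus in-frame, positions within
2 nucleotides of an intron–exon boundary as splicing, and membership in
a known non-coding target region as `known_noncoding`.  Plus and minus
strands are supported through complementation.  MAF categories follow
common >= 5%, 1% <= low frequency < 5%, rare < 1% (the band notation
"1% <= MAF > 5%" is read as 1–5%, the only reading consistent with
common >= 5%), with missing-MAF variants split by database presence:
known rsid but no frequency is *rare*, absent from the databases
entirely is *novel*.  Deleteriousness flags are scaled CADD > 20
(strictly — 20.0 is not flagged), SIFT < 0.05, PolyPhen-2 > 0.85, NA
where a score is missing; in-silico assessment is restricted to
protein-coding change and stop gain/loss, and the scores always arrive
in an annotation table — the package never computes them.  The
rare-versus-common deleterious-proportion comparison builds a 2×2 table
per score and uses the chi-squared test without continuity correction,
switching to Fisher's exact test when any expected cell is below 5.
The exonic denominator for MAF-category percentages (all classes except
`known_noncoding`) is reported explicitly as
`exonic_denominator` to remove any ambiguity.

## Phenotype prediction and concordance

The CYP2D6 activity model scores *1 and *2 at 1.0, *41 at 0.5, and the
null alleles *3, *4, *5 at 0; a duplicated allele counts twice.  Bands
are PM = 0, IM (0, 1], NM (1, 2], UM > 2 — the unique simple banding
consistent with every validated CNV-carrier diplotype, including
*1/*5 → IM and *1/*4 with a duplicated *4 → IM.  It is documented as
consistent with that validation set, not as a current CPIC table.  When
copies exceed two but the duplicated allele is unknown, both candidate
phenotypes are reported with an ambiguity flag instead of guessing.

Concordance compares zygosity exactly; a false positive is an
orthogonal homozygous wildtype called a carrier, a false negative an
orthogonal carrier called homozygous wildtype, and a het/hom mismatch is
discordant without being either.  Sensitivity is 1 − FN/carriers,
specificity 1 − FP/wildtypes, with Wilson score 95% intervals (the
interval `prop.test` computes without continuity correction;
exact binomial available via `ci_method = "exact"`), all percentages at
one decimal.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty read sets error in
`read_qc`; zero overall coverage errors in CNV scoring; the caller caps
eps at 0.49; SD floors and MAD floors are described above; allele-count
ties in the caller break lexicographically and posterior ties at the
threshold are calls.  The test suite runs the full pipeline on
simulated cohorts of 12–45 samples at 80–100x over the ten-gene
miniature genome, and the recovery gates (>= 95% of CNV states over 100
seeded runs, >= 99% of repeat genotypes over 100 seeded runs, >= 95% of
all truth states end-to-end) use narrowed gene subsets where only one
locus is under test; these sizes were chosen to exercise every rule
while keeping a full run in the minutes range on a single core.

## Known limitations

Pileup walks CIGARs but the simulator emits ungapped alignments, so
indel calling is exercised through constructed observations rather than
simulated reads; the repeat genotyper assumes the repeat plus anchors
fits within a read; the CNV caller emits whole-gene states only (no
breakpoints, no hybrid alleles); the transcript model is single-isoform;
and phenotype prediction ships an activity model for CYP2D6 only,
though `cyp2d6_activity_model()`'s structure accepts any allele table.
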