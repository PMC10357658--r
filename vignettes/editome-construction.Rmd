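---
title: "Constructing a high-confidence A-to-I editome from multi-caller calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing a high-confidence A-to-I editome from multi-caller calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

A-to-I editing surveys based on RNA-seq face a signal-to-noise problem:
an A→G mismatch at a transcribed adenosine can be real editing, a DNA
variant, a mis-mapped read, or a caller artifact, and the relative
frequency of the artifact classes dwarfs the signal once repeats are
excluded.  `editomer` encodes an integration procedure whose individual
rules were each calibrated against large-scale Sanger validation of
candidate sites in a single cell type.  The package deliberately begins
*after* read alignment and per-caller site calling: the inputs are
normalized per-sample, per-method candidate tables (`chrom`, `pos`,
`strand`, `editing_level`, `coverage`), because the supported callers
emit mutually incompatible native formats and wrapping them would tie
the pipeline to their execution environments.  Converting a caller's
output to the dialect is a few lines of awk or R per caller.

A site identity is (contig, 1-based position of the edited adenosine,
strand); on the minus strand the forward-strand change reads T→C.  All
user-facing coordinates are 1-based (the convention of VCF and of the
caller outputs).  Internally, interval arithmetic is delegated to
`GenomicRanges`/`IRanges`, whose native 1-based closed representation is
used throughout; BED and BedGraph inputs are converted on import by
`rtracklayer`, so half-open boundary semantics of those formats are
honored without any hand-rolled coordinate shifting.

## Filtering rules and their parameters

Filters run in a fixed order — variants, repeats, mappability — and every
call lands in exactly one bin, which makes the per-stage tallies
conserved and auditable.

* **Variants** (strand-blind positional match).  A DNA variant produces
  the mismatch on both strands, so strand is ignored.  The variant list
  should contain common SNPs plus any genotype-specific variants
  available for the sample source.  Importantly, variants *absent* from
  the list (unannotated heterozygous A/G sites) pass this filter — this
  is a fundamental limit of sequence-level filtering, demonstrated by
  the simulator's hidden-SNP contaminants, and is the reason orthogonal
  genomic DNA validation remains necessary.
* **Repeats** (strandless interval overlap).  Repeat-hosted editing
  (mostly Alu) is biologically real but analytically distinct and
  mapping-artifact prone; this pipeline targets the non-repeat genome.
  The Alu share of removed calls is reported as a sanity indicator.
* **Mappability.**  A site needs a 100mer alignability score of 1 at its
  position (tested as ≥ 1 − 10⁻⁹ to tolerate text-float round trips) and
  a mean 24mer alignability strictly above 0.5 over the window of
  2·150 + 1 = 301 positions centred on it.  The window is always
  divided by 301: positions beyond a contig end, or with no BedGraph
  record, contribute 0.  Treating undefined as zero is deliberately
  conservative — uniqueness must be positively demonstrated — and gives
  one consistent rule at assembly edges, where the window would
  otherwise be ambiguous.

## Consensus semantics

Within one sample, the editing level of a site detected by several
methods is the arithmetic mean of the per-method levels.  The retention
thresholds — maximum aggregated level strictly above 0.2, and at least
two samples — are applied to the *aggregated* level, since aggregation
precedes thresholding in the procedure the rules were calibrated with.
The method set of a site is the union across samples, even when only one
sample's level clears the threshold: a site found by RED-ML at 0.1 in
one sample and SPRINT at 0.3 in another counts as detected by both.
HPC-REDItools evidence is ingested and exported (`methods_all`) but
excluded from every decision (`methods`), reflecting its auxiliary role.

## Context classification

Each site receives exactly one label by precedence: CDS, 5′UTR, 3′UTR,
lncRNA exon, intron, vlincRNA, antisense exon, antisense intron,
intergenic.  Sense categories require the site to lie on the feature's
strand (an editing substrate must be on the transcript strand); the
antisense categories fire only when the sole overlap is with the
opposite strand.  Two points of this ordering are conventions this
package fixes rather than inherits: (1) when a position is exonic in one
transcript and intronic in another, the exonic label wins, because the
mutually exclusive label distribution is most informative about
mature-mRNA impact; (2) a same-strand intron outranks a same-strand
vlincRNA, so "vlincRNA" always means *not intronic in any annotated
gene*.  UTR5/UTR3 are derived from GFF3 CDS features in transcript
orientation; transcripts without CDS contribute non-coding exons.

## Compendium decisions

Annotated sites (present in the editing databases) are kept when
detected by RED-ML or SPRINT; REDItools-only sites are dropped, since
they validated at 0%.  Unannotated sites must be detected by RED-ML,
and outside introns and vlincRNAs also by SPRINT — in those two
non-coding contexts RED-ML alone proved reliable, elsewhere it did not.
The RED-ML requirement is kept even for intron/vlincRNA sites (rather
than "any single method") because SPRINT-only sites validated at 0%.
Sites discovered adjacent to Sanger-validated sites join the unannotated
editome after three guards: dedup against pipeline sites, exclusion of
database-annotated positions, and rejection of known-variant positions.
Database records without strand match either strand; stranded records
must match exactly, accommodating the mixed strand reporting of the
source databases.

## Statistics

* **Weighted validation ratio.**  Sanger tests only a sample t of each
  stratum of N sites, with p positives; the estimate for a union of
  strata is Σ N·(p/t) / Σ N, i.e. each member inherits its stratum's
  ratio.  The stratum choice is the caller's: the published single-sample
  figure, for example, is the weighted average over the two
  detected-in-exactly-one-sample strata.
* **Minimal false fraction.**  Expected failures are rounded to whole
  sites per stratum before summing, matching how such tallies are
  reported, then divided by the combined population.
* **Enrichment odds ratios.**  For each context the 2×2 cross-product
  (a·d)/(b·c) of site counts against background counts.  The background
  definition is not canonical; this package defaults to the count of
  strand-resolved adenosines (A on +, T on −) in each context class over
  the non-repeat, 100mer-unique genome — the positions where the
  pipeline could have reported a site — computed from the bundle by
  `count_editable_background()`.  Any other background can be supplied
  directly.  Zero denominators yield a flagged `NA`, never infinity.
* **Motif profile.**  Transcript-sense base fractions over ±5 bp
  (reverse-complemented for minus-strand sites, T reported as U).
  Position 0 must be A; violations indicate upstream corruption and are
  excluded with a warning rather than silently absorbed.

## The synthetic study

`sim_config()` defaults define the simulated study: a 2 Mb, 2-contig
genome; 60 single-transcript genes (70% coding); ~40% repeat cover, half
Alu; 8 stranded vlincRNAs in gene-free territory; 5% low-mappability
patches; 12 samples; 400 true sites placed mostly in introns
(placement weights 0.66 intron, 0.10 3′UTR, 0.05 lncRNA exon, 0.04
vlincRNA, 0.06 intergenic, 0.03 + 0.03 antisense, 0.02 5′UTR, 0.01 CDS,
echoing the context distribution of validated editomes); U at −1 with
probability 0.5; Beta(2,2) editing levels; per-method sensitivities 0.6
(REDItools), 0.8 (RED-ML), 0.5 (SPRINT); singleton false positives 300
per sample for REDItools versus 30 for the others (the order-of-magnitude
asymmetry observed in practice); 20 recurrent artifact hotspots seen in
2–4 samples; 15 hidden heterozygous A/G SNPs absent from the variant
list and called at level ≈ 0.5 by every method in every sample; half of
the truth marked as database-annotated, a fifth of those records
strandless.  Where no published value constrains a parameter (e.g. exon
and intron length ranges, Beta(2,2)), values were chosen once as
realistic for a compact simulated locus set and are exposed in
`sim_config()` rather than hidden.

What the simulator does *not* emulate: read-level effects (coverage is
drawn, not computed from alignments), expression-dependent detection,
correlated errors between callers, hyper-edited clusters, and genuine
repeat-hosted editing.  Passing the end-to-end tests therefore shows the
*rules* behave as specified under the assumed error structure, not that
the pipeline's numerical yield on real data is reproduced.

The generator is deterministic: one integer seed fixes every file
byte-for-byte.  Truth placement never touches repeats, low-mappability
patches, or the 200 bp contig margins, and sites are at least 12 bp
apart so the planted −1 base of one site cannot overwrite another.

## Numerical and degenerate-input choices

* Editing levels are validated into [0, 1]; malformed rows are rejected
  individually and counted, a missing column fails the whole file.
* Site-table serialization prints levels with 17 significant digits, so
  write → read round-trips doubles exactly.
* A contig absent from the mappability tracks removes its sites (with a
  warning): uniqueness unknown is uniqueness unshown.
* Empty inputs are legal everywhere: an empty call directory yields an
  empty compendium with a valid manifest; `weighted_validation_ratio`
  refuses strata with `tested = 0` by contract rather than returning
  NaN.
* Ties: sites are ordered (chrom, pos, strand) in every output, making
  reruns byte-identical.

## Problem sizes used in the test suite

The shared test fixture is one default-configuration simulated study
(2 Mb genome, 12 samples, ~15,000 calls), run once per suite; the
brute-force oracle checks use ≥ 1000 randomized small instances per
operation (interval overlap, consensus group-by, window means).  These
sizes exercise every rule path while keeping the whole suite around a
minute on one CPU.

## Known limitations

* The decision rules are cell-type-calibrated heuristics; applying them
  to tissues with very different editing landscapes (e.g. brain, with
  abundant recoding) may be conservative in CDS contexts, where the
  rules are strictest.
* The annotated/unannotated split inherits whatever biases the supplied
  database has; the package treats it as ground annotation, not truth.
* Validation outcomes are consumed as a table; electropherogram
  interpretation is upstream of this package.
* Differential editing between conditions is out of scope: with one
  sample per condition the per-site level estimates were judged too
  unstable for such claims, and nothing here changes that.
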