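---
title: "Models and methods behind microgliaLOH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microgliaLOH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgliaLOH)
```

# The scientific problem

In a heterozygous `Cx3cr1^CreER-Eyfp/wt` mouse the protein-coding exon of
one *Cx3cr1* allele is replaced by a CreERT2–EYFP cassette. Mitotic
homologous recombination in G2 can resolve so that one daughter cell
inherits both wild-type chromatids and the other both knock-in chromatids —
reciprocal loss of heterozygosity (LOH). The wild-type daughter founds a
lineage that carries no label, cannot be Cre-depleted, and expresses twice
the CX3CR1 of its heterozygous neighbours. This package implements the
measurement pipelines that make such a population visible — coverage-based
zygosity calling, PCR band logic, morphometry, stereology, flow gating and
allele-dosage-aware expression analysis — together with generators that
produce synthetic inputs whose ground truth is known, so every pipeline can
be validated end to end without any external data.

# The toy locus and the hybrid reference

`make_locus_model()` builds a random 50 kb genome contig with a 1.5 kb
protein-coding exon (`exon2`), 8 kb normalisation flanks on either side, a
10 kb-padded analysis window, and a 6 kb cassette of which a 5 kb interval
is integrated into the genome on the knock-in haplotype. These sizes keep
all analysis windows well separated while read simulation and alignment run
in seconds; the exon must be at least 290 bp because its first 290 bases
form the dedicated `exon2_head` dosage window. The wild-type haplotype is
the genome as-is; the knock-in haplotype replaces the exon with the inserted
cassette segment.

`build_hybrid_reference()` mirrors the mapping strategy used for real data:
the genome contig (retaining the wild-type exon) plus the *inserted part
only* of the cassette as a separate `cassette_nongenomic` contig — the
plasmid backbone never appears in sequencing data and is excluded. A
coordinate map relates knock-in haplotype positions to hybrid coordinates;
round-tripping is the identity wherever a position has an image. All
internal coordinates are 0-based half-open; SAM output converts to 1-based,
which confines off-by-one risk to a single I/O layer.

# Read simulation, alignment and filtering

`simulate_wgs_readpairs()` draws fragments uniformly from the haplotypes
implied by the genotype (a binomial 50:50 split for the heterozygote),
truncated-normal fragment lengths (mean 350 bp, sd 50 bp), 75 bp FR mates,
iid substitution errors, and optional PCR duplicates that re-emit a chosen
fragment's coordinates with independent errors.

The aligner is deliberately minimal: exact 31-mer seeds at three offsets per
mate and strand, full-length mismatch extension (budget 6), MAPQ 60 for a
unique best placement and 0 for ties. A binary MAPQ model is sufficient
because the downstream rule is a hard `MAPQ < 20` exclusion. Duplicate
marking groups proper pairs by (contig, fragment start, fragment end,
orientation), keeps the highest base-quality record (ties broken by
lexicographically smallest template id, for determinism) and only ever
flags; `filter_alignments()` only ever removes, recording per-reason counts.
The dedup-then-MAPQ order is fixed and stated in the provenance log.
Cross-contig pairs are not "proper" but are the knock-in junction evidence,
so the proper-pair drop is switchable (`require_proper = FALSE`) and the
junction counter consumes the permissive set.

# Physical coverage and zygosity calling

Physical coverage is fragment-span coverage: the number of retained
fragments whose outer mapping span covers a base, accumulated with a
difference array (tested for exact equality against naive per-base
counting). Region means are normalised per million retained fragments; the
normalisation constant is a package choice, made explicit because plotted
"normalized coverage" rarely states one.

The dosage estimate anchors on the flanks, present on both alleles:
`wt_dosage = 2·cov(exon2)/cov(flank)` and
`ki_dosage = 2·cov(cassette)/cov(flank)`, with expectations (2,0), (1,1),
(0,2) for `wt/wt`, `ki/wt`, `ki/ki`. The genotype call is Poisson maximum
likelihood over fragment-midpoint counts in the exon and cassette regions
plus the two junction counts, with per-copy rates derived from the flank
fragment density. A junction is "wt-spanned" when a genome-contig fragment
strictly contains the junction point with at least one base on each side;
"ki-supported" when mates split between a genomic flank and the cassette
contig. Each observed count gets a small background rate (1 % of the
per-copy rate + 0.05) so that a single stray mismapped fragment cannot veto
a genotype: reads overhanging a junction by a few bases can legitimately
map within the mismatch budget. A Poisson rather than negative-binomial
likelihood is used because at toy scale there is no overdispersion source;
the call is `argmax` with the best-minus-second log-likelihood ratio as
confidence, and an absent flank anchor produces a no-call error rather than
a guess.

Sampling noise in this design is worth stating: at 30× fragment depth the
mean exon coverage over 1.5 kb has a relative SD of ~6 % (`wt/wt`) and
~11 % (`ki/wt`), because fragments covering a window of that size number
only in the dozens. A two-genotype coverage *ratio* estimated from 5 + 5
samples therefore carries ~5 % relative SD — recoveries of the factor-2
dosage relationship should be read against that yardstick.

# In-silico PCR

`find_primer_sites()` reports plus-strand matches of the primer and of its
reverse complement (substitutions only, no indels);
`predict_amplicons()` pairs every forward-oriented site with every
downstream reverse-oriented site within `max_len`, with product length
measured outer edge to outer edge as gel sizes are. The synthetic primer
set mirrors the real assay's layout — a common forward primer upstream of
the exon, a wild-type reverse inside the exon, a mutant reverse inside the
cassette, and a long-range reverse downstream spanning the whole insertion
— with sequences lifted verbatim from the generated locus so they bind
uniquely. Band logic follows directly: wt-band only for `wt/wt`, both for
`ki/wt`, mutant-band only for `ki/ki`; on any single haplotype the wt and
mutant bands are mutually exclusive because the insertion removes the
wt-reverse site. The published primer sequences for the two real assays are
shipped as a CSV fixture; since the real mouse locus is not shipped, their
expected product sizes are untestable and the unit tests exercise the
matcher on synthetic 300 bp neighbourhood stubs instead.

# Morphometry

The image pipeline is brightness gain → 3×3 median de-speckle → threshold →
Zhang–Suen thinning → pixel classification (endpoint = 1 neighbour, slab =
2, junction ≥ 3, with adjacent junction pixels merged into one junction) →
length as the sum of adjacent-pixel steps, 1 orthogonal and √2 diagonal.
The threshold is a fixed absolute value by default — the generator emits
calibrated intensities — with Otsu available for external images, since no
thresholding rule is inherent to the method. Channel subtraction is
performed at the summary level (totals and cell counts, floored at zero),
matching how reporter-negative cell metrics are derived from the Iba-1 and
reporter channels; a pixel-level mask-difference mode exists behind a flag
for sensitivity analysis. Cell counting opens the mask with a disc brush
(removing thin processes) and counts components above a minimum soma area.
Convex-hull process area is the shoelace area over `chull()` of the process
endpoints, with a degenerate flag for collinear inputs.

Two numerical choices deserve note. First, thinning a soma blob can leave
short terminal artefacts, so `prune_spurs()` removes terminal branches of
at most 4 px that end at a junction — well below the 20 px minimum process
length, so genuine processes are never pruned. Second, the generator draws
processes ~3 px wide at multiples of 45°, which makes the recovered
centre-line chain length exactly computable (1 or √2 per step) and lets the
suite assert per-cell endpoint counts exactly and lengths within 10 %
(rasterisation tolerance). Branches that would collide with unrelated
structure are skipped at render time so that ground truth stays exact; the
per-cell grid placement errors out after a bounded number of jitter
retries rather than silently overlapping cells.

# Stereology

`apply_counting_frames()` places 150 µm counting frames on a 300 µm
systematic grid (`asf = 0.25`) with a uniform random offset per section and
applies the unbiased counting rule — inclusion edges top and right,
exclusion edges bottom and left — implemented as a half-open modular
interval, which makes the estimator exactly unbiased under random offsets
(verified by a 500-offset simulation within 3 SE). The total estimate is
`N̂ = ΣQ/(asf·ssf·tsf)` with `ssf = 1/36` by default (25 µm sections
sampled every 36th) and `tsf = 1`, counting the full section thickness, as
no optical-disector height is part of the design. The Schmitz–Hof second
coefficient-of-error estimate is

CE = sqrt( m/(m−1) · ( Σq² / (Σq)² − 1/m ) ),

algebraically the sample CV of section counts divided by √m; the suite pins
it against a hand computation and checks that spreading a total across
sections lowers the CE versus concentrating it. Whether a CE below 0.1 is
treated as a design target or an observed property is an open question in
the field's practice; here it is an output check only, never a stopping
rule. Percent-of-control uses the control-group mean as denominator; its
sampling error therefore carries both group variances (a delta-method SE is
used when the recovery is tested).

# Flow cytometry

Events are labelled draws from per-population log-normal channel models
(linear, compensated scale). The default populations encode the biology of
interest: the reporter-negative population's CX3CR1 location parameter is
twice the heterozygote's, and its reporter channel sits at background.
Hierarchical gating evaluates 1-D thresholds or 2-D rectangles top-down, so
each event's memberships form a root-to-node chain, and fractions are
counts against an ancestor gate. Gate thresholds sit at log-scale midpoints
between the high and low states — with ≥ 4 log-sd separations
(sd_log = 0.35) the recovery of simulated labels is effectively exact, so
fraction recovery error is binomial counting noise only. MFI is the
arithmetic mean on the linear scale by default (geometric behind a flag)
— the convention matters only by a known factor for log-normal channels.
No spillover or compensation is modelled; exclusion of samples is never
automated and must be explicit in configuration.

# Expression simulation and testing

Counts are negative binomial around log-normal base means with per-sample
library factors and a fixed dispersion of 0.02, reflecting the low
biological noise of sorted 100-cell pools. The allele-dosage rules are
structural: the Cx3cr1 mean doubles in the reporter-negative group (two
wild-type alleles), Cre and Eyfp means are exactly zero there, and those
three genes are themselves true DEGs — so `n_planted_deg` counts them,
mirroring DEG lists in which the transgene products and Cx3cr1 appear. At
the defaults the Cx3cr1 group-ratio estimate from 5 pairs carries ~9 %
relative SD, so single-draw recoveries of the factor 2 scatter accordingly.

Tests are Welch (heteroscedastic, two-sided), paired t, or the classical
one-way F, run on `log2(RPKM + 1)`; fold changes use mean RPKM with a
pseudocount of 1 (no fold-change definition is canonical; the pseudocount
guards the zero-mean transgenes). Genes with all-zero counts or zero
variance are excluded before testing and before the Benjamini–Hochberg `m`.
BH is delegated to `stats::p.adjust`; the suite verifies it against an
independent brute-force implementation of the step-up formula. PCA scores
come from the SVD of row-centred data, genes prefiltered at p < 0.05
(multigroup F when ≥ 3 groups), sign fixed by making each component's
largest-magnitude loading positive; z-scoring drops constant rows with a
record of what was dropped.

# The branching population model

No repopulation equations exist to transcribe, so the simulator is the
minimal mechanism reproducing the qualitative biology with six parameters:
synchronous developmental divisions with reciprocal LOH (probability
`mu_loh` per heterozygous division produces one `wt/wt` and one `ki/ki`
daughter), then daily logistic growth (division probability
`g·(1 − N/K)` per genotype), LOH at heterozygous divisions throughout, a
one-day Bernoulli kill restricted to cassette-carrying residents, and
Poisson peripheral influx scaled by remaining niche room from the depletion
day onward. Counts are updated with exact binomial/Poisson draws, which is
distribution-identical to per-cell simulation and fast at any population
size. The census label-free fraction has closed form `mu_loh·n/2` after `n`
divisions (each LOH event contributes one wild-type daughter among the two
produced per division), verified against simulation within 3 SE; at the
defaults (`mu_loh = 1e-3`, 15 divisions) the expected fraction is 0.75 %,
comfortably below the 1 % homeostatic bound, and with homozygous knock-in
founders it is exactly zero — there is no wild-type allele to recombine
with. The `ki/ki` daughters are tracked as a compartment but are off by
default in summaries, since such cells are not observed in practice;
keeping the compartment preserves the reciprocity of the mechanism.
Growth-rate defaults order the genotypes by receptor dosage
(`wt/wt` 0.35 > `ki/wt` 0.25 > `ki/ki` 0.18 per day), encoding the
proliferative advantage that drives the post-depletion takeover.

# What the generators do and do not emulate

The generators reproduce the *statistical structure* each analysis assumes:
binomial allele sampling and Poisson fragment placement (WGS), log-normal
channel intensities with ground-truth labels (flow), homogeneous Poisson
cell fields (sections), NB counts with planted effects (expression), and
clean rasterised cell geometry (images). They deliberately omit: GC and
mappability bias, indels and structural noise in reads; spillover,
autofluorescence and doublets in flow; tissue shrinkage, lost caps and
inhomogeneous densities in sections; batch effects and count outliers in
expression; optics (PSF, z-blur), touching cells and staining gradients in
images. Passing tests therefore demonstrate correctness of the estimators
under their own assumptions — not robustness to every artefact of real
acquisitions, which is the usual division of labour between unit validation
and field use.

# Problem sizes and reproducibility

Every stochastic routine takes an explicit seed and restores the caller's
RNG state, so library use never perturbs a session's stream, and the
orchestrator derives stable per-stage sub-seeds from one global seed —
re-running a single stage reproduces its slice of a full run. The default
validation sizes are chosen for a laptop-minutes budget: 30× WGS recovery
over 10 seeds per genotype (plus 50 per genotype at 3×, where accuracy
stays ≥ 90 %), 6 × 50,000 flow events, 20 replicate animals per stereology
group, 2,000-gene matrices over 10 seeds, 200 branching replicates, and
500-offset unbiasedness checks. All are plain function arguments; nothing
in the code depends on these particular sizes.

# Known limitations

The aligner handles substitutions only (reads crossing an insertion
junction simply fail to map contiguously, which the junction evidence then
exploits); per-cell morphometry assumes non-touching cells; the stereology
module does not model optical-disector z-sampling or shrinkage; the flow
module reads no FCS binaries; the expression module models counts, not
read-level quantification. Each boundary is deliberate: the methods under
study live on the analysis side of those interfaces.
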