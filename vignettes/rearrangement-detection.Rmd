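---
title: "Detecting genome restructuring on a dual-haplotype hybrid reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genome restructuring on a dual-haplotype hybrid reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taqing)
```

## The biological setting

A heat-activated four-base restriction endonuclease (recognition motif
TCGA, the motif of TaqI) can be switched on transiently inside a living
cell, producing on the order of 200 simultaneous double-strand breaks
(DSBs).  In a *fused hybrid diploid* — a cell made by fusing two haploid
parents whose genomes differ at roughly 6.5 SNVs/kb and 0.7 InDels/kb
(~0.72% overall) — the repair of those breaks leaves a rich, detectable
record:

* **Translocations (TLs)** joining segments of different chromosomes.
  Because TaqI cleaves `T^CGA` leaving 2-nt 5′ `CG` cohesive overhangs,
  direct religation of two different cut sites reconstitutes an intact
  TCGA spanning the junction with *zero* net base loss.  Alternative
  end-joining instead leaves a 2–3 nt microhomology at the junction, and
  homologous recombination joins chromosomes through dispersed repeats
  (Ty-like retrotransposons, rDNA).
* **Break-induced repair (BIR)**: one-ended repair copies the homolog from
  an internal breakpoint to the chromosome end, producing a terminal
  chimeric tract.
* **Short gene conversion (SGC)**: an internal 0.7–30 kb tract is
  non-reciprocally copied from one homolog to the other.
* **Aneuploidy and segmental CNVs**: whole-chromosome or sub-chromosomal
  copy-number changes.

Because the two parental haplotypes are distinguishable at almost every
kilobase, BIR and SGC appear as *reciprocal* coverage signals when reads
are mapped to the combined dual-haplotype reference: the converted tract
has zero coverage on the acceptor haplotype and double coverage at the
homologous position of the donor.

This package implements the full detection pipeline on that dual
reference, together with a simulator that plants all of the above event
classes in a mechanism-faithful way, so every stage is testable without
any external data.

## The dual reference and coordinate conventions

`simulate_parental_pair()` builds parent A as uniform random sequence
with planted repeat families and derives parent B by applying SNVs and
short InDels at the requested densities.  The inter-haplotype variant map
is computed by `build_variant_map()` from the colinear alignment blocks,
and `liftover()` maps intervals between homologs by interpolation between
block anchors — the lifted length differs from the input only by net
InDel content.

All coordinates inside the package are **1-based closed** intervals, the
native convention of R and Bioconductor (`Biostrings`, `IRanges`); BED,
BEDPE and bedGraph exports convert to 0-based half-open at the file
boundary.  This was a deliberate choice: interval arithmetic in package
code then composes directly with Bioconductor containers, and the
off-by-one conversions are confined to two small writer functions.

Repeat families deserve a note.  Dispersed repeats are generated as
*subfamilies* of two near-identical copies (>= 99% identity within a
subfamily) placed on different chromosomes, with different subfamilies
unrelated to one another.  This mirrors the subfamily structure of real
LTR retrotransposons and gives repeat-mediated recombination a defined
substrate: a crossover joins the two copies of one subfamily.  A single
family of many near-identical copies would instead make repeat-mediated
junctions intrinsically unlocalizable — any copy pair would explain the
junction reads — which is not how resolvable junctions present in real
hybrid data.

## What the simulator emulates — and what it does not

`plant_events()` applies sequence-level edits through *segment maps*:
each chromosome copy of the fused diploid is an ordered list of source
intervals on the parental references.  The derivative sequence, the
expected copy number of every reference bin, and the truth record all
derive from the same segment map, so the truth set cannot drift from the
emitted data.

Mechanism fidelity is enforced at construction:

* restriction-direct TLs cut two TCGA sites after the T and religate
  crosswise, so both junction sequences carry an intact motif with both
  breakpoints at canonical cut positions (audited in the tests on the
  emitted sequences, not just the labels);
* microhomology junctions are chosen where the two flanks share an exact
  2–3 nt suffix and nothing longer, with no motif spanning the join;
* homologous TLs cross over inside a repeat subfamily at an offset where
  the two copies differ, so the junction has a defined base-exact
  position;
* BIR/SGC replace acceptor tracts with the lifted homolog interval.

Breakpoints are additionally placed where the local sequence window
(about one read length) contains at least one inter-haplotype SNV on each
side and differs from every other repeat copy.  Real junction calling
relies on exactly this property — the source strains were chosen for a
variant density "sufficient to distinguish the two alleles" — and making
it explicit keeps *base-exact recovery* a well-defined target.  The
consequence for interpretation: passing round-trip tests show the
detectors are correct when junctions are locally resolvable; they say
nothing about junctions buried in long perfect repeats (real pipelines
report those only approximately, as does the homolog-coverage machinery
here).

Coverage is synthesized from the copy-number oracle (expected depth =
copy number × per-copy depth, negative-binomially noised, variance
$\mu + 0.1\mu^2$ at the default dispersion), not by simulating and
aligning reads.  Read alignment is outside the package's scope — the
detectors consume tracks — and the coverage signal at desk scale is fully
characterized by its expectation and dispersion.  Consequences: mapping
artifacts (multi-mapping in repeats, GC bias, chimeric alignment noise)
are not emulated; the rDNA array and telomeres are masked in all
statistics, exactly as a real analysis masks them for the same reason.
Junction evidence likewise carries no per-base sequencing errors (clips
are exact substrings of the derivative), which is why the partner search
can use a mismatch-tolerant exact-width scan; the mismatch tolerance and
E-value machinery exist so that moderately noisy clips would still
resolve.

Default scales: 16 chromosomes × 125 kb per haplome (2 Mb each, a
yeast-like karyotype shrunk ~6-fold), 80× per-copy depth (within the
73–254× range of the motivating resequencing design), 100 bp coverage
bins, Poisson(200) DSBs per cell of which only the requested events
resolve — the rest religate silently and leave no sequence trace.  These
sizes make a full simulate–detect round trip run in seconds while keeping
every threshold at its realistic value.

## Detection methods and tunable parameters

**Aneuploidy** (`call_aneuploidy`): per chromosome, the median copy ratio
of the two haplotype tracks is averaged; a gain needs ratio ≥ 1.35 and a
loss ≤ 0.65 (midway between euploid 1.0 and the single-copy-change
expectations 1.5/0.5 in a diploid), *and* the median array-CGH log10
ratio beyond ±log10(1.25).  Only dual-platform support yields status
`aneuploidy`; single-platform candidates are `unconfirmed`, and a missing
array can never produce an aneuploidy call.  Medians, not means, are used
throughout so a focal CNV cannot drag a whole chromosome across a
threshold.

**Local CNVs** (`segment_local_cnv`): run-length thresholding of the
combined ratio track with gap merging (1 kb default) and a minimum length
(100 kb default for "large" CNVs, configurable — the smallest event the
motivating data reports is 0.27 Mb, but the floor is a user choice).
Run-length thresholding rather than an HMM/CBS segmenter is deliberate:
the procedure being modeled is threshold-based, and the operation
contract keeps fancier segmenters swappable.

**BIR/SGC** (`call_homolog_events`): zero-coverage candidate tracts
(depth ≤ 0 over ≥ 500 bp, gaps ≤ 200 bp bridged, masked bins neutral)
are lifted to the homolog and pass if the homolog's mean ratio ≥ 1.6
(expected 2.0; 1.6 leaves headroom for noise without admitting euploid
regions).  Passing tracts reaching a chromosome end (telomere mask +
1 kb slack) are BIR; internal tracts are SGC; tracts spanning essentially
the whole chromosome are routed to the aneuploidy/LOH logic; failing
tracts are left to the CNV module (a deletion explains them).

**Junctions** (`call_breakpoints`): windows where soft-clipped reads
exceed 10% of depth become boundary regions; the longest clip is the
consensus; the partner locus is the best scoring (+1/−2) hit across both
haplomes and strands, reported only below the classical E < 1e-4
threshold using a Karlin–Altschul E-value (λ solved at runtime for the
score scheme, K fixed at 0.28 — an order-of-magnitude constant, which is
all an acceptance threshold this far from 1 requires).  Score ties are
broken deterministically and flagged ambiguous.  A junction is
*reciprocal* when it is independently reconstructed from the clip regions
on both of its sides, and *confirmed* when ≥ 2 discordant pairs with
junction-consistent orientation straddle it.  Exact-overlap
(microhomology) is computed symmetrically by extending the flank
comparison left and right of the join.

**Mechanism classification** (`classify_mechanism`) applies rules in
priority order: repeat context (both breakpoints inside same-class
repeats ± 50 bp) → restriction-direct (motif spans the join, both
breakpoints at canonical cut positions, nothing inserted) →
microhomology (2–3 nt overlap, no motif) → unclassified.  Repeat context
is tested first because repeat-mediated events need not preserve any
junction-level signature — and note that a restriction-direct junction
*always* shows a 4 nt "microhomology" (the reconstituted motif itself),
which is why the motif rule must outrank the overlap rule.  rDNA
junctions are reported but flagged non-verifiable, mirroring the fact
that junctions inside a tandem array cannot be independently confirmed
by locus-specific amplification.

**Small-variant post-filters** (`filter_yeast_variants`,
`filter_plant_variants`) implement the published elimination rules as
pure per-record predicates (masked regions; local coverage < 50% of the
sample average; variants shared by all samples; control-shared calls;
frequency > 0.4 strict; InDels with < 2 control reads and a unique
footprint; multi-allelic SNV loci).  "InDel uniqueness" is not precisely
defined in the source procedure; it is operationalized here as *no second
candidate InDel overlapping the record's reference footprint*, and the
filter report records the rule by name.  The AT-rich mask, where no
curated annotation exists, defaults to 100 bp windows with AT fraction
> 0.80 (`at_rich_mask`) — an explicit, overridable choice.

**3D proximity** (`random_pair_null`, `place_pairs`): translocation
partner loci are placed within an empirical null of 10,000 random locus
pairs drawn uniformly per base pair of genome span (chromosome-uniform
sampling is available as a flag) from a chromosome coordinate model
(anchors + linear interpolation, no extrapolation).  The published yeast
coordinate model is an external download; the package therefore ships a
synthetic generator (`simulate_coordinate_model`: per-chromosome confined
random walks inside a 2 µm nucleus) to exercise and test the machinery,
and reads any real model from a five-column TSV.  Converting a published
model into that TSV — including its scaling to micrometres — is the
converter's job and its metadata, not something this package hard-codes.

## Numerical and degenerate-input choices

* Rounding of reported rates/percentages is **half-up** at the printed
  precision; raw ratios are retained as attributes, because published
  tables mix precisions (0.275 vs 0.28 for the same quantity).
* The two-sided F-test p-value is `2 * min(pf, 1 - pf)` capped at 1;
  identical samples give ratio 1, p = 1.
* Zero-depth negative-binomial bins are exact zeros (mu = 0), so the
  zero-coverage cutoff can stay at 0 by default; it is exposed for data
  with background noise.
* Empty inputs return typed empty data.frames rather than NULL; a missing
  platform degrades calls rather than erroring, with a warning.
* All simulator functions take explicit seeds and are byte-reproducible;
  sub-seeds for the observation channels are derived arithmetically from
  the planting seed.

## Known limitations

* Junction orientation is head-to-tail (+/+); inversions are not in the
  event vocabulary and reverse-strand partner hits are reported but not
  assembled into junctions.
* The homolog liftover is anchor-interpolated, exact only up to one InDel
  of ambiguity near gap edges.
* Coverage bins quantize BIR/SGC boundaries to ±1 bin (100 bp default).
* The segment-map coverage oracle cannot represent mapping-induced
  artifacts; conclusions about detector behaviour in long perfect repeats
  or low-complexity sequence do not follow from the simulations here.
* The variance-ratio comparison assumes approximate normality of the
  trait distributions, as any F test does.
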