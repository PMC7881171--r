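---
title: "Quantifying two-cut NHEJ replacement editing with replaceq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-cut NHEJ replacement editing with replaceq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experiment this package models

Replace editing exchanges a genomic segment for a donor sequence without
homology arms: two CRISPR/Cas9 cuts excise the segment, and non-homologous
end joining (NHEJ) ligates a linear donor into the gap. Because NHEJ is
active throughout the cell cycle, this route can modify cells that
homology-directed repair serves poorly. The price is a zoo of alternative
products — the religated deletion, the donor in inverted orientation, the
donor inserted at one cut with the original segment retained — and a
junction mutation spectrum that has to be measured, not assumed.

`replaceq` models the experiment end to end: the design geometry and its
directional (re-cutting) logic, a truth-tagged read simulator, and three
quantification pipelines mirroring how such experiments are read out by
sequencing — long-read amplicon structural-variant binning, single-primer
(UDiTaS/LAM-style) UMI quantification, and donor-anchored integration-site
mapping — plus the closed-form FACS arithmetic used for cell-level
headline numbers.

## Coordinates and cut-site model

All coordinates are 0-based and half-open; cut positions are inter-base,
which makes ligation arithmetic exact string concatenation. SpyCas9's
canonical blunt cut is placed between protospacer positions 17 and 18 —
3 nt from the PAM-proximal end of the protospacer — so a plus-strand guide
starting at `start` cuts at `start + 17` and a minus-strand guide at
`start + 3`. This is the standard SpyCas9 geometry; descriptions that
place the cut "downstream of the PAM" are direction-ambiguous, and we fix
the convention here once. Staggered (non-blunt) cutting is deliberately
*not* part of outcome enumeration: it is a repair-time phenomenon and
lives in the junction mutation model instead.

## Outcome enumeration and the directional design

`enumerate_outcomes()` builds the eight perfect cut-and-ligate products
(original, deletion, replacement and insertion in both orientations). Each
junction records which side of a Cas9 break each ligated end derives from
— PAM-proximal or protospacer-side — together with the guide and its
orientation. These labels are what the rest of the package keys on.

A directional design exploits re-cutting: junctions of undesired products
(deletion, inverted donor) reform an intact protospacer + NGG and are
re-cleaved, recycling those alleles, while correct integration disrupts
every target site. `junction_recleavable()` scans a ±30 nt window around a
junction on both strands; the window size is our choice (a full site is
23 nt, and 30 nt also covers staggered-cut remnants), as no published
value exists. `validate_design()` errors when the designed orientation
remains cleavable (that would destroy the product being selected for),
warns when the deletion junction is *not* cleavable (a guide against the
deletion product should be added), and checks the sacrificial buffers
against the recommended 30 nt minimum that absorbs typical junction
resection. "fwd" always means the orientation the designer declares
desired; the software never infers intent.

`example_design()` produces a reporter-style geometry in which one guide
targets two identical plus-strand sites flanking the exchanged segment and
the donor ends are the reverse-complemented break remnants of that same
guide. This makes the deletion and inverted-donor junctions reform the
full site while the designed orientation disrupts it — and it places a
PAM/PAM ligation at the downstream replacement junction, the configuration
where templated insertions arise.

## The junction mutation model

`outcome_mixture()` holds the population model: weights over the eight
outcome classes and a per-junction mutation spectrum with three branches.

* **Perfect ligation** with probability `p_perfect_junction` (default
  0.79, a typical measured InDel-free rate for this kind of editing).
* **Templated staggered-cut insertion** (`p_stagger1` = 0.10,
  `p_stagger2` = 0.03 by default). Cas9 sometimes cuts the non-target
  strand 1–2 nt PAM-distal of the canonical position; fill-in of the
  resulting 5' overhang duplicates protospacer position 17 (or 16–17) onto
  the PAM-proximal fragment. When two filled PAM ends ligate, those bases
  appear as a +1/+2 insertion that matches the protospacer just beyond the
  cut — never a random base. Insertions are therefore only realized at
  junctions whose *both* sides are PAM-proximal; at any other junction the
  drawn insertion mass falls through to the resection branch, which keeps
  the InDel-free fraction of every junction equal to
  `p_perfect_junction` regardless of its side labels. Where the two PAM
  ends come from different guides, the left (upstream) end's guide
  templates the fill-in — a deterministic convention, since the data this
  emulates cannot distinguish the two.
* **Resection** otherwise: a geometric small deletion with support
  starting at 1 (a junction chosen for deletion loses at least one base;
  mean `1/del_geom_p`, default p = 0.3), plus — with probability
  `p_large_resection` = 0.02 — an exponential large-deletion component
  (mean `large_resection_scale` = 300 nt) applied to one uniformly chosen
  side of the junction, reproducing the observed *asymmetry* of large
  resections. No published size distribution exists for these events; the
  geometric + exponential mixture was chosen once to reproduce the
  qualitative shape (majority < 30 bp, rare large one-sided) and is not a
  fitted quantity.

Default class weights (16% unedited, 26% deletion, 39% designed-orientation
replacement with a 5:1 orientation ratio, remainder insertions) reflect
single-primer quantification of a typical endogenous exon replacement.

## What the simulator emulates — and what it does not

`simulate_longread()` emits full two-primer amplicons; sampling weights
can be tilted by `exp(-alpha * length)` to emulate the PCR bias that
over-represents short amplicons in two-primer libraries (off by default;
this is exactly why the long-read pipeline is not treated as quantitative).
Molecules whose resection erodes a primer footprint could not have been
amplified and are redrawn (counted in `n_resampled`). `simulate_linamp()`
emits single-primer reads that start at the anchor and extend a
tagmentation-determined random distance; every read carries a UMI, and
molecule-level sampling (`n_molecules`, `mean_reads_per_molecule`) is
available for UMI-deduplication studies. Donor-anchored mode plants
on-target, off-target and concatemer (head-to-tail or head-to-head)
continuation events at configurable rates; the 34% concatemer default is
a realistic measured rate for exogenous dsDNA donors.

Deliberately absent: instrument error models (qualities are constant
placeholders; an optional uniform substitution rate exists for robustness
testing only), chimeric PCR artifacts other than concatemers, and
translocations/chromosomal fusions. Reads are consensus-grade by
construction, so passing tests demonstrate the *logic* of the pipelines —
classification, junction attribution, UMI collapse, mapping — not
robustness to raw-read noise.

`simulate_genome()` builds random chromosomes (defaults: 5 × 1 Mb),
scatters predicted Cas9 off-target sites (default 293, a realistic
genome-wide prediction count), embeds the design's locus, and plants donor
integration loci (default 28) kept ≥ 5100 bp from every predicted site —
just beyond the conventional 5000 bp proximity screen, so the expected
result of the proximity analysis on simulated data is a null.

## The three pipelines

**Long-read structural variants.** Reads (and their reverse complements)
are aligned to all eight expected amplicons with affine-gap scoring
(match +2, mismatch −4, gap open 6, gap extend 1); the best reference
assigns class and orientation. A best-vs-runner-up margin below 10 score
units yields `unclassified` rather than an arbitrary call — ties are real
in this problem (e.g. reads ending inside a shared donor segment).
Junction InDels are attributed within ±20 nt of each expected junction;
an InDel overlapping the window at all is attributed to it. Deletions
above 500 bp set the `large_deletion` flag. Per-base deletion profiles
divide deletion coverage by total coverage, with uncovered positions
reported `NA` rather than 0. Long-read calls are read-level: this
protocol carries no UMIs, so PCR duplicates are not collapsed — the same
caveat that makes the long-read pipeline qualitative.

**Single-primer quantification.** Expected references are rebuilt from
the anchor primer through each outcome and clipped 300 nt past the last
junction (bounding alignment cost while exceeding read length). Reads
must begin with the anchor (≤ 2 substitutions); InDel calls require the
read to span the junction by ≥ 10 nt on both sides — a package choice, as
no published minimum exists — and reads that fall short still count for
their class. Molecules are distinct UMIs; a UMI observed with conflicting
classes resolves by strict majority and is discarded on a tie. UMI
matching is exact: synthetic UMIs are error-free, and a Hamming-1 merge
is out of scope for the defaults.

**Integration mapping.** Donor-anchored reads are checked for correct
priming, trimmed to the expected break by aligning the donor terminal
segment (≤ 10% error), and the residual flank is classified. The
donor-self-match (concatemer) test runs *before* genome mapping, because
donor-derived flanks would otherwise multi-map to the vector record.
Genome mapping is exact-seed (k = 15) plus affine extension; the contract
— best-scoring unique hit wins, score ties at distinct loci are
`unmapped/multi` — is what matters, not the indexing strategy. Flanks
mapping within 1000 nt of either cut are on-target (generous, to absorb
resection ahead of the junction). Sites are clustered within 100 nt and
annotated with the distance to the nearest predicted off-target site
(5000 bp proximity threshold, boundary-inclusive). Where concatemers
belong in the denominator is genuinely ambiguous in this field's reports;
the call table keeps all categories so either denominator can be formed.

## FACS arithmetic

With independent editing across alleles, an observed positive-cell
fraction $f$ at ploidy $n$ implies per-allele probability
$p = 1-(1-f)^{1/n}$ and a ploidy-$m$ equivalent $1-(1-p)^m$
(`ploidy_convert()`; monotone, identity at $n = m$, exact round-trip).
For dual-donor experiments in a diploid with equal independent donor
choice, dual-positive cells are homozygous knock-ins with discordant
donors — half of all homozygous knock-ins — so $h = 2 f_{double}$
(`homozygous_fraction()`; the assumptions are stated in the return value
because the formula is a reconstruction, not a published derivation).
`combined_replacement()` multiplies a FACS-positive fraction by the
genotyped correct-given-positive fraction. Integer percents round half
away from zero; raw fractions are always retained, and recomputing a
published headline from *rounded printed inputs* can legitimately land one
point off the published figure.

## Numerical choices and degenerate inputs

* Alignment tie-breaking is delegated to the (deterministic) affine DP;
  classification ambiguity is handled by the score margin, not by
  tie-break luck.
* Resection is clamped so it cannot run through a neighbouring junction
  or off the molecule; this truncates the exponential tail at toy scale
  and is irrelevant at the decay lengths the profiles measure.
* Degenerate toy inputs (cuts < 40 nt apart, donors < 50 nt) warn rather
  than error so that small test designs remain usable.
* One integer seed drives every stochastic operation through a local RNG
  scope that restores global state; simulators document their consumption
  order implicitly by being byte-reproducible from the seed.

## Problem sizes used by the test suite

The shipped tests run on compact fixtures chosen as the package's own
desk-scale defaults: a ~730 nt locus with a ~140 nt donor (amplicons
~560–750 nt), 5000-read mixture-recovery runs, a 4 × 100 kb genome with
40 predicted sites and 28 planted integration loci for the mapping
pipeline, and $10^5$ simulated cells for the homozygosity parameter
recovery. Statistical checks compare estimates to simulation truth at
3 binomial standard errors. The generator *defaults* (1 Mb chromosomes,
293 predicted sites, the mixture above) remain at realistic scale; the
fixtures only shrink the sequence lengths, not the models.

## Known limitations

* Classification is reference-complete: products outside the eight
  enumerated structures (translocations, complex rearrangements) are not
  called — they surface as `unclassified`, which is the honest output for
  a two-cut model. Fusion calling is explicitly out of scope.
* Junction InDel counting in the long-read pipeline is per read, not per
  molecule; without UMIs the two cannot be distinguished.
* Replacement and same-orientation insertion products are
  indistinguishable to single-primer reads that end inside the donor;
  such reads are `unclassified` by the margin rule, and the simulator's
  default read length is chosen to make them rare rather than impossible.
* The homozygosity estimator assumes exactly two alleles and symmetric
  donor uptake.

## A worked design check

```{r, eval = FALSE}
library(replaceq)
design <- example_design(seed = 1)
validate_design(design)
outcomes <- enumerate_outcomes(design)
vapply(outcomes, function(a) nchar(a$sequence), numeric(1))
```

See the README for the full simulate → classify → quantify walk-through
with the numbers it prints.
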