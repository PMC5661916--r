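---
title: "Methods: small RNA analysis of plant cold response without replicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA analysis of plant cold response without replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldsmRNA)
```

## The experimental design this package models

`coldsmRNA` targets the classic plant small-RNA survey design: deep
sequencing of 18–30 nt RNAs from a small number of single (unreplicated)
libraries — here two cultivars sampled before and after a short cold
treatment, giving libraries `F0`, `F3`, `R0`, `R3`. The design has three
statistical consequences that shape the whole pipeline:

* every inference rests on *tag counts* (unique sequences with per-library
  read counts), not on replicate variance;
* differential expression must use a replicate-free count model;
* miRNA identity must come from sequence-intrinsic evidence (precursor
  matching, hairpin structure), not expression patterns.

## Read cleaning

Cleaning applies filters in a fixed order so each removed read is
attributed to exactly one cause: low quality → 5′-adapter contamination →
missing 3′ adapter → adapter trimming → empty insert → poly-A insert →
length out of [18, 30] nt. The order matters only for attribution (the
surviving set is order-independent), but attribution is what per-library
accounting tables report, so it is pinned down and tested. Definitions
that the underlying protocol leaves open are parameterized with defaults
chosen from common Illumina small-RNA practice:

* *low quality*: any `N`, or more than 1 base below Q20
  (`quality_threshold`, `max_low_quality_bases`);
* *poly-A insert*: ≥ 80 % A or an A-run ≥ 10 nt (`polya_frac`,
  `polya_run`);
* *5′ contaminant*: the 5′ adapter anywhere in the read with ≤ 1 mismatch;
* *3′ adapter located* by the exact leftmost match of its first 8 nt.

Cleaning an already-clean tag set is a no-op (idempotence), and
`raw = clean + Σ removals` holds by construction and is asserted in tests.

## Sequence matching and the alphabet policy

All sequences are stored in the DNA alphabet; U is rewritten to T on
ingestion and sequences are converted to RNA only at the folding boundary.
One canonical alphabet removes any chance of a U/T mismatch between tag
sets and references. Tag-to-reference matching is exact substring search on
both strands (mismatch allowance configurable, default 0): at 18–30 nt
query length, permissive local-alignment statistics effectively demand
near-exact matches anyway, and exact matching is deterministic and fast.
Category conflicts are resolved by a fixed precedence (rRNA > scRNA >
snoRNA > snRNA > srpRNA > tRNA > repeat), reflecting the
annotate-and-remove-before-miRNA-matching convention.

## Known miRNAs

A tag is a known miRNA when (1) it matches a known precursor with zero
mismatches and (2) its interval on the precursor overlaps the annotated
mature interval by at least 16 nt. Computing the overlap on precursor
coordinates makes "offsets allowed" precise, and the boundary is sharp:
overlap 16 passes, 15 fails (tested). Tags matching several references
contribute their full count to each by default; fractional 1/k splitting
is available (`multi = "fraction"`). Identical matures under different ids
are reported per id, not merged, matching how published tables list them.
No extra cap is imposed on the offset beyond the overlap rule itself.

## Novel miRNA prediction

Unannotated tags of 18–25 nt are mapped to the reference; tags with more
than 20 exact loci are discarded as repetitive. At each locus two precursor
hypotheses are excised — tag on the 5′ arm or the 3′ arm — extending
`max_space + tag length + flank` (300 + L + 20 nt) inward and 20 nt
outward, truncated at reference edges. Both arms are always tested since
the mapped arm is not known a priori. Windows are folded (ViennaRNA
`RNAfold` by default; the engine is a plug-in function so any
sequence → (dot-bracket, MFE) implementation can be substituted), and a
candidate is accepted iff all five criteria hold:

| criterion | default | unit |
|---|---|---|
| precursor MFE | ≤ −18 | kcal/mol |
| miRNA/miRNA* pairs | ≥ 16 | bp |
| largest bulge | ≤ 4 | nt |
| duplex asymmetry | ≤ 4 | nt |
| miRNA–miRNA* space | ≤ 300 | nt |

The miRNA* is the set of pairing partners of the mature extended by the
canonical 2-nt 3′ overhang (Dicer product geometry). The duplex span on
each strand runs between its outermost paired bases; a bulge is the
longest unpaired run within a span, asymmetry the absolute difference of
unpaired counts between the strands, and space the unpaired distance
between the pairing-defined inner ends of mature and star. Acceptance is
conjunctive over fixed metrics, so relaxing any threshold can only grow
the accepted set (a tested monotonicity property), and both thresholds
with worked boundary cases (−18.0 vs −17.5 kcal/mol; 16 vs 15 pairs) are
tested as inclusive.

Per tag, one best candidate is kept: lowest MFE, ties broken by shorter
precursor, then leftmost locus — a deterministic ordering so identical
inputs yield identical calls.

The parameter pair `min_ref_len`/`max_ref_len` (20/23) is retained from
the conventional parameter block but is ambiguous in its original context
(mature length vs. window length). It is interpreted here as the mature
length range for reported annotation only, not as a tag-eligibility
filter; tag eligibility uses `min_mirna_len`/`max_mirna_len` (18/25). The
interpretation is configurable.

## Normalization and differential expression

Expression is normalized as RPM = count / clean reads × 10⁶ and reported
to 2 decimals. Values used in ratios are floored at 0.01 — the floor is
inferred from how published tables print 0.01 for absent miRNAs and print
fold changes consistent with ratios against 0.01 (e.g. 3.71/0.01 →
log₂ = 8.54). The fold change is log₂(treatment/control), antisymmetric
by construction, and never infinite or NaN thanks to the floor.

No replicate-free test is named by the protocols this pipeline follows, so
the package adopts the Audic–Claverie test, the de-facto standard for
digital expression without replicates: conditional on observing count *x*
in a library of *n₁* clean reads, the count *y* in a library of *n₂* reads
follows p(y|x) = (n₂/n₁)^y (x+y)! / (x! y! (1+n₂/n₁)^{x+y+1}), which is the
negative binomial with size x+1 and success probability n₁/(n₁+n₂) — the
implementation uses that identity via the stable distribution function,
and the test suite checks it against direct summation of the tail. The
reported p-value is two-sided (twice the smaller tail, capped at 1); two
zero counts give p = 1 by convention. Significance requires |log₂FC| ≥ 1
and p ≤ 0.05, both inclusive; no multiple-testing correction is applied
across miRNAs, matching the pipeline generation this reproduces.

A table-reproduction mode (`reproduce_tables()`) recomputes fold changes
from printed 2-decimal RPM values rather than from unrounded internal
values, and flags rows whose printed fold change disagrees at 2 decimals.
On the shipped worked-example tables this flags two sign anomalies
(expression rises but the printed fold change is negative), three rows
whose printed value is far from any ratio of the printed RPMs, and a set
of last-digit (±0.01–0.02) offsets expected when printed values were
derived from unrounded counts. Flagged rows are reported, never repaired.

## Targets and enrichment

Target sites are scored with the classic plant complementarity scheme:
mismatch 1.0, G:U wobble 0.5, gap 2.0, all doubled at miRNA positions 2–13
(seed and cleavage core), no gap at positions 10–11, acceptance at total
penalty ≤ 4.0. The scanner evaluates ungapped alignments and all
single-nucleotide bulges on either strand — with a gap worth ≥ 2.0 against
a budget of 4.0, wider gaps cannot participate in an accepted site, so the
single-bulge enumeration is exhaustive at the default threshold. All
qualifying sites are reported (the best variant per site start); a
brute-force rescorer in the test suite verifies the scan on planted sites.

Enrichment follows the printed hypergeometric formula
P(X ≥ m) = 1 − Σᵢ₌₀^{m−1} C(M,i)C(N−M,n−i)/C(N,n) with N the annotated
background, n the candidates within it, M the term's genes and m the
candidate genes in the term, evaluated through the stable hypergeometric
distribution function (agreement with direct summation is exhaustively
tested for all N ≤ 30). GO mode corrects by Bonferroni, KEGG mode by
Benjamini–Hochberg FDR, both at 0.05 on the corrected value. The term set
tested (and hence the Bonferroni multiplier) is the set of terms annotated
to at least one candidate; candidates absent from the background are
dropped with a warning. Genes are used as flat annotation units — no GO
graph propagation. Whether candidates are pooled across comparisons or
kept per comparison is a caller decision; the pipeline pools by default.

## qPCR quantification

`ddct()` implements 2^−ΔΔCt with amplification efficiency fixed at 2 (the
method's assumption; no standard-curve correction). Technical replicates
are averaged before ΔCt. The standard error of ΔCt combines the replicate
standard deviations of the target and reference wells; the ΔΔCt error adds
the calibrator's ΔCt error in quadrature, and the expression error is
ln 2 · 2^−ΔΔCt · SE(ΔΔCt). The calibrator is exactly 1 with SE 0 by
construction. Expressions are invariant to any constant shift of all Ct
values (tested).

## The synthetic-data generator

The generator emulates the study design — four libraries (two cultivars ×
two timepoints), ~9 % known-miRNA reads, rRNA/tRNA-dominated contaminants
at a few percent, ~1 % of raw reads removed as artifacts, a length
distribution peaking at 24 then 21 nt, and prescribed log₂ fold changes on
a subset of miRNAs — at a default depth of 10⁶ reads per library.
Proportions, not absolute counts, carry the signal, so desk-scale depths
preserve the study's structure.

Design choices worth knowing:

* **Unpairable background.** The genome background is drawn over {A, C}
  only (C-rich). A/C sequence cannot base-pair with itself, so excised
  windows fold to the planted hairpin alone; deliberately unpaired duplex
  positions in bulge/asymmetry constructs are likewise A/C. This makes
  pass/fail labels exact rather than probabilistic.
* **Verified planting.** Every hairpin is built to satisfy (or violate
  exactly one of) the five criteria, then verified by running the
  package's own excision, folding and duplex code — first in isolation,
  then on the assembled genome via `call_novel()` itself. Constructs whose
  label does not hold under the real engine are redrawn (bounded
  rejection sampling), so ground truth is guaranteed under the actual
  thermodynamic engine, not just by intent.
* **Exact fold changes.** Treated libraries scale perturbed miRNAs by
  2^lfc and the unannotated background absorbs the mass shift, so planted
  proportions realize the intended fold change exactly (no
  renormalization bias); multinomial sampling adds only binomial noise
  (≈ ±0.05 in log₂ units at 10⁶ depth for the planted miRNAs).
* **Exact artifact bookkeeping.** Planted artifact reads (adapter dimers,
  poly-A, short fragments, low-quality, 5′ contaminants) are counted
  deterministically, so the cleaning stage's per-filter statistics can be
  compared for equality, not approximately.

What the generator does **not** emulate: sequencing errors beyond clean
reads, quality-score realism, isomiR ladders around matures, genomic
repeat structure, GC-content biases, or cross-hybridizing miRNA families.
Passing recovery tests therefore demonstrates the correctness of the
pipeline's logic under its stated assumptions, not robustness to every
artifact of real libraries.

## Problem sizes and determinism

The shipped tests run the generator at 2×10⁴ reads/library for the
end-to-end FASTQ path and 10⁶ for count-level DE recovery (20 seeded
simulations); hairpin recovery uses 20 passing and 10 single-criterion-
failing plants; the hypergeometric check enumerates every configuration
with N ≤ 30. These sizes were chosen so the whole suite completes in a
few minutes on one core while keeping multinomial noise far from every
tested margin. All stochastic steps are seeded; identical seeds give
byte-identical generator output and identical pipeline results, which the
suite asserts via output hashing.

## Known limitations

* Exact matching (default 0 mismatches) will miss known miRNAs with SNPs
  or sequencing errors; raise `classify_max_mismatch` at your own risk of
  category bleed-through.
* The replicate-free test measures sampling, not biological, variance;
  with n = 1 per condition its p-values overstate certainty, which is
  intrinsic to the design being reproduced.
* Target prediction is complementarity-only; no degradome or expression
  anti-correlation evidence is used.
* Hairpin calling reports one best precursor per tag; paralogous loci are
  visible through `map_tags()` but not annotated as families.
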