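---
title: "Methods: simulating and recovering a pseudoautosomal boundary shift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and recovering a pseudoautosomal boundary shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parshift)
```

## The rearrangement being modelled

The X and Y chromosomes recombine only in the pseudoautosomal regions; the
boundary of PAR1 (the PAB) separates shared from sex-specific sequence.
parshift models a PAR1 length polymorphism created by non-allelic
homologous recombination (NAHR) between two short paralogous LTR repeats:
repeat **A** sits inside PAR1 about 5 kb distal of the PAB, repeat **B** in
X-specific sequence about 110 kb proximal of it. Misalignment of B (on an
X) with A (on a Y) during male meiosis, followed by a crossover inside the
repeat homology, produces two reciprocal products:

```
derY = donorX[0 .. B_start + delta) + Y[A_start + delta .. y_length)
delX = Y[0 .. A_start + delta)      + donorX[B_start + delta .. x_length)
```

`derY` gains the *duplicon* — the X-specific segment between the repeats
plus the proximal PAR1 segment — extending its PAR1 while leaving the
original Y PAB junction intact; `delX` loses the same span. Total sequence
length is conserved, which the tests verify for every crossover offset.

A male carrying `derY` plus a normal X holds the proximal PAR1 segment in
three copies and the X-specific duplicon in two. A heterozygous SNP on one
of `c` copies is read at frequency `m/c`, so sequencing shows three
stretches of heterozygous frequencies — 50% (distal PAR1, 1 of 2), 33%
(proximal PAR1, 1 of 3), 50% (duplicon, 1 of 2) — and no heterozygous
calls in the remaining hemizygous X-specific sequence. Recovering that
banding, the breakpoint between bands, the identity of the fusion repeat,
and the age of the carrier cluster is the package's whole inference chain.

## The synthetic genome and its deliberate simplifications

`build_reference()` realizes a toy X/Y pair. The default geometry keeps
the studied locus' coordinates unscaled — repeat A at 2,694,151, repeat B
at 2,808,549, each 548 bp with 15 diagnostic paralogous sequence variants
(PSVs) — and places the PAB at 2,699,500. The true PAB coordinate is not
part of the model's inputs; 2,699,500 is an analog chosen so the "5 kb
proximal PAR1 / 110 kb X-specific" structure holds, and nothing downstream
depends on its exact value. The Y is PAR1 plus a 1 Mb Y-specific tail (a
Y shorter than PAR1 would be geometrically impossible).

What the generator emulates, and what it does not:

* **Repeat pair.** Both repeats share a random consensus and differ at
  exactly `n_psv` substitution offsets (plus two registered "extra
  variant" offsets, below). PSV offsets keep a minimum spacing of 21 bp so
  that every 10 bp anchor window used by the typing module is invariant
  sequence. Real LTR6B elements additionally differ by a single indel;
  indel alignment inside a 548 bp repeat is anchor-fragile, so the indel
  is modelled as one of the extra-variant flags rather than a 16th PSV.
* **SNPs.** Catalogued at `snp_density` (default 3×10⁻³/bp, the density of
  a diversity-rich pseudoautosomal segment; PAR1 diversity is elevated
  relative to the genome average) with alleles on three haplotype columns:
  the carrier's own X, the donor X that enters the NAHR event, and the Y
  (PAR1 only). Alleles are drawn polymorphic among co-occurring copies, so
  catalogued sites are *heterozygous-capable*, not guaranteed het — e.g.
  only two thirds of distal-PAR1 sites are het in a male, as the two
  retained columns may agree. SNPs falling inside the repeats are
  catalogued (their read counts matter for the MQ0 diagnostics) but not
  embedded in the repeat sequences, which keeps the repeats usable as
  amplicon typing references.
* **Background.** Uniform random sequence at a set GC fraction, uppercase
  ACGT with no N runs (simplifies the k-mer oracles). No telomeres, PAR2,
  centromere, or repeat families beyond the two paralogs.

The crossover offset `delta` defaults to half the repeat (274). The split
is half-open: fusion offsets `< delta` come from the donor (X) side,
`>= delta` from the acceptor (PAR) side. A PSV lying exactly at `delta`
therefore belongs to the acceptor side — the emitted sequence and the
truth origin vector must agree, and the base at `delta` physically comes
from the acceptor repeat. Gene conversion (`apply_gene_conversion()`)
rewrites a half-open tract of the fusion repeat back to the X state,
modelling the transition from the recombinant junction (Junc1) to the
fully X-specific one (Junc2).

All randomness flows from one root seed fanned out per component by fixed
labels (`component_seed()`), so each module is independently reproducible.

## Read counts

The inference consumes per-position variant frequencies, so
`simulate_site_table()` works at site level rather than emulating reads:
raw depth is Poisson with mean `mean_depth · c/2`; reads are thinned by
mapping-quality, pairing and base-quality failures; surviving reads
support the alt allele with probability `f(1−ε) + (1−f)ε`, a symmetric
single-parameter error model (only the location of the frequency bands
matters downstream). Sites inside the repeat homology lose 99.5% of reads
to the mapping-quality filter by default — two-copy repeats map ambiguously,
so in real data more than 99% of reads there carry mapping quality 0. This
masking is what forces the breakpoint to be delineated from the flanking
informative sites. Chimeric read pairs and split reads, which the repeat
flanks would also suppress in real data, are not modelled at all.

## Profiling and segmentation

`filter_and_frequency()` computes `f = n_alt / (n_ref + n_alt)` from
passing reads only; sites under 100× effective depth yield no call (never
a division error). A call is heterozygous when `0.25 ≤ f ≤ 0.75`
(inclusive bounds) at callable depth. Heterozygous sites store the folded
frequency `min(f, 1−f)`: with three copies and unknown phase, `(1,3)` and
`(2,3)` states are indistinguishable from frequencies alone, and folding
collapses them onto the single 33% band — which is also why the band means
are the folded set {1/2, 1/3}.

Segmentation assigns each het site to the band maximizing its binomial
likelihood, subject to every segment containing at least `min_run = 3`
sites (a guard against single-site noise; the value is a package default,
not an empirical constant). Rather than greedy per-site assignment with
post-hoc merging of short runs, the implementation solves the constrained
assignment exactly by dynamic programming (O(n · bands) with a running
maximum), so the result provably maximizes the joint log-likelihood — the
test suite checks it against exhaustive enumeration on small profiles.
Profiles with fewer than `min_run` sites are returned as a single segment
flagged low-confidence. Classification is by likelihood against band
means, not by matching an exact frequency: observed band means wobble
(a 33% band can average 30% or 35% at realistic depths) and the likelihood
rule absorbs that.

Breakpoints are the open intervals between boundary-adjacent evidence
sites: the last site of the distal segment and the first site of the
proximal one, with no sub-site interpolation. With the repeat interior
masked by MQ0, the first interval (50%→33%) spans repeat A and contains
the true crossover; the second (33%→50%) tightly brackets the PAB — it
cannot overlap a repeat, because the copy-count transition there is the
PAB itself, ~5 kb from either repeat. `annotate_with_repeats()` reports
overlapping repeat annotations and raises `mq0_flag` when more than 99% of
raw reads at interval-interior sites are MQ-failures.

Copy models are compared on pooled folded binomial likelihoods over a
segment's sites, default candidates (m,c) ∈ {(1,2), (1,3)}; calls with a
log-likelihood margin under 2 are flagged ambiguous (≈ a likelihood ratio
of e², roughly "positive" evidence; at depth 300 × 3 sites the margin
between 1/2 and 1/3 exceeds this comfortably unless the data sit near the
midpoint).

## Junction typing

`extract_states()` locates each PSV in an amplicon by exact match of its
two 10 bp flanking anchors (taken from the repeat consensus), reads the
base between them, and assigns X / PAR / other / missing; orientation is
normalized by scanning both strands and keeping the one that locates more
PSVs; fewer than 50% located positions is an alignment failure.
Classification then follows the origin-block structure (missing positions
ignored for switch counting, as a real amplicon's unsequenced first
position must not break a block):

* all X in a junction-spanning amplicon → **JUNC2**; the identical
  sequence at a reference locus → X_REF. The two are sequence-identical
  by construction and distinguishable only by where the molecule sits, so
  the disambiguation is a context flag on the profile, and a crossover at
  `delta = repeat_length` (all PSVs donor-side) also types as JUNC2 in a
  junction context.
* all PAR → PAR_REF.
* one distal-X → proximal-PAR switch → **JUNC1**, promoted to **JUNC1C**
  when the rs211656-analog extra variant is present. The rs2316283-analog
  is recorded as an annotation but does not gate the class: its
  association with Junc1 is an observation about carriers, not a defining
  feature of the junction type.
* anything else — two or more switches, or the reciprocal-deletion
  pattern of a single PAR→X switch — → **MERGED_COMPLEX**, the
  deletion-merged class.

## Y-STR cluster age

Haplotype relatedness is summarized as the number of differing loci
(`pairwise_diff_matrix()`, missing loci excluded pairwise). For the age
model the package deliberately uses the infinite-alleles style
approximation: locus *i* differs after `t` generations per lineage with
probability `p_i(t) = 1 − exp(−μ_i t)` (two lineages: `2t`), any mutation
making the locus differ. The data are counts of *differing loci*, not step
distances, so a full stepwise likelihood would add little; the
stepwise-mutation simulator (`simulate_str_cluster()`, Poisson mutation
counts, ±1 steps) quantifies the approximation error — homoplasy (a locus
returning to its founder state) is below ~10% of differing-locus
probability at the `μt ≤ 0.2` scales of interest, and the credible
interval's empirical coverage at a known cluster age of 20 generations is
near-nominal in the acceptance checks.

The cluster model assumes a star genealogy from a founder reconstructed as
the locus-wise modal haplotype (ties broken by the median; an all-distinct
panel falls back to the median with a warning): each sampled lineage is an
independent descent of `t` generations. The true genealogy of a real
cluster is of course not a star; correlated branches share mutations and
the interval is anti-conservative to a degree that grows with genealogy
imbalance. The prior is flat on a grid `t = 0, 1, …, 500` generations —
no informative prior presents itself, and the posterior is insensitive to
`t_max` once the likelihood has decayed (a warning fires when mass abuts
`t_max`). Equal-tailed 95% credible intervals are read off cumulative grid
sums with outward integer rounding; on a uniform grid posterior over
0..100 this yields (2, 98), the atoms at which the cumulative mass first
reaches 2.5% and 97.5%. Calendar conversion maps a generation interval
through `year = ref_year − t · span`, with spans of 25 and 35 years per
generation bracketing the plausible historical range.

The shipped per-locus mutation-rate table
(`inst/extdata/ystr_rates_default.tsv`) is synthetic: 26 single-copy loci
with rates at representative published magnitudes (10⁻⁴–10⁻²). It exists
so simulations run out of the box and is labelled non-authoritative;
analyses of real panels must supply measured rates.

## Numerical and design notes

* Coordinates are 0-based half-open internally; printed-style ranges
  `"chr:a-b"` parse with length `b − a`, which reproduces the 551 bp and
  548 bp repeat lengths from their printed coordinate pairs.
* Likelihoods are computed in log space with max-subtraction before
  normalization; `log(0)` at `t = 0` grid points is floored at `1e-300`.
* Degenerate inputs: zero-depth sites are no-calls; an empty het profile
  returns zero segments; a single segment yields no breakpoint; an
  all-missing origin vector yields zero blocks and AMBIGUOUS; a
  conversion tract of zero width is the identity.
* Filters are order-independent by construction — the simulator emits
  already-categorized counts, and the profiler only ever sums the passing
  categories.
* Determinism: identical run configurations produce byte-identical report
  JSON; every output carries the configuration hash. Site tables read
  back from disk are not re-verified against a hash of the producing
  configuration (the hash is carried, not enforced).

## Problem sizes

Simulation studies use a scaled geometry — a 450 kb X with the PAB at
300 kb and the same local structure (repeat A 5,349 bp distal of the PAB,
repeat B 99,549 bp proximal) — which preserves every distance that matters
to the inference while keeping a single replicate under a quarter of a
second. The package's standing checks run 200 breakpoint-recovery
replicates (observed recovery ≥ 95%) and 100 TMRCA-coverage replicates at
depth-300 sequencing, 20 lineages and 26 loci; sequence-level invariants
(k-mer presence/absence, FASTA/BED round trips) run on a 70 kb toy genome,
and the full-coordinate (3 Mb) genome is realized where the printed
coordinates themselves are the input, as in the duplicon-size check.

## What passing tests do and do not show

The simulations demonstrate that the inference chain is *internally
consistent*: the implemented caller recovers the structure the implemented
generator planted, at the depths and densities configured. They do not
demonstrate robustness to alignment artifacts other than the summarized
failure categories, to non-uniform SNP ascertainment, to reference bias,
or to repeat families more complex than one paralogous pair — real data
carry all of these. The TMRCA coverage result likewise certifies the
estimator under its own star-genealogy assumption, not under arbitrary
real genealogies.
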