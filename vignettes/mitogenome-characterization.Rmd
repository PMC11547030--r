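---
title: "Characterizing an annotated mitochondrial genome: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing an annotated mitochondrial genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocodon)
```

`mitocodon` reproduces the standard descriptive analysis of an annotated
insect mitochondrial genome: gene organization, nucleotide composition and
strand skew, codon-usage bias, Ka/Ks and nucleotide diversity, and repeat
content. This vignette explains the models and the conventions behind each
module, the parameters that matter, what the synthetic-data generators do and
do not emulate, and the design choices we made where the field's tools
disagree or are underspecified.

## Coordinates and gene organization

All public interfaces use 1-based inclusive coordinates, the convention of
GenBank feature tables and of published annotation tables; half-open
coordinates appear nowhere. A circular genome is explicit
(`topology = "circular"`), and a feature whose `end` precedes its `start`
wraps the origin; its length is `genome_length - start + 1 + end`.

Adjacency arithmetic uses one convention throughout:

```
gap(i -> i+1) = start(i+1) - end(i) - 1
```

A positive gap is an intergenic spacer of that many bp, a negative gap an
overlap of `|gap|` bp, and zero means abutting features, counted in neither
class. On circular genomes the pair (last feature -> first feature) is
evaluated across the origin. Non-coding regions (the control region and the
aphid repeat region) are first-class features and participate in adjacency
like genes. Applied to the shipped *R. nymphaeae* annotation
(`waterlily_aphid_genome()`), this convention reproduces every printed
intergenic value of the published table, including the 52 bp NAD5/tRNA-His
spacer, the 20 bp ATP8/ATP6 overlap and the 1 bp origin-crossing gap:

```{r}
intergenic_profile(waterlily_aphid_genome())
```

The report prints two protein-coding size sums because they genuinely differ:
the raw sum of the printed sizes (10,952 bp, implying 3,639 codons after
dropping stop codons and the incomplete terminal T of COX1 and NAD4), and the
published text figures (10,943 bp / 3,636 amino acids). The 9 bp discrepancy
is internal to the source annotation and cannot be resolved from coordinates
alone, so we report both rather than guess.

## Composition and skew

`AT skew = (A - T)/(A + T)` and `GC skew = (G - C)/(G + C)`, signed. Skews
are computed from counts, never from pre-rounded percentages — except that
`skews()` deliberately accepts percentages too (the ratio is scale-free), so
published composition tables can be replayed directly. Replaying the
*R. nymphaeae* full-length row gives +0.0666 and −0.2618; published aphid
tables sometimes print skew magnitudes unsigned, so we treat the signed
formula as authoritative. `N` bases are excluded from denominators.

Regions containing minus-strand features have two defensible readings:
each feature 5'→3' on its own strand (its coding sequence), or the
plus-strand slice of the same span. `region_profiles()` emits both, labelled
`(annotated)` and `(plus)`, because published per-region tables rarely state
which was used; the two differ only by skew sign symmetry
(`at_skew(s) == -at_skew(revcomp(s))`).

## Codon usage

The genetic code defaults to NCBI translation table 5 (invertebrate
mitochondrial: ATA=Met, TGA=Trp, AGA/AGG=Ser). Synonymous families split
codons that share an amino acid but not their first two bases — Leu1 (CTN)
vs Leu2 (TTR), Ser1 (AGN) vs Ser2 (TCN) — matching how mitogenome RSCU
figures label them. Under this convention table 5 has 13 twofold and 9
fourfold families (62 sense codons), and GC3s coincides with GC3 because no
codon is outside a family of size ≥ 2 (both are still computed and labelled
separately, since they differ under other codes).

Stop codons, and the incomplete terminal T/TA completed by polyadenylation,
never enter codon-usage statistics.

**ENc.** Wright's estimator: per family with `n ≥ 2` observed codons, the
homozygosity is `F̂ = (n Σ p̂ᵢ² − 1)/(n − 1)`; `F̂` values are averaged within
each degeneracy class, and `ENc = Σ N_class / F̄_class` (22 at maximal bias,
62 at uniform usage under the split table-5 convention). Families with
`n < 2` or `F̂ = 0` are excluded from their class mean. If an entire class
has no estimable family we impute the mean homozygosity of the available
classes and warn: the classical fallback (interpolating a missing 3-fold
class from the 2- and 4-fold classes) has no analog when only two classes
exist. Values above the nominal 61 are reported raw and flagged, not clamped.
The ENc-plot expectation under mutation alone is
`ENc_exp = 2 + s + 29/(s² + (1 − s)²)` with `s` = GC3s as a fraction.

**PR2.** Third-position parity coordinates `x = G3/(G3 + C3)`,
`y = A3/(A3 + T3)`; (0.5, 0.5) is the mutation–selection balance point. AT-rich
mitochondrial genes can lack G (or G and C) entirely at third positions:
`x = 0` when only G3 is zero, and `NA` with a warning when the denominator
vanishes — degenerate points are flagged rather than silently dropped.

**Neutrality plot.** Ordinary least squares of GC12 on GC3 (`stats::lm`),
with the two-sided t-test for the slope on `n − 2` df. A slope near 1 means
mutation pressure dominates; a flat, weakly correlated cloud — the usual
mitochondrial outcome — indicates selection. At least 3 points are required
and zero GC3 variance is an error, not an NA.

## Ka/Ks and nucleotide diversity

`nei_gojobori()` implements the unweighted-pathway Nei–Gojobori (1986)
method, the default of the desktop tools used for mitogenome papers:
synonymous site counts per codon are the fraction of single-nucleotide
changes preserving the amino acid (averaged over the two sequences); codons
differing at 2–3 positions average their synonymous/nonsynonymous step counts
over all minimal mutational pathways with equal weight. Two conventions are
worth stating exactly, because implementations differ:

* Changes into (or out of) a stop codon count as nonsynonymous — the stop is
  treated as its own residue and no pathway is excluded. This keeps
  `S + N = 3 × codons` exactly and makes the estimator well-defined on every
  codon pair; the test suite verifies it against exhaustive permutation
  enumeration to 1e-12.
* Codons containing a gap or `N` in either sequence are wholly excluded from
  both site and difference counts (pairwise deletion).

Both proportions receive the Jukes–Cantor correction
`d = −(3/4)·ln(1 − 4p/3)`; `p ≥ 3/4` is flagged `NaN` (saturation), and
`ω = Ka/Ks` is `NA` when `Ks = 0`. The Jukes–Cantor/equal-pathway combination
assumes no transition/transversion bias: when sequences evolve with κ > 1 the
estimator recovers ω with a documented downward bias (~15% at ω = 1, κ = 2 in
our simulations), which is a property of the method, not a defect of the
implementation — the recovery tests therefore run at κ = 1, where the
estimator's assumptions hold.

`sliding_pi()` computes π per window as the mean over sequence pairs of
(differences / compared sites), excluding gap/N sites pairwise, with the
window (200 bp) and step (20 bp) defaults of standard sliding-window scans;
when step equals window the window values recombine exactly to the
full-alignment π.

## Repeats

**Microsatellites.** `find_ssrs()` reports perfect SSRs only, at the
conventional thresholds of 10/5/4/3/3/3 copies for motif lengths 1–6.
A repeated region is reported once, under its shortest (primitive) motif —
`(A)10` is never also `(AA)5` — as the maximal non-extendable run, spanning
the complete copies from the run start. Compound/interrupted SSR merging is
deliberately out of scope. Circular inputs can be scanned with the usual
doubling trick (run on `paste0(s, s)`, keep starts ≤ length, dedupe modulo
length); the suite verifies rotation invariance this way.

**Dispersed repeats.** `find_dispersed()` finds maximal *exact* repeats
≥ 30 bp (the conventional floor) in four orientation classes: forward
(identical copy), reverse (reversed copy), palindromic (reverse-complemented
copy — an inverted repeat), complementary (base-complemented, not reversed).
Detection is seed-and-extend on shared k-mers; the tests check it against an
exhaustive diagonal-scan oracle, at the 30 bp floor with planted copies and
at a reduced floor where spurious maximal repeats occur naturally. Unlike
E-value-based tools, no mismatches are allowed; every reported pair satisfies
its class relation exactly and is maximal (extending either copy breaks it).

**Tandem decomposition.** `decompose_tandem()` detects the fundamental period
as the smallest shift whose exact-match autocorrelation reaches the identity
threshold (default 0.8, chosen to tolerate the unit variation seen between
control-region variants of conspecific mitogenomes), segments the region into
period-length blocks, and splits blocks in two when a trailing partial copy
marks the internal boundary of a composite two-unit period — the layout of
aphid control regions, where units of two different lengths alternate
(e.g. 142 bp and 93 bp units in the order I-II-I-II-I). Unit types are
labelled by Roman numerals in order of first occurrence and clustered at the
same identity threshold. Periods up to twice `max_unit` (default 200 bp) are
scanned so a composite two-unit period still fits. No periodicity is a valid
outcome: the empty decomposition, not an error.

**Stem-loops.** `stem_loop_candidates()` is purely combinatorial: maximal
inverted-repeat arm pairs with a loop of 0–`max_loop` (default 50) bp and
arms ≥ `min_stem` (default 5) bp. Overlapping-arm configurations are not
candidates (a hairpin needs a loop), and no thermodynamic folding is
attempted — candidates are meant for downstream folding tools.

## Synthetic data: what it emulates, and what it does not

The generators exist so that every module has inputs with known ground truth:

* `make_genome()` lays features head-to-tail from an explicit plan of lengths
  and signed gaps (which must tile the circle exactly), fills the background
  iid at a target AT fraction (default 0.8434, the aphid scale), rewrites
  each protein-coding gene as sense-codon draws with a valid ATN start and
  TAA/TAG (or incomplete T/TA) stop on its own strand, and plants requested
  repeats by overwriting. `codon_profile_at()` tilts the base weights so the
  sense-codon profile hits the AT target exactly in expectation (naively
  removing the AT-rich stop codons would leave coding regions about a point
  low). Where annotated features overlap, the later-written feature wins the
  shared bases, so a deeply 3'-overlapped gene (ATP8 inside ATP6 in the
  replay plan) can lose its stop codon — as in the real genome, where the
  overlap is resolved by transcript processing, not by the DNA.
* `make_codon_set()` is a multinomial draw from a user profile plus a TAA
  stop: the ground truth for RSCU/ENc/PR2 recovery.
* `evolve_pair()` runs a Gillespie simulation of a continuous-time codon
  model on a star tree: single-nucleotide moves at rate κ (transitions) or 1
  (transversions), × ω when nonsynonymous, stops forbidden; rates are
  normalised so `branch_length` is the expected substitutions per codon along
  one branch. True synonymous/nonsynonymous event counts are recorded per
  tip. Defaults: uniform ancestral codons, κ = 1 (see above), ω and branch
  length caller-chosen.

What the generators do **not** emulate: real mitogenomes have
position-dependent composition, gene-specific codon bias, context-dependent
mutation and indels; the simulators are iid along the sequence and gap-free.
Passing recovery tests therefore demonstrates estimator correctness under the
stated models, not robustness to alignment error or compositional
heterogeneity in field data.

All generators are pure functions of (spec, seed): the same seed yields
byte-identical output, which the suite asserts.

## Test and replay problem sizes

The suite runs the published-table replays exactly (they are deterministic
arithmetic), RSCU invariants on 1,000 random codon tables, pathway-oracle
equivalence on 500 random codon pairs plus 200-codon sequence pairs,
SSR/dispersed-repeat oracle equivalence on 50 random 1–2 kb sequences, ω
recovery at 500 codons (a 10-taxon star tree for ω = 0.1; eight independent
replicates for the ω = 1 confidence interval, since pairwise estimates within
one tree share branches and are not independent units), and π recovery on
4 × 2 kb alignments. These sizes were chosen so each oracle comparison is
informative (spurious repeats genuinely occur; sampling error is small
relative to the asserted tolerances) while the whole suite stays in the
minutes range on one CPU.

## Known limitations

* Ka/Ks is the uncorrected-for-κ Nei–Gojobori estimator by design; no
  maximum-likelihood (Goldman–Yang) or branch models.
* Dispersed repeats are exact-match only; no degenerate copies.
* Tandem decomposition assumes one dominant (possibly composite) period; it
  does not model nested or heavily mutated arrays.
* The GenBank reader covers the flat-file subset needed for mitogenome
  records (CDS/tRNA/rRNA/misc_feature/D-loop, `join`/`complement`
  locations); it is not a general GenBank parser.
* `enc()` requires at least one family with two observed codons; single-codon
  genes are refused rather than extrapolated.
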