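---
title: "Methods: barcode-based species discrimination and marker design"
author: "specimark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-based species discrimination and marker design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specimark)
```

# Scope and model

`specimark` takes a panel of single-read chloroplast barcode sequences
(matK- or rbcL-like, several genotypes per species) through sequence
acceptance, alignment, distance-based and tree-based species
discrimination, and the automated design plus in-silico validation of
species-specific PCR markers. This vignette records the scientific choices
behind each stage: the models, the defaults and their units, the numerical
conventions, and what the simulation-based tests do and do not establish.

# Sequence acceptance criteria

Raw single-pass sequences carry per-base PHRED scores
(−10·log10 of the base-call error probability). Three rules decide
acceptance, applied in this order:

1. **End trimming.** Bases are deleted from each end until at least
   `window = 10` contiguous bases all have a score strictly greater than
   `window_min_phred = 20`. We operationalize "trim to minimize low-quality
   ends" as retaining the maximal interval bounded by the outermost
   qualifying windows — from the first window's start to the last window's
   end. Interior low-quality dips are therefore retained (and handled by
   masking), which is the simplest reading consistent with an
   end-trimming rule; alternates can be had by changing `QCParams`.
2. **Masking.** Retained bases with score strictly below
   `mask_below_phred = 20` become `N`. Note the deliberate asymmetry at a
   score of exactly 20: it cannot anchor a trim window (strict `> 20`) but
   is not masked (strict `< 20`). Masking runs after trimming so trim
   decisions use raw scores, never N's.
3. **Rejection.** A sequence is rejected when the fraction of `N` among
   retained bases strictly exceeds `max_n_fraction = 0.40`, or when no
   qualifying window exists at all. N's present in the input count toward
   the fraction exactly like masked ones — the criterion is about
   information content, not provenance. As a calibration point, a
   real-world read with 61 masked bases out of ≈800 retained (fraction
   0.076) is comfortably accepted.

The full pass is idempotent, and `trim_ends()` is property-tested against
a brute-force scan over all windows.

# Alignment

Bench workflows of this kind conventionally delegate alignment to an
external tool (MUSCLE, MAFFT); alignment is instrumental here, not a
contribution, so the package accepts pre-aligned FASTA as first-class input
(`ingest_alignment()`) and also ships a native progressive aligner so that
everything runs with no external tool. `pairwise_align()` is
Needleman–Wunsch/Gotoh with affine gaps (a gap of length *k* costs
`gap_open + (k−1)·gap_extend`; defaults +1/−1/−5/−1) and a deterministic
traceback (tie preference diagonal > up > left). `progressive_msa()`
computes p-distances from all pairwise alignments, builds a UPGMA guide
tree (ties broken by input order, for determinism), and merges profiles
with the same affine-gap DP, scoring column pairs by the average pairwise
substitution score. `N` is scored as a mismatch against everything during
alignment — conservative placement — but treated as missing data in
distances, which keeps the distance estimator unbiased. Because the exact
behavior of any particular external aligner version is unrecoverable,
distance-level results are validated with tolerances, never bit-exactly.

# K2P distances

For each pair of aligned rows, columns with a gap or `N` in either row
are excluded (*pairwise deletion* — the convention that preserves data in
ragged-ended barcodes; the per-pair comparable-site count `sites_used` is
reported so the choice is auditable). With transition proportion $P$ and
transversion proportion $Q$ over $n$ comparable sites,

$$d = -\tfrac12 \ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right].$$

Distances are kept at full precision internally and rounded only in
reports (6 decimals). Saturation ($1-2P-Q \le 0$ or $1-2Q \le 0$) yields
an explicit undefined flag with a warning — a silent zero or NaN would
corrupt the downstream gap extrema. The implementation is cross-checked
in the test suite against an independent reference implementation
(`ape::dist.dna`, model K80, pairwise deletion) and against Monte-Carlo
recovery of a known generating divergence.

# Barcoding gap

Per species: the intraspecific distance set is all within-species pairs;
the interspecific set is all pairs between that species and *all* others
(a single min/max per species, not a per-species-pair breakdown, though
the pairwise sets are recoverable from the matrix). The verdict is
`max_intra < min_inter` with **strict** inequality — a tie is a failure to
discriminate. Species with one sample have no intraspecific pairs and are
*not assessable* (`NA`), which is distinct from failing. Undefined
distances are excluded from extrema with a warning. A panel with a single
species has no interspecific pairs and errors.

# Neighbor joining and bootstrap

`nj_tree()` implements Saitou–Nei agglomeration with the standard
Q-criterion. Numerical conventions: ties in the Q minimization are broken
by the lexicographically smallest pair of representative labels (a joined
node is represented by the smallest leaf label it contains), making
results platform-independent; negative branch lengths are clamped to zero
with the deficit transferred to the sister branch, preserving path
lengths, which matches common practice in distance-tree software. On
additive matrices NJ is exact; the suite verifies topology and branch
lengths to 1e-9 on random additive trees of 4–8 taxa and cross-checks
against `ape::nj` on noisy matrices.

`bootstrap_support()` resamples alignment columns with replacement,
recomputes K2P + NJ per replicate, and maps supports onto the
point-estimate tree (not a consensus tree): the support of an internal
edge is the percentage of replicates whose tree contains the same
bipartition. Replicates with saturated distances are dropped and counted
with a warning. Everything is reproducible under a fixed seed. Rendered
output conventionally blanks supports below 50% (`render_supports()`);
machine output keeps all values. `species_monophyly_check()` asks, per
species, whether some bipartition of the unrooted tree separates exactly
that species' leaves — i.e. monophyly on the best possible rooting;
single-leaf species are monophyletic by convention.

# Diagnostic sites and marker design

A column is diagnostic for a target species when every target row carries
the same unambiguous base and that base occurs in no non-target row.
Within-target polymorphism disqualifies a column: fixation is required,
which guarantees the marker amplifies every target genotype. A gap or `N`
among the background states still counts as "absent" but marks the site
lower-confidence; strict mode drops such sites.

`design_primer_pairs()` enumerates pairs with at least one primer's 3′
terminal base on a diagnostic site. Defaults, chosen from the observed
range of a working species-specific primer panel: length 17–27 nt, Tm
window 52–68 °C, pair ΔTm ≤ 5 °C, product 120–800 bp, minimum multiplex
band separation 30 bp (the smallest separation in a published working
multiplex is 32 bp). Doubly anchored pairs are preferred; free partners
are enumerated (on a 3-base grid, since placement slack makes single-base
resolution unnecessary) only when no doubly anchored pair is feasible.
Ranking is documented and deterministic: more anchored primers first, then
smaller ΔTm, then product size closest to `size_target`. Every candidate
is validated by in-silico PCR against the full training alignment — it
must yield exactly one product on each target row and none on any
non-target row — so the marker/specificity consistency invariant holds by
construction and is asserted as a test. Annealing temperature is an
input, defaulting to the pair's minimum Tm plus a configurable offset; no
formula from Tm to an optimal annealing temperature is inferred, because
working protocols routinely run primers well above or below naive
predictions.

## Melting temperature calibration

The Tm model is nearest-neighbor with Breslauer (1986) stack
thermodynamics, a helix-initiation term, the CT/4 symmetry factor for
non-self-complementary duplexes, and the 16.6·log₁₀[Na⁺] salt correction.
Since different online calculators combine these ingredients differently,
the shipped default (`tm_params()`: ΔH_init = −3.4 kcal/mol, ΔS_init =
−10.8 cal/mol/K, CT = 5.5 nM, [Na⁺] = 50 mM) was **calibrated once**
against a reference panel of 14 species-specific chloroplast primers with
known Tm values, by the grid search in `scripts/calibrate_tm.R`; it
reproduces the panel within ±0.07 °C (all 14 within the suite's ±0.5 °C
acceptance band) and was frozen before any other use. Tm is
duplex-symmetric (a sequence and its reverse complement melt identically)
and non-decreasing under G/C extension — both property-tested.

## Interaction screening and multiplexing

Primer-dimer risk is screened as the longest antiparallel complementary
run that includes either primer's 3′ terminus (3′-recessed dimers prime
extension); runs ≥ 5 are flagged by default. Hairpins are flagged for
self-complementary stems ≥ 4 enclosing a loop ≥ 3. Multiplex groups are
built greedily in input order within each annealing temperature: members
must keep every pairwise product-size difference ≥ 30 bp and no flagged
cross-member 3′ interaction; violators stay ungrouped with the reason
recorded. Note that incidental 5-base 3′ complementarities do occur among
real published primers that nonetheless multiplex fine at the bench — the
threshold is deliberately conservative and configurable.

# In-silico PCR

Binding-site search is exact-match by default (`max_mismatch = 0`), since
gel-validated species-specific markers behave as clean presence/absence;
a mismatch budget exists for robustness probing but the 3′-terminal
`clamp = 3` bases must always match perfectly. An `N` in the template
never matches. Product length is gel-facing: inclusive of both primer
footprints (`rev_end − fwd_start + 1` in plus-strand coordinates). All
products up to 5000 bp are reported; "specific" requires exactly one band
on every target sample and none elsewhere. Chloroplast markers are
maternally inherited, so on a hybrid template exactly one amplifying
candidate-parent marker identifies the seed parent
(`infer_maternal_parent()`); zero or several amplifying markers are
inconclusive.

# The simulator and what passing tests mean

`simulate_species_set()` evolves a random ancestor along a star tree:
species branches of $d_\text{inter}/2$ (so any between-species pair has
expected divergence $d_\text{inter}$), then individual branches of
$d_\text{intra}/2$, using the closed-form site transition probabilities
of the Kimura two-rate model with ratio κ — *exactly the model the K2P
distance inverts*, so parameter recovery is a closed loop that tests the
estimator against its own assumptions. Defaults mirror the observed
regime of closely related chloroplast barcode panels: 7 species × 3
genotypes × 800 bp, $d_\text{inter} = 0.016$ (the midpoint of the
0.008–0.024 range seen between congeneric species), $d_\text{intra} =
0.001$ (most such species show zero observed intraspecific divergence),
κ = 2, and 3 guaranteed planted diagnostic sites per species, recorded in
a truth registry for assertions. Divergences are expected substitutions
per site, not percent identity. Indels are off by default (these barcodes
are coding and nearly gap-free) and exist only to exercise the aligner.
Quality simulation produces end ramps below the trim threshold, a high
plateau and random dips, and returns the expected QC outcome computed by
a generator-side brute-force application of the same rules.

What passing simulated tests do **not** show: real chromatogram noise is
not i.i.d., real interspecific divergence is tree-structured rather than
star-shaped, chloroplast loci can carry microinversions and mononucleotide
runs the simulator omits, and real background panels (e.g. public-database
sequences of further congeners) can erode diagnostic sites that look fixed
in a small training panel. Marker designs should always be re-validated
in-silico against every new sequence added to the reference set — the
pipeline does this automatically when rerun.

# Problem sizes and reproducibility

The shipped test-suite and acceptance checks use: 200 random quality
profiles against the QC oracle; 1000 random (P, Q) draws for the
K2P-vs-p-distance inequality; 100 random additive trees (4–8 taxa) for NJ
exactness; 100 replicate sequence pairs (800 bp, $d = 0.02$, κ = 2) for
parameter recovery; and one full 7 × 3 × 800 bp end-to-end panel
(alignment → gap → design → specificity → hybrid inference). Bootstrap
defaults to 1000 replicates in production use; tests use 20–100 since
support estimates only need binomial-level precision there. A single
integer seed drives every stochastic stage, is mandatory in `SimParams`,
and is recorded in the pipeline manifest together with per-artifact MD5
checksums, so a rerun of the same configuration byte-reproduces every
deterministic artifact.

# Known limitations

* The aligner is a plain progressive scheme without iterative refinement;
  for heavily gapped or non-coding loci an external alignment should be
  ingested instead.
* Only K2P and p-distances are offered (no gamma correction, no other
  substitution models), matching the method family this pipeline
  automates.
* Interaction screening is combinatorial, not thermodynamic: it flags
  complementary runs, not ΔG of dimer formation.
* In-silico PCR models binding and the 3′ clamp, not extension
  efficiency, band intensity or gel migration.
* The discrimination verdict is the plain barcoding-gap criterion;
  probabilistic species delimitation is out of scope.
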