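# specimark

DNA-barcode based species identification and the design of
species-specific, multiplexable PCR markers.

Closely related congeneric species — the motivating case is the cultivated
*Annona* fruit trees (cherimoya, sugar apple, soursop and their relatives) —
are often impossible to tell apart from leaf material in the field. Two
complementary molecular strategies solve this from a panel of chloroplast
barcode sequences (matK, rbcL):

1. **Distance-based discrimination.** Align the barcodes, compute pairwise
   Kimura 2-parameter distances, and test each species for a *barcoding
   gap*: the species is discriminated when its largest within-species
   distance is strictly smaller than its smallest distance to any other
   species. Neighbor-joining trees with bootstrap support give the
   complementary tree-based identification.
2. **Character-based diagnosis.** Find alignment columns whose state is
   fixed in one species and absent from all others, anchor a PCR primer's
   3′ terminal base on such a diagnostic site (3′ mismatches abolish
   extension on non-target templates), and stagger amplicon lengths so
   several species-specific markers can run in one multiplex reaction and
   be read off a single gel lane. Because chloroplasts are maternally
   inherited, the same markers identify the seed parent of interspecific
   hybrids.

`specimark` implements both strategies end to end for R users working on
species identification in closely related plant groups: PHRED-based
sequence acceptance (end trimming, low-quality masking, N-fraction
rejection), a native progressive aligner, K2P distances with pairwise
deletion, barcoding-gap analysis, neighbor joining with nonparametric
bootstrap, diagnostic-site discovery, nearest-neighbor melting
temperatures, primer-dimer screening, multiplex grouping, in-silico PCR
validation, and a sequence simulator for closed-loop testing.

## The core quantities

**K2P distance.** For an aligned sequence pair with transition proportion
*P* (A↔G, C↔T) and transversion proportion *Q* over the *n* comparable
sites (columns with a gap or N in either row are excluded pairwise),

    d = −½ · ln[(1 − 2P − Q) · √(1 − 2Q)]

Saturated pairs (a log argument ≤ 0) are reported as undefined, never as a
silent zero.

**Discrimination criterion.** Species *s* is discriminated iff
`max(intra_s) < min(inter_s)` (strict), where `intra_s` are distances
within *s* and `inter_s` are distances from *s* to all other species.

**Melting temperature.** Primer Tm uses the nearest-neighbor model with
Breslauer (1986) stack thermodynamics,

    Tm = 1000·(ΔH + ΔH_init) / (ΔS + ΔS_init + R·ln(CT/4)) − 273.15
         + 16.6·log₁₀[Na⁺]

with a parameter set (ΔH_init = −3.4 kcal/mol, ΔS_init = −10.8 cal/mol/K,
CT = 5.5 nM, [Na⁺] = 50 mM) calibrated once against a 14-primer reference
panel of species-specific chloroplast primers with known Tm values; see
`scripts/calibrate_tm.R`. The panel is reproduced to within 0.07 °C.

## Worked example

```r
library(specimark)

sim <- simulate_species_set(sim_params(n_species = 4, n_per_species = 3,
                                       seq_length = 600, seed = 7))
aln <- progressive_msa(sim$sequences, species_of = sim$species_map)
dm  <- distance_matrix(aln)            # K2P, pairwise deletion
gap <- gap_analysis(dm)
print(gap, digits = 3)
#>   species n_samples min_intra max_intra min_inter max_inter discriminated
#> 1     sp1         3         0   0.00334    0.0254    0.0324          TRUE
#> 2     sp2         3         0   0.00167    0.0272    0.0341          TRUE
#> 3     sp3         3         0   0.00000    0.0254    0.0306          TRUE
#> 4     sp4         3         0   0.00000    0.0289    0.0341          TRUE
discrimination_count(gap)
#> [1] 4
```

Every species' largest intraspecific distance sits well below its smallest
interspecific distance, so all four simulated species show a barcoding gap.
Designing a marker for one of them:

```r
pairs <- design_primer_pairs(aln, "sp2",
                             design_constraints(product_min = 150,
                                                product_max = 500))
pairs[[1]]
#> MarkerPair sp2F1/sp2R1 -> sp2: 287 bp, Ta 63 C (Tm 62.9/62.9)

specificity_matrix(list(pairs[[1]]), sim$sequences, sim$species_map)
#>             sp1_1 sp1_2 sp1_3 sp2_1 sp2_2 sp2_3 sp3_1 sp3_2 sp3_3 ...
#> sp2F1/sp2R1                   287   287   287
```

The designed pair is 3′-anchored on a site diagnostic for `sp2`, melts at
62.9 °C on both sides, and — validated by in-silico PCR during design —
produces exactly one 287 bp band on every `sp2` genotype and none on any
other sample.

A thin command-line front end over the same functions lives at
`inst/cli/specimark.R` (subcommands `simulate`, `qc`, `align`, `dist`,
`gap`, `tree`, `design`, `multiplex`, `ipcr`, `pipeline`), and
`run_pipeline()` orchestrates all stages with a JSON manifest recording
inputs, outputs, parameters, checksums and the single RNG seed.

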