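# lipidfrags

Mass-balanced enumeration and shorthand nomenclature of lipid fragment ions
for tandem (MS²) and multi-stage (MS³) mass spectrometry.

## The problem

Shotgun- and LC-MS lipidomics identifies lipids from the fragment ions their
precursor ions release on collision-induced dissociation (CID). Intact lipid
molecules have a standardized shorthand (`PC 34:1`, `PS 16:0-22:6`,
`SM 18:1;2/17:0`), but the fragment ions that actually carry the structural
evidence are still annotated ad hoc — as bare m/z values, chemical formulas
(`C5H15NO4P`), or misleading intact-lipid aliases (`[NEFA 16:0-H]-`).
`lipidfrags` implements a systematic three-step alternative for anyone who
curates fragmentation databases, reviews MS² spectra, or builds lipid
identification pipelines:

1. **Mass-balanced reactions.** Every observed m/z value is represented by a
   reaction in which the atoms of the charged fragment and of all neutral
   fragments sum exactly to the precursor ion, so each m/z has *two* readings:
   the charged fragment and the composite of neutral losses.
2. **Fragment-type-specific names.** Charged fragments are named bare, neutral
   fragments with a leading `-`. Lipid class-selective fragments (LCFs) are
   named `class(nominal mass)` — `SM(184)`, `-PE O-(141)`; single-chain
   fragments (MLFs) by their hydrocarbon-chain attribute plus a signed
   elemental delta relative to a fixed reference base — `FA 18:3(+C7H16NO6P)`,
   `-FA 17:0(-H)` (ketene loss); multi-chain fragments (iMLFs) analogously —
   `DAG 28:2(+C6H11O9P2)`; double-bond-specific fragments (DBFs) carry the
   double-bond position — `FA 18:1(9)(+O -C7H15)`. Stable isotope labels
   render inline: `PC(+[2]H13)(197)`, `-FA 16:0(+[2]H3)(-H)`.
3. **One annotation per m/z.** A decision tree prioritizes fragment types in
   the order DBF > MLF > LCF > iMLF; on a type tie the side with the lower
   total fragment mass (not m/z) wins.

For the fatty-acyl chain the reference base is the acylium composition
C<sub>c</sub>H<sub>2c−1−2db</sub>O<sub>1+oh</sub>, so `FA x:y(+O)` is the
carboxylate anion, `(+HO)` the free fatty acid, `(-H)` the ketene, and the
bare name the acylium itself.

## Worked example

```r
library(lipidfrags)

prec <- precursor_ion("PC 18:3-18:3", "+CH3COO")
prec
#> [PC 36:6+CH3COO]-  m/z 836.5447  (C46H79NO10P, z=-1)

fragment_table(enumerate_fragments(prec))[, c("mz", "dual")]
#>         mz                                        dual
#> 1 762.5079               -PC(74) | DAG 36:6(+C4H9NO3P)
#> 2 277.2173         FA 18:3(+O) | -FA 18:3(+C10H21NO7P)
#> 3 502.2939  -FA 18:3(-H) -PC(74) | FA 18:3(+C7H16NO6P)
#> 4 484.2833 -FA 18:3(+HO) -PC(74) | FA 18:3(+C7H14NO5P)
```

Row 3 is the classic combined loss of methyl acetate (74 Da, from the acetate
adduct) and one 18:3 ketene: the prioritized reading (left of `|`) is the
neutral composite because its total mass (334.3 Da) is below the charged
fragment's (502.3 Da). Annotating a measured ion-trap peak list:

```r
peaks <- data.frame(mz = c(269.2, 448.2, 466.2), intensity = c(100, 80, 60))
annotate_spectrum(peaks, "PE 17:0-17:0", adduct = "-H", tol_da = 0.3)[[1]]
#> [PE 34:0-H]-: 3 matched peak(s), 0 unmatched; identified as PE 17:0-17:0 [molecular level]
#>   observed_mz theoretical_mz       ppm          name
#> 1       269.2       269.2486 -180.5167   FA 17:0(+O)
#> 2       448.2       448.2833 -185.9286 -FA 17:0(+HO)
#> 3       466.2       466.2939 -201.4038  -FA 17:0(-H)
```

The carboxylate, fatty-acid loss and ketene loss each carry single-chain
evidence, so the precursor is identified at the molecular species level.
MS³ chains off any MS² reaction (`enumerate_ms3()`), a queryable fragment
database over chain-enumeration ranges is built with `build_fragment_db()` /
`search_mz()`, and `simulate_spectrum()` generates seeded synthetic spectra
with ppm jitter and decoy peaks for validation. `exec/lipidfrags` exposes the
same operations as a command-line tool (`calc`, `fragments`, `builddb`,
`search`, `simulate`, `annotate`).

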