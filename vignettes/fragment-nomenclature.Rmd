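---
title: "Mass-balanced fragment reactions and shorthand nomenclature for lipid MSn spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-balanced fragment reactions and shorthand nomenclature for lipid MSn spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidfrags)
```

## The model

CID of an ionized lipid proceeds by charge-mediated and charge-remote
pathways that are strongly conserved within a lipid class. `lipidfrags`
encodes this regularity in three layers.

**Compositions.** Molecules and fragments are multisets of nuclides; heavy
nuclides (`[2]H`, `[13]C`, `[15]N`, `[18]O`) are first-class entries, so an
isotope-labeled lipid is just a composition with some light atoms replaced.
m/z is computed as (mass − z·mₑ)/|z|, always including the electron mass:
the phosphocholine cation C₅H₁₅NO₄P⁺ is 184.0733 only with the electron
subtracted. Deprotonation removes one H and keeps its electron; nuclide
masses are CODATA/AME values to ≥9 decimals.

**Structures.** Each lipid class is a template: a backbone composition plus
chain slots with a linkage chemistry (ester, amide, ether/vinyl-ether,
long-chain base, sterol). A chain of c carbons, db double bonds and oh
hydroxyls contributes a linkage-specific formula (ester:
C_c H_{2c−2−2db} O_{1+oh}, i.e. the free acid minus water, and so on). An
alkenyl ("p") chain counts its vinyl-ether double bond in db, so alkyl and
alkenyl chains share one contribution formula and the distinction is purely
annotational. The same machinery yields the *reference bases* used for
fragment naming: the fatty-acyl base is the acylium composition
C_c H_{2c−1−2db} O_{1+oh}, chosen so that the common fragment contexts are
short deltas (`+O` carboxylate, `+HO` free acid, `-H` ketene); long-chain
bases use the free sphingoid base, sterols the intact sterol (so that
`ST 27:1` is cholesterol and `SE 27:1/19:0` the cholesteryl ester).

**Reactions.** Fragmentation rules are data, not code (a packaged TSV). A
rule is scoped to classes, adducts and MS level and lists one charged part
and zero or more neutral parts drawn from a small vocabulary: a fixed
composition (class-selective fragments), a chain slot plus a signed delta
(single-chain fragments, iterated over every applicable chain), a chain
*pair* (multi-chain fragments of cardiolipin), and exactly one remainder
defined as precursor-minus-everything-else. The remainder closes the atom
balance, so *every* enumerated reaction satisfies the central invariant —
charged atoms + neutral atoms = precursor atoms, hence mass balance to below
1e−9 Da — by construction, and `validate_rules()` additionally proves
non-negativity of every part on a probe lipid per class. Reactions that are
atom-identical (two identical chains in one lipid) are collapsed, with their
chain-slot evidence merged; that is why a TAG with three distinct acyls has
12 single-chain reactions and a TAG with two identical acyls only 8.

## Naming and prioritization

Remainder fragments are named by how many chains they retain: none — a plain
parenthesized formula; one — as a single-chain fragment, delta relative to
that chain's base (this is how the charged counterpart of a ketene loss from
PC acquires the name `FA 18:3(+C7H16NO6P)`); two or more — as a sub-lipid
(`DAG`, `Cer`, `TAG` per class registry) at species-level totals plus a
delta, e.g. `-Cer 35:1;2(-H2O)` behind `SM(184)`. Deltas render as signed
Hill groups (`(+O -C7H15)`); the metal adduct atoms Na/K/Li render last
(`(+ONa)`, `(+HONa)`), matching field convention rather than strict Hill
order — the alternative (`+NaO`) appears nowhere in practice.

The decision tree ranks fragment types DBF > MLF > LCF > iMLF; within a type
tie the side (charged fragment vs neutral composite) with the lower total
fragment mass wins. Two boundary cases were genuinely open and are decided
here: an exact mass tie goes to the charged side, and when the "neutral"
complement is itself an ion (charge splitting of a doubly deprotonated
cardiolipin) the charged fragment always annotates its own m/z. Neutral
composites render chain-derived terms before head-group terms
(`-FA 18:3(-H) -PC(74)`), and term order never influences the winner.

## Isotope labels

Labels attach to the class symbol (`PC(+[2]H13) 16:1-18:1`), to individual
chains (`PC 16:0(+[2]H3)-16:0(+[2]H3)`) or to species-level totals, and
propagate into compositions by substitution, so the mass shift is exactly
the sum of nuclide mass differences (13 × 1.00628 Da for ²H₁₃). Head-group
labels transfer onto class-selective fragments only where the rule says so
(`label_lcf`): the phosphocholine cation becomes `PC(+[2]H13)(197)` — the
nominal mass counts heavy mass numbers — while an ammonia loss from a
labeled TAG stays `-TAG(17)`. Chain deltas remove light atoms first, so a
ketene loss from a methyl-labeled chain keeps its label
(`-FA 16:0(+[2]H3)(-H)`); the one curated exception is the long-chain-base
fragment of ceramide, which loses the labeled head end and therefore removes
heavy nuclides first, printing the removal explicitly
(`LCB 18:0;3(+[13]C2[15]N)(-[13]CH8[15]NO)`).

## Annotation and identification levels

`annotate_spectrum()` matches each observed peak to the nearest theoretical
fragment within tolerance — 5 ppm default for FT-type spectra, 0.3 Da
(`tol_da`) recommended for ion traps — one annotation per peak per
candidate; isomeric candidates are annotated independently and never
arbitrated. The identification level is: double-bond-defined if any DBF
matched; molecular species level if *every* chain slot has direct
single-chain evidence (a stricter criterion than counting two fragments,
and indirect evidence from remainder ions deliberately does not count);
species level otherwise when any class-selective, multi-chain or partial
single-chain fragment matched. The last clause — partial MLF evidence still
supports a species-level call — is this package's reading of an underdefined
case; it never upgrades a call.

## Synthetic spectra

`simulate_spectrum()` emulates an FT instrument's mass error as relative
(ppm) Gaussian jitter — constant-ppm error across the m/z range, which is
what Orbitrap-type analyzers approximately show — plus uniform decoy peaks
and a uniform or rank-decay intensity model, all under one seed. Decoys
avoid windows of max(3σ, 5) ppm around true peaks, so at matching tolerances
up to that width they cannot force false matches; with zero jitter,
annotation recall is exactly 100% at 1 ppm. It does not emulate isotope
envelopes, chimeric precursors, detector saturation or chromatography, so
passing tests demonstrate the correctness of the annotation logic, not
robustness to real spectral artifacts.

## Numerical choices and problem sizes

Tolerances default to 5 ppm / 0.3 Da as above; atom balance is asserted
exactly on integer counts, mass balance at 1e−9 Da. The fragment database
defaults deliberately enumerate small chain ranges (tests use 2–4 carbon
values × up to 7 double-bond counts, a few hundred molecular species); the
full catalogue scale of the public lipid databases depends on unpublished
enumeration ranges and is out of scope. Test simulations use single lipids
with ≤ 50 decoys and 12 replicate spectra for the recall estimate —
comfortably sized for the properties they check.

## Known limitations and measured outliers

Two printed literature values disagree with compositional arithmetic by more
than instrument accuracy: the serine-loss fragment of PS 42:10 reported at
m/z 767.4591 (arithmetic from the deprotonated precursor gives 767.4657) and
a TAG fatty-acid-loss fragment reported at 577.5215 where the arithmetic
value for the stated 18:2 loss is 579.5347 — the printed value instead
matches an 18:1 loss, suggesting a transposition. Both are treated as
measured values, never fitted, and excluded from numeric assertions.
Likewise the long-chain-base fragment convention reproduces the printed
*name* for the labeled ceramide fragment; its computed m/z (268.2363) sits
7 ppm from the reported 268.2344, consistent with a measured low-intensity
ion. Ozone-induced double-bond chemistry is supported only as curated DBF
rule entries (single-double-bond chains); sn-position inference, intensity
prediction, quantification and FDR estimation are out of scope. mzML input
is not provided; peak lists arrive as two-column TSV or MGF.
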