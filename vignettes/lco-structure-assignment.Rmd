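---
title: "Assigning lipochitin oligosaccharide structures from CID mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning lipochitin oligosaccharide structures from CID mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcoms)
```

## The problem

Rhizobia signal to their legume hosts with lipochitin oligosaccharides
(LCOs, Nod factors): short chains of three to five β-1,4-linked
N-acetylglucosamine (GlcNAc) residues whose non-reducing-terminal residue
carries a fatty N-acyl chain in place of its N-acetyl group. Host
specificity is governed by small decorations of this scaffold. For
*Neorhizobium galegae* the relevant decorations are a carbamoyl group (Cb)
on the non-reducing-terminal residue, an ester-linked O-acetyl (OAc) on
the residue adjacent to it, and occasionally a methyl on the
reducing-terminal residue. Whether a putative acetyltransferase (noeT)
installs the O-acetyl is decided purely mass-spectrometrically: compare
the LCO species of the wild type with those of the noeT knockout, and show
that the +42 Da decoration disappears.

`lcoms` re-implements that entire desk analysis as tested, reusable code:
structure enumeration, mass prediction, fragment annotation, and the two
inference procedures (wild-type/mutant differential, mild-base
de-O-acetylation consistency).

## The mass model

Every structure is reduced to an elemental composition over C, H, N, O,
Na by residue-level rules:

* an in-chain GlcNAc residue is C8H13NO5 (nominal 203); the intact
  molecule adds one water for the free reducing end;
* the acyl chain replaces the N-acetyl (a ketene equivalent, C2H2O,
  −42) of residue 1 with C(c)H(2c−2−2d)O(1+h) for c carbons, d double
  bonds and h chain hydroxyls;
* substituent increments relative to H: Cb +CHNO (+43), OAc +C2H2O
  (+42), methyl +CH2 (+14).

Two mass scales are carried everywhere, and keeping them distinct is the
package's central numerical decision. Printed unit-resolution tables use
*nominal* masses (integer lightest-isotope masses, C=12, H=1, N=14, O=16,
Na=23) compared with exact equality. Real spectra are matched on
*monoisotopic* masses with a Da tolerance. The two scales drift apart by
roughly 0.5–0.6 Da in this mass range — the monoisotopic [M+H]+ of
IV(C20:3, Cb, OAc) is 1162.59, which conventional rounding would print as
1163 — so reproducing an integer table through the monoisotopic route
would silently fail. Charge is fixed at +1 (no multiply charged LCO
species are modeled) and the electron mass is neglected (<0.001 Da,
below every tolerance used).

## Fragmentation

CID of protonated or sodiated LCOs is dominated by glycosidic cleavage
with charge retention on the non-reducing portion: B ions. Bk is the sum
of the k non-reducing-end residue compositions plus the charge carrier;
sodiated precursors give sodiated fragments (adduct retention), which is
why the B1 of a [M+Na]+ species sits 22 u above its [M+H]+ counterpart.
Three diagnostic rules fall out of the residue model and are enforced as
exhaustive properties in the test suite:

* B(k+1) − B(k) = 203 across an unmodified GlcNAc, 245 across the
  O-acetylated residue 2;
* precursor − B(n−1) = 221 (GlcNAc + water) for an unmethylated reducing
  residue, 235 when methylated — the reducing-end methyl is invisible to
  the whole B series;
* O-acetylated ions lose neutral acetic acid (C2H4O2, −60): companions
  are generated for the precursor and for every Bk with k ≥ 2, the ions
  that contain residue 2. Note the distinct constants: the substituent
  adds +42 (ketene equivalent) but eliminates as −60 (acetic acid).

Y/C/Z ions, cross-ring cleavages, internal fragments and multiple neutral
losses are out of scope: every fragment in the reference tables is
explained by B ions plus −60 companions.

One modeling question the data do not settle is whether the
reducing-terminal methyl is O- or N-linked; it is treated as a mass-only
+CH2 on the reducing residue, which is all the B-series (methyl-blind)
and precursor arithmetic can see anyway.

## Candidate enumeration and annotation

Candidates come from a configurable `search_space()`. The defaults are
the observed repertoire: tetrameric backbone, even acyl chains of 16–22
carbons, up to 4 double bonds, at most one chain hydroxyl, all three
substituents optional — 640 structures, 1280 (structure, adduct)
candidates. Odd chain lengths are chemically fine and accepted by the
model, but excluded from the default space because only even chains are
observed. A wider backbone range {3, 4, 5} is available for exploratory
work.

Annotation matches the query precursor against all candidates (exact
integer equality in nominal mode, ±`tolerance_da` monoisotopic
otherwise), then scores each surviving candidate as the number of
predicted non-precursor ions (B ions plus loss companions) matched by at
least one observed peak; matching is greedy nearest-neighbour with each
observed peak consuming at most one predicted ion, ties to the lower
predicted m/z. Intensities are never scored — these assignments argue
from ion presence, not abundance — but are carried through for reporting.
The ranking key is (score, fewer substituents, nomenclature): parsimony
breaks ranks, never ties at the top. Genuinely isobaric assignments —
e.g. nominal m/z 1162, where IV(C20:3, Cb, OAc) [M+H]+ and
IV(C18:0, Cb, OAc) [M+Na]+ predict identical nominal ion sets — are
co-reported with `ambiguity_flag = TRUE`, since only chromatographic or
biological context (unavailable to the tool) can separate them. The
default monoisotopic tolerance of 0.5 Da suits the unit-resolution
instruments of the source data; it is a documented default, not a
measured property. `min_fragment_matches` defaults to 0 so precursor-only
rows can still be annotated.

## The two inferences

`pair_by_acetyl()` works on accepted *assignments*, not on raw peaks,
because that is the level at which the biological claim lives ("none of
the mutant species is acetyl-bearing"). Structures differing only in
adduct are collapsed first — ionization is not chemistry. Each
O-acetylated structure in sample A is paired with the structure in B that
is identical except for the acetyl; the verdict is `ACETYLATION_LOST`
when A has at least `min_acetylated` (default 1) acetylated structures
and B has none, `NO_CHANGE` when the counts agree, `INCONCLUSIVE`
otherwise. On the packaged reference assignments this yields 6 distinct
acetylated wild-type structures (7 table rows; one structure appears
under both adducts), 0 in the mutant, verdict `ACETYLATION_LOST`.

`verify_base_treatment()` encodes the mild-base experiment: ester
cleavage removes OAc (−42 on both adducts' precursors), B1 is conserved,
every Bk with k ≥ 2 shifts −42, and the acetic-acid companions vanish.
This is a model-level theorem — it holds for all 320 O-acetylated
(structure, adduct) pairs in the default space, and the test suite proves
it exhaustively — but the function also accepts observed before/after
peak lists for empirical corroboration.

## What the synthetic generator emulates — and what it does not

`sim_config()` / `generate_peaklist()` produce spectra with the structure
the analysis assumes: each predicted fragment at its monoisotopic m/z
plus Gaussian jitter (default SD 0.05 Da, a realistic calibration spread
for unit-resolution instruments), log-normal intensities, 20 uniform
decoy peaks over 400–1250 m/z, and an optional arithmetic polymer ladder
(default repeat 44 Da, an ethylene-oxide-like period) standing in for the
strongly UV-absorbing polymeric contaminant that co-purifies in early
HPLC fractions — its composition is unknown, so it exists to stress
unmatched-peak handling, not to mimic chemistry. One spectrum is
generated per (structure, adduct); co-elution can be simulated by merging
peak lists but is off by default. Not emulated: isotope envelopes,
chemical noise structure, detector saturation, chromatography. Passing
the recovery benchmark therefore demonstrates correctness of the
annotation logic under calibrated noise, not instrument-grade robustness
on real data.

`generate_experiment()` builds the paired design: wild-type truth is the
distinct wild-type structure repertoire of the reference table; mutant
truth applies `de_O_acetylate()` to every acetylated structure. The seed
fully determines the output.

## Problem sizes and runtime choices

All reproduction analyses are exact desk-scale arithmetic and complete in
well under a second. The property suites run exhaustively over the 640
default-space structures. The recovery benchmark uses 200 spectra at the
default noise (jitter 0.05 Da, 20 decoys, seed 42) and must recover the
true structure among co-ranked top candidates in at least 95% of spectra;
the observed rate is 0.995, the one miss being a decoy-inflated
competitor. Precursor tables are cached per (space, adducts) so repeated
annotation queries cost microseconds, not a re-enumeration.

## Known limitations

* Positions of Cb/OAc/methyl are fixed model constants; regio-isomers
  within a residue (C-6 vs C-4 esters) are indistinguishable by these
  masses and are not represented.
* Sulfated, fucosylated or otherwise decorated LCOs of other rhizobia are
  out of scope.
* Nominal-mode annotation inherits the blindness of integer masses:
  isobar groups can only shrink with adduct knowledge or monoisotopic
  data.
* No FDR machinery over decoy structures; ambiguity is reported, not
  scored probabilistically.
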