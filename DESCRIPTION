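Package: lcoms
Title: Mass Spectrometric Structure Assignment of Lipochitin Oligosaccharide Nod Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning structures to rhizobial lipochitin
    oligosaccharide (LCO) Nod factors from single-stage and CID product-ion
    mass spectra. Enumerates candidate LCO structures over a configurable
    search space, computes elemental compositions with nominal (integer) and
    monoisotopic masses, predicts protonated and sodiated precursor ions,
    B-series glycosidic fragments and acetic-acid neutral-loss companions,
    annotates observed peak lists with ranked candidates and isobar
    reporting, and implements the wild-type versus acetyltransferase-mutant
    differential test and the mild-base de-O-acetylation consistency check.
    Includes a synthetic spectrum generator (m/z jitter, decoy peaks,
    polymer-ladder contaminant) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
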