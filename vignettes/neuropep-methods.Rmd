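---
title: "Methods: prohormone processing, spectrum matching, and family classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prohormone processing, spectrum matching, and family classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropep)
```

## Scope and model

`neuropep` implements the in-silico arm of invertebrate neuropeptide
discovery as practiced on cephalopod prohormones such as the cuttlefish
FLGamide (So-orcokinin B) precursors: predict mature peptides from a
precursor protein, compute their theoretical masses and fragment series,
match them against centroided MALDI-TOF/TOF peak lists, classify them into
orcokinin-type families by degenerate motifs, and summarize tissue FPKM
expression. Every stage can be exercised on seeded synthetic data with an
exact ground-truth manifest, so the full pipeline is testable without raw
instrument files.

## Prohormone processing

The processing model is the standard prohormone-convertase +
carboxypeptidase-E picture:

* **Signal peptide.** Either annotated (`signal_end=` tag in the FASTA
  header, the recommended route for curated fixtures) or predicted by a
  hydrophobicity heuristic: the strongest 8–15-residue Kyte–Doolittle core
  within the first 40 residues must reach a mean hydropathy of 1.6, and the
  cut is placed after the first small residue (A/G/S/C) following the core.
  This is a deliberately simple stand-in for a trained signal-peptide
  predictor (out of scope); tests on curated fixtures therefore rely on the
  annotation, and only the *relative* position of the heuristic cut is
  asserted.
* **Cleavage sites.** Maximal K/R runs of length 2–3 (di-/tribasic).
  Monobasic cleavage exists in vivo but is rarer and noisier, so it is off
  by default and exposed as a flag. Runs longer than 3 are reported as one
  tribasic site anchored at the C-terminal end of the run, which avoids
  generating zero-length peptides; at excision time each site is extended
  back to its containing run so stray basic residues never enter a peptide.
* **Excision.** Mature peptides are the maximal segments strictly between
  basic runs (basic residues removed, matching the absence of K/R on mature
  neuropeptide termini). Segments shorter than `min_len` (default 4) are
  treated as spacers and dropped.
* **PTMs.** A Gly immediately before a cleavage site is consumed as the
  amide donor: the peptide is amidated and loses the Gly (−0.98402 Da on
  the intact mass). A segment at the precursor C-terminus keeps its Gly and
  stays unamidated. An N-terminal Gln marks a *possible* pyroglutamate; the
  search keeps both forms as variants, mirroring variable-modification
  searching. Met oxidation states are enumerated at library-build time
  (none / oxidation / dioxidation per Met); dioxidation is restricted to
  Met, an assumption the modification catalogue documents. Cys
  carbamidomethylation is fixed when the sample-prep `alkylated` flag is
  set, matching iodoacetamide alkylation.

Coordinates are 1-based inclusive; a trailing `*` (stop codon) is stripped
at parse time. The invariant suite checks that signal peptide, excised
segments and basic runs tile each precursor exactly, and that excision on
generated precursors recovers the embedded payloads, their order, and copy
counts exactly.

## Masses and fragment ions

Monoisotopic and average residue masses ship as a plain-text table; the
proton mass used in all m/z arithmetic is 1.007276 Da (the `[M+H]+` MALDI
convention, not the atomic H weight). Fragment series follow the standard
arithmetic: `b_i` = N-terminal sum + proton, `a_i = b_i − CO`
(27.994915 Da), `y_i` = C-terminal sum + water + proton. N-terminal
modifications shift a/b, C-terminal modifications shift y, residue-site
modifications shift whichever series spans the site. Charge states use
`(m + zH)/z`; the default maximum charge is 1 because MALDI ions are
predominantly singly protonated. The `b_i + y_{n−i} = M + 2H`
complementarity identity is enforced to below 1e-9 Da in the tests.

## Spectrum matching and scoring

Tolerances default to the MALDI-TOF/TOF values this pipeline targets:
200 ppm on precursor (MS) masses, 0.6 Da on fragment (MS/MS) masses, and a
700–4000 Da precursor acquisition window. One numerical choice deserves
note: applied literally, a 700 Da floor would delete most b/y ions of a
~1 kDa peptide, which no fragment search does; the instrument window is
therefore enforced on level-1 peaks and precursor m/z, while level-2
fragment peaks use a wider default range (50–4000 Da).

The library search is enzyme-free: every predicted mature peptide enters
as-is, expanded over its modification variants. Level-1 spectra are matched
by precursor mass only; level-2 spectra additionally get a greedy
nearest-first fragment assignment in which each observed peak is usable
once (so isotope clusters cannot inflate the match count) and ties on
|Δm/z| break toward the lower ion index. The PSM score is the binomial
survival function: with `n` peaks spread over the observed m/z span, a
random ion lands within ±0.6 Da of some peak with probability
`p = min(1, n·2·tol/span)`, and the score is
`−log10 P(X ≥ n_matched), X ~ Binomial(n_theoretical, p)`. This is the
simplest defensible probabilistic score; it is *not* equivalent to Mascot's
and is validated against exact tail enumeration, not against Mascot.
Intensities never enter the match or the score. The best PSM per spectrum
above the score threshold is retained.

The default threshold (1.5) was calibrated once on the packaged seeded null
simulation — level-2 noise-only spectra with random precursors — so that the
noise false-positive rate stays at or below 1%; in practice a noise spectrum
almost never even passes the 200 ppm precursor gate. The threshold lives in
the configuration, not in code.

## Motif scanning, alignment, and family calls

Degenerate motifs are ordered columns of fixed residues, residue classes,
or wildcards; scanning is an exact window scan reporting overlapping
matches and is property-tested against a regular-expression oracle.
Pairwise global alignment uses BLOSUM62 with affine gaps (open −10,
extend −1, the short-peptide standard) and is verified against an
exhaustive enumeration of all alignments on short pairs. Multiple
alignment, where needed, is progressive pairwise alignment to the first
sequence — adequate for the short, near-identical peptide blocks this
package handles and documented as a limitation.

Consensus construction works per column: a fixed residue at ≥ 80%
frequency; a two-residue class `(X/Y)` when the top two residues jointly
reach the majority **and** are conservative substitutes (positive BLOSUM62
score); otherwise a wildcard. The similarity condition is what separates a
genuine class such as (L/I) from coincidental disagreement such as A vs C
in a two-sequence block, which collapses to a wildcard.

Family classification is a rule cascade: `orcokinin_B` when the
D(S/T)(L/I)GGG class motif hits (the Thr variant covers the PYY-type
members whose hexapeptide reads DTLGGG); otherwise `orcokinin_C` when the
orcokinin-C core pattern hits; otherwise `FCAN` when the FCAN consensus
aligns at ≥ 50% identity; otherwise `unclassified`. The strict DS(L/I)GGG
hexapeptide is packaged separately for motif-position reporting. The
orcokinin-C and FCAN pattern entries are synthetic stand-ins (the published
consensus blocks are graphical), so family calls against them are asserted
only on sequences whose family the text states.

## Expression profiling

FPKM tables are descriptive summaries of pooled-animal transcriptomes, so
no replicate statistics are attempted. Profiles can be normalized to a
reference (housekeeping) gene per tissue, and restriction is classified by
a scale-invariant cascade: `silent` (all zero), `CNS_restricted` (all
non-CNS tissues zero), `CNS_dominant` (CNS share ≥ 0.9), else `broad`.

## The synthetic-data generator

The generator's defaults encode the study conditions the pipeline is meant
to handle, and they are not tuned per test:

| parameter | default | what it emulates |
|---|---|---|
| payloads per precursor | 6 | the six-peptide precursor complement |
| repeated payload copies | 7 | the 7-fold multicopy repeat |
| amidated fraction | 0.5 | the mixed amidated / PYY-type complement |
| tribasic site probability | 0.2 | mostly dibasic, occasional tribasic sites |
| ppm error SD | 30 | MALDI reflector mass error (instrument precision better than 50 ppm) |
| fragment m/z SD | 0.1 Da | centroiding error well inside the 0.6 Da tolerance |
| fragment retention | 0.7 | incomplete fragment series |
| noise peaks per MS2 | 20 | chemical/electronic noise |
| tissue panel | ANG, MNG, OvG, PSG, OL, SupEM, SubEM, OG | the 8-tissue panel, CNS = OL/SupEM/SubEM |

Payloads and spacers are K/R-free and payloads never end in Gly unless an
amidation signal is intended, so the excision ground truth is unique.
Noise peaks are added to level-2 spectra; level-1 spectra carry the true
`[M+H]+` values under ppm error. FPKM tables use negative-binomial noise
(size 10) around class means, with a reference transcript positive
everywhere. All outputs are byte-reproducible from `(config, seed)`, and
each generator restores the caller's RNG state.

What the generator does **not** emulate — LC retention, isotope envelopes,
detector saturation, correlated noise, homologous near-miss peptides,
incomplete transcripts — bounds what a passing synthetic run shows: it
validates the bookkeeping and the statistical machinery under the stated
error model, not performance on real tissue extracts.

## Problem sizes and determinism

The packaged validation runs are deliberately small: 2 precursors × 6
payloads, 5 detection tissues (30 embedded peptide–tissue pairs, 85
spectra), 400 noise-only spectra for the false-positive estimate, and
fuzz corpora of a few dozen cases for the motif and alignment oracles
(alignment pairs capped at 8 residues, where exhaustive enumeration is
exact and fast). All randomness flows through explicit seeds; searches and
pipeline commands are deterministic given inputs and configuration.

## Known limitations

* The signal-peptide heuristic is a hydrophobicity rule of thumb, not a
  trained model; curated annotations should be preferred when available.
* The binomial score has no target-decoy FDR control; that is noted as
  future work.
* Charge states above 2 and isotope-aware peak assignment are out of
  scope for MALDI data.
* The FCAN/orcokinin-C patterns are stand-ins; only the orcokinin-B logic
  is anchored to sequences stated in the text.
* Splice-variant structure between the two fixture precursors is stored
  verbatim, not modelled.
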