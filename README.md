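# neuropep

Neuropeptide prohormones are translated as multi-peptide precursors: a
signal peptide, then mature peptides flanked by runs of basic residues
(Lys/Arg) that prohormone convertases cleave, often with a C-terminal
glycine converted into an amide and an N-terminal glutamine cyclized to
pyroglutamate. Confirming the predicted peptides in tissue relies on
peptidomics: matching theoretical `[M+H]+` masses and a/b/y fragment-ion
series against centroided MALDI-TOF/TOF peak lists at ppm/Da tolerances,
and relating the peptides to known families (the orcokinin B/C and FCAN
families, whose hallmark is a conserved DS(L/I)GGG hexapeptide around a GGG
core) by degenerate-motif scanning and global alignment. `neuropep`
implements this entire in-silico workflow for R, aimed at invertebrate
(e.g. cephalopod) neuropeptide studies:

* **prohormone** — cleavage-site detection (di-/tribasic runs, optional
  monobasic), signal-peptide annotation or hydrophobicity heuristic,
  peptide excision with amidation/pyroglutamate rules, copy counting for
  multicopy repeats;
* **peptide chemistry** — monoisotopic/average masses, a fixed modification
  catalogue (amidation −0.98402 Da, pyroGlu −17.02655 Da, Met ox/diox,
  carbamidomethyl-Cys), a/b/y fragment series, variable-modification
  variant enumeration;
* **spectrum matching** — MGF and plain peak-list I/O, 200 ppm / 0.6 Da
  matching, greedy one-peak-one-ion fragment assignment, a binomial-tail
  PSM score, tissue × peptide detection tables;
* **motif & family** — degenerate-motif scanning, BLOSUM62 global alignment
  with affine gaps, consensus-pattern construction, orcokinin-B/C/FCAN
  rule-cascade classification;
* **expression** — FPKM tables, reference-gene normalization, CNS
  restriction calls;
* **synthetic data** — a seeded generator producing ground-truthed
  precursors, spectra, and FPKM tables with exact manifests, so the whole
  pipeline is validated end to end without raw instrument data.

## Worked example

The package ships a synthetic reconstruction of the two FLGamide
(So-orcokinin B) precursors, constrained by the facts published about them;
`flga_fixture()` returns its path.

```r
library(neuropep)

pre <- read_precursors(flga_fixture())
pep <- excise_peptides(pre[[1]])
pep[!duplicated(pep$sequence), c("sequence", "start", "end", "amidated")]
#>               sequence start end amidated
#>  GAESGEAHVFDSLGGGHVPYY    23  43    FALSE
#>          VFDTLGGGHVPYY    46  58    FALSE
#>            FDSLGGGSFLG    61  72     TRUE
#>            DSIGGGSHFLG   159 170     TRUE
#>           NEDSLGGGTFLG   173 185     TRUE
#>          SGDSLGGGHAFYE   189 201    FALSE
```

Six distinct mature peptides: the first two end in PYY and are not
amidated, three carry an amidation glycine before their cleavage site, and
the C-terminal peptide is unamidated. The multicopy peptide appears seven
times on precursor A and eight on B:

```r
count_copies(pep)
#>           DSIGGGSHFLG           FDSLGGGSFLG GAESGEAHVFDSLGGGHVPYY
#>                     1                     7                     1
#>          NEDSLGGGTFLG         SGDSLGGGHAFYE         VFDTLGGGHVPYY
#>                     1                     1                     1

peptide_mh("FDSLGGGSFLG", "amidation")
#> [1] 1055.516
```

`1055.5156` is the singly protonated mass a MALDI search would look for.
The 21-residue peptide carries the family's hexapeptide domain at
position 11 and classifies as orcokinin B:

```r
classify_family("GAESGEAHVFDSLGGGHVPYY")
#> <family_call> orcokinin_B (B hits: 11; C hits: ; FCAN id 0.05)
```

A full synthetic run — generate precursors, spectra and FPKM tables, then
push them back through the pipeline — is three calls:

```r
cfg   <- generator_config(seed = 1)
paths <- run_simulate("sim", cfg)
run_predict(paths$fasta, "sim/peptides.tsv")
run_search("sim/peptides.tsv", paths$mgf,
           psms_tsv = "sim/psms.tsv", detection_tsv = "sim/detection.tsv")
```

A command-line wrapper with the same stages (`predict`, `search`,
`classify`, `expression`, `simulate`) is installed at
`system.file("scripts", "neuropep-cli.R", package = "neuropep")`.

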