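# tmdcover

Transmembrane-domain coverage analysis for bottom-up proteomics, in R.

Membrane-spanning helices (transmembrane domains, TMDs) are chronically
under-sampled in shotgun proteomics: trypsin cuts after lysine and arginine,
which are rare inside the hydrophobic helix, so the peptides that reach the
mass spectrometer mostly come from the soluble loops. `tmdcover` quantifies
how well an experiment actually covers TMDs, and compares sample-preparation
workflows on that axis — for example a urea/trypsin workflow (UR-TLC) against
a formic-acid workflow that adds cyanogen bromide (CNBr) cleavage at
methionine before trypsin/Lys-C (FA-CTLC), which cuts *inside* helices and
releases TMD peptides of detectable length.

It is aimed at proteomics researchers who have (a) a protein database in
FASTA, (b) TMHMM-style topology predictions, and (c) identified-peptide
tables from a search engine — or nobody's data at all, because a seeded
synthetic-data generator makes the entire pipeline runnable offline.

## What it computes

**Peptide-to-TMD classification.** Every occurrence of every detected
peptide is located in the proteome (all positions, including overlapping
ones) and evaluated against every predicted TMD of that protein. A peptide
span *P* and TMD span *T* produce a hit when

* `CONTAINS` — *P* ⊇ *T* (the peptide encompasses the whole helix);
* `WITHIN` — *P* ⊆ *T* (the peptide lies entirely inside the helix);
* `N_PARTIAL` / `C_PARTIAL` — *P* crosses exactly one boundary of *T* with
  an overlap of at least 2 residues (`|P ∩ T| ≥ 2`).

Anything else — in particular a single-residue boundary overlap — is not a
hit. A TMD hit by several peptides counts once: "unique TMDs identified" is
the number of distinct (protein, TMD ordinal) pairs with ≥ 1 hit.

**Supporting analyses.**

* In-silico digestion: trypsin/Lys-C (C-terminal of K/R), CNBr (C-terminal
  of M, converting it to homoserine/homoserine lactone), their sequential
  combination, missed cleavages, optional proline block.
* GRAVY hydropathy: mean Kyte–Doolittle value per residue; score > 0 flags
  a likely membrane protein.
* Protein grouping: accessions sharing an identical set of identified
  peptides collapse into one protein group.
* Method comparison: TMD-count histograms over TMP groups, Pearson χ²
  goodness of fit against the proteome-wide TMD distribution (low-expectation
  bins merged), per-bin two-sample t-tests over replicate fractions,
  replicate reproducibility (|∩| / |∪| with pairwise Jaccard and Venn
  counts), and exact two-sided binomial enrichment of functional categories
  with Benjamini–Hochberg correction.
* Synthetic data: seeded proteomes with planted TMD architectures and
  per-method Bernoulli peptide-detection models, plus a hydropathy-window
  surrogate TMD predictor (clearly labelled `surrogate-window`) so no
  external predictor is needed.

## Worked example

```r
library(tmdcover)

cfg <- sim_config(n_proteins = 200)        # synthetic study conditions
gen <- generate_proteome(cfg, seed = 7)
det <- dplyr::bind_rows(
  simulate_detection(gen$proteome, gen$tmds, cfg, "UR-TLC",  seed = 7),
  simulate_detection(gen$proteome, gen$tmds, cfg, "FA-CTLC", seed = 7)
)
cmp <- compare_methods(det, gen$proteome, gen$tmds)
tidy(cmp)[, c("method", "n_protein_groups", "tmp_fraction",
              "unique_tmd_count", "gravy_positive_fraction")]
```

```
# A tibble: 2 × 5
  method  n_protein_groups tmp_fraction unique_tmd_count gravy_positive_fraction
  <chr>              <int>        <dbl>            <int>                   <dbl>
1 UR-TLC               197        0.173                7                  0.0102
2 FA-CTLC              199        0.181               46                  0.0101
```

Both workflows identify nearly every synthetic protein (loop peptides are
equally detectable under either chemistry), but the CNBr-based workflow
recovers 46 of the planted TMDs against 7 for the urea workflow — the
helix-interior cleavage is what gives peptides access to the membrane-embedded
segments. `plot_tmd_histogram(cmp)` draws the per-bin TMD-count
distributions with replicate error bars and significance stars, and
`glance(cmp)` condenses the contrast into one row.

The same analysis runs from the shell:

```sh
Rscript inst/cli/tmdcover.R demo --seed 7 --out demo_out
```

writes the simulated dataset plus `method_summary.tsv`, `histogram.tsv`,
`chisq.txt`, `ttest.tsv`, `reproducibility.tsv`, per-method hit tables and
BED-style coverage maps, all byte-reproducible for a fixed seed. Subcommands
`digest`, `gravy`, `predict-tmd-surrogate`, `map-tmd`, `compare` and
`simulate` expose the individual stages for real data.

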