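---
title: "Measuring transmembrane-domain coverage: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transmembrane-domain coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmdcover)
```

## The problem

Transmembrane proteins (TMPs) carry one to several dozen membrane-spanning
helices (TMDs) of roughly 18–25 mostly hydrophobic residues. In bottom-up
proteomics the protein is digested to peptides before mass spectrometry, and
trypsin/Lys-C cuts after lysine and arginine — residues that are rare inside
a membrane helix. The tryptic peptide that contains a helix is therefore
often too long, too hydrophobic, or simply never released from the membrane,
and TMDs end up systematically under-represented even when their parent
proteins are identified from loop peptides. Chemical cleavage with cyanogen
bromide (CNBr), which cuts after methionine and converts it to homoserine
(Hse) or homoserine lactone (Hsl), introduces cut sites *inside* helices and
is the mechanism by which a formic-acid/CNBr workflow (here labelled
FA-CTLC) is expected to outperform a urea/trypsin workflow (UR-TLC) at
TMD-level coverage.

`tmdcover` makes that comparison quantitative: it classifies every detected
peptide against every predicted TMD, counts distinct TMDs with evidence, and
wraps the surrounding statistics.

## The hit model

For a peptide occurrence spanning residues $P = [p_1, p_2]$ and a TMD
spanning $T = [t_1, t_2]$ (both 1-based, inclusive):

* `CONTAINS` when $P \supseteq T$; `WITHIN` when $P \subseteq T$
  (containment in either direction is a hit regardless of overlap length);
* `N_PARTIAL` / `C_PARTIAL` when $P$ crosses exactly one boundary of $T$
  and $|P \cap T| \ge m$, with $m = 2$ by default;
* otherwise no hit — in particular a peptide touching a helix in exactly one
  residue.

Three tie-breaks are worth stating because they are invisible in the rules
above. Identical spans classify as `CONTAINS`, so `CONTAINS` and `WITHIN`
are mutually exclusive. A peptide that protrudes beyond both boundaries is
`CONTAINS` (precedence over the partial categories). The overlap minimum
$m$ applies only to boundary-crossing peptides; a short peptide entirely
inside a helix is accepted, subject only to the global minimum peptide
length (default 6, the usual search-engine floor).

"Unique TMDs identified" counts distinct (protein, TMD ordinal) pairs with
at least one hit: a helix covered by five peptides is one identified helix.
Because reporting conventions differ, `count_peptide_tmd_pairs()` exposes
the per-peptide count as well.

Peptides are located by exact substring matching (all occurrences, including
overlapping ones, in every matching protein). Isoleucine/leucine
equivalence is available (`il_equivalent = TRUE`) but off by default: when
the peptide tables come from a search against the same database, exact
matching reproduces the search engine's own placements. Peptides matching
more than one protein contribute to every match (protein grouping absorbs
the redundancy); `unique_only = TRUE` restricts to single-protein peptides.

## Digestion

Cleavage rules are site sets with optional next-residue exceptions:
trypsin/Lys-C cuts after K/R, CNBr after M. Two deliberate choices:

* **No proline block by default.** The modelled search-engine specificity is
  plainly "C-terminal of K and R"; the classical KP/RP exception is
  available via `block_proline = TRUE`.
* **Homoserine bookkeeping.** CNBr's Met→Hse conversion is recorded on the
  C-terminal residue of fragments produced by an actual cleavage; a
  protein's native C-terminal methionine is not converted, because no
  cleavage event touched it. `normalize_homoserine()` strips `(Hse)`/`(Hsl)`
  annotations so peptides match the database-space sequence, and rejects
  markers on non-methionine residues.

Sequential digestion (CNBr then trypsin/Lys-C) keeps coordinates in protein
space; at zero missed cleavages it is provably identical to a single pass
with the union of site sets, which is also how a search engine states the
combined specificity ("C-terminal of M, K and R") — provided as
`rule_cnbr_trypsin_lysc()`. For multi-stage digests with missed cleavages,
a fragment's `missed_cleavages` is defined against the union of all stages'
site sets, which makes it a property of the fragment's span rather than of
the generation path. The default missed-cleavage allowance is configurable
everywhere; the detection simulation uses 0 (see below).

## Hydropathy

GRAVY is the mean Kyte–Doolittle hydropathy per residue; the scale is the
published 20-residue table (I = 4.5 … R = −4.5). A protein is called
hydrophobic when GRAVY is strictly greater than 0 — exactly 0 is *not*
hydrophobic, a boundary decision that is documented and tested rather than
left to floating-point accident. Unknown residues (e.g. `X`) are an error
by default; `skip_unknown = TRUE` removes them from both numerator and
denominator.

The package also ships a sliding-window surrogate predictor (19-residue
centred mean, runs strictly above 1.6 of length ≥ 18) whose only purpose is
to let the full pipeline run without an external topology predictor. It is
labelled `surrogate-window` in every output and is *not* an HMM; on real
data you should feed TMHMM (or comparable) output, which the parser accepts
in both its long and short text dialects.

## Comparison statistics

* **TMD histograms** are computed over TMP protein groups (≥ 1 TMD), with
  zero-TMD groups reported separately; bins are 1…10 and ">10". A group's
  TMD count is the **maximum** over member proteins — conservative in the
  sense that a group is as membrane-bound as its most membrane-bound member
  (the mean is selectable).
* **χ² goodness of fit** compares a method's histogram against the
  proteome-wide TMD distribution. Bins with expected count < 5 are merged
  right-to-left into their left neighbour and the merges logged; with fewer
  than two usable bins the test is reported as not testable rather than
  fabricated.
* **Per-bin t-tests** compare the two methods' per-replicate bin fractions
  with a classical two-sided Student t-test (Welch selectable), starred at
  0.05 and 0.01. Zero variance in both groups is degenerate and flagged.
* **Reproducibility** across replicates is |intersection| / |union| × 100.
  No standard definition exists for "x% reproducible" in proteomics
  reporting, so the pairwise Jaccard table and the full Venn region counts
  are emitted alongside, letting any alternative be recomputed.
* **Binomial enrichment** tests each functional category's count in method A
  against the pooled proportion $(a+b)/(n_A+n_B)$, exact and two-sided, with
  Benjamini–Hochberg q-values across categories (raw p-values are retained;
  a screen across ~20 categories without correction overstates itself).

## The synthetic study conditions

The generator exists so that every stage of the pipeline can be exercised,
timed and demonstrated without any download. Its defaults are the study
conditions; they are fixed once and the tests are written against them.

| parameter | default | why |
|---|---|---|
| proteins | 1000 | desk-scale stand-in for a proteome; large enough that per-method fractions are not dominated by O(1/n) sampling noise |
| TMP fraction | 0.23 | typical predicted-TMP share of a plant proteome |
| TMDs per TMP | geometric, ~½ mass at 1, truncated at 30 | about half of real TMPs are single-spanning; transporters reach dozens |
| TMD length | 18–25, uniform | canonical helix span |
| loop length | exponential, mean 60 | inter-helix and terminal soluble stretches |
| soluble length | lognormal, median 300 | typical protein length |
| detectable peptide | 6–45 residues | search-engine length window |
| replicates | 3 | standard biological triplicate |
| detection, loop peptide | 0.30 (both methods) | loops are equally accessible to both chemistries |
| detection, TMD peptide | 0.02 (UR-TLC) / 0.20 (FA-CTLC) | the helix-access difference that is the phenomenon of interest |
| missed cleavages | 0 | simplest candidate set; the detection probabilities already absorb incomplete digestion |

TMP sequences are alternating hydrophilic loops (rich in D/E/K/R/S/G) and
hydrophobic TMD blocks (rich in I/L/V/F/A with ~6% M so CNBr can cut inside
them); compositions are fixed tables so hydropathy behaviour is identical
across platforms. Detection is peptide-wise independent Bernoulli — a
candidate peptide overlapping a true TMD by ≥ 2 residues uses the method's
TMD probability, any other its loop probability — with replicate sub-seeds
derived deterministically from the master seed (so adding a replicate never
perturbs earlier ones). Everything downstream of the generator is the real
pipeline: the simulated tables are written to disk, re-read through the
parsers, mapped and compared exactly as user data would be.

**What the simulation does not model.** Protein abundance and dynamic range
(the dominant cause of irreproducibility in real runs — simulated
replicate reproducibility is therefore far higher than the ~50% seen in
practice), ionization/retention behaviour, FDR and decoys, modification
chemistry beyond homoserine, and solubilization differences at the protein
level. Whole-protein GRAVY under the default loop model is dominated by the
hydrophilic loops, so the fraction of identified proteins with GRAVY > 0 is
only a few percent — much lower than the ~17–20% of real proteomes — and
the GRAVY comparison between methods is meaningful only directionally. A
passing test suite therefore shows that the algorithms are correct and that
the method contrast has the expected direction under a mechanism-only
model; it does not certify magnitudes on real data.

## Numerical and degenerate-input policy

Strict inequalities are used at every documented boundary (GRAVY > 0,
profile > threshold, partial overlap ≥ 2). The χ² statistic is computed as
$\sum (O-E)^2/E$ with $df = \text{bins} - 1$ and an upper-tail p-value; the
t-test falls back to p = 1 (equal means) or a flagged p = 0 (unequal means)
when both groups have zero variance. Empty sequences, empty peptide cells,
out-of-bounds TMD intervals, duplicate accessions, Hse markers on
non-methionine, and PredHel/Topology disagreements are all hard errors that
name the offender. Orphan peptides (no database occurrence) and promiscuous
peptides (> 100 proteins) are kept and reported, not silently dropped.

## Problem sizes used by the test suite

The correctness properties run against brute-force oracles: 10,000 random
span pairs for the hit classifier, 1,000 random sequences (10–2,000
residues) for digestion tiling and missed-cleavage enumeration, 1,000
shuffles for GRAVY invariance, 200 null simulations for t-test calibration,
and 100 seeded end-to-end runs for the directional method contrast. These
sizes were chosen to make the binomial/sampling error of each check small
relative to the property being asserted while keeping a full run on one CPU
comfortable.
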