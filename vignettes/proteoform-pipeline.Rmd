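---
title: "Proteoform-level identification, quantification and variant filtering"
author: "proteoforma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteoform-level identification, quantification and variant filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoforma)
```

## The analysis

Top-down proteomics assigns tandem mass spectra to intact proteoforms,
producing per-run tables of proteoform–spectrum matches (PrSMs): a spectrum
identifier, a protein accession, a proteoform string, a neutral
monoisotopic precursor mass, an E-value and a feature intensity, plus the
run context (condition, replicate, fraction). In a deep two-state
comparison those tables come from hundreds of runs and contain a mixture of
correct matches, incorrect target matches, and decoy matches from a
shuffled companion database. `proteoforma` implements the downstream
computation: merge, two-tier false discovery rate control, proteoform
clustering, label-free quantification, differential testing, profiling,
and a confidence filter for single amino acid variant (SAAV) proteoforms.

## Target–decoy FDR, in two tiers

All PrSMs are pooled and ranked by ascending E-value, ties grouped. With
$D(k)$ and $T(k)$ the decoy and target counts at or above rank $k$, the raw
FDR estimate is

$$\widehat{\mathrm{FDR}}(k) = \frac{D(k)}{\max(1, T(k))},$$

and the q-value of rank $k$ is the minimum raw FDR over all ranks at or
below it, so q-values are monotone non-decreasing in E-value. The $D/T$
convention (rather than $(D+1)/T$) matches the tool family that produces
these tables. Validity rests on the exchangeability assumption: incorrect
target matches and decoy matches are draws from the same score
distribution, so the decoy count estimates the incorrect-target count at
any cutoff.

Filtering happens twice. First at the spectrum level (default 5%): both
targets and decoys passing the threshold are kept, because the decoy
survivors are needed for the second tier. Survivors are clustered into
proteoforms (next section) and the cluster representatives — one scored
item per cluster, inheriting decoy status — are filtered at the proteoform
level (default 1%; 5% is conventional for variant-database searches, where
the target space is larger and the stakes per identification higher). Only
then are decoys discarded.

The package filters the merged set of all runs, not per-run sets;
computing FDR per search and merging afterwards is a documented alternative
the pipeline does not take, since the merged set is what the proteoform
tier operates on.

## Proteoform clustering

PrSMs matching the same protein accession whose precursor masses differ by
at most `mass_tol` (default 2.2 Da) are considered the same proteoform.
The window is deliberately wider than any ppm-scale measurement error: its
purpose is to absorb ±1 and ±2 Da isotopologue errors from spectral
deconvolution (1.00235 Da per misassigned isotope peak). The boundary is
inclusive (a difference of exactly 2.2 Da merges); masses are compared in
Da, not ppm, because the window models an absolute error mode.

Linkage is greedy best-score seeding: within each protein, the unassigned
PrSM with the lowest E-value (ties broken by lexicographic spectrum id)
seeds a cluster and collects every unassigned PrSM within the window of the
seed mass. This makes the rule "the best E-value PrSM is the cluster
representative" well-defined by construction, bounds the within-cluster
mass spread at twice the window, and is independent of input row order.
Decoy PrSMs are clustered by the identical procedure — necessary for the
proteoform-level decoy counts to be comparable with target counts.

## Label-free quantification

The abundance of a proteoform in one replicate is the sum of its feature
intensities over the fractions of that replicate (duplicates within a
fraction resolve to the maximum, which is deterministic and conservative
against double counting). Missing fractions contribute zero; a proteoform
with no measured intensity anywhere in a replicate is missing, not zero.
Summation precedes any ratio computation — the only order consistent with
one abundance value per run.

Cross-run matching re-clusters the union of per-replicate representatives
with the same protein/mass-window rule (the matching tolerance defaults to
the same 2.2 Da as clustering; it is a separate, configurable parameter).
Rows with a value in every run ("complete cases") are kept — no imputation
is attempted — and normalized in three steps: divide each cell by the
same-row cell of the reference run (converting intensities to ratios);
divide each column by its median so ratios center at 1 exactly (the median
of an even-length column is the mean of the central order statistics);
log2-transform. The composition is scale-equivariant: multiplying any
input column by a positive constant leaves the final matrix unchanged,
which is the property that makes per-run loading differences irrelevant.

## The differential test

On the log2 matrix the package computes the S0-moderated statistic

$$d = \frac{\bar{x} - \bar{y}}{s + s_0}, \qquad
  s = s_p\sqrt{1/n_x + 1/n_y},$$

with $s_p$ the pooled standard deviation. With $s_0 = 0$, $d$ is exactly
Student's equal-variance $t$; with $s_0 > 0$ (default 1, applied on the
log2 scale where the test runs) low-variance rows are damped, which is the
practical content of the Perseus "S0" setting. The exact curved-threshold
rule Perseus applies varies subtly across versions; this package
implements the SAM-family formulation explicitly and documents it as a
reimplementation, not a Perseus call.

Significance is assessed by permuting condition labels. A balanced shuffle
reassigns the labels preserving group sizes. The observed labeling and its
mirror are excluded from the null set: they reproduce the observed
statistics rather than the null, and including them imposes a hard floor
of $2/\binom{n}{n_1}$ on every q-value — in a 3 vs 3 design the floor
would be 0.1, making a 5% FDR threshold unreachable by construction, which
contradicts how this test is used in practice. With the exclusion, a 3 vs
3 design has 18 informative shuffles, all enumerated; larger designs fall
back to seeded sampling of `n_permutations` shuffles (default 1000). The
q-value of row $i$ is an $E[V]/R$ estimate — the mean over shuffles of the
fraction of permuted $|d|$ at or above $|d_i|$, divided by the fraction of
observed $|d|$ at or above it — capped at 1 and monotonized. A row is
significant when $q \le$ `fdr` (default 0.05).

Simple two-group mean ± SD comparisons elsewhere in the workflow (overlap
percentages, correlation summaries) use the classical equal-variance
two-tailed $t$ test; degenerate zero-variance inputs report the numeric
underflow floor rather than a literal zero p-value.

## Profiling

The overlap of identification sets is directional: the cell for set A on
the x-axis against set B on the y-axis is $|A \cap B| / |B|$, so each row
reads "what fraction of B was also seen in A".

The PTM census assigns each modified proteoform to at most one nominal
mass-shift bin by its total modification mass (named modifications plus
unexpected shifts; carbamidomethylation is excluded as a fixed search
artifact). Bins: +42 (N-terminal acetylation, isobaric with trimethylation
at nominal resolution — the bin is labeled accordingly and additionally
requires a modification span covering core position 1), +80/+160
(single/double phosphorylation), +14 (methylation), +16 (oxidation), +122
(acetyl + phospho), +96 (phospho + oxidation), +58 (acetyl/trimethyl +
oxidation). The default bin half-width is 1.5 Da: shift annotations on
intact proteoforms are nominal (printed values like 78 or 81 Da for
phosphorylation occur), so binning tighter than ~1 Da would misclassify;
the tolerance is configurable and reported with every census. Proteoforms
fitting no bin are counted as unassigned, never double-counted.

A proteoform family summary covers the proteoforms of one gene: the start
position histogram, each proteoform's share of the family PrSM count (a
rough relative-abundance estimate), and the intact/truncated split.
"Intact" is operationalized as start position ≤ 2 (N-terminal methionine
removal allowed) with the end at the full protein length.

## SAAV confidence filtering

Variant databases add one entry per single-residue substitution, accession
suffixed with the variant (e.g. `P04637_P72R`); reference entries are
retained. Theoretical b/y fragment masses are

$$b_k = \sum_{i \le k} m_i, \qquad
  y_k = \sum_{i > n-k} m_i + m_{\mathrm{H_2O}},$$

with fixed carbamidomethylation on cysteine; only b/y series are used,
matching collisional dissociation. A localized modification contributes to
a fragment only when the fragment fully contains its span.

A SAAV proteoform identification is confident when it carries no
unexpected mass shift — in that case the precursor mass itself pins the
variant — or when every SAAV site has at least three matched fragment ions
(15 ppm) whose backbone cleavage lies strictly between the variant residue
and the nearer edge of the shift's localization interval. Those flanking
cleavages are the ones that separate the variant evidence from the
unexplained mass; ions beyond the shift cannot disambiguate the two.
Counting is per ion species (a matched b and a matched y at one cleavage
contribute 2): the evidence unit in spectrum annotation is the matched
ion, not the cleavage site. A site inside the shift interval has no
flanking corridor and cannot reach the threshold. An alternative reading —
counting ions on either side of the site — is available behind the
interval argument (pass the full core span), but the corridor reading is
the default because it is the one that actually excludes shift/variant
confusion.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the analysis assumes: 2 conditions × 3 technical replicates × 6
fractions; true-hit E-values log-uniform on $[10^{-12}, 10^{-5}]$ and a
single shared false-target/decoy distribution log-uniform on
$[10^{-4}, 10^{1}]$ (the exchangeability that makes target-decoy FDR
valid); precursor ppm noise with SD 2 ppm and a 2% chance of a
±1.00235 Da isotope error (exercising the 2.2-Da window); per-proteoform
base log2 abundance normal over a 20–30 range (mean 25, SD 2.5) with a
0.5-log2 run effect; unimodal Gaussian fraction profiles; detection by a
logistic draw on log2 intensity (midpoint 16, slope 1), so missingness is
intensity-dependent rather than completely at random — the complete-case
filter is therefore meaningfully exercised; 10 spiked proteoforms with
log2 fold changes from {−2, −1, 1, 2}; 5 SAAV proteoforms with fragment
coverage probability 0.7. The defaults were chosen once as plausible
desk-scale values: nothing in the source workflow characterizes its actual
E-value or intensity distributions, so these are stated assumptions, not
estimates from real data.

Structural choices worth knowing:

* Each (proteoform, run) slot is a true attempt with probability
  `true_hit_fraction` and otherwise emits one noise record, equally likely
  a false target or a decoy. Decoys are independent records against
  shuffled-accession proteins — the simplest model under which $D/T$
  estimates FDR.
* Proteoform masses within one protein are kept at least 5 Da apart, so
  truth-registry identity is well-defined under the 2.2-Da window and the
  noise-free pipeline recovers the registry exactly.
* Fragment jitter is drawn strictly inside the 15-ppm matching tolerance
  (±14.9 ppm), so retained fragments always re-match; the boundary case is
  exercised separately in unit tests, not left to floating-point luck.
* Isoleucine is excluded from generated sequences (leucine is kept):
  the two are isobaric and would create artificial mass-identical
  proteoforms.
* All randomness derives from a single integer seed via fixed per-module
  offsets; the same configuration reproduces byte-identical tables, and
  the caller's RNG state is left untouched.

What the generator does **not** emulate: spectra (no isotope clusters, no
fragment intensity models, no m/z peak lists beyond neutral fragment-mass
lists), chromatographic or electrophoretic structure beyond a smooth
fraction profile, correlated modifications, shared peptides across genes,
or realistic E-value dependence on proteoform length. Passing tests
therefore demonstrate that the pipeline's logic is correct under its
stated assumptions — calibrated FDR under exchangeability, exact recovery
without noise, unbiased fold-change recovery — not that those assumptions
hold for any particular instrument or search engine output.

## Numerical choices and degenerate inputs

* E-values must be strictly positive; zero or unparseable rows are
  rejected at read time with a reported count.
* Ties in E-value share one rank group and one q-value, so FDR results are
  independent of input order.
* "Not larger than 2.2 Da" is implemented as ≤ (inclusive).
* Constant columns yield missing (not crashing) Pearson correlations; a
  single value has an undefined sample SD, reported as missing.
* Zero reference-run abundances drop the row with a warning rather than
  producing infinities.
* The permutation q-value is capped at 1 and monotonized by a running
  minimum from the least significant row upward.

## Problem sizes

The test suite and the acceptance script run the calibration suites at
desk scale, chosen so each suite completes in well under a minute while
keeping binomial error informative: 20 seeds of ~6,000–7,500 PrSMs for the
two-tier FDR calibration; 20 small no-missingness simulations for
fold-change recovery; 8 replicates of a 500-row matrix with 50 spiked rows
(|log2 FC| = 2, σ = 0.35, 3 vs 3) for power; 20 null matrices of 300 rows
for the null false-discovery proportion. Tolerances on stochastic
quantities are three standard errors computed from the runs themselves
(with a small floor for granularity), not tuned constants.

## Known limitations

* Cross-protein clustering (proteoform families sharing sequence across
  accessions) is out of scope; clustering keys on the accession.
* No imputation and no batch correction; the quantification path is the
  complete-case, reference-ratio design described above.
* Indel variants are accepted in variant tables but skipped when building
  entries; only substitutions generate variant sequences.
* The permutation FDR with few replicates has coarse granularity; with 18
  informative shuffles the smallest nonzero q increments are ~0.056/R, and
  the E[V]/R estimate is anti-conservative at the very top rank: under a
  complete null in a 3 vs 3 design the probability of at least one
  (necessarily false) discovery at q ≤ 0.05 is roughly 0.1 rather than
  0.05. This is intrinsic to plug-in permutation FDR with tiny shuffle
  sets, not specific to this implementation; more replicates, not more
  permutations, are the cure.
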