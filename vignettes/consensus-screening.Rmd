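---
title: "Consensus screening of TPMT missense variants: methods and design"
author: "tpmtscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus screening of TPMT missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmtscreen)
```

## The problem and the model

Thiopurine S-methyltransferase (TPMT, 245 residues, UniProt P51580)
inactivates thiopurine drugs; missense variants that destabilise the enzyme
or impair its function cause severe treatment toxicity. In-silico effect
predictors are cheap but individually unreliable, and their outputs are
heterogeneous: categorical labels of many vocabularies, stability changes
in kcal/mol, melting-point shifts in °C, probability scores. `tpmtscreen`
treats a panel of such predictors as a set of noisy, approximately
independent votes around a latent deleterious/benign state, and prioritises
variants by a two-stage k-of-n consensus:

1. **Stage 1 (sequence evidence):** at least `kSeq = 9` of `nSeq = 12`
   sequence-based tools must call the substitution deleterious.
2. **Stage 2 (structural evidence):** at least `kStruct = 6` of
   `nStruct = 8` structure-based stability predictors must call it
   destabilising.

The consensus rationale is that the tools' methodological diversity makes
coincident false positives unlikely; formally, if tool $t$ votes with
probability $p_t$ conditional on the truth state, the stage pass
probability is the Poisson-binomial tail $P(\sum_t X_t \ge k)$. The package
carries this analytic model alongside the empirical pipeline
(`consensusOperatingPoint()`, `operatingCharacteristics()`) so the screen's
operating point can be computed exactly rather than estimated.

## Harmonisation choices

All raw outputs are mapped to `NEUTRAL < DELETERIOUS <
STRONGLY_DELETERIOUS`, with `UNKNOWN` for missing or unmappable cells.

* **Label vocabulary** (`defaultVocabulary()`): damaging-family labels —
  including PolyPhen-2 "Possibly damaging" and Mutation Assessor "Medium" —
  count as `DELETERIOUS`. This borderline-inclusive reading is required for
  internal consistency of the bundled candidate table, where variants
  retained by the 9-of-12 rule carry such labels; "Low" and the
  benign-family labels count as `NEUTRAL`. Matching is case-insensitive
  after whitespace normalisation, and anything unmapped sinks to `UNKNOWN`
  with a warning rather than an error, so one stray cell cannot abort a
  screen.
* **Score rules** (`defaultScoreRules()`): PoPMuSiC ΔΔG > 0 destabilising,
  ≥ 4 kcal/mol strong; HoTMuSiC ΔTm < 0, ≤ −10 °C strong; SNPMuSiC > 0,
  ≥ 1 strong; CScape family p-score strictly above 0.5 oncogenic. The
  strong cutoffs are descriptively "close to" these values in the tools'
  documentation; we implement them as inclusive comparisons at exactly
  4 / −10 / 1 with zero tolerance, because a guessed fuzziness would be
  irreproducible. Every cutoff is overridable. By construction a strong
  score call always satisfies the destabilising condition, so severity
  order is respected. Both pathways (verbal labels and numeric scores) are
  provided because either may be the primary record; they agree wherever
  both exist.
* **MuSiC strictness:** discovery screening uses *strict* mode (the MuSiC
  trio votes only on strong calls — the screen is hunting the most
  deleterious variants), validation uses *lenient* mode (any destabilising
  call votes — the benchmark re-detects variants already known to be
  deleterious). This asymmetry is deliberate and is exposed as
  `musicMode`.
* **Missing data:** `UNKNOWN` counts against the variant (the vote
  denominator stays at the panel size), except that a variant whose entire
  structural panel is `UNKNOWN` — e.g. M1V, whose residue is absent from
  the 2H11 crystal structure — is flagged non-evaluable, fails stage 2,
  and is excluded from validation denominators. Residue numbering is
  always 1-based on the full UniProt sequence; missing structure is data,
  never a renumbering.

## Bundled tables

The package ships curated call tables for 53 consensus-candidate TPMT
substitutions (12 sequence-tool labels each), the structural calls of the
six stage-2 passers, and 25 experimentally characterised variants with 20
calls plus study-level evidence each (`tpmtExample()`). Two encoding
decisions matter:

* The structural candidate table as published interleaves sub-predictor
  columns (mCSM/SDM/DUET components, SVM/NN sub-methods) with the eight
  voting tools, with ambiguous header alignment. The bundled table adopts
  the unique reading under which every row satisfies the strict 6-of-8
  rule its caption asserts: four destabilising-family cells map to CUPSAT,
  DUET, I-Mutant 3.0 and MUpro, the first "Decrease" to INPS-MD, the three
  MuSiC-vocabulary cells to PoPMuSiC, HoTMuSiC and SNPMuSiC, and the
  remaining sub-predictor cells ride along as non-voting `aux_*` columns
  (collapsed to one call per tool; the reader reports and skips them into
  an `auxiliary` attribute).
* The gold-standard table's `tools_reported` column is an annotation, not
  an input: the pipeline recomputes votes from the calls. For three rows
  (A167G, Y240C, Y240S) the recorded cumulative count exceeds the calls
  present in the row by one; the consistency test documents the
  discrepancy, and no downstream number depends on the column.

`extremely_deleterious` membership is carried as an explicit curated
column: the verbal rule (very dangerous in multiple studies, or very
dangerous with corroborating reports) is also implemented in
`classifyEvidence()` for tables without the column, but applied blindly to
the tabulated reports it would swap one member (M1V for Y240S, whose wider
experimental literature is not itemised in the table). Data beat
re-derivation here; the column is user-editable.

## Relative deleteriousness scoring

Eight categories are scored per candidate mutation: sequence-tool and
strict structure-tool vote counts (SQBT, SRBT), a cumulative conservation
score, summed CScape/CScape-somatic p-scores, binding-pocket impact (Å³),
distances to the nearest amyloid-forming region and PTM site (residues),
and a molecular-dynamics binding-energy shift (kJ/mol). Each category is
normalised to its worst mutation (`100·value/max`), proximity categories
are inverted (`100 − …`) because *smaller* distances are worse, and the
`Total` is the renormalised row sum. Numerical conventions: ties at the
maximum all score 100; an all-zero worth category scores 0 everywhere with
a warning; an all-zero proximity category scores 100 everywhere (everything
sits inside a region); negative worth values are an error directing the
caller to re-baseline — which is exactly why the binding-energy category
uses `bindingEnergyScore()`, the difference ΔG~mutant~ − ΔG~wild-type~,
rather than raw (negative) binding energies: normalise-by-maximum is
ill-defined for negative values, and the difference makes weaker binding
score worse. SRBT uses strict-mode vote counts, consistent with the
discovery screen that produced the candidates.

The bundled feature table mixes computed/printed values (votes, oncogenic
sums, amyloid distances, binding-energy shifts, three of five PTM
distances) with entries whose sources are supplementary materials we do
not have: per-residue CDD conservation counts, two ConSurf colour scores
known only to be "8 or 9", CASTp pocket-volume changes, and the PTM
distances of W78R and W150G. Those entries are synthetic stand-ins chosen
once to be consistent with the qualitative record and flagged
`provenance = "synthetic"` in the file. The headline ranking
(W33G > W150G > V89E > L182P > W78R, W33G = 100) emerges from the table;
tests that depend on synthetic entries establish internal consistency of
the scoring procedure, not independent confirmation of those raw values.

## The synthetic panel generator

`simulatePredictions()` emulates exactly the structure the screen assumes:
a latent Bernoulli truth per variant (default prevalence 0.3, a screening
regime where most catalogue variants are benign), conditionally
independent label tools with per-tool sensitivity/specificity (default
0.9/0.9, typical mid-range accuracy for effect predictors), truth-
conditional Gaussian scores for the MuSiC trio (defaults put deleterious
variants at ~95% destabilising-call rate with tool-dependent strong-call
rates of ~16–60%, benign variants at ~10% false calls), an optional
per-cell missingness rate, and an optional common-latent-factor
correlation knob for robustness studies (the analytic operating points
assume independence and warn otherwise). Reproducibility is defined by the
seed in the config: a fixed seed gives byte-identical output.

What the generator does **not** emulate: real predictors share training
data and evolutionary features, so their errors correlate positively in
ways a single latent factor only sketches; score distributions are not
two-component Gaussians; and accuracy varies by residue context. Passing
tests therefore certify the pipeline's arithmetic and its agreement with
the exact Poisson-binomial analytics under the stated error model — not
the real-world operating point of any predictor panel.

Problem sizes used in the test suite were chosen for tight Monte-Carlo
bounds at interactive runtimes: 20 000 variants for the
simulation-vs-analytics comparison (3 standard errors ≈ 1.5 percentage
points), 8 000–10 000 for missingness and correlation checks, exhaustive
enumeration up to panels of 12 for the Poisson-binomial oracle.

## Limitations

* The screen inherits every bias of its member predictors; the consensus
  reduces variance, not shared bias.
* Vote thresholds (9/12, 6/8) are the pipeline's defining constants, not
  fitted parameters; `screeningConfig()` exposes them for sensitivity
  analyses.
* The relative-score Total weights all categories equally on the
  normalised scale; categories with compressed dynamic range (e.g. SQBT,
  where all candidates hold 12/12 votes) contribute no discrimination.
* Molecular-dynamics quantities (binding energies) and external server
  outputs (conservation, pockets, PTM maps) are consumed as inputs; the
  package computes nothing about them beyond re-baselining and
  normalisation.
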