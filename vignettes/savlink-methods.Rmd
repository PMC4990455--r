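---
title: "Linking molecular-effect predictions of protein variants to disease: methods"
author: "savlink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{savlink methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Single amino acid variants (SAVs, written `XnY`: wild-type residue `X` at
1-based position `n` replaced by `Y`) can disrupt a protein's molecular
function, and a subset of such disruptions manifests as Mendelian disease.
Computational predictors assign each SAV a score that is thresholded into a
binary *effect* / *neutral* call. savlink provides the analysis machinery for
asking how such molecular-effect calls relate to disease annotations:

* validating curated disease-SAV tables against protein sequences,
* lifting variants across species through pairwise global alignment,
* building *conservation-matched* null variant sets that control for the
  single strongest confounder — sequence conservation at the variant
  position,
* summarizing binary calls per labeled set (effect fractions with bootstrap
  intervals, pairwise method agreement), and
* simulating synthetic protein families with all of the statistical
  structure the analysis assumes, so the whole pipeline is testable without
  any external database.

## Curated-variant validation

Curated annotations frequently disagree with the sequence they reference.
`validate_variant()` classifies each record: *match* (the sequence carries
the wild-type residue at the annotated position), *match+1* (the residue is
found one position to the right, which happens when a database sequence is
stored without its initiator methionine), *mismatch*, *no sequence*,
*synonymous*, plus *aa-deletion* and *nonsense* categories that are recorded
and excluded from SAV analysis. Only the single `+1` offset is ever tried;
searching over arbitrary offsets would rescue annotations at the price of
silently re-interpreting them. The plain match is checked first and the
shift only applies when it fails. We note a tension in the convention: a
sequence stored *without* its initiator methionine shifts annotations made
*with* the methionine to the left, so the direction of a `+1` correction
depends on which coordinate system the curator used; the package implements
the `+1` check literally and surfaces shifted records with a `shifted` flag
so users can audit them.

The package ships a **synthetic** stand-in for a curated animal-disease SAV
table (`inst/extdata/synthetic_s2_variants.tsv` with matching sequences),
constructed to the marginals such curation efforts report: 117 SAVs over 99
distinct sequences, a taxon composition dominated by dog (46/117 ≈ 39%) and
cattle (25/117 ≈ 21%), and 110 plain plus 7 shift matches. It exercises
every reader and the attrition protocol; it contains no real gene symbols,
sequences or diseases.

## Cross-species variant transfer

Ortholog pairs are aligned with global affine-gap alignment (BLOSUM62,
gap open −10, gap extend −0.5 by default, terminal gaps penalized). The
cost model charges the opening penalty for the first gap character and the
extension penalty for each further one, so a length-`k` run costs
`open + (k−1)·extend`. The dynamic programming is delegated to
`Biostrings::pairwiseAlignment()` with penalties mapped onto its
convention; an exhaustive-enumeration scorer (`align_score_bruteforce()`,
exponential, for short sequences) provides an independent reference, and
the test suite checks score equality over randomized short pairs under
several penalty settings, with and without terminal-gap charges. Traceback
is deterministic (Biostrings' internal tie order); alternative optimal
paths never change the score. Whether terminal gaps should be charged is
a genuine modeling choice for domain-vs-full-length pairs; both are
supported, and the default charges them.

`coordinate_map()` turns an alignment into a per-residue source→target
position map (or gap). `transfer_variant()` lifts a variant's position
through the map and applies two drop rules: positions aligned against a
gap are dropped, and variants whose target sequence already carries the
mutant residue are dropped as synonymous-in-target. The wild/mutant
letters are never rewritten to the target's residues — disagreement between
source and target natives is a quantity of interest
(`native_identity_fraction()`), not an error to fix silently.

## Conservation and the matched null

Conservation is measured as information content per position: the relative
entropy (bits) of the gap-excluded column residue distribution against a
background, `I_j = Σ_a p_aj log2(p_aj / b_a)`. The background defaults to
uniform and the additive pseudocount to `1/depth`; with pseudocount 0 a
fully conserved column scores `log2(20) ≈ 4.32` bits and a
background-distributed column 0 bits. An import path for PSI-BLAST ASCII
PSSMs (`read_psiblast_pssm()`) lets externally computed information columns
drive the same sampling machinery, since production pipelines typically
take conservation from a PSSM rather than a raw MSA.

Null positions for a disease variant at position `n` must (i) carry no
known disease variant, (ii) avoid the first and last 10 residues (a
predictor-window guard; configurable), and (iii) satisfy the conservation
constraint — at least as conserved as `n` for the "conserved" null,
strictly less for the "not conserved" null. Values are compared after
rounding to 4 decimals so the ≥/< split is not decided by floating-point
noise. If no position qualifies (the disease position is strictly the most
conserved in its protein), the variant is *skipped* and counted. Case (i)
substitution re-uses the disease variant's mutant residue at a position
carrying the same wild-type residue; case (ii) draws one random
SNV-possible substitution of the null position's native residue. The
native-residue constraint is applied on top of the conservation filter and
defaults to on — the `XmY` construction implies it, and turning it off is a
single flag. Sampling is one uniform draw per variant (exhaustive "all @"
mode enumerates every eligible position instead); different variants may
hit the same position, which matched-sampling does not forbid.

SNV-possible substitutions are defined at the amino-acid level: the union
over all codons of the wild-type residue of every single-base edit,
translated, with stops and identity excluded (150 directed residue pairs
under the standard code). This is the appropriate granularity when the
underlying DNA is unknown; a codon-resolved treatment would require the
actual coding sequence. Stop-reachable edits are excluded from the sample
space entirely, consistent with nonsense variants being excluded from the
analysis.

The *conservation-threshold baseline* is the trivial predictor that calls
every SNV-possible SAV above a conservation threshold an effect. Comparing
its effect-call count against the number of curated disease SAVs at equally
conserved positions shows how strongly a threshold-only rule over-predicts.

## Binary calls and summaries

Cutoff rules (threshold, orientation, tie policy) are configuration, not
code: the packaged `cutoff_rules.yaml` documents common conventions
(SNAP2-like scores > 0, probability-like classifiers > 0.5, p-value-like
scores < 0.05) and is user-replaceable, since "default cutoff" is a
per-tool property. Effect fractions are reported with the set size and a
percentile bootstrap interval (default 2,000 resamples, seeded). The
bootstrap is additional rigor on top of the bare fractions and is labeled
as such in reports. Pairwise method agreement is the percentage of
co-present variants with identical binary calls.

## The synthetic-data generator

`generate_family()` draws an ungapped MSA column-wise from
dominant-residue distributions: each column has one dominant residue with
probability `q` and the remaining mass uniform over the other 19. `q` is
solved numerically (monotone closed form, `uniroot`) so the column's
expected information hits a per-position target drawn from a Beta(1.5, 3)
distribution scaled to [0, log2 20] bits — a right-skewed profile in which
roughly a tenth of positions are strongly conserved. This gives direct
control of exactly the quantity the sampling logic consumes. What it does
*not* emulate: phylogenetic correlation between sequences, residue
exchangeability structure (columns mix with a uniform alternative, not a
substitution model), gaps within the family, and correlation between
adjacent positions. Passing tests therefore demonstrate the correctness of
the pipeline's logic under controlled conservation structure, not
performance on real alignments.

Disease SAVs are planted at distinct interior positions in the top
conservation decile (quantile 0.9), with SNV-possible mutants — emulating
the observation that curated disease SAVs sit at well-conserved positions.
Orthologs are simulated with per-position substitution probability
proportional to `1 − conservation/log2(20)`, normalized so the expected
substituted fraction equals the divergence parameter (default 0.1);
substitutions are SNV-possible. Single-residue indels occur at configurable
rates and are restricted to below-median-conservation positions by default,
so planted (conserved) variants deterministically exercise the
transferred/synonymous paths; a flag lifts the restriction for attrition
experiments.

The synthetic predictor scores a variant as
`plogis(intercept + w_c·bits + w_e·planted + ε)`, `ε ~ N(0, sd)`. The
default scenario (50 families, length 300, depth 200, 2 planted SAVs per
family, `w_c = 2` per bit, `w_e = 2`, intercept −6, noise sd 0.5, cutoff
0.5) was chosen so that conservation is the dominant signal — as for an
alignment-based predictor that never sees disease labels — with the
planted-effect term a smaller boost encoding that planted variants are
genuinely deleterious. Under these conditions `run_scenario_analysis()`
recovers the qualitative pattern the analysis is designed to expose:
planted disease SAVs and conservation-matched nulls are predicted alike
(the planted boost leaves a gap of roughly 10–20 percentage points at
saturating conservation), both far above the less-conserved nulls, and the
single-threshold baseline over-predicts effect by well over an order of
magnitude relative to the number of planted variants. The acceptance test
evaluates this pattern at a fixed seed; problem sizes (50 × 300 × 200, and
25 families × 20 variants for transfer attrition) are the package's chosen
study conditions for these checks.

## Numerical and degenerate-input choices

* Empty sequences in `global_align()` produce a single all-gap run scored
  `open + (k−1)·extend` (0 if terminal gaps are free) rather than an error.
* A `+1`-shift position beyond the sequence end is a mismatch, not an
  error.
* `eligible_positions()` returning empty is a counted skip, never an error.
* Conservation comparisons round to 4 decimals (see above); information is
  computed with `0·log 0 = 0`.
* All randomness flows through explicit seeds; per-family seeds are derived
  from the scenario seed by a fixed integer recurrence, so scenario runs
  are byte-reproducible.

## Known limitations

* The packaged curated set is a synthetic stand-in with the documented
  marginals; analyses of real curated data must supply their own tables
  and sequences in the same TSV/FASTA formats.
* Scores from real predictors (SNAP2, SIFT, PolyPhen-2, ...) are consumed
  from score tables; the package never runs or re-trains predictors.
* Reachability is amino-acid-level; codon-usage weighting of SNV draws is
  out of scope.
* The conservation profile is column-independent; comparisons against
  PSSM-derived information from iterated profile searches will differ in
  scale, which is why the sampling logic only ever uses *within-protein*
  comparisons of conservation values.
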