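---
title: "Screening methods: models, parameters and design choices"
author: "quinscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quinscreen)
```

This vignette is the package's own account of the science it implements:
the staged prioritization of substituted heteroaromatic compounds as
multifunctional antioxidant / neuroprotector candidates, the models and
assumptions behind each stage, the parameters that matter, and the
choices made where the design was genuinely open.

## 1. Enumeration of the derivative space

A `Scaffold` is a SMILES template with placeholder sites (`{R1}`,
`{R2}`, ...); a `SubstituentLibrary` maps group names to monovalent
fragments. `enumerateDerivatives()` emits, for every substitution order
`k = 1..maxK`, each k-subset of sites crossed with every assignment of
groups, i.e. `choose(s, k) * g^k` records, plus the unsubstituted parent.
For the default quinoline scaffold (7 CH sites, positions 2–8) and the
six-group library this gives 42 + 756 + 7560 substituted structures,
8,359 with the parent.

Assumptions and conventions:

* **No tautomers or stereochemistry.** Substituents are attached as
  written; each substitution pattern is one compound. This matches how
  such libraries are treated at the screening stage, where per-pattern
  property estimates are the unit of analysis.
* **Canonicalization.** Structures are canonicalized with OpenBabel
  (through `ChemmineOB`), so spelling-invariant deduplication is a string
  comparison. All 8,359 quinoline-space structures are pairwise distinct
  because quinoline's seven CH positions are symmetry-distinct; for
  scaffolds with symmetric sites the canonical strings collapse
  duplicates and the count identity no longer applies.
* **Identifiers.** `dQ<index>` in the deterministic enumeration order
  (sites lexicographic, group assignments odometer-style, parent first).
  The id is a pure function of the pattern. No mapping to any external
  numbering of the same chemical space is attempted or supported.

## 2. Descriptors and drug-likeness rules

`computeDescriptors()` takes molecular weight, Crippen-type logP, TPSA
and molar refractivity from OpenBabel, and computes the remaining counts
by definitions a reviewer can reproduce by hand: HBD is the number of
O–H plus N–H hydrogens, HBA the number of N plus O atoms (the classic
Lipinski counts), rotatable bonds the single acyclic non-terminal bonds
between non-triple-bonded heavy atoms, ring count the
smallest-set-of-smallest-rings size (ring-closure count of the SMILES),
and atom counts come from the molecular formula.

`applyRules()` evaluates the five rule sets at their standard literature
thresholds with **inclusive boundaries** (a value exactly at a limit
passes): Lipinski (mw ≤ 500, logP ≤ 5, HBD ≤ 5, HBA ≤ 10; up to one
violation tolerated, the usual reading), Ghose (160 ≤ mw ≤ 480, −0.4 ≤
logP ≤ 5.6, 40 ≤ MR ≤ 130, 20 ≤ heavy atoms ≤ 70), Veber (rotb ≤ 10,
TPSA ≤ 140), Egan (logP ≤ 5.88, TPSA ≤ 131.6), Muegge (200 ≤ mw ≤ 600,
−2 ≤ logP ≤ 5, TPSA ≤ 150, rings ≤ 7, C > 4, heteroatoms > 1, rotb ≤ 15,
HBD ≤ 5, HBA ≤ 10). Failing two or more rule sets raises an
informational bioavailability-concern flag; elimination remains
score-driven.

Synthetic accessibility (0–100, higher = easier) and the four toxicity
endpoints — rodent oral LD₅₀ in mg/kg, Ames mutagenicity and
developmental toxicity as probabilities, bioaccumulation factor as
log₁₀ — are external estimates and enter as columns; `firstScreen()`
eliminates every compound missing at least one endpoint before any
scoring, so the scoring functions may (and do) refuse `NA` inputs.

## 3. Selection and elimination scores

Both scores compare a compound to a reference set of neuroprotectors
summarized by per-property means and standard deviations
(`referenceStats()`; zero-variance properties are excluded with a
warning, since they cannot be standardized).

The **selection score** is the weighted mean of three blocks, each on a
0–4 scale so no single ingredient dominates:

* rule compliance: satisfied rule sets (0–5) rescaled by 4/5;
* toxicity: per endpoint `4 * pnorm(z)`, with `z` signed so that
  safer-than-reference (higher LD₅₀; lower mutagenicity, developmental
  toxicity, bioaccumulation) is positive, averaged over the four
  endpoints — a probit desirability that saturates smoothly instead of
  rewarding extreme values linearly;
* synthetic accessibility: SA/25.

A compound exactly at the reference centroid scores 2 on the toxicity
block; the score is monotone in every safety/ease direction. The exact
functional form is this package's own operationalization of
"average desirability of rule compliance, safety and manufacturability";
its absolute values have no meaning outside the package, only
comparisons within a run (candidates must beat the parent's score and
the reference average — both computed in-run, never hardcoded).

The **elimination score** is deliberately direction-agnostic:
`s_elim = Σᵢ |xᵢ − μᵢ| / σᵢ` over the thirteen scored properties. It
measures atypicality with respect to molecules already credible as
neuroprotectors, so the parent — a bare 10-atom bicycle scored against
drug-sized references — lands at the top of the range, and deviations in
the "good" direction still count: a compound 15 standard deviations
safer than every reference is chemically suspicious, not 15 times
better. Nested component sums (`S_ADME2` = mw + logP; `S_ADME8` adds
HBD, HBA, TPSA, rotb, MR, heavy atoms; `S_ADMET` adds the four toxicity
coefficients; `S_ADMETSA` adds SA and equals `s_elim`) expose which
panel drives the deviation. Survivor ordering is ascending `s_elim` with
descending `s_sel`, then id, as tie-breaks — fully deterministic.

## 4. Acid–base speciation

`speciesFractions()` implements the closed form for a single macroscopic
deprotonation ladder: with `n` strictly ascending pKa values, the
species with `j` protons removed has relative weight
`10^(j·pH − Σ_{i≤j} pKa_i)`; fractions are the normalized weights. This
is algebraically identical to chaining Henderson–Hasselbalch ratios
`10^(pH − pKa_j)` step by step, which is exactly how the test-suite
oracle computes it. Branched microspecies (parallel deprotonation paths)
are out of scope — per-compound tables in this setting report one ladder.

Numerical choices: the weights are evaluated in log₁₀ space with
max-subtraction, so pH or pKa values far outside the physiological range
cannot overflow; fractions then sum to 1 within 1e−12 by construction.
At `pH = pKa` the monoprotic case gives exactly 0.5/0.5 in floating
point. An empty ladder yields a single species with fraction 1. At most
four pKa values are accepted (the most a tri-substituted derivative of
this library can reasonably present); non-ascending ladders are a
validation error.

Charge labels: pKa values alone do not identify which species is
neutral. By default each step with pKa < 7 is attributed to a cationic
site (ring-N–H⁺ in quinolines deprotonates in the acidic range, phenols
and thiols above it), so a `[4.8, 9.9]` ladder reads HA⁺ / A / H₋₁A⁻.
The assignment affects labels only, never fractions, and can be
overridden per compound (`maxCharge`).

The relevance threshold is 1 % **inclusive** — a species at exactly 1 %
counts as present. The same convention is used when renormalizing
fractions for docking aggregation.

## 5. The donation map (IP vs minimum BDE)

For each relevant species the map plots ionization potential (electron
donation, SET axis) against the minimum bond dissociation energy over
its H-donor sites — phenolic O–H, amine N–H, thiol S–H, ester methyl
C–H (HAT axis). Lower is better on both axes. Classification against
each reference antioxidant is strict dominance with a ±0.1 kcal/mol
"similar" band; comparisons against the H₂O₂/•OOH oxidant target are
reported separately for each axis rather than collapsed into one verdict,
since H-atom donation to •OOH and electron donation to the target are
distinct thermodynamic questions. Rankings order by number of reference
antioxidants dominated on both axes, then ascending BDE, then ascending
IP. Classification is invariant under a shared unit change (kcal/mol ↔
kJ/mol), which the suite verifies.

The map plots *species*, not compounds: fractions do not weight the
classification. A compound-level summary takes the best class among its
relevant species — an explicit assumption, since a 1 % anion that is a
superb donor may dominate the compound's observed chemistry or may not,
depending on kinetics this package does not model.

The built-in reference panel values (Trolox, α-tocopherol, ascorbate,
H₂O₂/•OOH) are **synthetic placeholders** at literature-plausible
aqueous magnitudes; real applications must supply computed or measured
panel energies via `referencePanel()`.

## 6. Affinity aggregation and the polygenic score

Docking scores ΔG_B (kcal/mol, best pose, negative = favorable) are
aggregated per compound and enzyme as the **linear** fraction-weighted
average over relevant species, with fractions renormalized over the
scored subset. Linear weighting (rather than Boltzmann-weighting the
implied affinities) keeps the aggregate inside the species' score range
and makes "substrate-equivalent weighted score ⇒ log-ratio exactly 0"
hold identically.

The per-enzyme term is `log₁₀(ΔGᵂ_B / ΔG_B,sub)` against the natural
substrate of each target — dopamine for COMT, phenylethylamine for
MAO-B, acetylcholine for AChE. Both arguments must be strictly negative;
zero or positive scores are a domain error rather than silently clamped.
Base 10 is the default and is configurable; the choice only rescales all
terms. The polygenic score is the **sum** of the three terms — a mean
would differ by a constant factor and preserve every ranking, so the sum
is chosen for the convenient reading "0 = matches all three substrates".
The default substrate baselines are synthetic placeholders, like the
donation panel.

## 7. The synthetic cohort generator

`simulateCohort()` generates every input table the pipeline consumes so
the whole analysis is testable without external QSAR, DFT or docking
software. Its defaults are the campaign conditions: 8,359 compounds
including the parent, a 2033/8358 compound-level missing-toxicity rate,
a 30-compound reference set, pH 7.4, 1 % relevance, 25 selected
candidates. Distributions are chosen once at field-plausible values:
derivatives are smaller than the reference neuroprotectors (mw ≈ 240 ±
45 vs 330 ± 80), slightly safer on LD₅₀ (log-normal around 700 mg/kg vs
600) and mutagenicity (Beta mean 0.25 vs 0.38), clearly safer on
developmental toxicity (0.29 vs 0.50), lower but widely dispersed on
bioaccumulation, and easier to synthesize (SA 65 ± 10 vs 45 ± 12). pKa
ladders have 0–3 strictly ascending values in 2–12; IP (90–130) and BDE
(70–95 kcal/mol) bracket the reference panel; docking scores are uniform
in −9 to −4 kcal/mol. The parent carries quinoline's fixed descriptor
block, a quinolinium-like pKa of 4.85, and always-complete toxicity.

What the generator does **not** emulate: structure–property coupling (a
compound's descriptors, toxicity and reactivity are drawn independently,
so passing tests show the machinery is correct, not that any real QSAR
relationship is reproduced), assay noise correlated across endpoints,
and the real tails of toxicity distributions. Conclusions about real
compounds require real tables, which drop into the same schemas.

`plantKnownWinners()` overwrites `k` compounds to be recoverable by
construction: every scored property sits on the empirical reference
centroid (elimination score ≈ 0, the unbeatable minimum) except SA,
which is set to its 100 cap — that alone lifts the selection score well
above both thresholds without making the compound atypical. The planted
margin then only widens the reactivity gap below Trolox and the binding
advantage over the substrates, so recovery is insensitive to the margin
scale (the suite checks ×10). This construction was chosen over
"toxicity `margin` standard deviations safer" precisely because the
elimination score treats extreme safety as atypicality: winners must be
reference-like, not extreme.

## 8. Pipeline, problem sizes and limitations

`runPipeline()` chains the stages, records per-stage counts in a
manifest (plus MD5 hashes when stage tables are written to disk), halts
with an explicit `"empty cohort"` status when screening removes
everything, and proposes the candidates that both dominate Trolox on the
donation map (any relevant species, both axes) and have a positive
polygenic score, ordered by descending polygenic score.

Problem sizes used by the shipped checks, chosen to keep a full run on
one core in well under two minutes: the full 8,359-structure enumeration
with canonicalization; 1,000 random speciation instances against the
mass-balance oracle (agreement to 1e−9 asserted, observed ≈ 1e−16);
500 random chained-affinity instances (same tolerances); 20 seeded
end-to-end recovery runs at the full default cohort size with `k = 4`
planted winners. Unit tests use 400–800-compound cohorts.

Known limitations: macro-pKa ladders only; no kinetic (rate-constant)
antioxidant modeling; no structure-based coupling in the simulator;
rule thresholds are the standard literature values, not re-fitted; the
selection-score functional form is an operationalization whose absolute
values are not comparable across packages; docking scores, pKa values,
IP/BDE and toxicity are inputs — the package aggregates them and
deliberately does not predict them.
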