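---
title: "Scoring critical aggregation-prone regions in antibodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring critical aggregation-prone regions in antibodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solubis)
```

## The model

Short aggregation-prone regions (APRs) drive beta-aggregation of proteins:
five or more consecutive residues combining high hydrophobicity, high
beta-sheet propensity, and low net charge. Sequence-based predictors report
the *intrinsic* aggregation propensity — the risk the segment would pose in
a fully unfolded chain. In a folded antibody most APRs are buried in the
hydrophobic core of the immunoglobulin fold, where the thermodynamic
stability of the native state protects them; the APRs that can nucleate
aggregation under native conditions — the *critical* APRs — are the ones
whose local structural context is insufficiently stabilizing. Because CDR
loops are selected for antigen binding, not for structure, and because
paratopes are enriched in exactly the aromatic/hydrophobic residues that
favour aggregation, critical APRs concentrate in CDRs.

The package turns this picture into a score in three steps:

1. **Intrinsic profile.** Every residue gets an aggregation-propensity score
   in [0, 100]; APRs are the maximal runs of at least `min_len = 5` residues
   scoring at least `threshold = 5`. Each APR carries the sum of its
   per-residue scores (`tango_sum`).
2. **Local stability.** For each APR, the per-residue contributions to the
   free energy of folding (kcal/mol, negative = stabilizing) are summed over
   the APR interval, giving its stability contribution
   $\Delta G^{contrib}$.
3. **Corrected score.** The stability contribution is clipped to
   $[-5, +5]$ kcal/mol and mapped linearly to a weight
   $w = \mathrm{clip}\big((\Delta G^{contrib} + 5)/10,\, 0,\, 1\big)$: 0 for
   a thermodynamically protected APR, 1 for an unstable one. The APR's
   corrected score is $\mathrm{tango\_sum} \times w$, an APR is *critical*
   when its corrected score reaches `critical_threshold = 50`, and the
   **Solubis score** of the antibody is the sum of corrected scores over
   both chains. Protected APRs ($\Delta G^{contrib} \le -5$) contribute
   exactly nothing, so the total is dominated by critical APRs.

The per-APR points $(\Delta G^{contrib}, \mathrm{tango\_sum})$ form the
*stretch-plot* (`plot()` on a fitted object); scanning gatekeeper
substitutions over a critical APR gives the *MASS* spectrum
(`mass_scan()`), each mutation a point
$(\Delta\Delta G, \Delta \mathrm{tango})$.

## The aggregation surrogate and its calibration

The intrinsic profile is a documented surrogate with the interface and
conventions of established beta-aggregation predictors (per-residue 0–100
scale, APR calling at five residues of score five, gatekeeper response).
For a 5-residue window $w$:

$$E_w = \sum_{j \in w} (h_j + b_j) \;-\; \lambda\,|q_w| \;-\; \gamma\,n_P(w)$$

with $h$ the min–max-normalized Kyte–Doolittle hydropathy, $b$ the
normalized Chou–Fasman beta-sheet propensity, $q_w$ the window net charge
(K/R +1, D/E −1, H neutral) and $n_P$ the proline count. Residue $i$ scores
$100\,\sigma\!\big((\max_{w \ni i} E_w - E_0)/s\big)$ with the logistic
$\sigma$.

The defaults $E_0 = 10$, $s = 0.3$, $\lambda = 2$, $\gamma = 2$ are a fixed,
versioned calibration, not a runtime fit. They were chosen once so that:

* poly-charged and poly-proline controls stay below the APR floor
  everywhere (the $\lambda$ and $\gamma$ penalties dominate);
* a planted I/V-rich hexapeptide in a polar context is called with *exact*
  boundaries: windows fully inside the segment carry energies above 9.6,
  windows crossing its boundary at most 8.9, and the steep logistic
  ($s = 0.3$) turns that gap into scores of ~30 inside versus <2 outside.

The steep boundary cut has a price: hexapeptides whose best window includes
moderately polar residues (the classic Ser/Thr-containing amyloid
hexapeptides) fall below the calling threshold, because their window
energies (~7.5) are indistinguishable from the boundary windows of stronger
segments. No single threshold can separate both; we chose exact boundary
recovery, since every downstream design operation (gatekeeper enumeration,
variant scoring) depends on the called interval being the planted one. The
surrogate is therefore deliberately high-specificity/low-sensitivity.
Per-residue output of a real aggregation predictor can be supplied at any
time through the generic TSV reader and flows through every downstream
stage unchanged.

## The stability surrogate

Full force-field energetics are out of scope; the per-residue contribution
to the free energy of folding is estimated by a three-term empirical
potential,

$$\Delta G_i = -\big(\alpha\,(1 - \mathrm{RSA}_i)\,\tilde H_i
  + \beta\,\mathrm{HB}_i\big) + \kappa\, C_i$$

with defaults $\alpha = 0.8$, $\beta = 0.5$, $\kappa = 1.0$ kcal/mol.
$\mathrm{RSA}$ is Shrake–Rupley relative accessibility (probe 1.4 Å,
deterministic golden-spiral point set, Gly-X-Gly reference maxima);
$\tilde H$ is the positive part of the Kyte–Doolittle scale rescaled to
[0, 1], so hydrophilic residues gain nothing from burial;
$\mathrm{HB}$ counts donor–acceptor N/O pairs under 3.5 Å (non-adjacent
residues, with a C–O⋯N angle proxy > 90°); $C$ counts non-bonded heavy-atom
pairs under 2.5 Å. All cutoffs are configurable (`stability_params()`).

The surrogate is built to reproduce the qualitative contract the corrected
score needs — buried hydrophobic, hydrogen-bonded APRs get strongly
negative sums (weight → 0), exposed APRs get sums near zero (weight ≈ 0.5),
strained ones positive — and the ±5 kcal/mol clipping in the scoring step
deliberately absorbs its inaccuracy. Mutation $\Delta\Delta G$ recomputes
only the site's burial term with the mutant's $\tilde H$ (dropping
side-chain hydrogen bonds on polar→apolar changes); no repacking or
relaxation is attempted, so $\Delta\Delta G$ ranks mutations and is not a
calorimetric prediction. When per-residue output of a real force field is
available it is the preferred input (`read_residue_energy_table()`), and
with an external table the coordinates are provably never consulted.

Without either structure or table, every residue gets $\Delta G = 0$, every
APR weight 0.5, and reports are flagged `sequence-only` — structure is
required to *discount* APRs, never to inflate them.

## Annotation and numbering

CDRs are located by Chothia-style anchor rules (conserved cysteines, the
tryptophan closing CDR-L1, the `WG.G` / `FG.G` motifs closing CDR-H3 and
CDR-L3; offsets documented in `?annotate_chain`). Full scheme alignment is
out of scope; the anchors are robust for standard Fv domains and an
external-numbering sidecar gives an exact escape hatch for anything else.
Net charge counts K/R as +1 and D/E as −1; histidine is neutral by default
(a convention, exposed as a flag), and "outside the CDRs" means all
framework plus constant-region residues.

## Variant design

`mass_scan()` enumerates every substitution of an APR residue to one of the
five aggregation gatekeepers (D, E, K, R, P — charged residues or the
beta-breaker proline), skipping positions that already hold that
gatekeeper: $5L - k$ candidates for an APR of length $L$ with $k$
gatekeeper positions. `select_mass_candidates()` keeps candidates with
$\Delta\Delta G \le$ `max_ddg` (+0.5 kcal/mol by default — the intent is
"minimal unfavorable effect on stability", and the chosen default is echoed
in every output) and ranks by aggregation suppression.
`supercharge_scan()` enumerates, outside the heavy-chain CDRs, the
chemically conservative substitutions that raise net charge: X→K/R for any
X not already K/R, plus the acid→amide changes D/E→N/Q; the alphabet is a
package choice (the minimal set realizing a charge increase) and is
configurable in the sense that any candidate list can be filtered before
composition. `compose_variant()` applies mutations (wild-type letters
verified, one per position), re-runs profile → APR calling → scoring, and
inherits the wild-type stability profile — numbering and regions are
preserved under point substitution.

## Evaluation machinery

Antibodies are labelled aggregation-prone when the melting temperature
exceeds the aggregation-onset temperature by strictly more than 5 °C
(`gap_cutoff`; the strict inequality is a package convention), with an
override mechanism for antibodies that aggregate before measurement is
possible. ROC curves place thresholds at every distinct score; AUC uses the
Mann–Whitney pair-counting identity with ties worth one half, making the
tie convention explicit rather than hidden in a trapezoid. MCC is the
standard coefficient with the degenerate-denominator case defined as 0.
Pearson correlation wraps `stats::cor()` with guards.

The bundled benchmark panel (`mab_benchmark()`) hard-codes the published
values for nine producible wild-type antibodies and ten engineered
variants: raw aggregation totals, Solubis scores, APR counts, classes, and
thermal gaps. Gaps reported only as "less than one degree" are encoded as
0.5 °C; the score–gap correlation rounds to 0.89 under any encoding in
[0, 0.9] (asserted in the test suite). On the wild-type panel the positive
scores (93–681) and negative scores (4–71) separate completely, so any
threshold in (71, 93] classifies without error — AUC 1.0, MCC 1.0.

## Synthetic fixtures

`make_toy_fv()` builds ~110-residue heavy/light pairs: polar S/T/G/N/Q
framework, the anchor motifs above, a few K/E scattered into the framework
(kept ≥5 positions from the APR so window locality leaves the planted
segment untouched), and one alternating-I/V APR planted in CDR-H3 or in
heavy-chain FR3. The alternating pattern is a deliberate restriction of the
hydrophobic alphabet: with i.i.d. draws from {I,V,F,L,Y} the energies of
core windows and boundary windows overlap (an all-Y core window scores
below a four-V boundary window), and no fixed threshold could recover
planted intervals exactly.

`make_toy_structure()` lays the chains on a deterministic lattice (7 Å
residue spacing, four backbone atoms plus one pseudo side-chain atom).
"Exposed" places everything on the convex surface (planted-APR RSA > 0.75,
no hydrogen bonds); "buried" wraps the APR in a packed shell of occluding
atoms (RSA < 0.25) with one hydrogen-bond partner per APR residue, driving
the APR's stability sum below −5 kcal/mol. The two variants share every
byte of sequence, so any downstream score difference is attributable to the
stability mechanism alone. Fixture structures are topological stand-ins,
not immunoglobulin folds: single-pseudo-atom side chains keep the
surface-area oracle simple while still exercising the burial term.

What passing tests on these fixtures shows — and what it does not: the
pipeline arithmetic, the boundary behaviour, the gatekeeper response and
the burial mechanism are exercised end to end, but the fixtures contain
none of the messiness of real data (heterogeneous APR composition,
insertion-coded numbering, imperfect anchors, real geometry), so fixture
results do not certify predictive accuracy on real antibodies. The
published benchmark panel provides the real-data anchor for the evaluation
machinery.

## Numerical choices and degenerate inputs

* Window sums are computed per window, not via running sums, so a point
  mutation leaves windows outside its ±4-residue reach bitwise unchanged.
* `X` residues score 0 and invalidate every window containing them,
  breaking APR runs.
* Sequences shorter than the window give an all-zero profile with a
  warning; empty APR sets give score 0.
* Alternate locations resolve to the highest occupancy, ties to file
  order; `MSE` maps to M, other non-standard residues to `X` with a
  warning.
* Ranking ties in candidate shortlists break by stability, then position,
  then mutant letter, so outputs are reproducible byte for byte.
* Reports render floating-point values with six significant digits;
  rerunning any command with the same inputs and configuration produces
  identical files.

## Problem sizes in the test suite

The suite exercises the APR-calling oracle on 1000 random profiles, the
AUC pair-counting identity on 500 random instances, gatekeeper
monotonicity on every interior position of planted fixtures across seeds,
lengths and both host regions, and the surface-area implementation against
an independent dense-sampling oracle on a 10-residue excerpt. These sizes
were chosen to cover the combinatorics the operations expose while keeping
the default suite quick to run.

## Known limitations

* The aggregation surrogate is high-specificity by design and will miss
  genuinely amyloidogenic hexapeptides with polar positions; inject real
  predictor output for production use.
* The stability surrogate ignores electrostatics, rotamer packing and
  backbone relaxation; its $\Delta\Delta G$ is a ranking heuristic.
* Chain-pairing effects (heavy/light interface energetics) are not
  modelled.
* Anchor-based annotation assumes standard Fv architecture; unusual
  frameworks need the external-numbering sidecar.
* The benchmark panel is small (nine wild types); perfect separation on it
  is a property of the published values, not a general performance claim.
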