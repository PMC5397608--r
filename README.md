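# solubis

Scoring and engineering of native-state aggregation risk in monoclonal
antibodies, for protein engineers and developability-assessment teams.

Protein particles are a central liability in antibody development, and most
of them trace back to short **aggregation-prone regions** (APRs): runs of
five or more residues with high hydrophobicity, high beta-sheet propensity
and low net charge. In the folded antibody, most APRs are buried in the
immunoglobulin core and thermodynamically protected; the dangerous ones —
the **critical APRs**, typically in CDR loops selected for binding rather
than structure — sit in regions of low local stability and can nucleate
aggregation without any global unfolding.

## The score

For each APR the package computes

* `tango_sum` — the summed per-residue intrinsic aggregation propensity
  (0–100 per residue; APRs are maximal runs of ≥ 5 residues scoring ≥ 5),
* ΔG<sup>contrib</sup> — the summed per-residue contribution to the free
  energy of folding over the APR interval (kcal/mol, negative =
  stabilizing), from a structure or an external per-residue energy table,
* a stability weight `w = clip((ΔG_contrib + 5) / 10, 0, 1)` — the summed
  ΔG is cut off at ±5 kcal/mol and rescaled, so a thermodynamically
  protected APR (ΔG ≤ −5) gets weight 0 and an unstable one gets 1,
* the corrected score `tango_sum × w`; an APR is **critical** when this
  reaches 50.

The **Solubis score** of the antibody is the sum of corrected scores over
both chains — dominated by critical APRs, with protected APRs contributing
exactly nothing. On top of the score sit design scans: gatekeeper
substitutions (D, E, K, R, P) over critical APRs ("MASS" spectra of
ΔΔG versus Δaggregation per mutation) and net-charge-increasing
substitutions outside the heavy-chain CDRs, plus classifier evaluation
(ROC/AUC by pair counting, Matthews correlation, Pearson score–gap
correlation) against melting/aggregation-onset temperature data.

The intrinsic-propensity and stability calculators are documented
surrogates with the interface, scales and calling conventions of the
established external predictors; real per-residue output from those tools
can be injected through a TSV reader and flows through every downstream
stage unchanged. See `vignette("critical-apr-scoring")` for the model,
its calibration, and its limits.

## Worked example

Every input can be generated in-package — a toy Fv with one planted
hydrophobic APR in CDR-H3, and a lattice structure placing that APR either
on the surface or inside a packed shell:

```r
library(solubis)

fx  <- make_toy_fv(seed = 1)                      # H/L chains, APR planted
st  <- make_toy_structure(fx, burial = "exposed")
fit <- solubis(heavy = fx$heavy, light = fx$light,
               structure = st$structure, id = "toy-mab")
summary(fit)
#> <solubis> toy-mab  [structure]
#>   Solubis score: 81.2 (raw aggregation total 178.7)
#>   APRs: 1, critical: 1 (corrected score >= 50)
#>
#>   Stretch points:
#>  chain region start end sequence tango_sum dg_contrib weight corrected_score
#>      H   CDR3    96 101   IVIVIV     178.7      -0.46   0.45            81.2
#>  critical
#>      TRUE
```

The exposed APR keeps a weight of 0.45 (its ΔG<sup>contrib</sup> of
−0.46 kcal/mol maps to (−0.46 + 5)/10) and is flagged critical. The same
sequences over the buried coordinates silence it completely:

```r
stb <- make_toy_structure(fx, burial = "buried")
solubis(heavy = fx$heavy, light = fx$light,
        structure = stb$structure, id = "toy-mab")
#> <solubis> toy-mab  [structure]
#>   Solubis score: 0.0 (raw aggregation total 178.7)
#>   APRs: 1, critical: 0 (corrected score >= 50)
```

Gatekeeper design on the critical APR (5 substitutions per position, 30
candidates for the 6-residue APR), and composition of the top pick:

```r
ms <- mass_scan(fit, "H", 1)
head(select_mass_candidates(ms), 3)
#>   chain position ins wt mut   d_tango        ddg d_charge
#> 1     H       99      V   E -178.7058 0.03066728       -1
#> 2     H       99      V   D -178.7058 0.03066728       -1
#> 3     H       99      V   K -178.7057 0.03066728        1

compose_variant(fit, list("VH99D"))
#> <variant> VH99D
#>   net-charge change: -1
#>   Solubis score: 0.0 (0 APRs, 0 critical)
```

A single central gatekeeper removes the APR entirely (Δtango −178.7),
at a predicted stability cost of 0.03 kcal/mol.

Evaluation against the bundled benchmark of published antibody scores and
thermal gaps:

```r
b <- mab_benchmark(include_mutants = FALSE)
roc_curve(b$solubis_score, b$label)$auc     # 1  (scores separate at 71/93)
pearson(b$solubis_score[!is.na(b$gap)], b$gap[!is.na(b$gap)])  # 0.8858
```

A thin command-line wrapper over the same functions lives at
`inst/cli/solubis.R` (`score`, `design`, `evaluate`, `fixtures`
subcommands).

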