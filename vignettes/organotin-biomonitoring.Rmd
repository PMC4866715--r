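---
title: "Imposex indices, organotin chemistry and tissue-residue risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imposex indices, organotin chemistry and tissue-residue risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otrisk)
```

`otrisk` supports long-term biomonitoring of organotin pollution with
neogastropod sentinels. This vignette is the package's own account of the
science it implements: the indices and their definitions, the probabilistic
risk model and its assumptions, the statistical dialects that were fixed and
why, and what the synthetic generator can and cannot establish.

## The biological endpoint: imposex

Tri-substituted organotins masculinise female neogastropods. The imposex
stage of a female is scored 0–6 on the vas deferens sequence; stages 5–6
block the oviduct and leave the female sterile. Site-level indices:

* **VDSI** — mean (and median) stage over the females of a site.
* **% imposex** — share of females with stage > 0.
* **% sterile females** — share at or above the sterile threshold. The
  threshold defaults to stage 5 but is configurable
  (`imposex_config()`), because scoring schemes differ between programmes.
* **RPSI** — `100 × (mean female penis length / mean male penis length)^3`.
  The cube is the classical convention (penis bulk scales roughly with the
  cube of its length); the exponent is configurable. Females whose imposex
  penis is present but unmeasurable enter the female mean as 0 mm: this
  keeps the index defined for every surveyed site and biases it, if at all,
  downward (conservative).
* **Condition index** — `fresh tissue × 100 / (fresh tissue + dry shell)`,
  averaged over all individuals of both sexes; a body-condition covariate,
  not an imposex measure.

`summarize_site()` assembles these into one row per site-year; a
brute-force recomputation from the raw stage vector is part of the test
suite, so the composition cannot drift from the component definitions.

## The chemical panel

Six analytes are tracked: the butyltins MBT/DBT/TBT and phenyltins
MPT/DPT/TPT, in µg compound per kg dry tissue.

* **Censoring.** Field panels are left-censored at analyte-specific
  detection limits (0.2–1.5 µg kg⁻¹ dw is typical for GC-MS tissue work).
  The default substitution is ½·DL — the long-standing ecotoxicology
  convention — with `zero` and `dl` as bounding alternatives. The censored
  flag is preserved after substitution, so analyses can still drop
  censoring-dominated replicates. No distributional imputation is
  attempted: with 3–4 replicates per site there is nothing to fit.
* **Replicate pooling.** Tissue replicates (pools of 8–15 snails, 3–4 per
  site) are averaged per site-year, and totals, composition and degradation
  indices at the site level are derived from the mean analyte
  concentrations. Sites — not replicates — are the unit of every downstream
  analysis, matching how monitoring programmes plot one point per site.
* **Degradation indices.** `BDI = ([MBT]+[DBT])/[TBT]`,
  `PDI = ([MPT]+[DPT])/[TPT]`. Values < 1 indicate fresh input of the
  parent compound; > 1, aged residues. A zero denominator yields an
  explicit `*_defined = FALSE` flag rather than an error: a triorganotin-free
  site is a finding, not a fault.
* **Units.** Programmes report either µg compound kg⁻¹ dw or µg Sn kg⁻¹ ww.
  `dw_to_ww_sn()` multiplies by the analyte's cation tin mass fraction
  (Sn = 118.71 over the cation mass built from C = 12.011, H = 1.008; e.g.
  TPT 118.71/350.03 ≈ 0.339) and by `1 − moisture`. The default moisture of
  0.80 is the standard figure for gastropod soft tissue. Against published
  paired values this reproduces dw↔ww-Sn equivalences to within ~0.3 %; the
  residual suggests the original conversions used a slightly different
  speciation basis (hydride or chloride masses) or sample-specific
  moisture, so both knobs are arguments, not constants.

## Tissue-residue probabilistic risk

The risk quotient is `RQ = MTC / PNETC`: the measured tissue concentration
in the sentinel over a predicted no-effect tissue concentration from
chronic toxicity literature. A population with RQ ≥ 1 is at risk. Because
both numerator (across sites) and denominator (across species/tests) are
distributions, the package propagates both:

1. **Inputs.** One MTC per site-year — the replicate-mean total butyltins
   or total phenyltins — and an endpoint set of PNETCs (typically ~6
   published chronic values). Endpoint sets smaller than 3 are rejected:
   a 2-point MLE of a 2-parameter family is degenerate.
2. **Fitting.** Both a log-logistic distribution
   (`F(x) = 1/(1+(x/α)^(−β))`; fitted as a logistic MLE on log values,
   BFGS, relative tolerance 1e-10) and a Pareto distribution
   (`F(x) = 1−(x_m/x)^a`; closed-form MLE `x_m = min`,
   `a = n / Σ log(x_i/x_m)`) are fitted. The family with the smaller
   Kolmogorov–Smirnov distance to the empirical CDF is selected — risk
   software conventionally ranks candidate fits by a GOF statistic, and KS
   is the statistic such tools report; AIC is recorded alongside, and both
   candidate fits are kept in the result so either choice can be replayed.
   An all-equal sample yields a flagged degenerate Pareto (shape ∞, a point
   mass) rather than a silent fit.
3. **Simulation.** Per repeat, `iterations` independent (MTC, PNETC) pairs
   are drawn by inverse-CDF sampling, RQ formed, the distribution truncated
   at RQ ≥ 0 (vacuous for positive-support families; retained verbatim for
   extensibility), and P(RQ ≥ 1) estimated as the exceedance fraction. The
   default protocol is 10 000 iterations × 10 repeats; the reported
   probability is the mean over repeats, with their SD and the pooled
   5/50/95 % RQ quantiles alongside. Independence of MTC and PNETC draws is
   an assumption — no dependence structure is defined by the method — and
   exposure and sensitivity have no mechanistic coupling at the level of a
   site mean.
4. **Reproducibility.** A single user seed deterministically derives one
   substream per repeat (`sample.int` of repeat seeds, then per-repeat
   `set.seed`), so reports are byte-identical across runs and platforms
   with the same R RNG defaults.

The Monte-Carlo estimator is validated against an independent 1-D
quadrature oracle, `P(MTC ≥ PNETC) = ∫₀¹ (1 − F_MTC(Q_PNETC(u))) du`,
within 3 binomial standard errors, and P(RQ ≥ 1) is exactly invariant under
a common rescaling of the concentration units of both inputs.

## Trend statistics: fixing the dialect

Monitoring papers rarely state their tie- and zero-handling conventions;
this package fixes one dialect and validates it against the published test
statistics it must reproduce:

* **Paired t on log₁₀ data** (`paired_t_log10`): `d = log10(y) − log10(x)`,
  two-sided; zero variance of differences is a hard error, non-positive
  values are a domain error. On the packaged table this reproduces the
  published t = 2.412 (mean VDSI, 2010 vs 2015), t = 2.429 (RPSI, 2010 vs
  2015) and t = 4.350 (RPSI, 2004–06 vs 2010) exactly.
* **Wilcoxon signed-rank** (`wilcoxon_signed_rank`): drop zero differences,
  midranks on |d|, tie-corrected variance
  `n(n+1)(2n+1)/24 − Σ(t³−t)/48`, **no** continuity correction, two-sided
  normal p. This combination — and no other common one — reproduces the
  published Z = 0.330 for mean VDSI 2004–06 vs 2010, which is what pinned
  the dialect. One published statistic (Z = 3.943 for % sterile females,
  2004–06 vs 2010) is not reproducible under any plain transform of the
  tabulated percentages and is deliberately not asserted anywhere.
* **Spearman + Holm** (`spearman`, `holm_adjust`): midrank ρ with the
  t-approximation p on n−2 degrees of freedom; "sequential Bonferroni" is
  implemented as the Holm step-down rule, applied per correlation family
  (one table at a time).

Two properties claimed for these tests deserve caveats that the test suite
makes explicit. First, the signed-rank Z is *not* invariant under arbitrary
strictly monotone transforms of both pair members — a convex transform can
reorder the absolute differences and change W⁺ — so the suite asserts the
true sub-property, invariance under positive affine maps. Second, the
normal-approximation p agrees with the exact 2ⁿ enumeration in *ordering*
only among fixtures of equal effective n: the exact p's granularity changes
with n, so cross-size ordering inversions of a few hundredths are inherent
to the approximation, not an implementation defect. The suite asserts exact
ordering agreement within equal-n groups and a rank correlation > 0.98
overall.

## The packaged survey table

`load_table1_fixture()` returns the published site-level indices of the
Hong Kong rock-shell programme: 29 sites × three epochs (2004–06 pooled as
one baseline, 2010, 2015), with mean/median VDSI, % imposex, % sterile
females, RPSI, condition index (2010 and 2015 only) and each site's
distance to the nearest facility with intense shipping activity. One site
(Heng On) was not recoverable in 2010 (its shore had been converted to a
concrete promenade) and 19 sites were not revisited in 2015; those cells
are `NA`, and all paired analyses join on `site_id` and drop incomplete
pairs. The 2004–06 column is treated as a single epoch because the paired
published comparisons treat it so.

## The synthetic generator: a stated world

`generator_config()` fixes one synthetic world; its defaults are not tuned
to any test outcome:

* 29 sites, 40 individuals per site, shell lengths 23–36 mm, sexes
  Bernoulli(½) — the sampling design of a territory-wide survey.
* A single latent exposure per site, `E_s = exp(a − b·distance + ε)` with
  `a = 1.2`, `b = 0.25 km⁻¹`, `ε ~ N(0, 0.3²)`, drives *both* the female
  stage distribution (latent normal around `4.6 + 0.55·log E_s`, SD 0.9,
  rounded and clamped to 0–6) and the tissue geometric means (per-analyte
  base GM × `E_s`, GSD 1.9, TPT-dominated at 1500 µg kg⁻¹ dw vs 20–90 for
  the rest). Coupling both endpoints to one latent variable makes
  cross-module correlations (stage vs TPT, index vs distance) real,
  recoverable signals. The parameter values were chosen once so that
  site-level summaries span the ranges of the published table
  (VDSI ≈ 2.6–5.7, RPSI ≈ 1–95) — spanned, not asserted.
* Censoring is emitted below per-analyte detection limits of
  0.2–1.5 µg kg⁻¹ dw; 3 and 4 replicates alternate across sites.
* Toxicity endpoint sets are drawn from a known SSD family with the truth
  recorded, so fitting is checked by parameter recovery, not by eye.

What a green end-to-end test establishes: the pipeline detects a
distance-decaying exposure gradient (negative, Holm-significant Spearman ρ
at 25 sites), recovers generating SSD parameters, and matches the
quadrature oracle for P(RQ ≥ 1). What it does not establish: anything about
real-world toxicokinetics, seasonal or depuration effects, spatial
autocorrelation between neighbouring shores, or the field accuracy of the
published endpoint sets — none of which the generator emulates.

## Numerical and design choices

* CSV dialect: comma-separated, UTF-8, `.` decimal, mandatory header,
  missing = empty string; integer `site_id` (1–29 in the packaged table) is
  the join key, names are labels.
* Validation is all-or-nothing per file with row-numbered messages; a
  malformed row rejects the read rather than silently dropping data.
* Log-logistic convergence failures raise an error carrying the optimiser
  code; they do not fall back silently to Pareto. Family selection only
  skips a candidate whose fit *errors* (or is degenerate).
* Workflow functions (`run_indices`, `run_chem`, `run_risk`, `run_trends`,
  `run_simulate`) are the package's command layer: thin, file-in/file-out,
  deterministic given a seed, with errors raised as R conditions. JSON
  reports carry a schema tag and round statistics to 6 significant digits
  so regression diffs are stable.

## Known limitations

* The published per-individual raw data are not available, so the packaged
  fixture is site-level only; individual-level code paths are exercised by
  the generator.
* The published risk probabilities (17.6 % / 69.4 % for phenyltins in
  2010/2015; 3.4 % for butyltins in 2015) depend on supplementary
  measured-concentration and endpoint tables that are not redistributable
  here; the package reproduces the published *trend statistics* exactly and
  validates the risk machinery by oracle properties instead.
* The Wilcoxon normal approximation is used for all n, as the source
  analyses did; for very small n (< 6) an exact test would be preferable,
  and the enumeration oracle in the test suite shows the size of the
  discrepancy.
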