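# otrisk

Imposex indices and probabilistic organotin risk assessment for gastropod
biomonitoring.

Organotin antifouling agents — tributyltin (TBT) and triphenyltin (TPT) and
their mono-/di-substituted degradation products — masculinise female
neogastropods. The resulting **imposex** (superimposition of a penis and vas
deferens on females) is the classic field endpoint for organotin pollution,
and the rock shell *Reishia clavigera* is the standard sentinel along
Asian-Pacific coasts. `otrisk` implements the full analysis chain such a
monitoring programme needs:

- **Imposex indices** from individual records: the Vas Deferens Sequence
  Index (VDSI, mean female stage on the 0–6 scale), the Relative Penis Size
  Index (RPSI = 100 · (mean female penis length)³ / (mean male penis
  length)³), % imposex, % sterile females (stage ≥ 5), and the condition
  index (fresh tissue weight × 100 / (fresh tissue weight + dry shell
  mass)).
- **Tissue chemistry** for the six-analyte panel MBT/DBT/TBT/MPT/DPT/TPT:
  left-censoring substitution (½·DL by default), replicate pooling, totals
  and composition, butyltin/phenyltin degradation indices
  (BDI = ([MBT]+[DBT])/[TBT], PDI = ([MPT]+[DPT])/[TPT]), and conversion
  from µg compound kg⁻¹ dry weight to µg Sn kg⁻¹ wet weight via cation tin
  mass fractions and a configurable tissue moisture (default 80 %).
- **Probabilistic risk**: the risk quotient RQ = MTC / PNETC (measured
  tissue concentration over predicted no-effect tissue concentration).
  Log-logistic and Pareto distributions are fitted by maximum likelihood to
  the site-level MTCs and to the literature endpoint set, the better family
  is selected by Kolmogorov–Smirnov distance, and P(RQ ≥ 1) is estimated by
  Monte-Carlo simulation (10 000 iterations × 10 repeats by default, fully
  seeded).
- **Trend statistics**: paired t tests on log₁₀ data, the tie-corrected
  normal-approximation Wilcoxon signed-rank test (drop-zeros, no continuity
  correction), Spearman rank correlations with Holm (sequential Bonferroni)
  step-down flags.
- **A packaged site table** of the published Hong Kong surveys (29 sites;
  2004–06, 2010, 2015 epochs) and a **seeded synthetic-data generator**
  whose single latent exposure gradient drives both stages and tissue
  concentrations, so the whole chain is testable offline.

## Worked example

Epoch-to-epoch trends on the packaged survey table:

```r
library(otrisk)
epoch_trends()
#>   variable    epoch_from epoch_to method         statistic    df n_pairs p_value
#> 1 mean_vdsi   2004-06    2010     wilcoxon_sign…     0.330    NA      28 7.41e-1
#> 2 mean_vdsi   2010       2015     paired_t_log10     2.41      9      10 3.91e-2
#> 3 rpsi        2004-06    2010     paired_t_log10     4.35     27      28 1.74e-4
#> 4 rpsi        2010       2015     paired_t_log10     2.43      9      10 3.81e-2
#> 5 pct_sterile 2010       2015     wilcoxon_sign…     1.89     NA      10 5.93e-2
```

Reading: mean VDSI was flat between the 2004–06 baseline and 2010
(Z = 0.330, p = 0.74 over the 28 sites surveyed in both epochs) but rose on
the 10 sites revisited in 2015 (t = 2.41, p < 0.05); RPSI increased in both
intervals. Unit conversion:

```r
dw_to_ww_sn(11108.0, "TPT")   # 753.4  µg Sn/kg ww  (TPT is 33.9 % tin)
dw_to_ww_sn(422.0,   "TBT")   # 34.5   µg Sn/kg ww
```

A fully synthetic risk run (generate → summarise → fit SSDs → Monte Carlo):

```r
cfg   <- generator_config(seed = 1)            # 29 sites, 40 snails each
paths <- run_simulate(cfg, "sim")
run_indices(paths[["survey"]], "sim/summaries.csv")
run_risk(paths[["tissue"]], paths[["toxicity"]], group = "PT",
         out_json = "sim/risk_PT.json", seed = 1)
#> risk (PT): P(at risk) = 0.2746 -> sim/risk_PT.json
#> PT: P(at risk) = 0.275; 13/29 sites above the lowest PNETC
```

`P(at risk)` is the mean exceedance fraction P(RQ ≥ 1) over the 10 Monte
Carlo repeats; the report JSON also records both candidate SSD fits, the
repeat-level spread and the 5/50/95 % RQ quantiles. With this generator
configuration roughly a quarter of the simulated phenyltin RQ mass lies
above 1 — a heavily contaminated scenario, as the 13 sites whose measured
concentrations exceed the lowest no-effect endpoint indicate.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the whole chain from scratch: the paired trend tests and
distance correlations on the packaged table, then a seeded synthetic
dataset pushed through indices, chemistry and both (butyltin and phenyltin)
risk assessments, writing the run's summary JSON to `--out`.

## Documentation

The methods vignette (`vignettes/organotin-biomonitoring.Rmd`) describes
the model assumptions, the numerical choices (censoring policy, SSD family
selection, Monte-Carlo protocol, test dialects) and the limits of what the
synthetic generator can establish.
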