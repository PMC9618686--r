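# metgxe

Multi-environment trial (MET) analysis of genotype-by-environment
interaction and stability, built around cassava processed-product traits.

## The problem

When cassava roots are processed into gari or dried fufu, the conversion
rate — product weight as a percentage of the fresh-root weight loaded into
processing — differs among genotypes and among environments, and a
genotype's rate in one environment predicts its rate elsewhere only
imperfectly. Breeding for high conversion rate therefore needs the
standard MET toolkit: variance components and heritability to show whether
selection can work at all, genotype-by-environment interaction (GEI)
models to characterise how ranking changes across environments, and
stability indices to pick genotypes that are both superior and consistent.
`metgxe` implements that pipeline end to end for plot-level trial data,
plus a synthetic-trial generator with known truth so that every estimator
is validated by parameter recovery.

It is aimed at breeders and quantitative geneticists analysing
variety-trial networks (the defaults mirror a 67-genotype × 8-environment
× 2-replicate uniform yield trial in two overlapping sets), but every
piece works on any long-format genotype × environment × replicate table.

## Models

* **Derived traits** — gari% = 100·(gari weight)/(starting root weight),
  likewise fufu%, peel loss%, fiber content%; FYLD (t/ha) =
  RTWT/(plants harvested × 0.8 m²) × 10; DYLD = FYLD·DM/100; product
  yields = FYLD × rate/100.
* **Variance components** (own sparse REML engine on the mixed-model
  equations; EM warm-up + bounded quasi-Newton):
  y = Xβ + Z_g u_g + Z_E u_E + Z_r(E) u_r + Z_gE u_gE + e, identity
  covariances, fixed row/column spatial trends; one-sided z-tests, percent
  variance explained, BLUPs with PEV.
* **Heritability** — entry-mean
  H² = σ²_g / (σ²_g + σ²_gE/e + σ²_ε/(er)) and Cullis
  H² = 1 − v̄_Δ/(2σ²_g) with the exact pairwise mean variance of BLUP
  differences; per-trial Cullis heritabilities per environment.
* **Deregression** — DRBLUP = BLUP/reliability, reliability
  = 1 − PEV/σ²_g, with a reliability floor; cross-trait Pearson
  correlations of DRBLUPs with t-tests.
* **GEI** on the genotype × environment BLUE table: Finlay–Wilkinson
  sensitivities (on the standardised table), AMMI (SVD of the
  double-centred interaction, Gollob df), GGE (SVD of the
  column-centred table, symmetric-scaled biplot coordinates,
  which-won-where hull flags), all partitioning one total SS.
* **Stability** — Wricke ecovalence W_i (Σ W_i = interaction SS) and the
  geometric adaptability index (geometric row mean), ranks, and the
  above-mean + top-k selection rule.

## Worked example

```r
library(metgxe)

sim <- simulate_met(sim_config(seed = 2024),
                    correlations = cassava_uyt_correlations())
fit <- fit_reml(sim$pheno, trait = "gari_pct")
fit
#> REML fit: gari_pct, n = 1101 plots, logLik = -2491.059 (converged)
#>          term estimate        SE         z      p_value pct_explained pinned
#>      genotype  0.83316 0.2155635  3.865022 5.553964e-05          9.02  FALSE
#>   environment  3.23260 1.8385817  1.758219 3.935509e-02         35.01  FALSE
#>    rep_in_env  0.30085 0.2838485  1.059885 1.445985e-01          3.26  FALSE
#>  genotype_env  1.40630 0.2261209  6.219153 2.499234e-10         15.23  FALSE
#>      residual  3.46010 0.2079136 16.642209 0.000000e+00         37.48  FALSE
```

The gari conversion rate is heritable (genotype variance 0.83, z = 3.9) but
environment and GEI together explain half the phenotypic variance — the
classic MET picture. On an entry-mean basis across 8 environments × 2
replicates:

```r
h2_standard(fit, e = 8, r = 2)$value   # 0.680
h2_cullis(fit)$value                   # 0.674
```

Build the genotype × environment table of adjusted means and rank
genotypes by adaptability, keeping only candidates above the population
mean:

```r
tw <- complete_table(two_way_means(sim$pheno, "gari_pct"))
st <- rank_and_select(stability_table(tw), "gai_top_k", k = 5)
head(st[order(st$GAI_rank), ], 5)
#>    genotype  mean    Wi Wi_pct_gei Wi_rank   GAI GAI_rank rank selected
#> 14      G09 22.93 22.93     1.5528      39 22.81        1    1     TRUE
#> 43      G38 22.49 42.68     2.8900      65 22.25        2    2     TRUE
#> 29      G24 21.91 15.62     1.0579      21 21.80        3    3     TRUE
#> 20      G15 21.86  8.60     0.5823       3 21.78        4    4     TRUE
#> 54      G49 21.80 10.04     0.6801       7 21.75        5    5     TRUE
```

G09 has the best geometric adaptability (GAI 22.81% conversion) but only
middling static stability (Wi rank 39 of 67, contributing 1.6% of the
interaction SS); G15 combines a top-5 GAI with a top-3 ecovalence. The
`selected` flag applies the above-mean + top-k rule. `fit_fw()`,
`fit_ammi()` and `fit_gge()` take the same table (`scale_table(tw)` for
Finlay–Wilkinson), and `run_pipeline(list(seed = 1), "out/")` executes the
whole chain — simulation or CSV ingest, trait derivation, REML,
heritabilities, DRBLUP correlations, the three GEI models and stability —
writing every table as CSV plus a JSON manifest, byte-reproducibly per
seed.

See `vignettes/met-analysis-methods.Rmd` for the models, their
assumptions, default parameter rationale, and known limitations.

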