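# siginfo

Information-theoretic analysis of single-cell cytokine signalling:
**how robust is STAT3 activation to cell-to-cell variation in STAT3
expression, and how many cytokine doses can a cell actually tell apart?**

`siginfo` is written for systems biologists working with multiplexed
intracellular flow cytometry of the IL-6/JAK-STAT pathway (and analogous
single-cell readouts). It implements:

* **Mutual information (MI)** between per-cell STAT3 expression *S* and
  STAT3-Y705 phosphorylation *R*,

  MI(S;R) = ∬ p(S,R) log₂ [ p(S,R) / (p(S)·p(R)) ] dR dS,

  estimated by Gaussian kernel density estimation with a covariance-scaled
  Scott bandwidth and adaptive Gauss–Legendre quadrature. Low MI is read as
  high *robustness*: activation that does not depend on the individual
  cell's STAT3 content.
* **Channel capacity (CC)** between the discrete Hy-IL-6 dose ladder and
  the continuous pSTAT3 response, CC = max over p(S) of MI(S;R), in bits;
  2^CC is the number of distinguishable dose states. Two estimators:
  classical Blahut–Arimoto iteration on kernel-estimated conditionals, and
  a classifier-based estimator (regularised multinomial logit with
  out-of-fold posteriors and input-weight reweighting).
* The accompanying **statistical scheme**: per-group centring/scaling,
  Kolmogorov–Smirnov normality screening, N-way and pairwise 1-way ANOVA,
  unbiased Cohen's d (d_unb = (m_A − m_B)/s_AB with
  s_AB = √((SS_A+SS_B)/(df_A+df_B))), effect classification at 0.2/0.5/0.8,
  and the two-stage flagging rule p ≤ 0.05 AND |d| > 0.2.
* A **synthetic single-cell generator** with genotype presets (wild-type,
  SHP2 ΔEx3, ΔEx3 + SHP2, MEK-inhibited wild-type) emulating heterogeneous
  dose-independent STAT3 expression and dose-dependent phosphorylation
  with a basal floor, so the whole pipeline runs and is tested end-to-end
  without instrument data.

See `vignettes/signalling-information.Rmd` for the model, estimator
details and design rationale.

## Worked example

```r
library(siginfo)

cfg <- synthetic_config(seed = 1)            # default study conditions

# robustness: MI between expression and phosphorylation, one replicate
basal <- log_transform(generate_condition(cfg, "wt", 0,   "early", 1))
sat   <- log_transform(generate_condition(cfg, "wt", 150, "early", 1))
estimate_mi(basal$stat3, basal$pstat3)
#> MI = 0.0872 bits (n = 6700, quadrature error 1.6e-07 bits)
estimate_mi(sat$stat3, sat$pstat3)
#> MI = 1.7622 bits (n = 6700, quadrature error 1.2e-06 bits)

# information transfer: capacity over the 7-dose ladder, one replicate
tabs <- lapply(DEFAULT_DOSES, function(d) generate_condition(cfg, "wt", d, "early", 1))
ch   <- channel_samples_from_events(study_table(tabs))
blahut_arimoto(conditional_densities(ch))
#> Channel capacity = 1.0776 bits (2^CC = 2.110 states; blahut_arimoto, 238 iterations)
```

Unstimulated wild-type cells show near-zero MI (0.09 bits): basal
phosphorylation is dominated by background and is *robust* to the ~3-fold
spread in STAT3 expression. At a saturating dose the phospho-signal is
proportional to expression and MI rises to 1.76 bits. Early wild-type
signalling over the full ladder transmits ~1.1 bits — the cell
distinguishes roughly two dose states (2^CC ≈ 2.1).

The full factorial pipeline (simulate → MI → CC → ANOVA/effect sizes →
CSV/JSON reports with a manifest) runs from one configuration object:

```r
res <- run_all(run_config(seed = 1, output = "out/"))
```

An example YAML configuration is shipped at
`inst/extdata/example_run.yaml` (`run_config_from_yaml()` reads it).

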