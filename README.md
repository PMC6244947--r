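# rtktraffic

Bayesian dissection of receptor tyrosine kinase (RTK) trafficking and its
reprogramming under MAPK-pathway inhibition.

Targeted kinase inhibitors in triple-negative breast cancer cells trigger
*RTK reprogramming*: non-genetic, coordinated shifts in the abundance of
receptors such as Axl, Met, EGFR and Her2 that blunt drug response. A
measured rise in total receptor is ambiguous — it could reflect faster
synthesis, slower degradation, slower endocytosis, faster recycling, or
reduced ectodomain shedding. `rtktraffic` is for systems biologists who
want to separate those contributions quantitatively from two standard
experiment types, without radioactive-ligand assays or broad-spectrum
inhibitors.

## The model

Receptor amounts live in three pools — surface $r_s$, internal $r_i$, and
free shed ectodomain $r_f$ — coupled by five rates:

$$
\dot r_i = k_{end} r_s - (k_{rec} + k_{deg}) r_i,\qquad
\dot r_s = P_{syn} + k_{rec} r_i - (k_{end} + k_{shed}) r_s,\qquad
\dot r_f = k_{shed} r_s,
$$

with $P_{syn}$ in molecules cell⁻¹ min⁻¹ and the four rates in min⁻¹.
The parameter posterior for each receptor/treatment/cell-line is obtained
by fitting jointly to

* **24-h end-point data**: replicated lysate ($r_t = r_s + r_i$) and
  supernatant ($r_f$) abundances in molecules/cell (converted from
  bead-ELISA readouts through a 5-parameter-logistic standard curve), and
* **pulse-chase biotinylation time courses**: total and internal labeled
  signal at 5–90 min,

under a log-normal error model, using a two-stage scheme: 100-start
latin-hypercube pattern search for the global optimum, then 4-chain
adaptive Metropolis (Haario-style covariance adaptation) with Gelman–Rubin
diagnostics. Downstream, single-parameter substitution attributes the
predicted abundance change to individual rates, posterior resampling
produces simulated-data envelopes, and PCA of the per-condition parameter
(or fold-change) matrices maps treatment and cell-line signatures. A
synthetic-data generator reproduces the study design (n = 12 end point,
n = 18 time course, LLOQ censoring) so the entire pipeline is testable
without any measurement files.

## Worked example

Simulate a Mek-inhibition-like study, fit the control and treated Met
analog, and attribute the abundance change (the sampler is scaled down to
20,000 iterations here; defaults are 100,000):

```r
library(rtktraffic)

sc  <- scenario(c("control", "mek_like"))
st  <- make_study(sc, seed = 1)
ctrl <- st$data$control$Met
trt  <- st$data$mek_like$Met

pri <- default_priors(kshed = estimate_kshed_prior(
  mean(ctrl$endpoint_supernatant), sd(ctrl$endpoint_supernatant),
  mean(ctrl$endpoint_lysate),      sd(ctrl$endpoint_lysate), seed = 1))
cfg <- am_config(n_iter = 20000, burn_in = 4000, seed = 1)

ctrl_fit <- fit_condition(ctrl, pri, cfg, n_starts = 30, seed = 2)
trt_fit  <- fit_condition(trt, update_treatment_priors(pri, ctrl_fit), cfg,
                          n_starts = 30,
                          rt0_prior = list(mean = mean(ctrl$endpoint_lysate),
                                           sd   = sd(ctrl$endpoint_lysate)),
                          seed = 3)
trt_fit
#> Trafficking model fit (4 chains, 20000 iterations, burn-in 4000)
#>   parameter       mean        sd        q05     median        q95
#> 1     p_syn  2.560e+00 7.739e-02  2.427e+00  2.564e+00  2.660e+00
#> 2     k_deg -2.093e+00 1.158e-01 -2.308e+00 -2.064e+00 -1.916e+00
#> 3     k_end -2.319e+00 2.482e-02 -2.362e+00 -2.317e+00 -2.284e+00
#> 4     k_rec -1.614e+00 6.453e-02 -1.735e+00 -1.595e+00 -1.528e+00
#> 5    k_shed -3.211e+00 5.411e-02 -3.295e+00 -3.204e+00 -3.129e+00
#> ...
```

The posterior medians sit within ~0.1 decades of the generating truth
(log10 P_syn 2.48, k_deg −2.14, k_end −2.32, k_rec −1.60, k_shed −3.22):
the treated Met analog's raised synthesis and lowered
degradation/endocytosis/shedding are all resolved. Attribution then asks
which rate changes *matter* for the 24-h lysate level:

```r
single_param_substitution(posterior_means(ctrl_fit), posterior_means(trt_fit),
                          rt0 = mean(ctrl$endpoint_lysate))
#>   parameter fold_change
#> 1     p_syn        1.40
#> 2     k_deg        1.13
#> 3     k_end        1.20
#> 4     k_rec        1.04
#> 5    k_shed        1.18
#> 6       all        2.37
```

Substituting the treated synthesis rate alone raises the predicted lysate
1.40-fold; degradation, endocytosis and shedding changes contribute
secondary 1.1–1.2-fold effects; all five together predict the observed
~2.4-fold increase. `run_pipeline()` chains these stages (simulate →
priors → fit → attribute → PCA) for all receptors and treatments from one
seeded config.

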