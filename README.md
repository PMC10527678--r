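# softsensr

Soft sensors for soluble-compound concentrations in fed-batch
*Escherichia coli* cultivations, estimated from off-gas measurements.

Offline assays for acetate and other solutes (lactate, glutamate,
glutamine, isoleucine) are slow and invasive; off-gas analysis is neither.
`softsensr` implements a hybrid estimator that turns the oxygen uptake
rate (OUR) and carbon dioxide production rate (CPR) into real-time solute
estimates, for bioprocess engineers and modellers who monitor fed-batch
runs:

1. **Latent physiology.** The strain oxygen balance
   `OUR = α dX/dt + β (X − X_cX)` — with the maintenance term β engaging
   once the cumulative biomass-time integral exceeds `k_cX` — is inverted
   to recover the latent biomass `X(t)`; from it follow the specific
   growth rate `μ = (dX/dt)/X` and the population's average and cumulative
   cell age (`cAge = Age · X`).
2. **Recurrent sensor.** A fixed LSTM stack — 23-step windows,
   LSTM(23, ReLU), dropout 0.2, dense(10, ReLU), dropout 0.2, a
   non-negative output unit — is trained with Adam (lr 0.001, batch 16)
   on the modified mean-square loss `MMSE = mean((|A*−A|+1)²)`, with
   early stopping on an experiment-level hold-out.
3. **Ensemble.** Input groups of 3–11 variables are enumerated from the
   measured + latent pool, screened (groups with MAE > 0.5 g/L or
   dominated by a better-scoring subset are dropped), retrained, ranked,
   and combined with RMSE-derived weights
   `wᵢ = (ΣRMSEⱼ − RMSEᵢ)/(ΣRMSEⱼ·(n−1))`. The committee size maximizes
   the Shannon entropy `H = −Σ p(x) log₂ p(x)` of the members'
   input-variable occurrence probabilities (or of LIME-style local
   surrogate importances).
4. **Simulator.** A mechanistic fed-batch generator (Monod growth,
   overflow-metabolism acetate, exponential feed, configurable noise)
   stands in for the proprietary cultivation campaigns, with two shipped
   scenarios: short dense runs (20 h, feed start 5–7 h) and long sparse
   runs (66 h, feed start 21 h, isoleucine co-feed, multi-solute).

The recurrent engine (BPTT, Adam, dropout, non-negativity constraints) is
implemented in C++/Armadillo inside the package and verified against
finite differences in the test suite.

## Worked example

Simulate a small campaign, fit the ensemble on six runs, validate on two
held-out runs:

```r
library(softsensr)

camp   <- generate_campaign(8, site = 1, base_seed = 42)
strain <- strain_params(alpha = 1.0, beta = 0.03, k_cX = 5)

fit <- soft_sensor(camp[1:6], camp[7:8], target = "acetate",
                   strain = strain,
                   pool = c("time", "our", "cpr", "biomass", "mu"),
                   sizes = 3:4, trials = 2,
                   config = sensor_config(max_epochs = 30, patience = 30),
                   seed = 42)
fit
#> Soft sensor for acetate: 15 groups screened, 10 retrained, committee of 10
#>   committee entropy 2.211 bits (occurrence probabilities)
#>   validation: MAE 0.0787 g/L, R2 0.976, nMAE 0.024 (best single model 0.1216 g/L)

round(weights(fit), 4)
#>  [1] 0.1064 0.1037 0.0991 0.0997 0.0983 0.0987 0.0992 0.0994 0.0982 0.0974

head(predict(fit, camp[[7]]))
#>    experiment time_h  estimate
#> 1 site1_run07    1.0 0.1372733
#> 2 site1_run07    2.2 0.1927254
#> 3 site1_run07    3.4 0.3006123
#> 4 site1_run07    4.6 0.5471987
#> 5 site1_run07    5.7 0.9366542
#> 6 site1_run07    6.9 1.6305849
```

Reading the output: 15 candidate input groups were screened, 10 survived
the MAE and subset-dominance filters, and the entropy criterion kept all
10 as the committee. On the two held-out runs the weighted committee
estimates acetate with a mean absolute error of 0.079 g/L (2.4% of the
observed range, R² 0.976), versus 0.122 g/L for the single best-ranked
model — the ensemble's gain. The weights are nearly uniform because the
members' RMSEs are close; `predict()` returns the committee estimate at
each assayed instant of a new run.

`run_pipeline(pipeline_config(site = 1, seed = 1), out_dir = "out")`
executes the same flow at the documented desk scale (12 + 5 runs, pool of
8, 182 groups) and writes every artifact (records, latent states,
evaluation table, committee manifest, predictions, metrics, manifest) as
CSV/YAML. A thin command-line wrapper with per-stage subcommands ships in
`inst/cli/softsensr`.

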