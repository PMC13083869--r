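# ecoassemble

Step-wise eco-evolutionary assembly of ecological communities with
multiple interaction types, for theoretical ecologists studying how
selection and inheritance of interactions shape network structure, and for
microbial ecologists comparing model communities against macroecological
patterns in abundance data.

## The model

Species abundances follow generalized Lotka-Volterra dynamics with
mutualistic (+/+), competitive (-/-) and consumer-resource (+/-)
interactions, Type II functional responses, and a per-link harvesting cost
on positive interactions:

```
(1/x_i) dx_i/dt = r_i - n⁺_i δ - s_i x_i - Σ_j c_ij x_j
                  - Σ_j p⁻_ij x_j / (1 + h_p Σ_k p⁺_jk x_k)
                  + Σ_j p⁺_ij x_j / (1 + h_p Σ_k p⁺_ik x_k)
                  + Σ_j m_ij x_j / (1 + h_m Σ_k m_ik x_k)
```

Communities assemble from five unlinked species through 500 introduction
events, each newcomer arising either by **speciation** — the offspring
copies its parent's interactions with at most Δ changes (interaction
inheritance) — or by **invasion** with randomly assigned interactions.
The balance between interaction strength σ and link cost δ splits
outcomes into competition-dominated (T1) and mutualism-dominated (T2)
regimes; a mean-field analysis locates the cost-benefit threshold in the
number of mutualistic links a species can profitably hold. The package
also computes network-structure metrics (connectance, degree entropy,
modularity) scored against Erdős–Rényi nulls, and macroecological
statistics (standardised log-mean abundance distribution, pairwise
correlations, Wasserstein distances) from stochastic (Euler–Maruyama)
abundance time series, for comparison with microbial OTU tables.

## Worked example

```r
library(ecoassemble)

# strong-benefit (T2) evolutionary assembly, desk scale
params <- model_params(delta = 0.01, sigma = 0.2)
config <- assembly_config("evo", Delta = 5, n_events = 150)
tr <- run_assembly(config, params, seed = 42)
glance(tr)
#> # A tibble: 1 × 11
#>   scenario     S     L connectance complexity prop_m prop_c prop_cr
#>   <chr>    <int> <int>       <dbl>      <dbl>  <dbl>  <dbl>   <dbl>
#> 1 evo         42  1170       0.663       27.9  0.624 0.0154   0.361
#> # ℹ 3 more variables: n_extinctions <int>, survival_rate <dbl>,
#> #   n_nonconverged <int>
```

After 150 events at strong benefits the community holds 42 species whose
links are 62% mutualistic and only 1.5% competitive — the T2 signature;
the same run at `delta = 0.025, sigma = 0.05` yields a sparse,
competition-dominated community. `tidy(tr)` returns the per-event log
(mechanism, survival, extinctions), `autoplot(tr)` the structural
trajectory.

```r
# structural metrics with Erdős–Rényi null scores
metrics_report(tr$final$comm, n_null = 50, seed = 7)

# mean-field: at high cost even the first mutualistic link fails to pay
k1_threshold(meanfield_params(r = 0.1, delta = 0.02, mu = 0.16, gamma = 1))$threshold
#> [1] 1

# stochastic time series and macroecology
noise <- noise_config(sd = 0.1, n_samples = 300)
tab <- simulate_em(tr$final$comm, tr$final$state$x, noise, params, seed = 3)
mad <- mad_standardized(to_relative(tab))
autoplot(mad)
```

A thin command-line front end is installed as `exec/ecoassemble`
(subcommands `run`, `meanfield`, `metrics`, `macroeco`, `heatmap`,
`trajectory`); see `vignettes/community-assembly.Rmd` for the methods.

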