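---
title: "Eco-evolutionary community assembly with multiple interaction types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary community assembly with multiple interaction types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ecoassemble` simulates the step-wise assembly of ecological communities in
which species are coupled by three interaction types — mutualism (+/+),
competition (-/-) and consumer-resource (+/-) — under generalized
Lotka-Volterra dynamics with Type II (saturating) functional responses on
the positive terms. The per-capita growth rate of species $i$ is

$$
\frac{1}{x_i}\frac{dx_i}{dt} =
 r_i - n^+_i\,\delta - s_i x_i - \sum_j c_{ij} x_j
 - \sum_j \frac{p^-_{ij} x_j}{1 + h_p \sum_k p^+_{jk} x_k}
 + \frac{\sum_j p^+_{ij} x_j}{1 + h_p \sum_k p^+_{ik} x_k}
 + \frac{\sum_j m_{ij} x_j}{1 + h_m \sum_k m_{ik} x_k},
$$

where $x_i$ is abundance, $r_i$ the intrinsic growth rate, $s_i$
intraspecific competition, and $m_{ij}$, $c_{ij}$, $p^{\pm}_{ij}$ the
non-negative interaction strengths (zero without a link; all interactions
are interspecific). $n^+_i$ counts the links in which $i$ is a mutualist or
a consumer; each such link costs $\delta$ in baseline reproduction — the
energetic burden of acquiring and maintaining a benefit. Note the asymmetry
in the consumer-resource terms: the loss a resource suffers saturates over
the *consumer's* total resource intake ($\sum_k p^+_{jk} x_k$), whereas
gains saturate over the focal species' own sources. The balance between the
interaction-strength scale $\sigma$ (new strengths are $|N(0,\sigma^2)|$)
and the per-link cost $\delta$ decides whether accumulating positive links
pays off, and this cost-benefit balance separates two community regimes:
weak benefits give sparse, competition-dominated networks (called T1 here),
strong benefits give highly connected, mutualism-dominated ones (T2).

Consumer-resource pairs obey a trophic-inefficiency constraint: the
consumer's gain coefficient never exceeds the resource's loss coefficient
($p^+_{ij} \le p^-_{ji}$); sampled or mutated gains are capped at the paired
loss.

## Assembly mechanisms

Assembly starts from five unlinked founder species (abundances uniform on
$[0, 0.02]$) and proceeds by introducing one newcomer per event at the
extinction-threshold abundance $10^{-6}$, always after the community has
relaxed to ecological equilibrium. Newcomers arise by

* **speciation** (`scenario = "evo"`): a uniformly chosen parent's
  pair-links are copied with small multiplicative strength noise
  ($w' = w\,|1 + N(0, (0.05 w)^2)|$, types preserved), then $d \sim
  U\{1..\Delta\}$ modifications are applied — $U\{1..d\}$ creations, the
  rest deletions, converting impossible deletions into creations and vice
  versa. New links pick their type from two independent fair signs (so 1/4
  mutualism, 1/4 competition, 1/2 consumer-resource). Growth rate and
  self-regulation are re-sampled, not inherited. Small $\Delta$ means
  strong inheritance.
* **invasion**: the invader links to each resident independently with a
  connectivity drawn uniformly from $[\rho_1, \rho_2] = [0.01, 0.5]$.
  Under `inv_rand` every link takes one of the four roles (mutualist,
  competitor, consumer, resource) with probability 1/4; under `inv_prop`
  each invader first draws its own role proportions uniformly on the
  simplex (flat Dirichlet), which creates among-invader variability in
  interaction-type composition that ecological filtering can act on.

Every introduction counts as one assembly event whether or not the
newcomer persists; survival is recorded in the event log. Whether an event
should instead require a *thriving* newcomer is a genuine ambiguity of the
design; counting all introductions is the default, and
`assembly_config(retry_failed = TRUE)` switches to retrying failed
introductions (capped at 50 attempts per event) so that every event
establishes a species. The choice matters for scenario comparisons:
mechanisms differ in establishment rate, and only the count-all convention
lets that difference show up in richness trajectories. After the first
20 events, species left with no interactions are removed after each event.

## Key parameters

| parameter | meaning | default |
|---|---|---|
| `delta` | cost per positive link (growth-rate units) | 0.01 |
| `sigma` | interaction-strength scale | 0.2 |
| `h_p`, `h_m` | handling times (time units) | 0.1 |
| `mu_r`, `sigma_r` | growth-rate distribution | 0.1, 0.1 |
| `K_log_mu`, `K_log_sigma` | lognormal carrying capacities | -2.2, 0.5 |
| `x_ext` | extinction threshold | 1e-6 |
| `Delta` | max parent-offspring link changes | 5 |
| `rho1`, `rho2` | invader connectivity bounds | 0.01, 0.5 |
| `n_events` | assembly events | 500 |

Growth rates are drawn half-normal, $|N(\mu_r, \sigma_r^2)|$, which
guarantees the positivity the model assumes; a plain-normal variant with
resampling of non-positive draws is available via
`model_params(growth_dist = "normal")`. Self-regulation is set as
$s_i = r_i / K_i$ with lognormal $K_i$. Competition pair strengths
$c_{ij}, c_{ji}$ are drawn independently, mirroring the independent
sampling of the two mutualistic directions.

## Numerical choices

**Equilibrium criterion.** A community is at equilibrium when every
surviving species changes by less than 0.01% (relative) over ten
consecutive steps of size 0.01 time units. Relative change uses
$|\Delta x| / \max(x, x_{ext})$ so near-zero abundances cannot blow up the
criterion. Because this stopping rule triggers while per-capita growth
rates are merely small (not zero), relaxed states sit within a few percent
of the exact fixed point; tests that compare against analytic equilibria
use tolerances of that order, and the two-route integration test compares
the solvers at the same time horizon instead.

**Integration.** The equilibrium relaxation uses an adaptive
Dormand-Prince 4(5) stepper (rtol $10^{-8}$, atol $10^{-10}$, far tighter
than the equilibrium tolerance), implemented in compiled code because a
full assembly run performs hundreds of relaxations. Evaluating the
criterion at every 0.01-unit checkpoint across runs that may span
$5 \times 10^4$ time units would cost millions of checkpoints, so the
integrator alternates candidate equilibrium windows (ten 0.01-unit steps,
checked stepwise) with coarse chunks whose length doubles from 1 up to 64
time units; extinctions are applied at window steps and chunk boundaries.
A species falling strictly below `x_ext` is zeroed immediately, the
equilibrium window restarts, and — because extinct species leave the
system — the positive-link cost counts $n^+$ of its partners are updated
on the spot. An independent `deSolve::lsoda` route is kept in the test
suite as a cross-check of the compiled integrator. Relaxations hitting
`max_integration_time` ($5 \times 10^4$) are accepted as-is and counted in
`n_nonconverged`.

**Degenerate states.** If every species goes extinct, the next event
introduces a fresh unlinked species sampled like a founder (speciation has
no parent and invasion no residents to link to); this is practically
unreachable at the default parameters but keeps long runs total. The
extinction comparison is strict (`<`), so newcomers introduced exactly at
`x0_new = x_ext` are not removed on arrival.

## Mean-field threshold analysis

Treating the community as an average background, the equilibrium abundance
$\bar{x}$ of a focal species with $k_1$ mutualistic links of mean strength
$\mu$, interspecific competition $k_2$ and self-regulation $\gamma$ solves

$$0 = r - \delta k_1 + \frac{k_1 \mu x}{1 + k_1 h_m \mu x} - k_2 \mu x - \gamma x,$$

and one extra mutualistic link pays off when
$\mu \bar{x} / (1 + h_m k_1 \mu \bar{x}) - \delta > 0$. `k1_threshold()`
scans a grid of $k_1$ (link counts, hence a grid rather than continuous
root-finding) and returns the first degree at which the benefit fails.
The balance equation can have several positive roots; the largest is taken
as the background abundance reached when assembling from positive
abundance, found by a dense sign scan plus `uniroot` refinement (residuals
below $10^{-10}$); the linear case $h_m = 0$ uses its closed form. The
threshold moves to lower $k_1$ under higher cost $\delta$ and under
stronger self-regulation $\gamma$ — the mean-field explanation of the
T1/T2 separation. $\gamma$ defaults to 1, matching the scale of the
simulated $s_i$ (median carrying capacity $e^{-2.2} \approx 0.11$ at
$r \approx 0.1$).

## Network metrics

Structural metrics are computed on the undirected, unweighted projection
(one edge per interacting pair; isolated species remain as degree-0
nodes), while connectance keeps its directed definition $C = L/S^2$ with
every pair contributing two directed links. Degree entropy is
$H = -\sum_k P(k)\ln P(k)$ over the empirical degree distribution;
modularity follows the explicit resolution formula
$\sum_c (L_c/m - \epsilon\,(k_c/2m)^2)$ at $\epsilon = 1$, evaluated on
Louvain partitions (igraph implementation, five seeded vertex-order
restarts, best formula value kept, since Louvain is order-dependent). Both
metrics are expressed as effective increases $Z_s = (Z - Z_r)/Z_r$ over
the mean of 50 Erdős–Rényi graphs; the nulls are undirected $G(S, p)$ with
$p$ matched to the projected network's edge count, which is the object the
metrics are actually computed on. For weighted variants the pair's two
directed strengths are summed into the edge weight, and node strength is
binned into 20 equal-width classes before the entropy formula (a binning
choice that makes the weighted entropy well defined).

## Macroecology

To compare assembled communities with microbial abundance data, the final
equilibrium is perturbed with multiplicative environmental noise:
$dx_i = x_i g_i\,dt + \text{sd}\,x_i\,dW_i$ (sd = 0.1), integrated with
Euler–Maruyama at $dt = 10^{-3}$, sampling `n_samples = 300` rows at
1-time-unit spacing after a 50-unit burn-in (the sampling cadence is a
package default; only "evenly spaced, non-overlapping" is inherent to the
design). Negative excursions clip to 0, which is absorbing because both
terms are proportional to abundance; recorded values below `x_ext` appear
as 0 but species are not pruned. The no-interaction null re-runs the same
scheme with all interaction matrices zeroed, starting from the exact
logistic equilibria $K_i = r_i/s_i$ so sampling begins at the new
equilibrium.

Statistics mirror standard microbial macroecology: the standardised
log-mean relative abundance distribution (MAD; per-taxon mean relative
abundance, logged, z-scored across taxa, zero-mean taxa excluded and
counted) and the distribution of pairwise Pearson correlations of relative
abundances (the estimator is configurable; the correlation transform used
in the original analyses is not fully determined, and Pearson-on-relative
is the default here). Distributions are compared by the 1-D Wasserstein
distance (quantile-function $L_1$), computed on raw value lists, with
densities (Freedman–Diaconis histograms) kept only for display. The
summary score $(W_{se} - W_{ee})/W_{ee}$ relates the mean
simulated-empirical distance to the mean empirical-empirical distance.

Empirical tables are TSV/CSV counts (samples x taxa or taxa x samples,
auto-detected) filtered to samples with at least 10,000 reads. The bundled
generator `generate_fixture_table()` produces synthetic stand-ins —
lognormal taxon means, optional per-sample lognormal fluctuations,
multinomial sampling at fixed depth — that emulate the abundance spectrum
and sampling depth of real tables but contain **no ecological
interactions and no real taxa**: tests passing against fixtures show the
statistics pipeline is correct, not that the model matches real
microbiomes.

## Problem sizes

The full study scale is 500 events with 15 (heatmap) or 20 (trajectories,
macroecology) replicates over a 6x6 `(delta, sigma)` grid. The package's
desk-scale profile — used by its own test suite and acceptance script —
runs 150 events with 3–5 replicates at the two regime points T1
(`delta = 0.025, sigma = 0.05`) and T2 (`delta = 0.01, sigma = 0.2`),
which already separates the regimes cleanly while keeping a full check
run in minutes. Scaled-down runs reproduce orderings and regime
classifications, not the exact figures of the full scale.

## Known limitations

* No rewiring of established links, no trait or spatial structure, no
  Type III responses, no stability analysis of the mean-field fixed point.
* The equilibrium stopping rule accepts states a few percent away from the
  exact fixed point (by construction); quantities derived from equilibria
  inherit that tolerance.
* The desk-scale scenario comparisons are stochastic over few replicates;
  orderings among similar scenarios (e.g. the two invasion flavours) can
  flip between seeds at 150 events even though the T1/T2 regime split is
  robust.
* Compositional artefacts of relative abundances (negative correlation
  bias, CLR-type corrections) are deliberately not addressed.
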