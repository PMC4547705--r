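# mgwnet

Estimation of T cell proliferation, death and trafficking parameters from
generation-resolved (CFSE) cell counts, using a multi-type Galton–Watson
branching process with migration on a feedforward network of lymphoid
organs.

## Who this is for

Quantitative immunologists and modellers analysing in vivo CFSE dilution
experiments in which antigen-specific T cells are primed in a draining
lymph node and disseminate to distal organs, and anyone needing a
discrete-time branching-process engine (exact simulation + closed-form
moments + frequency likelihood) for generation-structured populations on
a recirculation-free compartment network.

## The model

Types are pairs (compartment, generation `i` = number of divisions,
0..p).  Compartments are a source (draining lymph nodes, `DR`), `K`
serial transfer stages representing the lymphatic/blood transit, and sink
organs (`SPL`, `ILN`, `MLN`).  Per time step (Δt = 4 h) a cell of
generation `i`:

| fate      | probability              | offspring                          |
|-----------|--------------------------|------------------------------------|
| divide    | γ_i                      | 2 cells of generation i + 1        |
| quiesce   | δ_i                      | itself                             |
| migrate   | m (source, i ∈ {1,2,3})  | 1 cell entering the transfer line  |
| die       | 1 − γ_i − δ_i − m_i      | none                               |

γ_i, δ_i are generation-specific for i = 0, 1, 2 (later generations
inherit i = 2) and shared across organs; cells leaving the transfer line
split onto the sinks with probabilities ρ = (ρ_spl, ρ_il, ρ_mes),
Σρ = 1.  A 12 h transit at 4 h steps gives K = 3 transfer legs, so
migrants reach the sinks three steps after egress.

The package provides, for the 10-parameter vector
θ = (δ₀, γ₀, δ₁, γ₁, δ₂, γ₂, m, ρ_spl, ρ_il, ρ_mes):

* exact first/second moment recursions of per-type counts,
  μ(n+1) = Mᵀμ(n), Σ(n+1) = Mᵀ(Σ(n) − diag μ(n))M + diag(Qᵀμ(n));
* delta-method moments (π, Ω) of per-animal relative frequencies, the
  observable robust to inter-animal population-size differences;
* the normal-approximation negative log-likelihood
  ½ Σ_a [(f_a − π)ᵀΩ⁻¹(f_a − π) + log det 2π̃Ω] on the reduced
  (last-category-dropped) frequency space;
* constrained multi-start maximum likelihood with observed-Fisher
  standard errors, a relative-sensitivity statistic S(θ_i), an exact
  stochastic simulator, and a synthetic sacrifice-design data generator.

See `vignettes/tcell-network-model.Rmd` for the full methods account.

## Worked example

Generate the canonical synthetic dataset (true θ = the reference
estimates, 5 animals sacrificed at each of n = 0, 3, 6, i.e. 72/84/96 h,
initial draining-node population 5×10⁴ cells over generations 0–4), fit
it, and profile the sensitivities:

```r
library(mgwnet)

topo  <- network_topology()        # DR -> 3-leg transit -> SPL/ILN/MLN
fx    <- default_fixture()         # counts + generating truth
fit   <- fit_mle(fx$data, topology = topo)
print(fit)
```

```
Branching-network maximum-likelihood fit
  NLL = -1163.09  (20 starts, scope = global)
        estimate std_error
delta0    0.4350    0.0092
gamma0    0.0631    0.0074
delta1    0.3143    0.0089
gamma1    0.2995    0.0086
delta2    0.2308    0.0056
gamma2    0.2442    0.0051
m         0.1471    0.0090
rho_spl   0.9509    0.0010
rho_il    0.0097    0.0004
rho_mes   0.0394    0.0009
```

Every estimate sits within a few standard errors of the generating values
(δ₀ = 0.43, γ₀ = 0.06, δ₁ = 0.31, γ₁ = 0.29, δ₂ = 0.23, γ₂ = 0.24,
m = 0.14, ρ = 0.95/0.01/0.04): undivided cells die with probability
≈ 0.5 per step, about 14% of once-to-thrice-divided cells leave the
draining node per step, and 95% of emigrants end up in the spleen.

```r
prof <- relative_sensitivity(fit, fx$data, fit$initial, topo)
summary(prof)
```

```
   parameter      max_S
1     gamma2 7.80422551
2     delta1 1.32527504
3     delta0 1.30074559
4     delta2 1.21901716
5          m 1.21808769
6    rho_spl 1.21208683
7     gamma1 0.54869397
8    rho_mes 0.09154019
9     gamma0 0.03823778
10    rho_il 0.02157173
```

The likelihood is most sensitive to γ₂, δ₁, δ₀ and ρ_spl — the
parameters this experimental design pins down best.

## Command line

A thin wrapper over the same functions lives in `inst/cli/mgwnet`:

```sh
mgwnet synth --animals 5 --steps 0,3,6 --seed 11 --out-prefix demo
mgwnet fit --data demo_counts.csv --out fit.json
mgwnet sensitivity --fit fit.json --data demo_counts.csv --out sens.csv
mgwnet simulate --initial init.csv --steps 6 --paths 1000 --out paths.csv
mgwnet moments --initial init.csv --steps 6 --out moments.csv
```

Counts CSV schema (exact header):
`animal_id,time_hours,n,organ,generation,count`, with
`time_hours = 72 + 4 n`.  Fit results are JSON with full-precision
`theta`, `se`, `nll`, per-start convergence diagnostics and
identifiability flags.

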