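# occumeta

Occupancy modeling for functional presence/absence in metagenomes.

## The problem

When a gene or pathway is not annotated in a metagenome, there are two
explanations: the function is genuinely absent from the community (a true
negative), or sequencing depth, assembly, or annotation missed it (a false
negative). Metagenomic surveys usually cannot tell these apart.
Macroecology has faced the same problem for decades — a bird not seen in a
forest may be absent or merely undetected — and solved it with **occupancy
models**. `occumeta` adapts that framework to metagenomics for researchers
who screen many metagenomes for a function of interest and want a
quantified probability that an absence is real.

The key adaptation: instead of revisiting a site on multiple days, the
*independent marker genes* of an enzyme complex inside a single metagenome
serve as the replicate surveys. The built-in panels cover the methane
cycle — methyl-coenzyme M reductase (MCR; subunits McrA/McrB/McrG,
methanogenesis) and particulate methane monooxygenase (pMMO; subunits
PmoA/PmoB/PmoC, aerobic methanotrophy) — but any panel of markers can be
declared with `marker_panel()`.

## The models

**Single species.** Each site *i* (a metagenome, or an aggregate of
metagenomes sharing coordinates) has latent occupancy
*z_i* ~ Bernoulli(Ψ_i) and, given presence, each of the K markers is
detected independently with probability *p_i*:

    logit(Ψ_i) = x_i' β        logit(p_i) = w_i' α

For a history y with s = Σy detections the site likelihood is
`Ψ p^s (1−p)^(K−s)` when s > 0 and `Ψ (1−p)^K + (1−Ψ)` when s = 0.
Covariates (ecosystem category, latitude, √ add date) enter either
component; models are fitted by maximum likelihood and compared with
AIC = −2ℓ + 2k. The naive estimate — the share of sites with ≥ 1
detection — has expectation Ψ(1−(1−p)^K) and *underestimates* Ψ whenever
p < 1; the model corrects this.

**Two species.** Joint presence of two functions follows a multivariate
Bernoulli with natural parameters f1, f2, f12: the four latent states get
log-weights (0, f1, f2, f1+f2+f12). f12 > 0 means positive co-occurrence;
`conditional_occupancy()` turns the fitted state probabilities into
P(function A present | function B present/absent). Detection is
intercept-only per species.

Upstream of the models, a curation pipeline reduces candidate marker
sequences to credible true positives: a protein-specific length window
(reference span ± 50 aa), classification by best labeled homology hit,
and a phylogenetic screen (nearest labeled leaf + long-branch rule).

## Worked example

```r
library(occumeta)

# a synthetic survey with ecosystem-structured occupancy and imperfect
# detection (p = 0.45), 1000 metagenome-sites, 3 markers
cfg <- simulation_config(
  n_sites = 1000, K = 3,
  psi_terms = "ecosystem",
  beta_psi  = c(qlogis(0.3), qlogis(0.7) - qlogis(0.3), 0.2),
  alpha_p   = qlogis(0.45), seed = 42)
sim <- simulate_single(cfg)

naive_occupancy(sim$history)
#> [1] 0.501

fits <- list(
  occu(sim$history, sim$sites, "p ~ 1, psi ~ 1"),
  occu(sim$history, sim$sites, "p ~ 1, psi ~ ecosystem"),
  occu(sim$history, sim$sites, "p ~ sqrt(numeric.add.date), psi ~ latitude"))
delta_aic(fits)
#> # A tibble: 3 × 4
#>   model                                      n_params   AIC delta_AIC
#>   <chr>                                         <int> <dbl>     <dbl>
#> 1 p ~ 1, psi ~ ecosystem                            4 3260.       0
#> 2 p ~ 1, psi ~ 1                                    2 3327.      66.2
#> 3 p ~ sqrt(numeric.add.date), psi ~ latitude        4 3331.      70.2
```

AIC selects the ecosystem model that generated the data. Predicted
occupancy per ecosystem, with 95% Wald intervals on the link scale:

```r
best <- fits[[2]]
predict_occupancy(best, tibble::tibble(
  ecosystem = c("engineered", "environmental", "host-associated")))
#> # A tibble: 3 × 3
#>   estimate lower upper
#>      <dbl> <dbl> <dbl>
#> 1    0.342 0.228 0.478
#> 2    0.691 0.640 0.738
#> 3    0.295 0.218 0.386
```

Note the naive estimate (0.501) sits well below the fitted occupancy of
the dominant environmental category (0.691): with p ≈ 0.45 and K = 3,
roughly 17% of occupied sites show no detection at all.

Co-occurrence of two functions:

```r
cfgm <- simulation_config(n_sites = 3000, K = 3, beta_f12 = 1.5,
                          p1 = 0.5, p2 = 0.5, seed = 4001)
simm <- simulate_multi(cfgm)
fitm <- occu_multi(simm$history1, simm$history2, n_starts = 2)
st <- state_probs(fitm$coef[["f1_(Intercept)"]],
                  fitm$coef[["f2_(Intercept)"]],
                  fitm$coef[["f12_(Intercept)"]])
conditional_occupancy(st, 1, given_present = TRUE)   # 0.812
conditional_occupancy(st, 1, given_present = FALSE)  # 0.501
```

The fitted interaction (f̂12 = 1.46, truth 1.5) translates into a
function being far more likely present where its partner is present.

`tidy()`, `glance()` and `autoplot()` work on both fit classes, and the
`run_*()` functions (or `inst/cli/occumeta.R` from a shell) chain
curation → table building → fitting on files.

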