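---
title: "Occupancy modeling for metagenome-derived functional surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy modeling for metagenome-derived functional surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occumeta)
```

## Motivation and model

A gene missing from a metagenome is ambiguous: genuinely absent, or
missed by sequencing and assembly. Occupancy models resolve this
ambiguity by separating *presence* from *detection*. `occumeta`
implements the single-season occupancy model and its two-species
extension with metagenome-specific plumbing: the replicate surveys of a
site are the independent marker genes of an enzyme complex, screened
simultaneously in one assembly.

For site $i$ with detection history $y_{i1},\dots,y_{iK}$ and
$s_i = \sum_k y_{ik}$:

$$
L_i(\psi_i, p_i) =
\begin{cases}
\psi_i \, p_i^{s_i} (1-p_i)^{K-s_i} & s_i > 0\\[2pt]
\psi_i (1-p_i)^K + (1-\psi_i) & s_i = 0
\end{cases}
$$

with $\mathrm{logit}(\psi_i) = x_i^\top\beta$ and
$\mathrm{logit}(p_i) = w_i^\top\alpha$. The logit link is the standard
choice for this model family and is used for both components. Because
all $K$ markers come from one DNA extraction, the closure assumption
(no change of occupancy state between surveys) holds by construction;
independence across sites holds when samples are not cross-contaminated;
heterogeneity in $\psi$ and $p$ is absorbed by covariates; and the
no-false-positive assumption is the job of the curation pipeline below.

The two-species model is the multivariate Bernoulli parameterization:
the joint latent states $(z_1,z_2) \in \{00,10,01,11\}$ receive
log-weights $(0, f_1, f_2, f_1+f_2+f_{12})$, normalized by softmax
(`state_probs()`, computed with max-subtraction so extreme natural
parameters cannot overflow). $f_{12}=0$ factorizes exactly into two
independent logistic occupancies — a property the test suite checks by
comparing the jointly maximized likelihood with the sum of the two
single-species fits. Detection in the two-species model is
intercept-only per species; site- or survey-varying detection there is
out of scope.

## Curation: from candidate sequences to evidence

Candidate marker proteins (e.g. KO-annotated hits for McrA) pass three
screens, each recorded per sequence in a disposition ledger so the
stages always partition the input:

1. **Length window.** Per marker, candidates must lie within
   [min − 50, max + 50] residues of the *true-positive* reference
   lengths (floored at 1). False-positive references (off-target
   homologs such as ammonia monooxygenase subunits, or ANME-associated
   MCR) do not shape the window — the window describes the target
   family, the false positives exist only to catch confusable
   sequences.
2. **Top hit.** A candidate is kept only when its maximum-bit-score hit
   is a reference labeled `true_positive`. Ties are resolved
   conservatively: the candidate survives only if *every* tied-best
   subject is a true positive, serving the model's no-false-positives
   assumption. Candidates absent from the hit table are removed
   (`no_hit`): missing homology evidence cannot certify a true
   positive. The classification is provably invariant to hit-row order.
3. **Tree screen.** Where a tree over candidates and labeled references
   is available, a candidate is flagged when its nearest labeled leaf
   by patristic distance is a false positive, or when its terminal
   branch exceeds `median + c · MAD` of all terminal branches. The MAD
   here is the raw median absolute deviation (no 1.4826 normal-
   consistency factor — the cutoff is a robust rule of thumb, not a
   normal-theory estimator). The default `c = 6` is deliberately
   permissive: the stage is meant to catch order-of-magnitude outliers,
   and raising `c` can only grow the kept set (tested property). This
   rule is an explicit, reproducible stand-in for manual phylogenetic
   judgment; it is not claimed to replicate any particular expert
   decision. ANME exclusion is handled by labeling ANME reference
   sequences `false_positive`, so both the top-hit and tree stages
   remove candidates closest to them without needing a distance
   threshold.

Thresholds used upstream of the package (e.g. e-value cutoffs of the
homology search that produced the hit table) are properties of that
search, not of this pipeline; the pipeline consumes whatever rows the
table contains.

## Sites, aggregation and covariates

Three site definitions are supported: each metagenome its own site;
metagenomes with identical geographic coordinates merged (soil cores and
depth profiles collapse to one site); and coordinate groups additionally
split by ecosystem category, since co-located but physically separate
systems (a rumen and the pasture soil around it) should not be one site.
Within a site, detections are OR-ed: one member metagenome encoding the
marker suffices.

Decisions worth knowing:

* **Grouping key.** Coordinates are compared as trimmed text, exactly
  as they appear in the metadata. Numeric rounding would silently merge
  distinct sites; textual identity never does.
* **Aggregated covariates.** Ecosystem is uniform by construction under
  the coordinate + ecosystem scheme and is *not emitted* under the
  coordinate-only scheme (members may disagree; only latitude and date
  models are meaningful there). The aggregate add date is the earliest
  member date. Latitude/longitude come from the shared coordinates.
* **Sample date** never participates in grouping; a `mixed_dates` flag
  and an `n_mixed_dates` attribute report how many aggregated sites mix
  sampling dates.
* **Dates** become integer days since 2006-01-01 (the epoch maps to 0);
  earlier dates are an error, not clamped. The detection covariate is
  the square root of this count and enters the model unstandardized.
* **Missing metadata** is handled by listwise removal only, with the
  required covariates named explicitly; `drop_incomplete()` is
  idempotent.
* **Factor coding.** Ecosystem uses treatment contrasts against the
  lexicographically first level ("engineered" for the standard three).
  Likelihood and AIC are invariant to this choice (tested); only
  coefficient labels change.

## Fitting, uncertainty, and numerical choices

Both fitters maximize the exact marginal likelihood by BFGS from five
starts (the zero vector plus four seeded standard-normal perturbations;
the seed is stored in the fit). The best likelihood wins; non-convergence
of the best start is a warning carried on the object. Standard errors
come from the inverse observed information (numerical Hessian at the
optimum); when that matrix is near-singular the Moore–Penrose
pseudo-inverse is used and a warning raised.

Degenerate situations are flagged, never hidden:

* any fitted $\psi_i$ or $p_i$ within $10^{-6}$ of 0/1 sets the
  boundary flag (e.g. all-ones histories);
* $K = 1$ makes only the product $\psi p$ identifiable — the fit
  proceeds and warns;
* a species never detected anywhere yields a non-identifiability
  warning;
* rank-deficient designs error, naming the collinear columns;
* a two-species interaction coefficient exceeding 10 in absolute value
  raises a quasi-separation flag.

Wald intervals for predictions are computed on the linear predictor and
mapped through the inverse logit, so they stay inside (0,1) and always
contain the point estimate. Conditional-occupancy curves default to a
parametric bootstrap (1000 draws from the normal approximation of the
coefficient vector, seeded): conditional occupancy is a ratio of sums of
transformed Gaussians, and the delta method can misbehave near
boundaries. The delta method remains available (`method = "delta"`) and
agrees with the bootstrap to within 0.05 on well-behaved fits (tested);
with `n_boot = 0` points are returned without intervals.

AIC is $-2\ell + 2k$ with $k$ the total count of design columns (plus
the two detection intercepts in the two-species model; the headline
ecosystem / ecosystem + √date / ecosystem structure counts
$3+4+3+2 = 12$). Comparison tables order by ascending AIC with ties in
input order; the file exports keep a full-precision copy beside the
2-decimal display copy.

## What the synthetic data does and does not emulate

`simulation_config()` defaults describe a global metagenome survey:
ecosystem categories drawn at 0.806 / 0.133 / 0.062 for environmental /
host-associated / engineered (normalized internally, as published
rounded shares may exceed 100%), latitude uniform on [−60, 75]
(inhabited-latitude sampling), longitude uniform, add dates uniform over
the first 13 years of the epoch. Covariates, latent states and
detections use separate sub-seeded streams, so one seed fixes every
artifact and generators are bit-reproducible.

The generator emulates the *statistical* structure the models assume —
Bernoulli latent states, conditionally independent detections,
logit-linear covariate effects. It does not emulate spatial
autocorrelation between nearby sites, sampling-effort bias toward
well-studied regions, metadata missingness patterns, sequence evolution,
or assembly/annotation error processes. Passing recovery tests therefore
demonstrates correctness of the estimators under the model's own
assumptions, not robustness to their violation in real surveys. The
curation fixture (`make_curation_fixtures()`) is likewise constructed:
~20 candidates engineered to exercise every disposition reason with a
ground-truth ledger, not realistic protein families.

Problem sizes used by the test suite and the acceptance script — 2,000
sites for point recovery, 500 replicates of 500 sites for coverage,
3,000 sites for interaction recovery, a 10⁻³ grid oracle on ≤ 10-site
instances — were chosen so that asymptotic approximations are visibly at
work while a full run stays comfortably interactive.

## Known limitations

* Detection covariates are site-level; survey-varying (per-marker)
  detection is not modeled, though marker-specific detectability is
  plausible (shorter genes assemble more readily).
* No false-positive-augmented variants: curation is assumed to have
  removed false positives, as the model requires.
* No spatial correlation corrections, no multi-season dynamics, at most
  two species jointly.
* Coefficient-scale comparisons with other implementations require care
  with factor coding; AIC and likelihood are coding-invariant, the
  coefficients are not.
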