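---
title: "Multievent CMR models of reproduction-survival covariation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multievent CMR models of reproduction-survival covariation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owlcmr)
```

## The question and the model

Life-history theory predicts that reproduction is costly: individuals that
allocate heavily to a brood in year $t$ should, all else equal, survive or
reproduce less well in year $t+1$. Testing this at the population level with
field data requires estimating, jointly, survival, state transitions, and
imperfect detection from encounter histories of marked birds. `owlcmr`
implements that estimation for an annually monitored owl population in which
each adult's reproductive allocation is classed, each breeding season, as

* **N** — no reproductive success (failed breeder or non-breeder),
* **L** — low success (brood size at most the median, or brood mass below
  the median),
* **H** — high success,

with **D** (dead) completing the state space. Between occasions an
individual in live state $s$ survives with probability $\Phi_s$ and, given
survival, moves to state $s'$ with probability $\psi_{ss'}$ (survival acts
first, then the breeding transition; death is absorbing). At each occasion a
live individual is captured with constant probability $p_c$; the dead are
never seen.

Two measures of allocation are supported. Under the **brood-size** measure
the observed event at a capture is simply the state (a multistate model:
events 0–3 for "not seen", N, L, H). Under the **brood-mass** measure some
captured breeders have broods that were never weighed, so their L/H class is
unknown: a captured breeder is *assigned* with probability $\gamma_B$ and
otherwise produces event 4 ("captured, success low or high but not
assigned"). This is a multievent model: the event relates probabilistically
to the latent state, and the likelihood marginalizes over the uncertainty.

The per-history likelihood is a hidden-Markov forward recursion over
$\{N,L,H,D\}$. Entry is conditioned on first capture: the first occasion
contributes the initial-state distribution
$(1-\pi_{SB},\ \pi_{SB}/2,\ \pi_{SB}/2)$, weighted by the first event's
*assignment* probability but **not** by $p_c$. This convention matters
twice. First, it makes $\pi_{SB}$ identifiable in the mass model, where a
first event can be 4. Second, it reproduces the published parameter counts
of the twelve-model set exactly (each count exceeds the structural
$\Phi/\psi/p$ tally by one — the initial-state parameter). Because
likelihood constants differ across software conventions here, absolute AIC
values are comparable only within a convention; model *ranking* is the
meaningful output.

## The twelve-model set

The model set crosses three survival structures — common $\Phi$;
$\Phi_{SB}$ vs $\Phi_N$ (successful breeders vs others); full
$\Phi_N,\Phi_L,\Phi_H$ — with four breeding structures — common $\psi$;
$\psi_{SB},\psi_N$; $\psi_N,\psi_L,\psi_H$; and the free six-parameter
$\psi_{ss'}$ table. Reduced breeding structures split success equally
between arrival states L and H (e.g. $\psi_{LL}=\psi_{LH}=\psi_{SB}/2$).
With one detection and one initial-state parameter this gives K = 4, 5, 6,
5, 6, 7, 6, 7, 8, 9, 10, 11 free parameters for M1–M12 (brood size; the
mass measure adds $\gamma_B$). Negative covariation between current
reproduction and subsequent performance appears as $\Phi_H<\Phi_L<\Phi_N$
or $\psi_{SB}<\psi_N$ in the better-supported models.

Age- and sex-structured variants replicate every survival and transition
parameter per stratum (*interactive* effects, so different ages may covary
in different directions). Age uses four classes (1, 2, 3, 4-and-older) that
advance deterministically each occasion and cap at 4+; detection stays
shared across ages but is sex-specific in the sex variants, matching how
the study reported it.

Models are compared by AIC ($-2\log L + 2K$; AICc is not used). The
retained model is the lowest-AIC one unless others lie within 2 units, in
which case the fewest-parameter candidate is retained; remaining ties break
by lower AIC and then model order, making selection deterministic and
order-invariant.

## Estimation and numerical choices

* **Links.** All probabilities are optimized unconstrained: logit for
  $\Phi$, $p_c$, $\gamma_B$, $\pi_{SB}$ and the two-outcome $\psi$
  structures; a multinomial logit with the "stay-unsuccessful" cell as
  reference for the six-parameter rows (softmax evaluated stably). The
  bijection round-trips to $10^{-12}$ and every constructed matrix is
  row-stochastic to the same tolerance.
* **Optimizer.** BFGS with numerical gradients on the link scale, default
  five starts: the origin (all rates 0.5) plus N(0,1) jitters, seeded.
  Multievent likelihoods can be multimodal in small data; restarts are
  cheap because identical (history, covariate) rows are collapsed to
  weights before optimization and the forward pass is compiled.
* **Intervals.** 95% Wald intervals are computed on the logit of each
  reported probability (delta method from the link-scale Hessian) and
  back-transformed, so they always lie inside $[0,1]$. Profile intervals
  are out of scope.
* **Non-identifiability.** A parameter with $|\text{link value}| > 15$, or
  with Hessian curvature below $10^{-8}$ along its direction, is flagged
  `not_estimated` rather than reported with a meaningless interval — the
  situation the study hit for the oldest age class, where no
  unsuccessful-at-$t$ birds of age 4+ were ever re-observed breeding.
* **Degenerate inputs.** Histories must contain a capture; events before
  first capture are rejected; a mass-alphabet history cannot be scored
  under a size spec. Forward probabilities are rescaled every occasion, so
  long histories do not underflow.

## State coding from field measurements

Brood size codes L for sizes up to the median (3 in the study; ties code L
per the published class list) and H above. Brood mass is the sum over
nestlings of the Scaled Mass Index
$\mathrm{SMI}_i = M_i\,(L_0/L_i)^{b}$, with $L_0$ the reference tarsus
(median tarsus, 35.1 mm in the study) and $b$ the standardized-major-axis
slope of log mass on log tarsus, fitted once on the pooled nestling table.
SMA is the symmetric estimator $\mathrm{sign}(r)\,\hat\sigma_y/\hat\sigma_x$;
the robust variant applies Huber downweighting (tuning constant 1.345) of
SMA residuals, iterating the weighted ratio to $10^{-8}$ with at most 50
iterations. The SMA is fitted on the log scale, as is standard for this
index (the source analysis does not say explicitly). Broods with some
unmeasured nestlings contribute the partial sum over measured ones; broods
with no measured nestlings have undefined mass and code event 4. The mass
cutoff is strict ("lighter than"): a brood exactly at the cutoff codes H.
Thresholds are computed as medians of the analysed dataset by default and
can be forced to the study's values (3 owlets; 424.16 g) for reproduction
runs; whichever is used is frozen into the run manifest.

Raw capture records are collapsed to one per individual and year before
encoding. The collapse prefers a record carrying brood information; if two
informative records conflict, the larger brood size is kept with a loud
warning — the source does not describe this case, and the maximum preserves
the most captures as analysable. Conflicting sexes are an error; a known
sex fills unknown-sex records of the same bird. Three dataset filters
mirror the study: the first two survey years (almost no adult captures) are
dropped; individuals first captured in the final year are dropped entirely
(no survival information); and, for the brood-size measure, breeder
captures with missing brood size are dropped.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions: 607 individuals over 14
annual occasions (2008–2021), staggered entry (uniform entry weights — the
empirical entry distribution is not published), survival 0.56/0.63/0.76 for
N/L/H, breeding success 0.82 (successful breeders) vs 0.56, detection 0.51,
assignment 0.88, the observed sex composition (79% female among sexed, 21%
unsexed) and entry-age mix (38/25/13/24% across classes 1–4+, 35% of
unknown age). Latent life before first capture is not simulated, because
the likelihood conditions on first capture. Each individual has a random
substream derived deterministically from the run seed, so enlarging a
sample leaves earlier individuals' histories untouched, and equal-seed runs
are byte-identical.

The nestling generator draws log tarsus uniformly on a 28–42 mm range
(nestlings are measured near fledging, around the 35.1 mm adult median) and
adds Gaussian noise (SD 0.05) around a slope-2 log-log allometry. The range
is chosen wide enough that the SMA attenuation term
$\sigma^2/\mathrm{Var}(\log L)$ stays small at the default noise, so the
fitted slope recovers the generating slope closely; symmetric-noise SMA is
still biased upward in principle, which is why exact-recovery checks use
zero noise.

Passing tests on these data show that the estimator recovers parameters
from data generated by *its own model*, with the study's rates, sample
sizes and missingness. They do not validate the model against features real
data may have and the generator omits: within-year multiple captures,
time-varying detection or survival, territory/spatial structure,
pair-correlated fates (both parents of a brood are treated as independent
histories, as in the source analysis), or individual heterogeneity beyond
the modelled states.

## Problem sizes used by the checks

The test suite and the acceptance script size their Monte Carlo runs for a
single core: likelihood-vs-enumeration agreement uses 200 random draws with
up to six occasions (the exhaustive oracle enumerates all $4^T$ latent
paths); parameter recovery refits M6 on 20 datasets of 2,000 individuals
over 12 occasions, checking pooled 95%-interval coverage and a median
absolute survival error below 0.03; selection-consistency spot checks in
the suite use three replicates of 1,500 individuals; end-to-end pipeline
checks run at the study scale (607 individuals, 14 occasions). Nesting
monotonicity is checked on one 800-individual dataset across the
M1–M2–M3 and M1–M4–M7–M10 chains with a $10^{-6}$ tolerance.

## Known limitations

* Real-data reproduction of the published tables requires the archived
  field dataset; with synthetic data the package demonstrates the identical
  machinery and recovers its own generating truth instead.
* Goodness-of-fit testing (the study used external contingency-style
  tests) is out of scope, as are model averaging, random effects, memory
  models, and profile or bootstrap intervals.
* At the study's sample size the three-state survival split and the
  successful-breeder split are often within 2 AIC of each other; the
  parsimony rule then decides, and single synthetic realizations can
  legitimately retain a neighbouring model in the set.
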