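# owlcmr

Multistate and multievent capture–mark–recapture (CMR) models for asking a
classic life-history question with field ringing data: do individuals that
allocate more to reproduction in year *t* survive or breed worse in year
*t*+1? The package was built around a long-term study of little owls
(*Athene noctua*) monitored in nest boxes over 14 breeding seasons, but the
machinery is generic for any three-state reproductive classification with
annual occasions.

Each adult's season is classed **N** (no reproductive success), **L** (low:
brood size or Scaled-Mass-Index brood mass at/below the population median)
or **H** (high), with **D** (dead) absorbing. Between seasons an individual
in state *s* survives with probability Φ_s and, given survival, breeds next
season in state *s′* with probability ψ_ss′; live birds are detected with
constant probability p_c. Under the brood-mass measure some captured
breeders have unweighed broods, so their L/H class is unknown: they are
assigned with probability γ_B and otherwise produce the dedicated
"unassigned" event — a multievent model whose hidden-Markov forward
likelihood marginalizes the uncertainty. Twelve nested models (M1–M12)
cross three survival structures (common Φ; Φ_SB vs Φ_N; Φ_N, Φ_L, Φ_H) with
four breeding structures (common ψ; ψ_SB, ψ_N; ψ_N, ψ_L, ψ_H; free six-ψ
table), optionally replicated per sex or per age class (1, 2, 3, 4+,
interactive), and are compared by AIC with a parsimony rule: within 2 AIC
units the model with fewer parameters is retained. Negative covariation
(a reproductive cost) appears as Φ_H < Φ_N or ψ_SB < ψ_N; the reverse
pattern is positive covariation.

The package covers the whole workflow: a synthetic-data generator with
known truth, ingestion of raw capture records and nestling morphometrics,
standardized-major-axis Scaled Mass Index brood-mass coding, encounter
encoding (including MARK-style `.inp` export), a compiled forward
likelihood, maximum-likelihood fitting with Wald intervals, AIC selection,
and an orchestrated pipeline with markdown reports.

## Worked example

Simulate a study-scale dataset (607 individuals, 14 occasions; the default
generating rates are the whole-dataset estimates of the brood-size
analysis), fit the twelve models and select:

```r
library(owlcmr)

sim <- simulate_histories(sim_config(entry_weights = c(rep(1/13, 13), 0), seed = 20))
rs  <- run_model_set(sim$histories, covariate = "none",
                     options = fit_options(n_restarts = 2, seed = 20))
rs$selection
rs$fits[[rs$selection$chosen]]$estimates
```

which prints (abridged):

```
<owlcmr_selection> chosen: M6 (rule: fewest_params_within_2)
   model  K      aic    delta chosen
1     M1  4 4854.99  53.11   FALSE
...
6     M6  7 4802.75   0.87    TRUE
...
9     M9  8 4801.88   0.00   FALSE

  parameter  stratum estimate lower upper
      phi_N      all    0.541 0.479 0.601
      phi_L      all    0.639 0.575 0.699
      phi_H      all    0.805 0.739 0.857
     psi_SB      all    0.820 0.779 0.855
      psi_N      all    0.566 0.479 0.649
          p (shared)    0.519 0.477 0.561
      pi_SB (shared)    0.588 0.549 0.627
```

M6 — state-dependent survival with breeder-dependent breeding — is retained
(M9 has the lowest AIC but one more parameter, within the 2-unit window).
The estimates recover the generating truth: survival rises from 0.54 (no
success) to 0.80 (high success) and successful breeders are far more likely
to breed successfully again (0.82 vs 0.57) — a *positive* covariation
between current reproduction and subsequent performance, as the defaults
encode. Detection is ~0.52 and about 59% of first captures are successful
breeders.

The numbered scripts under `analysis/` run the full workflow as a
narrative: `01_simulate.R` writes raw-schema CSVs, `02_prepare.R` ingests,
filters and encodes them (including SMI brood-mass coding against the
424.16 g cutoff), `03_fit_models.R` runs the whole-dataset, known-age and
known-sex model sets, and `04_report.R` renders the AIC/estimate reports
under `results/`.

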