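# photopop

Photo-identification population analysis for small coastal dolphin
populations, built around the analysis chain of a decade-long ecotour-based
photo-ID programme in southern Port Phillip Bay (south-eastern Australia):
image quality grading, robust-design capture–recapture, social structure,
and reproductive parameters — together with a synthetic photo-ID data
generator that stands in for the study's non-public sighting tables and
provides ground truth for validating every estimator.

## Who this is for

Cetacean ecologists (and anyone running mark–recapture on natural-mark
photo-ID catalogues) who need a single, tested workflow from raw sighting
records to abundance, survival, emigration, association and calving
estimates. The package is plain R with S3 classes; the numbered scripts
under `analysis/` are thin narrative drivers over the exported functions.

## The models in brief

**Quality grading (Urian scheme).** Five component scores per image —
focus (2/4/9), contrast (1/3), angle (1/2/8), partial fin (1/8), frame
fill (1/5) — sum to a total banded *excellent* (6–9), *average* (10–12) or
*poor* (>12). Only excellent/average images identify individuals; the
capture–recapture set keeps adults with distinctive fins (D1/D2).

**Robust design capture–recapture.** Season-years are primary occasions
(population open between: apparent survival S, temporary emigration), the
months within a season are secondary occasions (population closed within:
capture probability p, abundance). Between primaries each animal moves
among latent states {in-area, emigrant, dead}: an in-area animal survives
with S and then emigrates with probability γ″; an emigrant survives with S
and stays out with γ′ (γ″ = γ′ is *random* emigration, γ″ ≠ γ′
*Markovian*, γ″ = γ′ = 0 none). The likelihood is a hidden-state forward
recursion conditional on first capture (Huggins-type); the marked
abundance per primary is derived as N̂ = n / p̂*, where n is the number of
distinct animals seen and p* = 1 − Π(1 − p_s) the probability of at least
one detection. Models crossing the emigration scenarios with
constant/time-varying S and p are ranked by AIC. A likelihood-ratio
staggered-availability diagnostic checks within-primary closure and a
parametric bootstrap of the model deviance checks overall fit.

**Social analysis.** Photographs ≤15 min apart on a day form one
encountered group. Pairwise association uses the half-weight index
HWI = X / (X + ½(Ya + Yb)) at daily granularity. Preferred companions are
tested by Markov-chain checkerboard swaps of the group × individual
incidence matrix within sampling days (preserving all margins);
hierarchical clustering is validated by the cophenetic correlation
coefficient (reliable ≥ 0.8) and Newman's weighted modularity (meaningful
≥ 0.3); individual metrics (strength, eigenvector centrality, reach,
clustering coefficient, affinity) carry bootstrap SEs; lagged association
rates with jackknife SEs are summarised by exponential decay models
ranked by AIC.

**Reproduction.** Older calves are backdated one year to their birth
season; the calving rate is births per identified adult per year; the
inter-birth interval (IBI) averages consecutive birth gaps within mothers
and then across mothers; annual counts are regressed on effort days with
a Poisson GLM.

## Worked example

```r
library(photopop)

cfg   <- sim_config()                       # study-condition defaults
truth <- simulate_population(cfg, seed = 11)
sg    <- simulate_sightings(truth, seed = 12)

rec  <- grade_records(sg$records)
cr   <- filter_for_analysis(rec, "capture_recapture")
hist <- build_capture_histories(cr, cfg$calendar)
fit  <- fit_rd(hist, rd_model_spec("random", "constant",
                                   "primary_by_secondary"), seed = 1)
fit
```

prints (abridged):

```
RD model: emigration=random(constant), S=constant, p=primary_by_secondary
logLik -1427.596 on K=51 parameters; AIC 2957.19; 84 individuals
 parameter estimate     se    lcl   ucl
         S    0.935 0.0130 0.9041 0.956
  gamma_pp    0.125 0.0244 0.0845 0.181
derived abundance (marked):
 season_year n_detected    N    se
        2012         40 44.5 2.752
        2013         46 49.1 2.100
        2014         42 44.4 1.886
        ...
        2021         42 46.2 2.687
```

S is annual apparent survival of marked adults, `gamma_pp` the random
temporary-emigration probability, and each N the derived in-area marked
abundance for that season. This replicate was generated at S = 0.93,
γ = 0.09 and expected in-area abundance ≈ 45; the estimates sit within
one to two standard errors of those values, as single replicates do. The full decade workflow —
grading and effort, model selection with diagnostics, the social module
and the reproductive parameters — is scripted in `analysis/01…05`, each
writing its tables under `results/`.

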