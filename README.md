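# polypillcea

A lifetime Markov cohort cost-utility model of a four-component
cardiovascular polypill (aspirin 81 mg, hydrochlorothiazide 12.5 mg,
atorvastatin 20 mg, valsartan/enalapril) versus each component given as
monotherapy, for primary prevention in adults aged 35+. It is written for
health-economics analysts who want a transparent, fully scripted
re-implementation of a published TreeAge-style cost-utility analysis:
every input is a plain-text config, every result is reproducible from a
seed, and every divergence from the printed inputs is logged.

## The model

A cohort enters event-free at age 35 and moves through annual cycles over
nine states — event-free; stroke, heart failure and peripheral vascular
disease (chronic); acute/post myocardial infarction and acute/post angina
(one-cycle tunnel plus chronic state); dead. From the event-free state the
five first events compete: baseline risk `p_e(a)` (age-interpolated where
printed as a range) under the strategy's relative effect `e` on the rate
scale, `1 - (1 - p_e)^e`, split into immediately fatal and nonfatal
shares; background mortality comes from a life table (a calibrated
Gompertz stand-in by default), chronic states die at
`1 - (1 - q_x)^SMR`, and a treated disease-specific hazard acts from the
event-free state. Rewards are half-cycle corrected and discounted at
5.8%/year (costs) and 3%/year (QALYs):

    Cost_k  = sum_t (1.058)^-t * x_t(k) . c        QALY_k = sum_t (1.03)^-t * x_t(k) . u
    ICER    = (Cost_1 - Cost_2) / (QALY_1 - QALY_2)
    NMB_k   = WTP * QALY_k - Cost_k,   WTP = 21,768 USD/QALY

Uncertain inputs carry method-of-moments Beta/Gamma/log-normal
distributions; one-way tornado analysis (±20%), Monte-Carlo probabilistic
sensitivity analysis and cost-effectiveness acceptability curves are
built in. See the vignette
(`vignettes/polypill-cost-utility-model.Rmd`) for the model's assumptions
and design choices.

## A worked example

```r
library(polypillcea)

params <- load_parameters()            # packaged base-case config
res <- run_strategies(params)
incremental_analysis(res)
```

```
             strategy     cost    qalys delta_cost delta_qalys icer            status
1 hydrochlorothiazide 1637.786 17.53966         NA          NA    -          dominant
2        atorvastatin 2222.873 16.99508         NA          NA <NA>         dominated
3             aspirin 2223.960 16.66456         NA          NA <NA>         dominated
4           enalapril 2268.093 17.01672         NA          NA <NA>         dominated
5           valsartan 2268.093 17.01672         NA          NA <NA>         dominated
6            polypill 2284.839 17.39466         NA          NA <NA>         dominated
```

Each row is one arm's discounted lifetime cost (USD/person) and QALYs.
Here hydrochlorothiazide is strictly dominant: with the printed input
table it is both the cheapest arm and the most effective, because its
printed MI hazard ratio (0.34) is far stronger than the polypill's (0.66)
and MI is the costliest, deadliest event in the model. The polypill
accrues 17.39 QALYs at 2,284.8 USD.

Uncertainty, from the same config:

```r
tb <- tornado(params)                  # ±20% one-way bars, sorted
head(tb, 3)
#              parameter       low      high    spread
# 1   effect.polypill.mi  751.0765 -7828.084 -8579.160
# 2 effect.hydrochlorothiazide.mi -7320.05 -678.00 6642.05
# 3 effect.hydrochlorothiazide.stroke -6867.31 -1052.30 5815.01

psa <- run_psa(params, n = 5000, seed = 1)
ceac(psa, wtp_grid = 21768)
#     wtp            strategy probability
# 1 21768            polypill      0.2562   # probability cost-effective at WTP
# ...
```

Command-line equivalents (`run`, `tornado`, `psa`, `fixtures`) live in
`inst/cli/polypillcea`; each writes CSVs, plots, a validation report and
a run manifest into its output directory.

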