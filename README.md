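# spacedselect

Machine-learning instruction sequencing for spaced repetition: which
items should a learning app put into the next study session, and how do
you measure whether a selection algorithm helps people remember?

`spacedselect` is an R toolkit for that question, built around four
pieces:

* **Memory model.** The exponential forgetting curve with binary
  recalls: recall probability `m = exp(-n Δ)` with per-item forgetting
  rate `n` (1/day) that moves multiplicatively after each review —
  `n(1-α)` on success, `n(1+β)` on failure — and a count-based
  half-life-regression estimator (`fit_hlr()`) for the per-item initial
  rates `n0` and the global multipliers.
* **Policies.** The closed-form optimal selection probability
  `p* = (1 - m)/√q` (SELECT), implemented as the deterministic ranking a
  deployed app would show, plus the two baseline arms of a randomized
  trial: easiest-first circular order and uniform random with
  replacement.
* **In-silico randomized trial.** `simulate_trial()` generates a full
  three-arm trial — Poisson session arrivals, geometric session sizes and
  dropout, heterogeneous item difficulties — with ground truth retained,
  so every estimator in the package can be tested against the truth that
  generated the data.
* **Evaluation.** The trial statistics: empirical forgetting rate
  `n̂ = -log(r̃)/Δ` of each pair's last (test) review, normalized by item
  initial difficulty; controlled (same #reviews, similar study period T)
  arm comparisons via Mann–Whitney U tests with Bonferroni correction;
  the spacing-effect Huber regression
  `n̂/n̂0 = c + w_T (T - T_median) + w_difficulty I_difficulty +
  w_random I_random`; and per-arm engagement metrics.

## Worked example

Simulate a 300-learner, 40-question, 30-day trial, fit the memory model
on the simulated review log, and run the evaluation:

```r
library(spacedselect)

cfg <- population_config(n_learners = 300, n_items = 40,
                         horizon_days = 30, seed = 42)
sim <- simulate_trial(cfg)
sim$log
#> <review_log> 35467 events, 297 learners, 40 questions

obs <- recall_observations(sim$log)$observations
fit_hlr(obs)
#> <hlr_params> 40 items | alpha = 0.3127, beta = 0.5863, l2 = 0.001
#>   n0: median 0.0333/day [0.0021, 0.3916]
```

The fitted multipliers sit within a few hundredths of the generating
truth (α = 0.3, β = 0.6), and the item rates recover the log-normal
difficulty spread. The evaluation then compares the arms within
controlled cells:

```r
rep <- evaluate_trial(sim$log, n_reviews_range = 2:4)
s <- rep$comparison$summary
#> cells: 9  contrasts: 18  select-lower: 100.0%  significant: 61.1%
rep$regressions[, c("n_reviews", "c", "w_T", "w_random", "w_difficulty")]
#>   n_reviews         c          w_T   w_random w_difficulty
#> 1         2 0.1152622  0.000394675 0.11034664   0.05507238
#> 2         3 0.1206028 -0.002283114 0.08459975   0.02362446
#> 3         4 0.1397247  0.002801691 0.08077323   0.06269272
```

In this short-horizon trial the select arm's median normalized
forgetting rate is the lowest in every controlled cell (significantly so
after Bonferroni in 61% of contrasts), and both baseline-arm regression
coefficients are positive — learners sequenced by SELECT forget more
slowly than either baseline, after controlling for how much and how long
they studied. At longer horizons the picture inverts in the high-review
strata; the methods vignette (`vignettes/spaced-selection-methods.Rmd`)
explains the mechanism and what it says about the model's assumptions.

A thin command-line wrapper over the same functions ships with the
package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","spacedselect.R",package="spacedselect"))') \
    pipeline --config config.json --out-dir run1
```

with subcommands `simulate`, `fit`, `schedule`, `evaluate`, `regress`
and `pipeline`.

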