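# mbil — Markov blanket and interactive risk-factor learning for discrete clinical data

Late distant recurrence of breast cancer — metastasis 5, 10 or even 15
years after the primary diagnosis — is driven not only by single clinical
risk factors but by *combinations* of factors whose joint effect is
nonadditive: neither member predicts much alone, together they do.  `mbil`
implements a score-based pipeline for finding both kinds of factor in a
flat table of categorical clinical variables, for analysts working with
EHR-derived breast-cancer cohorts (or any discrete outcome table of
similar shape).

## The model

Each candidate family (outcome `T`, parent set `S`) is scored with the
Bayesian Dirichlet equivalent uniform (BDeu) marginal likelihood.  With
`r` outcome states, `q` parent configurations, counts `N_ijk` (parents in
configuration `j`, outcome in state `k`), row sums `N_ij`, and the prior
equivalent sample size `α` spread uniformly over configurations and cells:

    log P(T | S) = Σ_j [ lnΓ(α/q) − lnΓ(α/q + N_ij) ]
                 + Σ_j Σ_k [ lnΓ(α/(rq) + N_ijk) − lnΓ(α/(rq)) ]

On top of this score the package provides:

* **Interaction detection** — a set `S` (of 2 or 3 variables) is an
  *interactive risk factor* exactly when its family score beats every
  proper subset of `S`, including the empty set; singletons are reported
  when they beat the empty set.  Results are ranked by score.
* **Markov-blanket learning** — greedy forward selection over the reported
  sets, maximizing the outcome's family score, with backward pruning.  For
  a leaf outcome the learned parent set is its Markov blanket: the direct
  risk factors, which screen the outcome off from upstream "noise"
  variables.
* **α (PESS) as an interactivity dial** — runs are repeated at
  α ∈ {1, 120, 480} for the 5-, 10- and 15-year outcomes (nine results),
  since larger α admits more strongly interacting structures.
* **A synthetic-cohort generator** with planted single effects, XOR-type
  pair effects (zero marginals, pure interaction) and a 3-way "jackpot"
  effect on the shipped 31-variable breast-cancer schema, so the whole
  pipeline is testable without any private clinical data.
* **The reporting layer** — causal-set listings per horizon × α,
  partner-frequency tables for a focus variable (with race/ethnicity,
  smoking/alcohol and the two lymph-node columns merged for quantitation),
  and per-horizon focus counts.

## Worked example

```r
library(mbil)

spec   <- build_lsm_like_spec(seed = 11)          # planted ground truth
cohort <- simulate_cohort(spec, 2000, seed = 11, schema = lsm_schema())
bl <- learn_markov_blanket(cohort, "Metastasis_10yr", alpha = 120, max_size = 3)
bl
#> <mbil_blanket of Metastasis_10yr (alpha=120): 1 direct set(s), union {ER, n_tnm_stage, Surgical_margins}>
bl$direct_sets[, c("size", "log_score", "gain_over_best_subset", "classification")]
#>   size log_score gain_over_best_subset classification
#> 1    3 -567.5201              15.69389    interactive
```

The learner recovered the planted 3-way interaction exactly: ER status,
nodal TNM stage and surgical margins jointly raise 10-year metastasis risk
(`gain_over_best_subset` is the log-score margin over the best pair or
single inside the triple — positive means genuinely nonadditive).

The reporting layer reproduces partner-frequency tables from transcribed
interaction lists:

```r
rows <- read_interaction_table(system.file("extdata", "table2_alpha1.csv",
                                           package = "mbil"))
rec  <- records_from_table(rows[merge_variables(rows$variable) == "ER", ], 1)
tabulate_partner_frequencies(rec, "ER", 1)
#>   focus            partner n_times  years total percent
#> 1    ER              n-TNM       2  5, 10     6   33.33
#> 2    ER               HER2       2  5, 15     6   33.33
#> 3    ER LN positive/status       2 15, 15     6   33.33
```

ER interacted six times in total at α = 1; a third of those were with
nodal stage, a third with HER2, a third with lymph-node positivity.

A command-line front end covers validation, simulation, learning and
tabulation, e.g.

```sh
Rscript -e 'mbil::mbil_cli()' simulate --spec builtin:lsm --n 1000 --seed 7 --out cohort.csv
Rscript -e 'mbil::mbil_cli()' learn --data cohort.csv --alphas 1,120,480 --horizons 5,10,15 --max-size 3 --out report.csv
```

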