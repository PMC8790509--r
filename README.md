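# testleteq

Monte Carlo machinery for studying how local item dependence distorts
the **equating of testlet-based test forms** under the non-equivalent
groups with anchor test (NEAT) design.

Standardized tests are routinely assembled from *testlets* — bundles of
items sharing a passage or stimulus. Within a testlet, responses stay
correlated after conditioning on general ability, which violates the
local-independence assumption behind ordinary IRT calibration. When two
forms built from testlets are linked through a common anchor block by
*concurrent calibration* (one multiple-group estimation run with shared
anchor parameters), that violation propagates into the equated item
parameters and ability scores. `testleteq` implements the full
simulation experiment for quantifying this: data generators, the four
response models, a concurrent-calibration engine, EAP scoring, and the
equating error summaries.

## Models

For dichotomous item *j* and examinee *i*, the two-parameter logistic
model (2PLM) and its testlet extension (2PTM):

    P(y_ij = 1) = logistic{ a_j (θ_i − b_j) }                 (2PLM)
    P(y_ij = 1) = logistic{ a_j (θ_i − b_j − γ_id(j)) }       (2PTM)

where `d(j)` is the testlet containing item *j* and
`γ_id ~ N(0, σ²_γd)` is a person-by-testlet random effect whose
variance σ²_γd *is* the testlet effect. For 5-category graded items,
the graded response model (GRM) uses cumulative boundary probabilities
`P*_x(θ) = logistic{ a(θ − b_x) }` with category probabilities
`P_x = P*_x − P*_{x+1}`; the graded response testlet model (GRTM)
subtracts `γ_id(j)` inside the logit. No 1.7 scaling constant is used.

Calibration is multiple-group marginal maximum likelihood EM with
bifactor-style dimension reduction over the testlet effects (the base
group fixed at N(0,1), the new group's mean and variance estimated,
anchors shared), and equating error across replications is summarised
by Bias, SEE and RMSE with the exact decomposition
`RMSE² = Bias² + SEE²`.

## Worked example

Simulate one NEAT condition (dichotomous study, high testlet effect,
testlets of 5 items, 1000 examinees per group, using the published
item pools), fit both the misspecified IRT model and the testlet model
to the *same* data, and summarise equating error for the new form's
testlet items:

```r
library(testleteq)

cond <- simulation_condition("dichotomous", "high", testlet_length = 5,
                             sample_size = 1000, n_replications = 3,
                             seed = 42)
fp   <- printed_form_pair("dichotomous", testlet_length = 5,
                          testlet_effect = "high")   # published item pools
run  <- run_condition(cond, form_pair = fp)
summarize_condition(run)
```

```
#> # A tibble: 6 x 7
#>   model param     bias    see  rmse n_units scope
#>   <chr> <chr>    <dbl>  <dbl> <dbl>   <int> <chr>
#> 1 2PLM  a     -0.312   0.0819 0.348      20 new_testlet
#> 2 2PLM  b      0.0353  0.0865 0.135      20 new_testlet
#> 3 2PTM  a      0.108   0.124  0.180      20 new_testlet
#> 4 2PTM  b      0.00713 0.0911 0.120      20 new_testlet
#> 5 2PLM  theta -0.0379  0.314  0.317    3000 new
#> 6 2PTM  theta -0.0254  0.295  0.297    3000 new
```

Each row is one condition-table cell: the per-item error statistics
across replications, averaged over the 20 new-form testlet items (or
pooled over the 3 x 1000 new-form examinees for `theta`). The pattern
of interest is already visible at 3 replications: ignoring a strong
testlet effect flattens the marginal response curves, so the 2PLM's
discrimination estimates are strongly attenuated (bias -0.31, RMSE
0.35), while the correctly specified 2PTM stays close to the
generating values (RMSE 0.18) and scores abilities a little more
accurately.

A single calibration is just as direct:

```r
fp   <- printed_form_pair("dichotomous", testlet_length = 5,
                          testlet_effect = "low")   # published item pools
base <- form_items(fp, "base"); new <- form_items(fp, "new")
pb   <- sample_persons(1000, "base", fp$testlets[fp$testlets$testlet_id %in% base$testlet_id, ])
pn   <- sample_persons(1000, "new",  fp$testlets[fp$testlets$testlet_id %in% new$testlet_id, ])
resp <- assemble_concurrent(generate_responses(base, pb),
                            generate_responses(new, pn), fp)
fit  <- fit_concurrent(resp, fp, "2PTM")
fit
glance(fit)          # one-row fit summary
tidy(fit)            # item estimates, one row per parameter
eap_score(resp, fit) # posterior-mean abilities
```

`autoplot()` methods draw item-estimate maps and truth-versus-estimate
recovery plots; `plot_study_summary()` draws the error statistics
across a full factorial grid produced by `run_study()`. A thin CLI over
the same functions ships in `inst/cli/testleteq-cli.R` with
`simulate` / `fit` / `study` / `summarize` subcommands.

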