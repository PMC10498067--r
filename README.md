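# difolr

Differential item functioning (DIF) for polytomous questionnaires by the
iterative hybrid ordinal-logistic-regression / item-response-theory
procedure, with a synthetic graded-response generator for validation
against known truth.

## Who this is for

Psychometricians and biostatisticians screening an ordered-category
instrument — the motivating case is the 36-item, 5-category Dental Anxiety
Inventory (DAI-36) — for items that behave differently across gender,
education or age groups at the same underlying trait level. Items with
large uniform DIF invalidate between-group comparisons of the total score;
the package both detects them and quantifies what removing them does to the
group comparison.

## The method

For each item with ordered categories `k = 0..m-1`, trait `θ` and binary
group `g`, three nested proportional-odds models are compared:

    M1: logit P(Y ≤ k | g, θ) = β0k + β1·θ
    M2: logit P(Y ≤ k | g, θ) = β0k + β1·θ + β2·g
    M3: logit P(Y ≤ k | g, θ) = β0k + β1·θ + β2·g + β3·θg

The M1-vs-M2 likelihood-ratio χ² (1 df) tests **uniform** DIF, M2-vs-M3
tests **nonuniform** DIF. Effect sizes accompany the tests: the
pseudo-R² differences `ΔR1 = 1 − lnL(M2)/lnL(M1)` and
`ΔR2 = 1 − lnL(M3)/lnL(M2)` (large above 0.070) and the
Crane–van Belle–Larson beta change
`Δβ1 = |(β1(M1) − β1(M2))/β1(M1)|` (large above 0.01).

The matching trait `θ` is an EAP score from a graded response model
(`P(Y ≥ k+1 | θ) = logistic(a(θ − b_k))`), estimated by marginal maximum
likelihood EM. The **hybrid loop** purifies it: iteration 0 scores from all
items and flags by the χ² tests; each later iteration re-scores from the
unflagged (anchor) items only and re-tests everything, until the flagged
set repeats or an iteration cap is hit.

Also included: reliability and one-factor CFA fit indices (Cronbach's α,
McDonald's ω, Guttman's λ6, RMSEA, SRMR, CFI, TLI) per demographic
subgroup, and group comparisons of the mean item score with and without
the uniform-DIF items (pooled t-test and exact/tie-corrected Mann–Whitney
U-test).

## Worked example

Simulate the shipped 20-item scenario — two uniform-DIF items (item03,
item07; focal thresholds shifted by 0.5) and two nonuniform-DIF items
(item12, item17; focal discrimination doubled), 500 persons per group, no
true trait difference — then run the hybrid analysis:

```r
library(difolr)
sim <- simulate_responses(default_scenario(seed = 1))
fit <- dif_olr(sim$data, dif_config(refit_anchors = FALSE))
print(fit)
#> Iterative hybrid OLR/IRT DIF analysis
#>   groups: reference (reference) vs focal (focal), n = 1000
#>   items analysed: 20; purification iterations: 4 (converged)
#>   flagged (chi-square, alpha = 0.05): uniform 2, nonuniform 3, either 5
#>   flagged items: item01, item03, item07, item17, item20
```

Both uniform items are found with overwhelming evidence (item03: uniform
χ² = 63.08, p < .0001, Δβ1 = .031; item07: χ² = 50.15, Δβ1 = .020 — both
beyond the 0.01 large-DIF bound), one of the two nonuniform items is found
(item17: nonuniform χ² = 13.82, p = .0002; nonuniform detection is
attenuated under estimated-trait matching), and two clean items are
false-flagged at α = .05, as expected at this error rate. Removing the
flagged uniform items changes the group comparison exactly as the design
says it should — the spurious gap created by uniform DIF collapses:

```r
compare_with_without_dif(fit)
#>    correction     level   n mean    sd p_t_test p_mann_whitney
#> 1 uncorrected reference 500 3.01 0.789   0.0658         0.0702
#> 2 uncorrected     focal 500 2.91 0.821   0.0658         0.0702
#> 3   corrected reference 500 2.95 0.790   0.3698         0.3718
#> 4   corrected     focal 500 2.90 0.823   0.3698         0.3718
```

`summary(fit)` prints the full per-item statistics table and the
purification trace; `plot(fit)` draws the per-group test characteristic
curves of the flagged items. The published per-item DIF statistics for the
DAI-36 (25 item-by-grouping rows) ship as a fixture,
`dai36_published_dif_stats()`, and reclassifying them with
`classify_item()` at α = .05 reproduces the published flag counts — 7/7/4
nonuniform and 2/5/4 uniform items across gender/education/age — with every
published ΔR below the 0.070 large-DIF cutoff.

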