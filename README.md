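# enrichsel

Design and estimation for clinical trials with subpopulation selection.

When a predictive biomarker splits the trial population into disjoint
subgroups with known prevalences, a trial can *select* the most promising
candidate population — a subgroup, a nested union of subgroups, or the full
population — and test the treatment effect there. enrichsel plans such
trials (single-stage, or multistage with enrichment of later stages to the
selected population) and quantifies what selection does to the naive
maximum-likelihood estimate of the treatment effect. It is aimed at
biostatisticians planning confirmatory subgroup or adaptive enrichment
designs and at methodologists studying selection and reporting bias.

## The method in brief

Standardized statistics follow $Z_s \sim N(I_s\theta_s,\,1)$ with
information (reciprocal standard error)
$I = 1/(\sigma\sqrt{1/n_T + 1/n_C})$; nested candidate populations
$U \subset V$ are correlated with
$\mathrm{corr}(Z_U,Z_V)=\sqrt{\mathrm{prev}(U)/\mathrm{prev}(V)}$.
Selection takes the maximum statistic (the worst case for both the
family-wise error rate and bias). All design quantities derive from the
joint density of the selected statistic and selection index,

$$p(z, w;\Theta) = \varphi\!\left(z-\theta_w I_w^{(1)}\right)\,
\Psi_{S\setminus w}(z,\dots,z;\Theta),$$

with $\Psi$ the conditional multivariate-normal CDF of the non-selected
statistics given $Z_w=z$. The critical value solves
$\sum_w\int_C^\infty p(z,w;\Theta_0)\,dz=\alpha$ (weak control at the
global null implies strong control). Multistage designs propagate the
selected statistic through the independent-increment Gaussian transition
law and calibrate one free boundary constant (O'Brien–Fleming
$C\sqrt{K/k}$, error spending, or no-stage-1-stopping) the same way; sample
sizes are the smallest (per-stage) totals reaching the requested power,
under either of two power definitions (select a prespecified target and
reject its null, or reject any false null). A seeded Monte-Carlo engine
simulates the resulting trials exactly on sufficient statistics (or from
patient-level counts) and reports standardized bias ($\mathrm{bias}/SE$)
and standardized root-MSE of the MLE under three conditionings: none,
selection, and selection plus a significant result.

## Worked example

Three nested candidate populations with equal subgroup prevalences 1/3, an
effect of 0.5 in the first subgroup only ($\sigma=1$), one-sided FWER
0.025, 80% power to select the first subgroup and reject its null:

```r
library(enrichsel)

pop    <- population_set(c(1, 1, 1)/3, members = list(1, 1:2, 1:3))
design <- design_spec(pop, effect_config(c(0.5, 0, 0)),
                      power_definition = "select-target-and-reject",
                      target = "S1", selection = "sequential3")
cal <- calibrate_design(design)
glance(cal)
#> # A tibble: 1 x 7
#>   stages n_total alpha power_target achieved_power power_definition         boundary_family
#>    <int>   <dbl> <dbl>        <dbl>          <dbl> <chr>                    <chr>
#> 1      1     575 0.025          0.8         0.8002 select-target-and-reject single-stage

records <- simulate_trials(cal, n_reps = 1e5, seed = 2026)
assess_estimates(records)
#> # A tibble: 11 x 7
#>    population conditioning      stage   bias_over_se rmse_over_se proportion_pct n_cell
#>    <chr>      <chr>             <chr>          <dbl>        <dbl>          <dbl>  <int>
#>  1 F          none              overall     0.005427       1.001         100     100000
#>  2 F          selected          overall     0.9670         1.317           3.927   3927
#>  3 F          selected+rejected overall     1.313          1.472           3.045   3045
#>  4 S1         none              overall     0.001048       1.003         100     100000
#>  5 S1         selected          overall     0.09538        0.9791         88.43   88432
#>  6 S1         selected+rejected overall     0.2780         0.8741         79.94   79940
#>  7 S1+2       none              overall     0.002164       1.001         100     100000
#>  8 S1+2       selected          overall     0.7593         1.199           7.641   7641
#>  9 S1+2       selected+rejected overall     1.024          1.263           6.435   6435
#> 10 familywise selected          overall     0.1803         1.013         100     100000
#> 11 familywise selected+rejected overall     0.3669         0.9336         89.42   89420
```

Reading the table: 575 patients suffice for the design; the correct
subgroup is selected 88% of the time, and conditional on that the MLE
overshoots by only ~0.10 standard errors — but conditional on selecting the
*full population* (rare, 3.9%) the estimate is ~0.97 SE too high, rising to
~1.3 SE among significant-and-reported trials. Unconditionally
(`none`) the estimator is unbiased with root-MSE 1, the sanity anchor of
the standardized scale.

Planning-level comparison of strategies for one 50%-prevalence subgroup
(effect 0.23, SD 0.72, 25 patients/month, 3-month endpoint):

```r
compare_strategies(0.23, 0.72, prevalence = 0.5, rate = 25, delay = 3)
#> # A tibble: 5 x 6
#>   strategy                    max_fwer n_total pct_superior duration_months path
#>   <chr>                          <dbl>   <dbl>        <dbl>           <dbl> <chr>
#> 1 separate-studies             0.04938     616           50           27.64 -
#> 2 separate-studies-bonferroni  0.02484     748           50           32.92 -
#> 3 single-stage                 0.025       684           50           30.36 -
#> 4 two-stage                    0.025       552           50           25.08 full population se…
#> 5 two-stage                    0.025       552           75           36.12 subgroup selected
```

The two-stage enrichment design needs the fewest patients and studies 75%
of them in the truly benefiting subgroup when that subgroup is selected, at
the price of a longer trial on that path.

Scenario files (YAML) drive the same pipeline reproducibly via
`run_scenario()` / `write_report()`, including prevalence sweeps with
`autoplot()` displays; `inst/scripts/enrichsel` wraps the package as a
command-line tool with `design`, `simulate`, `assess`, `compare` and
`sweep` subcommands.

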