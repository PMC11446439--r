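# recmicro

Recurrence-microstate entropy analysis of multichannel EEG: does repetitive
movement make cortical activity *simpler*?

`recmicro` is for researchers who want to quantify brain complexity from EEG
with recurrence methods and compare it across within-subject behavioral
conditions — here, rest vs. stationary cycling crossed with eyes open/closed
on eight bipolar derivations (F3-Fz, F4-Fz, C3-Cz, C4-Cz, P3-Pz, P4-Pz,
O1-A2, O2-A1). Because raw recordings for this design are not publicly
deposited, the package includes a deterministic synthetic-EEG cohort
generator with the statistical structure the analysis assumes (occipital
alpha with eyes closed, beta suppression and pedaling-locked regularity
during cycling, per-subject random intercepts, step artifacts), so the whole
pipeline is testable end to end with known ground truth.

## The statistic

For a segment $x_1,\dots,x_L$, a recurrence microstate is the $N\times N$
binary block of the recurrence matrix
$R_{ij}=\mathbf{1}\{|x_i-x_j|\le\varepsilon\}$ anchored at a random pair
$(i,j)$, encoded as an integer. Sampling $K$ anchors gives a distribution
$p$ over the $2^{N^2}$ patterns, and the segment's complexity is the
maximised Shannon entropy

$$S_{\max} = \max_{\varepsilon} \Big(-\sum_i p_i(\varepsilon)\,\ln p_i(\varepsilon)\Big),$$

with the threshold grid taken on quantiles of the segment's own pairwise
distances (which makes $S_{\max}$ invariant to amplitude rescaling). Each
2-minute recording is split into 100 equal pieces and summarised by the
**median** $S_{\max}$; medians are compared across conditions with
random-intercept models (`median_entropy ~ eyes + (1|subject)` for
validation; `median_entropy ~ state * eyes + (1|subject)` per region-side)
and two-sided within-subject permutation tests (10,000 repetitions,
add-one p-values).

## Worked example

```r
library(recmicro)
library(dplyr)

cfg <- pipeline_config(seed = 2024, n_subjects = 8, duration = 12,
                       n_pieces = 30,
                       entropy = entropy_config(K = 2000,
                                                seed = derive_seed(2024, "entropy")),
                       n_perm = 2000, artifact_rate = 0)
res <- run_pipeline(cfg)

res$entropy
#> # A tibble: 256 × 8
#>   subject region side  state eyes  median_entropy n_segments eps_median
#>   <chr>   <chr>  <chr> <chr> <chr>          <dbl>      <int>      <dbl>
#> 1 S01     F      left  rest  open            3.07         30       4.29
#> 2 S01     F      right rest  open            3.28         30       5.21
#> 3 S01     C      left  rest  open            3.18         30       5.00
#> 4 S01     C      right rest  open            3.19         30       4.60
#> # ℹ 252 more rows

filter(res$stats, term == "statecycling") |>
  select(region, side, estimate, t_value, p_perm)
#> # A tibble: 8 × 5
#>   region side  estimate t_value   p_perm
#>   <chr>  <chr>    <dbl>   <dbl>    <dbl>
#> 1 C      left    -1.23    -41.8 0.000500
#> 2 C      right   -1.21    -34.1 0.001000
#> 3 F      left    -1.25    -43.6 0.000500
#> 4 F      right   -1.25    -38.4 0.000500
#> 5 O      left    -0.992   -30.1 0.000500
#> 6 O      right   -0.982   -27.6 0.000500
#> 7 P      left    -1.15    -31.9 0.000500
#> 8 P      right   -1.17    -40.2 0.000500
```

Every `estimate` is the cycling − rest contrast in nats: entropy is lower
under cycling on all eight region-sides, and each permutation p-value is
small (the floor at this `n_perm` is 1/2001 ≈ 0.0005). The printed report
adds the validation contrast:

```
GLM1 validation (occipital-right, rest): eyes closed - open estimate -0.5937 nats,
t = -11.852, perm p = 0.0115
```

i.e. closing the eyes lowers occipital entropy, the expected alpha-rhythm
signature. `autoplot(res$entropy)` draws the condition boxplots and
`plot_topo(res$topo)` the 32-cell topographic summary; `tidy()`/`glance()`
work on fitted models. A command-line wrapper with `simulate`, `preprocess`,
`entropy`, `stats`, `report` and `run-all` subcommands is installed under
`inst/cli/recmicro`.

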