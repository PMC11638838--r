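# testcross

Line-by-tester combining-ability analysis for multi-environment maize
testcross trials.

## The problem

Hybrid maize breeding programs screen hundreds of new inbred lines by
crossing each of them to a few fixed *testers* (here: single-cross hybrids
from the opposite heterotic group) and evaluating the resulting testcross
hybrids in replicated, multi-location trials — typically under both managed
drought stress and optimum management. The questions the analysis must
answer are:

* How much of the variation among hybrids is genetic, and how repeatable is
  it (broad-sense heritability)?
* Is hybrid performance driven by *general combining ability* (GCA — the
  additive contribution a parent makes across all its crosses) or by
  *specific combining ability* (SCA — cross-specific deviations)?
* Which lines transmit favourable alleles for grain yield and for the
  secondary drought traits (anthesis-silking interval, plant and ear
  height)?
* Can untested hybrids be predicted from parental GCA alone, so that more
  lines can be screened with the same field resources?

`testcross` implements this entire workflow for the incomplete line-by-tester
design (each line crossed to a subset of the testers), together with a
synthetic trial generator so every stage can be verified without access to
raw field data.

## Models and statistics

**Plot-level trait derivation.** Grain yield (t/ha) from field weight,
shelling fraction and grain moisture standardised to 12.5%:
`GY = FW × 0.80 × (100 − MOI)/87.5 × 10/area`; anthesis-silking interval
`ASI = SD − AD`.

**Stage 1 — combined genotype model** (REML, per regime), with environment
and replication-within-environment fixed:

    y_ijkb = μ + E_j + R(E)_kj + B(RE)_bkj + G_i + GE_ij + ε_ijkb

with incomplete block `B`, genotype `G` and genotype-by-environment `GE`
random. Broad-sense heritability on an entry-mean basis:

    H² = σ²_g / (σ²_g + σ²_ge/e + σ²_ε/(r·e))

**Stage 2 — line-by-tester partition** (checks excluded), across
environments:

    y_ijdkm = μ + E_d + R(E)_kd + B(RE)_mkd + L_i + T_j + LT_ij
              + LE_id + TE_jd + LTE_ijd + ε_ijdkm

giving σ²_GCA(line), σ²_GCA(tester), σ²_SCA and their environment
interactions. Each component is tested by a likelihood-ratio test against
the 50:50 mixture of χ²₀ and χ²₁ (the null value lies on the boundary).
From the components:

    Baker's ratio = 2(σ²_GCA_L + σ²_GCA_T) / (2(σ²_GCA_L + σ²_GCA_T) + σ²_SCA)

and the proportional contributions of line, tester and line×tester to the
total combining-ability variance.

**Stage 3 — GCA/SCA effects** from entry means by least squares under
sum-to-zero constraints, `mean(i,j) = μ + g_i + g_j + s_ij`, with t-tests of
each effect against its constrained normal-equations standard error.

**Stage 4 — GCA-based prediction.** Leave-one-hybrid-out cross-validation:
each hybrid is predicted as `μ + g_line + g_tester` with its own record held
out; the Pearson correlation r(GCA, TCP) between observed and predicted
performance measures the predictability of hybrids from GCA alone.

## Worked example

Simulate a drought-regime trial (50 lines in two heterotic groups, each
crossed to the 3 opposite-group testers, 3 environments, 2 replications,
alpha-lattice blocks) and run the full pipeline:

```r
library(testcross)

cfg <- sim_config(regime = "drought", n_lines = c(A = 20, B = 30),
                  n_env = 3, block_size = 25, seed = 2025)
sim <- simulate_trial(cfg)
report <- run_full_analysis(sim$data, plan = sim$plan,
                            traits = c("GY", "ASI"))
report
#> Trait summary (grand mean, CV%, heritability):
#>   regime  trait n_env n_rep grand_mean minimum maximum   sed cv_pct heritability
#> 1 drought GY        3     2       1.68 6.80e-4    3.50 0.582   58.8        0.595
#> 2 drought ASI       3     2       2.57 2.22e-1    4.74 0.800   44.8        0.492
#>
#> Baker's ratio:
#>   regime  trait bakers_ratio
#> 1 drought GY           1
#> 2 drought ASI          0.982
#>
#> Leave-one-hybrid-out r(GCA, TCP):
#>   regime  trait     r     n
#> 1 drought GY    0.722   150
#> 2 drought ASI   0.743   150
```

Baker's ratio near 1 says hybrid performance for these traits is governed
almost entirely by additive (GCA) gene action, which is why the GCA-only
leave-one-out predictions correlate strongly with observed performance.
The per-parent effects live in broom-style accessors:

```r
tidy(report$combining$drought$GY)
#>   role     line_id  effect    se t_value  p_value signif tester_id
#> 1 gca_line L001    -1.05   0.240  -4.38  1.31e- 5 "***"  NA
#> 2 gca_line L002    -0.0633 0.240  -0.264 7.92e- 1 ""     NA
#> ...

report$contributions
#>    line tester line_x_tester regime  trait
#> 1 100     0             0    drought GY
#> 2  86.6   9.77          3.62 drought ASI
```

`autoplot()` methods draw the correlation heatmap, the observed-vs-predicted
scatter and the GCA effect distribution; `write_report(report, dir)` writes
every table as CSV plus a JSON summary.

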