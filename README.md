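# tsdpso

Traction switching-delay particle swarm optimization (TSDPSO) and the full
diagnostic-classification pipeline built around it, for binary clinical
classification problems such as distinguishing fracture-related infection
(FRI) from uninfected fracture on wide tabular feature sets.

## What it implements

**The optimizer.** TSDPSO is a particle swarm variant designed against
premature convergence. Each iteration it computes an *evolution factor*
from the swarm's spatial spread,

E_f = (d_g − d_min) / (d_max − d_min),  d_i = (1/s) Σ_j ‖x_i − x_j‖,

classifies the search phase into one of four evolutionary states
(convergence / exploration / development / jump-out), passes the
classification through a tridiagonal Markov transition matrix for
stochastic persistence, and then lets the state steer the update: the
inertia weight follows ω(E_f) = 0.5·E_f + 0.4, the acceleration
coefficients follow a fixed per-state table, and the velocity update reads
the personal and global best positions from τ₁ and τ₂ iterations in the
past (*switching delays*, chosen per state). Particles whose personal best
has stalled for 10 iterations receive an additive *traction* pull toward
the delayed global best, scaled by their relative fitness deficit.

**The pipeline.** Around the optimizer: z-score data cleaning, min–max
normalization, PCA with cumulative explained-variance component selection,
RBF-kernel SVM tuning over (log₂ C, log₂ γ) with stratified-CV error as the
fitness (the SVM dual is solved by libsvm via e1071), confusion-matrix
metrics, ROC/PR curves, uncorrected Pearson χ² two-proportion model
comparison, six classical benchmark functions for optimizer validation, and
a synthetic FRI-style cohort generator so everything is testable without
patient data.

See `vignettes/tsdpso-methods.Rmd` for the model details, parameter
defaults and design rationale.

## Worked example

```r
library(tsdpso)

# the optimizer on a multimodal benchmark
obj <- benchmark_objective("rastrigin", 10)
res <- optimize_tsdpso(obj, swarm_config(convergence_tolerance = 0), seed = 1)
glance(res)
#> # A tibble: 1 × 3
#>   method gbest_fitness iterations_used
#>   <chr>          <dbl>           <int>
#> 1 tsdpso          9.95             500
```

A final fitness of 9.95 on 10-D Rastrigin (global minimum 0, typical
standard-PSO result ~40 under the same budget) reflects the jump-out and
traction machinery escaping local minima.

```r
# end-to-end on a strong-signal synthetic cohort (150 patients per class,
# 3-sigma class separation)
res <- run_pipeline(run_config(
  cohort = cohort_spec(n_per_class = 150, delta = 3, seed = 11),
  seed = 1))
round(res$metrics, 2)
#>   accuracy recall specificity   fpr precision    f1
#> 1      100    100         100     0       100     1
res$auc
#> [1] 1
```

On a cohort with 3σ separation on 22 informative features the tuned SVM
separates the held-out 20% perfectly — the expected outcome for a
strong-signal sanity check, not a claim about clinical data.

```r
# model comparison from printed percentages: accuracy 96.74% vs 92.86%
# at n = 1904 per group
chi_square_two_proportions(96.74, 92.86, 1904)
#> # A tibble: 1 × 6
#>   chi_sq      p_value     a     b     c     d
#>    <dbl>        <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1   29.2 0.0000000662  1842    62  1768   136
```

The χ² of 29.17 (p < 0.01) says the 3.9-point accuracy difference between
the two models is far outside sampling noise at these group sizes.

A command-line wrapper for the full pipeline lives at
`inst/scripts/pipeline.R`:

```sh
Rscript inst/scripts/pipeline.R --n-per-class 150 --delta 3 --seed 1 --out-dir run1
```

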