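# admixpulse

Dating gene flow between populations — and asking how *long* it lasted —
from the genetic traces it leaves behind.

When chromosomes from a donor population (say, Neandertals) enter a
recipient population (modern humans), recombination breaks the introduced
material into ever-shorter ancestry segments, and the linkage
disequilibrium between donor-derived alleles (ancestry LD, "ALD") decays
with genetic distance. Both signals are classically fit with a
one-generation "pulse" of gene flow at time `t_m`, under which segment
lengths are exponential with rate `t_m` and the ALD decay is
`A e^(-t_m l) + c`. Real gene flow, however, can span many generations.

`admixpulse` implements an **extended pulse** model that adds a single
duration parameter. The per-generation migration rate is Gamma
distributed over time with mean `t_m` and shape `k`, summarised by the
duration `t_d = 4 t_m / √k`. This keeps everything in closed form:

* segment lengths are **Lomax** (Pareto II) with shape `k + 1` and scale
  `k / t_m` — mean `1 / t_m` for every `k`, variance
  `(k+1)/((k−1) t_m²)`;
* the ALD decay is `A (1 + t_m l / k)^(−k) + c`;
* `k → ∞` recovers the simple pulse; `k = 1` is constant migration;
* the two observables are duals: `D(l) ∝ ∫_l^∞ P(x)(x−l) dx` and
  `P(l) ∝ D″(l)`.

The package provides the closed-form densities and duality transforms, a
synthetic-data generator (segments, ALD curves, and discretized migration
schedules for coalescent simulators), maximum-likelihood fitting of
segment lengths, differential-evolution-seeded nonlinear least squares
for ALD curves, a parametric-bootstrap likelihood-ratio test against the
simple pulse (needed because the simple pulse sits on the boundary
`k → ∞`), a power analysis of that test, recombination-map utilities, and
a command line. It is aimed at population geneticists dating admixture —
archaic introgression in humans or recent hybridization in other systems.

## Worked example

Simulate 10,000 segments from a 1,000-generation pulse centred 1,500
generations ago, then ask whether the data reject a single-generation
pulse:

```r
library(admixpulse)

p <- pulse_params(t_m = 1500, t_d = 1000)
p
#> Extended admixture pulse parameters
#>   mean time  t_m   = 1500 generations
#>   shape      k     = 36
#>   duration   t_d   = 1000 generations
#>   fraction   alpha = 0.03

segs <- simulate_segments(10000, p, seed = 1)
fit <- fit_segments_extended(segs$lengths)
fit
#> extended pulse fit (converged)
#>   t_m = 1519.4 generations
#>   k   = 39.4079  (t_d = 968.146 generations)
#>   loglik = 63263.819  (8 starts)

lrt_extended_vs_simple(segs$lengths, n_boot = 100, seed = 2)
#> Parametric-bootstrap LRT: extended vs simple pulse
#>   LR = 3.15, empirical p = 0.01 (100 bootstrap replicates)
#>   REJECT simple pulse at level 0.05 (cutoff 1.604)

generations_to_ky(fit$t_m)   # 29-year generations
#> [1] 44
```

The fitted mean time (1,519 generations ≈ 44 ky) and duration (≈ 970
generations) sit within sampling error of the generating values, and the
bootstrap LRT correctly detects that gene flow was extended: the observed
log-likelihood ratio of 3.15 exceeds the empirical 95% null cutoff of
1.6. The same inference runs on ALD decay curves:

```r
g <- seq(5e-4, 0.01, by = 2e-5)   # 0.05-1 cM, in Morgan
curve <- simulate_ald_curve(g, t_m = 1500, k = 36, A = 0.5, c = 0.01,
                            noise_sd = 2e-3, seed = 3)
fit_ald(curve, "extended", seed = 4)
#> extended pulse fit (converged)
#>   t_m = 1485.21 generations
#>   k   = 44.0294  (t_d = 895.317 generations)
#>   A   = 0.494841, c = 0.0101825
#>   rss = 0.0019673241  (10 starts)
```

The same operations are available from the shell via the thin wrapper in
`inst/cli/` (`simulate`, `fit-segments`, `fit-ald`, `lrt`, `power`):

```sh
admixpulse simulate --tm 1500 --td 1000 --n 10000 --seed 1 --out segs.tsv
admixpulse fit-segments segs.tsv --model extended
admixpulse power --config power.yaml --out grid.tsv
```

See the vignette (`vignettes/extended-pulse-model.Rmd`) for the model's
derivation, the inference and power-analysis design, and the package's
numerical choices and limitations.

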