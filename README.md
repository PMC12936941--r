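# auxofate

Quantitative analysis of amino-acid **auxotroph fate in spatially
structured microbial populations**, from single-cell tracking tables to
leakage-rate inference.

When an *E. coli* mutant loses an amino-acid biosynthesis pathway it
saves the cost of synthesis, but in a dense colony it must live off what
its wildtype neighbors leak. `auxofate` is for microbial ecologists and
systems biologists who study this trade-off in microfluidic time-lapse
experiments. It provides:

* **Track tables** — a validated long-format CSV interchange schema
  (one row per cell per frame: position, length, area, strain label),
  with gap splitting and value-exact round trips.
* **Synthetic chambers** — a generator emulating 40 µm monolayer
  growth chambers seeded ~90% wildtype / ~10% auxotroph, 5-minute
  frames over 12 h, exponential growth with division, measurement
  noise, spurious length jumps, washout at the open side, and growth
  rates coupled to the local auxotroph fraction.
* **Single-cell growth rates** — log-linear fits of `ln(length)` vs
  time over each track's lifetime with the standard quality filters
  (±15 % frame-to-frame jump rule, ≥ 5 consecutive frames, R² > 0.8)
  and doubling-time conversion `t_d = 60·ln 2 / µ` minutes.
* **Neighborhood statistics** — the local auxotroph area fraction in a
  circular neighborhood (default 5 µm; 5/9/13 µm sweep), Spearman rank
  correlations with growth, and seeded 10,000-draw permutation tests.
* **Exchange model** — the leakage/uptake growth model for an auxotroph
  among producers,

  ```
  r = (1 + s) · î / (K_M + î),
  î = K_M · [εL − ľ + √((εL + ľ)² + 4εL(1 + s))] / (2((1 + s) + ľ)),
  ```

  with fitness benefit `s = (µ_max,aux − µ_wt)/µ_wt`, relative leakage
  flux `L = l_wt·I_C/(µ_wt·K_M)`, relative auxotroph leakage
  `ľ = l_aux/µ_max,aux`, and defaults `ε = 1`, `I_C = 20·K_M`. Includes
  the relative-growth heatmap over leakage × benefit and the
  equal-growth (critical leakage) contour `r(L*) = 1`.
* **Leakage inference** — extrapolate auxotroph growth to a fully
  wildtype neighborhood, invert the monotone model for the shared
  leakage rate, and report the fold-change to the invasion threshold.
* **Replicate-level statistics** — paired t-tests on replicate means,
  Kruskal–Wallis, and a deterministic end-to-end pipeline driver.

## Worked example

A reduced synthetic experiment (five replicates, two chambers each,
6 h; the defaults run 5 × 5 chambers over 12 h):

```r
library(auxofate)

cfg <- default_config(
  synthetic    = list(duration_h = 6, n_chambers = 2, n_replicates = 5),
  neighborhood = list(n_permutations = 1000L))
res <- run_pipeline(cfg, seed = 42, out_dir = "run1")

res$summary[res$summary$replicate_id == "pooled", ]
#>    replicate_id cell_type mean_mu_h  sem_mu_h     n
#> 6        pooled       AUX    0.2146 0.0017587   214
#> 12       pooled        WT    0.7042 0.0002514 18044

res$sweep
#>   radius_um cell_type     rho p_value     n n_dropped
#> 1         5       AUX -0.7605   0.000   214         0
#> 3         9       AUX -0.5877   0.000   214         0
#> 5        13       AUX -0.4538   0.000   214         0
#> ...

res$inference[c("mu_max_obs", "l_fit", "L_fit", "L_star", "fold_to_threshold")]
#> $mu_max_obs 0.2350   $l_fit 0.00421   $L_fit 0.1203
#> $L_star 4.051        $fold_to_threshold 33.7
```

Reading: wildtype cells grow at 0.704 /h (doubling ≈ 59 min) while
auxotrophs average 0.215 /h (≈ 194 min) — roughly three-fold slower.
The pooled auxotroph growth rate falls with the local auxotroph
fraction (ρ = −0.76 at 5 µm, permutation p < 0.001, weakening at 9 and
13 µm), the signature of neighbors competing for a scarce leaked amino
acid. Extrapolating auxotroph growth to a fully wildtype neighborhood
gives 0.235 /h, which the model explains with a shared leakage rate of
≈ 0.004 /h (relative leakage flux L ≈ 0.12); the equal-growth threshold
sits at L\* ≈ 4.05, i.e. leakage would have to be ~34-fold higher for
these auxotrophs to stop being disadvantaged. The paired replicate-level
t-test (t = 239, p < 0.001) confirms the strain gap.

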