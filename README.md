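# dnacoop

Quantifying cooperative protein–DNA recognition from molecular ensembles.

Transcription factors such as OCT4 assemble on regulatory DNA together with
partners such as SOX2, and their binding cooperativity arises from an
interplay of direct protein–protein contacts and DNA-mediated allostery —
one protein deforming the double helix and thereby changing the binding
free energy of the other. Simulation studies quantify this by umbrella
sampling of domain unbinding along the minimal protein–DNA heavy-atom
distance d_min, plus interface analytics on the bound ensembles. `dnacoop`
packages that analysis chain for computational structural biologists:

* **Free-energy core** — the piecewise umbrella restraint
  U = Σ k (d_ij − d_c)² (all pairs below the window center) or
  k (d_min − d_c)² (minimal pair beyond it); WHAM reconstruction of
  G(d_min) with Bayesian-bootstrap errors; the consecutive-window
  consistency diagnostic θ; and the macroscopic binding free energy

  ΔG = −k_B T ln [ ∫_bound ρ(d_min) dd_min / ∫_unbound ρ(d_min) dd_min ],
  ρ ∝ exp(−G/k_B T),

  swept over bound/unbound thresholds (3.1–4.3 Å, upper limit 5.5 Å).
* **Cooperativity bookkeeping** — per-domain ΔG with/without the partner
  combined into ΔΔG_coop = δ_POU_S + δ_POU_HD with quadrature errors,
  domain comparisons, and an audit that recomputes printed cooperativity
  columns and flags inconsistent rows.
* **Interface analytics** — 4.5 Å heavy-atom contact maps with
  recurrent/non-stable classification (>50% occupancy), per-residue
  profiles and unbinding contact fractions; Rock/Tumble docking-helix
  angles in a DNA-based frame with conformational-area ratios; simplified
  groove widths and axis bending with block-averaged errors; and
  dynamical-network analysis (Cα/Cβ + nucleotide backbone/base nodes,
  persistence-filtered edges weighted −log|C|, shortest/suboptimal
  communication paths, Girvan–Newman communities).
* **Synthetic generators** — idealized B-DNA duplexes, toy protein–DNA
  complexes with designed contact persistence and node covariance, and a
  Brownian (overdamped Langevin, Rcpp) umbrella sampler on a reference
  free-energy profile. Every estimator is tested against these ground
  truths; no trajectories or downloads are needed.

Results are tibbles (or small S3 objects with `tidy()`/`glance()`/
`autoplot()` methods), so everything composes with the tidyverse.

## Worked example

Cooperativity from the packaged per-domain affinity table (kcal/mol; the
audit flags the two rows whose printed values do not recompute):

```r
library(dnacoop)
cooperativity(utf1_affinity_table())[, c("threshold", "cooperativity", "error")]
#> # A tibble: 7 × 3
#>   threshold cooperativity error
#>       <dbl>         <dbl> <dbl>
#> 1       3.1          0.96  0.2
#> 2       3.3         -2     0.15
#> 3       3.5         -2.59  0.16
#> 4       3.7         -3.49  0.16
#> 5       3.9         -4.51  0.12
#> 6       4.1         -5.73  0.12
#> 7       4.3         -5.79  0.12
```

At the 3.3/3.5 Å thresholds — where the profiles' sharp transition places
the bound/unbound boundary — the recomputed cooperativities are −2.00 and
−2.59 kcal/mol; the rows at 4.1/4.3 Å disagree with their printed
cooperativity column, which `table_audit()` reports.

A synthetic free-energy pipeline end to end: sample 20 umbrella windows by
Brownian dynamics on a double-well reference profile, reconstruct it by
WHAM, and integrate the profile into a binding free energy:

```r
dw   <- pmf_double_well()                       # reference G(x), barrier 4 kcal/mol
wins <- tibble::tibble(center = seq(2.6, 5.4, length.out = 20), k = 15)
ds   <- gen_bd_umbrella(dw, wins,
                        bd = bd_params(n_steps = 2e5, save_stride = 10,
                                       seed = 42))
fp   <- wham(ds)
fp
#> <fe_profile> 293 sampled bins of width 0.01 A; WHAM converged in 510 iterations
threshold_sweep(fp, thermo(300), thresholds = c(3.5, 3.85, 4.1), upper = 5.4)
#> # A tibble: 3 × 5
#>   threshold    dG error lower upper
#>       <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1      3.50 -1.04    NA  2.52  5.40
#> 2      3.86 -1.05    NA  2.52  5.40
#> 3      4.10 -1.05    NA  2.52  5.40
max(theta_consistency(ds)$theta)
#> [1] 0.280502
```

The recovered ΔG ≈ −1.05 kcal/mol is the double well's closed-form value
to within the sampling error, and θ < 0.3 for every window pair indicates
consistent sampling. `autoplot(fp)` draws the profile;
`run_pipeline(pipeline_config(...))` chains the synthetic-complex,
contact, orientation, groove, network and free-energy stages and writes
TSV/JSON artifacts alongside the resolved configuration.

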