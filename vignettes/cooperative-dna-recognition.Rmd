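---
title: "Quantifying cooperative protein-DNA recognition from molecular ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cooperative protein-DNA recognition from molecular ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnacoop)
library(tibble)
```

## The problem

Transcription factors such as OCT4 bind regulatory DNA cooperatively with
partners such as SOX2. Part of that cooperativity comes from direct
protein-protein contacts, part from *DNA-mediated allostery*: one protein
deforms the double helix and thereby changes the binding free energy of the
other even without touching it. Molecular-simulation studies quantify this
by (i) characterizing the protein-DNA interfaces of the bound ensembles
(contacts, docking-helix orientation, DNA groove geometry, correlation
networks) and (ii) pulling each DNA-binding domain off the DNA in umbrella-
sampling simulations and turning the resulting free-energy profiles into
macroscopic binding free energies, with and without the partner.

`dnacoop` implements that full analysis chain as reusable, tested R
functions, together with seeded synthetic-data generators that emulate the
statistical structure of the molecular ensembles. The generators make every
stage testable against ground truth on a laptop; they do not replace
molecular dynamics, and passing tests demonstrate estimator correctness,
not biological results.

## Unbinding free energies

### Collective variable and bias

Domain unbinding is described by $d_{\min}$, the minimal heavy-atom
distance between the pulled domain and the DNA (`min_distance()`). During
biased sampling the restraint has the piecewise form implemented by
`bias_energy()`:

$$U = \begin{cases}
\sum_{ij:\, d_{ij} < d_c} k\,(d_{ij}-d_c)^2 & d_{\min} < d_c\\
k\,(d_{\min}-d_c)^2 & d_{\min} \ge d_c
\end{cases}$$

so no atom pair may come closer than the current window center $d_c$, while
pairs are free to separate — hierarchical unbinding. For the 1D analysis,
the bias is modelled as $k\,(x-d_c)^2$ in the scalar coordinate: the
multi-pair branch is not representable in a one-dimensional reweighting,
and the profile being reconstructed is one-dimensional in $d_{\min}$. The
exact multi-pair form is retained in `bias_energy()` for
configuration-level checks. The default protocol is 60 windows every
0.05 Å from 2.55 to 5.5 Å (`window_grid()`) with
$k = 300\;\mathrm{kcal\,mol^{-1}\,Å^{-2}}$.

### WHAM

`wham()` solves the standard self-consistent weighted-histogram equations
on a 0.01 Å grid (default), iterating until every window free energy moves
by less than $10^{-6}\,k_BT$ (cap $10^5$ iterations), and anchors the
profile at $\min G = 0$. Unsampled bins are `NA`; consecutive windows with
no shared sampled bins trigger a warning because the profile may then
consist of mutually unanchored segments. The solution is invariant to
window order (the dataset container sorts windows by center) and agrees
with a histogram-free MBAR-style estimator on identical data in the test
suite.

### Errors

`wham_error()` performs a Bayesian bootstrap: each window's series is
subsampled at its statistical-inefficiency stride
($g = 1 + 2\sum_t \rho(t)$, autocorrelation summed until it first drops
below 0.05), each replicate reweights those samples with Dirichlet weights
and re-solves WHAM warm-started from the base solution. Replicates are
aligned on the well-sampled region (count-weighted mean over bins holding
at least 10 samples) rather than on the global minimum bin: the minimum
bin of a noisy profile is often a lucky tail bin with a handful of
samples, and anchoring there would impose its shot noise on every other
bin.

Two error estimates for the macroscopic $\Delta G$ are provided.
`dG_error()` implements first-order propagation through the log-ratio of
trapezoidal sums treating per-bin errors as independent (and a Monte Carlo
variant resampling bins from independent normals). Because profile errors
are in reality strongly correlated across bins — they accumulate through
the chain of window free energies — the independence assumption
underestimates the uncertainty of $\Delta G$. For an honest statistical
error, `wham_error(keep_replicates = TRUE)` returns the aligned replicate
profiles, and the spread of $\Delta G$ recomputed per replicate preserves
those correlations; this is what the package's own acceptance checks use.

### Window-consistency diagnostic

`theta_consistency()` compares each pair of consecutive windows: both
histograms are unbiased into local density-of-states estimates
($h_b\,e^{+U(x_b)/k_BT}$), normalized over the shared support, and compared
by L1 distance, so $\theta \approx 0$ for consistent sampling and
$\theta = 2$ for disjoint windows. Only bins with at least `min_count`
(default 10) samples in *both* windows enter the comparison: the
exponential unbiasing factor otherwise amplifies single-count tail bins
into the diagnostic even for perfectly converged data. The bin width
(default 0.02 Å) and `min_count` trade resolution against shot noise; the
diagnostic's role is relative (flagging under-sampled windows), not
absolute. The exact formula is this package's definition; it preserves the
diagnostic behaviour of the original convergence analysis (near zero when
consistent, growing when a window is starved).

### From profile to binding free energy

`pmf_to_dG()` integrates the Boltzmann weight of the profile,

$$\Delta G = -k_BT \ln
\frac{\int_{\mathrm{lower}}^{\mathrm{threshold}} e^{-G(x)/k_BT}\,dx}
     {\int_{\mathrm{threshold}}^{\mathrm{upper}} e^{-G(x)/k_BT}\,dx},$$

by the trapezoid rule on the profile grid, with the threshold and upper
limit snapped to grid points and the lower limit at the lowest sampled
bin. The upper limit defaults to 5.5 Å; because of the exponential, the
result is insensitive to it. Note the sign in $e^{-G/k_BT}$: the source
analysis prints the density relation with a positive exponent, which would
make the high-$G$ region dominate the *bound* integral and flip every sign;
the negative sign is required for the bound well (low $G$) to dominate, and
is treated here as the corrected reading. `threshold_sweep()` evaluates the
bound/unbound boundary at 3.1-4.3 Å in 0.2 Å steps (default), the range
tested when profiles lack a clear transition state.

## Cooperativity bookkeeping

With per-domain binding free energies for the POU-specific domain (POU_S,
residues 1-88, including the helical linker part) and the POU homeodomain
(POU_HD, residues 95-152), each with and without the partner protein,
`cooperativity()` computes the partner-induced cooperativity as the sum of
the per-domain changes,
$\Delta\Delta G = \delta_S + \delta_{HD}$ with
$\delta_X = \Delta G_X(+) - \Delta G_X(-)$, assuming the partner alters
neither the inter-domain cooperativity nor the linker contribution. Errors
combine in quadrature (`cooperativity_error()`), consistent with
independent linear propagation; rounding for table reproduction is half
away from zero at 2 decimals. `domain_deltas()` reports the per-domain
changes and the domain comparison with and without the partner.
`table_audit()` recomputes the cooperativity column from the four
per-domain columns and flags rows whose printed value does not reproduce
within 0.01 kcal/mol, and columns that break their monotone trend — the
packaged table (`utf1_affinity_table()`) contains two such rows (4.1 and
4.3 Å), which the audit flags and never silently corrects.

```{r coop}
co <- cooperativity(utf1_affinity_table())
co[co$threshold %in% c(3.3, 3.5), ]
table_audit(utf1_affinity_table())
```

## Interface analytics

**Contacts.** An atom-atom contact is a heavy-atom pair within 4.5 Å,
boundary included. A contact is *recurrent* when present in strictly more
than 50% of frames, *non-stable* otherwise; the two labels partition all
observed pairs. Per-residue profiles count atom pairs (a residue touching
one DNA atom through two of its atoms counts 2); the base/backbone split
classifies the DNA atom by name (primed and phosphate-group atoms are
backbone). Distances are superposition-invariant, so contacts are computed
on raw coordinates. `unbinding_profile()` reports, per minimal-distance
label, the fraction of the unbiased ensemble's recurrent contacts still
formed and the number of non-stable contacts — the contact-level view of
the unbinding transition.

**Orientation.** `dna_frame()` builds the DNA-based frame: $v_x$ joins the
centers of mass of the first and last base pairs of the binding site;
$v_t$ joins the two strands' backbone reference atoms of the first base
pair (P, falling back to C3' — the printed definition names "the backbone
of the bases from the first base pair" without atoms, and this is the
reading that yields a transverse vector); $v_z = v_x \times v_t$,
$v_y = v_x \times v_z$. The docking-helix axis is the principal component
of the helix CA positions signed N→C — stable for 8-15 residue helices and
directly testable against parametric constructions, unlike a rotational
fit. Rock is the signed angle (atan2) of the axis projected on the
$v_y/v_z$ plane measured from $v_y$; Tumble likewise on $v_x/v_z$ from
$v_x$. Frames where a projection vanishes are flagged `NA` with a warning.
`ellipse_area_ratio()` compares sampled orientation areas via
$\sqrt{\lambda_1\lambda_2}$ of the 2D covariance — the confidence-ellipse
area at any fixed confidence level, which cancels in the ratio.

**DNA geometry.** Groove widths use a phosphate-register convention
(tagged `pp-register`): the minor width at level $i$ is the minimal
cross-strand P-P distance over strand-2 partners offset $+2..+5$ levels
(major: $-5..-2$), minus 5.8 Å for the phosphate radii. On the idealized
duplex this reproduces the canonical B-DNA minor-groove scale (~5.4 Å).
It is *not* a curvilinear-axis groove definition, so absolute values from
helicoidal-analysis programs are not comparable; relative changes are.
Bending is the angle between base-pair-center chords $c_i - c_{i-2}$ and
$c_{i+2} - c_i$, with centers at the midpoint of the paired base atoms;
the two terminal levels (and levels whose register window leaves the
duplex) are flagged undefined. `block_se()` provides block-averaged
standard errors: block sizes double until fewer than 8 blocks remain, and
the SE at the largest retained size is reported — for series whose
correlation time is resolved this is the plateau value.

**Dynamic network.** Nodes: protein residues contribute a CA node and a CB
node (side chain), except Gly/Ala/Pro which get a single CA node;
nucleotides contribute a backbone node anchored on C3' and a base node
anchored on N3 (purines) or C4 (pyrimidines). Edges require at least one
atom-atom contact between the represented sets persisting in more than 75%
of frames, excluding pairs within one protein residue, sequence-adjacent
CA-CA pairs, and sequence-adjacent backbone-backbone pairs on one strand.
Weights are $d_{mn} = -\log|C_{mn}|$ with $C_{mn}$ the normalized scalar
covariance of the anchor-atom displacements (the standard dynamical-network
convention; anchor atoms, not set centroids) computed on a superposed
ensemble — the fit selection is the caller's choice. $|C| = 0$ edges are
dropped with a message; correlations that exceed 1 by rounding are clamped
so weights stay non-negative. `shortest_path()` is a Dijkstra solve with a
deterministic lexicographic tie-break; `suboptimal_paths()` enumerates all
simple paths within an additive offset (default 5, dimensionless, matching
the weights) of the optimum by depth-first search with an admissible
remaining-distance bound and an explosion guard, and reports per-edge
traversal counts. `communities()` uses Girvan-Newman edge-betweenness
(weights as distances) cut at the maximum of the *unweighted* modularity —
with $-\log|C|$ weights, small weights mean strong coupling, so using them
as modularity strengths would invert their meaning.

## Synthetic data: what it emulates, and what it does not

`gen_ideal_bdna()` places a reduced nucleotide representation (P, C3',
C1', N3/C4 base proxy) of both antiparallel strands on a regular
right-handed helix (rise 3.38 Å, twist 36°), dyad-symmetric per base pair.
The phosphate azimuth was fixed once so that the cross-strand register
minima reproduce canonical B-DNA groove widths; the base proxies straddle
the helix axis at hydrogen-bond distance, standing in for the paired
H-bond edge, which keeps base-pair centers near the axis and the chord
bend estimator flat on the ideal duplex.

`gen_toy_complex_ensemble()` emulates the statistics the interface
analytics consume: designated protein-DNA contacts toggle between bound
(3.0 Å) and unbound (6.5 Å) distances by independent Bernoulli draws with
designed persistence (contact atoms track their displaced DNA target, so
designated pair distances are exact in both states), and each protein
residue and base-pair level undergoes rigid Gaussian displacements drawn
from a designed covariance, i.i.d. across x, y, z — so positional
cross-correlations between node anchors recover the designed correlations.
`gen_unbinding_schedule()` produces ensembles labeled by minimal distance
in which contacts break monotonically per schedule.
`gen_bd_umbrella()` samples each umbrella window by overdamped
Euler-Maruyama dynamics (Rcpp) on a piecewise-linear reference profile
plus the harmonic bias, reflecting at the grid edges, discarding an
initial equilibration fraction (default 6/22.5, the discarded share of a
22.5 ns window after 6 ns of equilibration).

What the toys do **not** have: chemistry (no force field, no solvent, no
sequence effects), realistic protein architecture (pseudo-residues with a
handful of atoms), correlated contact breaking, or anharmonic DNA
elasticity. Passing tests therefore certify that the estimators recover
known ground truth — occupancies, correlations, angles, groove scales,
free-energy surfaces — not that any biological conclusion is reproduced.

## Numerical choices

* Coordinates in Å, energies in kcal/mol,
  $k_B = 0.0019872041\;\mathrm{kcal\,mol^{-1}\,K^{-1}}$, default
  $T = 300$ K.
* Contacts: heavy atoms only, everywhere (the restraint definition speaks
  of heavy-atom pairs); cutoff boundary included; recurrence strictly
  greater than the threshold.
* Brownian integrator defaults $D = 0.1\;\mathrm{Å^2/ps}$,
  $\Delta t = 0.01$ ps. Two enforced stability bounds: profile drift
  $|\partial G/\partial x|\,\Delta t\,D/k_BT < 0.1$ on the grid, and
  harmonic-bias resolution $2kD\Delta t/k_BT < 0.1$ (the discrete
  stationary variance is inflated by $\approx 1/(1-\theta/2)$ at
  relaxation factor $\theta$). Stiff restraints
  ($k = 300\;\mathrm{kcal\,mol^{-1}\,Å^{-2}}$) therefore need
  $\Delta t \lesssim 2\times10^{-4}$ ps.
* Superposition by SVD-based Kabsch least squares; reference is the first
  frame unless overridden; fitting is idempotent; degenerate (collinear or
  <3 atom) fit selections error.
* Contact scans are fully vectorized frame-chunked pairwise scans. At the
  ensemble sizes this package targets (10^2-10^3 atoms) this is faster and
  simpler than a cell-list neighbor search and is exactly the brute-force
  computation, bit for bit.
* WHAM bin width 0.01 Å, tolerance $10^{-6}\,k_BT$; $\Delta G$
  quadrature by trapezoid with thresholds snapped to the grid (at 0.01 Å
  bins the snap changes smooth-profile results by $\ll 10^{-3}$ kcal/mol).
* Ties and degenerate inputs: zero-variance nodes error by name;
  zero-variance base-pair levels get `NA` off-diagonal correlations;
  disconnected path queries return an explicit no-path result; equal-length
  paths resolve to the lexicographically smallest node sequence.
* The test problem sizes (20 windows x 10^6 Brownian steps for the
  free-energy pipeline; 500-2000 frames for estimator recovery; <=8-node
  graphs for exhaustive path/community enumeration) were chosen so each
  property is measured well inside its sampling tolerance.

## Limitations

* The groove convention and the helix-axis construction are this package's
  documented choices; published figures based on Curves+ helicoidal
  analysis or other axis fits are not numerically comparable.
* The θ diagnostic's formula is this package's definition (the original
  analysis defers to a reference without printing one); use it
  comparatively.
* Linear $\Delta G$ error propagation assumes independent per-bin errors
  and is known to understate the statistical error of $\Delta G$;
  replicate-based errors are provided and preferred.
* Reading biased trajectories assumes the scalar-coordinate harmonic bias;
  datasets generated with the multi-pair restraint branch active below the
  window center are reweighted approximately, exactly as in the original
  one-dimensional analysis.
* XTC trajectories are not readable (no installed reader); use DCD,
  multi-model PDB, or CSV frame tables.
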