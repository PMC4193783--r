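---
title: "Modelling tissue patterning by cell sorting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tissue patterning by cell sorting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(pottsort)
```

## The biological question and the model

During development, sharply delineated domains of distinct cell fates can
arise not only by positional read-out of a morphogen (the classical
French-flag picture) but also by *cell sorting*: fates are first assigned
imprecisely, or even at random, and cells then rearrange into ordered
bands. `pottsort` implements a two-dimensional Cellular Potts Model (CPM)
of this process with two candidate sorting mechanisms that can be switched
on independently:

* **chemotaxis** — each cell type carries a chemotactic potential
  $\mu(\tau)$ coupling it to a diffusible morphogen concentration $C(x)$,
  so types are pulled towards (or pushed away from) the source with
  type-graded strength; and
* **differential adhesion** — unlike-type cell contacts pay a surface
  energy that grows with the distance between the two types in the target
  order, so like-type contacts are favoured.

The lattice holds $N$ cells (default 100) as connected domains of sites on
a bounded grid with a one-site inaccessible boundary ring. The energy of a
configuration is

$$H \;=\; \sum_{\langle x,x'\rangle} J\!\left(\tau(\sigma_x),
\tau(\sigma_{x'})\right)\left(1-\delta_{\sigma_x \sigma_{x'}}\right)
\;+\; \lambda \sum_i \left(a_i - A_{\tau(i)}\right)^2
\;-\; \sum_x \mu\!\left(\tau(\sigma_x)\right) C(x),$$

with 4-neighbour site pairs counted once, $a_i$ the current cell areas,
$A_\tau$ the 49-site target area, $\lambda = 0.2$ the area-constraint
strength and $T = 1$ the fluctuation temperature. Dynamics are Metropolis
Monte Carlo: an interior site and one of its four neighbours are drawn
uniformly at random, and the neighbour's identity is copied onto the site
with probability $\min(1, e^{-\Delta H/T})$. One Monte Carlo step (MCS) is
as many elementary attempts as there are interior sites. The chemical term
is the standard per-site CPM chemotaxis coupling: for a single copy at
site $x$ it contributes $-(\mu_{\text{gain}}-\mu_{\text{loss}})\,C(x)$,
which gives directed motion along the gradient and, at type interfaces,
a pressure proportional to the local absolute concentration.

## Parameters and their defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `lambda` | area-constraint strength | 0.2 | energy/site² |
| `temp` | membrane-fluctuation temperature | 1 | energy |
| `a_target` | target area per cell | 49 | sites |
| `j` | differential-adhesion magnitude | scenario-swept | energy/contact |
| `j_same` | like-type contact energy | 1 | energy/contact |
| `j_bnd` | cell–boundary contact energy | 1 | energy/contact |
| `mu0` | chemotactic magnitude | scenario-swept | energy/concentration |
| `r` | fate-specification error ratio | 1 or `default_error_ratio()` | — |
| `c0` | source concentration | 5 | concentration |
| `lambda_d` | gradient decay length | 140 | sites |
| `k` | morphogen degradation rate | 10⁻³ | 1/step |
| `eta` | gradient noise magnitude | 0 | concentration/step^½ |

Several of these are genuinely open design choices, resolved as follows.

**Grid geometry.** The interior is an exact tiling of 20 × 5 cells of
7 × 7 sites (140 × 35 sites inside a 142 × 37 bounded grid), so that 100
cells of 49 sites fill the tissue and the rightmost accessible sites abut
the morphogen source column at $x = 142$. The four fate regions are
35-site-wide bands along $x$; region 4 is adjacent to the source. A
210-cell variant (30 × 7 cells, 212 × 51 grid) is available as
`grid_spec(30, 7)`.

**Contact-energy matrix.** Only relative differences
$j\,\lvert\tau-\tau'\rvert$ drive sorting, so the like-type contact energy
`j_same = 1` and the boundary contact `j_bnd = 1` merely set a reference
scale; both are exposed. The `uniform` mode (`j_same + j` for every unlike
pair) implements the equal-dislike variant, which sorts more poorly
because a cell that cannot discriminate among unlike neighbours settles at
two-type boundaries.

**Chemotactic potentials.** The bipolar default
$\mu = \mu_0(-2, -1, +1, +2)$ mirrors the graded contact matrix: types 3
and 4 are attracted, 1 and 2 repelled, with even spacing so the sorted
order reads 1|2|3|4 away from the source. `attract_only` and `repel_only`
modes keep the strict ordering with all-positive or all-negative
potentials.

**Gradient calibration.** The source amplitude and decay length are not
independently constrained by the study conditions, which instead require
that the swept chemotactic magnitudes $\mu_0 \in \{0.25,\dots,1.5\}$ all
sort correctly with sorting time decreasing in $\mu_0$. Two failure modes
bracket the calibration. If $\mu_0 C$ near the source is too large
(empirically $\mu_0 c_0 \gtrsim 8$), cells of the weaker-attracted type
are squeezed to near-minimal area at type interfaces and become immobile —
runs jam with extra clusters that never resolve. If the far-field
concentration (and its slope) is too small, the repelled types at the far
edge barely feel the gradient and sorting outlasts any practical horizon
at $\mu_0 = 0.25$. A sweep over $c_0 \in \{2,\dots,10\}$ and
$\lambda_d \in \{70, 140\}$ located $c_0 = 5$, $\lambda_d = 140$ (the full
tissue length) as the point satisfying both requirements; with it,
ensemble sorting times decrease monotonically over the sweep
(≈63k / 32k / 15k / 12k / 9k MCS) and every run sorts. These values were
frozen before the acceptance checks and are exposed in
`gradient_params()`.

**Fate-specification error.** A cell whose centroid lies in region $p$
takes fate $\tau$ with probability $\propto r^{\lvert\tau-p\rvert}$,
normalised over the valid fates. This is the simplest scheme satisfying
the three constraints that define the error ratio: perfect specification
at $r = 0$, uniform fates at $r = 1$, and errors concentrated in adjacent
regions in between. Cells are exact tiles at initialisation, so the
region of the centroid is unambiguous. The small-$r$ default is not a
magic number: `default_error_ratio()` solves, by exact enumeration, for
the $r$ whose expected misspecified count on the standard tiling is 2.5
(two-to-three wrongly specified cells out of 100), giving
$r \approx 0.0169$. Because errors favour adjacent regions, a draw can
start with every error touching its own type's band — or with no errors
at all — i.e. already at four clusters, which tells us nothing about
sorting; the differential-adhesion ensembles therefore redraw fates until
the initial cluster count exceeds the number of types
(`init_cells(require_unsorted = TRUE)`). Without this conditioning a
fraction of runs would be trivially "correct" even at adhesion strengths
where misplaced cells are demonstrably frozen.

**Cell persistence and connectivity.** Copy attempts that would annihilate
a cell are rejected (`allow_vanish = FALSE`), since every metric assumes
100 persistent cells; transient fragmentation of a cell is allowed, as in
the standard CPM, and the cluster counter (below) handles fragments
naturally.

## The morphogen field

The deterministic gradient is the steady state of synthesis at a source
column, diffusion, and uniform first-order degradation:
$C(x) = c_0\, e^{-(x_s-x)/\lambda_d}$, uniform in $y$. The stochastic
field integrates
$\partial_t C = D\,\nabla^2 C - kC + \eta\,\xi$ with i.i.d. standard
Gaussian noise per site and step, using implicit Euler for the
deterministic operator (unconditionally stable; the sparse SPD system is
Cholesky-factorised once and reused) and explicit addition of the noise
increment; negative excursions are clipped to zero because the chemical
energy is linear in $C$.

Boundary conditions deserve care. The source column is Dirichlet at
$c_0$ and the two $y$ edges are zero-flux, but a zero-flux condition at
the *far* $x$ edge would not reproduce the exponential: with
$\lambda_d$ comparable to the domain length the zero-flux steady state is
a cosh profile roughly twice the exponential at the far edge. The far
edge therefore uses an exponential-outflow (Robin) ghost,
$C_{0} = C_1 e^{-1/\lambda_d}$, the discrete analogue of the semi-infinite
exponential tail. Likewise $D$ is chosen lattice-consistently as
$D = k / \left(2(\cosh(1/\lambda_d) - 1)\right) = k\lambda_d^2\,(1 +
O(\lambda_d^{-2}))$, so the closed-form profile is an *exact* fixed point
of the discrete scheme rather than merely an $O(\lambda_d^{-2})$
approximation. With $k = 10^{-3}$ the field relaxes on a 1000-step scale,
so the 50 000-step burn-in used before noisy sorting runs is comfortably
sufficient.

```{r gradient, fig.height = 3}
f <- closed_form_gradient(grid_spec())
plot(f$conc[, 1], type = "l", xlab = "x (sites)",
     ylab = "concentration", main = "deterministic gradient")
```

## Metrics

A **cluster** is a connected component of the cell-adjacency graph
restricted to same-type edges, where two cells are adjacent iff any of
their sites are 4-neighbours (`count_clusters()`; cross-checked in the
test suite against an independent site-level flood fill). A run is
**correct** if the recorded cluster count reaches the number of types at
some time after the gate (0 normally; 500 MCS for delayed-adhesion runs),
the **sorting time** $t_s$ is the first such time, and a correct run is
**stable** if every recorded count from $t_s$ to the end stays there.
`summarize_ensemble()` turns per-run classifications into the fraction of
correct runs $F_C$, the fraction of stable runs among correct $F_S$
(flagged undefined when nothing sorts), and sorting-time statistics.
Cluster counts are recorded every 100 MCS; breakups shorter than the
cadence are invisible, which can only overstate stability — the
published read-out has the same property and the limitation is inherited
deliberately.

Supporting metrics: `size_variation()` (population standard deviation
over the four per-type mean areas divided by their mean — a flag for
chemotactic squeezing), `cell_speeds()` (mean centroid displacement per
100-MCS window, split by misspecified status), `cluster_lifetimes()`
(durations between intermittent breakups of the sorted state),
`merging_time()` (the 16-cell two-type fixture: first MCS at which the
marked cell's centroid crosses the initial interface), and
`initial_cluster_stats()` (pooled-variance two-sample t-test of initial
cluster counts in correct vs incorrect runs, gated at two runs per group,
and a Spearman test of initial count against sorting time, gated at three
correct runs).

## What the generator emulates — and what it does not

Scenario ensembles (`scenario()`, `run_scenario()`) reproduce the study
designs: chemotaxis-only with uniform-random fates ($r = 1$, $j = 0$,
swept $\mu_0$, 10 × 100 000 MCS), differential-adhesion-only with a
handful of misspecified cells (small $r$, $\mu_0 = 0$, swept $j$,
30 × 200 000 MCS), the combined sweep, one-signed chemotaxis, the
210-cell grid, the equal-dislike contact matrix, noisy-gradient sweeps,
and chemotaxis with adhesion switched on at 500 MCS under noise (total
horizon 2000 MCS; where the published description is internally
inconsistent about the post-onset span, the 500–2000 MCS sorting-time
window is taken as authoritative). Each scenario has a reduced `smoke`
profile with fewer, shorter runs for desk-scale work; the acceptance
checks run chemotaxis at 5–10 runs with horizons of 30 000–100 000 MCS
and adhesion at 10 runs × 100 000–130 000 MCS, sizes chosen so the whole
suite completes on one CPU in minutes while keeping binomial sampling
bands meaningful.

Passing these in-silico checks says nothing about real tissues beyond the
model's assumptions: cells neither grow, divide nor die; fates never
re-specify; the tissue is a flat sheet with a rigid frame; the morphogen
does not interact with the cells' occupancy; and noise enters only as
additive Gaussian fluctuations of the gradient.

Two quantitative reproductions deserve an honest caveat. First, the
per-type potential spacing and the absolute gradient amplitude are
reconstructed, not printed, so absolute sorting times carry an O(1)
calibration factor even though their ordering and ratios (adhesive
sorting roughly an order of magnitude slower than chemotactic) are
robust. Second, the initial cluster count of uniform-random fates on the
20 × 5 tiling is a fixed combinatorial quantity — mean ≈ 57, range
roughly 40–72 over hundreds of draws under 4-neighbour adjacency — while
the published observed range is 37–60; no adjacency convention
reproduces that range exactly, so the package reports what its own
counter (verified against the flood-fill oracle) measures.

## Numerical choices

* All randomness flows through R's RNG; `set.seed()` makes any run, and
  `run_scenario()`'s derived per-run seeds make any ensemble, bit-identical.
* The Metropolis kernel draws one uniform variate per attempt to pick the
  (site, direction) pair jointly; energy changes are evaluated locally in
  O(1) and validated against full recomputation to 10⁻⁹.
* Area and centroid bookkeeping is incremental and checked against full
  recounts (`check_consistency()`), which `total_energy()` performs on
  every call.
* Ties in the Metropolis rule ($\Delta H = 0$) are accepted; same-cell
  copies are accepted as no-ops; copies from the boundary ring are
  rejected.
* The union-find cluster counter ignores zero-area cells (possible only
  with `allow_vanish = TRUE`).
* Degenerate inputs fail fast with messages: non-tileable geometries,
  error ratios outside $[0,1]$, schedule times outside the run, empty
  traces, missing types in the size-variation ratio.

## Known limitations

* Stability fractions are cadence-limited (see above) and, at the
  default conditions, chemotaxis-only stability at $\mu_0 = 1.5$ sits at
  the low end of the published ~20% band.
* The merging fixture's published initial layout is not fully recoverable;
  the implemented one (marked type-2 cell at tile column 2, row 2,
  interface after tile column 2) is config-visible in `make_fixture()`.
* Long noisy runs advance the PDE once per MCS from R, which costs about
  a millisecond per step; full-scale noisy sweeps are minutes-long, not
  seconds.
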