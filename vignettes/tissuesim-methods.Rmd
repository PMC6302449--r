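---
title: "Models and numerical methods in tissuesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in tissuesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

tissuesim couples three models: a multi-substrate reaction-diffusion
microenvironment, an off-lattice center-based cell population, and a
stochastic cancer-immune interaction layer, all driven by one multi-rate
loop. This vignette explains each model, its assumptions, the numerical
choices, and the design decisions taken where the underlying biology or
published practice leaves the choice open. Nothing here reports an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The biotransport model

Each substrate density $\rho$ (oxygen, an immunostimulatory chemokine, ...)
obeys

$$\partial_t \rho = D \nabla^2 \rho - \lambda \rho
  + S(\rho^* - \rho) - U \rho
  + \sum_i \delta(x - x_i)\,\frac{W_i}{V}\,
    \big[ S_i(\rho_i^* - \rho) - U_i \rho \big],$$

with diffusion $D$ (µm²/min), decay $\lambda$ (1/min), bulk source/uptake
$S, U$ toward a saturation density $\rho^*$, and per-cell secretion/uptake
$S_i, U_i$ applied in the voxel containing the cell center, scaled by the
cell volume over the voxel volume ($W_i/V$) so the Dirac delta becomes a
density rate.

The solver is first-order operator splitting in exactly this order: bulk
sources first, then cell-centered exchange, then diffusion-decay. The
first two are backward-Euler rational updates
$\rho \leftarrow (\rho + \Delta t\,S\rho^*) / (1 + \Delta t\,(S + U))$,
which are unconditionally stable, positivity-preserving, and have the
fixed point $S\rho^*/(S+U)$. The diffusion-decay step uses the locally
one-dimensional (LOD) method: one implicit tridiagonal solve per axis,
each performed by the Thomas algorithm whose forward-elimination
coefficients depend only on (mesh, $D$, $\lambda$, $\Delta t$) and are
precomputed and cached. Internally the solves are arranged so the
recurrence runs across whole planes of contiguous strips (the x-axis pass
transposes each slab), which keeps the inner loops vectorizable.

Numerical choices:

* **Decay apportioning.** $\lambda$ is split evenly across the active axis
  solves ($\lambda/3$ per axis in 3-D, $\lambda/2$ in 2-D) so every 1-D
  system stays tridiagonal and the axes are interchangeable.
* **Boundaries.** No-flux is the zero-gradient closure in the end rows of
  each tridiagonal system. Dirichlet is enforced by pinning the
  domain-boundary voxels to the configured value after every axis solve —
  the far-field semantics wanted for oxygen supplied by vasculature
  outside the domain. Bulk sources are applied everywhere, including
  boundary voxels, and the pin re-asserts the Dirichlet value afterwards.
* **Accuracy.** Centered second-order differences in space, first-order
  backward Euler in time; the acceptance suite fits the observed orders on
  a decaying-sinusoid closed form (spatial slope ≈ 2, temporal slope ≈ 1)
  and verifies each axis solve against a dense solve to 1e-12.
* **Time step.** Biotransport runs at $\Delta t = 0.01$ min. The implicit
  scheme remains stable and monotone at 100 times that step; the default
  is chosen for accuracy, not stability.
* **2-D as a slab.** Two-dimensional simulations use an `nz = 1` mesh of
  thickness 20 µm so densities and volumes keep 3-D units and one code
  path serves both geometries.

## The cell-agent model

Cells are off-lattice spheres with position, velocity, volume (radius
derived), a live/apoptotic/necrotic state, and a phenotype. Each mechanics
step ($\Delta t = 0.1$ min) performs, in order: microenvironment update
(10 biotransport sub-steps), phenotype advancement when a phenotype step
(6 min) is due, serial processing of cached division/removal lists, the
immune interaction step, velocity evaluation, and the position update.

**Mechanics.** For a pair at center distance $d$ with radii $R_i, R_j$,
repulsion acts when overlapping with speed
$c_r (1 - d/(R_i+R_j))^2$ and adhesion within
$d_\max = f\,(R_i+R_j)$ with speed $c_a (1 - d/d_\max)^2$, both along the
center line. Defaults $c_r = 10$ µm/min, $c_a = 0.4$ µm/min, $f = 1.25$
give confluent, non-overlapping packings. These are the standard smooth,
compactly supported polynomial potentials of center-based frameworks;
coincident centers are separated along a deterministic pseudo-random
direction derived from the pair indices so the force is never singular.
Neighbor search uses a uniform spatial hash with bin edge at least the
maximum interaction distance; a 3×3×3 stencil is then guaranteed to
contain every interacting partner, and the tests require exact agreement
with an all-pairs evaluation.

**Motion.** Positions advance by second-order Adams–Bashforth
($x \leftarrow x + \Delta t\,(1.5 v - 0.5 v_{prev})$), bootstrapped with
forward Euler on each cell's first step. Positions are clamped to the
domain; the studies are sized so tumors stay away from the boundary.

**Phenotype.** Death is evaluated before division within a phenotype
step. A live tumor cell: (i) becomes apoptotic with probability
$\min(1, a\,\Delta t)$ (background rate $a = 7\times10^{-5}$/min);
(ii) becomes necrotic deterministically when its local oxygen falls
strictly below the 5 mmHg threshold; (iii) otherwise divides with
probability rate·$\Delta t$ where
rate $= p \cdot r_{\max} \cdot
\mathrm{clamp}\!\left(\frac{pO_2 - 5}{38 - 5}, 0, 1\right)$ — a linear
ramp that vanishes at the necrosis threshold and saturates at physioxia
(38 mmHg), scaled by the cell's oncoprotein expression $p$. Daughters
take half the parent volume and are placed at $\pm R/2$ along a random
unit vector; live cells relax their volume back to target at 0.01/min.
Dead cells shrink exponentially (half-life 30 min apoptotic, 720 min
necrotic) and are removed below 5% of their at-death volume. The maximum
cycle entry rate $r_{\max} = 3.5\times10^{-4}$/min (roughly one division
per two days at saturation) is a calibration choice: it reproduces a
realistic epithelial tumor doubling time and keeps 48-hour populations at
a few thousand cells.

**Determinism.** One seeded generator drives every stochastic draw
(division placement, apoptosis, motility, attach/kill/detach) in a fixed
iteration order, so identical configurations are bit-identical, which the
tests assert.

## The hypoxia study

Oxygen enters through Dirichlet boundary voxels, diffuses with
$D = 10^5$ µm²/min and decays at 0.1/min, and is consumed by live cells.
The per-cell uptake rate (2/min) and the domain edge (1200 µm) were fixed
up front by a penetration-depth analysis: with uptake $U$, cell volume
fraction $\phi$ and local cell density $n_v$, the effective consumption is
$\lambda_{\mathrm{eff}} \approx n_v \phi U$ and the oxygen penetration
depth $\sqrt{D/\lambda_{\mathrm{eff}}}$ is ~250 µm. A 2000-cell seeding
that roughly doubles over 48 h reaches a ~500 µm radius, so at 60 mmHg
boundary oxygen the center stays above the 5 mmHg necrosis threshold
(nearly fully live populations), while at intermediate oxygenation
(≈ 8 mmHg) large seedings develop necrotic cores and small ones do not —
the crowding effect. Stronger uptake (e.g. 10/min) would necrose the
center even at 60 mmHg and contradict the intended well-oxygenated
behavior; the 1200 µm domain keeps the grown tumor off the boundary.

The study metric is the live cell fraction: live cells over all cells
still present in the final snapshot (removed cells have shrunk away;
0/0 is defined as 0). The default grids are oxygenation
{0, 2.5, 5, 8, 10, 15, 38, 60} mmHg by seeding {1, 10, 100, 1000, 2000}.

## The cancer-immune model

Tumor cells draw an oncoprotein expression $p$ from Normal(1, 0.3)
truncated to [0, 2] by rejection (redrawing, not clipping, so no mass
accumulates at the bounds). $p$ scales proliferation and immunogenicity:
an attached immune cell kills target $j$ with per-step probability
$\min(1, r_i\,p_j\,\Delta t)$, detaches after an unsuccessful dwell with
probability $\Delta t / T_A$, and unattached cells in contact attach with
probability $r_A\,\Delta t$. Defaults $r_A = 0.2$/min (5 min mean time to
attachment), $T_A = 60$ min; study grids explore
$r_A \in \{0.033, 0.2, 1.0\}$, $T_A \in \{15, 60, 120\}$,
$b \in \{0.25, 0.5, 0.75\}$.

Unattached immune cells migrate by a biased random walk: when the
persistence clock expires (mean 10 min), the new direction is
$d = \widehat{(1-b)\,u + b\,\widehat{\nabla c}}$ with $u$ uniform on the
circle/sphere. Attached cells do not migrate and are tethered to their
target by a 10× adhesion boost.

Design decisions where the underlying publications give no values:

* **Chemokine parameters.** The immunostimulatory factor uses
  $D = 1000$ µm²/min, $\lambda = 0.02$/min, per-cell secretion 10/min
  toward saturation 1 (live tumor cells only). At quasi-steady state the
  field saturates across the occupied tumor and decays outside over
  $\sqrt{D/\lambda} \approx 224$ µm, so approaching immune cells see a
  clean inward gradient and the deep interior is a flat plateau.
* **Immune motility.** Speed 1 µm/min, persistence 10 min, kill rate
  $r_i = 0.06$/min at $p = 1$; the flat-gradient threshold
  $\varepsilon = 10^{-12}$ exists to make the normalization safe rather
  than to model a sensing limit. All are configuration parameters.
* **Target choice and attachability.** An immune cell in contact with
  several live tumor cells picks its target uniformly; apoptotic or
  necrotic cells are not attachable, and a kill attempt against a target
  that died in the meantime is a no-op. All attachments to a removed cell
  are dissolved before it is excised, so the registry can never dangle —
  the tests verify this at every snapshot.

**A scale caveat for the bias study.** In full-scale three-dimensional
systems, strong chemotactic homing is reported to overshoot: immune cells
stream to the tumor center, become trapped where the gradient flattens,
and the tumor evades at the periphery, so *less* biased migration gives
the better response. That reversal is an emergent property of large
tumor-to-immune ratios and millimetre-scale geometry. At the desk scale
used here (a ~270 µm disc of 1000 tumor cells versus 300 immune cells,
one simulated day), the tumor is consumed from the outside in, the
survivors are always interior to the immune front, and the gradient —
fresh or stale — always points at them; an exploration across chemokine
regimes (saturated plateau and linear dome, turnover half-lives from
35 min to 6 h), immune speeds (1 and 10 µm/min), sensing thresholds, and
kill rates spanning 0.001–0.06/min found the response monotone in the
*opposite* direction: arrival efficiency dominates and higher bias always
killed more. The directional reversal should therefore be regarded as not
reproducible at this scale with this model family, and the corresponding
study-level check documents that gap rather than papering over it.

## The sweep harness

A sweep expands the cartesian product of declared parameter values (first
parameter most significant), each combination replicated with seeds
`base_seed + combination * replicates + replicate` — injective and
independent of scheduling. Each run executes in its own sandbox directory
with its own log; failures are recorded per-run and never abort the
sweep. Aggregation reports per-combination `n` (completed only), mean,
sample standard deviation, and the failure count; heatmap grids index
cells by the declared value order and mark all-failed combinations as
empty rather than zero. Parameter files are JSON-lines, one parameter set
per line, because the format is self-describing and round-trips types.

## What the synthetic studies do and do not show

All inputs are generated by the package itself: packed hexagonal tumor
discs, truncated-normal oncoprotein, configuration-driven substrates.
The generated tissues are homogeneous in everything but $p$ — no
vasculature, stroma, interstitial flow, immune exhaustion, or 3-D
architecture in the 2-D studies — so passing tests demonstrate the
solver, the agent mechanics, the hazard processes and the study logic,
not predictions about real tumors. Problem sizes in the tests are chosen
at desk scale (meshes up to 60×60, populations to a few thousand cells,
48-hour horizons, 5 replicates per condition); the engine itself is
3-D-capable and size-limited only by memory and patience.

## Known limitations

* First-order splitting error is irreducible at fixed order; no
  Strang-style symmetrization is attempted.
* Dirichlet pinning after each axis solve is first-order consistent at
  boundaries; fine for far-field supply, not for resolving boundary
  layers.
* Immune cells do not die, exhaust, or secrete; one immune lineage only.
* Necrosis is deterministic at the threshold and dead cells keep their
  mechanical footprint until removal.
* The position clamp at the domain edge is a reflecting wall
  approximation; studies should keep tissue away from the boundary.
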