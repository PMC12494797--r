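---
title: "Models and methods behind saxsfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind saxsfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

saxsfit analyses small-angle X-ray scattering (SAXS) curves of proteins in
solution and models them with coarse-grained structures.  It was built
around the kind of problem posed by flexible multi-domain homodimers --
enzymes whose catalytic core forms a well-defined two-fold symmetric dimer
while accessory domains hang off disordered linkers and take up a range of
positions -- but every component is generic.  This vignette documents the
models, the numerical choices, and what the synthetic-data tests do and do
not demonstrate.

## Primary curve analysis

**Guinier fit.**  `guinier_fit()` performs the weighted linear regression
of $\ln I(q)$ on $q^2$; the slope is $-R_g^2/3$ and the intercept
$\ln I(0)$.  Weights are $(I/\sigma)^2$, the propagated precision of
$\ln I$.  The automatic range is the largest low-$q$ window satisfying
$q_{\max} R_g \le 1.3$, found by self-consistent iteration (the window
defines $R_g$, which redefines the window).  The 1.3 limit is the field's
usual validity rule and is configurable.

On curves from genuinely compact particles the Guinier law is only the
leading term, and a fixed $q_{\max}R_g = 1.3$ window has a known
systematic: for an ideal sphere it overestimates $R_g$ by roughly 1.8%
(still 1.1% at a 1.0 limit).  `guinier_fit()` therefore applies a validity
guard by default (`refine_window = TRUE`): it trims the window while the
quadratic term of a weighted fit of $\ln I$ in $q^2$ is statistically
significant ($|t| > 3$).  On noise-free or very precise data the guard
removes the curvature bias (sphere $R_g$ accurate to about 0.2%); on noisy
data the curvature is not resolvable and the full window is kept, which is
exactly the classical behaviour.

**Dimensionless Kratky.**  `kratky_transform()` maps a curve to
$(R_g q,\, (R_g q)^2 I/I(0))$.  Globular particles peak near
$(\sqrt 3, 3/e)$ and decay; chains with flexible or disordered parts level
off at high $q$.  The reported plateau estimate is the mean transformed
value over the top decile of $q$; in the tests a globular sphere gives a
plateau well below 0.5 while a curve with a flat high-$q$ tail gives one
above 1.

**Porod volume.**  The invariant $Q=\int_0^\infty q^2 I\,\mathrm{d}q$ is
assembled from three pieces: the analytic Guinier extension below the
first measured point, the trapezoid rule on the data, and a $K q^{-4}$
Porod tail beyond the last point, with $K$ averaged over the last 15% of
points so that form-factor oscillations in $q^4 I$ do not bias it.  Then
$V_p = 2\pi^2 I(0)/Q$ and the mass estimate is $V_p$ divided by
1600 A$^3$/kDa, the standard protein calibration for apparent Porod
volumes (configurable).

**Correlation volume.**  $V_c = I(0)/\int_0^{q_c} qI\,\mathrm{d}q$ with
$q_c = 0.3$ A$^{-1}$ by default, and mass $= (V_c^2/R_g)/k_c$.  The
default $k_c = 0.10$ was calibrated against this package's own hydrated
coarse-grained forward model on compact globules of 250-700 residues; the
widely used experimental-data calibration 0.1231 is available through the
`kc` argument.  The recalibration was necessary because on exact forward
simulations -- where $I(0)$ obeys the $(\sum b)^2$ sum rule to machine
precision and $V_p$ matches the physical particle volume to a few percent
-- the 0.1231 constant leaves a 13-26% systematic deficit in the
$V_c$-derived mass; the constant absorbs instrument- and
processing-specific effects that a clean simulation does not have.

Both mass estimates assume a compact, globular particle.  For flexible or
transiently oligomerising systems they report the average scattering mass,
which can exceed the sequence mass of the monomeric unit -- that excess is
itself diagnostic of association.

## Indirect Fourier transform

`pr_transform()` represents $p(r)$ on a uniform grid over $[0, D_{\max}]$
with both endpoints pinned to zero, and solves the regularised weighted
least-squares problem for the forward model
$I(q) = 4\pi\int p(r)\,\mathrm{sinc}(qr)\,\mathrm{d}r$ with a
second-difference smoothness penalty (Dirichlet boundaries, so the penalty
matrix is nonsingular).  The penalty weight $\alpha$ is selected on a
30-point log grid by maximising the Gaussian marginal likelihood
("bayes" mode; ties broken toward the smoother solution) or by the
largest $\alpha$ keeping $\chi^2$ within 10% of its minimum ("classic"
mode).  Near-nonnegativity ($p \ge -0.01 \max p$) is enforced by
active-set clamping.  When $D_{\max}$ is not supplied it is scanned over
$[2R_g, 5R_g]$ in 25 steps and chosen by evidence.

Numerical behaviour worth knowing: the evidence-selected $D_{\max}$ of
shapes whose $p(r)$ approaches zero gradually (dumbbells, elongated
particles) is biased a few percent low, because the smoothness prior is
happy to absorb the thin tail; the recovery tests bound this at 10%.  The
$p(r)$ of a model with point-like scatterers also shows a peak near
$r = 0$ from the self-term of the Debye sum -- the physical
pair-distance features sit beyond it.

## The Debye forward model

`coarse_grain()` reduces a structure to one bead per residue at the
heavy-atom centroid with effective scattering length
$b = Z_{\mathrm{res}} - \rho_s V_{\mathrm{res}}$ (residue electron counts
and packing volumes from shipped tables, solvent density
$\rho_s = 0.334$ e/A$^3$) or one bead per heavy atom with atomic displaced
volumes.  Each bead carries a Gaussian form factor
$f(q) = b\exp(-q^2\sigma^2/2)$ whose width is set so the Gaussian's second
moment matches a uniform sphere of the bead's volume,
$\sigma = (3V/4\pi)^{1/3}/\sqrt 5$.

`debye_intensity()` evaluates
$I(q) = \sum_{ij} f_i f_j\,\mathrm{sinc}(q r_{ij})$ either exactly
($O(N^2)$ per $q$ point, in C++) or through per-type-pair distance
histograms.  Histogram bins are half-open with width 0.5 A by default; each bin is
evaluated at its *mean* pair distance with a second-order within-bin
variance correction, so the error is far below 0.1% at
$\Delta r = 0.5$ A over the working $q$ range and decreases monotonically
as $\Delta r \to 0$.

`add_hydration_layer()` models the ordered-water shell: candidate points
are placed at bead radius + 3 A outside every surface bead, points inside
any other bead's exclusion radius are rejected, survivors are thinned to
one bead per 15 A$^2$ of surface, and each shell bead scatters with 10%
of the water electron density over its 45 A$^3$ cell.  All three constants
are configurable; none are critical, but omitting the shell entirely
biases apparent volumes and masses low by 20-30%, which is why
`simulate_curve()` includes it by default when given a structure.

`fit_scale_background()` is the usual two-parameter weighted linear fit;
its reduced $\chi^2$ uses $N - 2$ degrees of freedom.

## Rigid-body refinement

`decompose_bodies()` splits a residue-level bead model into $K$ rigid
bodies from chain/residue-range segment definitions and generates a
connectivity spring at every sequence-adjacent residue pair separated by a
cut: rest length $3.8\,\mathrm{A} \times$ sequence gap, slack 1.5 A per
missing residue.  Cuts are best placed inside linkers; a cut through the
middle of a compact domain is allowed but its spring then starts
stretched.  The penalised objective is

$$\chi^2_{\mathrm{red}} + w_c \sum_{\mathrm{springs}}
\max(0, d - (\mathrm{rest}+\mathrm{slack}))^2 + w_e
\sum_{\mathrm{inter-body\ pairs}} \max(0, r_c - d)^2$$

with $w_c = 10$, $w_e = 1$, clash cutoff $r_c = 3.8$ A between bead
centres; spring-bonded pairs are excluded from the clash sum (bonded
neighbours are connectivity, not sterics).

`rb_refine()` runs independently seeded Metropolis simulated-annealing
trajectories (ten by default; run $r$ uses seed $+\,r-1$, so identical
seeds give bit-identical trajectories).  Each step rotates one random body
about its centroid (normal angle, 8 degrees s.d.) and translates it
(normal, 3 A s.d.), with a geometric temperature schedule from 2.0 to
0.01.  Intra-body Debye terms are invariant under rigid motion and are
cached; only the moved body's cross terms are recomputed, which makes the
per-step cost linear in $K$.  The refinement operates on the bare
coarse-grained model (no hydration shell): rebuilding a conformation-
dependent shell each step would dominate the cost while the shell term is
nearly conformation-independent at these resolutions.

When `fit_oligomer` is set, an unspecific-oligomer structure factor is
re-fitted periodically by grid search plus Nelder-Mead.  The model is the
decoupling approximation for a mass fraction $f$ of scattering units
transiently paired at centre-of-mass distance $d$:

$$I(q) = I_{\mathrm{unit}}(q)\,\bigl(1 + f\,\mathrm{sinc}(qd)\bigr),$$

so forward scattering scales as $1+f$, the first node of the interference
term sits at $q = \pi/d$, and the correction decays to 1 at high $q$.
With $f$ free, a dilute-limit dataset ($f \approx 0$) is degenerate with
small-$d$ pairing absorbed by the scale factor, so the fitted $f$ is only
meaningful when the interference oscillation is resolved.

**What placement recovery can mean.**  A rotationally averaged curve
constrains the *distance distribution* between bodies, not their absolute
frame: global rotations are invisible, quasi-spherical bodies can spin
about their own centroids freely, and a body can slide on shells of
constant distance spectra.  The recovery tests therefore measure body
*placement* -- per-body centroids after superposing the refined model onto
the target -- and use anisotropic test bodies and a perturbation that
changes the inter-body distance (a 40-degree spin plus a 15 A
translation).  Under those conditions ten runs recover placement to about
1 A; demanding per-bead RMSD instead would count the unobservable spins.

## Density-map vs SAXS check

`map_to_dummy_atoms()` turns every voxel at or above a threshold into a
uniform-contrast bead at the voxel centre ($b \propto$ voxel volume,
Gaussian width matched to the cube's second moment, $a/\sqrt{12}$);
over-budget models are decimated by 2x2x2 block merging.
`threshold_scan()` sweeps 50 thresholds between the 50th and 99.9th
percentile of positive map values, fits each dummy model's Debye curve to
the data, and reports the full $\chi^2$ profile with its minimiser.  Bead
count is non-increasing in threshold by construction.  On a map rasterised
from the very model whose curve is the data, the best $\chi^2$ is below
0.05 for fixtures rasterised at 3 A voxels with a 2.5 A Gaussian splat;
coarser rasterisation degrades the round trip smoothly.

## Structure geometry

SASA uses the Shrake-Rupley construction with 960 golden-spiral points per
heavy atom and a 1.4 A probe.  `buried_interface_area()` reports both
conventions explicitly because both are in common use: the PISA-style
interface area $(S_A + S_B - S_{AB})/2$ as the headline number, and the
unhalved buried area with its percentage of the free surface
$S_A + S_B$.  `find_c2_axis()` extracts the rotation operator of the
least-squares chain-onto-chain superposition; the axis direction is the
unit eigenvector, the angle comes from the trace, and the axis point
solves $(I-R)p = t_\perp$ in the least-squares sense (at exactly 180
degrees the axis sign is immaterial and the canonical choice is the
largest-component-positive one).  `align_axes()` then supports the hybrid-
assembly construction: making the two-fold axis of one sub-assembly
colinear and co-located with another's, with the residual spin about the
shared axis as an explicit parameter.

## Synthetic data: what it emulates, and what it does not

The generators (`make_model()`, `simulate_curve()`, `make_toy_map()`)
emulate a laboratory-source solution-SAXS experiment on a flexible
multi-domain homodimer: $q$ from 0.005 to 0.35 A$^{-1}$, relative errors
$\sigma(q) = \sigma_0 I(q)(1 + (q/q_0)^a)$ with $\sigma_0 = 0.01$,
$q_0 = 0.1$ A$^{-1}$, $a = 2$ (the error-growth shape of a pinhole
camera), an optional fraction of unspecific dimers-of-dimers, and default
dimer geometry of 350 + 150 + 210 residues per chain joined by 13-residue
linkers -- two chains related by an exact two-fold.

Two generator realism decisions matter for the analysis results and are
deliberate:

* **Packing.**  Pseudo-domain residues sit on a jittered cubic lattice at
  135 A$^3$ per residue (0.5 A jitter), not on independent uniform draws.
  Proteins are packed at near-uniform density; independent draws would add
  Poisson density fluctuations that inflate the Porod invariant and
  deflate $V_p$ by over 30%, which no real protein shows.  The jitter only
  exists to break lattice regularity, whose artefacts would appear far
  beyond the working $q$ range anyway.
* **Linkers.**  Inter-domain linkers are extended strands at 3.0 A per
  residue with 0.3 A jitter, so sequence-adjacent residues stay within a
  peptide spring's rest length and freshly decomposed models start with
  zero connectivity penalty.

What passing these tests shows: the estimators are unbiased and correctly
calibrated *for data whose forward model is known exactly*.  What they do
not show: robustness to buffer-subtraction errors, beam smearing,
inter-particle interference at high concentration, radiation damage, or
atomic-level hydration structure -- none of which the generator attempts
to produce.

## Problem sizes used in the test and acceptance runs

The shipped suites use spheres of 3000-5000 beads, globules of 250-700
residues, two-body refinement harnesses of 180 residues with 10 annealing
runs of 500 steps, oligomer harnesses of 368 residues with 3 runs, and
30-level map scans on ~30-voxel-cubed maps.  These sizes put every
recovery criterion comfortably inside its tolerance while a full run of
the suite stays in the minutes range; all of them scale up linearly (or
quadratically, for exact Debye sums) if heavier validation is wanted.

## Known limitations

* Intensities are on the forward model's electron-unit scale; absolute
  calibration (water reference) is the instrument's job and only enters
  through the units flag on curves.
* The oligomer structure factor is the decoupling approximation with a
  single interference distance; polydisperse association needs a mixture
  model the package does not provide.
* The IFT reports a single regularised solution per mode; it does not
  propagate $D_{\max}$ uncertainty into the quoted moments.
* No smearing/desmearing, no SEC-SAXS frame handling, no WAXS regime
  beyond $q \approx 0.35$ A$^{-1}$ at residue-level coarse graining.
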