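---
title: "Stretching ensembles and the Legendre-Fenchel transform"
author: "lfstretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stretching ensembles and the Legendre-Fenchel transform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfstretch)
```

## The problem

A single polymer pulled by its ends is a textbook small system: its
thermodynamics depends on *how* it is controlled.  Held at fixed end-to-end
distance $x$ (the **isometric** ensemble), the fluctuating observable is the
constraint force and the governing potential is the Helmholtz stretching
energy $F(T, N, x)$.  Pulled with a constant force $f$ (the **isotensional**
ensemble), the extension fluctuates and the governing potential is the Gibbs
stretching energy $G(T, N, f)$.  For a long chain the two descriptions are
equivalent and $G$ is the Legendre transform of $F$.  For a *short* chain
they are not: $F(x)$ can develop non-convex stretches (the mean force
*decreases* with extension over an interval), and then no Legendre transform
connects the two ensembles.

The package implements the resolution: the exact finite-size relation

$$e^{-\beta G(f)} \;=\; \beta f \int_0^{x_{max}} e^{-\beta\,[F(x) - f x]}\,dx,$$

and its saddle-point (large-system) limit, the **Legendre-Fenchel
transform**

$$-G_{LF}(f) \;=\; \max_x\,[\,f x - F(x)\,],$$

which, unlike the pointwise Legendre construction $F(x) - F'(x)\,x$, is
defined for arbitrary $F$ and always yields a convex conjugate.  A
non-convex anomaly of $F$ maps to a force at which $-G_{LF}$ has a *kink*
(a jump of the maximizer), dual to the Maxwell equal-area construction on
$F'$.  Conjugating twice gives the biconjugate $F^{**}$, the convex envelope
of $F$: ensemble inequivalence is precisely $F^{**} \ne F$.

Everything needed to demonstrate this sits in four layers:

1. **Chain model** -- a united-atom style bead-spring chain with Morse
   bonds, harmonic bends and cosine-series torsions, with analytic forces.
2. **Sampler** -- BAOAB Langevin dynamics in either ensemble, with
   simulated-annealing equilibration and replicated, block-averaged sweeps.
3. **Free energies** -- thermodynamic integration
   ($\Delta F = \int \bar f\,dx$, $\Delta G = -\int \bar x\,df$), response
   functions, shape-preserving interpolation.
4. **Transforms and oracles** -- Legendre, Legendre-Fenchel, exact integral
   transform, biconjugate; plus brute-force quadrature references for
   dimers/trimers, an analytic non-convex toy generator, and an independent
   convex-hull construction.

## Units and the model

Internal units are kcal/mol, Angstrom, fs, K and g/mol, with
$k_B = 0.0019872041$ kcal/(mol K) (`kB_kcal`).  The chain potential is

$$V = \sum_{bonds} D\,(1 - e^{-\alpha(r - r_0)})^2
    + \tfrac12 \sum_{bends} K_b\,(\theta - \theta_0)^2
    + \sum_{dihedrals}\sum_{c=1}^{C} K^t_c \cos^{c-1}\phi .$$

Non-bonded interactions are deliberately absent: the chain lives in an
implicit theta solvent, and the anomalies of interest are torsional, not
excluded-volume, effects.  The Morse bond saturates at the dissociation
energy $D$, so bonds can break; a sweep point where any bond passed
$\alpha(r - r_0) > 5$ (99.99% of the Morse plateau) is *flagged*, because
beyond that the extension is unbounded and thermodynamic integration through
the point is meaningless.

A helper `alpha_from_stiffness(K_s, D)` converts a harmonic stretching
constant to the Morse range parameter via $\alpha = \sqrt{K_s/(2D)}$, the
relation that equates the curvature of the two wells at $r_0$
($U''(r_0) = 2D\alpha^2$).  A square-root-free rendering of this relation
circulates in the literature; it is dimensionally inconsistent, and the
square-root form is used here.

### The default chain

The default `force_field(N)` is a homogeneous chain: mass 14 g/mol per
bead, $D = 80$ kcal/mol, $\alpha = 2$ A$^{-1}$, $r_0 = 1.5$ A,
$K_b = 60$ kcal/mol/rad$^2$, $\theta_0 = 1.9$ rad.  These magnitudes are
typical of united-atom backbone force fields (C-C-like bonds of ~1.5 A,
bending stiffness of tens of kcal/mol/rad^2) without reproducing any
specific chemistry.

The torsion series is the one genuinely *designed* parameter, because the
ensemble-inequivalence phenomenology lives in it.  The default
$K^t = (2.0, -2.7, -1.8, 6.0)$ kcal/mol gives, as a function of the
dihedral $\phi$,

* a global minimum at $\phi = \pi$ (*trans*, $-3.1$ kcal/mol relative to
  the constant term),
* local minima near $\phi = \pm 60^\circ$ (*gauche*, about 4 kcal/mol above
  trans),
* barriers of $\approx 1.5$ kcal/mol above gauche.

A cubic cosine series ($C = 4$) is the shortest series that admits such a
bistable profile; note that not every positive-looking coefficient set
does -- e.g. $(1, 2, -0.5, 3)$ has a derivative with no interior zero in
$\cos\phi$ and is single-welled.  The default barrier height is a
compromise fixed once: high enough that gauche/trans interconversion is a
rare event on the fs scale (giving a genuinely multi-well $F(x)$ for an
8-bead chain), low enough (2-3 $k_BT$ at 300 K) that desk-scale sampling
with annealing and replicas still equilibrates across it.

## The sampler

The integrator is the BAOAB splitting of underdamped Langevin dynamics
(half-kick, half-drift, exact Ornstein-Uhlenbeck step, half-drift,
half-kick).  With the friction set to zero the O-step is the identity and
the scheme is plain velocity Verlet, which is how the energy-conservation
test pins the integrator's symplectic behaviour.  Defaults: $dt = 0.5$ fs
against a stiffest-bond period of $2\pi/\omega \approx 45$ fs
($\omega = \sqrt{2D\alpha^2 \cdot 4.184\times 10^{-4}/m}$), damping time
100 fs, 300 K.

* **Isometric mode** pins bead 1 at the origin and bead $N$ at $(0,0,x)$;
  pinned beads are excluded from integration and thermostat, which realizes
  the fixed end-to-end vector exactly (and, as a by-product, a fixed centre
  of mass).  The recorded observable is the symmetric axial estimator
  $\tfrac12 (F_1 - F_N)\cdot\hat z$ of the internal forces on the pinned
  beads; its time average equals $dF/dx$ -- positive for a chain stretched
  beyond its preferred length.  (The opposite sign convention would make
  thermodynamic integration return $-\Delta F$; the dimer, where the force
  is deterministic and analytic, fixes the choice unambiguously.)
* **Isotensional mode** applies $-f\hat z$ to bead 1 and $+f\hat z$ to bead
  $N$ (no net force, so the centre of mass only diffuses) and records the
  $z$-projection of $r_N - r_1$.  The projection, not the magnitude, is the
  observable conjugate to $f$; the two differ by $O(k_BT/f)$.

Every sweep point runs an annealing schedule (default: half the
equilibration budget at $1.5\,T$, half at $T$), then production with the
observable sampled every 10 steps.  Standard errors come from block
averaging with 20 blocks within a replica and, when $R \ge 2$ replicas are
run, from the between-replica scatter ($s/\sqrt R$), which is the more
honest estimate for multi-well systems.  Seeds derive deterministically
from the base seed via `derive_seed(seed, grid_index, replica_index)`, so a
sweep is reproducible bit-for-bit while replicas stay decorrelated.

### What the sampler's accuracy is checked against

For $N \le 3$ the configurational partition function is computable by
quadrature: the dimer in closed form, the trimer by 2D adaptive quadrature
over the middle bead in cylindrical coordinates (azimuthal symmetry).  Two
isotensional references must be distinguished:

* the *scalar* partition function $\Delta(f) = \beta f \int Z(x)
  e^{\beta f x} dx$ -- the object the transform toolkit is built on; and
* the *orientational* average $\bar z(f)$ under the full 3D measure
  $d^3x\, Z(|x|)\, e^{\beta f z}$, which is what a 3D constant-force
  simulation actually measures.  Reducing the angular integral analytically
  leaves a 1D integral over $x$ (`oracle_xbar_isotensional`).

The distinction is orientational entropy, of order $k_BT \ln(\beta f x)$:
negligible for long stiff chains at strong force, but *dominant* for a
dimer at small $\beta f x$ -- a dimer under weak force points every which
way and its mean projection follows the rigid-rod (Langevin-function) law,
not the scalar convention.  Sampler tests therefore compare against the
orientational oracle, while transform-consistency tests compare the two
routes that share the scalar convention (direct $\Delta$ quadrature vs the
exact integral transform over tabulated $F$), which agree to $10^{-6}$
relative.  Momentum and $\hbar/N!$ prefactors are dropped everywhere: they
are independent of $x$ and $f$ and cancel in every difference the package
reports.

## Free energies and transforms: numerical choices

* **Thermodynamic integration** uses the composite trapezoid on the sampled
  grid, with no re-fitting; the error bars propagate through the trapezoid
  weights, $\mathrm{Var}(\Delta F) = \sum_i w_i^2\,s_i^2$.  Trapezoid
  convergence is second order, verified by grid halving.
* **Interpolation** is monotone Fritsch-Carlson piecewise cubic
  (`splinefun(method = "monoH.FC")`): exact at knots, overshoot-free, and
  monotone wherever the data are -- the property that matters when
  inverting force-elongation curves near kinks.
* **Derivatives** use the three-point non-uniform stencils; second
  derivatives drop one point at each end rather than inventing one-sided
  curvature.
* **The Legendre-Fenchel maximisation** takes the exact discrete maximum
  over the tabulated $x$ grid.  That value is convex in $f$ to machine
  precision, being a maximum of affine functions -- which is why the
  package refines only the *maximizer* (by a quadratic through the three
  bracketing points, sharpening kink locations from $O(\Delta x)$ to
  $O(\Delta x^2)$) and never the value, where refinement would trade exact
  convexity for a few parts in $10^6$ of accuracy.
* **Kinks** are detected as maximizer jumps exceeding 2% of the $x$ range
  between adjacent grid forces (separating true Maxwell gaps from
  refinement noise), then *refined* through the common-tangent identity
  $f^* = [F(x_2) - F(x_1)]/(x_2 - x_1)$, which locates the kink force far
  more precisely than the $f$-grid spacing.
* **The exact transform** factors the integrand maximum out of the
  exponential ($\beta[F - fx]$ spans hundreds of $k_BT$) and reinstates it
  in the log; the quadrature is adaptive Gauss-Kronrod.  The $\beta f$
  prefactor contributes $-k_BT\ln(\beta f)$: it diverges logarithmically as
  $f \to 0^+$, so the transform requires $f > 0$; the divergence is
  subdominant at any practical force and drops out of curvatures.
* **The biconjugate** conjugates twice, but on the second pass uses the
  exact breakpoint forces of the piecewise-linear first conjugate (the
  secant slopes between consecutive active maximizers).  The double
  discrete conjugate then coincides with the lower convex hull of the
  tabulated points to machine precision, which is what the independent
  monotone-chain hull construction verifies.  The internal force grid for
  this purpose spans *all* slopes of $F$, including negative ones;
  the default grid of `legendre_fenchel` itself spans
  $[10^{-6}, \max F']$ with 200 points, the physically loaded range.
* **Degenerate geometry**: when a bend angle is within $10^{-6}$ rad of
  $0$ or $\pi$ the dihedral is undefined; its force contribution is dropped
  there (a measure-zero set never hit by equilibrium sampling).

## The demonstration system

The end-to-end demonstration (`run_pipeline`, and the ninth acceptance
check) uses the default 8-bead chain: 5 dihedrals, an all-trans planar
length of $\approx 8.5$ A.  The isometric grid spans 3.5-9.5 A in 0.5 A
steps; the isotensional grid spans 0.25-12 kcal/mol/A.  Desk-scale
sampling -- $2\times10^4$ annealing plus $6\times10^4$ production steps and
6 replicas per point, about half a minute on one CPU for both sweeps -- is
a deliberate reduction of production-scale molecular dynamics (hundreds of
independent samples, ns trajectories); the phenomenology survives the
reduction because the chain is small and its barriers were chosen to be
crossable.

What the reduced experiment shows, reproducibly across seeds:

* the isometric force-elongation curve has statistically significant
  negative-slope intervals (the response $1/\kappa(x) = \partial^2 F /
  \partial x^2$ goes negative) in the torsional-unfolding window;
* the isotensional extension-force curve is monotone within noise, as
  $\kappa(f) = -\partial^2 G/\partial f^2 \ge 0$ requires;
* mapped onto a common axis through the isotensional force-elongation
  relation and anchored at the first shared point, the Legendre-Fenchel
  transform of the integrated $F$ tracks the integrated $G$ to about 1-1.5
  kcal/mol, the exact integral transform similarly, while the pointwise
  Legendre construction $\bar f x - F$ is off by tens of kcal/mol --
  a factor of 20-40 worse.

The residual 1-1.5 kcal/mol is not sampling noise: it is the orientational
entropy discussed above plus the finite-$\beta$ saddle-point correction
($O(k_BT \ln\beta f)$), both of which shrink with system size and force.
The acceptance suite checks the saddle-point mechanism separately by
scaling $\beta$ tenfold and hundredfold on a fixed toy curve and watching
the gap contract monotonically.

## What the synthetic references do and do not show

The toy free-energy generator ($\tfrac12 kx^2$ plus Gaussian bumps, with
analytic derivatives) stands in for the sampled curves wherever an *exact*
answer is needed: conjugate convexity, envelope identity, Maxwell duality,
kink counting.  It reproduces the *mathematical* structure of small-chain
free energies -- smooth non-convex anomalies of tunable strength -- but
none of their physics (no entropy, no temperature, no noise), so passing
those checks validates the transform machinery, not the sampler.  The
dimer/trimer quadrature oracles close that gap at small $N$; nothing at
desk scale validates the sampler at large $N$ beyond the equipartition,
determinism and symplecticity invariants, and that is the main known
limitation.  Other limitations worth stating plainly:

* mean forces carry an $O(dt^2)$ discretization bias (about $10^{-2}$
  kcal/mol/A at the default $dt$), visible only where standard errors are
  tighter than that;
* multi-well systems near a transition can trap replicas; the
  between-replica error bars are honest about it, but a grid point sitting
  exactly on a first-order-like transition will show large bars rather
  than a converged mean;
* the quadrature oracles stop at $N = 3$ (the curse of dimensionality);
* the transform toolkit assumes $F$ tabulated on a bounded grid with the
  chain unbroken; flagged sweep points are refused, not patched.

## Reproducing the numbers

`scripts/acceptance.R --seed S --out out.json` reruns the whole chain of
evidence -- gradient check, sampler-vs-quadrature comparisons, the three-way
Gibbs consistency, convexity/envelope/Maxwell/saddle-point properties, and
the 8-bead demonstration -- and writes each quantity with the problem size
it was computed at.  All randomness derives from the single seed; the run
takes well under a minute on one CPU.
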