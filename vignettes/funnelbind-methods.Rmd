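---
title: "Free energy methods for ligand unbinding: models, protocols and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free energy methods for ligand unbinding: models, protocols and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnelbind)
```

# What this package computes

Kinase inhibitors such as crizotinib bind in a pocket gated by the
phosphate-binding (P-)loop, and resistance mutations can act not by
breaking contacts but by changing the conformational free energy of that
loop — weakening binding and, independently, lowering the dissociation
barrier that sets the drug's residence time. Quantifying this requires
the absolute binding free energy and the unbinding barrier along a
physical pathway, which is what the enhanced-sampling machinery in this
package delivers:

* **well-tempered metadynamics with a funnel restraint**, producing a
  two-dimensional free energy surface (FES) over the ligand-pocket
  separation and a loop-conformation coordinate, a minimum-free-energy
  unbinding profile, the dissociation barrier $\Delta G_\mathrm{off}$,
  and a standard-state corrected binding free energy;
* **umbrella sampling** unbiased by the weighted histogram analysis
  method (WHAM) and **adaptive biasing force** (ABF) estimation, driving
  the staged restraint protocol of the Woo–Roux absolute binding free
  energy decomposition (conformational, orientational and translational
  restraints, the bulk surface term $S^*$, the separation integral
  $I^*$, the binding constant $K_\mathrm{bind}$);
* a **reproduction mode** that reassembles the published crizotinib–ROS1
  decomposition table from its printed components.

The samplers run on analytic toy potentials constructed to carry the
same features as the kinase landscape — a bound well, an induced-fit
conformational switch, an optional barrier at intermediate separation,
a flat bulk — so that every estimate can be checked against dense
quadrature of the defining integrals. All energies are in kcal/mol,
lengths in Å, temperatures in K; the working temperature is 310 K, with
$k_B = 0.0019872041$ kcal/mol/K and the standard-state volume
$1/C^\circ = 1661\,$Å$^3$.

# The models

## Overdamped Langevin dynamics

All sampling uses the Euler–Maruyama update
$x \leftarrow x - \nabla U\,\Delta t/\gamma + \mathcal N(0,\,2 k_B T\,
\Delta t/\gamma)$ per coordinate. This is the desk-scale stand-in for
solvated molecular dynamics: it has the correct stationary distribution
$e^{-\beta U}$ (verified by equipartition and total-variation tests in
the suite) and no inertial dynamics, which are irrelevant for
free-energy estimates. Two numerical constraints matter:

* **stability** — a harmonic term of constant $k$ requires
  $k\,\Delta t/\gamma < 2$; the stiffest terms here are the 100
  kcal/mol/Å$^2$ funnel and domain walls, which bounds the usable
  timestep at a given friction;
* **diffusion** — the coordinate diffusion constant is
  $D = k_B T/\gamma$, and since angular coordinates are carried in
  degrees, they would diffuse two orders of magnitude too slowly at the
  default friction. The angular ABF stages therefore run at
  $\gamma = 0.05$/ps with $\Delta t = 0.002$ ps, the funnel
  metadynamics at $\gamma = 0.1$/ps with $\Delta t = 0.001$ ps (fast
  mixing across the funnel disk, walls stable), and the umbrella stages
  at $\gamma = 1$/ps with $\Delta t = 0.005$ ps. These are tunable in
  the run configuration.

## Toy potentials

Potentials are sums of analytic terms (compact-support quartic bumps,
harmonics, switched and fading harmonics, one-sided walls, Gaussians, a
log-sin Jacobian weight), evaluated with analytic gradients in C++ and
cross-checked in the test suite against an independent R implementation
and against central differences. Compact-support bumps make the
advertised features exact: a landscape built with `depth = 5` and
`barrier_height = 12` has a conformation-minimized profile whose
minimum is exactly $-5$ and whose maximum-minus-minimum is exactly 12,
and its bulk is exactly flat.

Three generators matter:

* `make_binding_landscape()` — the 2-D "separation × loop conformation"
  landscape. The `barrier` kind couples the conformational coordinate
  $c$ to the separation $r$ through a quintic switch (bound reference
  $c = 1$ Å$^2$, unbound $c = 4$ Å$^2$, switching over $r = 4$–8 Å), so
  that crossing the saddle requires a conformational displacement — the
  induced-fit topology of a wild-type-like kinase. The `flat` kind
  decouples $c$: the mutant-like topology.
* `make_funnel_system()` — a point ligand in 3-D plus a conformational
  coordinate: an isotropic compact well of depth 8 kcal/mol
  (half-width 2.2 Å) around a site on the unbinding X-axis, with the
  same induced-fit switch on $c$. The potential is deliberately
  isotropic about the site so that the radial umbrella route and the
  quadrature oracle integrate clean spherical shells; the walls that
  close the funnel column (behind the site and at 24 Å) belong to the
  metadynamics *stage*, exactly as the protein and the funnel restraint
  do in the all-atom setup.
* `make_ray_system()` — the ligand position in generalized coordinates
  $(r, \theta, \Theta)$ (separation in Å, translational angles in
  degrees, $\Theta$ periodic) plus $c$, with the solid-angle Jacobian
  $-k_BT\log\sin\theta$ folded into the effective potential so that
  flat-measure Langevin sampling reproduces the spherical measure. The
  bound well sits at $r_0 = 5$ Å — the separation at which the
  fictitious anchor point of the restraint geometry is placed — with a
  fading harmonic angular confinement around
  $(\theta, \Theta) = (90^\circ, 0^\circ)$. The transverse Jacobian
  scale is fixed at the bulk reference $r^* = 24$ Å, making the
  Woo–Roux identity below exact for this system.

What these toys *do not* emulate: explicit solvent and friction
anisotropy, multiple metastable loop states, rugged landscapes,
orientational degrees of freedom of a structured ligand (the toy ligand
is a point, so the three orientational restraint components are exactly
zero and are exercised through their analytic operations instead), and
any force-field realism. Passing tests therefore demonstrate estimator
correctness — that the samplers and the assembly algebra recover known
answers — not that a particular kinase number is right.

## Collective variables

The CV library implements the observables the kinase study biases or
analyzes: mass-weighted centre-of-mass distance, interior angle,
signed dihedral (IUPAC convention: cis $=0$, trans $=180^\circ$; the
source study does not state one, so it is fixed and documented here),
MSD/RMSD without superposition (toy frames are generated pre-aligned —
a deliberate simplification of all-atom practice), the path-progress
variable, the funnel radial distance and population histograms with
circular binning for dihedrals.

The path-progress variable is
$s(R) = \sum_i m_i e^{-\lambda\,\mathrm{MSD}(R, f_i)} / \sum_i
e^{-\lambda\,\mathrm{MSD}(R, f_i)}$ with milestones
$m_i = (i-1)\,\delta$ for $P$ reference frames at consecutive-frame MSD
$\delta$ (defaults $P = 7$, $\delta = 1$ Å$^2$, so the variable runs
from 0 to 6 Å$^2$). The smoothing constant defaults to
$\lambda = 3/\delta$: with the common $2.3/\delta$ heuristic the
endpoint milestones are biased inward by $0.09\,\delta$ (the neighbour
weight $e^{-2.3}$ is not negligible), while $3/\delta$ reproduces every
milestone at its own frame to within 5% of the spacing. $\lambda$
remains user-settable.

# Well-tempered funnel metadynamics

Hills of initial height $\omega$ are deposited every $\tau$ ps at the
current CV position with the well-tempered scaling
$h = \omega\,e^{-V(s)/(k_B\Delta T)}$; the defaults are the published
protocol, $\omega = 1$ kcal/mol at one hill per ps, $\Delta T = 3100$ K
(a bias factor $\Delta T/T = 10$ at 310 K — the alternative
$(T+\Delta T)/T$ convention is *not* used, and a bias factor supplied in
a configuration is resolved as $\Delta T = \gamma\,T$). The FES
estimator is $F(s) = -\frac{T+\Delta T}{\Delta T} V(s)$ (factor 1.1 at
the defaults), using the bias grid averaged over the final 70% of the
deposition schedule, which suppresses the slow oscillation of the
instantaneous estimator.

Numerical choices: the bias and its gradient are accumulated on the
declared CV grid (defaults 400 bins over 0–24 Å and 350 bins for the
conformational coordinate) with a 6-$\sigma$ cutoff per hill and
(bi)linear interpolation during dynamics; depositions falling outside
the grid are clamped to the edge and counted. Soft walls at the grid
edges of the conformational CV prevent the accumulating bias from
pushing the walker off its grid — without them, edge pile-up visibly
corrupts the surface.

Hill widths should resolve the features of the system at hand. The
published $(0.4\ \text{Å}, 0.05\ \text{Å}^2)$ are the `wt_schedule()`
defaults and are used verbatim on the 1-D benchmark; for the funnel toy
the conformational width is set to $0.1$ Å$^2$, about a third of the
toy's conformational well width, after comparison with the quadrature
FES showed that a much narrower kernel inflates the column-minimum noise
of the minimum-free-energy path.

The funnel is a one-sided harmonic cylinder wall (defaults 15 Å radius,
100 kcal/mol/Å$^2$) around the unbinding axis. The 1-D profile is built
by taking, at each separation bin, the minimum of the FES over the
conformational bins ("connecting the lowest-energy bins along the
separation"), and

$$\Delta G_\mathrm{bind\text{-}Meta} = -D \;-\; k_BT
\log\!\big(\pi R_\mathrm{cyl}^2\, C^\circ\big),$$

where $D$ is the profile depth (bulk mean minus site minimum). The sign
of the correction deserves a note: the depth measured inside a funnel
already contains the disk entropy $-k_BT\log(\pi R^2)$ of the unbound
ligand, so the correction must *remove* it while referencing the bulk to
the standard concentration — only then is the corrected value
independent of the funnel radius, which the acceptance suite checks
across $R \in \{10, 15, 20\}$ Å. At $R = 15$ Å and 310 K the correction
term equals $+0.526$ kcal/mol. A caveat inherent to the published
method: using the profile *depth* rather than the site integral
$\int_\mathrm{site} e^{-\beta\Delta F(x)}\,dx$ implicitly assumes an
effective site width of 1 Å along the separation; the funnel toy's site
width is close to that, and the residual offset (about $-0.13$ kcal/mol
by quadrature) is well inside the 0.5 kcal/mol cross-method tolerance.

Convergence is diagnosed the way the kinase study does: by counting
completed unbind–rebind cycles of the separation CV with hysteresis
thresholds (defaults 8 and 18 Å; a run reporting fewer than 3 cycles is
flagged unconverged but its outputs are still written).

# Umbrella sampling, WHAM and ABF

Umbrella windows add $(k_i/2)(\xi-\xi_i^\mathrm{ref})^2$; the default
separation ladder is the published one (41 windows of 0.5 Å over 5–25 Å
at $k = 5$ kcal/mol/Å$^2$; the source text also says "40 windows", and
41 is the arithmetically consistent reading of inclusive 0.5-Å spacing).
Windows are seeded from a metadynamics trajectory by nearest CV value
(ties to the earliest frame) or analytically at their centres. The
first half of every window is discarded as burn-in, matching the
published use of the last half of each window.

WHAM iterates the window offsets and the unbiased density on shared
bins to a $10^{-7}$ kcal/mol tolerance with deterministic $f_i = 0$
initialization; the PMF is $-k_BT\log\rho$, min-aligned. In the
single-window zero-bias limit the estimator reduces *exactly* to direct
Boltzmann inversion of the histogram, and it is invariant under window
permutation — both are tested. Ladders whose adjacent windows do not
overlap are rejected as unstitchable. Optional error bars come from
block averaging over 4 blocks per window.

ABF bins a single coordinate CV (default bin 0.2 CV units, one window,
as published), accumulates the instantaneous collective force
$-\partial U/\partial\xi$, and applies minus the ramped running mean
(full cancellation after 200 samples per bin), yielding near-uniform
sampling; the PMF is minus the integral of the mean force by the
trapezoid rule, with an end-to-end closure check for periodic CVs. At
toy scale the CVs are literal coordinates, so the force projection is
direct and the extended-Lagrangian machinery used for curvilinear CVs
in all-atom codes is out of scope by design.

# The Woo–Roux assembly

Each restraint free energy comes from Boltzmann-factor integration over
the staged PMF,
$\Delta G = -k_BT\log\frac{\int e^{-\beta(w+u)}d\xi}
{\int e^{-\beta w}d\xi}$, the bulk orientational term from direct
quadrature of the isotropic measure, and

$$K_\mathrm{bind} = S^*\, I^*\,
\exp\!\Big(-\beta\big[(\Delta G_c^\mathrm{bulk} +
\Delta G_o^\mathrm{bulk}) - (\Delta G_c^\mathrm{site} +
\Delta G_o^{\alpha} + \Delta G_o^{\beta} + \Delta G_o^{\gamma} +
\Delta G_t^{\theta} + \Delta G_t^{\Theta})\big]\Big),
\qquad
\Delta G_\mathrm{bind\text{-}US} = -k_BT\log\!\big(K_\mathrm{bind}
C^\circ\big)$$

with $S^* = r^{*2}\!\int\! e^{-\beta u_t(\theta,\Theta)}\sin\theta\,
d\theta\,d\Theta$ (solid-angle measure; $4\pi r^{*2}$ with no
restraints) and $I^* = \int_\mathrm{site} e^{-\beta(W(r)-W_\mathrm{bulk})}dr$.
This algebra reassembles the published decomposition exactly: feeding
the printed components of both ROS1 systems reproduces
$K_\mathrm{bind} = 3.85\times10^{13}$ and $6.64\times10^{8}$ Å$^3$ and
$\Delta G = -14.70$ and $-7.95$ kcal/mol to the printed precision,
which fixes the sign placement of the site and bulk terms (the equation
bodies are images in the source article, so internal consistency is the
authority).

Two conventions needed a decision. First, the $r^2$ Jacobian at the
bulk reference is placed in $S^*$, and $I^*$ references the PMF either
to a flat bulk plateau (with a 0.05 kcal/mol/Å slope check over the
last 2 Å) or to the point value $W(r^*)$. The point reference is the
exact choice when the separation CV is a 3-D distance whose raw PMF
retains the $+2k_BT\log r$ shell term — then the $r^{*2}$ in $S^*$
cancels the bulk Jacobian identically, which is how the radial route on
the funnel toy is assembled. Second, the difference column of the
reproduction table follows the published layout row by row: restraint
rows as mutant-minus-wild-type, energy rows (separation PMF,
$\Delta G_\mathrm{bind}$, $\Delta G_\mathrm{off}$) as
wild-type-minus-mutant.

The staged protocol (`us_route()`) follows the published order:
conformational umbrella sampling in the bound site and in bulk, then
ABF on the translational angles with the previous restraints imposed,
then the separation ladder under all restraints. Three practical points
are worth knowing. During the site conformational stage, windows at
large conformational displacement flatten the toy's unbinding barrier,
so a soft wall at the outer site boundary pins the ensemble to the site
region — this wall *is* the site definition of the decomposition.
The conformational ladders span $-1$ to 3 (site) and $-1$ to 5 Å$^2$
(bulk) in 0.5-Å$^2$ windows at $k = 2$: the published RMSD ladders
start at zero because an RMSD cannot go negative, while the toy
coordinate can, and the restrained Boltzmann weight must decay inside
the sampled range (the published $k = 0.01$ kcal/mol/Å$^2$ for these
windows is ambiguous as printed and is treated as fully configurable).
The radial ladder includes two extra windows at 0.15 and 0.3 Å because
the $d^2$ shell factor otherwise leaves the flat bottom of the well
uncovered and $I^*$ loses about 10% of its mass. ABF windows cover
$\theta\in[40^\circ,140^\circ]$ and $\Theta\in[-70^\circ,70^\circ]$ —
outside these ranges the site confinement exceeds 10 kcal/mol and
contributes nothing to either integral of the restraint free energy.

Residence time enters through
$t_a/t_b = e^{\beta(\Delta G_\mathrm{off,a}-\Delta G_\mathrm{off,b})}$;
the published barriers of 12.10 and 5.53 kcal/mol imply a ratio of
$4.3\times10^4$ at 310 K.

# Validation strategy and problem sizes

Every estimator is validated against an independent reference:

* closed forms (equipartition variance, Gaussian restraint integrals,
  the $4\pi r^{*2}$ and Laplace limits of $S^*$, square-well $I^*$,
  single-hill FES);
* dense quadrature of the toy's defining configuration integrals,
  computed from an independent R implementation of the toy energies
  (itself cross-checked against the C terms to machine precision). On
  the ray system the staged quadrature PMFs, pushed through the full
  decomposition, reproduce the directly integrated binding constant to
  better than $10^{-5}$ relative — the Woo–Roux identity is exact for
  that geometry, so the residual is pure discretization;
* cross-estimator agreement: WHAM vs the analytic potential
  (0.15 kcal/mol RMS at 21 windows of $10^5$ steps), ABF vs WHAM
  (0.2 kcal/mol RMS), funnel metadynamics vs the radial umbrella route
  on the same Cartesian system (0.5 kcal/mol), and funnel-radius
  invariance of the corrected binding free energy (0.5 kcal/mol across
  10–20 Å).

The problem sizes used by the default configurations — $10^6$ steps for
the 1-D benchmark surface, $2\times10^7$ steps per funnel metadynamics
run, $6\times10^5$ steps per umbrella window, $2\times10^6$ steps per
ABF window — were chosen so that each estimator's statistical error is
comfortably below the tolerance it is tested at (for example, the
funnel depth estimator scatters by about $\pm0.12$ kcal/mol per run at
this length, and the cross-method and radius-invariance checks average
two to three independent runs, mirroring replicate practice). The whole
validation suite completes in a few minutes on one core.

# Known limitations

* The minimum-free-energy-path depth carries the $k_BT\log(\ell/1\,
  \text{Å})$ ambiguity discussed above; for sites much wider or
  narrower than 1 Å along the separation, prefer the $I^*$-based route.
* The well-tempered estimator's site-vs-bulk level fluctuates slowly
  when the unbound state is a large entropic region (the funnel disk);
  averaging the bias grid and running replicates are the provided
  mitigations.
* ABF assumes the CV is a coordinate; WHAM is 1-D; the toys have a
  single conformational mode and a point ligand; none of this is meant
  to extrapolate to all-atom accuracy claims.

# Reproducing the published table

```{r}
reproduce_table1()
```

The same computation, together with the toy-system diagnostics, is what
`scripts/acceptance.R` re-runs from scratch.
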