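---
title: "dnadyn: model, integrator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dnadyn: model, integrator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`dnadyn` simulates structured DNA assemblies (DNA origami and related
constructs) as a coarse-grained finite-element system embedded in a viscous
ionic solvent. Every base pair is a rigid body — a node with three
translational and three rotational degrees of freedom, carrying the summed
nucleotide mass of both strands, the principal inertia of a 1 nm x 0.34 nm
cylinder, a hydrodynamic radius, and an effective charge. Connections between
nodes are typed finite elements:

* **step** — intrahelical base-pair steps. The relative rigid-body geometry
  of the two frames is measured by the mid-step-triad (CEHS/3DNA) parameters
  (shift, slide, rise in nm; tilt, roll, twist in degrees), and the element
  energy is the quadratic form $E = \tfrac12\,\Delta q^\top K\,\Delta q$
  about an intrinsic geometry, with twist deviations wrapped to
  $(-180^\circ, 180^\circ]$.
* **crossover** — interhelical strand exchanges, same functional form with a
  softer stiffness table and a stored frame-flip convention so that the
  decomposition stays regular between antiparallel helices.
* **ssdna** — single-stranded connections, isotropic entropic springs with
  $k = 3 k_B T / (2 L_p L_c)$, persistence length $L_p = 1$ nm and contour
  length $L_c$ from the nucleotide count.
* **stacking** — breakable blunt-end contacts governed by the Morse potential
  $\Pi(r) = \varepsilon\,[1 - e^{-a (r - r_0)}]^2 - \varepsilon$ with
  defaults $\varepsilon = 42.79$ pN nm, $a = 2.668$ nm$^{-1}$,
  $r_0 = 0.3742$ nm (fitted from a potential of mean force of stacking
  distances; see below). A bond is reported *stacked* below the half-depth
  point $r_0 + \ln 2 / a \approx 0.634$ nm.

Units are pN, nm, ns throughout; the derived mass unit is
1 pN ns$^2$/nm $= 10^{-21}$ kg, and $k_B T = 4.1419$ pN nm at 300 K.

Forces on the two nodes of an elastic element are
$-J^\top K \Delta q$ where $J$ is the Jacobian of the six step parameters
with respect to the twelve nodal degrees of freedom (translations, and
multiplicative lab-frame rotation increments). The displacement rows of $J$
are analytic (they are the mid-triad axes); the angular rows are central
finite differences with step $10^{-6}$. The contract that matters — and that
the test suite enforces on batteries of random configurations — is that the
assembled force equals the negative gradient of the total energy to relative
$10^{-5}$ and that any isolated structure carries zero net force and torque.

## Elastic parameter table

The sequence-averaged defaults live in one editable table
(`default_parameter_table()`), so refined sequence-dependent tables can be
dropped in without touching code:

| quantity | value | origin |
|---|---|---|
| rise / twist | 0.34 nm / 34.3 deg | canonical B-DNA |
| stretch stiffness | 1100 pN / 0.34 nm = 3235 pN/nm | stretch modulus ~1100 pN |
| shear stiffness | = stretch | isotropic simplification |
| tilt/roll stiffness | $k_BT \cdot 50\,\mathrm{nm} / 0.34\,\mathrm{nm}$ = 609 pN nm/rad$^2$ | persistence length 50 nm |
| twist stiffness | $k_BT \cdot 100 / 0.34$ = 1218 pN nm/rad$^2$ | torsional persistence length 100 nm |
| crossover table | all six entries / 10 | junction flexibility (below) |

Softening *all* crossover components (not only the rotations) is a
deliberate choice. A crossover joins nodes in neighboring helices about
2.5 nm apart; with full translational stiffness the lever arm converts
3235 pN/nm into an effective rotational stiffness of order
$2\times10^4$ pN nm/rad$^2$ — stiffer than any intrahelical mode, which is
implausible for the demonstrably flexible junction region and would also put
the 5 ps operating point outside the integrator's stable region.

## Electrostatics

Electrostatics is reduced to a screened-Coulomb pair interaction between
nodes,
$E(r) = q_{\mathrm{eff}}^2\, l_B\, k_B T\, e^{-\kappa r} / r$, with
counterion-condensation effective charge $q_{\mathrm{eff}} = 2e \times 0.24$
per base pair, Bjerrum length $l_B = 0.714$ nm, cutoff $3\kappa^{-1}$, and
Debye length $\kappa^{-1} = 0.304/\sqrt{I}$ nm with
$I = c_{\mathrm{Na}} + 3 c_{\mathrm{Mg}}$ (mol/l, Cl$^-$ balanced). Ion
changes act only through $\kappa$; the Morse parameters are
salt-independent.

Excluded pairs are *bonded neighborhoods*: all node pairs within element-graph
distance two (plus, for the switch builder, the seam blunt-end pairs). One
bond more than the literal element pairs is excluded because point charges at
sub-nanometre bonded separations are outside the validity of the reduction —
they add spurious stiffness to geometry the elastic elements already govern,
and occasionally produce hard-core encounters (the evaluator treats
$r < 0.1$ nm as a hard error).

## Hydrodynamics

All nodes are identical spheres of radius $\sigma = 1.1$ nm in water at
$\eta = 0.89$ pN ns/nm$^2$ (890 uN s/m$^2$). The mobility operator is the
generalized Rotne-Prager-Yamakawa tensor over all 6N degrees of freedom —
translation-translation (Oseen plus finite-size correction),
rotation-rotation, and the antisymmetric translation-rotation coupling, with
the regularized overlapping-sphere expressions below $r = 2\sigma$
(continuous at the boundary, positive definite for every configuration,
including overlaps). The friction matrix is its inverse,
$Z = \Xi^{-1}$, computed by symmetric factorization; the Cholesky factor of
$Z$ also generates the correlated random forces. Assembly and inversion are
dense ($N \lesssim 10^4$); the friction matrix is refreshed every 1000 steps
by default (configurable, 1000-10000 is the sensible range — configurations
decorrelate over many steps at this damping).

Single-sphere identities anchor the implementation: translational friction
$6\pi\eta\sigma = 18.45$ pN ns/nm, rotational $8\pi\eta\sigma^3 = 29.77$
pN nm ns, and free diffusion $D_t = k_BT/6\pi\eta\sigma = 0.2245$ nm$^2$/ns,
$D_r = k_BT/8\pi\eta\sigma^3 = 0.139$ rad$^2$/ns, which the sampled dynamics
must reproduce (and does, within statistical error, in the test battery).

# The integrator

The Langevin equation $M \dot V = F - Z V + R$,
$\langle R^t R^\tau \rangle = 2 k_B T Z \delta(t-\tau)$, is integrated with
a Gronbech-Jensen–Farago (GJF) scheme extended by half-time stepping and
Simpson's rule for the internal force. With
$S = (M + \tfrac{\Delta t}{2} Z)^{-1}$ and discrete noise
$\beta \sim \mathcal N(0,\, 2 k_B T \Delta t\, Z)$:

$$\Delta x = \Delta t\, S\,\big(M v + \tfrac{\Delta t}{2} \bar f + \tfrac12 \beta\big),
\qquad
v' = v + M^{-1}\big(\Delta t\, \bar f - Z \Delta x + \beta\big),$$

where $\bar f = \tfrac16\,[f(x) + 4 f(x + \Delta x/2) + f(x + \Delta x)]$ is
made self-consistent with $\Delta x$ by fixed-point iteration (default: one
refinement, i.e. three force evaluations per step; `force_iterations` in the
protocol). $Z \Delta x$ costs no matrix product thanks to
$Z S = \tfrac{2}{\Delta t}(I - M S)$.

Why this form: for a force that is constant over the step, $\bar f = f$ and
the update *is* the published GJF scheme. Plain GJF, however, is
unconditionally unstable once $\omega \Delta t > 2$ for a harmonic mode of
frequency $\omega$ — no amount of friction rescues it (we verified the
amplification eigenvalues exceed 1 for all friction strengths). A base-pair
step's stretch stiffness with base-pair masses puts
$\omega \Delta t \approx 18$ at the 5 ps operating point, so *any* scheme
that reduces to explicit GJF for linear forces cannot run DNA elasticity at
5 ps. With the self-consistent Simpson average the linear-force limit is the
trapezoidal (A-stable) discretization instead: stiff stretch and twist modes
are integrated stably far beyond $\omega \Delta t = 2$, while the
configurational statistics of harmonic modes remain exact at stationarity —
the suite checks $\langle x^2 \rangle = k_BT/k$ to better than 2% at both
5 ps and 20 ps, and equipartition of a thermalized duplex to 10%. Velocities
follow Maxwell-Boltzmann initialization with variance $k_BT/M_{ii}$.

The fixed-point contraction factor is roughly $\Delta t\,k/\zeta_{\rm eff}$
per mode; with the crossover table above it stays well below 1 for every
structure the builders emit. The NaN guard aborts on non-finite states, and
a force-evaluation failure mid-run checkpoints the trajectory at the last
valid frame instead of discarding it.

# Stacking model and PMF machinery

The stacking element applies central forces $-\mathrm d\Pi/\mathrm dr$
between its two node reference points. Its parameters are obtained by the
same route a practitioner would take from simulation data: collect stacking
distances, build the distribution $g(r)$ of the *one-dimensional* reaction
coordinate (no $4\pi r^2$ Jacobian — the well depth is fitted directly to
the free-energy profile), invert to
$\Pi_{\rm PMF}(r) = -k_BT \log g(r)$ with empty bins masked rather than
zero-filled, and fit $\Pi(r) + C$ by weighted least squares
(`minpack.lm::nlsLM`, weights = bin counts). Self-consistency checks:
noise-free tables recover the generating parameters to relative $10^{-6}$;
Boltzmann-inversion of $10^6$ samples drawn from the Morse density
reproduces the potential with RMS error below 0.5 pN nm; a single bond
sampled by the integrator at 300 K matches the Boltzmann distance
distribution with Kolmogorov-Smirnov distance below 0.02. The per-bond free
energy of 42.2 pN nm corresponds to about 6.07 kcal/mol
(`pnnm_to_kcal_per_mol()`); the fitted well depth (42.79 pN nm) and the free
energy (42.2 pN nm) are distinct quantities and are never conflated.

# The synthetic switch and what it does (not) show

The ion-responsive demonstration (`switch_reconfiguration_demo()`) uses a
desk-scale synthetic structure, not a published origami design: two rigid
arms, each a 2x5 block of ten 10-bp helices, meeting head-on at a blunt-end
seam. Two Morse bonds bridge the hinge-distal blunt pairs at the
equilibrium distance (the closed state); two short single-stranded springs
on the innermost row form the hinge; and two slack 10-nt single-stranded
"retaining loops" run across the distal pairs, bounding how far the arms
can swing and biasing open arms back toward the seam — the role the
scaffold routing plays in real reconfigurable designs. Crossover elements
at the hinge would leave ~23 pN nm/rad$^2$ of rotational stiffness per
element — enough to suppress the tens-of-degrees opening that defines the
behavior — so the hinge is single-stranded, as the scaffold connections of
real switches are.

The design was sized from an explicit force budget computed with the
package itself (static evaluations, before any dynamics): the net screened
repulsion pushing the arms apart in the closed state is 16 pN at 25 mM
Mg$^{2+}$, 126 pN at 2 mM and about 170 pN at 0.25 mM, against a static
holding capacity of the seam (two bonds at the maximum Morse force
$\varepsilon a/2 = 57$ pN each, plus the soft springs) of roughly 120 pN.
High salt is therefore deeply closed. The low-salt operating point must be
chosen with care: near the capacity (1-2 mM) the seam only wedges partially
— single bonds break and re-stack alternately because the repulsion decays
as the gap opens while the Morse tail still captures at 1.5-2 nm. At
0.25 mM the repulsion exceeds the capacity *throughout* the release path,
so unstacking is deterministic on the segment timescale: the seam separates
to ~5 nm, the arms wedge open about the hinge to 25-40 degrees, and the
retaining loops hold them there. Restoring 25 mM removes the drive; the
loops pull the arms back within a few hundred ns until both bonds
re-stack. A real origami switch presents well over an order of magnitude
more charged contacts across its seam, which is why its experimental
operating window sits at 5-25 mM; the desk-scale schedule
(25 / 0.25 / 25 mM for 60 / 250 / 390 ns — the low-salt dwell a similar
fraction of the cycle as in origami-scale reconfiguration protocols —
5 ps steps, friction refreshed
every 5000 steps) is the same mechanism scaled to a ~200-node structure
that cycles in minutes on one core.

The opening angle is measured between rigid-body arm axes: each arm's
as-built geometry is superposed (Kabsch) onto the frame and its reference
axis carried along, so internal bending does not masquerade as opening.
Even so, the closed-state angle has a floor of ~5 degrees — thermal bending
of 3.4 nm arms at a 50 nm persistence length is irreducible — so the
"baseline" of the reconfiguration summary is the mean angle over the first
high-salt segment.

What passing this demonstration shows: the coupled machinery — screening
schedule, seam repulsion, breakable bonds, entropic tethers,
hydrodynamically correlated arm motion — produces the qualitative
reconfiguration pattern: release and opening only in the low-salt segment,
an opening angle several times the closed baseline, delayed
unstacking/restacking relative to the instantaneous electrostatic energy
steps, and a fully re-stacked final state. What it does not show:
quantitative agreement with any real switch design (16 bonds, thousands of
base pairs, sequence-dependent stiffness), kinetics on the experimental
microsecond-to-second scale, or the validity of the electrostatic reduction
at sub-nanometre separations or sub-mM ionic strength.

# Numerical choices and degenerate inputs

* Step decomposition: anti-parallel z axes are a hard error (the hinge is
  undefined); crossovers avoid the degeneracy by the stored frame flip.
* Angle wrapping at $\pm180^\circ$ applies to all rotational deviations, so
  crossover intrinsic twists near the branch cut cost no spurious energy.
* Static minimization: L-BFGS-B on a local chart re-centered between sweeps
  (rotations update multiplicatively), default tolerance $10^{-3}$ pN on the
  force max-norm; non-convergence within the sweep budget reports the final
  residual. Two mutually repelling disconnected bodies are the canonical
  non-convergent input.
* Mobility: equal radii are required (the superposition model assumes
  identical spheres); coincident nodes are an error; an operator with
  condition number beyond $10^{12}$ is rejected rather than inverted.
* PCA removes rigid-body motion by mass-weighted superposition *before*
  forming the fluctuation matrix; near-zero-variance modes are flagged, not
  inverted. NMA differentiates the total internal force numerically
  (central differences, step $10^{-5}$), demands an equilibrium within
  $10^{-2}$ pN, and labels modes below $10^{-3}$ times the smallest internal
  frequency as rigid-body (a free structure has exactly six).
* Generalized correlations use the Kraskov k-nearest-neighbor mutual
  information estimator with $k = 6$ (O($n^2$), adequate at map sizes used
  here), mapped through $r = \sqrt{1 - e^{-2I/3}}$; a Gaussian-copula
  estimator is available for small samples. The Pearson convention is the
  trace of the 3-D displacement cross-covariance over the RMSF product.
* The electrostatic neighbor list uses a 1 nm skin and rebuilds on
  half-skin displacement or a schedule switch.
* Trajectory containers serialize natively (`saveRDS`) with XYZ and
  pseudo-atom PDB text exporters; structures use a versioned JSON schema.

# Known limitations

Sequence-dependent stiffness is not modeled (one averaged table); caDNAno
import is a simplified dialect (no insertions/deletions); multi-arm ssDNA
vertices are crude isotropic springs; electrostatics is a pair-screened
reduction, not Poisson-Boltzmann; stacking strength is sequence- and
salt-independent; base-pair breakage at crossovers is not modeled. The
mobility model assumes one hydrodynamic radius for all nodes and no external
flow or walls.
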