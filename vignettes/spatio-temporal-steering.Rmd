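---
title: "Spatio-temporal steering in open quantum networks: models, programs and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal steering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the engineering behind `stsnet`:
the state space and master equation, the measurement and assemblage
conventions, the three semidefinite programs and the solver that backs
them, the synthetic-data generators used by the test-suite, and the
numerical choices and known limitations a user should be aware of.

## The physical model

### State space: the vacuum-plus-single-excitation sector

A network of $N$ two-level sites conserving excitation number is, for at
most one excitation, fully described on the $(N{+}1)$-dimensional span of
the vacuum $|\mathrm{vac}\rangle$ and the singly excited states
$|e_n\rangle$ (plus $|e_R\rangle$ when a reaction center is attached).
Every operator the package uses — the excitation-hopping Hamiltonian,
$\sigma_z$ dephasers, the reaction-center sink, and the local measurement
operators of the shipped scenarios — maps this sector to itself, so
working in it is *exact* for everything the package does, while keeping
the FMO model at dimension 9 instead of $2^7$. The test-suite verifies
sector equivalence against brute-force propagation in the full
$2^3$ tensor space for three-site networks to $10^{-8}$ per matrix
element.

One caveat is inherited from the restriction: a measurement element that
couples $|g\rangle$ and $|e\rangle$ on node $A$ also couples singly to
doubly excited states when *other* sites carry population. The package
compresses such operators into the sector (exact whenever the initial
state has no excited population outside the measured node, which holds
for every shipped scenario) and warns when the compression would be an
approximation.

### Master equation and conventions

Dynamics follow the Haken–Strobl/Lindblad form
$$\dot\rho = -\tfrac{i}{\hbar}[H,\rho] + \sum_k \gamma_k\,
\bigl(2A_k\rho A_k^\dagger - A_k^\dagger A_k\rho - \rho A_k^\dagger A_k\bigr),$$
deliberately **without** the conventional factor $\tfrac12$ in the
dissipator. Two consequences worth remembering:

* a $\sigma_z$ dephaser of rate $\gamma$ decays single-qubit coherences
  at $4\gamma$ and site–site coherences in the network at $8\gamma$;
  relative to the "orthodox" site-projector convention
  ($A_n = |e_n\rangle\langle e_n|$ in GKSL form) the rates differ by a
  factor 8, and `dephasing_rate_convert()` translates between the two;
* the sink $s = \sigma_+^{(R)}\sigma_-^{(3)}$ at rate $\Gamma$ drains the
  site-3 population at $2\Gamma$.

**Units.** Chain quantities are dimensionless (couplings in $J$, time in
$1/J$). FMO energies and rates are entered in cm$^{-1}$ and converted to
angular frequencies via $2\pi c = 0.18837\ \mathrm{ps}^{-1}/\mathrm{cm}^{-1}$;
time is in ps. With this convention the default rates
($\Gamma = 5.3\ \mathrm{cm}^{-1}$, $\gamma_{dp} = 7.7\ \mathrm{cm}^{-1}$ at
15 K) give a sink $1/e$ time of $\sim 0.5$ ps and a site–site coherence
$1/e$ time of $\sim 86$ fs — the accepted $\sim$1 ps transfer /
$\sim$100 fs dephasing picture. Whether *rates* (as opposed to energies)
should carry the $2\pi$ is a genuine convention ambiguity; the package
defaults to converting both and exposes `convert_rates = FALSE` in
`fmo_model()` to explore the alternative. The consequences for the FMO
steering curves are discussed under *Limitations*.

The vacuum-sector energy offset is set to zero. The induced relative
phase between sectors acts as one fixed unitary on the target qubit, and
both steering measures are invariant under exactly that transformation
(an invariance the test-suite checks), so the choice is harmless.

**Integrator.** The vectorized master equation (a $d^2$-dimensional
linear complex ODE driven by the precomputed Liouvillian) is integrated
with `deSolve::zvode` at `rtol = 1e-10`, `atol = 1e-12` (configurable).
These tight defaults keep the assemblages clean enough that the
semidefinite programs see constraint violations only at the
$10^{-10}$ level.

## Assemblages

Measuring node $A$ at time 0 with POVM element $F_{a|x}$, evolving for
$t$, and reducing to node $B$ yields the subnormalized members
$$\sigma_{a|x}(t) = \mathrm{tr}_A\{\Lambda_t[(\sqrt{F_{a|x}}\otimes 1)\,
\rho_0\,(\sqrt{F_{a|x}}\otimes 1)]\},\qquad p(a|x) = \mathrm{tr}\,\sigma_{a|x}(t).$$
Square roots are Hermitian spectral square roots with eigenvalue clipping
at zero (exact for the shipped projective sets). The default measurement
set is Pauli $X, Y, Z$ with outcome $+$ the $+1$ eigenvector and the
$\sigma_z$ $+1$ eigenstate identified with the *excited* state — a sign
convention that must be fixed once and is fixed here.

Two reductions recover the familiar special cases, and both are verified
member-for-member in the tests:

* **EPR reduction** — identity channel, bipartite $\rho_0$: for the
  Werner family the assemblage is
  $(\mathbb{1} \pm p\,\sigma_w^{T})/4$ in closed form;
* **temporal reduction** — one system measured and then evolved: the
  members equal $p(a|x)$ times the evolved conditional states.

A structural point: spatio-temporal assemblages generically **signal**
across settings ($\sum_a \sigma_{a|x}$ depends on $x$), because the
measurement disturbance itself propagates through the channel. This is
the phenomenon being quantified, not an error, so `validate_assemblage()`
reports the signalling magnitude without rejecting. The hidden-state
model is automatically non-signalling, so signalling assemblages simply
come out steerable.

## The three programs

All three optimize over the finite set of deterministic response
strategies $\lambda$ (one outcome per setting, $o^m$ of them, enumeration
capped at 4096); probabilistic strategies are convex mixtures whose
weights are absorbed into the positive-semidefinite variables
$\rho_\lambda$, so nothing is lost.

* **Feasibility** (is there a hidden-state model?) runs in two stages:
  a least-squares consistency check of the linear member equalities
  (which already fails for signalling assemblages), then a phase-I
  program minimizing the uniform negativity $t$ with
  $\rho_\lambda + t\mathbb{1} \succeq 0$; the model exists iff
  $t^\ast \le 10^{-6}$. Since $\mathrm{tr}\sum_\lambda \rho_\lambda = 1$
  is implied, $t^\ast > -1$ always, so the scalar variable is kept
  bounded by construction.
* **Weight**: $\min 1 - \mathrm{tr}\sum_\lambda\rho_\lambda$ subject to
  $\sigma_{a|x} - \sum_\lambda d_\lambda(a|x)\rho_\lambda \succeq 0$.
* **Robustness**: $\min \mathrm{tr}\sum_\lambda\rho_\lambda - 1$ subject
  to $\sum_\lambda d_\lambda(a|x)\rho_\lambda - \sigma_{a|x} \succeq 0$.
  The optimal noise assemblage is recovered from the certificate as
  $\tau_{a|x} = (\sum_\lambda d_\lambda(a|x)\rho_\lambda -
  \sigma_{a|x})/\alpha$ rather than carried as extra decision variables —
  algebraically identical, fewer unknowns.

Lagrangian duality gives independently coded second formulations
(`sts_weight_dual()`, `sts_robustness_dual()`); strong duality holds, and
the test-suite uses agreement to $10^{-6}$ as a correctness oracle,
alongside two closed-form anchors: the Werner threshold $1/\sqrt3$
recovered by bisection of the feasibility program, and the maximal Werner
robustness $2-\sqrt3$ from the octant hidden-state construction (the
optimal ensemble sits on the $(\pm1,\pm1,\pm1)/\sqrt3$ Bloch directions).

### The solver

No semidefinite-programming backend is assumed; the package includes a
primal–dual interior-point method specialized to what these programs are:
block-diagonal complex-Hermitian cones with $1\times1$ and $2\times2$
blocks and a few dozen linear constraints. It is an infeasible-start
path-following iteration with the HKM search direction, Mehrotra
predictor–corrector, per-block Schur-complement assembly via
$\mathrm{tr}(A_i X A_j Z^{-1}) = \mathrm{vec}(A_i)^\ast(Z^{-T}\!\otimes\!X)\,
\mathrm{vec}(A_j)$, eigenvalue-clamped inverses near the cone boundary,
and best-iterate tracking. Solves take milliseconds and report status,
duality gap and residuals; scans log them per time point so inaccurate
solves are visible rather than silent.

Numerical policy around the programs:

* members are Hermitized and eigenvalue-clipped at $-10^{-10}$ on entry,
  absorbing integrator noise (violations beyond that raise an error);
* members of trace below $10^{-11}$ (zero-probability outcomes, e.g. the
  impossible outcome of a deterministic measurement at $t=0$) are
  eliminated *exactly*: in the weight program they force their
  $\rho_\lambda$ to zero, in the robustness program their constraints are
  vacuous. Zero-probability outcomes are thus fully legal inputs, and the
  cone-boundary degeneracy they would inject into an interior-point
  iteration is removed without changing the optimum;
* "steerable" means a measure exceeds $10^{-6}$, and the feasibility cut
  on $t^\ast$ uses the same $10^{-6}$: for unsteerable models built from
  *pure* hidden states the optimum sits exactly on the cone boundary, so
  demanding much more than solver accuracy would misclassify;
* weakly feasible instances (members of reduced rank, ubiquitous in
  dynamics-generated assemblages) cannot reach the nominal $10^{-9}$
  accuracy; the solver then returns its best iterate, labelled
  `"inaccurate"` when residuals are below $10^{-6}$ and the gap below
  $5\times10^{-5}$. Spot checks against the dual formulation show such
  values are in practice accurate to better than $10^{-6}$.

## Synthetic generators and what the tests do (and do not) show

The generators make every component testable with no external data:

* `unsteerable_fixture(seed, m, o, n_lambda)` draws a hidden-state model
  (random weights, response tables, random Bloch-ball states) and
  assembles its members — unsteerable *by construction*, fully
  reproducible from the seed;
* `werner_scenario(p)` provides a calibrated steerable/unsteerable family
  with a known threshold;
* `discard_channel_scenario()` models a completely broken link (the
  channel installs a fixed target state), for which both measures vanish
  identically.

These generators probe the programs, the reductions and the dynamics
exactly where independent answers exist. What they do not emulate:
realistic spectral densities, non-Markovian memory, static disorder, or
measurement imperfections — passing tests say the implemented model is
solved correctly, not that the Markovian $\sigma_z$-dephasing model is an
adequate description of a real pigment–protein complex.

## Shipped scenarios and default grids

* **Three-qubit chain** — symmetric couplings $J_{12}=J_{23}=J$, qubit 1
  excited initially, measured with Pauli $X,Y,Z$; qubit 2 dephasing at
  $\gamma$; target qubit 3. The dephasing jump operator is taken as
  $\sigma_z^{(2)}$ in the same prefactor-free convention as the FMO
  dephasers, which is the main reason chain steering curves should be
  read qualitatively. Scans default to $t \in [0, 10]/J$ with 100 points.
* **FMO monomer** — the encoded 7-site Hamiltonian (diagonal 215, 220, 0,
  125, 450, 330, 280 cm$^{-1}$; strongest couplings $-104.1$ between
  sites 1–2 and $89.7$ between 5–6), sink $\Gamma = 5.3$ cm$^{-1}$ from
  site 3, seven $\sigma_z$ dephasers at
  $\gamma_{dp}(T) = (7.7/15)\,T$ cm$^{-1}$ (a one-point linear anchor; no
  spectral-density machinery is implemented). Initial state: site 6
  maximally mixed, everything else ground; site 6 measured. Steering
  scans default to $t \in [0, 1]$ ps at 60 points — steering under the
  default conventions lives and dies within the first $\sim$0.1 ps, and
  the acceptance computations use this grid as a deliberate budget/
  resolution compromise (121 points over $[0, 0.3]$ ps were used to
  confirm the reported peak orderings are not grid artifacts).

## Limitations

* **FMO site orderings are convention-sensitive.** Under the default
  conventions the strongest steering from site 6 goes to site 5 (via the
  89.7 cm$^{-1}$ coupling) and the second strongest to site 7, which the
  test-suite asserts and confirms. Two further properties one might
  expect from the 6→5→4→7 transfer pathway — the site-7 peak arriving
  *later* than the site-5 peak, and site-7 steering surviving longest —
  do **not** hold under the default $2\pi c$ rate conversion: the
  delayed pathway contribution is suppressed because site–site coherence
  decays on $\sim$86 fs while the pathway needs $\sim$200 fs. With
  rates converted by $c$ only (dephasing weaker by $2\pi$ relative to
  the coherent couplings) the delayed site-7 peak appears clearly
  (0.027 at 0.20 ps against 0.079 at 0.075 ps for site 5) but the
  longest-survival ordering remains marginal. The corresponding
  assertions are kept in the acceptance suite as written expectations and
  currently fail under the defaults; the underlying coherence transport
  (vac–site-7 coherence peaking with a clear delay at $\sim$0.18 ps) was
  verified directly, so this is a property of the model conventions, not
  a solver artifact.
* Exact steering-curve *values* for the FMO model should not be compared
  across codes without aligning three conventions first: the dissipator
  prefactor, the rate unit conversion, and the dephasing operator
  ($\sigma_z$ vs projector).
* The eighth FMO site, trimer-level structure, non-Markovian treatments
  and finite-temperature detailed balance are out of scope; fluorescence
  relaxation ($\sim$1 ns) is neglected as far slower than transfer.
* Measurement optimization (beyond the fixed Pauli set) and multipartite
  steering are not implemented.
* The strategy enumeration grows as $o^m$; the default cap (4096) covers
  the shipped scenarios with large margin but rules out many-setting
  studies.
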