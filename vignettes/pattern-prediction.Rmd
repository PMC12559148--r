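---
title: "Predicting cell-fate patterns from network spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cell-fate patterns from network spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synchropat)
```

This vignette is the package's own account of the model it implements,
the numerical choices behind it, and what its tests do and do not
demonstrate.

## The model and its assumptions

A developing tissue is treated as a *regular network* of identical
cells: a directed multigraph in which every cell receives the same
number of input arrows (the valence $\nu$), with no self-arrows.  Every
cell carries the same state vector $x_i \in \mathbb{R}^s$ of chemical
concentrations and obeys the same smooth rate law

$$\dot{x}_i \;=\; f\!\left(x_i,\; \overline{x}_i,\; \lambda\right),$$

where $\overline{x}_i$ is the arrow-count-weighted **mean** of the
input cells' states (cells average their neighbours' signals; the
worked linear fixture instead uses the raw weighted sum, and the
package supports both conventions) and $\lambda$ is a bifurcation
parameter assumed to vary much more slowly than the cell states.  The
underlying biological assumptions: cells are well-mixed compartments,
concentrations change smoothly, the cells start in a nearly identical
state with identical external inputs, and the tissue is a sufficiently
uniform lattice.  These make the system *admissible* for the network,
which has two structural consequences the package leans on throughout:

1. **Flow invariance.**  For every *balanced* coloring of the cells
   (same-colored cells receive identically colored input multisets),
   the *polysynchrony subspace* where same-colored cells agree is
   invariant under the flow of every admissible system.  Patterns of
   synchrony are therefore robust objects attached to the network, not
   to any particular rate law.
2. **Spectral factorization.**  At a synchronous point the Jacobian is
   $I \otimes Q + A \otimes R$ with $Q = D_u f$ (internal dynamics) and
   $R$ the per-arrow coupling derivative, so its spectrum is the union
   of the spectra of the reduced matrices $Q + \mu_j R$ over the
   adjacency eigenvalues $\mu_j$, with eigenvectors
   $u \otimes v_j$.

A pattern can only form when the synchronous branch loses stability;
the adjacency eigenspaces whose reduced matrices carry the critical
eigenvalues form the **critical pattern space**, and its eigenvector is
the spatial shape of the emerging pattern.  The first crossing is taken
as the preferred pattern: any later crossing happens while an unstable
direction already exists, so it cannot yield a stable branch, and the
quasistatic ramp parks the tissue on the first stable patterned branch.

For strongly connected networks the largest adjacency eigenvalue equals
the valence, is simple, and has the all-ones eigenvector
(Perron-Frobenius), so "the pattern at $\mu_k$" is exactly the fully
synchronous direction; and a zero-trace adjacency (no self-arrows)
forces an eigenvalue with negative real part, so $\mu_1 < 0 < \mu_k$.
The classifiers *refuse* networks with self-arrows, disconnected
networks, and non-real adjacency spectra rather than guessing: the
rule-table enumeration is only proved for real spectra.

## The classifiers

**One species.**  The real parts of the reduced eigenvalues lie on the
line $Q + u R$ over the real parts $u$ of the adjacency eigenvalues.
A line that was below zero and touches it can only do so at the left
end ($\mu_1$, slope $R < 0$), the right end ($\mu_k$, $R > 0$), or
everywhere at once ($R = 0$).  Hence the trichotomy implemented in
`classify_1d()`: negative coupling means a synchrony-breaking pattern
shaped by the smallest adjacency eigenvalue; positive coupling a
synchrony-preserving crossing; zero coupling is fully degenerate.

**Two species, singular coupling.**  When $\det R = 0$ (one signalling
channel between cells, true of standard lateral-inhibition models) both
the trace and the determinant of $Q + \mu R$ are *linear* in $\mu$:

$$p_1(\mu) = \operatorname{tr} Q + \mu \operatorname{tr} R,
\qquad
p_2(\mu) = \det Q + \mu B,
\qquad
B = \operatorname{tr}Q\operatorname{tr}R - \operatorname{tr}(QR).$$

Stability before the crossing pins $p_1 \le 0$ and $p_2 \ge 0$ at every
$\mu_i$, so each line's root set over the eigenvalues is structurally
one of *empty*, *only $\mu_1$*, *only $\mu_k$*, or *all* (the line is
identically zero).  The fifteen nonempty combinations are the
package's rule table (`classify_2d_detR0()`); rows 1-4 are the
nondegenerate cases (one line fires at one extreme eigenvalue), rows
5-15 require coincidences and are flagged `degenerate`.  A trace-only
root is an imaginary pair (Hopf-type crossing with frequency
$\omega = \sqrt{\det}$), a determinant-only root a real crossing, a
joint root a double real crossing.  Two sufficient nondegeneracy
certificates are evaluated (`ndg_conditions()`):
$\det Q > |\nu B|$ keeps the determinant line positive at every
eigenvalue (criticality must be an imaginary pair), and
$\operatorname{tr} Q < -|\nu \operatorname{tr} R|$ keeps the trace line
negative (criticality must be a single real crossing); both use the
valence being the spectral radius.  When neither inequality holds the
classifier certifies nondegeneracy by directly evaluating both lines at
every eigenvalue and says so in its notes.

**$\det R \le 0$.**  Then $p_2$ is a concave quadratic, nonnegative at
every eigenvalue just before the crossing, so it cannot first vanish at
an interior eigenvalue; criticality is confined to
$\{\mu_1, \mu_k\}$.  Contrapositive, used by
`infer_from_pattern_space()`: an observed pattern identified with an
interior eigenspace forces $\det R > 0$.

## Sign inference

`infer_signs()` makes the classification qualitative.  Entries of $Q$
and $R$ live in $\{+,-,0,?\}$ with interval semantics ($+$ means any
positive number).  Every assignment of $+/-/0$ to the unknown entries
is enumerated and filtered by (a) stability of the synchronous branch
($Q<0$ for one species, $\operatorname{tr} Q<0$ for two) and (b) the
observed outcome's necessary condition in the nondegenerate rule rows:
synchronous oscillation needs $\operatorname{tr} R > 0$, an oscillating
pattern $\operatorname{tr} R < 0$, a steady pattern $B > 0$.  A sum of
mixed signs is treated as satisfiable (it can take any value), so a
condition only eliminates an assignment when it is *forced* to fail.
What survives is intersected: entry signs constant across all survivors
are reported as forced, and pairs whose product sign is constant are
reported as relations ("$d\kappa > 0$", "signs of $b$ and $\kappa$
differ").  Degenerate rule rows are excluded from the filter by
default - coincident degeneracies are not expected in biological
systems - because including them (option `include_degenerate`) makes
almost nothing deducible.  The provenance strings name the rule that
eliminated each possibility.

## The lateral-inhibition fixture

The bundled `"collier"` model is a minimal two-species
Delta-Notch-type cell, chosen to realize the qualitative sign structure
of lateral inhibition rather than any particular published parameter
set (the theory depends only on the signs):

$$\dot D = \frac{1}{1 + (N/K_N)^h} - D,
\qquad
\dot N = \lambda\,\frac{(\bar D/K_D)^h}{1 + (\bar D/K_D)^h} - N,$$

with $\bar D$ the neighbour-averaged Delta, Hill exponent $h = 2$, and
thresholds $K_N = K_D = 0.5$ on the scale of the uncoupled equilibrium
($D \to 1$, $N \to 0$ at $\lambda = 0$).  Its linearization is
upper-triangular $Q$ with negative diagonal and negative
Delta-from-Notch entry, and $R$ has a single positive
Notch-from-neighbour-Delta entry, so $\det R = 0$,
$\operatorname{tr} R = 0$ and $B > 0$: rule row 1, a synchrony-breaking
steady crossing at the smallest adjacency eigenvalue.  The symmetric
threshold choice makes the crossing land at clean values: on the
six-cell line ($\mu_1/\nu = -1$) the synchronous state passes through
$(D, N) = (0.5, 0.5)$ at $\lambda_0 = 1$ exactly, and on the
$16\times16$ torus with nearest weight 3 / diagonal weight 1
($\mu_1/\nu = -0.5$) the crossing falls near $\lambda \approx 2.6$,
comfortably inside the default ramp range $[0, 4]$.  The torus shell
weights themselves (solid nearest-neighbour couplings of strength 3,
diagonal couplings of strength 1) are the assignment under which the
minimal eigenvalue is simple with a checkerboard eigenvector; swapping
them produces a multiplicity-2 stripe mode instead, which is the wrong
fixture for a checkerboard prediction.

What the generator emulates: a homogeneous field of cells with a
slowly rising coupling strength, perturbed once at $t=0$ by small
uniform noise (half-width $10^{-3}$, seeded).  What it does not
emulate: parameter heterogeneity between cells, intrinsic noise during
the dynamics, morphogen gradients, cell movement or growth.  Passing
simulation tests therefore show that the spectral prediction picks the
right attractor basin for idealized tissues; they say nothing about
robustness to structured heterogeneity.

## Numerical choices

* **Eigenvalue clustering** (`adjacency_spectrum`): eigenvalues within
  $10^{-8}\max(1,\rho(A))$ are one cluster; integer adjacency tables
  whose eigenvalues all sit within $10^{-6}$ of integers are snapped,
  preventing exact lattice spectra from splitting into spurious
  clusters.  Eigenspace and generalized-eigenspace bases come from
  rank-revealing SVD null spaces of $(A-\mu I)$ and its powers, not
  from a Jordan decomposition; basis vectors are unit norm with first
  nonzero entry positive so printed integer eigenvectors compare after
  rescaling.  Complex eigenvalues with equal real parts are ordered by
  imaginary part; nothing downstream depends on that tie-break because
  the classifiers refuse non-real spectra.
* **Criticality tolerance**: an eigenvalue is critical when
  $|\mathrm{Re}| \le 10^{-7}\max(1, \rho(Q+\mu_k R))$.  Exact theory
  works at exact crossings; numerics need a band.
* **Nondegeneracy certificates** use a $10^{-9}$ relative margin on
  their strict inequalities: at an exact crossing the boundary case
  $\det Q = |\nu B|$ holds to rounding error and must not certify.
* **Continuation** (`find_first_bifurcation`): 200 grid points across
  the requested range, damped Newton for the synchronous equilibrium at
  each point (residual $10^{-10}$), bisection of the first sign change
  of the maximal reduced growth rate to $10^{-9}$.  $Q$ and $R$ are
  taken from analytic blocks when the model provides them, else
  central differences with step $10^{-6}(1+|x|)$.  A continuation
  failure while all eigenvalues are still negative is reported as a
  suspected fold, distinct from "no crossing in range".
* **Integration** (`integrate_family`): `deSolve::ode` (lsoda,
  `rtol = 1e-7`, `atol = 1e-9`).  The quasistatic ramp default is
  $10^{-3}(\lambda_{\text{end}}-\lambda_{\text{start}})$ per unit time
  (a 1000-time-unit traverse) followed by a 400-unit settling window.
* **Degenerate inputs**: the coarsest balanced refinement of any seed
  coloring exists (worst case: every cell its own color); an
  eigenvector with nearly-equal entries induces its coloring at
  relative tolerance $10^{-6}$, and if that coloring is unbalanced the
  refined repair is reported and flagged.

Two floating-point realities are worth stating plainly.  First, past
the crossing the fully synchronous state is dynamically unstable, so
with a *zero* perturbation rounding error itself is exponentially
amplified and the integrator eventually leaves the synchronous
subspace; exact flow invariance is checked below the crossing or over
finite windows, and the seeded perturbation ($10^{-3} \gg$ rounding
error) is what makes simulated symmetry breaking reproducible.  Second,
eigenvalues of defective (non-diagonalizable) matrices are intrinsically
ill-conditioned - a perturbation $\varepsilon$ moves a $p$-fold
defective eigenvalue by $O(\varepsilon^{1/p})$ - so the dual-route
spectrum comparison (reduced matrices versus a dense eigensolve of the
assembled Jacobian) is performed on random networks drawn to be
comfortably diagonalizable (eigenvector matrix condition below
$10^6$); on defective draws the comparison would bound neither route.

## Problem sizes

The test-suite ensembles use networks of 3-8 cells (500 random
marginal-stability instances for the classifier-versus-brute-force
comparison, 200 for the nonpositive-determinant confinement, 200 for
the reduced-spectrum identity), the six-cell line, and the
$16\times16$ torus (256 cells, 512 equations) with five seeds per
lattice for the ramped simulations.  Dense linear algebra is ample at
these sizes; the largest eigenproblem is $512 \times 512$.

## Known limitations

* Classification covers one- and two-species cells; for $s \ge 3$, or
  two species with $\det R \neq 0$ away from the confinement result,
  the continuation still reports critical indices from the reduced
  spectra but no rule-table row.
* Only checking, refinement and vector-induced colorings are provided;
  the package does not enumerate all balanced colorings of a network.
* Irregular networks (non-uniform valence), 3-D lattices, stochastic
  dynamics, and continuation of the patterned branch beyond its onset
  are out of scope.
* When several balanced colorings intersect the critical eigenspace
  one-dimensionally the package searches basis vectors in order and
  reports the balanced coloring with the fewest colors; no biological
  preference among them is claimed.
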