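---
title: "Kinetic modeling, continuation and dynamic visualization with kinsolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling, continuation and dynamic visualization with kinsolve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinsolve)
```

## The model class

A kinetic model here is a biochemical reaction network with state vector
$x$ (species concentrations, in model-defined concentration units),
parameter vector $p$, and reaction rate laws $v(x, p)$.  The dynamics are

$$\frac{dx}{dt} = S\,v(x, p),$$

where $S$ is the stoichiometric matrix (species $\times$ reactions, entry =
product coefficient minus substrate coefficient).  Models are built from a
line-oriented reaction list (`id: 2*A + B => C`, `<=>` for reversible, an
empty side for an exchange flux).  Every reaction receives a mass-action
rate template $v = k_f \prod_i x_i^{s_i}$ (minus the reverse product term
for reversible reactions); any rate law can be replaced by an arbitrary
expression in the model-definition language.

```{r}
m <- kinetic_model("v1: A <=> B", initial = c(A = 2),
                   parameters = c(kf_v1 = 3, kr_v1 = 1))
m
```

## Conservation laws and system reduction

Left null vectors $c$ of $S$ satisfy $c^\top x = \text{const}$ along every
trajectory (conserved moieties).  They are computed by integer-preserving
Gaussian elimination — not floating SVD — so the returned coefficient
vectors satisfy $c^\top S = 0$ *exactly*.  Each basis vector is
canonicalized to the smallest integers with positive leading entry and the
basis is sorted lexicographically, making the output deterministic.

For the reduced ODE system one species per law is eliminated.  The law
matrix is re-eliminated right-to-left so that each law owns a distinct
pivot equal to its *last*-listed species with nonzero coefficient; that
pivot species becomes dependent and is reconstructed algebraically as
$x_\text{dep} = (T - \sum_{j \ne \text{dep}} c_j x_j)/c_\text{dep}$.  The
choice of the last-listed species is arbitrary in principle; it is fixed
here so that two runs (and two machines) always produce the same reduced
system.  A consequence worth noting: conserved totals are preserved to
machine precision along trajectories *by construction*, because the
dependent species never integrates.

## The model-definition language

Rate laws, auxiliary right-hand-side assignments, initial-value programs
and explicit functions share one small language: `;`-terminated
assignments, numeric literals, `+ - * / ^` (with `^` binding tighter than
unary minus and right-associative), comparisons, `if (cond) {…} else {…}`
blocks, and the function set `exp, ln, log10, sqrt, abs, pow, min, max`.
That inventory is the minimal set needed for mass-action and
Michaelis–Menten-style kinetics; there are deliberately no loops, arrays
or user-defined functions.  Programs compile to R expressions evaluated in
a reusable environment; a non-finite intermediate (division by zero,
logarithm of a non-positive number) raises an error carrying the statement
location.

Conditionals make right-hand sides piecewise continuous.  Every comparison
in a compiled model contributes a *margin* (left side minus right side)
registered as an integrator root function, so the ODE solver stops exactly
at each switching point and restarts on the new branch; discontinuities
are located by the integrator's own root finding rather than stepped over.

## Solvers

**Time courses** use LSODA (automatic stiff/non-stiff switching) with dense
output exactly at the user's time points — a requirement for fitting,
where residuals are evaluated at the data's time stamps.  Requested
accuracies default to `rtol = 1e-6`, `atol = 1e-9`.  Because LSODA's local
error control does not bound global error, the tolerances actually passed
to the integrator carry a fixed safety factor of 1/50; with it, the global
error observed on closed-form fixtures sits near the requested tolerance.
Fluxes are recomputed from the states at every output time rather than
interpolated.

**Steady states** are found by damped Newton iteration on the reduced
right-hand side: full steps are halved until the residual decreases,
convergence is declared at $\|f\|_\infty \le 10^{-9}$ (configurable), and
a maximum of 50 iterations applies.  Jacobians are finite-difference
(forward, relative perturbation $10^{-7}$, absolute floor $10^{-10}$);
analytic Jacobians are deliberately out of scope since every model-RHS is
user-programmable.

**Explicit scans** evaluate named explicit functions on a fixed grid; a
grid point whose evaluation fails records a missing value and the scan
continues, so a single domain error does not destroy a sweep.

## Continuation and bifurcation analysis

Steady-state branches over one parameter are traced by pseudo-arclength
continuation: the tangent of the extended system $F(x, p) = 0$ is the null
vector of $[\partial F/\partial x,\ \partial F/\partial p]$ oriented
continuously; the predictor steps along it; the corrector is Newton
iteration constrained to the hyperplane orthogonal to the predictor
tangent.  Step control: halve on corrector failure (minimum step
$10^{-6}$ of the initial step, then stop with a truncation flag), grow by
1.3 after three consecutive corrections that needed at most 3 Newton
iterations, cap at 10 times the initial step.  An angle guard rejects
steps whose new tangent deviates more than 30 degrees from the previous
one — this is what keeps the tracer from jumping between nearby branches.
When the parameter exits the requested interval the final point is
corrected exactly onto the boundary, so branch endpoints are comparable
across runs.

At every accepted point the reduced Jacobian, its eigenvalues, its
determinant and a stability label (stable/unstable node/focus, saddle)
are recorded.  Three test functions are scanned for sign changes between
consecutive points:

* **fold** — $\det J$; a candidate is accepted only if the branch's
  parameter direction also reverses in the surrounding window, the
  geometric signature of a turning point;
* **Hopf** — the largest real part over complex-conjugate eigenvalue
  pairs, requiring a genuinely complex pair at the crossing;
* **focus–node** — the minimum over eigenvalue pairs of (squared
  real-part difference minus squared imaginary-part difference), which
  changes sign where eigenvalues collide and the local geometry switches
  between monotone (node) and spiral (focus) approach.

Each bracket is refined by bisection along the secant chord between the
two branch points, using the same constrained Newton corrector at every
trial point, until the test function magnitude is at most $10^{-8}$ (a
point that fails to refine is reported at the bracket midpoint with an
`unrefined` flag).  Eigenvalue pairing is explicit — model sizes are tens
of species at most, so $O(n^3)$ eigensolves per point are cheap and far
easier to verify than bialternate-product test functions.  Equilibrium-
type events are visible as stability-label changes along the branch;
period-doubling and limit-cycle continuation are out of scope.

## Metabolic control analysis

Flux control coefficients $C^J_i = (v_i/J)\,\partial J/\partial v_i$ and
concentration control coefficients are computed by central finite
differences: the rate law of reaction $i$ is multiplied by $1 \pm \delta$
with $\delta = 10^{-4}$, the steady state re-solved (warm-started, at
tolerance $10^{-11}$), and log-responses differenced.  $\delta = 10^{-4}$
balances truncation error ($\propto \delta^2$) against cancellation
($\propto \text{tol}/\delta$) at the steady-state tolerance used.  The
summation theorems ($\sum_i C^J_i = 1$, $\sum_i C^S_i = 0$) are not
imposed; they emerge numerically and are asserted in the test suite to
$10^{-3}$.

## Fitting

Experimental data come in three kinds, freely mixable in one problem:
time courses (model integrated at the dataset's time stamps),
steady-state-versus-parameter sweeps (Newton solve per point, warm-started
along the sweep), and explicit-function tables.  Four discrepancy
functions are available: $\sum (Y_t - Y_e)^2$, $\sum |Y_t - Y_e|$,
$\sum (Y_t - Y_e)^2/Y_e^2$ and $\sum |Y_t - Y_e|/|Y_e|$; datasets carry
weights (default 1) so heterogeneous kinds can be combined sensibly.
A simulation failure at a trial point yields an infinite objective — the
optimizer simply rejects the step.

Two optimizers are provided as interchangeable realizations of a
zero-order and a first-order method: Nelder–Mead direct search (restarted
once from its solution to guard against simplex collapse; Brent search
for a single parameter) and bounded quasi-Newton (L-BFGS-B) with
finite-difference gradients.  Parameters with positive bounds are
optimized on log scale.  Termination: relative objective change below
$10^{-9}$ or an evaluation budget (default $10^4$).

Post-fit statistics are linearized (Gauss–Newton): the residual
sensitivity matrix $G$ is finite-differenced at the estimates, the
covariance is $s^2 (G^\top G)^{-1}$ with $s^2 = F_0/(n-p)$, and 95%
confidence intervals use the $t$ quantile with $n-p$ degrees of freedom.
The ANOVA table decomposes the weight-scaled total sum of squares about
the observation mean into regression (defined as total minus residual, so
the decomposition identity holds exactly for nonlinear models too) and
residual parts.  For modulus objectives the same linearization is applied
to the raw residuals and the result carries an explicit caveat flag — the
intervals are then heuristic, not exact.  A singular $G^\top G$ reports
infinite standard deviations with a non-identifiability flag rather than
failing.

## Visual maps and dynamic visualization

A visual map lives on an abstract canvas (origin top-left, x right, y
down — stated once, used everywhere).  `auto_layout()` builds it
deterministically from the stoichiometric matrix: arrows mode places one
node per species on a grid in first-appearance order and one arrow per
reaction from substrates to products (exchange reactions get a free
boundary point); bars mode lays one bar per species then one per reaction
left-to-right.  `map_to_stoichiometry()` inverts the construction, so
`auto_layout` followed by the inverse is the identity on
unit-coefficient networks; coefficients greater than one are stored as
endpoint multiplicity attributes, since a pure arrow picture cannot carry
them.  Modifier links render as dashed arrows — a presentation choice,
documented rather than inherited.

Maps serialize to XML under a schema published with this package (`map`,
`node`, `arrow`, `bar`, `annotation`, `bindings`); numeric attributes are
written at full double precision so the round trip is structurally
lossless, and the reader is strict — an element outside the schema is an
error naming it.  No compatibility with any earlier tool's map files is
claimed.

Simulation results travel in the PLT plain-text table: row 1 the number
of metabolites N1, row 2 the number of reactions N2, row 3 the column
titles with the independent column labelled `X[0]`, then data rows of
(time or parameter value, N1 concentrations, N2 fluxes).  Tabs are
written; tab, comma or whitespace are accepted on read; values carry 17
significant digits so write/read is bit-faithful.  Columns are matched to
map objects by title, not position, so a hand-edited map survives.

Animation maps each PLT row to a frame through the clamped linear scaling

$$r_i = \begin{cases}
0 & C_i < C_{\min} \\
\dfrac{C_i - C_{\min}}{C_{\max} - C_{\min}}\, r_{\max} & C_{\min} \le C_i \le C_{\max} \\
r_{\max} & C_i > C_{\max}
\end{cases}$$

for node circle radii, and the same form $(V, h)$ for arrow thicknesses,
rate circles and bar heights — the three animation styles.  Default
bounds are $[0, \text{column maximum}]$ so dynamics are always visible;
users override them per entity.  Every frame overlays a progress bar for
the current time/parameter value and a numeric legend of the scale
bounds, and stores its scaled geometry as metadata so tests can recompute
it independently of the rendered pixels.  Rendering uses a deterministic
software rasterizer (no graphics device), which keeps exported images and
videos byte-reproducible; video export writes an AVI container with
uncompressed 24-bit frames, and a minimal RIFF reader ships alongside for
decode-back verification.

## SBML exchange

Models import from and export to SBML Level 2 Version 4 on a declared
subset: compartments (sizes become scaling constants), species, global
and reaction-local parameters, reactions with kinetic laws, and
assignment rules.  On export, conservation-law dependent species become
assignment rules on boundary-condition species and explicit functions
become rules on non-constant parameters; on import, species rules must
coincide with conservation-derived dependent species (anything else is
reported as unsupported) and parameter rules map back to explicit
functions.  Events, algebraic rules, rate rules, function definitions,
constraints, initial assignments and delays are rejected with an error
naming the feature — nothing is silently dropped.  Semantic round-trip
(equal trajectories) is the contract; byte-level identity is only
guaranteed for exporting the same model twice.

## Bundled fixtures and synthetic data

`fixture_model()` bundles the models that exercise every subsystem:
linear decay ($k = 0.7$), an open chain, the four-species conserved cycle
`mini_krebs` whose first step is driven by the external substrate
parameter `S_ext` (resting value 2 concentration units, stepped to 10 in
the demonstration sweep — a miniature stand-in for a
glutamate-driven tricarboxylic-acid cycle), the fold normal form
$\dot X = p - X^2$, the Brusselator ($a = 1$, Hopf at $b = 1 + a^2$), a
damped oscillator with a focus–node transition at damping 2, a reversible
three-step chain for control analysis, and a Michaelis–Menten explicit
function ($V_m = 2$, $K_m = 0.5$).

`generate_fixtures()` writes these as definition files plus seeded noisy
datasets with independent Gaussian noise of standard deviation 0.02
concentration units — about 2% of the unit signal amplitude, a realistic
assay noise level — with 200 points for the decay time course.  The noise
model is deliberately simple: homoscedastic, uncorrelated, Gaussian.
Real kinetic data often violate all three (proportional error,
autocorrelated drift, outliers), so passing recovery and coverage tests
here demonstrates correctness of the estimator machinery, not robustness
to real-world error structure.

## Problem sizes and numerical choices, summarized

The test and acceptance workloads use: 50 random networks of up to 6
species for conservation checks; trajectories to $t = 10^3$ for drift;
branches of 30–300 points for continuation; 100 seeded replicates of a
20-point, 1%-noise decay fit for confidence-interval coverage.  These
sizes make every property check run in seconds while staying large enough
that the asserted tolerances ($10^{-6}$ integration error, $10^{-8}$
branch error, $10^{-4}$ bifurcation location, $10^{-3}$ summation
theorems) are meaningful.

Known limitations: no delay or algebraic-differential equations; no
stochastic simulation; no two-parameter bifurcation diagrams, Flip
(period-doubling) or limit-cycle continuation; no global optimizers or
Bayesian uncertainty; the SBML subset above; and video export is
uncompressed AVI only, which trades file size for zero codec
dependencies.
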