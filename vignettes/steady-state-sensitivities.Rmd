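---
title: "Computing steady states and objective gradients at steady state"
author: "eqsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing steady states and objective gradients at steady state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqsens)
```

## The problem

Kinetic models of biochemical reaction networks are initial value problems

$$\dot x = f(x(t,\theta,u),\,\theta,\,u), \qquad x(t_0) = x_0(\theta,u),$$

with state variables $x$ (species abundances), unknown kinetic parameters
$\theta$, and known experimental inputs $u$. Observables
$y = h(x,\theta,u)$ are measured with Gaussian noise of standard deviation
$\sigma(\theta)$, and parameters are estimated by minimizing the negative
log-likelihood

$$J(\theta) = \tfrac12 \sum_{i,j}\Big(\log(2\pi\sigma_{ij}^2) +
  \big(\tfrac{\bar y_{ij} - y_i(t_j)}{\sigma_{ij}}\big)^2\Big),$$

extended by analogous terms for steady-state measurements taken after the
system has equilibrated. Two equilibration situations occur in practice:
**pre-equilibration**, where the initial state of the dynamic experiment is
the steady state under a control input $u^e$, and **post-equilibration**,
where measurements (marked `time = inf` in the measurement table) refer to
the steady state under the experimental input $u$. Both can occur in one
condition; the dynamic phase then starts at the pre-equilibration steady
state, and post-equilibration continues from the last measured time point.

Gradient-based optimization needs $\partial J/\partial\theta$, and with
equilibration in the loop both the steady state $x^*(\theta,u)$ and the
sensitivity information at the steady state must be computed. This package
implements the six admissible combinations ("method pairs") of

* a **steady-state method** — stiff numerical integration until a weighted
  root-mean-square (WRMS) criterion on $\dot x$ passes, or a damped Newton
  iteration on $f(x) = 0$; and
* a **sensitivity method** — forward (FSA) or adjoint (ASA) sensitivity
  analysis, each either integrated through the equilibration phase or
  replaced by a single *tailored* linear solve against the (transposed)
  steady-state Jacobian

together with a benchmark harness that reproduces, at desk scale, the
evaluation protocol used to compare such method pairs: log-uniform
parameter sampling within bounds, failure-rate tabulation by category,
pairwise gradient-agreement statistics, and an equilibration-versus-total
timing decomposition.

Newton's method cannot be combined with integration-based sensitivity
computation: FSA is integrated coupled to the state trajectory that Newton
does not produce, and integrated ASA over the equilibration window would
need that trajectory too, while the tailored solve is available whenever
Newton itself converged. `method_pair()` rejects both combinations.

## Steady-state computation

**Integration.** The state ODE is integrated with `deSolve`'s `lsodar`
(automatic stiff/non-stiff switching with the analytic Jacobian supplied)
and the WRMS quantity

$$\mathrm{wrms}(\dot x, x) = \sqrt{\frac{1}{n_x}\sum_i
  \Big(\frac{\dot x_i}{\mathrm{rtol}\,|x_i| + \mathrm{atol}}\Big)^2}$$

is used as a *root function*: the solver stops at the first crossing of
$\mathrm{wrms} = 1$. Because a state exactly at the crossing is only
marginally converged, the integration then continues (without the root
function) to twice the crossing time, so the returned state sits strictly
inside the converged region; the integrated sensitivities benefit from the
same consolidation. The absolute value in the WRMS weight keeps it
positive for transiently negative states.

**Damped Newton.** Iterates
$x^{l+1} = x^l - \gamma\,(\partial f/\partial x)^{-1} f(x^l)$ with step
acceptance controlled by the same WRMS error: a step that reduces the
error is accepted and $\gamma$ grows by `gamma_up` (capped at 1); a step
that does not is rejected and $\gamma$ shrinks by `gamma_down`. The
schedule defaults to $\gamma_{\text{init}} = 1$, `gamma_up = 2`,
`gamma_down = 4`, $\gamma_{\min} = 10^{-10}$, at most 100 iterations —
aggressive re-growth with strong backoff, as is common damped-Newton
practice; all values are exposed in `eqsens_config()`. Failure categories
follow the standard taxonomy: `numerical_error` (including singular linear
solves), `newton_nonconverged` ($\gamma$ exhausted), `negative_state`
(solutions below `-neg_tol`), `no_steady_state` (horizon or step cap hit).
Both methods check convergence once at the initial state before doing any
work, so starting at a steady state is a no-op.

Newton iterates are not constrained to be non-negative, and converged
Newton solutions can lie far below zero where integration from a
non-negative start cannot; such solutions are classified `negative_state`.
`neg_tol` defaults to `atol`, so integrator undershoots at the tolerance
scale are not failures.

## Sensitivities at steady state

**Tailored FSA.** At a steady state $\dot s_k = 0$, so the forward
sensitivity ODEs collapse to the linear system
$(\partial f/\partial x)\,S = -\partial f/\partial\theta$, solved for all
parameter columns from one LU factorization
(`steady_state_sensitivities()`).

**Tailored ASA.** The adjoint quadrature over an equilibration window
collapses to $(\partial f/\partial x)^T p_{\text{integral}} = -p_b$
followed by the product $-p_{\text{integral}}^T\,\partial f/\partial\theta$,
where $p_b$ is the adjoint at the boundary of the window: the steady-state
residual adjoint
$\sum_i (\partial h_i/\partial x)^T (\bar y_i^* - y_i^*)/\sigma_i^{*2}$
for post-equilibration, or the dynamic-window adjoint $p(t_0)$ for
pre-equilibration (where it also replaces the
$-p(t_0)^T \partial x_0/\partial\theta$ term, because the adjoint has
decayed to zero at the far end of the pre-equilibration interval). The
sign convention is fixed by exact agreement with the central
finite-difference oracle on scalar problems with closed-form objectives;
the stable steady-state Jacobian also implies the adjoint handed from the
post-equilibration window back to the dynamic pass is zero in the tailored
route.

Both tailored solves require a full-rank Jacobian; a condition estimate
above `cond_max` (default $10^{12}$) signals
`tailored_method_inapplicable`, upon which integration-based methods
remain available.

**Integrated variants.** The fully integration-based routes augment the
state system with the sensitivity ODEs (FSA; stopping on the state WRMS,
optionally also on the sensitivity WRMS via `sens_wrms`, off by default
since the stopping rule is defined on $\dot x$), or integrate the adjoint
system backward over the stored dynamic and equilibration windows with
measurement jumps applied as integrator events (ASA). Backward passes
obtain $x(t)$ by cubic Hermite interpolation of the stored forward
solution using the exact derivatives $\dot x = f(x)$ at the stored points
— the dense-interpolation analogue of checkpointing schemes in compiled
simulators; the fixtures are small, so no re-simulation scheme is needed.
The quadrature $\int p^T \partial f/\partial\theta_k\,dt$ is carried as
$n_\theta$ extra backward components, not reconstructed afterwards.

One objective-function value is produced identically by every pair; the
pair changes only how $x^*$ and the gradient are computed. Gradients are
assembled in linear parameter space and converted to the declared
optimization scale at the boundary
($\partial J/\partial\log_{10}\theta_k = \theta_k \ln 10\,
\partial J/\partial\theta_k$). The gradient of the steady-state-measurement
block includes the full noise-derivative term
$(1/\sigma^*)(1 - r^2/\sigma^{*2})\,\partial\sigma^*/\partial\theta$, the
exact derivative of the extended objective; the correctness of this
(together with every other term) is pinned by requiring agreement with the
central-FD oracle on a fixture whose noise standard deviation is itself a
free parameter.

## Conserved quantities

A conservation law — a vector $c$ with $c^T f \equiv 0$ — makes the
Jacobian rank-deficient and all tailored methods (and Newton)
inapplicable. `detect_conservation()` finds a basis of such vectors
numerically, as the common left null space of Jacobian evaluations at
random probe points (SVD with relative threshold $10^{-10}$, candidate
vectors validated by $|c^T f| \approx 0$ at the probes). The detection is
numeric rather than stoichiometric because the model dialect stores
general rate expressions, not a stoichiometric matrix. `reduce_model()`
then eliminates one state per law — by default the one with the largest
absolute coefficient (ties to the lowest index) for a well-conditioned
substitution — replacing it by
$(\text{total} - \sum_{i \ne e} c_i x_i)/c_e$ everywhere and introducing
the conserved total as a new parameter whose defining expression
$c^T x_0(\theta,u)$ is retained so reduced-model trajectories can be
matched against the full model. Bounds for the total are obtained by
evaluating $c^T x_0$ at the parameter bound vectors, which is exact for
the monotone initial-value expressions used here. When Newton fails on a
singular Jacobian *and* conservation laws are detected, the failure is
reported as `tailored_method_inapplicable` (reduce the model first) rather
than a generic numerical error; a singular Jacobian without a conservation
law (e.g. pure drift $\dot x = k$) remains `numerical_error`.

## Numerical choices

* **WRMS tolerances vs. integrator tolerances.** Defaults: WRMS
  `rtol = 1e-8`, `atol = 1e-10`; integrator `sim_rtol = 1e-10`,
  `sim_atol = 1e-12`. The two pairs are deliberately two orders of
  magnitude apart: the WRMS criterion evaluates $f$ on the numerical
  trajectory, so with equal tolerances the criterion can be permanently
  drowned in integration noise for states of heterogeneous magnitude.
* **Sensitivity components get their own absolute tolerance**
  (`sim_atol_sens = 1e-8`). Sensitivities span many more orders of
  magnitude than states, and a component pinned at exactly zero under a
  state-tight scalar `atol` rejects every step on roundoff forcing from
  large coupled components.
* **Equilibration horizon** `max_time = 1e7`, with `max_steps = 1e6`. The
  horizon must stay below $1/\mathrm{rtol}$: for unbounded drift
  $x = kt$ the WRMS quantity behaves like $1/(\mathrm{rtol}\,t)$ and
  crosses 1 near $t = 1/\mathrm{rtol}$ regardless of $k$, so a longer
  horizon would misclassify divergent systems as equilibrated.
* **Analytic Jacobians everywhere.** `derive()` produces all first
  derivatives and the second derivatives
  $\partial^2 f/\partial x^2,\ \partial^2 f/\partial x\,\partial\theta$
  symbolically (base R `D()`, no numeric differencing), so the augmented
  forward-sensitivity system and the backward adjoint system also receive
  exact Jacobians; without them the stiff solver degrades badly at large
  stiffness ratios.
* **Degenerate inputs.** Empty sensitivity right-hand sides, zero
  residuals, zero-length dynamic windows (steady-state-only data) and
  measurement times exactly at $t_0$ are all exercised in the test suite.

## Fixtures and the synthetic-data generator

Five built-in fixtures with closed-form steady states stand in for
real-world benchmark problems, which are deliberately out of scope here;
each is small ($n_x \le 3$) because desk-scale tests can check the
*correctness* claims about the method pairs, not wall-clock performance at
scale:

* `decay2` — linear two-step chain, $x^* = (k_1 u/k_2,\ k_1 u/k_3)$,
  post-equilibration data; bounds $[10^{-3}, 10^3]$, log10 scale, true
  $\theta = (1, 2, 4)$, $u = 1$.
* `scalar_relax` — $\dot x = a - kx$ with a parameter-valued noise
  standard deviation (exercises $\partial\sigma/\partial\theta$ terms).
* `reversible_pair` — reversible isomerization with conserved total
  (singular Jacobian until reduced).
* `cascade_preeq` — three-step cascade whose condition pre-equilibrates
  under $u^e = 1$ and then runs dynamically under $u = 4$, so the initial
  state depends on $\theta$ through the pre-equilibration steady state.
* `no_steady_state` — $\dot x = k$, exercising the failure taxonomy.

`generate_synthetic_data()` simulates a fixture at its generating
parameters and adds i.i.d. Gaussian noise of a stated standard deviation
(default 0.01, of the order of a few percent of the observable scale —
typical for quantitative time-course assays); `time = inf` rows carry the
steady-state measurements. The generator emulates additive, homoscedastic,
independent noise on a correctly specified model. It does not emulate
model misspecification, outliers, censoring/detection limits, correlated
or multiplicative errors, or discontinuous experimental inputs — so
passing tests demonstrate the numerical correctness and mutual consistency
of the method pairs, not robustness of the inference under realistic
data pathologies.

## What the tests and the acceptance script compute

The test-suite problem sizes are chosen for a laptop-scale run: gradient
agreement across all six pairs and the central-FD oracle at 10 sampled
parameter vectors per fixture; steady-state method agreement at 5–10
sampled vectors; failure-rate tabulation over 100 sampled vectors on
`decay2` and the failure fixtures; and a 10-start gradient-based recovery
of the `decay2` generating parameters from 20 noisy data points
(noise 0.01). The FD oracle is run with tightened tolerances and step
$10^{-4}$ on the log10 scale; entries more than about six orders of
magnitude below the gradient norm are at the oracle's resolution limit
(finite differencing amplifies simulation noise by $1/\mathrm{step}$ —
the known instability of FD), which the comparisons account for with an
absolute floor of $10^{-6}$ times the gradient norm. The six method pairs
are compared among themselves *without* such a floor.

`scripts/acceptance.R` re-runs these computations from scratch against the
installed package and writes one JSON object with the headline numbers
(worst pairwise gradient deviation, worst FD deviation, minimum pairwise
Pearson correlation, steady-state agreement, tailored-vs-integrated
consistency, failure rates, recovery error).

## Known limitations

* Oscillatory or chaotic systems have no steady state in this sense and
  are out of scope, as are discontinuous right-hand sides (events) and
  non-negativity-constrained Newton variants.
* Conservation detection is numeric; laws whose coefficients depend on
  parameters, or exact integer stoichiometry reconstruction, are not
  attempted.
* Wall-clock timings in the benchmark report are diagnostic only; in an
  interpreted-R implementation the relative cost of the pairs is dominated
  by integrator callback overhead and does not transfer quantitatively to
  compiled simulators.

## A worked example

```{r example, eval = FALSE}
fx <- build_fixture("decay2")
data <- generate_synthetic_data(fx, noise_sd = 0.01, seed = 1)
th <- fx$true_theta * c(1.3, 0.7, 1.6)

objective_gradient(fx$model, fx$deriv, th, data, method_pair("int_lin_asa"))
finite_difference_gradient(fx$model, fx$deriv, th, data)

report <- run_benchmark(fx$model, fx$deriv, data, n = 25, seed = 1)
report
```
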