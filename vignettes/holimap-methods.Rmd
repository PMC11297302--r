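---
title: "Linear-mapping approximations for stochastic gene networks: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-mapping approximations for stochastic gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(holimap)
```

## The problem

A transcriptional network of $M$ genes is modelled as a Markov jump
process. Gene $j$ switches between an inactive state $G_j$ and an active
state $G_j^*$; it produces its protein $P_j$ with rate $\rho_j^0$
(inactive) or $\rho_j^1$ (active), in geometric bursts of size $k$ with
$P(k = n) = p^n(1-p)$ and mean $B = p/(1-p)$ (the degenerate choice
$p = 0$ means exactly one molecule per event); proteins decay with rate
$d_j$. Regulation is cooperative binding: $h$ copies of the regulator
bind the target promoter with the combinatorial (falling-factorial)
propensity $\sigma\, n(n-1)\cdots(n-h+1)$, either reversibly
($G + hP \rightleftharpoons G^*$, as in the single-, two- and three-gene
motifs) or as irreversible catalytic switching in either direction (the
random-network model, where binding consumes the regulator molecules).

The chemical master equation (CME) of such a network is nonlinear in the
sense that its propensities are second or higher order, so its moment
hierarchy does not close, and its joint state space grows too fast for
direct numerical solution beyond one or two genes.

## Conditional moments and the mapping

For joint gene state $s \in \{0,1\}^M$ and protein multi-order $m$ the
package works with conditional factorial moments
$\mu_{m,s} = E\!\left[\prod_j (n_j)_{m_j}\, ;\, S = s\right]$, with
$\mu_{0,s} = g_s$ the state probability. `derive_moment_system()`
generates $d\mu/dt$ exactly from the CME using two identities — the
product rule $(n)_a (n)_q = \sum_t \binom{a}{t}\binom{q}{t} t!\,
(n)_{a+q-t}$ and the Vandermonde shift $(n+\delta)_m = \sum_t
\binom{m}{t} (\delta)_t (n)_{m-t}$, with $(\delta)_t$ replaced by the
burst-size factorial moments $E[(k)_t] = t! B^t$ for geometric synthesis.
The generated operator is validated term-by-term against a brute-force
truncated CME generator (`rhs_oracle_check()`); agreement is to
$10^{-6}$ and better on random probability vectors.

The mapping replaces, per gene, the nonlinear switching channels by
first-order switches with effective rates:

* **LMA** (conditional-mean): the switch-on rate is the binding rate
  times the conditional falling-factorial mean of the regulator in the
  unbound state, $\hat\sigma_b = \sigma_b\,\mu_{h,0}/g_0$; directional
  off-fluxes are matched the same way.
* **2-HM**: both switching rates are determined by requiring the
  zeroth-order equation ($\dot g_0$) and the bound-state first-moment
  equation ($\dot\mu_{1,1}$) of the nonlinear and mapped networks to
  coincide — a $2\times 2$ linear system per gene, involving moments up
  to order $h+1$.
* **4-HM**: additionally replaces the two synthesis rates, fixed by
  matching the summed first- and second-order moment equations; the
  switching match then carries a synthesis correction term.
* **3-HM** (post-translational / post-transcriptional systems): gene
  switching is matched as in the 2-HM, and every nonlinear loss channel
  of the tracked species — bimolecular sequestration, enzymatic or
  Michaelis–Menten degradation, complex formation — is folded into an
  effective first-order decay rate $\tilde d$ equal to the intrinsic
  rate plus the **net** expected nonlinear loss flux (losses minus
  complex-dissociation releases) divided by the mean count. The net
  convention matters: for the microRNA–mRNA motif, whose complexes
  release intact mRNA, folding only the losses overestimated decay and
  quadrupled the Hellinger distance.

Because the synthesis and decay channels of the two networks are
represented by identical linear operators, matching full right-hand
sides is algebraically the same as the classical matching relations;
the implementation matches full right-hand sides, which generalizes
uniformly to many genes, multiple regulators and $h \ge 2$. For a
multi-regulator gene the fluxes are summed over incoming edges, giving
one effective switch-rate pair per gene.

One genuinely open design point: for a gene regulated by another gene's
protein, which moment enters the second matching equation? Conditioning
the *regulator* on the target's state looks natural but degenerates: in
the mapped network the genes are independent processes, so those cross
moments factorize and the matching matrix is exactly singular. The
package conditions the gene's *own* protein on its own state, which
reduces to the textbook construction for autoregulation and behaved
uniformly better in simulation benchmarks.

## Engines: self-consistent closure versus sampled moments

`holimap(engine = "ode")` closes the moment hierarchy by evaluating the
matching relations inside the right-hand side and integrating the
resulting ODE system (the moment state is conditioned on the joint gene
state, so its size grows exponentially with $M$; a guard refuses
$M > 12$ and points to the hybrid). `holimap(engine = "ssa")` is the
hybrid pipeline: a modest ensemble of exact trajectories (default
$N = 2000$) supplies sample moments per output time, the matching
converts them to effective rates, and the linear network is solved by
FSP — smooth distributions at simulation cost that is essentially the
SSA stage alone. `sufficiency_check()` compares hybrid outputs at $N$
and $3N$ trajectories and accepts $N$ when their time-averaged Hellinger
distance is below 0.02.

The parameter-space sweeps (`autoreg_accuracy_sweep()`,
`sweep_bimodal_region(engine = "moments")`) evaluate the mappings at the
*exact* conditional moments of the nonlinear FSP solution — the
infinite-ensemble limit of the hybrid. This isolates the mapping's
representational error from the self-consistency iteration, whose
fixed point can be non-unique in multistable regimes (see below).

## Numerical choices

* **Matching solves.** The per-gene $2\times2$ systems are solved with a
  tiny ridge penalty ($\lambda \sim (10^{-9}\,\mathrm{scale})^2$):
  indistinguishable from the exact solution when well conditioned,
  continuous and bounded as the system degenerates. Hard if/else
  fallbacks put discontinuities into the closure ODE and stall stiff
  integrators.
* **Degenerate matching.** When a gene state is essentially unpopulated
  ($g < 10^{-4}$), when the solve is singular, or when it returns a
  negative switching rate, the gene falls back to the conditional-mean
  (LMA) rates for that instant, with a structured note in the fit.
  Clamping a negative unbinding rate at zero instead freezes the linear
  gene in one state and locks the closure onto a spurious branch.
  Negative 4-HM *synthesis* rates raise an error by default
  (`negative = "clamp"` truncates and records a warning); in sweeps the
  4-HM degrades gracefully to the 2-HM parameter set before the LMA.
* **Steady states.** The closure inherits the network's multistability,
  so the steady solver integrates the closure ODE from the physically
  prepared initial state (genes inactive, no protein) to
  $t = 50/\min_j d_j$ and Newton-polishes the end point, accepting the
  refinement only if it stays near the integrated end point; a damped
  self-consistent iteration on the parameters and horizon doubling are
  fallbacks. The 4-HM closure ODE is unstable far from its fixed point
  and is therefore warm-started from the 2-HM solution.
* **FSP.** Stationary distributions solve $(Q - \varepsilon I)x = b$ by
  shifted inverse iteration with a sparse LU kept across iterations
  (appending a dense normalization row destroys sparse orderings).
  Transient solves use Crank–Nicolson with the generator frozen at each
  knot midpoint, one sparse LU per interval; truncations start at
  $\max(64, \lceil \mathrm{mean} + 10\,\mathrm{sd} \rceil)$ (rounded up
  to powers of two so component generators are reused across sweeps) and
  double until the tail mass is below tolerance. Geometric bursts enter
  the generator as upper-triangular jump terms truncated where the tail
  is below $10^{-12}$. The truncation deficit $1 - \sum p$ is tracked
  and reported on every distribution.
* **Tolerances.** Moment integration: `lsoda` at `rtol = 1e-8`,
  `atol = 1e-10` (the matched right-hand side is only piecewise smooth;
  if `lsoda` refuses, an explicit embedded pair takes over). Steady
  residual: $10^{-8}$. FSP deficit: $10^{-8}$ stationary, $10^{-6}$
  transient.
* **Mode counting.** A mode is a plateau-collapsed local maximum whose
  prominence over the higher flanking minimum exceeds $10^{-4}$
  (suppresses truncation ripple without hiding shallow modes); the
  boundary $n = 0$ may be a mode.

## The SSA

The exact simulator (compiled C++) uses the direct method with one
`mt19937_64` stream per trajectory seeded from (seed, trajectory index),
so ensembles are bitwise reproducible and trajectory streams do not
change when the ensemble grows. States are recorded by holding them
constant between events, which is exact for jump processes.
Michaelis–Menten channels evaluate the stated rate law directly.

## Benchmark fixtures and what they emulate

All fixture rate values are package choices, selected once to realize
the documented qualitative regimes at molecule numbers of tens to
hundreds; they are not fitted to any measured data set.

* `build_autoreg()`: bursty autoregulation; the accuracy sweep uses
  positive feedback $\rho_b = 50$, $\rho_u = 5$, $B = 1$, with both
  axes in decades around $d$ and the binding axis normalized by
  $(10)_h$ so comparable switching fluxes are probed for every
  cooperativity. The basal rate is kept away from zero so the
  cooperative propensity is active in both gene states.
* `build_fixture("toggle")`: mutual repression, $h = 2$,
  $\sigma_u = 20 \gg d$; deterministically bistable around
  $\sigma_b \approx 0.3{-}1$.
* `build_fixture("repressilator")`: cyclic repression, $h = 3$,
  $\rho_u = 60$, $\sigma_u = 0.3$, threshold $K = 30$; the rate
  equations show sustained oscillations (they do not for $h \le 2$).
* `build_fixture("two_node")`: non-cooperative negative feedback in the
  fast-switching regime ($\sigma_u = 20 \gg d$). Rare weak binding of
  P1 activates gene 2, whose short active episodes release large
  amounts of the repressor P2 ($\rho_b = 400 \gg \sigma_u$); P2 binds
  gene 1 strongly. The protein P1 is then bimodal although switching is
  fast and binding non-cooperative — bimodality that is neither
  ultrasensitive-positive-feedback (type I) nor slow-switching
  (type II).
* Post-regulation motifs (`sequestration`, `phosphorylation`,
  `mrna_degradation_control`, `mirna_mrna`): reaction systems with
  protein–protein binding, Michaelis–Menten (de)phosphorylation,
  enzymatic mRNA degradation and two-site microRNA binding. Rate values
  are documented placeholder defaults exposed as arguments.

What passing tests show — and do not show — about real data: the
synthetic networks exercise bursty synthesis, cooperative binding,
multistability, oscillation and post-regulation losses, but they are
Markovian, well-mixed, two-state-promoter models without cell division,
extrinsic noise, measurement noise or multi-state promoters. Accuracy
statements are relative to the model class, not to experiments.

## Known limitations

* The self-consistent closure can possess several fixed points in
  strongly bistable regimes and the integrated branch then depends on
  the initial condition; the hybrid and exact-moment engines do not
  share this failure mode and are preferred there.
* The 4-HM can produce negative effective parameters when binding and
  unbinding rates are large; this is surfaced, never silently repaired.
* Matching is per gene onto a two-state telegraph target; promoters
  with more than two effective states are outside scope, as are
  matching orders beyond the second moments.
* Direct nonlinear FSP is limited to one or two genes (the state-space
  guard suggests the SSA beyond that); the joint-moment closure refuses
  $M > 12$.
* The 2-HM's transient accuracy degrades for strongly phase-coherent
  oscillations, where a deterministic-rate telegraph cannot represent
  ensemble phase mixtures; the repressilator fixture was chosen at a
  molecule-number scale where the hybrid is still markedly more
  accurate than raw histograms of the same simulation size.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run at desk scale, chosen as
the smallest sizes at which the qualitative claims are stable: the
accuracy sweep uses $15\times15$ grids for $h = 1..4$; the telegraph
bimodality scan $20\times20$; hybrid comparisons use $N = 2000$
trajectories against a $10^5$-trajectory reference on $t \in [0, 12]$;
mask sweeps use $2\times2$ (two-node) and $3\times3$ (toggle) grids.
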