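---
title: "Second-order group knockoffs: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-order group knockoffs: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupknockoffs)
```

## The problem and the model

Given features $X = (X_1, \dots, X_p)$ with known correlation matrix
$\Sigma$ and a response $Y$, knockoff-based inference tests conditional
hypotheses by comparing each feature's importance with that of a synthetic
negative control constructed without looking at $Y$. When features are
highly correlated — the situation created by linkage disequilibrium in GWAS
— single-feature conditional tests have little power, and the object of
inference is better taken to be a *group* of correlated features. Group
knockoffs only need to be exchangeable with the originals under swaps of
whole groups, which relaxes the construction and buys power.

This package implements the *second-order* version: only the first two
moments of $(X, \tilde X_1, \dots, \tilde X_m)$ are matched, which is exact
for Gaussian features and a practical approximation otherwise. With
standardized features the requirement is that the joint covariance equal

$$G_S = \begin{pmatrix}
\Sigma & \Sigma - S & \cdots & \Sigma - S\\
\Sigma - S & \Sigma & \cdots & \Sigma - S\\
\vdots & & \ddots & \vdots\\
\Sigma - S & \cdots & & \Sigma
\end{pmatrix},\qquad
S = \mathrm{diag}(S_1,\dots,S_g),$$

with $0 \preceq S \preceq \frac{m+1}{m}\Sigma$; each $S_\gamma$ is a free
symmetric block on group $\gamma$'s indices. Writing
$D = \frac{m+1}{m}\Sigma - S$, two identities make everything computable in
$p$-dimensional pieces:

$$\log\det G_S = m\,\log\det S + \log\det D + p\log m, \qquad
\operatorname{Tr} G_S^{-1} = m\,\operatorname{Tr} S^{-1} +
\tfrac1m \operatorname{Tr} D^{-1}.$$

Both are verified against direct $(m+1)p$-dimensional computation in the
test suite.

## Objectives

`solve_group_knockoff()` minimizes one of

* **maxent**: $-[m \log\det S + \log\det D]$ — maximizes the entropy of the
  joint law, i.e. minimizes the mutual information between originals and
  knockoffs;
* **mvr**: $\operatorname{Tr} G_S^{-1}$ — minimizes the reconstructability
  of each feature from the rest and the knockoffs;
* **sdp**: $\sum_\gamma |A_\gamma|^{-2} \sum_{i,j \in A_\gamma}
  |S_{ij} - \Sigma_{ij}|$ — the grouped absolute-deviation criterion, with
  the $|A_\gamma|^{-2}$ weights preventing large groups from dominating;
* **equi** (`solve_equi()`): the closed-form equivariant family
  $S_\gamma = \tau \Sigma_\gamma$ with
  $\tau = \min\{1, \frac{m+1}{m}\lambda_{\min}(B\Sigma B)\}$,
  $B = \mathrm{diag}(\Sigma_\gamma^{-1/2})$. The multiple-copy bound
  $\frac{m+1}{m}$ is the direct generalization of the classical $m = 1$
  constraint $2\Sigma - S \succeq 0$; for $m = 1$ on an equicorrelated
  matrix with $\rho = 0.75$ it gives $\tau = \min\{1, 2(1-\rho)\} = 0.5$.

## The solver

The three optimized criteria share one engine:

1. **Coordinate sweeps.** Every within-block entry $(i, j)$ is updated as
   $S_{ij} \leftarrow S_{ij} + \delta$ (diagonal entries first, then the
   upper triangle row-major — a fixed order for determinism). The feasible
   range for $\delta$ follows from the determinant of $S$ and $D$ along the
   update direction, computed from the quadratic forms
   $e_i^\top S^{-1} e_j$ and $e_i^\top D^{-1} e_j$. For maxent the
   diagonal step has the closed form
   $\delta^* = (m s - d)/((m+1) s d)$ with $s = (S^{-1})_{ii}$,
   $d = (D^{-1})_{ii}$, and the off-diagonal step maximizes a concave
   scalar log-determinant gain; mvr uses exact rank-$\le 2$ trace-update
   identities inside a bounded 1-D search; sdp evaluates its
   piecewise-linear restriction exactly at the breakpoint and interval
   endpoints. Every step is accepted only if it improves the objective, so
   the per-round objective trace is non-increasing by construction.
2. **PCA sweeps.** Global rank-one moves $S \leftarrow S + \delta v v^\top$
   along the eigenvectors $v$ of $\mathrm{diag}(\Sigma_1,\dots,\Sigma_g)$
   (whose outer products respect the block pattern). For maxent,
   $\delta = (m\,v^\top S^{-1}v - v^\top D^{-1}v) /
   ((m+1)\, v^\top S^{-1}v\, v^\top D^{-1}v)$, which automatically lies in
   the feasible range; the other criteria do a bounded 1-D search. At
   $v = e_i$ the maxent PCA step coincides with the diagonal coordinate
   step — a cross-check in the tests.
3. **Cholesky maintenance.** Lower factors $C C^\top = S$ and
   $L L^\top = D$ are kept current through rank-one updates/downdates
   (compiled, $O(p^2)$ each); an off-diagonal coordinate step is applied as
   the rank-two combination
   $\delta U_{ij} = \frac{\delta}{2}[(e_i{+}e_j)(e_i{+}e_j)^\top -
   (e_i{-}e_j)(e_i{-}e_j)^\top]$, positive part first. If a downdate loses
   positive definiteness numerically the factors are rebuilt from scratch
   with a warning. After 100 random feasible updates on $p = 8$ the factors
   agree with refactorization to $10^{-8}$ (tested).

### Numerical safeguards

* Every feasible interval is shrunk by `eps_boundary` ($10^{-6}$ by
  default) at both ends so iterates stay strictly inside the PD cone.
* The printed off-diagonal interval
  $\big({-2}/(e_i{+}e_j)^\top S^{-1}(e_i{+}e_j),\;
  2/(e_i{+}e_j)^\top D^{-1}(e_i{+}e_j)\big)$
  bounds one PD constraint per side but can overshoot the other (take
  $\Sigma = I_2$, $S = 0.5 I$: it allows $\delta$ up to $1.5$ while $S$
  turns indefinite at $\delta = 0.5$). `feasible_interval()` reports the
  printed formula; all update rules additionally clip candidate steps to
  the exact determinant-root interval. The maxent line search needs no
  clipping in principle — its log barrier diverges at the true boundary —
  but is clipped anyway.
* Degenerate inputs: a rank-deficient $\Sigma$ must first pass
  `regularize()`, which shrinks toward the identity on a $0.01$ grid until
  $\lambda_{\min} \ge$ `eps_pd` ($0.01$ by default — enough to keep the
  Cholesky factorizations stable); the chosen weight is recorded.

### Initialization, alternation, stopping

The descent starts at $S^0 = \tau_0 \Sigma_{\mathrm{block}}$ with $\tau_0$
half the equivariant $\tau$ — strictly interior, so the first sweeps have
room to move. One coordinate sweep and one PCA sweep are run back-to-back
per round (the schedule is user-configurable). Two choices here were made
after the default failed in a way worth recording:

* **SDP leads with PCA.** On the piecewise-linear SDP criterion,
  coordinate-first greedily zeroes individual residuals and wedges the
  iterate against the PD boundary where no further *single-entry* move
  helps — on an 8-variable test instance it stalled at objective $0.45$
  where the equivariant point achieves $10^{-6}$. Leading with the global
  eigenvector moves avoids the trap.
* **SDP runs a second descent from the equivariant point** (shrunk by
  `eps_boundary`) and keeps the better endpoint. Since steps are only
  accepted when they improve, this makes "the optimized solution is at
  least as good as the equivariant one" structural rather than empirical.
  The smooth criteria never needed this; for them the first run dominates
  on every instance tested.

Iteration stops when the relative objective change between rounds falls
below `tol_obj` ($10^{-4}$ by default) or after `max_sweeps` (100) rounds.
The default tolerance targets sampling-quality solutions; tests that assert
entrywise convergence of $S$ (e.g. a single all-spanning group driving
$S \to \Sigma$) tighten it to $10^{-13}$, because MVR in particular
converges linearly with a slow rate on ill-conditioned instances.

The maxent solution is validated against an independent generic convex
optimizer (BFGS with analytic gradient over the free block entries, finite
barrier outside the PD cone) to $10^{-4}$ relative objective on two-group
instances; a convex-modeling library would serve the same role and this
oracle is deliberately kept free of any solver code.

## Groups and key variables

`hierarchical_cluster_groups()` clusters on the dissimilarity
$1 - |\Sigma_{ij}|$ with average linkage and cuts the tree so that merges
happen only strictly below $1 - \mathrm{cutoff}$. Absolute correlation is
used because the sign of LD correlation is an artifact of allele coding;
the strict cut means a pair at exactly the cutoff stays separate, which
pins down behavior on constructed matrices. Variables are permuted so each
group's indices are contiguous (stored in `perm`; the block-diagonal
parameterization requires it), and all user-facing outputs map back to the
input order.

`select_key_variables()` picks, per group, a greedy forward sequence of
*key* variables: start from the variable maximizing the explained
within-group variation
$EV(K) = \sum_{j \in A_\gamma} \Sigma_{jK}\Sigma_{KK}^{-1}\Sigma_{Kj}$
(the sum of within-group $R^2$ values), add the variable with the largest
gain (ties to the lowest index), and stop once
$EV(K)/|A_\gamma| \ge c$. Two deliberate choices: $EV$ is computed over
*all* group members, keys included (computing it over the remaining
variables only would be an equally defensible reading; the all-members form
makes $EV/|A_\gamma|$ a genuine fraction of total within-group variation);
and $c = 1$ short-circuits to "every variable is key", because with exact
duplicates the greedy criterion could otherwise reach fraction 1 early,
while $c = 1$ is defined as disabling the conditional-independence
assumption altogether.

Under *group-key conditional independence* — non-keys independent of
everything outside their group given their group's keys —
`ci_implied_sigma()` builds the covariance that satisfies the property
exactly (cross-group entries routed through keys; within-group blocks and
the key joint law preserved; idempotent by construction), and
`sample_knockoffs_group_key()` exploits it: solve and sample knockoffs for
the keys only, then draw non-keys from their within-group conditional law
$B_\gamma \tilde x_\star + N(0, R_\gamma)$,
$B_\gamma = \Sigma_{\dagger\star}\Sigma_{\star\star}^{-1}$,
$R_\gamma = \Sigma_{\dagger\dagger} -
B_\gamma \Sigma_{\star\dagger}$, independently across copies and groups.
For the maxent criterion, the two-stage construction provably reproduces
the law of full-matrix maxent knockoffs when the property holds exactly;
the tests verify this to max-abs $0.02$ on empirical covariances at
$n = 2\times10^5$. No such equivalence is claimed (or tested) for mvr/sdp.

## Sampling

Gaussian conditioning on $G_S$ gives the knockoff law
$\tilde x_k = P x + \varepsilon_k$ with $P = I - S\Sigma^{-1}$ and
$(\varepsilon_1,\dots,\varepsilon_m) \sim N(0, V)$, where $V$ has diagonal
blocks $2S - S\Sigma^{-1}S$ and off-diagonal blocks $S - S\Sigma^{-1}S$.
These forms are derived from the joint covariance, and the package treats
"the implied joint covariance equals $G_S$ entrywise" as part of the
contract (tested to $10^{-10}$). The square root of $V$ uses a symmetric
eigendecomposition with negative eigenvalues clipped at zero (tolerance
$10^{-8}$) — robust at the feasibility boundary where $V$ is singular.
The same law applied to a Z-score vector gives *ghost* knockoffs
$\tilde z = Pz + N(0, V)$: knockoff copies of GWAS summary statistics
without individual-level data. Columns are laid out copy-major (copy 1
first, then copy 2, …), a fixed convention the Lasso stage relies on.

## Importance, scores, filter

`group_importance_lasso()` fits the Lasso of $y$ on
$[X, \tilde X_1, \dots, \tilde X_m]$ (penalty by 10-fold cross-validation
with seed-fixed folds) and sums $|\hat\beta|$ within groups:
$Z_\gamma$ for originals, $\tilde Z^{(\ell)}_\gamma$ per copy.
`group_importance_ghost()` is a deliberately simple summary-statistic
surrogate — a joint ridge solve $(G_S + \epsilon_r I)^{-1}(z, \tilde z)$
with the same group-summing — documented as such; it is not a penalized
regression.

`knockoff_scores()` sets $\kappa_\gamma = 0$ when
$Z_\gamma \ge \max_\ell \tilde Z^{(\ell)}_\gamma$ (ties count as an
original win, matching the $\ge$ in the selection indicator), else the
index of the winning copy; $\tau_\gamma$ is the winner minus the median of
the remaining $m$ values; $W_\gamma = \tau_\gamma 1\{\kappa_\gamma = 0\}$.
With this margin convention $W$ on winning groups equals
$(Z_\gamma - \mathrm{median}(\tilde Z^{(1..m)}_\gamma))
1\{Z_\gamma \ge \max \tilde Z_\gamma\}$ exactly, so the printed statistic
and the $(\kappa, \tau)$ filter are mutually consistent.
`multiple_knockoff_threshold()` selects at the smallest positive margin $t$
with
$$\frac{1/m + (1/m)\,\#\{\gamma: \kappa_\gamma \ge 1, \tau_\gamma \ge t\}}
       {\max(1, \#\{\gamma: \kappa_\gamma = 0, \tau_\gamma \ge t\})} \le q,$$
the multiple-knockoff analogue of the knockoff-plus threshold (offset
$1/m$, nulls counted per copy). The end-to-end FDR simulation is the guard
on this convention.

## What the simulation harness emulates — and what it does not

`run_experiment()` mirrors a standard design: per replicate, a fresh
covariance from one of five synthetic families (equicorrelated blocks,
sparse Erdős–Rényi covariance or precision, AR(1), AR(1) with random
adjacent correlations), a Gaussian design with that covariance, a sparse
linear response $y = X\beta + N(0, I)$ with $k$ causal effects drawn
$N(0, \mathrm{effect\_sd}^2)$, groups defined from the *sample* correlation
of the observed design, knockoffs constructed from the *generating*
covariance, Lasso importance, and the multiple-knockoff filter. Reported
power is the fraction of causal groups (groups containing at least one
causal variable) discovered; FDR is the fraction of discoveries containing
none; empty selections count as zero for both.

The acceptance-scale study uses AR(1) with $\rho = 0.5$, $p = 200$,
$n = 750$, $k = 10$, $m = 5$ copies, maxent, $q = 0.1$, 40 replicates —
sizes chosen so the whole study runs in minutes on one CPU while the
binomial Monte-Carlo error on the FDR estimate stays a few percent.
Generator parameters not pinned by the study design (block size 5 with
per-block $\rho \sim U(0.3, 0.9)$; Erdős–Rényi edge probability $0.1$ with
signed $U(0.2, 0.6)$ weights; AR(1) $\rho = 0.5$; random-AR(1)
$\rho_j \sim U(0.2, 0.8)$) were fixed once at values standard in the
knockoff simulation literature and are exposed as configuration, not
revisited.

A passing suite shows the pipeline controls group FDR for *Gaussian*
designs whose covariance the solver knows exactly. Real genotypes are
discrete (0/1/2), their LD matrix is estimated from a reference panel that
may mismatch the study population, and causal effects are not Gaussian;
none of that is emulated here, so the simulations validate the machinery,
not robustness to covariance misspecification.

## Known limitations

* Dense linear algebra throughout: $p$ is bounded by memory and the
  $O(p^3)$ sweep cost; the intended use at scale is per-LD-block, with
  blocks of $10^2$–$10^3$ variants.
* MVR coordinate convergence is linear and can be slow near the optimum on
  ill-conditioned blocks; tighten `tol_obj` when entrywise accuracy of $S$
  matters.
* The summary-statistic importance is a ridge surrogate, adequate for the
  filter's arithmetic but weaker than a genome-scale penalized regression.
* Exact (non-second-order) knockoffs for discrete genotypes, HMM-based
  constructions, and low-rank $\Sigma = D + UU^\top$ accelerations are out
  of scope.
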