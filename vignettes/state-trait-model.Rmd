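---
title: "Penalized ordinal state-trait regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized ordinal state-trait regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statetrait)
```

## The scientific problem

Experience-sampling studies record mental-state variables repeatedly for each
participant, typically on short ordinal scales (say 1..7). For two such
variables $x$ (predictor) and $y$ (response), a central question is how much
of their association is *between-person* — people who are, say, chronically
more stressed think less pleasant thoughts on average — and how much is
*within-person* — in moments of higher-than-usual stress, thoughts are less
pleasant. The classical linear mixed model disaggregates these components by
regressing $y$ on the person mean of $x$ and the momentary deviation from it.
That model is ill-suited to ordinal data twice over: it treats adjacent
response categories as equidistant, and the person *mean* of an ordinal $x$
is not an attainable level.

`statetrait` implements an ordinal-by-ordinal alternative. The observed
response is modelled through a continuous latent response $\ell_{ij}$ with
cutpoints $\theta_1 < \dots < \theta_{M_y - 1}$: $y_{ij} = m$ iff
$\theta_{m-1} < \ell_{ij} < \theta_m$ (with $\theta_0 = -\infty$,
$\theta_{M_y} = \infty$). The trait construct is the person *median*
$\tilde{x}_i$, always an attainable level, and the latent model is

$$\ell_{ij} = \alpha + \tau_{\tilde x_i} + \gamma_{\tilde x_i, x_{ij}}
  + u_i + \varepsilon_{ij},$$

with random intercepts $u_i \sim N(0, \sigma_u^2)$ and standard logistic
errors, so that conditional on $u_i$ the response follows a cumulative
logistic (proportional-odds) model. Here $\tau_r$ is the effect of having
trait (median) level $r$, and $\gamma_{r,s}$ the effect of currently being at
state $s$ given trait $r$. Identifiability is imposed structurally:
$\tau_{\tilde x} = 0$ at the global median $\tilde x$ (or, if no subject
attains $\tilde x$ as a personal median, at the nearest attained trait
level), $\gamma_{r,r} = 0$, and $\theta_1 = -1$ (location-scale anchoring of
the latent scale).

Equivalently the fixed part is a surface $f(r, s) = \alpha + \tau_r +
\gamma_{r,s}$ on the *key set* $K$ of trait-state pairs that actually occur;
the inverse map is $\alpha = f(\tilde x, \tilde x)$, $\tau_r = f(r,r) -
f(\tilde x,\tilde x)$, $\gamma_{r,s} = f(r,s) - f(r,r)$ (`zeta_to_f()`,
`f_to_zeta()`). When $f$ is linear, $f(r,s) = \beta_0^* + \beta_1^* r +
\beta_2^* s$, the model collapses to the familiar 3-coefficient
disaggregation model $\ell_{ij} = \beta_0 + \beta_1 \tilde x_i + \beta_2
(x_{ij} - \tilde x_i) + u_i + \varepsilon_{ij}$ (`mode = "linear"`).

## The linearity penalty

The saturated surface has $|K|$ fixed effects (up to $M_x^2$), many attached
to rare cells, and overfits; the linear model may underfit. The compromise is
ridge-type shrinkage of the surface *towards linearity*: maximize

$$\ell(\zeta, \theta, \sigma_u) - \tfrac{\lambda}{2}\, \zeta^\top P \zeta,$$

where $\zeta^\top P \zeta$ is a discrete analogue of the thin-plate energy:
the sum over all admissible windows of squared second differences of $f$ in
the trait direction and the state direction, plus twice the squared mixed
second differences. A window is admissible when every cell it references
occurs in $K$. The quadratic form vanishes iff the second differences all
vanish, which holds exactly for linear $f$; on a full grid the null space of
$P$ is exactly the 3-dimensional space of linear surfaces, so
$\lambda \to \infty$ recovers the classical model and $\lambda = 0$ the
saturated one. `penalty_matrix()` realizes $P = A^\top D^\top D A$, with one
row of $D$ per admissible window (mixed rows pre-scaled by $\sqrt 2$) and $A$
the cell-to-coefficient incidence; the construction is verified in the test
suite against direct summation of the definition.

Rare cells can optionally be merged before fitting (`min_count`): a rare cell
is absorbed by its nearest neighbour (Chebyshev distance) among sufficiently
frequent cells, preferring the same off-diagonal band $s - r$ — where a
linear surface is constant — then bands closer to the diagonal, with
deterministic index tie-breaks. The default is no merging.

## Estimation

The marginal likelihood integrates the random intercept out of the
conditional cumulative-logistic likelihood. The integral is approximated by
adaptive Gauss–Hermite quadrature (default 15 nodes) centred at each
subject's posterior mode with the curvature there setting the scale; the
$\sigma_u = 0$ boundary falls back to the independent ordinal likelihood.
Free cutpoints are parametrized as $\theta_1 = -1$ plus cumulative
exponentiated increments, guaranteeing monotonicity, and $\sigma_u$ enters
through its logarithm. The optimizer is a safeguarded Newton method (ridge
escalation plus backtracking) on analytic gradients and an analytic full
Hessian derived from posterior-expectation identities of the quadrature
approximation, with a PORT quasi-Newton fallback; convergence requires a
penalized-objective gradient below `1e-5` in max norm (`st_control()`).
Initialization is deterministic: cutpoints from pooled cumulative response
frequencies (shifted so $\theta_1 = -1$), $\zeta = 0$, $\sigma_u = 1$.
Responses with empty categories are rejected with an informative error —
with 7 declared levels the top category can be empty in small or strongly
shifted samples, and cutpoints for unobserved categories are not estimable.

**Shrinkage selection.** $\lambda$ is chosen by a Laplace-approximate
marginal criterion in which the penalized coefficient directions are viewed
as random effects with precision $\lambda P$:

$$\ell_{\text{pen}}(\hat\zeta_\lambda)
  + \tfrac{1}{2}\,\mathrm{rank}(P)\log\lambda
  - \tfrac{1}{2}\log\det(H + \lambda P),$$

with $H$ the negative Hessian of the unpenalized log-likelihood at the
estimate, maximized over a log-spaced grid ($10^{-2}$ to $10^6$, 17 points,
warm-started in ascending order; ties resolved towards more shrinkage). The
criterion is validated in the tests against brute-force numeric integration
of the hierarchical marginal likelihood on a low-dimensional toy model.

**Complexity and AIC.** The effective degrees of freedom of the fixed part
are $\mathrm{tr}(F)$ with $F = (H + \lambda P)^{-1} H$, partitioned across
the $\alpha$/$\tau$/$\gamma$ blocks by the corresponding diagonal entries;
they equal the coefficient count at $\lambda = 0$ and fall to 3 as
$\lambda \to \infty$. For model comparison the package reports
$\mathrm{AIC} = -2\hat\ell + 2\,(df_{\text{fix}} + (M_y - 2) + 1)$, counting
the free cutpoints and $\sigma_u$ as full parameters. For penalized fits
$df_{\text{fix}}$ is the bias-corrected count $\mathrm{tr}(2F - F^2)$ rather
than $\mathrm{tr}(F)$: the plain trace is the right notion of fitted
complexity but understates the optimism of a penalized fit whose $\lambda$
was itself selected, and the corrected count — the convention of
likelihood-based smoothing engines — shares the same limits ($|K|$ at
$\lambda = 0$, 3 at $\lambda = \infty$) while penalizing intermediate
flexibility appropriately. In our simulation checks the corrected count is
what makes AIC rank the three model variants in accordance with the
generating truth.

## Summaries

*Latent $R^2$* (`latent_r2()`) is the share of latent-response variance
explained by the fixed surface:
$\widehat{\mathrm{Var}}(\hat f) / (\widehat{\mathrm{Var}}(\hat f + \hat u) + c)$,
sample variances over observations with the predicted random intercepts
repeated within subject. The error-variance constant defaults to $c = 1$;
since the latent errors are standard logistic, $c = \pi^2/3$ is arguably the
coherent choice and is exposed via `error_var = "logistic"` — the default
keeps the simpler unit convention, and the choice only rescales, never
reorders, comparisons made with a fixed convention. Coefficients standardized
by the latent SD $\sqrt{\widehat{\mathrm{Var}}(\hat f + \hat u) + c}$
(`standardize_coefs()`, `tidy()`) are comparable across models with different
cutpoints. The *trait-only* model deletes the $\gamma$ term; its penalty is
the second difference of the trait profile (the paper-level machinery reused
one dimension down), and the ratio $R^2_T / R^2_{TS}$ indexes how
trait-driven an association is. The *lagged* model adds the previous response
$y_{i,j-1}$ as a numeric, unpenalized predictor, dropping the first
observation per subject (or per subject-day), with `AIC/n` reported for
cross-sample comparisons; the lagged response enters raw, not centred.

## The synthetic-data generator

`simulate_panel()` reproduces the structure of the package's method-
comparison study: 400 subjects with median levels 1..7 at frequencies
(16, 46, 85, 106, 85, 46, 16) (so the global median is 4), 15 observations
each (6000 in total), latent response

$$\ell_{ij} = 0.17 - 0.15\,\mathrm{sgn}(\tilde x_i - 4)\,|\tilde x_i - 4|^p
  - 0.72\,\mathrm{sgn}(x_{ij} - \tilde x_i)\,|x_{ij} - \tilde x_i|^p
  + u_i + \varepsilon_{ij},$$

$u_i \sim N(0,1)$, logistic errors, cutpoints $(-1, 1, 3, 5, 7, 9)$. Setting
$p = 1$ makes the truth linear; $p = 1/3$ makes it nonlinear. The conditional
law of the states around the median is not pinned down by these facts, so the
generator must choose one: states are drawn i.i.d. from a shifted binomial
$1 + \mathrm{Bin}(M_x - 1, q_r)$ centred near the target median (with $q_r$
clipped away from the degenerate endpoints), mixed with a 10% uniform
component so that every trait-state cell is reachable, and the batch is
redrawn until its lower median equals the target (a deterministic repair
guarantees termination; acceptance rates stay above 50% for every target
level). This respects the printed marginal facts — exact median frequencies,
support, a full-coverage key set in most replicates — while giving state
deviations a realistic multi-level spread. Because any such choice differs
from whatever the original study used, AIC win proportions and MSE reductions
are expected to be reproduced only approximately, and the package's checks
use correspondingly tolerant bounds.

`run_study()` fits the linear, unpenalized and penalized models to each
replicate and tabulates AIC wins (`study_wins()`), per-coefficient bias and
MSE against the generating truth mapped through the surface decomposition
(`study_mse()`), and the EDF distribution of the penalized fits. Replicates
in which a fit fails — most commonly because the top response category drew
no observations — are excluded from the tallies and counted. Everything is
reproducible from a master seed with per-replicate derived seeds.

**What passing these checks does and does not show.** The generator draws
states independently within subject given the median, uses a single
predictor, equal $J_i$, and no missingness or person-level covariates. Real
experience-sampling data are serially dependent, unbalanced and missing-prone;
the simulation checks therefore validate the estimation machinery and the
penalty's behaviour, not robustness to those features.

## Problem sizes and numerical choices

The packaged checks use full-size replicates (6000 observations) with 38
generated replicates per setting, retaining at least 30 complete ones — a
size at which binomial error on a win proportion is about 5-9 points, which
the widened acceptance bounds absorb. Quadrature uses 15 adaptive nodes
(doubling changes the log-likelihood by under $10^{-6}$); posterior modes are
located to $10^{-10}$ relative precision so that derived quantities stay
smooth in the parameters; penalty admissibility and merging are exact integer
computations. Unpenalized fits on cells with a single extreme observation can
drift towards large coefficients (quasi-separation); the optimizer's box
bounds ($|\zeta| \le 30$) cap this harmlessly — such cells are precisely the
instability the penalty exists to fix.

## Known limitations

Only the logit link and random intercepts are implemented; person-level
covariates, multiple simultaneous ordinal predictors, probit links, random
slopes and smooth-lag models are out of scope. Standard errors for
$\tau$/$\gamma$ are not reported. The merging rule is a pragmatic
deterministic choice; a band-smoothing penalty would be a principled
alternative for very sparse grids.
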