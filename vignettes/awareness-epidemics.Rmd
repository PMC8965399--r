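---
title: "Epidemics with awareness feedback in a partly distrusting population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epidemics with awareness feedback in a partly distrusting population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awaresir)
```

## The model

`awaresir` couples an SIR epidemic to the contact-based spread of outbreak
awareness in a population that is heterogeneous in how it handles
information. Each individual carries three labels:

* a disease state $X \in \{S, I, R\}$;
* a behavioural group: *trusting* ($T$) or *distrusting* ($D$);
* an awareness level $i \in \{0, 1, 2, \dots\} \cup \{\infty\}$, where $0$ is
  first-hand information about the outbreak, larger $i$ means the
  information has degraded (been passed on or faded) $i$ times, and $\infty$
  marks complete unawareness.

Awareness matters because an individual at level $i$ scales their
transmission-relevant contacts by the protection factor $1 - \rho^i$, where
$\rho \in [0, 1)$ is the effectiveness of the available non-pharmaceutical
interventions. Both parties of a potential transmission contribute their
factor, so a susceptible at level $k$ is infected at rate
$$\frac{\beta}{N}\,(1 - \rho^k) \sum_i I_i\,(1 - \rho^i),$$
with $I_i$ the total infected population at level $i$ and level-$\infty$
contributing the factor $1$. An infected individual at level $0$ — someone
who just learned of their own infection — does not transmit at all, which is
how strict self-isolation after diagnosis enters the model.

Information moves by pairwise encounters, and the two groups move through
it in opposite directions:

* a **trusting** individual at level $j$ who meets anyone at a *better*
  level $i < j - 1$ adopts the information at level $i + 1$ (one copy
  worse than the source);
* a **distrusting** individual at level $j$ who meets anyone at a *worse*
  level $i > j$ adopts it at level $i + 1$ — distrust here means preferring
  older, degraded, or contrarian accounts over fresher expert information;
* all awareness *fades* one level at rate $\lambda$ when not refreshed;
* infected individuals *refresh* to level $0$ at rate $\omega$ (the rate at
  which they realise their condition — diagnosis, testing, symptoms).

Encounter rates are $\alpha_T$ and $\alpha_D$ per day for the two groups.
The distrusting fraction of the population is $d$, held constant through the
outbreak. Summing the full system over levels and groups yields exactly SIR
dynamics with the time-varying effective transmission rate
$$\tilde\beta = \beta \sum_{i,j} (1-\rho^i)(1-\rho^j)\,
  \frac{I_i}{I}\frac{S_j}{S}, \qquad R_e = \tilde\beta / \sigma,$$
which the package reports along every trajectory. With everyone unaware and
$\omega = 0$ the model is the classical SIR model with rate $\beta$; the
test suite pins this reduction against an independent SIR integration.

## Truncating the awareness ladder

The level index is unbounded in principle. The package resolves levels
$0 \dots K-1$ explicitly and keeps a single reservoir for $\infty$. The
default $K$ is the smallest with $\rho^{K-1} < 10^{-6}$: beyond that depth
the protection factor is indistinguishable from the unaware limit at the
solver's working accuracy, so deeper structure cannot affect transmission.
A test doubles $K$ and verifies that epidemic summaries move by less than
$10^{-6}$ relative.

The truncation requires boundary conventions, chosen to preserve the
monotone better/worse rules and exact population conservation:

* fading out of level $K-1$ enters the reservoir;
* information passed on *from* level $K-1$ falls below the resolved range:
  the recipient becomes (or stays) unaware;
* a trusting unaware individual accepts any resolved source at level
  $i \le K-2$, landing at $i+1$;
* a distrusting individual who meets an unaware source becomes unaware
  ($\infty + 1 = \infty$); unaware distrusting individuals never change by
  exchange;
* unaware infected individuals are included in the $\omega$-refresh: the
  outbreak is seeded entirely in the reservoir, and the first cases must be
  able to generate the first information.

The printed recovered-distrusting balance equation in the source
formulation omits its fading-gain and information-gain terms; the package
implements those dynamics fully symmetrically with the other distrusting
compartments, since otherwise the population is not conserved.

## Parameters

| name | meaning | units | typical values used here |
|---|---|---|---|
| `beta` | baseline transmission rate | /day | 0.267–0.667 ($R_0$ = 2–5 at $\sigma$ = 0.133) |
| `sigma` | recovery rate | /day | 0.133 (≈7.5-day infectious period) |
| `rho` | NPI effectiveness | — | scanned over (0, 1) |
| `alpha_T`, `alpha_D` | information-encounter rates | /day | 0.5–500; $10^6$ for the fast limit |
| `lambda` | awareness fading rate | /day | 0.2 |
| `omega` | awareness refresh rate of infecteds | /day | 0.33 (≈3 days to diagnosis) |
| `d` | distrusting density | — | scanned over [0, 1) |
| `K` | resolved awareness levels | — | default $\rho^{K-1} < 10^{-6}$ |
| `N` | population size | people | 1 (densities) |

All dynamics are homogeneous of degree one in the compartments, so the
package integrates densities and uses `N` only as an output scale; a test
confirms that summaries for $N = 1$ and $N = 10^6$ agree to $10^{-9}$
relative. The standard initial condition seeds $5 \times 10^{-6} N$
infected, unaware individuals in *each* group, the rest susceptible and
unaware, split $1-d$ / $d$.

## Suppression, mitigation, and the phase boundary

For $R_0 > 1$ every outbreak starts with unrestricted growth, because no
awareness exists yet. What happens next depends on whether the information
response can drive $R_e$ below one:

* **suppression** — the feedback extinguishes the outbreak while it is
  still tiny; peaks are low and *early*, and increasing $\rho$ makes them
  earlier;
* **mitigation** — the outbreak runs its course with a reduced, *delayed*
  peak; increasing $\rho$ within this regime pushes the peak later.

At the boundary the two effects balance, infection plateaus, and the
epidemic is very long. `classify_regime()` labels a run suppression when
its peak stays strictly below `peak_threshold` (default $10^{-4} N$, ten
times the total seeding — "very low peak" has no canonical quantitative
definition, so the cut-off is configurable). `critical_rho_numeric()`
instead locates the boundary as the $\rho$ that *maximises the time to
peak* at fixed $d$: this detector needs no arbitrary cut-off, maps directly
onto the plateau picture, and is the primary boundary estimate; the
threshold classifier is the cross-check. Both are package choices — the
source analysis characterises the regimes qualitatively.

## The fast-information limit

When $\alpha_T, \alpha_D \to \infty$, information equilibrates instantly on
the disease timescale: trusting individuals sit at levels 0 or 1 (level 1
is the best a non-infected individual can reach) and distrusting
individuals are unaware. Five compartments remain —
$S_1, S_\infty, I_0, I_1, I_\infty$ — implemented in
`fast_limit_rhs()`. Assuming the infected compartments are metastable at
the boundary (all three derivatives zero) and $S_1/N \approx 1-d$,
$S_\infty/N \approx d$ after the initial growth phase gives a quadratic for
$x = 1 - \rho$:
$$x^2 (1-d)(1+dy) + x\,d\!\left(1 + dy - \tfrac{y}{R_0}\right)
  - \tfrac{1}{R_0}\!\left(1 + \tfrac{\omega}{\sigma+\lambda}\right) = 0,
  \qquad y = \frac{\beta}{\sigma - \beta d},$$
whose positive root gives the critical effectiveness
$\rho_c(d) = 1 - x^+(d)$. Two facts are worth recording:

* substituting $y$ shows the linear coefficient vanishes identically
  ($1 + dy - y/R_0 \equiv 0$), so
  $x^+ = \sqrt{(1 + \omega/(\sigma+\lambda)) / (R_0 (1-d)(1+dy))}$; the
  code nevertheless builds the quadratic as printed and takes its positive
  root, and a property test keeps the residual at machine precision;
* at $d = 0$ this gives
  $\rho_c(0) = 1 - \sqrt{(\sigma/\beta)(1 + \omega/(\sigma+\lambda))}$.
  A radical-free variant of this expression circulates in print; it is
  inconsistent with the quadratic it is derived from, and the package
  follows the quadratic.

The denominator of $y$ changes sign at the **critical distrusting density**
$d_M = \sigma/\beta = 1/R_0$: beyond it the metastable unaware infected
population would be negative, meaning no $\rho < 1$ can suppress the
outbreak. $d = d_M$ itself is reported unachievable ($y$ is singular
there). Roots giving $\rho_c \le 0$ are clamped to 0 and flagged
`suppression_at_any_rho`. As $d \to d_M^-$, $\rho_c \to 1$.

```{r curve, fig.width = 6, fig.height = 4}
p <- aware_params(beta = 0.467, sigma = 0.133, rho = 0.5,
                  alpha_T = 1e6, alpha_D = 1e6, lambda = 0.2, omega = 0.33,
                  d = 0, K = 8)
critical_density(p)
ggplot2::autoplot(critical_curve(p, d = seq(0, 0.284, by = 0.004)))
```

## Numerical choices

* **Integrator.** `deSolve::ode` with `lsoda` (automatic stiff/non-stiff
  switching), `rtol = 1e-8`, `atol = 1e-12 N`. The fast-information regime
  ($\alpha \sim 10^6$) is severely stiff — explicit methods are
  impractical there — which is why an automatic switching method is the
  default rather than an explicit Runge–Kutta pair.
* **Compiled core.** The right-hand side is implemented twice: a vectorised
  R reference (`full_rhs()`, the documentation of record) and a C routine
  used by the integrator, with a test asserting the two integrate
  identically. All per-level sums use running prefix/suffix accumulation,
  so one evaluation is $O(K)$.
* **Early termination.** Integration stops at the root
  $I(t) = \tfrac{1}{2}\,\texttt{end\_threshold}\,N$: once the epidemic is
  over, following the exponentially decaying infected compartments toward
  the denormal range serves no purpose and eventually underflows the
  step-size control. If `lsoda` still fails (near-empty compartments under
  very fast exchange), the segment is retried with BDF at
  `atol = 1e-16`.
* **Horizon.** Default `t_max = 1000` days, doubled automatically (to at
  most 16000) while $I(t_{\max})$ is above `end_threshold` ($10^{-7}$,
  i.e. one infected per $10^7$): near the phase boundary epidemics plateau
  for thousands of days. The epidemic duration is the first time after the
  peak with $I < \texttt{end\_threshold}\,N$ — the source material never
  defines "duration" operationally, so this is the package's convention.
* **Peak refinement.** The peak is the vertex of a parabola through the
  three output points around the discrete maximum; plateaus make the raw
  argmax noisy at any finite output resolution.
* **Negative values** are never altered inside the right-hand side; tiny
  solver undershoots (within $10\,\mathrm{atol}$) are clipped to zero in
  post-processing only.
* **Boundary search.** Coarse grid (default 13 points) to bracket the
  time-to-peak maximum, then golden-section refinement to `tol = 0.005` in
  $\rho$. A maximum sitting at the top of the search interval means no
  interior boundary exists (the $d > d_M$ situation) and is reported as
  unachievable.

## Problem sizes used by the tests

The test suite and the acceptance script run the model end to end at desk
scale: truncations $K \le 133$ (the default rule at $\rho = 0.9$),
$\rho$/$d$ grids of around ten points per axis, three probe densities per
transmission regime for the numeric-vs-analytic boundary comparison
(agreement within $\pm 0.03$ in $\rho$ at $\alpha = 10^6$), and information
rates spanning $0.5$–$500$ for the sensitivity orderings. These sizes
resolve every qualitative claim comfortably; finer grids change the
pictures, not the conclusions.

## What the model does and does not capture

The generator emulates a well-mixed population with constant composition:
no contact network or spatial structure, no opinion dynamics moving people
between the trusting and distrusting groups, no births, deaths, waning
immunity or reinfection, and no stochastic extinction — as a deterministic
ODE model it happily tracks "fractional individuals", which is also why a
suppressed epidemic can in principle resurge once awareness fades; the
early-termination rule deliberately ends the run before that artefact
matters. Passing tests therefore demonstrate internal correctness of the
model and its analysis, not forecasts for any real epidemic. The critical
curve $\rho_c(d)$ is exact only in the fast-information limit; at moderate
$\alpha$ the transition is gradual and the numeric detectors are the
authoritative description.
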