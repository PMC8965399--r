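# awaresir

Epidemic dynamics coupled to the spread of outbreak awareness in a
population that is only partly willing to listen.

## The problem

Non-pharmaceutical interventions — masks, distancing, self-isolation — only
curb an epidemic to the extent that people know about the outbreak and act
on that knowledge. Public-health information competes with misinformation:
some people seek out and act on good information, others distrust it and
gravitate toward degraded or contrarian accounts. `awaresir` implements a
compartmental model for exactly this situation, for epidemic modellers who
want behaviour-change feedback with an explicit misinformation axis.

The population carries three labels: disease state (S/I/R), behavioural
group (trusting T / distrusting D, with fixed distrusting density *d*), and
an awareness level *i* ∈ {0, 1, 2, …, ∞} (0 = first-hand information,
∞ = unaware). An individual at level *i* cuts transmission by the factor
1 − ρ<sup>i</sup>, where ρ is the intervention effectiveness. Trusting
individuals adopt better information from their contacts, distrusting
individuals adopt worse; awareness fades at rate λ; infecteds refresh to
level 0 at rate ω. Summed over levels the model is SIR with the effective
transmission rate

$$\tilde\beta = \beta \sum_{i,j}(1-\rho^i)(1-\rho^j)\,\frac{I_i}{I}\frac{S_j}{S},
\qquad R_e = \tilde\beta/\sigma .$$

Two regimes emerge: **suppression** (the awareness feedback extinguishes
the outbreak while it is tiny) and **mitigation** (a reduced, delayed, but
large outbreak). The package locates the boundary ρ<sub>c</sub>(*d*)
numerically and, in the fast-information limit (α → ∞), evaluates it in
closed form from a quadratic in *x* = 1 − ρ, including the critical
distrusting density **d<sub>M</sub> = σ/β = 1/R₀** beyond which no ρ < 1
suppresses the epidemic.

## Worked example

```r
library(awaresir)

fig_params <- function(rho)
  aware_params(beta = 0.667, sigma = 0.133, rho = rho,     # R0 = 5.015
               alpha_T = 5, alpha_D = 5, lambda = 0.2,
               omega = 0.333, d = 0.1)

glance(simulate_epidemic(fig_params(0.2)))   # weak interventions
#>   peak_I t_peak final_S duration total_infected converged
#> 1  0.213   40.9   0.181     228.          0.819 TRUE

glance(simulate_epidemic(fig_params(0.9)))   # strong interventions
#>      peak_I t_peak final_S duration total_infected converged
#> 1 0.0000407   5.34   1.000     111.       0.000111 TRUE
```

With weak interventions (ρ = 0.2) the epidemic is only mitigated: it peaks
late (day 41) with 21% of the population infected at once and 82% ever
infected. With ρ = 0.9 it is suppressed: the peak is four orders of
magnitude lower, *earlier* (day 5), and almost nobody is ever infected —
the signature of the feedback-driven phase transition rather than a simple
rate rescaling.

The analytic threshold in the fast-information limit:

```r
p <- aware_params(beta = 0.333, sigma = 0.133, rho = 0.5, alpha_T = 1e6,
                  alpha_D = 1e6, lambda = 0.2, omega = 0.33, d = 0, K = 8)
critical_density(p)                 # d_M = sigma/beta
#> [1] 0.3994
critical_rho_analytic(c(0, 0.1, 0.2), p)
#>       d rho_c achievable suppression_at_any_rho     x
#> 1   0   0.108 TRUE       FALSE                  0.892
#> 2   0.1 0.186 TRUE       FALSE                  0.814
#> 3   0.2 0.296 TRUE       FALSE                  0.704
```

So at R₀ = 2.5, a population with 20% distrusting needs ρ ≥ 0.30 for
suppression, and past 40% distrusting no intervention strength suffices.
`critical_rho_numeric()` recovers the same boundary from full simulations;
`phase_diagram()` maps both regimes over a (ρ, *d*) grid and
`ggplot2::autoplot()` renders trajectories, phase grids and critical
curves. `tidy()`/`glance()` return tibbles throughout.

A thin CLI mirrors the R interface for scripted scans
(`inst/cli/awaresir simulate|phase|critical-curve --config run.yaml`),
reading a YAML config and writing CSV/JSON.

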