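# fvcox

Survival regression for studies where a covariate's effect is modified by a
continuous variable *and* a predictor is an entire curve. `fvcox` fits the
functional varying-coefficient Cox model

$$
h_i(t) = h_0(t)\exp\Big(V_i^\top\theta + Z_i^\top\alpha(U_i) +
\textstyle\int_0^1 X_i(t)\,\beta(t)\,dt\Big),
$$

where $V_i$ are ordinary covariates with fixed coefficients, the effect of
each $Z_{ik}$ is an unknown smooth function $\alpha_k$ of an index variable
$U_i$ (e.g. a disease-severity score whose effect varies with age), and
$X_i(t)$ is a densely observed functional covariate (e.g. hippocampal
radial-distance profiles) acting through a functional coefficient
$\beta(t)$. Estimation follows the standard reduction: functional principal
component analysis truncates the functional term to $m$ score–loading
products $\sum_{g\le m}\hat\xi_{ig}\eta_g$, clamped B-splines expand each
varying coefficient as $\pi(u)^\top\gamma_k$, and the expanded design is fit
by Newton–Raphson on the Cox log partial likelihood, with standard errors
from the observed information. Intended users are biostatisticians analysing
time-to-event cohorts with imaging or other curve-valued markers.

The package is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods for fits, `autoplot()` for fits and study tables, and a
fully seeded simulator plus replicated Monte Carlo study driver.

## Worked example

```r
library(fvcox)

sim <- simulate_dataset(sim_config(n = 500, censor_rate = 0.1, seed = 2))
sim
#> <fvc_sim> n = 500, censoring target 0.1 (realized 0.106), seed 2

fit <- fit_fvcox(sim$data, sim$functional)
fit
#> Functional varying-coefficient Cox fit
#>   n = 500, events = 447, m = 2, spline order 4 with 3 interior knots
#>   loglik = -1989.665, AIC(m) = 3983.33
#>   theta:
#>              V1     V2     V3
#> estimate 0.9609 0.1146 0.3684
#> se       0.0632 0.0472 0.0519
#>   eta (functional component loadings):
#>             xi1    xi2
#> estimate 0.8916 3.1664
#> se       0.0891 0.2553
```

The data were generated with $\theta_0 = (1, 0.15, 0.35)$ and functional
loadings $\eta_0 = (1, 3)$: every estimate sits within about one standard
error of its target. The truncation $m = 2$ was selected by AIC
($2m - 2\log L$ over candidate truncations); three interior knots follow
the default $n^{1/5}$ rule. `tidy(fit)` returns the full coefficient table
(spline coefficients included), `glance(fit)` the one-row model summary,
and `autoplot(fit)` draws the reconstructed $\hat\alpha_k(u)$ and
$\hat\beta(t)$ curves; `fit$alpha` and `fit$beta` hold them as tibbles.

A replicated accuracy study over sample-size × censoring cells:

```r
st <- run_study(tibble::tibble(n = c(500, 1000), censor_rate = 0.1),
                n_reps = 200, seed = 11)
autoplot(st)
```

which reports root-average-squared errors for the scalar parameters and
integrated squared bias / error for the coefficient functions, with Monte
Carlo standard errors (see the methods vignette for the two normalizations
reported).

A thin command-line wrapper covering `simulate`, `fit`, `study` and
`fixture` lives at `inst/scripts/fvcox`:

```sh
Rscript inst/scripts/fvcox simulate --n 500 --censor 0.1 --seed 7 \
    --out data.csv --func func.csv
Rscript inst/scripts/fvcox fit --data data.csv --functional func.csv \
    --m aic --out report.json
```

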