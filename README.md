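# indlinpk

Inductive linearization solvers for nonlinear pharmacokinetic models,
with eigendecomposition (EVD) matrix-exponential integration, ordinary
least squares estimation, and a stochastic simulation–estimation (SSE)
harness, demonstrated end to end on a one-compartment Michaelis–Menten
model with first-order absorption.

## Who this is for

Pharmacometricians and modelers who need to solve and fit nonlinear
PK/PD ODE systems and want an alternative to time-stepping solvers: the
inductive-linearization approach converts the nonlinear system into a
sequence of *linear time-varying* systems defined over the whole time
span, each integrated exactly (per step) by matrix exponentials. The
package adds the efficiency machinery that makes the idea practical —
a successive-error stopping rule, a slope-based adaptive step grid, and
a warm-start ("smart update") scheme for use inside gradient-based
parameter estimation.

## The model and the method

The system, in amounts (depot `y1`, central `y2`, observed
concentration `C = y2 / V`):

    dy1/dt = -ka * y1
    dy2/dt =  ka * y1 - Vmax * C / (Km + C)

At iteration `n` the saturable coefficient is frozen on the previous
iterate's trajectory, giving the rate matrix

    K = [ -ka                          0 ]
        [  ka    -(1/V) * Vmax / (Km + C_prev(t)) ]

which is propagated across a step grid with per-step matrix
exponentials `exp(K dt)` computed via eigendecomposition. The loop stops
when the successive absolute relative error
`max_t |(C_n - C_{n-1}) / C_n|` drops below a tolerance (default 1e-6).
Because the cold start plugs in zeros, the first iterate is exactly the
Bateman function with `k10 = Vmax / (V Km)` — a built-in closed-form
oracle. Estimation minimizes `OFV = sum((y_i - g_i)^2)` with a
Levenberg–Marquardt search; the smart update initializes each
linearization from the previous objective evaluation's converged
predictions instead of zeros.

## Worked example

```r
library(indlinpk)

theta  <- pk_params(ka = 1, V = 1, Vmax = 0.2, Km = 0.5)  # /h, L, mg/h, mg/L
design <- nominal_design()                                # 3 mg dose, 13 times to 30 h

sol <- inductive_linearize(theta, dose = 3, output_times = design$times,
                           config = indlin_config(step = step_fixed(0.01)))
print(sol)
#> inductive linearization solution: 3001 nodes, 15 iterations, successive error 6.9e-07 (converged)

round(predict_conc(sol, c(0.5, 2, 8, 30)), 4)
#> [1] 1.1299 2.3076 1.7401 0.0084
```

The solver needed 15 linearization iterations to bring the
between-iterate relative change below 1e-6; the concentrations rise
through absorption (1.13 mg/L at 0.5 h), peak just above 2.3 mg/L
around 2–4 h where elimination is saturated, and are nearly gone by
30 h.

```r
set.seed(42)
dataset <- simulate_observations(theta, design, sigma = 0.1)  # 10% CV lognormal error
fit <- fit_mm(dataset, estimation_config("indlin", smart_update = TRUE))
print(fit)
#> Michaelis-Menten least-squares fit (converged)
#>   ka = 0.9004 /h, V = 0.9091 L, Vmax = 0.2028 mg/h, Km = 0.5703 mg/L
#>   OFV = 0.174877 (mg/L)^2 after 94 objective evaluations
```

Estimates land near the simulation truth (1, 1, 0.2, 0.5); `Km` shows
the largest scatter because the OLS surface is nearly flat in it for a
single 13-sample subject. The residual sum of squares of 0.175 (mg/L)^2
is what 10% proportional noise on this profile produces.

`run_sse()` repeats the simulate-and-fit cycle with lognormal
between-subject variability and fits each replicate's dataset with
every configured solver variant (reference Runge–Kutta, fixed-step
EVD, adaptive-step EVD), returning a replicate table and bias/OFV
summaries. A command-line launcher over the same functions is installed
at `inst/scripts/indlinpk-cli.R` (`simulate`, `fit`, `sse`
subcommands).

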