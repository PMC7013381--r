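---
title: "Modelling anti-CRISPR phage dynamics with acrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anti-CRISPR phage dynamics with acrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrdyn)
```

## The model

Some phages carry anti-CRISPR (Acr) proteins that inhibit the CRISPR-Cas
immune system of their bacterial host. Inhibition has two distinct
consequences. Privately, an Acr-positive phage may complete its lytic cycle
on a CRISPR-resistant cell. Publicly, a *failed* Acr infection leaves the
cell transiently immunosuppressed: residual Acr protein blocks immunity for
a while, and any phage — including Acr-negative ones — can exploit such a
cell. An Acr's "strength" therefore decomposes into two parameters with
different evolutionary consequences: the lysis probability $\varphi$
(private benefit) and the immunosuppression duration $1/\gamma$ (a public
good available to competitors).

`acrdyn` implements a five-compartment ODE model of this biology. Bacteria
are sensitive ($W$), CRISPR-resistant ($R$) or immunosuppressed ($S$);
free phage are Acr-positive ($V_1$) or Acr-negative ($V_2$). With
$N = W + R + S$ and $V = V_1 + V_2$:

$$
\begin{aligned}
\dot W &= rW(1-kN) - (aV_1 + aV_2 + m)W\\
\dot R &= A\,aVW + rR(1-kN) - \bigl(a(1-\rho)V_1 + m\bigr)R + \gamma S\\
\dot S &= a(1-\rho)(1-\varphi)\,V_1 R - (aV + m + \gamma)S\\
\dot V_1 &= a(1-\rho)\varphi B\,V_1 R + aB\,V_1\bigl(S + (1-A)W\bigr) - aN V_1\\
\dot V_2 &= aB\,V_2\bigl(S + (1-A)W\bigr) - aN V_2
\end{aligned}
$$

Every free phage adsorbs to any cell at rate $a$; adsorption to a cell
that does not support lysis destroys the phage. A sensitive cell acquires
CRISPR resistance upon infection with probability $A$, otherwise it lyses
and releases $B$ particles. On a resistant cell, an Acr-positive phage is
destroyed before *acr* expression with probability $\rho$ (resistance
level; rises with the number of targeting spacers); given expression
succeeds it lyses with probability $\varphi$, else the cell becomes
immunosuppressed and reverts at rate $\gamma$. Bacteria grow logistically
(rate $r$, density-dependence $k$) and die at rate $m$. There is no free
phage decay term, so in a cell-free culture phage densities are constant —
a property the tests exploit.

## Parameters, defaults, units

Time is in arbitrary "model units"; no mapping to hours is asserted.
Densities are per notional culture volume. The reference parameter set for
mixed infections is $a = 10^{-3}$, $A = 0.2$, $B = 5$, $\rho = 0.5$,
$\varphi = 0.3$, $\gamma = 1$; the remaining constants are package
conventions chosen to give the familiar qualitative picture (host
expansion, resistance evolution, phage persistence): $r = 1$, $m = 0.1$,
$k = 10^{-6}$ (carrying density $(1-m/r)/k = 9\times 10^5$), $W(0) = 10^3$,
$V_1(0) = V_2(0) = 100$, and a horizon of `t_end = 30`. All are
overridable through `acr_params()` / `acr_design()` or a config file, and
every trajectory CSV carries a JSON sidecar echoing the exact parameters
used, so runs are self-describing.

BIM host presets map one targeting spacer to $\rho = 0.5$ and two spacers
to $\rho = 0.9$; only the one-spacer value is a reference value, the
two-spacer value is a package convention encoding "resistance increases
with spacer number".

## Numerical choices

* **Integrator.** `deSolve::ode` with lsoda, `rtol = 1e-8`,
  `atol = 1e-10`. The system is mildly stiff when $aBV$ is large; when
  lsoda's dense-output interpolation fails on violently stiff decays the
  simulator retries once with the BDF method (`vode`) before declaring
  failure. The compiled C right-hand side is cross-checked in the tests
  against an R-level transcription of the equations and against an
  independent fixed-step RK4 integration.
* **Negative densities.** Post-step values in $(-\texttt{clip\_tol}, 0)$
  (default $10^{-9}$, matched to the default tolerances) are round-off and
  clipped to zero; anything more negative aborts as integrator failure,
  carrying the last valid state. This distinguishes round-off from genuine
  blow-up.
* **Extinction.** A compartment is *reported* extinct when its density
  falls below $10^{-3}$ (less than one particle per notional volume). The
  ODE keeps integrating the raw value — extinction is a reporting concept,
  since a deterministic ODE never reaches exact zero.
* **Serial transfers.** The bench protocol transfers cultures daily at
  1:100; the model as analysed runs without transfers. `acr_simulate()`
  accepts an optional transfer schedule that multiplies every compartment
  by the dilution factor; a sample time that coincides with a transfer
  reports the pre-transfer state (the sample is "taken just before the
  transfer", matching bench practice).
* **Ratio sentinels.** `final_phage_ratio()` never divides blindly: if
  $V_2$ is extinct while $V_1$ is not the result is a flagged infinite
  advantage, and both-extinct is a flagged undefined ratio.

## Experiment designs and sweeps

`acr_design()` encodes the standard infection experiments: sensitive
(wild-type) hosts, CRISPR-knockout hosts ($A$ forced to 0), or
pre-resistant BIM hosts, each with an arbitrary phage mix.
`sweep_phi()` and `sweep_gamma_inv()` re-run a mixed-infection design
across a grid of one strength parameter, reporting the final
$V_1/V_2$ ratio, extinction flags, $\int S\,dt$ and $\max_t S$. Default
grids are 11 points, $\varphi \in [0.05, 0.95]$ equally spaced and
$\gamma^{-1} \in [0.1, 10]$ log-spaced (a duration parameter deserves log
spacing); the axes behind the published figures are not printed, so these
are package conventions.

Two directions of effect are robust under the defaults: the final log
ratio is non-decreasing in $\varphi$ (fewer failed infections means fewer
immunosuppressed cells for the competitor to exploit) and non-increasing
in $\gamma^{-1}$ (longer immunosuppression feeds the Acr-negative phage).

One subtlety deserves a note. "More immunosuppressed cells accumulate at
larger $\gamma^{-1}$" is a statement about the infection wave: the peak
density $\max_t S$ rises monotonically with $\gamma^{-1}$, and so does
$\int S\,dt$ restricted to the wave (roughly $t \le 3$ under the
defaults). The *full-horizon* integral $\int_0^{30} S\,dt$ moves the other
way, because fast reversion (small $\gamma^{-1}$) preserves the resistant
subpopulation, which keeps regenerating $S$ in a long shallow tail that
dominates the integral. Sweep results therefore expose both `integral_S`
(full horizon) and `peak_S`; monotonicity claims about accumulation are
made on `peak_S`.

## Assay statistics

The measurement layer implements the formulas used on the bench:

* fraction of a competitor from paired quantities,
  $f_1 = Q_1/(Q_1+Q_2)$;
* relative fitness as the odds ratio between two timepoints,
  $w = \frac{f_x(1-f_0)}{f_0(1-f_x)}$ — equal to 1 under no change, and
  exactly reciprocal under label swap;
* efficiency of centres of infection,
  $\mathrm{ECOI} = \text{centres}/(\text{cells}\times\mathrm{MOI})$, and
  the $\varphi$ estimator
  $\hat\varphi = \mathrm{ECOI}_{\mathrm{BIM}}/\mathrm{ECOI}_{\mathrm{KO}}$;
* one-sample t tests of replicate estimates against a theoretical value,
  run on the log scale by default (ratios are the appropriate case for a
  log transform), with the 95% CI back-transformed, the tail stated
  explicitly by the caller, and a Shapiro–Wilk check reported as advisory
  only — never an automatic branch;
* the Bonferroni threshold $\alpha/a$.

Boundary fractions (0 or 1, a competitor below detection) produce flagged
sentinel fitness values and are excluded from t tests; how extinct
competitors should enter fitness calculations is genuinely underdetermined
and silent numeric infinities would be worse. With zero variance among
replicates the test takes a flagged exact-equality fast path ($t = 0$,
$p = 1$ when equal to the null; $p = 0$ or 1 by sign convention
otherwise).

Phage fitness from qPCR can be computed per replicate (default) or from
replicate-averaged quantities (`average_quantities = TRUE`), since the
bench description of averaging is ambiguous on this point.

## Synthetic data

The generators emulate the statistical structure of the competition and
ECOI assays so the whole analysis chain is testable without any external
data: 6 biological replicates, sampling at days 0, 1 and 3, multiplicative
log-normal measurement noise on titre/qPCR quantities (default
$\sigma_{\log} = 0.2$, about a 20% CV — typical of serial-dilution
titres; the true value for any given assay is unknowable from a methods
section), and optional Poisson counting noise after dilution. Plaque
counts in the ECOI generator are Poisson. Competition odds evolve by the
fitness ratio per day. Trajectory observations default to the quantities
actually measurable on the bench — total bacteria $N$ and the two phage
titres — because colonies are not clone-typed; a full-observation mode
exists for oracle tests. Zero densities are floored at the extinction
threshold before taking logs, i.e. treated as at the detection limit.

What the generators deliberately do **not** emulate: phage escape
mutants, surface-mutant evolution, spatial structure, demographic
stochasticity, or any real-assay artefact beyond the two noise stages.
Passing tests therefore demonstrate internal consistency of the method
chain under the stated noise model, not robustness to everything a real
experiment can produce.

Every generator is a pure function of (truth, noise model, seed): it
restores the caller's RNG state, and a fixed seed reproduces output
byte-identically.

## Fitting $(\varphi, \gamma)$

`fit_phi_gamma()` estimates the two strength parameters from noisy
log-density observations by least squares, all other parameters and the
design being known. The loss can be multimodal in $(\varphi, \gamma)$, so
the search evaluates a $5\times5$ grid ($\varphi$ equally spaced, $\gamma$
log-spaced within bounds) and then runs Nelder–Mead on the unconstrained
scale $(\mathrm{logit}\,\varphi, \log\gamma)$ from the best grid points.
The grid doubles as an identifiability diagnostic: a flat loss profile
along one axis (relative variation below `flat_tol`) flags that parameter
as non-identifiable instead of silently returning a number — the canonical
case is $A = 0$, where resistance never evolves and $\gamma$ (indeed both
parameters) only act through compartments that stay empty. Estimates at
the search bounds are flagged as boundary solutions. The ODE inside the
loss runs at `rtol = 1e-6` (the loss is noise-dominated), with the final
fit report at the same tolerance; noise-free self-consistency recovers the
generating $(\varphi, \gamma)$ to well under 1%.

The fitted object answers the usual questions: `coef()`, `summary()`,
`residuals()`, `fitted()`, `predict()` (the trajectory at the estimates)
and `plot()` (observations against the fitted curves).

## Problem sizes used in the tests

The test-suite simulations use the default 301-sample trajectories, an
RK4 oracle with $h = 10^{-4}$ on $t \in [0,5]$, 1000 synthetic
experiments for the type-I-error calibration ($n = 6$ replicates each),
and 100 seeded replicates at $\sigma_{\log} = 0.1$ for the parameter
recovery study. These sizes give Monte-Carlo standard errors comfortably
below the assertion margins while keeping a full run to a couple of
minutes.

## Known limitations

* The model is deterministic; extinction is a threshold convention, not a
  demographic event. Near-threshold conclusions should be checked at a
  different threshold.
* Absolute time and density scales are conventions; only qualitative and
  ordinal statements (persistence, monotonicity, ratios) transfer to the
  bench.
* The fitting layer assumes every parameter except $(\varphi, \gamma)$ is
  known exactly; misspecification of, e.g., $\rho$ biases
  $\hat\varphi$.
* lsoda can fail on violently stiff corners of parameter space; the BDF
  fallback covers the cases we probed, but the integrator-failure error
  path (carrying the last valid state) remains the honest outcome for
  genuinely pathological parameters.
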