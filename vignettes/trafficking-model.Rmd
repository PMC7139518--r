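---
title: "A four-stage steady-state model of lymphocyte blood-CSF trafficking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A four-stage steady-state model of lymphocyte blood-CSF trafficking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphtraffic)
```

## The model

Lymphocytes of one lineage (CD4 or CD8 T cells, B cells, NK cells) are
classified into four stages: naive or differentiated, within peripheral
blood (PB) or within cerebrospinal fluid (CSF).  Four memoryless transition
processes connect the stages:

* `alpha1` — migration of naive cells from PB to CSF,
* `beta1` — differentiation of naive cells within PB,
* `alpha2` — migration of differentiated cells from PB to CSF,
* `beta2` — differentiation of naive cells within CSF.

Each rate is the per-step probability of the transition, stored as a
fraction in $[0,1]$ (tables are usually printed in percent).  Under the
stationarity assumption the stage probabilities
$(x_1, x_2, x_3, x_4)$ — PB/naive, CSF/naive, PB/diff, CSF/diff — satisfy
the linear balance system

$$x_1 = 1-\alpha_1-\beta_1,\qquad
  (1+\beta_2)\,x_2 = \alpha_1,\qquad
  (1+\alpha_2)\,x_3 = \beta_1,\qquad
  x_4 = \beta_2 x_2 + \alpha_2 x_3,$$

whose coefficient matrix has determinant $(1+\beta_2)(1+\alpha_2) > 0$, so a
unique solution always exists; `steady_state()` evaluates the closed form
and `stage_system()` exposes the matrix for independent verification.  Total
mass is conserved analytically ($\sum_i x_i = 1$), and all probabilities are
nonnegative exactly when $\alpha_1 + \beta_1 \le 1$ — a constraint the
package enforces on every rate set.

Two structural assumptions matter for interpretation.  First, migration is
one-way: recirculation from CSF back to blood is not represented, so
`alpha1`/`alpha2` are net rates.  Second, the model has no intrathecal
de-novo generation of a subset; lineages produced only inside the CNS
compartment (plasmacytoid B cells in some conditions) are outside its reach,
and the stationary formulation cannot describe transient dynamics.

A note on the CSF naive balance: the compartment semantics of the stage
diagram require the CSF differentiation rate `beta2` in the $x_2$ and $x_4$
equations, and that is the package default.  Because mass is conserved under
either choice, conservation alone cannot discriminate a variant in which
the blood rate `beta1` is reused there; that variant is available as
`steady_state(r, csf_rate = "beta1")` for sensitivity analysis only.

Measured immune profiles are reported per compartment, so
`compartment_profile()` renormalises the stage probabilities into the
naive/differentiated split within PB, the split within CSF, and the two
compartment masses.  Degenerate inputs (an empty compartment) raise an error
rather than returning silent zeros.

```{r}
r <- reference_rates("CD8", "controls")
steady_state(r)
compartment_profile(steady_state(r))
```

The bundled `reference_rates()` table provides rate estimates for five
clinical groups (non-inflammatory controls, treatment-naive RRMS,
natalizumab- and alemtuzumab-treated RRMS, Susac syndrome) and serves as
ground truth for all synthetic experiments.

## Calibration and what is identifiable

Given $K$ measured four-stage vectors $X_k$, `fit_rates()` minimises the
unweighted mean squared deviation
$\frac1K\sum_k \lVert X(\alpha,\beta)-X_k\rVert^2$ over the box
$[0,1]^4$ with the added feasibility constraint $\alpha_1+\beta_1\le 1$.
The solver is bounded quasi-Newton (L-BFGS-B) with the analytic gradient;
the non-box constraint enters through a steep quadratic penalty (weight
$10^6$) followed by projection of any numerically infeasible optimum.  The
requested objective-decrease tolerance defaults to $10^{-16}$; since that is
below what double precision can resolve for a general objective, it is
mapped to the tightest achievable setting (`factr = max(1, tol/eps)`).
Optimisation restarts from a deterministic grid (default three values per
free rate, 0.1/0.5/0.9, plus the box centre); ties are broken by the
smaller L2 norm of the rate vector and then by grid order, making the
result bit-for-bit reproducible.

The steady state depends on the four rates only through three
combinations,

$$s_1=\alpha_1+\beta_1 = 1-x_1,\qquad
  s_2=\frac{\alpha_1}{1+\beta_2} = x_2,\qquad
  s_3=\frac{\beta_1}{1+\alpha_2} = x_3,$$

so a four-parameter fit to steady-state data is structurally
under-determined: a one-parameter family of rate sets attains the same
objective.  `equivalent_rates()` constructs members of that family
explicitly, and every `calibration_result` reports the identifiable
combinations together with the feasible width of the family instead of
pretending the raw rates are unique.  Consequently the package's own
recovery guarantees are stated for $(s_1,s_2,s_3)$; raw rates are only
recoverable in profile calibration (`profile_fit()`), e.g. with both
migration rates held fixed, where the closed forms
$\beta_1 = x_3(1+\alpha_2)$ and $\beta_2 = \alpha_1/x_2-1$ make the reduced
problem well posed.

```{r}
truth <- reference_rates("CD8", "SuS")
v <- stage_vectors(steady_state(truth))
profile_fit(v, fixed = c(alpha1 = truth$alpha1, alpha2 = truth$alpha2))
```

Assembling the four-vectors from per-compartment percentages requires a
relative compartment mass, which flow-cytometry reports do not contain.
`assemble_stage_vectors()` therefore offers three modes: `count_weighted`
(masses proportional to absolute counts; the default, and an error with
guidance when counts are missing), `fixed_weight` (a common CSF mass,
default 0.001 — an explicit assumption reflecting the roughly
thousand-fold lower CSF cellularity, not an estimate), and `joint` for data
that already carry a joint four-way split.

## Blood-only prediction of the CSF profile

Blood data constrain a single degree of freedom, so per-patient
conditioning personalises only the blood differentiation rate: solving the
steady state for the `beta1` that reproduces the patient's observed blood
naive fraction $p$ gives

$$\beta_1^{(\text{patient})} =
  \frac{(1-p)(1-\alpha_1)}{p/(1+\alpha_2) + (1-p)},$$

and `predict_csf()` substitutes it, with the cohort's other three rates,
into the steady state to obtain the CSF split.  This choice reproduces the
patient's blood profile exactly with the fewest moving parts; predicting
from the cohort model's own blood profile returns the cohort model's own
CSF profile (a round trip the tests assert to $10^{-10}$).

`bootstrap_prediction()` quantifies the dependence of such predictions on
the particular training cohort: resample patients with replacement,
recalibrate, re-predict, and report percentile intervals (default
$B = 1000$, 95%).  The interval reflects training-cohort variability, not
the new patient's own measurement error.  Failed refits are counted and
skipped; more than half failing is an error.

## The stochastic oracle

The balance equations admit a simple event-level interpretation that the
package simulates exactly (`simulate_trafficking()`): cells arrive as a
Poisson stream with intensity $\Lambda$, are assigned at entry to CSF-naive
with probability $\alpha_1$, PB-differentiated with probability $\beta_1$,
and PB-naive otherwise; CSF-naive cells convert to CSF-differentiated at
rate $\beta_2$, PB-differentiated cells at rate $\alpha_2$; every cell is
cleared at unit rate in every stage.  Assignment happens at entry (not per
capita from the PB-naive pool) because the balance equations route the
stage-1 outflows in proportion to the source.  This is the unique simple
linear birth-death system whose expected stationary occupancy divided by
$\Lambda$ equals the model's stage probabilities, which makes the
simulation an independent oracle for the closed form.  Because cells are
independent, the exact simulation needs no event queue: each cell's birth
time, assignment and exponential holding times are drawn directly, and the
event tally always satisfies births = deaths + survivors.

Monte Carlo standard errors use batch means (default 10 batches).  Two
numerical cautions, reflected in the tests: batches should be long
relative to the unit clearance time for the SE to be trustworthy, and the
SE estimate itself carries relative sampling error of about
$1/\sqrt{2(n_\text{batches}-1)}$, which agreement checks at a fixed number
of SEs should allow for.

## The synthetic-cohort generator

Patient-level data of this kind are not publicly deposited, so the
generator (`generate_cohort()`) emulates post-gating flow-cytometry
summaries from known rates: compute the compartment profile, then draw the
observed naive percentages by binomial sampling of the gated events —
10,000 events per blood sample and 200 per CSF sample by default, the
latter reflecting the low cellularity of CSF material.  Absolute counts
are `total_cells` (default $10^6$) times the compartment masses.  Optional
between-patient heterogeneity jitters each rate on the logit scale (so
jittered rates stay in $(0,1)$); draws violating
$\alpha_1+\beta_1 \le 1$ are retried a bounded number of times.  Every
record is reproducible from the seed and the patient index alone.

The generator emulates event-count sampling noise and rate heterogeneity.
It does not emulate gating error, antibody spillover, panel drift, or any
systematic disagreement between the model family and real biology — so
passing recovery tests demonstrates the estimation machinery is correct
and well calibrated under the model's own assumptions, not that the model
fits any particular clinical data set.

```{r}
cohort <- generate_cohort(reference_rates("CD8", "controls"),
                          generator_config(5, seed = 1))
cohort[, c("patient_id", "pb_naive_pct", "csf_naive_pct",
           "pb_total_count", "csf_total_count")]
```

## Problem sizes and numerical choices

The test-suite and acceptance experiments use desk-scale problem sizes
chosen to keep every run deterministic and fast while leaving clear
statistical headroom: cohorts of 75 synthetic patients (the control-group
size the reference rates correspond to) for parameter recovery, 14
training / 19 prediction patients for the bootstrap-coverage scenario with
$B = 200$, and a stochastic-oracle run at $\Lambda = 10^4$ over 200 time
units with a burn-in of 20.  Tie-breaking, start grids and seeds are fixed
as described above, so every reported number is reproducible to the last
bit on one CPU.

Known limitations worth restating: raw transition rates are not
identifiable from steady-state data (only $s_1, s_2, s_3$ are); the
stationary model cannot speak to dynamics or recirculation; and the
default CSF-mass assumption in `fixed_weight` assembly is a convention,
not an inference.
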