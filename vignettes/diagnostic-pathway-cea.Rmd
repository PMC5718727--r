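---
title: "Modelling sequential prostate-cancer diagnostics: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sequential prostate-cancer diagnostics: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcea)
```

# The problem

Men referred with a suspicion of prostate cancer belong to one of four true
disease subgroups — no cancer, low-risk (non-clinically-significant) cancer,
intermediate-risk and high-risk cancer, the last two jointly constituting
clinically significant (CS) cancer. Three tests are available: MPMRI
(imaging, scored 1–5 for suspicion), TRUSB (standard biopsy, more sensitive
when MRI-targeted) and TPMB (template mapping biopsy, treated as a perfect
reference standard). A *diagnostic strategy* is a history-dependent sequence
of up to three tests with a rule mapping the observed results to a final
diagnosis. `pathcea` evaluates such strategies exactly and ranks them
economically.

# The decision-tree engine

## Test-performance tables and conditional independence

All accuracy information enters through subgroup-conditional classification
rows P(NC, nonCS, CS | context, subgroup). A *context* is the test plus the
situation in which it is applied; for TRUSB the context is one of five types
(first biopsy; repeat after a negative biopsy; repeat after a non-CS
finding; MRI-targeted after a suspicious scan; MRI-targeted repeat after a
prior biopsy and a suspicious scan). Given the context and the true
subgroup, successive test results are conditionally independent: all history
dependence is carried by the context. This is exactly the granularity at
which the source tables are published; no richer dependence structure is
available to estimate.

Two structural constraints are enforced at construction time: biopsy rows
for cancer-free men are fixed at (NC = 1, 0, 0) — a biopsy cannot detect
cancer that is absent — and TPMB rows are the identity mapping of truth to
class. Together with the diagnosis rule below these make every strategy
perfectly specific under the packaged tables, a property the tests check
exhaustively.

Two of the transcribed MPMRI rows sum to 0.99 and 1.01 (printed rounding in
the source). The loader renormalises rows to sum to one and reports how many
it touched; the transcription itself is kept verbatim in
`inst/extdata/`. The rows entering the headline worked examples sum to one
exactly and are unaffected.

## Strategy grammar and routing

Labels follow `"<combination> <digits>"` — combination code, biopsy
histology definition (1–2), and, when MPMRI is used, the MPMRI definition
(1–2) and cut-off (2–5). Cut-offs 2–4 mean "suspicion at or above"; 5 means
"equal to 5", matching the published table layout. The full grid enumerates
400 labelled strategies.

The main text of the source analysis describes the combination families and
several specific combinations but leaves the complete per-combination
routing to supplementary material that is not available. The following
completions are therefore package design decisions, chosen to be consistent
with every combination that *is* described:

* **M1–M7** (MPMRI first): referral to MRI-targeted TRUSB on CS suspicion
  (M1, M3, M5, M7) or any suspicion (M2, M4, M6); repeat MRI-targeted TRUSB
  when the scan was suspicious of CS cancer and the first biopsy found
  non-CS cancer (M3, M4), nothing (M5, M6), or no CS cancer (M7); no repeat
  for M1, M2. The printed descriptions of M1, M3, M4 and M7 all fit this
  grid.
* **T1–T9** (TRUSB first): T2/T3/T4 repeat the biopsy after a negative /
  non-CS / either result. T5–T9 offer MPMRI to men whose biopsy found
  nothing (T5, T8), non-CS cancer (T6), or either (T7, T9), with an
  MRI-targeted repeat on CS suspicion (T5–T7) or any suspicion (T8, T9);
  the printed descriptions of T6 and T7 fit, and T9 is the most sensitive
  variant, consistent with its role in the published sensitivity analyses.
* **N1–N7 / P1–P9** (reference-standard terminal): P1 is TPMB alone. The
  other N/P combinations follow the corresponding M/T structure for imaging
  and first biopsy, but *every man in whom CS cancer has not been detected
  terminates in a TPMB*. This is the reading under which these strategies
  have sensitivity exactly 1 — the property the source analysis attributes
  to them — and it respects the three-test limit. Its cost is that the
  rebiopsy-trigger distinctions collapse: some N/P variants coincide in
  expected outcomes (e.g. P2, P3, P4) while remaining distinct labels. The
  published analysis prunes the 400-variant grid to 383 using rules in the
  unavailable supplementary material, plausibly removing exactly such
  coincidences; the enumerator reports the grid size, warns about the
  discrepancy, and exposes an `exclude` hook rather than guessing the
  pruning.

One further assignment the source leaves implicit: a repeat TRUSB that
follows *both* a prior TRUSB and a suspicious MPMRI uses the type-5 context
regardless of whether the prior biopsy found nothing or non-CS cancer. This
matches the only fully worked example available (strategy M7 222 in
intermediate-risk men: referral 0.98, first-biopsy detection 0.74, and the
remaining 0.26 — negative *or* non-CS — rebiopsied with detection 0.87).
MPMRI performance after a negative TRUSB (T and P families) reuses the
first-line MPMRI rows, since no conditional imaging performance is
published.

## Diagnosis rule

The final diagnosis is the most severe *biopsy* result on the path
(CS > nonCS > NC); imaging suspicion alone never yields a cancer diagnosis,
and a man with no biopsy exits as diagnosed cancer-free. The source states
that a CS diagnosis requires a biopsy but not how conflicting biopsy results
combine; maximum severity is the clinically conservative reading (a positive
biopsy is not erased by a later negative one).

## Exact propagation and the microsimulation oracle

`execute_strategy()` enumerates every path (at most $3^3$ per subgroup),
multiplying classification probabilities along branches; per-subgroup cell
probabilities sum to one within $10^{-9}$ by construction and the tests
assert it on random tables. Sensitivity is computed through the complement
(one minus the non-CS diagnosis mass) so that strategies with no structural
route to a missed CS cancer report sensitivity exactly 1 rather than
$1-10^{-16}$. `microsim_oracle()` pushes `n` simulated men through the same
routing rules with an independent code path and a mandatory seed; the test
suite checks agreement with the exact engine at $n = 10^5$ for all 400
strategies, judging each empirical sensitivity against three binomial
standard errors of a proportion among the simulated CS men.

# The cohort Markov model

Each (subgroup, management) cell runs a discrete-time cohort: states
{localised, metastatic, dead} for men with cancer, {alive, dead} otherwise;
death absorbing. Defaults, all configurable through `econ_settings()`:
cycle length 1 year, start age 65, stop at age 100 or when survivorship
falls below $10^{-12}$, QALY and cost accrual on start-of-cycle occupancy
with no half-cycle correction (a flag enables the half-cycle average), both
discount rates 3.5%/year, prices in 2015 GBP. The source states the discount
rate and price base; cycle structure, accrual timing and cohort age are not
stated and these are the conventional defaults. Accrual at cycle start makes
constant-hazard configurations match the geometric closed forms
$\sum_t s^t = 1/(1-s)$ exactly, which the tests exploit at $10^{-9}$
tolerance.

Background (other-cause) mortality is layered multiplicatively on the
disease transitions: per cycle, death probability
$1-(1-p_{\text{bg}})(1-p_{\text{disease}})$, survivors progressing with the
stated metastasis probability, so rows remain stochastic. The default
schedule is a synthetic Gompertz hazard ($2\times10^{-5} e^{0.095\,a}$,
roughly 1% at 65) standing in for a national life table.

Management follows the diagnosis: CS diagnosis → immediate radical
treatment (one-off cost at diagnosis, treatment-specific transition row);
cancer without a CS diagnosis → surveillance (per-cycle cost in the
localised state, no treatment benefit, no delayed-detection pathway — the
source itself notes repeat-testing protocols could not be evaluated);
no cancer → background mortality only. HRQoL: baseline utility declining
linearly with age, a per-cycle metastatic decrement, a one-off QALY
decrement per TPMB, and no TRUSB decrement (as in the source). Utilities are
clamped to $[0,1]$ after decrements.

# Calibration

Long-term transition probabilities are rarely observed directly; trials
report survival and metastasis-free fractions at given times.
`calibrate_transitions()` fits the three free probabilities of each
(subgroup, management) cell by weighted least squares between model-implied
and stated targets, using L-BFGS-B within $[0, 0.9]$ bounds and seeded
multi-start (default 10 starts; objective tolerance $10^{-8}$; an
identifiability diagnostic flags cells with fewer targets than parameters).
Least squares is the transparent default in the absence of a stated
objective; weights emulate differing target precision. The forward map runs
the three-state model *without* background mortality — targets are
interpreted as disease-specific, which keeps the closed-form oracles exact
and separates calibration from the life table. Times that are not multiples
of the cycle length are interpolated linearly. On noiseless targets
generated from the model itself, parameters are recovered to better than
$10^{-3}$ (a seeded test).

# Economics

* **Frontier.** Dominated points (another strategy costs no more and
  achieves at least as much, strictly better on one axis) are removed, then
  the frontier is built greedily from the least costly point by repeatedly
  taking the smallest ICER; remaining exclusions are extended dominated. The
  ICER sequence along the frontier is strictly increasing. Exact ties on
  both axes keep the lexicographically first label; ICER ties are broken
  towards the larger effect, which drops collinear intermediate points. The
  tests verify equivalence with a brute-force threshold sweep (a point is on
  the frontier iff it uniquely maximises net benefit $\lambda E - C$ at some
  $\lambda > 0$) on 100 random instances.
* **Detection frontier.** The same algorithm in the (testing cost, CS
  cancers detected per man) plane.
* **PSA.** Dirichlet uncertainty on classification rows and prevalence
  (concentration = point estimate × effective sample size; structural zeros
  frozen, so perfect specificity survives), beta on probabilities and
  utility decrements, gamma on costs — the standard conjugate conventions,
  stated here as a design decision since the source does not print its
  families. All distribution means equal the point estimates exactly.
  Default 1000 Monte-Carlo simulations, as in the source. CEAC = fraction of
  simulations in which a strategy maximises net benefit at a threshold (ties
  to the first label, so columns sum to 1); CEAF follows the strategy with
  the highest *expected* net benefit — the standard convention, adopted
  because the source does not define it. Frontier-membership probability
  (the bubble-size quantity of cost-effectiveness planes) counts frontier
  membership per simulation by default; net-benefit optimality at supplied
  thresholds is available as an alternative since the source is ambiguous
  about which it plots.
* Default willingness-to-pay thresholds: £13 000, £20 000, £30 000 per QALY.
  Euro figures are presentation only and never enter model logic.

# Synthetic data: what it does and does not emulate

`generate_parameter_set()` produces seeded, reproducible bundles:
Dirichlet-perturbed performance tables (effective sample size 200 by
default; `Inf` reproduces the packaged tables exactly), a configurable
synthetic prevalence (default 0.30 / 0.20 / 0.30 / 0.20 — a plausible
secondary-care mix, *not* an estimate from any study), unit costs drawn
±25% around £350 (MPMRI), £450 (TRUSB), £1300 (TPMB) — magnitudes chosen to
be realistic for NHS tariffs with complication management folded in — and
long-term costs, utility decrements and transitions drawn from ranges that
enforce the treatment-benefit ordering (radical treatment progresses no
faster than surveillance), which makes the sensitivity-monotonicity property
testable. Calibration targets are generated from the bundle's own
transitions, enabling end-to-end recovery experiments.

What passing tests therefore show: the engine, Markov model, calibration and
economic machinery are internally correct and reproduce every structural
property the source analysis states (referral percentages, perfect
sensitivity/specificity, strictly increasing frontier ICERs). What they do
not show: agreement with the published lifetime ICERs (e.g. the printed
£/QALY values), which depend on unpublished supplementary unit costs,
utilities and trial-derived transitions. Synthetic bundles are labelled as
such throughout and no synthetic value is presented as an estimate of the
source's inputs.

# Numerical choices and problem sizes

Row-stochasticity and prevalence normalisation are enforced at $10^{-9}$;
frontier comparisons use exact arithmetic on doubles; the calibration
objective tolerance is $10^{-8}$ with `factr = 1e3`; cohort runs stop at
survivorship $10^{-12}$. The test suite uses problem sizes chosen to keep a
full run in the low minutes on one core while leaving Monte-Carlo error well
inside the asserted bounds: $10^5$ men per strategy for the exhaustive
oracle comparison, 1000 PSA simulations for mean-preservation checks, 100
random instances for the frontier oracle, and 400-draw mean-preservation
checks for the generator.

# Limitations

* The per-combination routing beyond what the source's main text describes,
  and the pruning from 400 to 383 variants, are reconstructions; the
  enumerator flags the count discrepancy rather than hiding it.
* No PI-RADS scoring, transperineal biopsy, radiotherapy arm, individual
  covariates, or delayed-detection re-testing pathways.
* Long-term results are only as meaningful as the parameter bundle supplied;
  the shipped bundles are synthetic stand-ins.
* TPMB is treated as exactly perfect (the reference-standard reading),
  including when it terminates N/P strategies; histology definitions apply
  to TRUSB only.
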