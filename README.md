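# pathcea

Cost-effectiveness analysis of sequential diagnostic pathways for clinically
significant (CS) prostate cancer.

Men referred to secondary care with a suspicion of prostate cancer can be
investigated with three tests: multiparametric MRI (**MPMRI**, non-invasive,
scored on a 1–5 suspicion scale), transrectal ultrasound-guided biopsy
(**TRUSB**, cheap but insensitive, more sensitive when targeted by a prior
MRI), and template prostate mapping biopsy (**TPMB**, the reference standard
— near-perfect but resource-intensive). Which *sequence* of tests — and which
CS-cancer definitions and MPMRI cut-offs — detects the most CS cancers per
pound spent, and maximises lifetime quality-adjusted survival per pound of
NHS spend?

`pathcea` answers this with three connected components:

1. **An exact decision-tree engine.** A diagnostic strategy is a labelled,
   history-dependent sequence of up to three tests (32 combinations
   `M1–M7, N1–N7, T1–T9, P1–P9`, crossed with two biopsy histology
   definitions, two MPMRI definitions and four cut-offs — 400 labelled
   variants). Given subgroup-conditional classification tables
   P(result | test context, true subgroup), the engine enumerates every path
   exactly, yielding the joint distribution over (true subgroup, final
   diagnosis, tests administered). Sensitivity, specificity, referral rates
   and expected testing costs are exact, not simulated; a seeded
   microsimulation oracle is included for validation.
2. **A cohort Markov model.** Per (subgroup, management) cell: states
   {localised, metastatic, dead} for men with cancer ({alive, dead}
   otherwise), yearly cycles, QALY and cost accrual at the start of each
   cycle, discounting at 3.5%/year. A CS diagnosis triggers immediate radical
   treatment; anything else is surveillance. Transition probabilities can be
   **calibrated** to stated survival / metastasis-free targets by bounded
   weighted least squares with seeded multi-start.
3. **Economics.** Efficiency frontiers (dominance + extended dominance),
   incremental cost-effectiveness ratios ICER = Δcost/Δeffect, net monetary
   benefit `λ·E − C`, and probabilistic sensitivity analysis (Dirichlet /
   beta / gamma parameter uncertainty; cost-effectiveness acceptability
   curves and frontier-membership probabilities).

The package ships transcriptions of the published test-performance tables
(point estimates). The individual-level long-term parameters behind the
published ICERs are not public, so lifetime analyses run on clearly labelled
**synthetic** parameter bundles from `generate_parameter_set()`; published
ICER values are not reproduced, but every structural property of the
analysis is.

## Worked example

Strategy `M7 222`: MPMRI (definition 2, cut-off ≥2) for all men; MRI-targeted
TRUSB (histology definition 2) in men with a suspicion of CS cancer; repeat
MRI-targeted TRUSB when the first biopsy did not find CS cancer.

```r
library(pathcea)

perf <- packaged_performance_tables()
prev <- subgroup_prevalence(0.30, 0.20, 0.30, 0.20)  # synthetic case mix
d <- execute_strategy(parse_strategy_label("M7 222"), perf, prev)
referral_rates(d)
#>                            subgroup p_biopsy e_mpmri e_trusb e_tpmb
#> no_cancer                 no_cancer     0.93       1   1.860      0
#> low_risk                   low_risk     0.92       1   1.840      0
#> intermediate_risk intermediate_risk     0.98       1   1.235      0
#> high_risk                 high_risk     1.00       1   1.000      0
```

98% of intermediate-risk men, 92% of low-risk men, 93% of cancer-free men and
all high-risk men are referred to the first biopsy — the engine reproduces
the published referral percentages for this strategy exactly. Cancer-free men
who are referred always rebiopsy (a biopsy cannot find absent cancer), hence
the expected 1.86 TRUSBs.

A deterministic base case on a synthetic bundle, for a handful of strategies:

```r
bundle <- generate_parameter_set(synthetic_config(seed = 42))
run_base_case(bundle,
              strategies = c("M1 125", "T1 2", "T7 223", "M7 222", "P4 2"))
#>    label sensitivity detected testing_cost qalys lifetime_cost qaly_frontier qaly_icer
#> 1 M1 125      0.3861   0.1930        503.7 9.215          9600         FALSE        NA
#> 2   T1 2      0.7479   0.3740        445.6 9.450          9332          TRUE        NA
#> 3 T7 223      0.9367   0.4683        851.0 9.529          9711          TRUE      4770
#> 4 M7 222      0.9722   0.4861       1055.3 9.544          9910          TRUE     13318
#> 5   P4 2      1.0000   0.5000       1273.2 9.551         10125          TRUE     31806
```

Reading the table: `P4 2` (TRUSB for all, TPMB for anyone without a CS
finding) is perfectly sensitive but most expensive; `M1 125` is dominated;
the remaining strategies form a cost-effectiveness frontier whose ICER
sequence strictly increases (£/QALY versus the next-best member to the
left). At a £20 000/QALY threshold the net-benefit-maximising strategy here
is `M7 222`. The QALY and cost magnitudes follow the synthetic bundle, not
the published supplementary inputs.

`run_psa()`, `ceac_ceaf()` and `frontier_probability()` propagate parameter
uncertainty; `calibrate_transitions()` fits Markov transitions to survival
targets; `run_scenario()` re-runs the pipeline under parameter overrides.
See `vignette("diagnostic-pathway-cea")` for the model, its assumptions and
the design decisions.

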