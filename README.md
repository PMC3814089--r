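# petsep

Separation of dynamic PET whole-tissue time-activity curves into blood, EES
and EIS components using DCE-MRI-derived volume fractions, and kinetic
modelling of the separated curves.

## The problem

A dynamic PET voxel measures one whole-tissue time-activity curve (TAC): the
volume-weighted mixture of the tracer concentration in whole blood, the
extravascular-extracellular space (EES) and the extravascular-intracellular
space (EIS),

    C_tissue(t) = v_b C_b(t) + v_EES C_EES(t) + v_EIS C_EIS(t).

DCE-MRI measures exactly those volume fractions (extended Tofts model:
Ktrans, v_EES, v_p, with v_b = v_p/(1 − Hct) and v_EIS closing the
partition), and MRI voxels are much smaller than PET voxels. Within a 5×5
window of MRI voxels the compartment curves can be taken as shared while the
fractions vary per voxel, so the window stacks into an overdetermined linear
system C_tissue = A·C whose least-squares (pseudoinverse) solution recovers
the three compartment TACs — including a local arterial input function. The
separated curves then drive a direct fit of the three-physical-compartment
model

    dC_EES/dt = K1·Cp − (k2+k3)·C_EES + k4·C_EIS
    dC_EIS/dt = k3·C_EES − k4·C_EIS

whose analytic solution is biexponential in the eigen-rates α1, α2 of the
tissue subsystem; both curves are fitted simultaneously over (K1, k2, k3,
k4). The package is aimed at quantitative-imaging researchers studying
PET/MR kinetic analysis: it provides the forward models, the window
separation, the simultaneous fit, Lin's concordance correlation coefficient
(CCC), and a fully seeded Monte-Carlo framework quantifying accuracy against
tissue noise and against volume-fraction error.

## Worked example

Simulate one 25-voxel window realization at baseline noise (multiplier 1)
with 5% volume-fraction error, separate it, and refit the rate constants:

```r
library(petsep)
cfg <- study_config(n_realizations = 1, seed = 7)
out <- run_single_realization(cfg, noise_multiplier = 1, dce_error_pct = 5)
print(out$truth$params)
#> <pet_params> K1=0.4088 mL/min/g, k2=0.4819, k3=0.1402, k4=0.1628 1/min (alpha1=0.1176, alpha2=0.6673)
round(out$ccc, 4)
#>     Cb  C_EES  C_EIS
#> 0.9900 0.9996 0.9982
print(out$fit)
#> <fit_result> converged after 14 iterations (start 1), SSR = 1.19085e+09
#> <pet_params> K1=0.4711 mL/min/g, k2=0.5269, k3=0.154, k4=0.1827 1/min (alpha1=0.1315, alpha2=0.7321)
#>   relative error (%): K1=15.2, k2=9.35, k3=9.89, k4=12.2
```

The three CCC values compare each separated curve with its truth over the
full time course: at this noise level all three are concordant above 0.99,
with the blood curve — the most noise-amplified component, since v_b spans
only 0.04–0.12 — the lowest. The refitted rate constants land within
9–16% of the generating values; errors grow with tissue noise and with
volume-fraction error, which the sweep drivers quantify:

```r
res <- run_noise_sweep(study_config(n_realizations = 200, seed = 1))
plot_ccc_sweep(res)     # CCC vs noise multiplier, mean with min-max band
plot_error_sweep(res)   # parameter error vs noise, mean +/- SE
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/petsep.R` (subcommands `simulate`, `separate`, `fit-pet`,
`fit-dce`, `metrics`).

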