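# micrograze

Estimation and evaluation of microzooplankton grazing mortality rates.

Grazing by phagotrophic protists is the dominant loss process for
picophytoplankton such as *Prochlorococcus* in oligotrophic oceans, yet the
two field methods used to measure it for decades — the **dilution
technique** and the disappearance of **fluorescently labeled bacteria
(FLB)** — are rarely checked against conditions where the true mortality
rate is known. `micrograze` implements both estimators, plus the direct
"observed mortality" benchmark, and pairs them with a deterministic
prey–grazer–virus–bacteria community simulator whose loss ledger provides
exact true rates. That makes it possible to characterize estimator
accuracy and precision under controlled conditions, and to reproduce the
known failure modes of each method (saturated grazer feeding for the
dilution technique, surrogate-prey selectivity for FLB).

The intended audience is aquatic microbial ecologists who run or interpret
grazing-rate experiments, and method developers who want a virtual testbed.

## The three rate computations

All rates are per day; abundances are cells mL⁻¹.

- **Apparent growth** in a bottle: `k = ln(N_t / N_0) / t`.
- **Dilution technique** (Landry–Hassett): a dilution series at fractions
  `D` of whole water is incubated; Model I (OLS) regression of `k` on `D`
  gives `k = μ − m·D`. The intercept `μ` estimates grazer-free growth and
  `m = −slope` the grazing mortality rate. A non-significant or positive
  slope is a non-detect, reported as 0. A two-point variant uses only the
  two most dilute bottles (`D` = 0.2 and 0.4 in the laboratory design).
- **FLB disappearance**: tracer decay `g = −ln(F_t / F_0) / t` in grazed
  bottles, minus the mean decay rate in grazer-free control bottles
  (non-grazing losses such as wall adsorption).
- **Observed mortality**: the same decay form applied directly to prey
  counts in the undisturbed culture over the identical time window.

Every experiment is indexed by the log-mean prey abundance
`P̄ = (P₂ − P₁)/(ln P₂ − ln P₁)`, the time-averaged abundance under
exponential change. The comparison pipeline computes percent differences
`100·(estimated − observed)/observed`, removes outliers with Tukey
fences (1.5 × IQR by default), bins by `log₁₀ P̄`, aligns abundance curves
at a reference abundance (log₁₀ = 5.6) to compare crash shapes, and
summarizes groups as mean ± SE with Welch, Wilcoxon (Bonferroni-adjusted)
and Kruskal–Wallis tests.

## Worked example

Run one paired experiment under ideal conditions (prey far below the
grazer's half-saturation abundance, unselective tracer, Poisson counting
noise; the true grazing rate is `c_max · G = 1 d⁻¹`):

```r
library(micrograze)
sc <- scenario("linear_regime")
ex <- run_experiment(sc, t_start = 0, duration = 0.5,
                     sampling = sampling_model(1, "poisson", seed = 1))
ex$dilution
#> <dilution> 0.9856 d^-1 (se 0.00927, n 12, p 1.33e-16), mean log10 P = 4.95
ex$flb
#> <flb> 0.9852 d^-1 (se 0.00599, n 3, p 3.69e-05), mean log10 P = 4.95
ex$observed
#> <observed> 0.4955 d^-1 (se 0.00265, n 3, p 2.86e-05), mean log10 P = 4.95
ex$truth$grazing
#> [1] 1.000002
```

Both estimators recover the true grazing rate of 1 d⁻¹ to within ~1.5%.
The observed rate is the *net* prey loss (grazing 1 d⁻¹ minus intrinsic
growth 0.5 d⁻¹ ≈ 0.5 d⁻¹), which is why grazing-specific estimators are
compared against truth via the ledger rather than against net decline
alone. `scenario("saturated")` and `scenario("selective_flb")` reproduce
the failure modes: under saturated feeding the dilution slope collapses
(grazing is underestimated, typically to a non-detect), and a tracer
cleared at one tenth the rate of natural prey yields FLB estimates near
one tenth of truth — roughly the order-of-magnitude method gap the field
comparison scenarios show.

A subcommand CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","micrograze.R",package="micrograze"))')" \
    make-fixtures --scenario lab_high_grazer --seed 3 --out out/
```

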