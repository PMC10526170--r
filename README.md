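# tumorHDC

Hybrid discrete-continuum (HDC) modelling of glioblastoma tumoroid
growth and invasion in a collagen matrix that is softened by
collagenase perfused from a surrounding channel.

A tumoroid embedded in fibril collagen invades in two modes at once: a
*ring* of collectively migrating cells expanding from the tumoroid, and
*fingers* — individual cells that detach from the ring and run ahead of
it. Supplying collagenase (MMP1) through the channel degrades the
collagen near the rim, and invasion increases with the dose. `tumorHDC`
is for modellers who want a small, fully reproducible simulator of this
system: continuum reaction–diffusion fields coupled to a discrete cell
walk, invasion metrics, a synthetic chip-experiment generator, and a
calibration loop for the degradation kinetics.

## The model

Four fields on a polar grid over the chamber (cells $C_p$, nutrient
$n$, collagenase $M$, collagen $f$):

$$
\begin{aligned}
\partial_t C_p &= \nabla\!\cdot\!\left(D_i \nabla C_p
  - \chi_{hap} C_p \nabla f\right) + \eta_p(n)\,C_p, &
\partial_t n &= D_n \nabla^2 n - \lambda(C_p, n),\\
\partial_t M &= D_M \nabla^2 M - \zeta M f, &
\partial_t f &= -\delta M f,
\end{aligned}
$$

with Monod growth gated by a packing-stress proxy, Dirichlet boundary
values on the rim (nutrient supply, enzyme dose, absorbing for cells),
and an axisymmetric default. Individual invading cells are a biased
random walk on the same lattice whose five-way movement probabilities
are the central-difference stencil coefficients of the cell equation —
so the walk's drift and diffusion match the continuum physics by
construction. Cells are shed from the invasive front with probability
proportional to the local cell density and collagen gradient, which
makes the expected finger count scale with the enzyme dose. Parameter
defaults are the published table for this system ($D_i = 10^{-8}$
cm²/s, $\chi_{hap} = 2.6\times10^3$ cm² s⁻¹ M⁻¹,
$\delta = 10^{-2}$ s⁻¹ M⁻¹, ...); doses in mg/mL are converted to
molar boundary values via a configurable molar mass (55 kDa default).
See `vignette("hdc-model")` for the full account, including the
numerical scheme and the reasoning behind every free default.

## A worked example

Three doses, three seeded replicates each, day-3 invasion metrics:

```r
library(tumorHDC)

cfg <- hdc_config()                       # published defaults
sw  <- sweep_collagenase(cfg, doses = c(0, 0.001, 0.01), replicates = 3)
m3  <- metrics_at_days(sw, 3)
aggregate(cbind(L_overall_um, L_ring_um) ~ dose_mg_per_ml, data = m3, FUN = mean)
```

```
  dose_mg_per_ml L_overall_um L_ring_um
1          0.000     1663.718  1663.718
2          0.001     2644.832  1663.718
3          0.010     2800.387  1663.719
```

Untreated tumoroids only form a ring (≈1.66 mm in three days at these
parameters); under enzyme, fingers overtake the ring and the overall
invasion length increases with dose. A single run exposes everything
else:

```r
cfg$boundary$m0 <- dose_to_molar(0.01)    # 1.82e-7 M
sim <- run_hybrid(cfg, seed = 1)
tail(sim$metrics[, c("day", "L_ring", "L_finger", "pattern")], 3)
write_outputs(sim, "run1")                # metrics.csv, tracks.csv,
                                          # snapshots/, manifest.json
```

The synthetic chip experiment and the calibration loop:

```r
d <- generate_experiment(synth_spec(seed = 1))
compare_conditions(d, 0.001, 0.01, day = 1)   # one-sided permutation test

cfg <- recovery_config(seed = 5)
dat <- simulate_experiment(cfg, c(0.001, 0.01),
                           days = c(1.5, 2, 2.5, 3), replicates = 2)
fit_degradation_rate(dat, cfg)$estimate       # recovers delta ~ 1e-2
```

A thin command line sits over the same functions:

```sh
Rscript inst/cli/hdc.R sweep --doses 0,0.001,0.01 --replicates 3 --out sweep.csv
Rscript inst/cli/hdc.R synth --out synth.csv --seed 4
```

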