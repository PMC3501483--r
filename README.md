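# chr2pore

Analysis chain for light-evoked channelrhodopsin-2 (ChR2) photocurrents
recorded by two-electrode voltage clamp (TEVC), for anyone asking the
question that motivates alkali-substitution experiments: **how wide is
the narrowest part of the pore, and how do mutations change it?**

The package takes raw current sweeps (time, current, holding potential,
light window, construct/cell/day/solution metadata, organized by a JSON
manifest) through four stages:

1. **Trace kinetics** — sweep segmentation around the light window;
   mono/biexponential fits giving apparent `tau_on`, `tau_decay`,
   `tau_off`; peak and stationary currents; the inactivation ratio
   `I_ss/I_p`; same-day wild-type normalization.
2. **Reversal potentials** — stationary-current I–V assembly per
   construct and solution; `E_rev` by piecewise-linear zero crossing;
   shifts `dErev = E_rev,X − E_rev,Na` under bi-ionic substitution.
3. **GHK permeability** — the Goldman–Hodgkin–Katz relation
   `P_x/P_Na = exp(z F dErev / RT)` for equal-concentration
   substitution, with the full multi-ion GHK voltage equation available
   for simulation and validation.
4. **Excluded-volume pore size** — ordinary least squares of
   `sqrt(P_x/P_Na)` on dehydrated ionic radius `R_x`,

   ```
   sqrt(P_x/P_Na) = a + b R_x
   d_min = 2a/|b|          (minimum pore diameter)
   R_Na  = (1 − a)/b       (apparent permeating sodium radius)
   ```

Because no recordings are deposited for studies of this kind, the
package ships a first-class synthetic generator: a four-state
photocycle (C1 → O1 ⇄ O2 → C2 → C1) integrated as a linear ODE, an
envelope-times-constant-field current model with inward rectification,
Gaussian recording noise and log-normal per-cell expression scatter,
and a ground-truth sidecar (true permeabilities, reversal potentials,
pore radii, off-decay eigen-taus) so every stage is testable by exact
round trip. See `vignettes/chr2pore-methods.Rmd` for the models and
all conventions.

## Worked example

```r
library(chr2pore)

# pore geometry from a published-style regression line
fit <- list(a = 1.37, b = -0.44)
cat(sprintf("d_min = %.2f A, R_Na = %.2f A\n",
            pore_diameter(fit), sodium_radius(fit)))
#> d_min = 6.23 A, R_Na = 0.84 A

# simulate a small wild-type study and recover its ground truth
cfg <- study_config(constructs = c(WT = 3.11), n_cells = 1,
                    protocol = protocol_spec(sample_rate_Hz = 2000),
                    expression_cv = 0)
dir <- file.path(tempdir(), "study")
generate_study(cfg, seed = 1, out_dir = dir)
report <- run_pipeline(file.path(dir, "manifest.json"))
report$permeability[, c("ion", "ratio", "delta_erev_mV")]
#>   ion     ratio delta_erev_mV
#> 1  Cs 0.4470292    -20.338988
#> 2   K 0.6847878     -9.565249
#> 3  Li 1.3737804      8.022268
#> 4  Rb 0.5813331    -13.702739
report$pore[, c("a", "b", "r2", "d_min_A", "R_Na_est_A")]
#>          a          b        r2  d_min_A R_Na_est_A
#> 1 1.451882 -0.4652555 0.9996407 6.241225   0.971256
```

The simulated wild type was generated from a true pore radius of
3.11 Å (diameter 6.22 Å) with sodium at 0.98 Å; the pipeline recovers
6.24 Å and 0.97 Å from the default noisy protocol — the residual ~0.3%
comes from the 20 mV interpolation grid. Cs⁺ is about 2.2-fold less
permeant than Na⁺ (`dErev ≈ −20 mV`), Li⁺ slightly more permeant, the
size-selectivity signature the regression turns into a diameter.

## The analysis scripts

`analysis/01_simulate.R` … `analysis/04_pore_size.R` run the same chain
as a narrated workflow on a three-construct synthetic study (wild type
plus a pore-constricted and a pore-widened variant), writing raw sweeps
under `scratch/` and derived tables (kinetics, reversal shifts,
permeability ratios, pore fits) under `results/tables/`. Run them in
order from the repository root.

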