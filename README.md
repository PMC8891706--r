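# mossreactor

Kinetic modelling of recombinant biopharmaceutical production in moss
photobioreactors.

Suspension cultures of the moss Physcomitrella (*Physcomitrium patens*)
grow autotrophically in stirred-tank photobioreactors and are used to
produce complex recombinant proteins such as the synthetic complement
regulator MFHR1. Process development for such cultures needs a dynamic
model: when does nitrate run out, when does the culture shade itself into
light limitation, what does a feed or a daily medium exchange do to
product yield, and can the rate constants be estimated from a handful of
daily samples?

`mossreactor` answers these questions with an unstructured kinetic model:

* **Growth** — Monod kinetics in nitrate and in light, combined by the
  minimum (threshold) law:
  `r_X = min( r_X,max·c_N/(c_N+k_N), r̄_X,I )`, with nitrate uptake slaved
  to growth through the biomass yield, `r_N = r_X / y_X,N`.
* **Light** — Beer–Lambert attenuation in a homogeneously side-illuminated
  cylinder; the mean intensity at radius *a* averages
  `I_0·exp(−σ_X·c_X·p(a,θ))` over all arrival angles along the chord
  `p(a,θ) = −a·cosθ + √(r_R² − a²sin²θ)`, and the light-limited rate is
  the volume average of the local Monod rate.
* **Product** — formation Monod in nitrate (`r_p = r_p,max·c_N/(c_N+k_p)`),
  first-order degradation (`r_p,d = k_pd·c_P`).
* **Reactor** — mass balances for biomass, nitrate, product and volume
  under batch, fed-batch (D = F/V), and semi-continuous operation, the
  latter either as a continuous dilution rate D or as discrete daily
  harvest-and-refill events with a cumulative harvest ledger.
* **Estimation** — bounded global least squares by differential evolution
  (seeded, bit-reproducible) with per-variable residual scaling and
  per-variable R², plus a synthetic-data generator that reproduces the
  study's measurement structure (daily sampling, duplicate measurements,
  multiplicative noise) for parameter-recovery studies.

The methods vignette (`vignettes/moss-bioreactor-kinetics.Rmd`) documents
the model, the numerical choices and the identifiability analysis.

## Worked example

Simulate a producer-line batch run (0.1 g DW/L inoculum, 500 mg/L nitrate,
5 L, 350 µmol m⁻² s⁻¹):

```r
library(mossreactor)

params <- kinetic_params(r_X_max = 0.699, k_N = 4.41, k_I = 15.29,
                         y_X_N = 7.042, r_p_max = 0.327, k_p = 1.010,
                         k_pd = 0.0801)
optics <- optical_geometry(sigma_X = 0.049, radius_cm = 8.75,
                           incident_light = 350)
schedule <- operation_schedule("batch", t_end = 8,
                               initial = reactor_state(c_X = 0.1, c_N = 500,
                                                       c_P = 0, V = 5))
simulate_reactor(params, optics, schedule, output_times = 0:8)
#> <moss_trajectory> batch run, 9 time points over 8 d
#>   time_d biomass_gDW_per_L nitrate_mg_per_L product_mg_per_L volume_L
#> 1      0            0.1000            500.0          0.00000        5
#> 2      1            0.1922            486.9          0.04583        5
#> 3      2            0.3624            462.7          0.13168        5
#> 4      3            0.6538            421.4          0.28536        5
#>   ...
#>   final: c_X = 3.22 g/L, c_N = 56.6 mg/L, c_P = 2.27 mg/L
#>   total product formed (in-vessel + harvested): 11.3 mg
```

Biomass grows at ~0.66 d⁻¹ while light limits, decelerates as the culture
shades itself, and approaches its nitrate-set ceiling
(`c_X0 + y_X,N·c_N0/1000 = 3.62 g/L`) as nitrate is exhausted; about 11 mg
of product accumulate in the 5 L vessel over 8 days.

Recover parameters from synthetic data for the parental (non-producing)
line — the generate → fit pipeline behind the recovery studies:

```r
fx <- builtin_fixtures()[["parental-batch"]]
ds <- generate_observations(fx, noise_model(cv = 0.05, replicates = 2, seed = 7))
fit_kinetics(ds, free = c("r_X_max", "k_N", "y_X_N"),
             bounds = recovery_bounds(fx$params, c("r_X_max", "k_N", "y_X_N")),
             base_params = fx$params, optics = fx$optics, seed = 11)
#> <moss_fit>
#>   datasets: parental-batch
#>   objective: 0.019639  (stagnated for 80 generations after 225 generations, 10170 evaluations)
#>   estimates:
#>     r_X_max  = 0.698   (bounds 0.0699 .. 6.99)
#>     k_N      = 24.95   (bounds 0.358 .. 35.8)
#>     y_X_N    = 9.613   (bounds 0.9615 .. 96.15)
#>   R^2: biomass = 0.999, nitrate = 0.998
```

The growth rate (0.698 vs 0.699 d⁻¹) and yield (9.613 vs 9.615 g/g) come
back within a fraction of a percent at 5% measurement noise; the nitrate
half-saturation constant `k_N` does not — nitrate never falls into its
sensitive range during the sampled window, a structural identifiability
limit discussed in the vignette.

A YAML-config command-line wrapper for the same pipeline ships in
`inst/cli/mossreactor.R` (subcommands `simulate`, `generate`, `fit`).

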