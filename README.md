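# slopespec

Nondestructive hemoglobin quantification in flexible blood bags from
VIS-NIR transmission spectra measured at several optical pathlengths.

PVC blood-bag walls attenuate 40–60% of transmitted light, scatter
strongly, and vary in thickness between batches, so a calibration built
on a transmission spectrum at one fixed plate separation inherits the
wall as a nuisance. `slopespec` implements the packaging-robust
alternative: squeeze the bag to several total thicknesses
$l = 4.2, 3.8, 3.4, 3.0$ mm, and per wavelength fit

$$\ln I_o^\lambda = a^\lambda l + b^\lambda .$$

Under the modified Beer–Lambert law
$\ln I_o^\lambda = \ln I_i^\lambda - \varepsilon^\lambda c\,(d_0 - 2d_1)\,B^\lambda - G$,
the unknown wall loss $G$ and wall thickness $d_1$ are constant across
plate separations and land in the intercept; the slope
$a^\lambda \approx -\varepsilon^\lambda c B^\lambda$ carries the analyte
signal with the wall cancelled. The slope spectrum
$[a^{\lambda_1},\dots,a^{\lambda_W}]$ feeds a PLSR calibration
$\mathbf{Y} = \mathbf{X B} + \mathbf{B}_0$ against hemoglobin
concentration, with RMSEC/RMSEP and $R^2$ as figures of merit. Curve
families are compared with the difference coefficient
$DC(P,Q) = \sum_i (p_i-q_i)^2 / \sqrt{\sum_i (p_i-\bar p)^2 \sum_i (q_i-\bar q)^2}$.

The package provides:

* **`montecarlo`** — an MCML-style layered photon-transport simulator
  (Henyey–Greenstein scattering, Fresnel boundaries, Russian roulette,
  NA-limited fiber detection) with exact correlated re-weighting across
  absorption grids and a local detector estimator, driving the
  simulation study that motivates the slope method;
* **`slopespec`** — multi-pathlength containers, per-wavelength
  least-squares slope extraction, and the difference coefficient;
* **`forward_model`** — the modified Beer–Lambert forward model and a
  seeded synthetic generator emulating the bench protocol (60 samples,
  72–161 g/L, 40/20 split, per-sample wall thickness and wall loss, an
  optional +0.3 mm film perturbation);
* **`chemometrics`** — deterministic NIPALS PLSR with cross-validated
  component selection;
* **a pipeline and CLI** — experiment runners, CSV/JSON persistence, and
  `inst/cli/slopespec` with subcommands `slopes`, `simulate`, `synth`,
  `train`, `evaluate`, `report`.

## Worked example

Generate a synthetic study and compare the slope-spectrum calibration
(Model 1) against a single-thickness calibration (Model 2), evaluating
both on matched (protocol 1) and perturbed (protocol 2: +0.3 mm film,
larger wall loss) prediction sets:

```r
library(slopespec)
rep <- run_model_comparison(synthetic_config(), n_samples = 60, seed = 11)
print(as.data.frame(rep), row.names = FALSE)
#>          model dataset                 role        r2       rmse n_components
#>   model1_slope      S1          calibration 0.9997801  0.3535715            1
#>   model1_slope      S1   prediction_matched 0.9993021  0.5350818            1
#>   model1_slope      S2 prediction_perturbed 0.9994447  0.4773076            1
#>  model2_single      A1          calibration 0.9171357  6.8638869            2
#>  model2_single      A1   prediction_matched 0.8661653  7.4097697            2
#>  model2_single      A2 prediction_perturbed 0.2541230 17.4925797            2
```

Both models calibrate well on matched data, but under the film
perturbation the single-thickness model's error balloons (here to
17.5 g/L) while the slope model is untouched (0.48 g/L): the slope
spectrum is exactly invariant to additive log-domain wall losses, which
is the point of the method.

The transport side, at interactive scale:

```r
st <- bag_stack(d1_mm = 0.5, mus1 = 75, mua2 = 0.35, d2_mm = 4.0)
run_mc(st, settings = mc_settings(n_photons = 1e5, seed = 1))
#> <mc_result> n = 100000 photons
#>   detected  0.00276059 (se 3.6e-05)
#>   transmit  0.0636066
#>   reflect   0.617629
#>   absorb    0.318765
```

`run_simulation_study()` sweeps the absorption grid 0.35–1.55 cm⁻¹ and
liquid thicknesses 3.0–5.0 mm for three wall configurations, extracts
intensity and slope curves, and reports the difference coefficients
between them; see the vignette for the study design and a discussion of
which reference contrasts it does and does not reproduce.

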