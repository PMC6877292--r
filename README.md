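# bbbflux

Quantification of blood–brain barrier (BBB) permeability from two-photon
time-lapse fluorescence imaging, for labs that probe the barrier in vivo
with intravenous tracers.

Two transport routes are scored:

* **Paracellular leak.** After a bolus of a free dye, the parenchymal
  fluorescence rises as tracer crosses the barrier.  With blood
  concentration $B(t) = C_0 e^{-\lambda t}$ and leak rate $k$ (per min),
  the parenchymal signal follows
  $P(t) = \tfrac{kC_0}{\lambda}(1 - e^{-\lambda t})$.  The leak score is
  the area under the curve (AUC) of the relative fluorescence increase
  $(F_t - F_0)/F_0$ over a 30-min window, in minutes.  When several dyes
  are injected sequentially into one detection channel, later traces are
  **decoupled** from earlier dyes by subtracting extrapolated exponential
  fits — fluorescence is additive, so the correction removes each
  predecessor's bounded worst-case contribution.
* **Transcytosis.** Albumin conjugate accumulates as discrete vesicle
  puncta on vessel walls.  The score is the cumulative vesicle surface
  density — distinct puncta per 100 µm² of vessel surface
  ($\pi d L$) — per microvessel category (pial arteriole/venule,
  penetrating arteriole, ascending venule, post-capillary venule,
  capillary), with its kinetics over a 2-h session.

Because in vivo recordings come with no ground truth, the package also
ships a **synthetic-data generator**: vessel trees rendered into 16-bit
TIFF hyperstacks with two-compartment tracer kinetics, Poisson vesicle
events, constant autofluorescence and Poisson + Gaussian noise — all with
known parameters, so every pipeline stage is validated by parameter
recovery.  A statistical layer reproduces the study-style tests:
normality-gated Welch / Mann-Whitney comparisons and log-transformed
one-way ANOVA with Tukey contrasts for electron-microscopy morphometry.

## Worked example

Simulate a three-tracer session (10-kDa FITC-dextran, Alexa Fluor 488,
sodium fluorescein, injected at ~30-min spacing into a shared channel) and
score it end to end:

```r
library(bbbflux)

truth <- groundTruth()               # leak & clearance rates, noise model
sched <- tracerSchedule()            # FITC-dx -> AF488 -> NaFluo
rs <- runParacellularSession(truth, sched, seed = 1, noise = FALSE)
sapply(rs$analysis$results, function(r) r@aucMin)
#>    FITC-dx      AF488     NaFluo
#> 0.01823038 0.90007666 4.60013992
```

The dextran barely leaks (AUC ≈ 0.02 min), the small dyes accumulate
appreciably (0.90 and 4.60 min) — the size-selectivity pattern of an
intact barrier; a leakier barrier raises these scores in proportion to its
leak rate.  Each `PermeabilityResult` carries the corrected relative
trace, the correction fits applied, and the blood decay fit.

The transcytosis arm, on a simulated albumin-conjugate session:

```r
rv <- runVesicleSession(groundTruth(), seed = 3)
head(rateRecovery(rv$analysis$records), 3)
#>                category slope_per_100um2_per_min
#> 1        pial_arteriole               0.002399326
#> 2           pial_venule               0.002837684
#> 3 penetrating_arteriole               0.002158505
```

per-category density slopes (puncta per 100 µm² per min) recovered from
automated wall-punctum detection, to compare against
`truth$vesicleRatePer100um2PerMin`.

Group statistics:

```r
percentDifference(0.078, 0.071)   # 9.86  (% endothelial thickening)
foldRatio(0.30, 0.099)            # 3.03  (penetrating vs pial density)
```

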