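# glxquant

Quantification of the glomerular endothelial glycocalyx (GEnGlx) and
filtration-barrier function from three kinds of imaging readouts, with a
synthetic-data module that generates every input with known ground truth.

## Who this is for

Renal physiology and microvascular imaging groups that measure glycocalyx
damage (e.g. in diabetic nephropathy models) with:

1. **Fluorescence peak-to-peak analysis** — two-channel confocal images of a
   capillary loop, one channel a glycocalyx-binding lectin (MOA / WGA /
   UEA-I), the other a membrane dye (R18). A profile line drawn from the
   lumen outward crosses the lectin peak first, then the membrane peak;
   Gaussian curves are fitted to each channel's intensity profile and the
   signed distance between the fitted centres (peak-to-peak, μm) indexes
   glycocalyx thickness. The automated mode places **200 perpendicular
   lines per loop** along the extracted membrane contour; the manual mode
   consumes 3 hand-drawn ROI segments per loop. Loops are excluded when the
   SD of their line values exceeds 7.5 (in an explicitly configured unit)
   and/or the signal-to-noise ratio falls below 15; retained loops are
   averaged loop → glomerulus → subject → group (unweighted mean of means).
2. **TEM morphometry** — grid-intersection annotation tables: glycocalyx
   thickness (Euclidean distance, nm, from the luminal phospholipid to the
   farthest glycocalyx point), coverage (% of intersections with thickness
   strictly above 10 nm; exactly 10 nm counts as uncovered), GBM /
   foot-process / slit widths, and linear densities (count per μm GBM).
3. **Albumin permeability (Ps′_alb)** — a trapped glomerulus is switched to
   unlabelled albumin at t = 0 and the luminal fluorescence decline over the
   first minute gives the rate k (ordinary least squares on I(t)/I(t0),
   window-bias corrected); permeability follows from the cylindrical
   volume-to-surface ratio, Ps′_alb = k·r/2.

The model behind the synthetic images: each channel is an ideal circle
(membrane radius R; glycocalyx radius R − Δ with Δ the true offset) blurred
by an isotropic Gaussian PSF, so the true peak positions are known
analytically; decay traces follow I(t) = I∞ + (I0 − I∞)·e^(−kt) with
k = 2·Ps/r.

## Worked example

```r
library(glxquant)

## simulate a two-group cohort: 2 subjects x 2 glomeruli x 3 loops each,
## true glycocalyx offsets 0.40 um (control) vs 0.20 um (diabetic), 2% noise
groups <- data.frame(label = c("control", "diabetic"),
                     mean_offset_um = c(0.40, 0.20),
                     sd_um = c(0.02, 0.02), n_subjects = c(2, 2))
spec <- cohort_spec(groups, glomeruli_per_subject = 2, loops_per_glomerulus = 3,
                    loop_params = loop_truth(noise_model = "gaussian",
                                             noise_sd_frac = 0.02),
                    seed = 42)
make_cohort(spec, "demo")

## run the automated 200-line peak-to-peak pipeline
out <- run_p2p(list(images = list(manifest = "demo/manifest.csv",
                                  seeds = "demo/seeds.csv"),
                    out_dir = "demo/out"))
out$subject
#>      group   subject_id mean_value n
#> 1  control  control_S01      0.400 2
#> 2  control  control_S02      0.386 2
#> 3 diabetic diabetic_S01      0.178 2
#> 4 diabetic diabetic_S02      0.178 2
out$group
#>      group mean_value n
#> 1  control      0.393 2
#> 2 diabetic      0.178 2
```

Subject means are the mean of glomerulus means, each the mean of its
QC-retained loops; they recover the simulated offsets (0.40/0.38 true for
the control subjects, 0.18/0.18 for the diabetic ones at this seed).

```r
## permeability from a noisy synthetic decay trace (truth: 0.025 um/s)
tr  <- make_decay_trace(decay_truth(ps_true = 0.025, radius = 5,
                                    noise_sd = 20, seed = 7))
fit <- fit_initial_decline(tr)            # first-minute linear fit
ps_alb_from_decline(fit, radius = 5)
#> k = 0.00966 1/s   Ps_alb = 0.0242 um/s (2.42e-06 cm/s)
```

A command-line wrapper lives at `inst/cli/glxquant.R`
(`Rscript glxquant.R p2p --config run.yaml`), with subcommands `p2p`,
`tem`, `perm` and `simulate-*`.

## Documentation

The methods vignette (`vignettes/glxquant-methods.Rmd`) describes the
measurement model, QC rules, the synthetic-data generators and their
limitations, and the numerical choices (fitting, bias correction,
tie-breaking) in detail.
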