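# mitograd

Quantifying membrane-potential gradients across the inner mitochondrial
membrane from dual-channel super-resolution images.

## The problem

The inner mitochondrial membrane (IMM) is split by crista junctions into
two electrically distinct compartments: the cristae membrane (CM), which
houses the proton pumps and carries the more negative potential
&Delta;&Psi;<sub>C</sub>, and the inner boundary membrane (IBM) apposed to
the outer membrane, at &Delta;&Psi;<sub>IBM</sub>. A cationic
potential-sensitive dye such as TMRM distributes between the two
compartments according to these potentials — concentrating in the cristae
at low load and spilling over to the IBM as the cristae saturate — while a
potential-insensitive reference dye (MitoTracker Green, MTG) marks the
geometry. Mitochondria are only ~200–300 nm across, so the readout needs
SIM-class resolution (~100–140 nm) and metrics that work below the
single-crista limit.

`mitograd` implements the two readouts that make this dye redistribution
measurable in living cells, plus everything needed to validate them end to
end on synthetic data with known ground truth:

- **IBM association index** — the reference channel is Otsu-thresholded;
  one binary erosion yields a *core* (CM proxy) mask and two dilations
  minus the core yield a hollow *rim* (IBM proxy) mask. The index is
  `mean(object intensity in rim) / mean(object intensity in core)`.
  Higher values mean more dye at the boundary membrane.
- **&Delta;FWHM** — width-averaged cross-section intensity profiles are
  measured in both channels at identical coordinates, their full widths at
  half maximum located by linear interpolation (subpixel), and
  `delta = FWHM_TMRM − FWHM_MTG`. Negative values mean the
  potential-sensitive dye runs narrower than the reference, i.e. is
  cristae-concentrated.

Around the metrics sit particle morphometrics in the ImageJ convention
(count *c*, area *a*, perimeter *p*, fitted-ellipse axes *x*, *y*, aspect
ratio `AR = y/x`, form factor `FF = p² / (4π·a)`), per-frame trace
assembly with baseline normalization and ordinary least-squares
correlation, fission-event detection by label-overlap tracking, and a
generative model of two-channel mitochondria images (Nernstian dye
partitioning with a saturable cristae cap, SIM-scale Gaussian PSF, shot
and read noise, histamine-, oligomycin- and fission-style protocols).

## Worked example

Simulate a calcium-stimulation time lapse (cristae hyperpolarize after the
stimulus at t = 20 s, so dye shifts from the boundary membrane into the
cristae), then measure everything per frame:

```r
library(mitograd)

scene  <- synthetic_scene(seed = 42)
sim    <- simulate_timelapse(scene, protocol_histamine(n_frames = 10, dt = 10, t_stim = 20))
traces <- compute_traces(sim$timelapse, atp = sim$truth$atp)
round(traces[, c("t", "ibm_index", "delta_fwhm_px", "c", "mean_ar", "mean_ff")], 4)
#>   t ibm_index delta_fwhm_px c mean_ar mean_ff
#>   0    0.3242       -0.0412 3  7.3063  2.7043
#>  10    0.3268       -0.0062 3  7.3294  2.7056
#>  20    0.3261       -0.0265 3  7.3578  2.7205
#>  30    0.3162       -0.0863 3  7.3043  2.7015
#>  40    0.3115       -0.1698 3  7.3388  2.7193
#>  50    0.3085       -0.1422 3  7.3213  2.7070
#>  60    0.3122       -0.1920 3  7.3522  2.7249
#>  70    0.3093       -0.1764 3  7.3569  2.7180
#>  80    0.3092       -0.1669 3  7.3251  2.7097
#>  90    0.3083       -0.1861 3  7.3380  2.7084
```

Both readouts fall after the stimulus — the IBM association index from its
0.3255 baseline by −0.0172, and &Delta;FWHM deeper into negative territory —
the signature of cristae hyperpolarization pulling dye inward. The index
co-varies with the simulated ATP rise:

```r
fit <- linear_fit(traces$ibm_index, traces$atp_proxy)
fit
#> <correlation_result> slope -9.826, intercept 4.207, R^2 = 0.846, p = 0.000166 (n = 10)
```

Single-frame pieces are available individually:

```r
fr    <- sim$timelapse$frames[[1]]
masks <- reference_masks(subtract_background(fr$reference))
masks
#> <mito_masks> whole 967 px, core 574 px, rim 1253 px (erode 1, dilate 2, otsu 4266)
ibm_association_index(subtract_background(fr$object), masks)
#> <ibm_index_result> index = 0.3242 (rim 86.05 / core 265.4; 1253/574 px)
```

Real two-channel stacks load from interleaved multi-page TIFF via
`load_stack()`; the same pipeline applies. A thin command line wraps the
workflow (`simulate`, `index`, `fwhm`, `morph`, `traces`, `correlate`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "mitograd.R", package = "mitograd"))') \
    simulate --protocol histamine --frames 10 --seed 42 --out scene.tif --truth truth.json
```

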