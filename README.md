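# spinescan

Estimating spinal tumor spread from single 2-D MRI-like slices, for image
analysts who need a fully inspectable, CPU-scale pipeline: entropy-based
saliency extraction, five-region spinal segmentation by combinable masks,
one tumor classifier per region, and a region-length-weighted aggregation of
the five calls into a cancer-spread probability, with a correlation gate
that controls continuous growth of the training pool. Every stage is
exercised end to end on a seeded synthetic spinal phantom generator that
ships with the package, so all results are reproducible without external
data.

## The model

For a slice with intensities in [0, 1], pixels are binned into *B* bins and
the slice entropy is the Shannon entropy of the bin distribution,
*H* = −Σ *p*(*v*) log₂ *p*(*v*). A pixel is foreground when its information
content −log₂ *p*(bin(*x*)) strictly exceeds *H*; everything else is
suppressed. The saliency map is split into the five spinal regions
(cervical, thoracic, lumbar, sacral, coccygeal) with per-region masks fused
as *a·B*(*p*) + *c·P*(*p*)^*f* + *d*^*f* and the segment transform
log(1 + SMI·mask), which is zero exactly outside mask support.

Each region's segment is scored by a classifier — leaky-ReLU convolution
banks, max pooling, variance-threshold feature selection
(*f*th = s̄·*p*v/(1−*p*v)), seven block statistics per retained map, and a
softmax head over {tumor, non-tumor}. With per-region pixel counts *N*ᵢ,
region lengths are *L*ᵢ = *N*ᵢ/Σ*N*, weights *W*ᵢ = *L*ᵢ/Σ*L*, and the
spread probability is Σ *T*ᵢ·*W*ᵢ (a variant divided by 5 is also recorded).
A batch of evaluated images joins the training pool only when the Pearson
correlation between obtained and actual spread probabilities exceeds 0.999.

## Worked example

```r
library(spinescan)

s <- generate_phantom(phantom_spec(tumor_regions = "lumbar",
                                   noise_sigma = 0.02, tumor_contrast = 0.4,
                                   seed = 4))
s
#> <phantom_sample> 96x64, tumors: lumbar, actual spread 0.250

sal <- extract_saliency(s$image)
sal
#> <saliency_result> 96x64, entropy 5.2075 bits, 2468 foreground px

seg <- segment_all_regions(sal, masks_from_labels(s$region_labels))
seg
#> <region_segmentation> pixel counts: cervical=304, thoracic=624, lumbar=384, sacral=144, coccygeal=80

w <- region_weights(region_lengths(seg))
round(w, 4)
#>  cervical  thoracic    lumbar    sacral coccygeal
#>    0.1979    0.4062    0.2500    0.0938    0.0521

spread_probability(setNames(as.numeric(s$tumor_status), SPINAL_REGIONS), w)
#> <spread_estimate> 0.2500 (normalized variant)
```

The entropy (5.21 bits) is the mean per-pixel information content; the 2468
foreground pixels are exactly the cord, whose intensity bins are rarer than
average. Pixel counts per region set the weights, so a lumbar-only tumor
(25% of cord pixels) yields a spread probability of 0.25.

The full pipeline — cohort generation, 60:10:30 split, per-region training,
scoring, aggregation, gating and metrics — is one call:

```r
res <- run_pipeline(pipeline_config(
  phantom = phantom_spec(noise_sigma = 0.02, tumor_contrast = 0.4, seed = 1),
  n_images = 200, tumor_prevalence = 0.5, seed = 2025
))
glance(res)  # accuracy %, mean Dice, mean PSNR dB, spread correlation, ...
tidy(res)    # per-region accuracy
```

`autoplot()` methods visualize phantoms, saliency maps, segmentations and
spread estimates; a thin command-line wrapper lives in `inst/cli/spinescan.R`
(subcommands `phantom`, `saliency`, `segment`, `run`, `config`).

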