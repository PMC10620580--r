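# morphvision

Receptor-noise-limited visual modelling of color-morph discriminability.

Green/brown color polymorphisms are common in grasshoppers and other
insects. Whether the morphs actually *look different* depends on the eye
doing the looking: a contrast that is striking to a human or an RGB camera
can be invisible to a lizard, and a pair of spectra that a camera confounds
can be cleanly separated by a tetrachromatic bird. `morphvision` is aimed at
sensory and evolutionary ecologists who want to answer this question
quantitatively from reflectance spectra. It provides:

* spectral data handling and preprocessing (replicate averaging,
  negative-offset correction, repair of a fixed instrument-artifact window,
  optional loess smoothing, peak finding by topographic prominence);
* photoreceptor sensitivity reconstruction from peak wavelengths
  (λmax) via the A1 visual-pigment template, with six built-in predator
  visual systems — lizard, jumping spider, honey bee, house fly, starling
  and peafowl — covering di- to tetrachromatic vision;
* quantum catches and chromatic (ΔS) / achromatic (ΔL) contrasts in
  just-noticeable-difference (JND) units under the receptor-noise-limited
  (RNL) model, with group comparison tables and discriminability calls;
* a ternary RGB chromaticity analysis locating the nymphal stage at which
  morph coloration diverges during development;
* synthetic-data generators emulating green/brown grasshopper reflectance
  and ontogenetic RGB measurements, so the whole pipeline is reproducible
  without any measurement files.

## The model in brief

Receptor quantum catches are
*Q*ᵢ = ∫ *R*(λ) *S*ᵢ(λ) *I*(λ) dλ over 300–700 nm, and receptor signals are
*f*ᵢ = ln *Q*ᵢ. With receptor noise *e*ᵢ = ν √(η_ref/ηᵢ) (Weber fraction
ν = 0.1, uniform densities by default), the chromatic distance between two
stimuli is, e.g. for a dichromat,

    ΔS = |Δf₁ − Δf₂| / √(e₁² + e₂²)

with analogous three- and six-pair forms for tri- and tetrachromats, and the
achromatic distance is ΔL = |Δf_achro| / e_achro using each system's
luminance channel (summed receptors, fly R1–6 template, or avian double
cone). Two morphs are called discriminable only when **both** mean ΔS and
mean ΔL strictly exceed 3 JND. Derivations, parameter tables, numerical
decisions and limitations are in the methods vignette
(`vignettes/morphvision-methods.Rmd`).

## Worked example

```r
library(morphvision)

sp  <- gen_morph_spectra()        # synthetic two-species study, default seed
sp  <- repair_artifact_window(sp)
sp  <- average_replicates(sp, by = c("species", "individual", "patch"))
fit <- morph_discrimination(sp)   # all six built-in predator systems
fit
#> Morph discriminability analysis (pairwise_mean, threshold 3 JND)
#>   144 spectra, 14 comparisons x 6 visual systems
#>   36 of 84 cells discriminable (both dS and dL > 3)
```

Inspecting the starling's view of the between-morph comparisons:

```r
tab <- as.data.frame(fit)
subset(tab, system == "starling" & grepl("view", label))
#>    species                                                label dS_mean dL_mean n_pairs discriminable
#>  sibiricus                 Green vs. brown morphs (dorsal view)    1.63    2.12     352         FALSE
#>  sibiricus                Green vs. brown morphs (lateral view)    1.63    2.10     352         FALSE
#>   dorsatus          Brown vs. dorsal green morphs (dorsal view)    5.07    3.76     168          TRUE
#>   dorsatus        Brown vs. lateral green morphs (lateral view)    4.89    4.00      96          TRUE
#>   dorsatus  Lateral green vs. dorsal green morphs (dorsal view)    5.08    4.01     112          TRUE
#>   dorsatus Lateral green vs. dorsal green morphs (lateral view)    4.92    4.60     112          TRUE
#>   dorsatus         Brown vs. dorsal green morphs (lateral view)    0.09    0.84     168         FALSE
```

The weakly dimorphic species sits below threshold for every system, while
the strongly dimorphic one is separable by bird vision wherever a brown and
a green body side meet. `summary(fit)` prints the full 84-cell table and
`plot(fit)` draws it as a dot chart. The developmental analysis is one call:

```r
divergence_stage(gen_rgb_ontogeny())$stage
#> [1] "N3"
```

Everything — reading or simulating spectra, preprocessing, distance tables,
reports and the RGB analysis — can also be driven from a single
configuration via `run_pipeline(run_config(out_dir = "out", seed = 1))`, or
from a YAML file with `read_config()`.

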