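# lifoseg

Automatic optic-disc segmentation in retinal fundus image regions of
interest, for researchers building retinal-image analysis pipelines
(glaucoma, diabetic-retinopathy and papilledema screening) who need a
classical, fully deterministic, annotation-free segmenter and its
evaluation metrics.

The optic disc is a bright, approximately elliptical region whose
boundary is routinely obscured by crossing blood vessels, smooth
intensity inhomogeneity and bright peripapillary atrophy (PPA). The
package segments it with a level-set active contour that minimises a
**local image fitting energy with an oval-shaped constraint** (LIFO):

$$E(\phi,\theta_e) = \tfrac12 \textstyle\sum_\Omega (I - I^{LFI})^2
 + \nu \sum_\Omega \delta_\epsilon(\phi)\,|\nabla\phi|
 + \tfrac{\alpha}{2} \sum_\Omega (H_\epsilon(\phi) - H(\phi_e))^2$$

where $I^{LFI} = m_1 H_\epsilon(\phi) + m_2(1 - H_\epsilon(\phi))$ is a
two-phase approximation built from windowed local region means (robust
to intensity inhomogeneity), the second term penalises contour length,
and the third constrains the contour's footprint to that of an ellipse
$\phi_e(x_e, y_e, \theta_e, a_e, b_e)$ whose five parameters co-evolve
with $\phi$ by gradient descent. Defaults: $\nu = 0.0001\cdot255^2$,
$\alpha = 1$. The initial contour is extracted automatically:
superpixel cellular-automata saliency → mean filter → Otsu threshold →
morphological cleanup → largest connected component.

Also included: pixelwise evaluation metrics (Jaccard overlap ratio,
precision/recall/F-score, the 75%-overlap success rule), a
deterministic generator of fundus-like synthetic fixtures with exact
ground truth (vessels, illumination fields, PPA-like crescents, blur,
noise), and a command-line interface.

## Worked example

```r
library(lifoseg)

# a 200 x 200 synthetic fundus-like image: bright elliptical disc,
# three vessels crossing it, illumination gradient, blur and noise
fx <- generate_fixture(fixture_spec(n_vessels = 3, blur_sigma = 1,
                                    noise_sigma = 2,
                                    inhomogeneity_amplitude = 0.1,
                                    seed = 42))

res <- lifo_segment(fx$image)   # adaptive initialisation + evolution
res
#> LIFO segmentation result
#>   grid: 200 x 200 px, area: 2077 px
#>   iterations: 31 (stationary)
#>   prior ellipse: center (99.7, 99.3), axes (28.7, 23.2), theta 0.061 rad

s <- precision_recall_f(fx$mask, res$mask)
round(c(overlap = s$overlap_t, f_score = s$f_score), 3)
#>  overlap f_score
#>    0.917   0.957
```

The printed result reports the final contour area, the number of outer
iterations until the footprint became stationary, and the fitted prior
ellipse (centre and semi-axes in pixels, rotation in radians). The
overlap of 0.917 against the known ground truth clears the 0.75
success threshold; the F-score is the Dice coefficient of the two
masks. `res$energy_trace` holds the per-iteration values of the three
energy terms.

From a real image file:

```r
img <- load_image("roi.png", channel = "red")  # disc is brightest in red
res <- lifo_segment(img)
save_mask(res$mask, "disc_mask.png")
```

Or from a shell:

```sh
Rscript inst/cli/lifo.R segment roi.png --out disc_mask.png --trace trace.csv
Rscript inst/cli/lifo.R evaluate --truth expert.png --pred disc_mask.png
Rscript inst/cli/lifo.R synth --difficulty vessels --n 20 --seed 7 --out-dir fx/
```

See the methods vignette (`vignettes/lifoseg-methods.Rmd`) for the
model, its assumptions, every tunable parameter, and the numerical
design choices.

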