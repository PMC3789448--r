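# skinoptics

Quantitative, non-invasive mapping of skin physiology from
multispectral images.  Given a stack of ten calibrated monoband camera
images, `skinoptics` reconstructs a reflectance cube (a spectrum at
every pixel, 420–780 nm) and inverts it, pixel by pixel, into five
physiological maps: melanosome volume fraction *f*<sub>mel</sub>,
epidermis thickness *D*<sub>epi</sub> (mm), haemoglobin volume
fraction *f*<sub>blood</sub>, oxygenated haemoglobin fraction
*C*<sub>oxy</sub>, and dermis thickness *D*<sub>dermis</sub> (mm).
It is aimed at tissue-optics and dermatology imaging work:
pigmentation disorders (vitiligo, melasma), tissue oxygenation
(ischemia/occlusion protocols), and phototype characterisation.

## The model and the inversion

Skin is modelled as two diffusing layers (epidermis over dermis).
Epidermal absorption mixes a melanin power law
µ<sub>a.mel</sub>(λ) = 6.6×10¹¹ λ⁻³·³³ cm⁻¹ with a baseline term;
dermal absorption is the saturation-weighted whole-blood
oxy/deoxyhaemoglobin absorption plus the same baseline.  Per
wavelength, each layer's diffuse reflectance/transmittance follows the
classical Kubelka–Munk two-flux solution with
K = √(k(k+2s)), β = √(k/(k+2s)), k = 2µ<sub>a</sub>, s = 2µ<sub>s</sub>:

    R = (1−β²)(e^{Kd} − e^{−Kd}) / ((1+β)² e^{Kd} − (1−β)² e^{−Kd})
    T = 4β / ((1+β)² e^{Kd} − (1−β)² e^{−Kd})

and the stack combines by the inter-reflection series
R<sub>tot</sub> = R₁ + T₁²R₂/(1−R₁R₂).  The inverse problem — find the
five parameters whose simulated spectrum matches a measured one — is
solved by a bounded real-coded genetic algorithm (population 100,
25 generations, RMSE fitness by default) whose genes can never leave
the physical bounds (*f*<sub>mel</sub> 1.3–45 %, *D*<sub>epi</sub>
0.01–0.15 mm, *f*<sub>blood</sub> 0.2–7 %, *C*<sub>oxy</sub> 25–90 %,
*D*<sub>dermis</sub> 0.6–3 mm).

Upstream of the inversion the package provides offset/flat-field
calibration of raw 12-bit frames (U = (R−O)/S, S = (F−O)/4096), a
linear heteroassociative memory (ridge-regularised, delta-rule
trained on a 24-patch chart) that maps band responses to reflectance
spectra, and a synthetic acquisition chain + skin phantom generator
(filter bank, illuminant, vignetting, sensor noise, quantisation,
lesions, occlusion series) so the entire pipeline can be exercised and
validated without hardware.  See the vignette
`vignettes/skin-parameter-mapping.Rmd` for the full model account,
parameter meanings, and design rationale.

## Worked example

Simulate a spectrum for a known skin, invert it, and analyse a
vitiligo phantom:

```r
library(skinoptics)

ctx <- km_context()                      # forward-model context
truth <- skin_params(f_mel = 0.10, d_epi = 0.05, f_blood = 0.02,
                     c_oxy = 0.70, d_dermis = 1.2)
spec <- forward_spectrum(truth, ctx)
spec
#> <skin_spectrum> 37 bands, 420-780 nm, range [0.1894, 0.6058]

cfg <- ga_config(population_size = 200, iterations = 100, n_best = 10,
                 n_random = 50, n_cross = 60, n_mutate = 4, rng_seed = 1)
invert_spectrum(spec, cfg, ctx = ctx)
#> <ga_fit> generation 100, fitness 5.525e-06
#> <skin_params> f_mel 10%, d_epi 0.05 mm, f_blood 2%, c_oxy 70%, d_dermis 1.2 mm
```

The fitness is the spectral RMSE of the best individual (5.5×10⁻⁶ —
machine-level agreement); all five parameters are recovered at the
printed precision.  A phantom with a hypopigmented lesion
(melanin × 0.27 inside an elliptical patch) run through per-pixel
inversion and region comparison:

```r
ph <- make_skin_phantom(lesion = "vitiligo", shape = c(14, 14), seed = 7)
pm <- invert_cube(ph$cube, ga_config(population_size = 100,
                                     iterations = 40), seed = 3)
compare_regions(pm, ref_mask = !ph$mask, measured_mask = ph$mask)
#>      param ref_mean measured_mean r_diff
#> 1    f_mel  12.5447        3.2567   0.26
#> 2    d_epi   0.0166        0.0167   1.01
#> 3  f_blood   1.6238        1.6806   1.03
#> 4    c_oxy  69.4160       68.7183   0.99
#> 5 d_dermis   1.0301        1.0314   1.00
```

`r_diff` is the lesion/healthy ratio per parameter: the melanin ratio
0.26 recovers the ground-truth contrast 0.27, while the other four
parameters stay within a few percent of unity — the expected signature
of vitiligo, which alters only melanin.  Fractions are reported in
percent, thicknesses in mm.

A thin command-line front end over the same functions is installed at
`inst/cli/skinoptics` (subcommands `simulate`, `calibrate`, `learn`,
`reconstruct`, `invert`, `compare`).

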