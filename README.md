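# nirmc

Monte Carlo photon transport for second near-infrared window (NIR-II)
fluorescence neuroimaging of the mouse head.

## The problem

Quantum dots emitting at 1100 nm make it possible to image cerebral
vasculature through the *intact* scalp and skull of a hairless mouse, but
the fluorescence is transient: the focal plane must be set before the
signal appears, and there is no time to refocus.  Choosing that plane well
requires knowing, quantitatively, from which depth the microscope collects
the most near-ballistic (image-forming) emission photons.

`nirmc` answers this with a weighted-photon Monte Carlo simulation of a
four-layer head model — scalp skin (0.2 mm), skull (0.1 mm), cerebrospinal
fluid (0.1 mm) and an effectively semi-infinite cortex — at the two
wavelengths of the experiment: 785 nm excitation in and 1100 nm emission.
It is aimed at researchers designing trans-cranial NIR-II imaging
experiments who need depth-resolved excitation dose, emission point-spread
behaviour, and aperture-limited detection yields for realistic tissue
optics.

## The model

Photons carry a statistical weight `W` through plane-parallel layers, each
described by refractive index `n`, absorption `mu_a` (cm⁻¹), scattering
`mu_s` (cm⁻¹), and Henyey–Greenstein anisotropy `g`:

* **hop** — free paths `s = -ln(xi) / mu_t` with `mu_t = mu_a + mu_s`;
* **drop** — at each interaction the fraction `mu_a / mu_t` of the weight
  is deposited into an `(r, z)` fluence grid;
* **spin** — a uniform azimuth and a Henyey–Greenstein zenith cosine,
  `cos(theta) = (1 + g² − ((1 − g²)/(1 − g + 2 g xi))²) / (2 g)`;
* **boundaries** — unpolarized Fresnel reflection/refraction with total
  internal reflection beyond the critical angle
  `theta_c = asin(n2 / n1)`; the specular entry loss is
  `R = ((n1 − n2)/(n1 + n2))²`;
* **roulette** — photons below weight 1e-4 survive with probability 1/10
  (weight ×10), keeping the transport unbiased; every run closes a weight
  ledger to ≤1e-6 relative error.

Fluorescence is coupled in three parts: a pencil-beam excitation run
scores the on-axis dose at candidate quantum-dot depths (0.4, 0.8, 1.4,
2.0 mm below the scalp); each depth then re-emits isotropically at 1100 nm
with an inherited initial weight (1, 0.011, 0.0015, 0.0005); exit photons
are filtered through the objective's numerical-aperture cone (NA 0.25,
half-angle pinned at 15°) and binned radially in 0.05 mm sections.  The
Berek equation `DOF = n·lambda/(2·NA²) + n·e/(M·NA)` supplies the depth of
field of the collection optics.

## Worked example

```r
library(nirmc)
study <- simulate_focus_study(depths_mm = c(0.4, 0.8, 1.4, 2.0),
                              n_photons_excitation = 1e5,
                              n_photons_emission = 1e5, seed = 7)
print(study)
#> <focus_study> seed 7, 1e+05 excitation + 1e+05 emission photons per depth
#>  depth_mm excitation_intensity relative_excitation inherited_weight
#>       0.4           961.373781          1.00000000           1.0000
#>       0.8           129.676152          0.13488630           0.0110
#>       1.4            19.354655          0.02013229           0.0015
#>       2.0             4.836421          0.00503074           0.0005
#>  accepted_count accepted_weight
#>            5042    2988.0250969
#>            4887      31.3657869
#>            4148       3.5518535
#>            3213       0.9780726
#> recommended focal depth: 0.4 mm
```

Reading the output: `excitation_intensity` is the summed weight of
downward photon crossings per launched photon per cm² on a 0.005 cm
on-axis disc at each quantum-dot depth — the excitation dose falls by
roughly an order of magnitude for every ~0.5 mm of cortex.
`accepted_weight` is the emission weight collected inside the 15°
acceptance cone: the 0.4 mm plane (the cortical surface) yields about a
hundred times more detectable fluorescence than 0.8 mm and three orders
of magnitude more than 2.0 mm, which is why the recommended focal depth
is 0.4 mm below the scalp surface.

The same machinery is scriptable from a shell:

```sh
Rscript inst/cli/nirmc.R focus-study --photons 100000 --seed 7 --out out/
Rscript inst/cli/nirmc.R excite --preset mousehead_785 --photons 100000 --seed 1 --out out/
```

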