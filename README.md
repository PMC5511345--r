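# sheathtrack

Simulation and kymograph analysis of contractile sheath assembly dynamics.

The bacterial type VI secretion system (T6SS) fires a spring-loaded sheath —
a VipA/VipB polymer wrapped around an Hcp tube, anchored to the envelope by
a baseplate. Live-cell fluorescence imaging shows the sheath polymerizing to
a fully extended state, contracting to about half its length in under 2 ms,
and being disassembled by ClpV. `sheathtrack` is for researchers who
quantify such movies and, in particular, who want to know **at which end a
growing polymer adds its subunits**. It implements, as tested code:

* a **forward simulator** of sheath life cycles inside rods and wall-less
  spheroplasts under three candidate assembly mechanisms — distal-end
  addition, baseplate (proximal) insertion, and intercalation — including a
  photobleach event with a Gaussian line footprint that also dims the
  soluble subunit pool;
* an **optics renderer** turning ground-truth polymer states into realistic
  image stacks (pixel-integrated Gaussian PSF, cytosolic background, Poisson
  shot noise, read noise) with multi-frame TIFF + YAML-sidecar I/O;
* **kymograph analysis**: line profiles with bilinear sub-pixel sampling,
  automatic assembly-origin location, sub-bin front tracking, OLS
  polymerization-speed regression `v_a` with `R²`, end-of-assembly
  detection, contraction quantification and high-frame-rate contraction
  detection;
* the **photobleach-chase analysis**: eligibility screening, classification
  of *bright* / *bleached* / *dim* sheath sections, tracking of section
  centroids and widths at the four canonical chase time points, per-time
  point intensity normalization (cytosolic background = 0%), and a
  mechanism call (distal / proximal / intercalation / ambiguous) from the
  bleached mark's drift, width change and intensity change;
* **population statistics**: morphology-by-dynamics fractions, the
  regression of longest fully extended sheath on cell diameter, and
  per-cell assembly counts.

The key observables, in the field's notation: polymerization speed
`v_a` (nm s⁻¹, slope of front distance vs time), contraction remaining
fraction `L_contr / L_ext` (~0.5), the contraction speed lower bound
`ΔL / Δt` (nm ms⁻¹), and the bleached-mark evidence triple
(drift, width change, intensity change) behind each mechanism call.

## Worked example

Simulate one photobleach-chase acquisition (a spheroplast, one sheath
polymerizing at 55 nm s⁻¹, bleached after 30 s) and run the full analysis:

```r
library(sheathtrack)

ev  <- simulate_chase_event("distal", seed = 11)
rep <- run_bleach_chase(ev$stack)
rep
#> <chase_report> distal; v_a pre 54.8 / post 55.5 nm/s; t_end 82 s
rep$call
#> <mechanism_call> distal (drift -0.1 nm/s, width change -1%, intensity change -4.4 pts)
subset(rep$track, section == "bleached",
       select = c(timepoint, centroid_nm, width_nm, intensity_pct))
#>   timepoint centroid_nm width_nm intensity_pct
#> 2        t2    898.3995 589.6253     5.6524095
#> 5        t3    871.7353 561.7876    -0.2639788
#> 8        t4    896.6418 582.3328     1.2199896
```

Reading the output: the pre- and post-bleach speeds agree (the same
assembly was followed through the bleach); the bleached mark stays within
one 65 nm distance bin of its position over the 50 s between t2 and t4 and
keeps a near-0% normalized intensity with no recovery — the signature of
subunits being added at the end distal from the baseplate, not at the
baseplate (the mark would drift at `v_a`) nor by intercalation (the mark
would stretch and brighten).

A command-line front end with `simulate` and `chase` subcommands is in
`inst/cli/sheathtrack`; configurations are validated YAML
(see `read_run_config()`), and every run writes its resolved configuration
next to its outputs.

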