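# vertebend

Automated digital bending of intervertebral joints: estimating osteological
range of motion (oROM) and a morphometric stiffness proxy from bone-only 3D
models.

## The problem

Joint function in rare, protected, or extinct species usually has to be read
off skeletons, because the soft tissues that actually limit motion are gone.
The vertebral column is well suited to this: each motion segment (two
vertebrae plus the joint between them) articulates tightly through the
centrum and the paired zygapophyseal facets, so a digitally articulated
segment can be bent about its joint until something stops it. Manual
digital bending is slow and subjective; `vertebend` automates it and makes
every modelling assumption an explicit, sweepable parameter.

`vertebend` is aimed at comparative biomechanists and functional
morphologists working from CT-derived surface meshes (or from the package's
own synthetic segments, which need no data at all).

## The method

A motion segment is two watertight triangle meshes in a neutral pose, a
joint coordinate frame (centre of rotation, with the x-axis along the
centrum, y dorsoventral, z mediolateral), and ten landmarks: one pair
spanning the left zygapophyseal joint, and pairs at the dorsal, ventral,
left, and right extremes of the facing endplates.

The posterior vertebra is rotated about the COR in half-degree increments,
separately in six directions (dorsiflexion, ventroflexion, left/right
lateroflexion, left/right axial rotation), until a constraint trips:

* **bony intersection** — the surface area *A*∩ of the mesh boolean
  intersection exceeds a threshold fraction of mean vertebral surface area,
  *A*∩ > *t* · Ā (a small *t* > 0 absorbs mesh unevenness);
* **zygapophyseal strain** — the craniocaudal component *d* of the facet
  landmark separation leaves ε = (*d* − *d*₀)/*d*₀ ∈ [ε⁻, ε⁺]
  (disarticulation below, overlap above);
* **centrum strain** — any of the four endplate pair distances leaves its
  strain bounds (compression/tension).

If nothing trips by 45°, the direction reports the cap. The reported stop
angle is the last non-violating probe. Left and right measures are summed
into lateral and axial totals; dorsiflexion + ventroflexion give sagittal.
An 8-run factorial (spacing ±10%, intersection threshold 0.25/0.5%, strain
±45/55%) quantifies sensitivity to model construction, summarised by
sequential ANOVA sums of squares.

Joint stiffness is proxied from morphometrics and oROM:

    stiffness = force × moment arm / oROM,   force = (h · w)^(3/2)

with sagittal arm *h*/2 + arch height and lateral arm *w*/2 (units mm⁴ per
degree; comparative only).

## Worked example

```r
library(vertebend)

bs  <- block_segment(gap = 2)      # synthetic two-vertebra segment, mm units
fit <- orom(bs$segment)            # default: all constraints, 50% strain
fit
#> Osteological range of motion, segment 'block'
#>   dorsiflexion     4.5 deg  [zyg-overlap]
#>   ventroflexion    4.5 deg  [zyg-disarticulation]
#>   left-lateral     6.0 deg  [zyg-overlap]
#>   right-lateral    6.0 deg  [zyg-disarticulation]
#>   left-axial       5.5 deg  [intersection]
#>   right-axial      5.5 deg  [intersection]
#>   totals: lateral 12.0, sagittal 9.0, axial 11.0 deg
```

Each line is the largest rotation the joint admits in that direction and
the constraint that stopped the next half-degree: the dorsal facet tabs
overlap in dorsiflexion, disarticulate in ventroflexion, and bone-on-bone
contact limits axial twist — the pattern expected from the anatomy. The
sensitivity factorial and its effect sizes:

```r
sens <- run_sensitivity(bs$segment)   # 8 variants x 6 directions
variance_decomposition(sens$table)
#>           term df        ss
#> 1    direction  5 29.901042
#> 2      spacing  1 11.505208
#> 3 intersection  1  4.380208
#> 4       strain  1  6.380208
#> 5    Residuals 39 40.828125
```

Direction of bending explains more variation than any construction
parameter. The stiffness proxy for a joint with centrum 8 mm high, 10 mm
wide, arch 3 mm, bending 15° sagittally and 12° laterally:

```r
estimate_stiffness(8, 10, 3, 15, 12, mode = "printed")
#>   force sagittal lateral
#> 1   716      334     298
```

A command-line wrapper covers the same workflow
(`Rscript $(Rscript -e 'cat(system.file("cli","vertebend.R",package="vertebend"))') bend --scene scene.json --out results/`,
plus `sensitivity`, `stiffness`, and `synth` subcommands).

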