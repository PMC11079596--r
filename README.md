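# leafedge3d

Curve-based three-dimensional reconstruction of leaf edges from multiview
images.

Leaves carry much of their functional morphology at the margin, but the
standard SfM/MVS photogrammetry pipeline returns point clouds in which edge
positions are implicit and real holes are indistinguishable from
reconstruction gaps. `leafedge3d` reconstructs each leaf edge directly as a
closed curve in 3D: per-view instance masks are traced into sub-pixel 2D
contours and split into overlapping curve fragments; fragments are matched
across nearby camera pairs along epipolar bands and triangulated; spurious 3D
fragments are removed by multiview reprojection support; and the surviving
points of each loop (outer margin, holes) are fit with a closed periodic
B-spline

    f(l) = w b(l),  l in [0, 1) periodic,

with `n - 1` coefficients per coordinate over a degree-`k` wrap-around basis.
Accuracy is scored with the standardized Frechet distance
`SFD = Frechet / sqrt(leaf area)`; occlusion with the occlusion index
`OI = (1/m) * sum_i (1 - n_i / n)`; and the support threshold `tau_t` is
chosen by a precision-recall sweep (30 mm match radius, precision > 0.99)
summarised in a Bayesian-ridge guideline of optimal thresholds against OI.

The package is audience-complete for phenotyping work at desk scale: it
includes a synthetic multiview scene generator (virtual leaves with lobes,
serrations, elongation and holes; cylindrical camera rigs with positional
noise; occluder pillars; exact ground-truth masks, edges and labeled point
clouds) that stands in for the instance-segmentation and SfM stages, plus
leaf correspondence identification (DBSCAN + hidden point removal +
reprojection counting) for multi-leaf scenes.

World units are mm; image units are px (0-based, origin at the top-left pixel
centre).

## Worked example

```r
library(leafedge3d)

# a 1500 mm^2 leaf photographed by 32 virtual cameras at 640x480
scene  <- make_scene(scene_spec(list(leaf_spec(1500)), n_views = 32L,
                                rng_seed = 3L))
bundle <- reconstruct_scene(scene)
print(bundle)
#> <reconstruction_bundle: 1 leaf edge set(s), status ok>
#>   leaf 1: 1266 kept fragment(s), 1 loop(s); Frechet 0.35 mm, SFD 0.009
```

The printed line says: all 2D fragments of the leaf produced 1266 supported
3D curve fragments, they grouped into one closed loop (no holes), and the
fitted edge lies within 0.35 mm (Frechet distance) of the true edge — an SFD
of 0.009, i.e. about 0.9 % of the leaf's length scale.

A threshold sweep on the same sketch:

```r
sk <- bundle$leaves[[1]]$sketch
pr <- sweep_support_threshold(sk, scene$true_edges[[1]][[1]])
optimal_support_threshold(pr)
#> $tau_t
#> [1] 0.875
#> $flagged
#> [1] FALSE
```

A command-line front end with subcommands `simulate`, `edges`, `correspond`,
`sketch`, `fit`, `evaluate` and `pipeline` is installed under `exec/leafedge`:

```sh
Rscript exec/leafedge simulate --out scene/ --seed 3 --leaves 1 --views 32
Rscript exec/leafedge pipeline --scene scene/ --out recon/
```

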