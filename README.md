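# archolimb

Quantitative tools for studying how hindlimb muscle leverage evolved along
the archosaurian bird-line — the lineage running from the crocodile–bird
split through theropod dinosaurs to crown birds. Locomotion on that line
shifted from *hip-based* (limb retraction by hip extensors, subvertical
femur) to the *knee-based* mechanism of living birds (subhorizontal femur,
retraction by knee flexion, balance by medial long-axis rotation of the
hip). `archolimb` is for comparative biomechanists who want to test such
shifts with explicit models rather than qualitative anatomy.

The package implements the full chain:

- **Limb models**: least-squares sphere/cylinder fitting of joint
  primitives from bone point clouds (STL/OBJ/XYZ), cartilage spacing (5%
  knee, 7.5% ankle of the proximal segment length), and muscle-tendon
  paths with via points and cylinder/sphere/ellipsoid wrapping surfaces,
  read from a plain-text YAML model spec.
- **Moment arms by virtual work**: the signed moment arm of a
  muscle-tendon unit (MTU) about a joint degree of freedom is
  `r = -dL/dtheta` (path length L, angle in radians), evaluated with a
  fourth-order central difference; curves are swept over fixed joint
  ranges of motion on a 1-degree grid and reduced to means normalized by
  segment length (femur for hip, tibiotarsus for knee, tarsometatarsus
  for ankle MTUs).
- **Ancestral character estimation**: maximum-likelihood Brownian-motion
  states at every internal node of a time-calibrated 13-taxon archosaur
  tree, `a_hat = (1'V^-1 1)^-1 1'V^-1 x` under re-rooting, with 95%
  confidence intervals matching the reference `fastAnc` estimator, plus a
  punctuated (all branch lengths = 1) sensitivity variant.
- **Trend analysis**: per-node sums of absolute ancestral estimates by
  action direction, the hypothesis ratios H1 (hip extension/flexion), H2
  (knee flexion/extension) and H3 (hip medial rotation/abduction),
  internodal percent changes against the a-priori >=20% (reliable) and
  >=10% (notable) thresholds, sign-switch and extremum reports, and
  hypothesis verdicts.
- **Synthetic data**: parametric limbs with closed-form moment arms
  (pulley and straight-line recipes), programmed leverage trends across a
  mock clade, and Brownian trait simulation — all seed-deterministic.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and result tables have `autoplot()` methods.

## Worked example

```r
library(archolimb)

# moment arm of a knee-extensor tendon wrapped on a condylar cylinder
m <- generate_limb()                       # parametric limb, femur 300 mm
moment_arm(m, "AMB", "knee", "FLEXEX")
#> [1] 42.63                                # = 0.1421 * 300 mm, the pulley radius

# full pipeline on a synthetic clade with a programmed -50% leverage decline
res <- run_pipeline(list(out_dir = tempfile("archolimb"), seed = 1))
amb <- subset(res$ace, tree == "time" & mtu == "AMB")
ch  <- internodal_changes(dplyr::rename(amb, ratio = "estimate"))
ch$pct_change[ch$segment == "overall"]
#> [1] -44.73234
```

The recovered overall change (−44.7%) sits within the expected shrinkage
of a phylogenetically weighted estimator applied to a programmed −50%
tip-to-tip decline. On the packaged table of published per-muscle mean
normalized ancestral moment arms:

```r
library(dplyr)
ref  <- reference_mean_ace() |> rename(estimate = mean_ace) |> mutate(node = "mean")
sums <- sum_by_action(ref)
ratio_series(sums, "H1")$ratio   # summed hip extensor / flexor means
#> [1] 2.523449
ratio_series(sums, "H2")$ratio   # summed knee flexor / extensor means
#> [1] 1.207469
```

These ratios of summed magnitudes (about 2.5 and 1.2) quantify how much
hip extension dominated hip flexion, and knee flexion dominated knee
extension, averaged across the bird-line's ancestral nodes.

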