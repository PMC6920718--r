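# bonemorph

Slice-wise ("global 2D") and targeted 3D micro-CT bone morphometry for
binarized long-bone image stacks, with synthetic voxel phantoms that carry
analytic ground truth.

## The problem

Conventional micro-CT analysis reports trabecular and cortical
microarchitecture as averages over hand-picked volumes of interest (VOIs).
Because bone architecture changes substantially over short distances, a VOI
placed a fixed offset from a landmark can blur or miss site-specific
effects. `bonemorph` instead computes every standard 2D morphometric
parameter on every cross-sectional slice and expresses the results as
*distributions over percent bone length*, so the whole scanned segment is
surveyed before any VOI is chosen. Targeted 3D morphometry on
percent-length VOIs then validates and extends what the distributions show.
The intended users are skeletal-biology and biomechanics groups analysing
rodent long bones (femur, tibia, humerus), e.g. in disuse-osteoporosis,
ageing, loading or knockout studies.

## What it computes

Per slice (2D), with bone = foreground of a binarized stack:

- Trabecular: area fraction BA/TA, plate-model thickness
  Tb.Th = 2·B.Ar/B.Pm, number Tb.N = (BA/TA)/Tb.Th, separation
  Tb.Sp = 1/Tb.N − Tb.Th (a local inscribed-disc thickness model is
  available as an alternative).
- Cortical: Ct.Ar, Tt.Ar, Ma.Ar (= Tt.Ar − Ct.Ar), Ct.Ar/Tt.Ar, periosteal
  and endocortical perimeters Ps.Pm/Ec.Pm (marching squares), annular-model
  Ct.Th = 2·Ct.Ar/(Ps.Pm + Ec.Pm), second polar moment of area
  J = Σ r²·a² + n·a⁴/6 about the section centroid, and eccentricity Ecc
  (semimajor/semiminor axis ratio of the moment ellipse).
- **Trabecular Extent (Tb.E)**: the distance, measured proximally from the
  growth-plate reference level along the native-resolution BA/TA
  distribution, to the first occurrence of BA/TA = 30%, 20%, 10% and 0,
  plus the absolute extent Tb.E_Abs to the most proximal slice with any
  trabecular bone. Tb.E quantifies how far the distal trabecular structure
  penetrates into the medullary cavity.

Per VOI (3D): BV/TV, direct (maximal-inscribed-sphere) Tb.Th and Tb.Sp,
Tb.N, bone surface to volume ratio BS/BV (0.5-iso surface), trabecular bone
pattern factor Tb.Pf, connectivity density Conn.D = (1 − χ)/TV from the
Euler characteristic of the voxel complex, and the un-plate index
uPi = Tb.Th/(2·BV/BS) (≈1 for plates, ≈2 for rods); cortical Ct.Th (direct
3D), slice-averaged areas, J and Ecc.

Statistics: Anderson–Darling and Kolmogorov–Smirnov (Lilliefors) normality
screening, classic Student's t-test at every 1% bone-length grid point,
significance bands (NS, .05 > p ≥ .01, .01 > p ≥ .001, .001 > p ≥ .0001,
p < .0001), difference profiles, and control-normalized VOI tables.

## Worked example

A synthetic distal-femur phantom (cortical tube + plate lattice whose BA/TA
decays linearly proximally from a virtual growth plate at slice 64) run
through the pipeline:

```r
library(bonemorph)
spec <- phantom_spec(length_slices = 80, outer_radius_px = 45,
                     inner_radius_px = 36, growth_plate_slice = 64,
                     trabecular_pattern = "plates", lattice_thickness_px = 8,
                     lattice_period_px = 18, epiphysis_ba_ta = 0.40,
                     density_decay = 0.02, seed = 11,
                     voxel_size_mm = 0.01, bone_length_mm = 2.0)
ph      <- make_phantom(spec)
masks   <- segment_stack(ph$stack)
frame   <- build_frame(ph$stack, ph$meta)
metrics <- slice_metrics_table(masks, frame)
metrics[metrics$slice %in% c(20, 40, 64),
        c("slice", "percent", "ba_ta", "ct_th_2d", "ct_ar_2d", "j_2d")]
#>    slice percent  ba_ta ct_th_2d ct_ar_2d   j_2d
#> 20    20      70 0.0000   0.0904   0.2308 0.0383
#> 40    40      80 0.1853   0.0904   0.2308 0.0383
#> 64    64      92 0.3274   0.0904   0.2308 0.0383
```

The cortical tube has a 9-pixel (0.09 mm) wall: the annular-model Ct.Th of
0.0904 mm and J of 0.0383 mm⁴ match the analytic annulus values (0.09 mm,
0.0380 mm⁴) to under 1%. BA/TA falls from 0.33 near the growth plate to 0
proximal of 70% bone length, reproducing the imposed decay. Trabecular
extent from the growth-plate level (92% bone length):

```r
trabecular_extent(metrics$percent, metrics$ba_ta, frame$bone_length_mm,
                  reference_percent = percent_of_slice(frame, 64))
#>   threshold crossing_percent      tbe_mm censored flag
#> 1       0.3         91.90369 0.001926190    FALSE
#> 2       0.2         91.55167 0.008966667    FALSE
#> 3       0.1         84.63556 0.147288742    FALSE
#> 4       0.0         83.50000 0.170000000    FALSE
#> Tb.E_Abs: 0.49 mm
```

Tb.E grows monotonically as the threshold drops, and the absolute extent
(0.49 mm, the most proximal slice with any bone) exceeds the
first-occurrence-of-zero distance — the first zero crossing (0.17 mm) hits a
locally pruned slice, which is exactly why several thresholds plus Tb.E_Abs
are reported. Two-group comparisons (`ttest_profile`,
`plot_profile_comparison`) and 3D VOI morphometry (`extract_voi`,
`trabecular_3d`, `cortical_3d`) continue from these tables; `run_pipeline`
chains all stages from a YAML config, and `inst/cli/bonemorph` wraps the
same functions for shell use.

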