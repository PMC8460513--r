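# fetalmorph

Surface-based morphometry of the fetal brain from labeled MRI
segmentations: structure volumetry, a global shape parameter, per-vertex
curvature descriptors of cortical folding, longitudinal vertex
correspondence between pre- and post-operative cortical surfaces, lobe-wise
summaries, posterior fossa biometry, and the nonparametric statistics to
compare an affected cohort (fetuses undergoing in-utero myelomeningocele
repair) against gestational-age-matched controls.

The package is aimed at researchers quantifying fetal neurodevelopment
from super-resolution-reconstructed MRI (isotropic labeled volumes of
unmyelinated white matter, ventricles and cerebellum). No patient data are
included; a synthetic gyrified brain phantom generator with analytic
ground truth stands in for study data and backs the entire validation
suite.

## The quantities at the core

For a structure with voxel set $S$ and spacing $(s_x, s_y, s_z)$:

- **Volume** $V = |S| \cdot s_x s_y s_z$ (mm³), and **surface area**
  $A = \sum_t \mathrm{area}(t)$ over the triangles of the extracted
  surface (mm²).
- **Shape parameter** $A/V$ (mm⁻¹) — global compactness; $3/R$ for a
  sphere, rising with folding.
- **Curvedness** $C = \sqrt{(k_1^2 + k_2^2)/2}$ (mm⁻¹) and **shape
  index** $SI = \frac{2}{\pi}\arctan\frac{k_1+k_2}{k_1-k_2} \in [-1,1]$
  from the principal curvatures $k_1 \ge k_2$: $SI = +1$ on gyral domes,
  $-1$ in sulcal cups, $0$ on saddles.
- **Longitudinal change per week**: $(x_{post} - x_{pre}) / (GA_{post} -
  GA_{pre})$ under a linear growth assumption, with gestational age in
  decimal weeks (`"23+6"` → 23 + 6/7).
- **Correspondence**: rigid coherent point drift (Gaussian-mixture EM)
  initialises the alignment; joint spectral matching pairs the surfaces'
  Laplacian eigenmodes through the initial links and matches vertices by
  nearest neighbour in the shared spectral coordinates, so post-operative
  fields can be pulled back to the pre-operative surface and differenced.
- **Statistics**: Kruskal-Wallis H (tie-corrected, exact permutation for
  small n), Anderson-Darling normality screen, median/IQR (type-7),
  Pearson r with strength bins (0.3/0.5/0.7 cut points).

See `vignettes/fetal-brain-morphometry.Rmd` for the full model,
parameter defaults, and design rationale.

## Worked example

```r
library(fetalmorph)

## a gyrified phantom with known truth, voxelized at 0.8 mm
sp <- phantom_spec(fold_amplitude = 2, ventricle_scale = 0.25, seed = 42)
ph <- generate_phantom(sp)
structure_metrics(ph$volume)
#>         structure volume_mm3 area_mm2 shape_param_mm_1            mesh_source
#> 1 unmyelinated_wm    62034.4   9209.8           0.1485 marching_tets+taubin10
#> 2      ventricles      987.1    532.7           0.5396 marching_tets+taubin10
#> 3      cerebellum     3611.6   1257.2           0.3481 marching_tets+taubin10

## longitudinal pair (default growth ~650 mm3/wk ventricles, folding +0.5 mm/wk)
pair <- generate_longitudinal_pair(sp, delta_ga = 2)
corr <- joint_spectral_match(pair$pre$mesh, pair$post$mesh, k = 30)
corr
#> correspondence (post_to_pre): 2562 pre vertices -> 2562 post vertices
#>   257 CPD links, 30 shared modes, mean match cost 0.1316

curvature_field(pair$pre$mesh)
#> curvature_field: 2562 vertices (100.0% valid)
#>   curvedness mean 0.05132 mm^-1, SI mean 0.606, gyral area fraction 0.947
curvature_field(pair$post$mesh)
#> curvature_field: 2562 vertices (100.0% valid)
#>   curvedness mean 0.05403 mm^-1, SI mean 0.521, gyral area fraction 0.905
```

Between the scans the phantom grew ~10% in volume while its folds
deepened by 1 mm: mean curvedness rises (0.0513 → 0.0540 mm⁻¹) and the
gyral area fraction falls as folding carves sulci into the convex base
shape. Pulling the post SI back through the correspondence and averaging
the change per lobe:

```r
dsi  <- delta_field(curvature_field(pair$pre$mesh)$shape_index,
                    transfer_field(corr, curvature_field(pair$post$mesh)$shape_index))
labs <- sector_parcellation(pair$pre$mesh)
regional_summary(dsi, labs, pair$pre$mesh)
#>   region n_vertices area_mm2    mean  median
#> 1     LF        312      980 -0.0973 -0.0676
#> ...                                          (8 lobes)
```

A synthetic cohort (12 affected with pre/post scans, 12 early + 12 late
controls) through the statistics layer:

```r
co <- generate_cohort(12, 12, 12, seed = 42)
ga <- run_group_analysis(co$table)
ga
#> group_analysis
#>   18 tests, 12 significant at alpha = 0.05
#>   moderate-or-stronger correlations:
#>     tcd_mm ~ cerebellum_volume_mm3: r = 0.95 (strong positive)
#>     vw_mm ~ ventricles_volume_mm3: r = 0.93 (strong positive)
#>     ...
```

The ventricular-rate contrast (affected median 2609 vs control 803
mm³/week, H = 14.1, p = 0.00017) reflects the elevated post-operative
ventricular growth the generator builds into the affected group.

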