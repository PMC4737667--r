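# fmridict

Sparse dictionary decomposition of whole-brain fMRI into concurrent
functional networks.

## What it does

Resting-state and task fMRI recordings mix the activity of many
functional brain networks in every voxel. `fmridict` unmixes them by
sparse representation: the voxel time series of one subject are
aggregated into a signal matrix *S* ∈ ℝ^{m×n} (*m* time points, *n*
in-mask voxels) and factorized as

>  min_{D ∈ C, α}  ½‖S − Dα‖²_F + λ‖α‖₁,  C = { D : dⱼᵀdⱼ ≤ 1 ∀j }

via online (mini-batch) dictionary learning. Each column of
*D* ∈ ℝ^{m×k} — an *atom* — is the temporal signature of one network;
the corresponding row of the sparse coefficient matrix α ∈ ℝ^{k×n} is
its spatial loading, which is mapped back to the brain grid, z-scored
and thresholded (|z| > 2 by default) into a candidate network map.
Candidates are identified against labeled resting-state network (RSN)
templates by spatial overlap (Jaccard by default) with greedy
one-to-one assignment, and per-subject matches are aggregated into
group-wise consensus networks.

The package is for researchers who want a small, fully reproducible,
tested implementation of this pipeline: NIfTI in, NIfTI/CSV/PNG/JSON
out, every random choice driven by one seed. It includes

* a voxel-sampling module that trains the dictionary on a fraction of
  voxel columns and then codes all voxels (a large speedup at nearly
  identical maps; at ratio 1 it is bitwise-identical to the plain path),
* a synthetic-fMRI generator that plants *K* compact networks with
  known time courses, per-subject boundary jitter and controlled SNR,
  so every stage can be validated against ground truth,
* a command-line front end (`inst/cli/fmridict`) with verbs `simulate`,
  `run-subject`, `run-group`, `report`.

## Worked example

Simulate a small multi-subject dataset with 4 planted networks, run the
per-subject decomposition and the group aggregation:

```r
library(fmridict)

spec <- synthetic_spec(grid_shape = c(16, 16, 16), n_networks = 4,
                       n_timepoints = 60, blob_size = 60,
                       n_subjects = 3, snr = 5, seed = 42)
ds  <- generate_dataset(spec, file.path(tempdir(), "demo"))

cfg <- pipeline_config(
  subjects = ds$subjects, mask = ds$mask, templates = ds$templates,
  output_dir = file.path(tempdir(), "demo_out"),
  odl = odl_config(k = 20, seed = 42), seed = 42,
  template_labels = ds$labels)

bundles <- lapply(ds$subjects, function(p) run_subject(cfg, p))
bundles[[1]]$match
#> <match_result> 4/4 templates assigned (jaccard overlap)
round(bundles[[1]]$match$overlaps, 2)
#> RSN01 RSN02 RSN03 RSN04
#>  0.62  0.56  0.59  0.65

grp <- run_group(cfg, bundles, dataset_id = "demo")
grp$tables$group
#>   dataset    RSN01     RSN02     RSN03     RSN04
#> 1    demo 0.755814 0.6923077 0.7590361 0.7272727
grp$tables$individual
#>   dataset       RSN01       RSN02       RSN03       RSN04
#> 1    demo 0.59 ± 0.02 0.59 ± 0.02 0.63 ± 0.05 0.60 ± 0.04
```

All four planted networks are identified in every subject (individual
Jaccard overlaps ≈ 0.56–0.65 against the ground-truth templates; the
jitter the generator injects between subjects caps what any single
subject can reach), and the group consensus maps are sharper than the
typical individual (0.69–0.76) — the pattern group-level analyses are
meant to show. Each subject directory also receives per-component z-map
NIfTIs, a component summary CSV, a match CSV and a JSON manifest;
`report(bundles[[1]])` renders one PNG mosaic per component.

The warning emitted along the way (`k = 20 is outside the recommended
over-complete regime`) is advisory: this demo uses few atoms because it
has few time points and networks; whole-brain runs typically use
`k = 400 > m`.

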