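test_that("templates are compact, mutually disjoint blobs inside the mask", {
  spec <- synthetic_spec(seed = 3)      # full default: K = 10 on 24^3
  tset <- generate_templates(spec)
  expect_length(tset$maps, 10)
  for (mp in tset$maps) {
    expect_true(all(!mp | tset$mask$grid))
    expect_gt(sum(mp), 0)
  }
  pairs <- combn(10, 2)
  for (p in seq_len(ncol(pairs))) {
    a <- tset$maps[[pairs[1, p]]]
    b <- tset$maps[[pairs[2, p]]]
    expect_lt(sum(a & b) / sum(a | b), 0.1)
  }
  # determinism
  tset2 <- generate_templates(spec)
  expect_identical(tset$maps, tset2$maps)

  single <- generate_templates(tiny_spec(n_networks = 1))
  expect_length(single$maps, 1)

  # blobs too large to place raise a placement error
  expect_error(
    generate_templates(synthetic_spec(grid_shape = c(8, 8, 8), n_networks = 6,
                                      blob_size = 120, seed = 1)),
    class = "fmridict_placement_error")
})

test_that("the noiseless, jitter-free limit reproduces time courses exactly", {
  spec <- tiny_spec(seed = 5, snr = Inf, jitter = 0)
  tset <- generate_templates(spec)
  subj <- generate_subject(spec, tset, 77)
  expect_identical(tset$maps, subj$maps$maps)
  # single-membership voxel carries exactly its network's time course
  multi <- Reduce(`+`, lapply(tset$maps, function(m) m * 1))
  for (kk in seq_along(tset$maps)) {
    vox <- which(tset$maps[[kk]] & multi == 1)[1]
    co <- arrayInd(vox, dim(multi))
    expect_equal(subj$data[co[1], co[2], co[3], ], subj$timecourses[, kk],
                 tolerance = 1e-12)
  }
})

test_that("out-of-network voxels carry noise at sd = 1/snr", {
  spec <- tiny_spec(seed = 6, snr = 5, n_timepoints = 200)
  tset <- generate_templates(spec)
  subj <- generate_subject(spec, tset, 88)
  any_net <- Reduce(`|`, subj$maps$maps)
  free <- which(tset$mask$grid & !any_net)
  sds <- vapply(free[1:50], function(vox) {
    co <- arrayInd(vox, dim(any_net))
    sd(subj$data[co[1], co[2], co[3], ])
  }, numeric(1))
  expect_lt(abs(mean(sds) - 1 / spec$snr) / (1 / spec$snr), 0.2)
})

test_that("subjects share geometry up to jitter but differ in noise", {
  spec <- tiny_spec(seed = 7)
  tset <- generate_templates(spec)
  s1 <- generate_subject(spec, tset, 101)
  s2 <- generate_subject(spec, tset, 102)
  expect_false(identical(s1$data, s2$data))
  for (kk in seq_along(tset$maps)) {
    expect_gt(spatial_overlap(s1$maps$maps[[kk]], tset$maps[[kk]]), 0.4)
    expect_gt(spatial_overlap(s2$maps$maps[[kk]], tset$maps[[kk]]), 0.4)
  }
  expect_identical(generate_subject(spec, tset, 101)$data, s1$data)
})

test_that("datasets land on disk with the declared shapes and exact payloads", {
  spec <- tiny_spec(seed = 8)
  dir <- file.path(tempdir(), "synthds")
  ds <- generate_dataset(spec, dir)
  expect_length(ds$subjects, spec$n_subjects)
  expect_length(ds$templates, spec$n_networks)
  img <- RNifti::readNifti(ds$subjects[1])
  expect_equal(dim(img), c(spec$grid_shape, spec$n_timepoints))

  # round-trip: on-disk matrix equals in-memory generation
  tset <- generate_templates(spec)
  subj <- generate_subject(spec, tset, spec$seed + 1000L + 1L)
  S_disk <- load_fmri(ds$subjects[1], ds$mask)
  S_mem <- as_signal_matrix(subj$data, tset$mask)
  expect_identical(S_disk$data, S_mem$data)

  # truth sidecar is evaluation-only: the pipeline runs without it
  file.remove(ds$truth)
  cfg <- pipeline_config(subjects = ds$subjects[1], mask = ds$mask,
                         templates = ds$templates,
                         output_dir = file.path(tempdir(), "synthds_out"),
                         odl = odl_config(k = 8, n_epochs = 1, seed = 1),
                         template_labels = ds$labels, write_maps = FALSE)
  b <- suppressWarnings(run_subject(cfg, ds$subjects[1]))
  expect_true(b$ok)
})
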