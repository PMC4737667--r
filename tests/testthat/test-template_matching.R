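test_that("spatial overlap follows the set formulas and their bounds", {
  dims <- c(10, 10, 3)
  A <- block_map(dims, 1:5, 1:10, 1:2)      # 100 voxels
  T1 <- block_map(dims, 1:5, 1:10, 1:2)

  expect_equal(spatial_overlap(A, T1), 1.0)
  disj <- block_map(dims, 8:10, 1:10, 1:2)
  expect_equal(spatial_overlap(A, disj), 0.0)

  # |A| = |T| = 100, |A & T| = 50 -> Jaccard 50/150
  A2 <- block_map(dims, 1:10, 1:10, 1)           # 100 voxels
  T2 <- block_map(dims, 1:10, 1:10, 2)           # disjoint plane
  T2[1:10, 1:5, 1] <- TRUE; T2[1:10, 1:5, 2] <- FALSE  # now T2 = 50 in plane1 + 50 in plane2
  expect_equal(sum(A2), 100); expect_equal(sum(T2), 100)
  expect_equal(sum(A2 & T2), 50)
  expect_equal(spatial_overlap(A2, T2), 50 / 150, tolerance = 1e-12)
  expect_equal(spatial_overlap(A2, T2, method = "dice"), 100 / 200, tolerance = 1e-12)
  expect_equal(spatial_overlap(A2, T2, method = "fraction_of_template"), 0.5)

  # symmetry and range
  expect_equal(spatial_overlap(A2, T2), spatial_overlap(T2, A2))
  empty <- array(FALSE, dims)
  expect_equal(spatial_overlap(empty, T2), 0)
  expect_error(spatial_overlap(A2, empty), class = "fmridict_value_error")
  expect_error(spatial_overlap(A2, block_map(c(5, 5, 5), 1, 1, 1)),
               class = "fmridict_shape_error")
})

test_that("matching is one-to-one, greedy and permutation-invariant", {
  dims <- c(12, 12, 4)
  t1 <- block_map(dims, 1:4, 1:4, 1:2)
  t2 <- block_map(dims, 7:10, 7:10, 1:2)
  templates <- template_set(c("net1", "net2"), list(t1, t2))

  # components identical to the templates match identically
  comps <- list(fake_component(t1, 1), fake_component(t2, 2))
  mr <- match_components(comps, templates)
  expect_equal(unname(mr$assignment), c(1L, 2L))
  expect_equal(unname(mr$overlaps), c(1, 1))

  # one component overlapping both templates is assigned to the better one
  both <- t1 | block_map(dims, 7:8, 7:10, 1:2)   # all of t1, half of t2
  mr2 <- match_components(list(fake_component(both, 1)), templates)
  expect_false(is.na(mr2$assignment[["net1"]]))
  expect_true(is.na(mr2$assignment[["net2"]]))

  # shuffling component order only relabels indices
  comps_shuffled <- list(fake_component(t2, 1), fake_component(t1, 2))
  mr3 <- match_components(comps_shuffled, templates)
  expect_equal(unname(mr3$assignment), c(2L, 1L))
  expect_equal(mr3$overlaps, mr$overlaps)

  # overlaps below the floor stay unassigned
  far <- block_map(dims, 11:12, 1:2, 3:4)
  mr4 <- match_components(list(fake_component(far, 1)), templates,
                          min_overlap = 0.05)
  expect_true(all(is.na(mr4$assignment)))
})

test_that("group consensus reduces to the subject map for one subject", {
  dims <- c(12, 12, 4)
  t1 <- block_map(dims, 2:5, 2:5, 1:2)
  templates <- template_set("net1", list(t1))
  subj_map <- block_map(dims, 3:6, 2:5, 1:2)
  comp <- fake_component(subj_map, 1)
  mr <- match_components(list(comp), templates)
  grp <- groupwise_networks(list(mr), list(list(comp)), templates,
                            consensus_thresh = 0.5)
  expect_identical(grp$group_maps[["net1"]], subj_map)
  expect_equal(grp$overlaps[["net1"]], spatial_overlap(subj_map, t1))

  # identical maps across subjects give the same group map
  grp3 <- groupwise_networks(rep(list(mr), 3), rep(list(list(comp)), 3),
                             templates, consensus_thresh = 0.5)
  expect_identical(grp3$group_maps[["net1"]], subj_map)

  # a label matched nowhere yields an empty map with zero overlap
  mr_none <- match_components(
    list(fake_component(block_map(dims, 10:12, 10:12, 3:4), 1)),
    templates, min_overlap = 0.05)
  grp0 <- groupwise_networks(list(mr_none), list(list(comp)), templates)
  expect_equal(sum(grp0$group_maps[["net1"]]), 0)
  expect_equal(grp0$overlaps[["net1"]], 0)
})

test_that("consensus over jittered subjects beats the average individual", {
  spec <- tiny_spec(seed = 31, n_subjects = 20)
  tset <- generate_templates(spec)
  matches <- list(); comp_lists <- list()
  for (s in seq_len(spec$n_subjects)) {
    subj <- generate_subject(spec, tset, 500 + s)
    comps <- lapply(seq_along(subj$maps$maps), function(i) {
      fake_component(subj$maps$maps[[i]], i)
    })
    matches[[s]] <- match_components(comps, tset)
    comp_lists[[s]] <- comps
  }
  grp <- groupwise_networks(matches, comp_lists, tset, consensus_thresh = 0.5)
  indiv <- do.call(rbind, lapply(matches, `[[`, "overlaps"))
  for (lab in tset$labels) {
    expect_gte(grp$overlaps[[lab]], mean(indiv[, lab]))
  }
})

test_that("overlap tables reproduce their own means and deviations", {
  group_results <- list(dsA = c(net1 = 1.0, net2 = 0.8))
  indiv <- matrix(c(0.3, 0.5, 0.2, 0.4), 2, 2,
                  dimnames = list(NULL, c("net1", "net2")))
  tabs <- overlap_tables(group_results, list(dsA = indiv))
  expect_equal(tabs$group$net1, 1.0)
  expect_equal(tabs$individual_mean$net1, 0.4)
  expect_equal(tabs$individual_sd$net1, 0.1, tolerance = 1e-12)  # population sd
  expect_equal(tabs$individual$net1, "0.40 ± 0.10")

  # recompute from scratch at tight tolerance
  expect_equal(tabs$individual_mean$net2, mean(indiv[, "net2"]), tolerance = 1e-12)
  expect_equal(tabs$individual_sd$net2,
               sqrt(mean((indiv[, "net2"] - mean(indiv[, "net2"]))^2)),
               tolerance = 1e-12)
})
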