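# Synthetic resting-state fMRI with planted networks.
#
# The generator emulates the structure the decomposition assumes: K
# spatially compact, mutually low-overlap networks inside an ellipsoidal
# "brain", each with its own smooth random time course; a voxel's signal
# is the sum of the time courses of the networks it belongs to, plus
# white noise whose standard deviation is 1/snr. Per-subject variability
# is a small rigid displacement (jitter) of each network. Ground truth
# (templates, subject maps, time courses, jitter) is returned for
# evaluation and never consumed by the analysis pipeline.

#' Specification of a synthetic dataset
#'
#' @param grid_shape 3D grid dimensions.
#' @param mask_radius semi-axes of the ellipsoidal brain mask as a
#'   fraction of the half-extent of each grid axis.
#' @param n_networks K, number of planted networks.
#' @param n_timepoints m, time points per subject.
#' @param blob_size mean network extent in voxels. Sizes vary uniformly
#'   within ±20% around it. Default 200 voxels, about 4% of the default
#'   mask — the order of real resting-state network extents relative to
#'   brain volume.
#' @param snr ratio of signal sd to noise sd (time courses have unit
#'   variance, so noise sd is `1/snr`). May be `Inf` for noiseless data.
#' @param n_subjects subjects per dataset.
#' @param jitter maximum per-network spatial displacement (Euclidean, in
#'   voxels) from template to subject map.
#' @param seed RNG seed; templates and all subjects derive from it.
#' @param tr_seconds repetition time stamped on generated files.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid_shape = c(24, 24, 24), mask_radius = 0.9,
                           n_networks = 10L, n_timepoints = 120L,
                           blob_size = 200L, snr = 5, n_subjects = 5L,
                           jitter = 1L, seed = 1L, tr_seconds = 2) {
  if (length(grid_shape) != 3L || any(grid_shape < 4)) {
    abort_value("grid_shape must be three dimensions of at least 4 voxels")
  }
  if (n_networks < 1L) abort_value("need at least one network")
  if (n_timepoints < 2L) abort_value("need at least two time points")
  if (!is.numeric(snr) || snr <= 0) abort_value("snr must be positive")
  if (n_timepoints < 2L * n_networks) {
    warning(sprintf("m = %d time points is small for K = %d networks (m >= 2K recommended)",
                    n_timepoints, n_networks), call. = FALSE)
  }
  structure(
    list(grid_shape = as.integer(grid_shape), mask_radius = mask_radius,
         n_networks = as.integer(n_networks),
         n_timepoints = as.integer(n_timepoints),
         blob_size = as.integer(blob_size), snr = snr,
         n_subjects = as.integer(n_subjects), jitter = as.numeric(jitter),
         seed = as.integer(seed), tr_seconds = tr_seconds),
    class = "synthetic_spec"
  )
}

ellipsoid_mask <- function(dims, mask_radius) {
  ctr <- (dims - 1) / 2
  semi <- pmax(mask_radius * ctr, 1)
  ax <- lapply(1:3, function(i) (((seq_len(dims[i]) - 1) - ctr[i]) / semi[i])^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  brain_mask(r2 <= 1)
}

# 6-connected neighbors of linear index `lin` that lie inside `allowed`
neighbor_lin <- function(lin, dims, allowed) {
  co <- arrayInd(lin, dims)
  out <- integer(0)
  for (ax in 1:3) {
    for (dlt in c(-1L, 1L)) {
      nb <- co
      nb[ax] <- nb[ax] + dlt
      if (nb[ax] < 1L || nb[ax] > dims[ax]) next
      l <- nb[1] + dims[1] * (nb[2] - 1L) + dims[1] * dims[2] * (nb[3] - 1L)
      if (allowed[l]) out <- c(out, l)
    }
  }
  out
}

# Grow one connected blob of `size` voxels by stochastic region growth.
# Frontier voxels are sampled with probability proportional to
# (number of in-region neighbors)^compact_power: concavities fill first,
# which keeps the blob spatially compact (as real functional regions
# are) while leaving the outline irregular — a perfect sphere would make
# downstream matching trivially easy.
grow_blob <- function(size, mask_grid, dims, compact_power = 4) {
  in_mask <- as.vector(mask_grid)
  region <- logical(length(in_mask))
  nb_count <- integer(length(in_mask))
  add <- function(v) {
    region[v] <<- TRUE
    for (l in neighbor_lin(v, dims, in_mask)) nb_count[l] <<- nb_count[l] + 1L
  }
  add(sample(which(in_mask), 1L))
  count <- 1L
  while (count < size) {
    cand <- which(nb_count > 0L & !region)
    if (length(cand) == 0L) break
    w <- as.numeric(nb_count[cand])^compact_power
    add(cand[sample.int(length(cand), 1L, prob = w)])
    count <- count + 1L
  }
  array(region, dims)
}

jaccard_arrays <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Generate ground-truth network templates
#'
#' Places K connected, random-walk-grown blobs inside an ellipsoidal
#' mask, retrying until every pair of templates has Jaccard overlap
#' below `max_pair_jaccard`. Deterministic under the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @param max_pair_jaccard pairwise overlap ceiling between templates.
#' @param max_attempts placement retries per blob before giving up.
#' @return a `template_set` (labels `"RSN01"`, ...) carrying the mask.
#' @export
generate_templates <- function(spec, max_pair_jaccard = 0.1, max_attempts = 200L) {
  dims <- spec$grid_shape
  mask <- ellipsoid_mask(dims, spec$mask_radius)
  if (spec$blob_size * 1.2 > mask$n_voxels) {
    abort_placement("blob_size does not fit inside the mask")
  }
  with_seed(spec$seed, {
    maps <- list()
    for (kk in seq_len(spec$n_networks)) {
      size <- max(2L, round(spec$blob_size * runif(1, 0.8, 1.2)))
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        cand <- grow_blob(size, mask$grid, dims)
        ok <- all(vapply(maps, function(mp) jaccard_arrays(cand, mp) < max_pair_jaccard,
                         logical(1)))
        if (ok) {
          maps[[kk]] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort_placement(sprintf(
          "could not place network %d under the pairwise-overlap constraint after %d attempts",
          kk, max_attempts))
      }
    }
    template_set(sprintf("RSN%02d", seq_len(spec$n_networks)), maps, mask = mask)
  })
}

# number of TRUE 6-neighbors per voxel, via array shifts
neighbor_count <- function(b) {
  dims <- dim(b)
  x <- array(as.integer(b), dims)
  s <- array(0L, dims)
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  s[-1, , ] <- s[-1, , ] + x[-n1, , ]
  s[-n1, , ] <- s[-n1, , ] + x[-1, , ]
  s[, -1, ] <- s[, -1, ] + x[, -n2, ]
  s[, -n2, ] <- s[, -n2, ] + x[, -1, ]
  s[, , -1] <- s[, , -1] + x[, , -n3]
  s[, , -n3] <- s[, , -n3] + x[, , -1]
  s
}

# Per-subject boundary jitter: every voxel within `jitter` voxels of the
# network border may independently flip membership (probability p per
# layer), so no voxel moves farther than `jitter`. Local, independent
# border variability is what makes group consensus across subjects
# informative; a rigid whole-network translation would be a degenerate
# perturbation whose majority vote is no better than a typical subject.
jitter_map <- function(mp, mask_grid, jitter, p = 0.25) {
  out <- mp & mask_grid
  layers <- floor(jitter)
  if (layers < 1) return(out)
  dims <- dim(out)
  for (layer in seq_len(layers)) {
    nb <- neighbor_count(out)
    inner <- out & (nb < 6L)
    outer <- (!out) & (nb > 0L) & mask_grid
    u <- array(runif(length(out)), dims)
    out <- (out & !(inner & u < p)) | (outer & u < p)
  }
  out
}

# smoothed (moving average, window 3, circular) unit-variance time courses
smooth_timecourses <- function(m, K) {
  tc <- matrix(rnorm(m * K), m, K)
  tc <- apply(tc, 2L, function(x) as.numeric(filter(x, rep(1 / 3, 3), circular = TRUE)))
  sweep(sweep(tc, 2L, colMeans(tc), "-"), 2L, apply(tc, 2L, sd), "/")
}

#' Generate one synthetic subject
#'
#' Subject maps are the templates with independent boundary jitter: each
#' voxel within `spec$jitter` voxels of a network border may flip
#' membership, so no voxel is displaced farther than `spec$jitter`.
#' Every in-mask voxel receives the sum of the unit-variance time courses
#' of the networks containing it, plus Gaussian noise with sd `1/snr`.
#'
#' @param spec a [synthetic_spec()].
#' @param templates output of [generate_templates()] for the same spec.
#' @param subject_seed RNG seed for this subject's jitter, time courses
#'   and noise.
#' @return a list: `data` (4D array), `mask`, `maps` (subject-level
#'   `template_set`), `timecourses` (m x K, unit variance),
#'   `jitter_voxels` (per network, voxels flipped relative to the
#'   template).
#' @export
generate_subject <- function(spec, templates, subject_seed) {
  mask <- templates$mask
  dims <- spec$grid_shape
  m <- spec$n_timepoints
  K <- spec$n_networks
  with_seed(subject_seed, {
    subj_maps <- lapply(seq_len(K), function(kk) {
      jitter_map(templates$maps[[kk]], mask$grid, spec$jitter)
    })
    tc <- smooth_timecourses(m, K)
    lin <- which(mask$grid)
    n <- length(lin)
    Mb <- vapply(subj_maps, function(mp) as.numeric(mp[lin]), numeric(n)) # n x K
    noise_sd <- if (is.infinite(spec$snr)) 0 else 1 / spec$snr
    V <- tc %*% t(Mb)
    if (noise_sd > 0) V <- V + noise_sd * matrix(rnorm(m * n), m, n)
    flat <- matrix(0, prod(dims), m)
    flat[lin, ] <- t(V)
    list(data = array(flat, c(dims, m)),
         mask = mask,
         maps = template_set(templates$labels, subj_maps, mask = mask),
         timecourses = tc,
         jitter_voxels = vapply(seq_len(K), function(kk) {
           sum(xor(subj_maps[[kk]], templates$maps[[kk]] & mask$grid))
         }, numeric(1)))
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes one 4D NIfTI per subject, the shared mask, one NIfTI per
#' ground-truth template, and a JSON truth sidecar (subject seeds,
#' jitter counts, time courses, template sizes). The sidecar exists only
#' for
#' evaluation; the analysis pipeline never reads it. Subject files are
#' written uncompressed so identical specs reproduce identical bytes.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return a manifest list: `subjects` (file paths), `mask`, `templates`
#'   (file paths), `truth` (sidecar path), `labels`, `spec`.
#' @export
generate_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tset <- generate_templates(spec)
  mask <- tset$mask
  mask_path <- file.path(dir, "mask.nii")
  write_volume(mask$grid * 1, mask_path, mask = mask)
  template_paths <- vapply(seq_along(tset$labels), function(i) {
    p <- file.path(dir, sprintf("template_%s.nii", tset$labels[i]))
    write_volume(tset$maps[[i]] * 1, p, mask = mask)
    p
  }, character(1))
  subject_paths <- character(spec$n_subjects)
  truth <- list(labels = tset$labels,
                template_sizes = vapply(tset$maps, sum, numeric(1)),
                subjects = list())
  for (i in seq_len(spec$n_subjects)) {
    sseed <- spec$seed + 1000L + i
    subj <- generate_subject(spec, tset, sseed)
    p <- file.path(dir, sprintf("subject_%02d.nii", i))
    write_volume(subj$data, p, mask = mask, tr_seconds = spec$tr_seconds)
    subject_paths[i] <- p
    truth$subjects[[i]] <- list(seed = sseed,
                                jitter_voxels = subj$jitter_voxels,
                                timecourses = subj$timecourses)
  }
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, digits = NA, auto_unbox = TRUE)
  list(subjects = subject_paths, mask = mask_path, templates = template_paths,
       truth = truth_path, labels = tset$labels, spec = spec)
}
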