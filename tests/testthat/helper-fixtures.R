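# Small in-code fixtures shared across test files. Everything is built
# at test time; nothing is read from disk except files the tests
# themselves write.

# desk-scale synthetic spec: 3 networks on a 14^3 grid, quick to decompose
tiny_spec <- function(seed = 11, ...) {
  args <- list(grid_shape = c(14, 14, 14), n_networks = 3L,
               n_timepoints = 40L, blob_size = 40L, snr = 8,
               n_subjects = 2L, jitter = 1, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_spec, args)
}

# one normalized tiny subject plus its ground truth
tiny_subject <- function(seed = 11, subject_seed = 101, ...) {
  spec <- tiny_spec(seed = seed, ...)
  tset <- generate_templates(spec)
  subj <- generate_subject(spec, tset, subject_seed)
  S <- normalize_signals(as_signal_matrix(subj$data, tset$mask))
  list(spec = spec, templates = tset, subject = subj, S = S)
}

# random dictionary with unit-norm atoms
random_dictionary <- function(m, k, seed = 1) {
  with_seed(seed, {
    D <- matrix(rnorm(m * k), m, k)
    sweep(D, 2, sqrt(colSums(D^2)), "/")
  })
}

# minimal stand-in component for matching tests that need only a binary map
fake_component <- function(binary_map, index = 1L) {
  structure(
    list(index = as.integer(index), timecourse = numeric(0),
         raw_map = binary_map * 1, z_map = binary_map * 1,
         binary_map = binary_map, n_active = sum(binary_map), empty = FALSE),
    class = "network_component"
  )
}

# small cuboid blob on a grid, for hand-built overlap cases
block_map <- function(dims, x, y, z) {
  a <- array(FALSE, dims)
  a[x, y, z] <- TRUE
  a
}
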