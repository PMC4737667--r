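# Identify candidate components as known resting-state networks by
# spatial overlap with labeled binary templates, assign them one-to-one,
# and aggregate per-subject matches into group-wise consensus networks.

#' Construct a template set
#'
#' @param labels character vector of template names.
#' @param maps list of 3D logical arrays, one per label, all on the same
#'   grid.
#' @param mask optional `brain_mask` the templates live on.
#' @return an object of class `template_set`.
#' @export
template_set <- function(labels, maps, mask = NULL) {
  if (length(labels) != length(maps)) abort_shape("labels and maps differ in length")
  if (length(maps) == 0L) abort_value("template set must contain at least one template")
  dims <- dim(maps[[1]])
  maps <- lapply(seq_along(maps), function(i) {
    mp <- maps[[i]]
    if (!identical(dim(mp), dims)) abort_shape("all templates must share one grid")
    mp <- array(mp != 0, dims)
    if (!any(mp)) abort_value(sprintf("template '%s' is empty", labels[i]))
    mp
  })
  names(maps) <- labels
  structure(list(labels = as.character(labels), maps = maps, mask = mask),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d templates on grid %s\n",
              length(x$labels), paste(dim(x$maps[[1]]), collapse = "x")))
  invisible(x)
}

#' Read a template set from NIfTI files
#'
#' Each file holds one binary template (any nonzero voxel is in-network).
#' The grids must already match the analysis grid; no resampling is done.
#'
#' @param paths character vector of NIfTI files, one per template.
#' @param labels template names; defaults to file names without extension.
#' @param mask optional `brain_mask`; if given, grids are checked against it.
#' @return a `template_set`.
#' @export
read_templates <- function(paths, labels = NULL, mask = NULL) {
  if (is.null(labels)) labels <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  maps <- lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    arr <- array(as.numeric(img), dim(img)[1:3])
    arr != 0
  })
  ts <- template_set(labels, maps, mask = mask)
  if (!is.null(mask) && !identical(dim(ts$maps[[1]]), dim(mask$grid))) {
    abort_shape("template grid does not match the analysis grid")
  }
  ts
}

#' Spatial overlap between two binary maps
#'
#' Default is the Jaccard coefficient `|A & T| / |A | T|`; `"dice"`
#' (`2|A & T| / (|A| + |T|)`) and `"fraction_of_template"`
#' (`|A & T| / |T|`) are available because the overlap-percentage
#' convention differs between studies. All three lie in [0, 1]; an empty
#' candidate map scores 0.
#'
#' @param A 3D logical candidate map.
#' @param T_map 3D logical template map (must be nonempty).
#' @param method `"jaccard"`, `"dice"` or `"fraction_of_template"`.
#' @return overlap score in [0, 1].
#' @export
spatial_overlap <- function(A, T_map, method = c("jaccard", "dice", "fraction_of_template")) {
  method <- match.arg(method)
  if (!identical(dim(A), dim(T_map))) abort_shape("maps must share one grid")
  A <- A != 0
  T_map <- T_map != 0
  nT <- sum(T_map)
  if (nT == 0L) abort_value("template map is empty")
  nA <- sum(A)
  if (nA == 0L) return(0)
  ni <- sum(A & T_map)
  switch(method,
         jaccard = ni / (nA + nT - ni),
         dice = 2 * ni / (nA + nT),
         fraction_of_template = ni / nT)
}

#' Assign components to templates by greedy one-to-one matching
#'
#' Repeatedly takes the (template, component) pair with the highest
#' overlap among the still-unassigned, until every template is assigned
#' or the best remaining overlap drops below `min_overlap`. Ties break to
#' the lower template index, then the lower component index, so the
#' assignment is deterministic.
#'
#' @param components list of `network_component` objects (their
#'   `binary_map` is scored).
#' @param templates a `template_set`.
#' @param min_overlap assignment floor; templates whose best remaining
#'   overlap is below it stay unmatched (`NA`).
#' @param method overlap definition, see [spatial_overlap()].
#' @return an object of class `match_result`: `assignment` (named integer
#'   vector, template label -> component index, `NA` if unmatched),
#'   `overlaps` (named numeric), `overlap_matrix` (templates x
#'   components), `method`.
#' @export
match_components <- function(components, templates, min_overlap = 0.05,
                             method = c("jaccard", "dice", "fraction_of_template")) {
  method <- match.arg(method)
  if (length(components) == 0L) abort_value("need at least one component")
  K <- length(templates$labels)
  k <- length(components)
  ov <- matrix(0, K, k, dimnames = list(templates$labels, NULL))
  for (i in seq_len(K)) {
    for (j in seq_len(k)) {
      ov[i, j] <- spatial_overlap(components[[j]]$binary_map,
                                  templates$maps[[i]], method = method)
    }
  }
  assignment <- rep(NA_integer_, K)
  overlaps <- rep(0, K)
  names(assignment) <- names(overlaps) <- templates$labels
  free_t <- rep(TRUE, K)
  free_c <- rep(TRUE, k)
  work <- ov
  repeat {
    work_masked <- work
    work_masked[!free_t, ] <- -Inf
    work_masked[, !free_c] <- -Inf
    best <- max(work_masked)
    if (!is.finite(best) || best < min_overlap) break
    # which() scans column-major, so the first hit has the lowest
    # component index among the lowest template indices -> deterministic
    hit <- which(t(work_masked) == best)[1]
    ti <- ((hit - 1L) %/% k) + 1L
    ci <- ((hit - 1L) %% k) + 1L
    assignment[ti] <- components[[ci]]$index
    overlaps[ti] <- ov[ti, ci]
    free_t[ti] <- FALSE
    free_c[ci] <- FALSE
    if (!any(free_t) || !any(free_c)) break
  }
  structure(
    list(assignment = assignment, overlaps = overlaps,
         overlap_matrix = ov, method = method),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d/%d templates assigned (%s overlap)\n",
              sum(!is.na(x$assignment)), length(x$assignment), x$method))
  invisible(x)
}

# binary map of the component matched to template label `lab`, or NULL
matched_map <- function(match, components, lab) {
  ci <- match$assignment[[lab]]
  if (is.na(ci)) return(NULL)
  idx <- vapply(components, function(cp) cp$index, integer(1))
  components[[which(idx == ci)[1]]]$binary_map
}

#' Group-wise consensus networks across subjects
#'
#' For each template label, the binary maps of the matched component in
#' every subject that matched it are stacked; the voxelwise proportion of
#' matching subjects is binarized at `consensus_thresh` to form the group
#' map, which is then scored against the template. A label matched in no
#' subject yields an empty group map with overlap 0.
#'
#' @param matches list of `match_result`, one per subject.
#' @param components_list list (per subject) of component lists, aligned
#'   with `matches`.
#' @param templates the `template_set` used for matching.
#' @param consensus_thresh proportion of matched subjects a voxel must
#'   reach to enter the group map (default 0.5).
#' @param method overlap definition for the group score.
#' @return a list with `group_maps` (named list of 3D logical arrays),
#'   `overlaps` (named numeric, group map vs template), `n_matched`
#'   (subjects matched per label).
#' @export
groupwise_networks <- function(matches, components_list, templates,
                               consensus_thresh = 0.5,
                               method = c("jaccard", "dice", "fraction_of_template")) {
  method <- match.arg(method)
  if (length(matches) < 1L) abort_value("need at least one subject")
  if (length(matches) != length(components_list)) {
    abort_shape("matches and components_list differ in length")
  }
  dims <- dim(templates$maps[[1]])
  group_maps <- list()
  overlaps <- rep(0, length(templates$labels))
  n_matched <- integer(length(templates$labels))
  names(overlaps) <- names(n_matched) <- templates$labels
  for (lab in templates$labels) {
    maps <- list()
    for (s in seq_along(matches)) {
      mp <- matched_map(matches[[s]], components_list[[s]], lab)
      if (!is.null(mp)) maps[[length(maps) + 1L]] <- mp
    }
    n_matched[[lab]] <- length(maps)
    if (length(maps) == 0L) {
      group_maps[[lab]] <- array(FALSE, dims)
      overlaps[[lab]] <- 0
      next
    }
    prop <- Reduce(`+`, lapply(maps, function(m) m * 1)) / length(maps)
    gm <- prop >= consensus_thresh
    group_maps[[lab]] <- gm
    overlaps[[lab]] <- spatial_overlap(gm, templates$maps[[lab]], method = method)
  }
  list(group_maps = group_maps, overlaps = overlaps, n_matched = n_matched)
}

#' Group and individual overlap tables
#'
#' The group table has one row per dataset and one column per template
#' (the group-map overlap); the individual table reports the per-dataset
#' mean and standard deviation (population form, n denominator) of the
#' per-subject overlaps, plus a formatted "mean ± sd" view.
#'
#' @param group_results named list: dataset id -> named numeric vector of
#'   group overlaps per template.
#' @param individual_results named list: dataset id -> subjects x
#'   templates numeric matrix of per-subject overlaps.
#' @return a list of data.frames: `group`, `individual_mean`,
#'   `individual_sd`, `individual` (formatted strings).
#' @export
overlap_tables <- function(group_results, individual_results) {
  datasets <- names(group_results)
  labs <- if (length(group_results) > 0) names(group_results[[1]]) else character(0)
  g <- do.call(rbind, lapply(group_results, function(v) as.data.frame(as.list(v))))
  group_df <- data.frame(dataset = datasets, g, check.names = FALSE, row.names = NULL)
  colnames(group_df) <- c("dataset", labs)

  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  mk <- function(f) {
    rows <- lapply(datasets, function(ds) {
      M <- individual_results[[ds]]
      vapply(labs, function(l) f(M[, l]), numeric(1))
    })
    out <- data.frame(dataset = datasets, do.call(rbind, rows),
                      check.names = FALSE, row.names = NULL)
    colnames(out) <- c("dataset", labs)
    out
  }
  mean_df <- mk(mean)
  sd_df <- mk(pop_sd)
  fmt <- mean_df
  for (l in labs) {
    fmt[[l]] <- sprintf("%.2f ± %.2f", mean_df[[l]], sd_df[[l]])
  }
  list(group = group_df, individual_mean = mean_df,
       individual_sd = sd_df, individual = fmt)
}
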