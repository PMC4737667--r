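# Per-subject and group orchestration: load -> normalize -> (sampled)
# dictionary learning -> component mapping -> template matching, with
# NIfTI/CSV/JSON artifacts and a manifest naming every file written.
# Manifests record file names relative to the bundle directory and carry
# no timestamps, so reruns with the same config and seed reproduce the
# CSV/JSON outputs byte for byte. Stage timings go to a separate plain
# .log file, which is informational only.

#' Pipeline configuration
#'
#' @param subjects character vector of 4D NIfTI paths, one per subject.
#' @param mask path to the 3D NIfTI brain mask shared by all subjects.
#' @param templates character vector of NIfTI template paths.
#' @param output_dir directory for all artifacts.
#' @param odl an [odl_config()].
#' @param sampling optional [sampling_config()]; `NULL` disables sampling.
#' @param z_thresh two-sided z threshold for component binarization.
#' @param overlap_method overlap definition, see [spatial_overlap()].
#' @param min_overlap assignment floor for [match_components()].
#' @param consensus_thresh group consensus proportion.
#' @param seed pipeline seed; propagated to the learning stage when the
#'   `odl` config does not override it explicitly.
#' @param write_maps write per-component z-map NIfTIs (disable to save
#'   disk on large k).
#' @param template_labels optional labels for the templates; defaults to
#'   file names.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(subjects, mask, templates, output_dir,
                            odl = odl_config(), sampling = NULL,
                            z_thresh = 2.0, overlap_method = "jaccard",
                            min_overlap = 0.05, consensus_thresh = 0.5,
                            seed = 1L, write_maps = TRUE,
                            template_labels = NULL) {
  for (p in c(subjects, mask, templates)) {
    if (!file.exists(p)) abort_value(sprintf("input file does not exist: %s", p))
  }
  overlap_method <- match.arg(overlap_method, c("jaccard", "dice", "fraction_of_template"))
  if (!inherits(odl, "odl_config")) abort_value("odl must be an odl_config")
  if (!is.null(sampling) && !inherits(sampling, "sampling_config")) {
    abort_value("sampling must be NULL or a sampling_config")
  }
  structure(
    list(subjects = subjects, mask = mask, templates = templates,
         output_dir = output_dir, odl = odl, sampling = sampling,
         z_thresh = z_thresh, overlap_method = overlap_method,
         min_overlap = min_overlap, consensus_thresh = consensus_thresh,
         seed = as.integer(seed), write_maps = isTRUE(write_maps),
         template_labels = template_labels),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors the arguments of [pipeline_config()]; `odl` and
#' `sampling` are nested maps passed to their constructors. Relative
#' input paths are resolved against the config file's directory.
#'
#' @param path YAML (.yml/.yaml) or JSON config file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  odl <- do.call(odl_config, raw$odl %||% list())
  sampling <- if (!is.null(raw$sampling)) do.call(sampling_config, raw$sampling) else NULL
  pipeline_config(
    subjects = resolve(unlist(raw$subjects)),
    mask = resolve(raw$mask),
    templates = resolve(unlist(raw$templates)),
    output_dir = raw$output_dir %||% file.path(base, "out"),
    odl = odl, sampling = sampling,
    z_thresh = raw$z_thresh %||% 2.0,
    overlap_method = raw$overlap_method %||% "jaccard",
    min_overlap = raw$min_overlap %||% 0.05,
    consensus_thresh = raw$consensus_thresh %||% 0.5,
    seed = raw$seed %||% 1L,
    write_maps = raw$write_maps %||% TRUE,
    template_labels = raw$template_labels
  )
}

write_manifest <- function(manifest, dir) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  path
}

# deterministic CSV writer (fixed row.names and quoting)
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the per-subject pipeline
#'
#' Executes load -> normalize -> (sampled) dictionary learning ->
#' component mapping -> template matching for one subject, writing z-map
#' NIfTIs, a component summary CSV, a match CSV and a JSON manifest into
#' `output_dir/<subject_id>/`. A stage failure is recorded in the
#' manifest (with the stage name) and already-written artifacts are
#' retained.
#'
#' @param cfg a [pipeline_config()].
#' @param subject_path 4D NIfTI file for this subject.
#' @param subject_id identifier used for the output subdirectory;
#'   defaults to the file name without extension.
#' @return a subject bundle: `ok`, `subject_id`, `dir`, and on success
#'   `fit`, `components`, `summary`, `match`, `manifest`.
#' @export
run_subject <- function(cfg, subject_path, subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(subject_path))
  }
  sdir <- file.path(cfg$output_dir, subject_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(subject_id = subject_id, ok = FALSE,
                   stages = list(), files = character(0))
  log_lines <- character(0)
  bundle <- list(ok = FALSE, subject_id = subject_id, dir = sdir)
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) e)
    el <- proc.time()[["elapsed"]] - t0
    log_lines <<- c(log_lines, sprintf("%s: %.2fs", name, el))
    if (inherits(val, "error")) {
      manifest$stages[[name]] <<- "failed"
      manifest$error <<- list(stage = name, message = conditionMessage(val))
      val <- NULL
    } else {
      manifest$stages[[name]] <<- "ok"
    }
    val
  }
  finish <- function() {
    mpath <- write_manifest(manifest, sdir)
    writeLines(log_lines, file.path(sdir, "stages.log"))
    bundle$manifest <- manifest
    bundle$manifest_path <- mpath
    bundle
  }

  S <- run_stage("load", load_fmri(subject_path, cfg$mask))
  if (is.null(S)) return(finish())
  S <- run_stage("normalize", normalize_signals(S))
  if (is.null(S)) return(finish())

  odl <- cfg$odl
  fit <- run_stage("learn", {
    if (!is.null(cfg$sampling)) {
      learn_dictionary_sampled(S, odl, cfg$sampling)
    } else {
      learn_dictionary(S, odl)
    }
  })
  if (is.null(fit)) return(finish())

  comps <- run_stage("components",
                     build_components(fit$dictionary, fit$alpha, S$mask,
                                      S$voxel_index, cfg$z_thresh))
  if (is.null(comps)) return(finish())

  templates <- run_stage("templates",
                         read_templates(cfg$templates, labels = cfg$template_labels,
                                        mask = S$mask))
  if (is.null(templates)) return(finish())
  match <- run_stage("match",
                     match_components(comps, templates,
                                      min_overlap = cfg$min_overlap,
                                      method = cfg$overlap_method))
  if (is.null(match)) return(finish())

  written <- run_stage("write", {
    files <- character(0)
    summ <- component_summary(comps)
    f1 <- "component_summary.csv"
    write_table_csv(summ, file.path(sdir, f1))
    files <- c(files, f1)
    match_df <- data.frame(template = names(match$assignment),
                           component = unname(match$assignment),
                           overlap = unname(match$overlaps))
    f2 <- "template_match.csv"
    write_table_csv(match_df, file.path(sdir, f2))
    files <- c(files, f2)
    if (cfg$write_maps) {
      wd <- max(3L, nchar(length(comps) - 1L))
      for (cp in comps) {
        fz <- sprintf("component_%0*d_zmap.nii", wd, cp$index - 1L)
        write_volume(cp$z_map, file.path(sdir, fz), mask = S$mask)
        files <- c(files, fz)
      }
    }
    list(files = files, summary = summ, match_table = match_df)
  })
  if (!is.null(written)) {
    manifest$files <- written$files
    bundle$summary <- written$summary
    bundle$match_table <- written$match_table
  }

  manifest$ok <- is.null(manifest$error)
  bundle$ok <- manifest$ok
  bundle$fit <- fit
  bundle$components <- comps
  bundle$match <- match
  bundle$templates <- templates
  finish()
}

#' Run the group-level pipeline
#'
#' Aggregates successful subject bundles into group-wise consensus
#' networks, writes the group and individual overlap tables as CSV, one
#' montage PNG per template (most informative axial slice), and a group
#' manifest.
#'
#' @param cfg a [pipeline_config()].
#' @param subject_results list of bundles from [run_subject()].
#' @param dataset_id label used in the tables and output directory.
#' @return a group bundle: `group` (consensus maps and overlaps),
#'   `tables`, `dir`, `manifest`.
#' @export
run_group <- function(cfg, subject_results, dataset_id = "dataset") {
  ok <- Filter(function(b) isTRUE(b$ok), subject_results)
  if (length(ok) == 0L) abort_value("no successful subjects to aggregate")
  gdir <- file.path(cfg$output_dir, paste0("group_", dataset_id))
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)

  templates <- ok[[1]]$templates
  matches <- lapply(ok, `[[`, "match")
  comps <- lapply(ok, `[[`, "components")
  grp <- groupwise_networks(matches, comps, templates,
                            consensus_thresh = cfg$consensus_thresh,
                            method = cfg$overlap_method)

  indiv <- do.call(rbind, lapply(matches, `[[`, "overlaps"))
  rownames(indiv) <- vapply(ok, `[[`, character(1), "subject_id")
  tabs <- overlap_tables(
    group_results = stats::setNames(list(grp$overlaps), dataset_id),
    individual_results = stats::setNames(list(indiv), dataset_id)
  )

  files <- character(0)
  f <- "group_overlap.csv"
  write_table_csv(tabs$group, file.path(gdir, f)); files <- c(files, f)
  f <- "individual_overlap_mean.csv"
  write_table_csv(tabs$individual_mean, file.path(gdir, f)); files <- c(files, f)
  f <- "individual_overlap_sd.csv"
  write_table_csv(tabs$individual_sd, file.path(gdir, f)); files <- c(files, f)
  f <- "individual_overlap.csv"
  write_table_csv(tabs$individual, file.path(gdir, f)); files <- c(files, f)
  for (lab in templates$labels) {
    f <- sprintf("montage_%s.png", lab)
    montage_png(grp$group_maps[[lab]], templates$maps[[lab]],
                file.path(gdir, f), label = lab)
    files <- c(files, f)
    fg <- sprintf("group_%s.nii", lab)
    write_volume(grp$group_maps[[lab]] * 1, file.path(gdir, fg),
                 mask = templates$mask)
    files <- c(files, fg)
  }
  manifest <- list(dataset_id = dataset_id, ok = TRUE,
                   n_subjects = length(ok), files = files)
  write_manifest(manifest, gdir)
  list(group = grp, tables = tabs, dir = gdir, manifest = manifest,
       templates = templates)
}

#' Render a per-component PNG gallery
#'
#' One axial-mosaic PNG per component, named with zero-padded sequential
#' indices, plus a JSON index listing every file.
#'
#' @param bundle a successful subject bundle from [run_subject()].
#' @param dir output directory; defaults to `<bundle dir>/report`.
#' @return the index list (`files`, `n_active`), invisibly.
#' @export
report <- function(bundle, dir = NULL) {
  if (!isTRUE(bundle$ok) && is.null(bundle$components)) {
    abort_value("bundle is incomplete; run_subject must succeed first")
  }
  if (is.null(dir)) dir <- file.path(bundle$dir, "report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comps <- bundle$components
  wd <- max(3L, nchar(length(comps) - 1L))
  files <- vapply(comps, function(cp) {
    f <- sprintf("component_%0*d.png", wd, cp$index - 1L)
    component_png(cp$z_map, file.path(dir, f),
                  title_text = sprintf("component %d (%d voxels)",
                                       cp$index - 1L, cp$n_active))
    f
  }, character(1))
  index <- list(files = files,
                n_active = vapply(comps, `[[`, integer(1), "n_active"))
  jsonlite::write_json(index, file.path(dir, "index.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(index)
}
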