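#' Z-spectrum stack
#'
#' The shared in-memory container for one subject's saturation data:
#' a 3-D array (x, y, offset) of signal, the offset axis, a voxel mask,
#' and optionally the unsaturated reference image S0. Signal may be raw
#' scanner units (then `normalized = FALSE` and [normalize_stack()]
#' divides by S0) or already normalized Z = S/S0. Everything downstream
#' consumes masked voxels only.
#'
#' @param signal numeric array, dim `c(nx, ny, n_offsets)`.
#' @param offsets_ppm numeric vector matching the 3rd dimension; must be
#'   strictly increasing.
#' @param mask logical matrix `nx` x `ny`; default: voxels finite at
#'   every offset.
#' @param reference optional S0 matrix (arbitrary units).
#' @param normalized whether `signal` is already S/S0.
#' @param schedule optional [saturation_schedule()] the data were
#'   acquired with.
#' @return object of class `zspec_stack`.
#' @export
zspec_stack <- function(signal, offsets_ppm, mask = NULL, reference = NULL,
                        normalized = TRUE, schedule = NULL) {
  if (length(dim(signal)) != 3L)
    stop("signal must be a 3-D array (x, y, offset)")
  offsets_ppm <- as.numeric(offsets_ppm)
  if (dim(signal)[3] != length(offsets_ppm))
    stop(sprintf("signal has %d volumes but %d offsets were supplied",
                 dim(signal)[3], length(offsets_ppm)))
  if (any(diff(offsets_ppm) <= 0))
    stop("offsets_ppm must be strictly increasing (use read_cest_study for unsorted data)")
  if (is.null(mask)) {
    mask <- apply(is.finite(signal), c(1, 2), all)
  }
  if (!is.logical(mask) || !all(dim(mask) == dim(signal)[1:2]))
    stop("mask must be a logical matrix matching the signal grid")
  if (!is.null(reference) && !all(dim(reference) == dim(signal)[1:2]))
    stop("reference must match the signal grid")
  bad <- mask & !apply(is.finite(signal), c(1, 2), all)
  if (any(bad))
    stop(sprintf("%d masked voxel(s) contain non-finite signal", sum(bad)))
  structure(list(signal = signal, offsets_ppm = offsets_ppm, mask = mask,
                 reference = reference, normalized = isTRUE(normalized),
                 schedule = schedule),
            class = "zspec_stack")
}

#' @export
print.zspec_stack <- function(x, ...) {
  cat(sprintf("<zspec_stack> %d x %d grid, %d offsets (%.2f..%.2f ppm), %d masked voxels, %s\n",
              dim(x$signal)[1], dim(x$signal)[2], length(x$offsets_ppm),
              min(x$offsets_ppm), max(x$offsets_ppm), sum(x$mask),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' ROI label map
#'
#' Integer label image plus a legend mapping label values to region
#' names. The canonical legend covers cortex, hippocampus,
#' piriform_cortex and thalamus; the whole-brain region is always
#' derived as the union of all labeled voxels and never stored as a
#' label of its own.
#'
#' @param labels integer matrix (0 = background).
#' @param legend named character vector, names = label integers.
#' @return object of class `roi_label_map`.
#' @export
roi_label_map <- function(labels, legend) {
  storage.mode(labels) <- "integer"
  if (is.null(names(legend))) stop("legend must be named by label integer")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(present, as.integer(names(legend)))
  if (length(missing))
    stop("labels contain values absent from legend: ",
         paste(missing, collapse = ", "))
  if ("whole_brain" %in% legend)
    stop("whole_brain must not be stored as a label; it is derived as the union")
  structure(list(labels = labels, legend = legend), class = "roi_label_map")
}

region_voxels <- function(label_map, region) {
  if (region == "whole_brain") return(which(label_map$labels > 0L))
  lab <- as.integer(names(label_map$legend)[match(region, unname(label_map$legend))])
  if (is.na(lab)) stop("unknown region: ", region)
  which(label_map$labels == lab)
}

#' Normalize a raw stack by its reference image
#'
#' Divides each voxel's signal by its unsaturated reference S0. Voxels
#' with S0 <= 0 cannot be normalized and are removed from the mask with
#' a warning reporting the count.
#'
#' @param stack a raw [zspec_stack()] carrying a reference image.
#' @return normalized `zspec_stack` (signal = S/S0).
#' @export
normalize_stack <- function(stack) {
  stopifnot(inherits(stack, "zspec_stack"))
  if (stack$normalized) return(stack)
  if (is.null(stack$reference))
    stop("stack has no reference image; if the data are already normalized, ",
         "construct the stack with normalized = TRUE")
  mask <- stack$mask
  bad <- mask & !(is.finite(stack$reference) & stack$reference > 0)
  if (any(bad)) {
    warning(sprintf("dropping %d voxel(s) with non-positive S0 from the mask",
                    sum(bad)))
    mask[bad] <- FALSE
  }
  sig <- stack$signal
  ref <- stack$reference
  ref[!mask] <- NA_real_
  for (j in seq_len(dim(sig)[3])) sig[, , j] <- sig[, , j] / ref
  zspec_stack(sig, stack$offsets_ppm, mask = mask,
              reference = stack$reference, normalized = TRUE,
              schedule = stack$schedule)
}

write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(
    list(offsets_ppm = schedule$offsets_ppm,
         b1_uT = schedule$b1_uT, t_sat_s = schedule$t_sat_s),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_nifti_array <- function(path) {
  x <- RNifti::readNifti(path)
  array(as.vector(x), dim(x))
}

read_schedule_json <- function(path) {
  if (!file.exists(path)) stop("missing offsets sidecar: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  saturation_schedule(j$offsets_ppm, j$b1_uT, j$t_sat_s)
}

write_nifti_vol <- function(x, path) {
  dt <- if (is.integer(x)) "int32" else "double"
  RNifti::writeNifti(RNifti::asNifti(x), path, datatype = dt)
  invisible(path)
}

#' Write a phantom study to disk
#'
#' Serializes a [generate_phantom_study()] bundle in the on-disk layout
#' the pipeline reads back: per subject `<id>_cest.nii.gz`,
#' `<id>_wassr.nii.gz`, `<id>_ref.nii.gz` and `<id>_b0truth.nii.gz`;
#' shared `labels.nii.gz`, JSON offset sidecars for both schedules,
#' `design.csv`, `ground_truth.csv` and a `manifest.txt` listing every
#' file written.
#'
#' @param study a `phantom_study`.
#' @param dir output directory (created if needed).
#' @param force overwrite an existing non-empty directory.
#' @return invisibly, the manifest (character vector of paths).
#' @export
write_phantom_study <- function(study, dir, force = FALSE) {
  stopifnot(inherits(study, "phantom_study"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force)
    stop("output directory ", dir, " is not empty; use force = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    write_nifti_vol(x, p)
    files <<- c(files, name)
    p
  }
  for (s in study$subjects) {
    wr(s$cest$signal, paste0(s$id, "_cest.nii.gz"))
    wr(s$wassr$signal, paste0(s$id, "_wassr.nii.gz"))
    wr(s$cest$reference, paste0(s$id, "_ref.nii.gz"))
    wr(s$b0_truth, paste0(s$id, "_b0truth.nii.gz"))
  }
  wr(study$labels$labels, "labels.nii.gz")
  write_schedule_json(study$config$schedule, file.path(dir, "cest_schedule.json"))
  write_schedule_json(study$config$wassr_sched, file.path(dir, "wassr_schedule.json"))
  utils::write.csv(study$design, file.path(dir, "design.csv"), row.names = FALSE)
  utils::write.csv(study$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  legend <- data.frame(label = as.integer(names(study$labels$legend)),
                       region = unname(study$labels$legend))
  utils::write.csv(legend, file.path(dir, "legend.csv"), row.names = FALSE)
  files <- c(files, "cest_schedule.json", "wassr_schedule.json",
             "design.csv", "ground_truth.csv", "legend.csv")
  writeLines(sort(files), file.path(dir, "manifest.txt"))
  invisible(c(files, "manifest.txt"))
}

#' Read a CEST study from disk
#'
#' Loads the study layout written by [write_phantom_study()] (or
#' assembled by hand in the same layout) into the in-memory bundle the
#' pipeline consumes. Offsets are sorted ascending with signal volumes
#' reordered to match; grid shapes and sidecar/volume counts are
#' validated with descriptive errors.
#'
#' @param dir study directory.
#' @return list with `subjects` (per subject: `id`, `group`, `cest` raw
#'   [zspec_stack()], `wassr` stack list), `labels`, `design`, and
#'   `truth` (NULL when no ground-truth table is present).
#' @export
read_cest_study <- function(dir) {
  if (!dir.exists(dir)) stop("study directory not found: ", dir)
  design_path <- file.path(dir, "design.csv")
  if (!file.exists(design_path)) stop("missing design table: ", design_path)
  design <- utils::read.csv(design_path, stringsAsFactors = FALSE)
  if (anyDuplicated(design$subject_id))
    stop("design.csv contains duplicate subject ids")
  sched <- read_schedule_json(file.path(dir, "cest_schedule.json"))
  wassr_sched <- read_schedule_json(file.path(dir, "wassr_schedule.json"))
  legend_df <- utils::read.csv(file.path(dir, "legend.csv"),
                               stringsAsFactors = FALSE)
  labels_img <- read_nifti_array(file.path(dir, "labels.nii.gz"))
  labels_mat <- matrix(as.integer(round(labels_img)),
                       dim(labels_img)[1], dim(labels_img)[2])
  legend <- stats::setNames(legend_df$region, legend_df$label)
  labels <- roi_label_map(labels_mat, legend)
  mask <- labels_mat > 0L
  subjects <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    id <- design$subject_id[i]
    cest_path <- file.path(dir, paste0(id, "_cest.nii.gz"))
    wassr_path <- file.path(dir, paste0(id, "_wassr.nii.gz"))
    ref_path <- file.path(dir, paste0(id, "_ref.nii.gz"))
    for (p in c(cest_path, wassr_path, ref_path))
      if (!file.exists(p))
        stop("subject ", id, ": expected file not found: ", p)
    cest <- read_nifti_array(cest_path)
    if (length(dim(cest)) != 3L)
      stop("subject ", id, ": CEST stack must be 3-D (x, y, offset)")
    if (dim(cest)[3] != length(sched$offsets_ppm))
      stop(sprintf("subject %s: sidecar lists %d offsets but the stack has %d volumes",
                   id, length(sched$offsets_ppm), dim(cest)[3]))
    if (!all(dim(cest)[1:2] == dim(labels_mat)))
      stop("subject ", id, ": CEST grid does not match the label map")
    ref <- read_nifti_array(ref_path)
    ref <- matrix(ref, dim(cest)[1], dim(cest)[2])
    wassr <- read_nifti_array(wassr_path)
    if (dim(wassr)[3] != length(wassr_sched$offsets_ppm))
      stop(sprintf("subject %s: WASSR sidecar lists %d offsets but the stack has %d volumes",
                   id, length(wassr_sched$offsets_ppm), dim(wassr)[3]))
    subjects[[i]] <- list(
      id = id, group = design$group[i],
      cest = zspec_stack(cest, sched$offsets_ppm, mask = mask,
                         reference = ref, normalized = FALSE,
                         schedule = sched),
      wassr = list(signal = wassr, schedule = wassr_sched,
                   edge = matrix(FALSE, dim(cest)[1], dim(cest)[2]))
    )
  }
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  list(subjects = subjects, labels = labels, design = design, truth = truth)
}

#' Sort an offset axis ascending, reordering signal to match
#'
#' Helper for data delivered with unsorted or descending offset tables.
#' Duplicated offsets are rejected.
#'
#' @param signal 3-D array (x, y, offset).
#' @param offsets_ppm offsets matching the 3rd dimension.
#' @return list with sorted `offsets_ppm` and reordered `signal`.
#' @export
sort_offsets <- function(signal, offsets_ppm) {
  if (dim(signal)[3] != length(offsets_ppm))
    stop(sprintf("signal has %d volumes but %d offsets were supplied",
                 dim(signal)[3], length(offsets_ppm)))
  if (anyDuplicated(offsets_ppm)) stop("duplicate offsets are not allowed")
  ord <- order(offsets_ppm)
  list(offsets_ppm = offsets_ppm[ord], signal = signal[, , ord, drop = FALSE])
}
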