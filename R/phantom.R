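# Synthetic sinus phantoms: an ellipsoidal low-intensity air cavity inside
# brighter tissue, wrapped in a thin mucosal lining, with optional lesions
# (polyp-like / cyst-like blobs protruding into the cavity, or locally
# thickened lining) and ground-truth lesion masks. These phantoms exercise
# every downstream stage without clinical MRI data.

#' Phantom generation parameters
#'
#' Intensities are dimensionless in `[0, 1]`. The mucosal lining shares
#' `lesion_intensity` (mucosa and the mucosa-derived lesions have the same
#' signal), so a noise-free normal phantom takes exactly the three configured
#' intensity values: tissue, air, and lesion/lining.
#'
#' @param cube_edge Cube edge length in voxels (32 for routine runs, 64 for
#'   full-scale volumes).
#' @param cavity_semi_axes Ellipsoid semi-axes of the air cavity in voxels;
#'   default scales with the cube edge. The cavity plus lining must fit
#'   strictly inside the cube.
#' @param lining_thickness Mucosal lining thickness in voxels.
#' @param tissue_intensity,air_intensity,lesion_intensity Intensities in
#'   `[0, 1]` for surrounding tissue, cavity air, and lesion/lining.
#' @param noise_sd Standard deviation of additive Gaussian noise (clipped to
#'   `[0, 1]`).
#' @param lesion_radius_range Min/max lesion radius in voxels.
#' @param lesion_type One of `"polyp_like"`, `"cyst_like"`,
#'   `"mucosal_thickening"`.
#' @param jitter Relative jitter of the cavity semi-axes and centre between
#'   phantoms (anatomical variability).
#' @param seed Integer seed; generation is a pure function of (seed, params).
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(cube_edge = 32L,
                           cavity_semi_axes = NULL,
                           lining_thickness = 2,
                           tissue_intensity = 0.8,
                           air_intensity = 0.05,
                           lesion_intensity = 0.6,
                           noise_sd = 0.05,
                           lesion_radius_range = NULL,
                           lesion_type = c("polyp_like", "cyst_like", "mucosal_thickening"),
                           jitter = 0.08,
                           seed = 1L) {
  lesion_type <- match.arg(lesion_type)
  cube_edge <- as.integer(cube_edge)
  if (is.null(cavity_semi_axes))
    cavity_semi_axes <- cube_edge * c(0.32, 0.27, 0.30)
  if (is.null(lesion_radius_range))
    lesion_radius_range <- cube_edge * c(0.09, 0.17)
  for (v in c(tissue_intensity, air_intensity, lesion_intensity))
    if (v < 0 || v > 1) stop("intensity parameters must lie in [0,1]")
  if (any(cavity_semi_axes + lining_thickness >= cube_edge / 2))
    stop("cavity plus lining does not fit strictly inside the cube")
  if (lesion_radius_range[1] > min(cavity_semi_axes))
    stop("lesion cannot fit inside the cavity")
  structure(list(cube_edge = cube_edge,
                 cavity_semi_axes = cavity_semi_axes,
                 lining_thickness = lining_thickness,
                 tissue_intensity = tissue_intensity,
                 air_intensity = air_intensity,
                 lesion_intensity = lesion_intensity,
                 noise_sd = noise_sd,
                 lesion_radius_range = lesion_radius_range,
                 lesion_type = lesion_type,
                 jitter = jitter,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' An MS volume container
#'
#' @param data 3D intensity array in `[0, 1]`.
#' @param patient_id Patient identifier string.
#' @param side `"left"` or `"right"`.
#' @param label Optional `"normal"` / `"anomalous"`.
#' @return An `ms_volume` object.
#' @export
ms_volume <- function(data, patient_id = NA_character_, side = "left", label = NULL) {
  stopifnot(length(dim(data)) == 3L)
  structure(list(data = data, patient_id = patient_id, side = side, label = label),
            class = "ms_volume")
}

#' @export
print.ms_volume <- function(x, ...) {
  cat(sprintf("<ms_volume> %s patient=%s side=%s label=%s\n",
              paste(dim(x$data), collapse = "x"), x$patient_id, x$side,
              x$label %||% "NA"))
  invisible(x)
}

# Squared normalized ellipsoid radius for every voxel (voxel centres at
# 1..edge, cavity centred at `centre`).
ellipsoid_r2 <- function(edge, centre, semi) {
  ax <- ((seq_len(edge) - centre[1]) / semi[1])^2
  ay <- ((seq_len(edge) - centre[2]) / semi[2])^2
  az <- ((seq_len(edge) - centre[3]) / semi[3])^2
  outer(outer(ax, ay, "+"), az, "+")
}

# Deterministic geometry draw shared by normal and anomalous phantoms of the
# same seed: cavity jitter uses stream (seed), lesion placement (seed + 1e6),
# noise (seed + 2e6), so erasing the lesion recovers the normal phantom.
phantom_geometry <- function(params) {
  with_seed(params$seed, {
    e <- params$cube_edge
    semi <- params$cavity_semi_axes * runif(3, 1 - params$jitter, 1 + params$jitter)
    centre <- (e + 1) / 2 + runif(3, -0.04 * e, 0.04 * e)
    list(edge = e, semi = semi, centre = centre)
  })
}

phantom_base <- function(params, geom) {
  e <- geom$edge
  r2_in <- ellipsoid_r2(e, geom$centre, geom$semi)
  r2_out <- ellipsoid_r2(e, geom$centre, geom$semi + params$lining_thickness)
  vol <- array(params$tissue_intensity, c(e, e, e))
  vol[r2_out <= 1] <- params$lesion_intensity  # mucosal lining
  vol[r2_in <= 1] <- params$air_intensity      # air cavity
  list(vol = vol, air = r2_in <= 1, lining = r2_out <= 1 & r2_in > 1)
}

phantom_noise <- function(vol, params) {
  if (params$noise_sd <= 0) return(vol)
  with_seed(params$seed + 2000000L, {
    clip01(vol + array(rnorm(length(vol), 0, params$noise_sd), dim(vol)))
  })
}

#' Generate a normal (lesion-free) sinus phantom
#'
#' @param params A [phantom_params()].
#' @return A `phantom_sample`: list with `volume` (an `ms_volume`),
#'   `lesion_mask` (all-zero integer array), `label = "normal"` and
#'   `metadata` (the parameters actually drawn). Identical seeds give
#'   bit-identical output.
#' @export
generate_normal_volume <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  geom <- phantom_geometry(params)
  base <- phantom_base(params, geom)
  vol <- phantom_noise(base$vol, params)
  structure(list(volume = ms_volume(vol, side = "left", label = "normal"),
                 lesion_mask = array(0L, dim(vol)),
                 label = "normal",
                 metadata = params),
            class = "phantom_sample")
}

# Voxels within `radius` of `centre`.
sphere_mask <- function(edge, centre, radius) {
  ax <- (seq_len(edge) - centre[1])^2
  ay <- (seq_len(edge) - centre[2])^2
  az <- (seq_len(edge) - centre[3])^2
  outer(outer(ax, ay, "+"), az, "+") <= radius^2
}

#' Generate an anomalous sinus phantom with its ground-truth lesion mask
#'
#' `polyp_like` and `cyst_like` lesions are bright spherical blobs attached to
#' the mucosal lining, protruding into the air cavity (the cyst-like variant
#' sits deeper in the cavity); `mucosal_thickening` thickens the lining shell
#' over a solid-angle patch. The lesion mask marks exactly the air voxels
#' whose intensity was replaced.
#'
#' @param params A [phantom_params()] with `lesion_type` set.
#' @return A `phantom_sample` with `label = "anomalous"` and a non-empty
#'   `lesion_mask`.
#' @export
generate_anomalous_volume <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  geom <- phantom_geometry(params)
  base <- phantom_base(params, geom)
  e <- geom$edge
  mask <- with_seed(params$seed + 1000000L, {
    if (params$lesion_type == "mucosal_thickening") {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      extra <- runif(1, params$lesion_radius_range[1] * 0.6,
                     params$lesion_radius_range[2] * 0.6)
      # air voxels within `extra` of the cavity wall on the chosen side
      r2_thick <- ellipsoid_r2(e, geom$centre, pmax(geom$semi - extra, 1))
      # direction field: cosine of the angle between voxel offset and u
      gx <- outer(outer((seq_len(e) - geom$centre[1]) * u[1],
                        (seq_len(e) - geom$centre[2]) * u[2], "+"),
                  (seq_len(e) - geom$centre[3]) * u[3], "+")
      rr <- sqrt(outer(outer((seq_len(e) - geom$centre[1])^2,
                             (seq_len(e) - geom$centre[2])^2, "+"),
                       (seq_len(e) - geom$centre[3])^2, "+"))
      cosang <- gx / pmax(rr, 1e-9)
      base$air & r2_thick > 1 & cosang > 0.5
    } else {
      rad <- runif(1, params$lesion_radius_range[1], params$lesion_radius_range[2])
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      depth <- if (params$lesion_type == "cyst_like") {
        # fully inside the cavity
        1 - (rad + 1) / min(geom$semi)
      } else {
        # centred on the lining so the blob protrudes from the wall
        1
      }
      if (depth < 0) depth <- 0
      centre <- geom$centre + u * depth * geom$semi
      sphere_mask(e, centre, rad) & base$air
    }
  })
  if (sum(mask) == 0L)
    stop("lesion could not be placed inside the cavity; enlarge the cavity or shrink the lesion")
  vol <- base$vol
  vol[mask] <- params$lesion_intensity
  vol <- phantom_noise(vol, params)
  structure(list(volume = ms_volume(vol, side = "left", label = "anomalous"),
                 lesion_mask = array(as.integer(mask), dim(vol)),
                 label = "anomalous",
                 metadata = params),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s edge=%d lesion_voxels=%d\n",
              x$label, x$metadata$cube_edge, sum(x$lesion_mask)))
  invisible(x)
}

#' Generate a labelled + unlabelled synthetic dataset
#'
#' Every sample receives a unique synthetic patient id. Lesion types of
#' anomalous samples cycle through polyp-like, cyst-like and mucosal
#' thickening. Hidden masks and labels of the unlabelled pool are returned
#' separately (for evaluation only). When `out_dir` is given, volumes and
#' masks are written as NIfTI (`.nii.gz`) and manifests as CSV with columns
#' path, patient_id, side, label.
#'
#' @param n_normal,n_anomalous Labelled sample counts.
#' @param n_unlabelled Unlabelled pool size.
#' @param anomaly_rate_unlabelled Probability that an unlabelled volume is
#'   anomalous.
#' @param seed Integer root seed; the full dataset is a pure function of
#'   (seed, params).
#' @param params A [phantom_params()] template.
#' @param out_dir Optional output directory.
#' @return A `phantom_dataset` list: `labelled` (list of `phantom_sample`),
#'   `unlabelled` (list of `ms_volume` without labels), `hidden` (data.frame
#'   of hidden unlabelled labels plus `hidden_masks` list), `manifest`,
#'   `unlabelled_manifest`.
#' @export
generate_dataset <- function(n_normal, n_anomalous, n_unlabelled = 0L,
                             anomaly_rate_unlabelled = 0.5, seed = 1L,
                             params = phantom_params(), out_dir = NULL) {
  if (any(c(n_normal, n_anomalous, n_unlabelled) < 0))
    stop("counts must be non-negative")
  if (anomaly_rate_unlabelled < 0 || anomaly_rate_unlabelled > 1)
    stop("anomaly_rate_unlabelled must lie in [0,1]")
  types <- c("polyp_like", "cyst_like", "mucosal_thickening")
  sub_seed <- function(i) as.integer((seed * 10007L + i) %% .Machine$integer.max)
  mk <- function(i, anomalous, lesion_type) {
    p <- params
    p$seed <- sub_seed(i)
    p$lesion_type <- lesion_type
    if (anomalous) generate_anomalous_volume(p) else generate_normal_volume(p)
  }
  labelled <- vector("list", n_normal + n_anomalous)
  idx <- 0L
  for (i in seq_len(n_normal)) {
    idx <- idx + 1L
    s <- mk(idx, FALSE, params$lesion_type)
    s$volume$patient_id <- sprintf("SYN%05d", idx)
    labelled[[idx]] <- s
  }
  for (i in seq_len(n_anomalous)) {
    idx <- idx + 1L
    s <- mk(idx, TRUE, types[(i - 1L) %% 3L + 1L])
    s$volume$patient_id <- sprintf("SYN%05d", idx)
    labelled[[idx]] <- s
  }
  unlab_anom <- with_seed(seed, runif(n_unlabelled) < anomaly_rate_unlabelled)
  unlabelled <- vector("list", n_unlabelled)
  hidden_masks <- vector("list", n_unlabelled)
  for (i in seq_len(n_unlabelled)) {
    idx <- idx + 1L
    s <- mk(idx, unlab_anom[i], types[(i - 1L) %% 3L + 1L])
    v <- s$volume
    v$patient_id <- sprintf("SYN%05d", idx)
    v$label <- NULL
    unlabelled[[i]] <- v
    hidden_masks[[i]] <- s$lesion_mask
  }
  lab_ids <- vapply(labelled, function(s) s$volume$patient_id, "")
  unl_ids <- vapply(unlabelled, function(v) v$patient_id, "")
  manifest <- data.frame(
    path = sprintf("labelled/%s.nii.gz", lab_ids),
    patient_id = lab_ids,
    side = rep("left", length(lab_ids)),
    label = vapply(labelled, function(s) s$label, ""),
    stringsAsFactors = FALSE)
  unlabelled_manifest <- data.frame(
    path = sprintf("unlabelled/%s.nii.gz", unl_ids),
    patient_id = unl_ids,
    side = rep("left", length(unl_ids)),
    label = rep(NA_character_, length(unl_ids)),
    stringsAsFactors = FALSE)
  hidden <- data.frame(
    patient_id = unlabelled_manifest$patient_id,
    label = ifelse(unlab_anom, "anomalous", "normal"),
    stringsAsFactors = FALSE)
  ds <- structure(list(labelled = labelled, unlabelled = unlabelled,
                       hidden = hidden, hidden_masks = hidden_masks,
                       manifest = manifest,
                       unlabelled_manifest = unlabelled_manifest,
                       seed = as.integer(seed), params = params),
                  class = "phantom_dataset")
  if (!is.null(out_dir)) write_phantom_dataset(ds, out_dir)
  ds
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> labelled=%d (%d anomalous), unlabelled=%d, edge=%d\n",
              length(x$labelled),
              sum(vapply(x$labelled, function(s) s$label == "anomalous", TRUE)),
              length(x$unlabelled), x$params$cube_edge))
  invisible(x)
}

write_phantom_dataset <- function(ds, out_dir) {
  dir.create(file.path(out_dir, "labelled"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "unlabelled"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in ds$labelled) {
    write_nifti_volume(s$volume$data, file.path(out_dir, "labelled",
                                                paste0(s$volume$patient_id, ".nii.gz")))
    write_nifti_volume(s$lesion_mask, file.path(out_dir, "masks",
                                                paste0(s$volume$patient_id, "_mask.nii.gz")))
  }
  for (i in seq_along(ds$unlabelled)) {
    v <- ds$unlabelled[[i]]
    write_nifti_volume(v$data, file.path(out_dir, "unlabelled",
                                         paste0(v$patient_id, ".nii.gz")))
    write_nifti_volume(ds$hidden_masks[[i]], file.path(out_dir, "masks",
                                                       paste0(v$patient_id, "_mask.nii.gz")))
  }
  write.csv(ds$manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(ds$unlabelled_manifest, file.path(out_dir, "unlabelled_manifest.csv"),
            row.names = FALSE)
  write.csv(ds$hidden, file.path(out_dir, "hidden_labels.csv"), row.names = FALSE)
  invisible(out_dir)
}
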