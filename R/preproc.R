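# Volume IO and preprocessing: NIfTI read/write, centroid-based MS-cube
# extraction, laterality harmonization, per-volume min-max normalization,
# stratified label-fraction subsampling and patient-grouped cross-validation
# splits.

#' Read / write a volume as NIfTI
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_nifti_volume` returns a plain 3D array;
#'   `write_nifti_volume` returns `path` invisibly.
#' @export
read_nifti_volume <- function(path) {
  v <- RNifti::readNifti(path)
  a <- as.array(v)
  attributes(a) <- list(dim = dim(a))
  a
}

#' @rdname read_nifti_volume
#' @param data 3D array to write.
#' @export
write_nifti_volume <- function(data, path) {
  RNifti::writeNifti(RNifti::asNifti(data), path)
  invisible(path)
}

#' Mean centroid of recorded MS centroids
#'
#' Component-wise arithmetic mean of 0-based voxel coordinates, rounded to
#' the nearest integer voxel (ties away from zero).
#'
#' @param centroids A list of length-3 integer vectors (i, j, k), or a matrix
#'   with one centroid per row.
#' @return An integer vector (i, j, k).
#' @export
mean_centroid <- function(centroids) {
  if (is.matrix(centroids)) centroids <- asplit(centroids, 1)
  if (length(centroids) == 0L) stop("need at least one centroid")
  m <- rowMeans(vapply(centroids, as.numeric, numeric(3)))
  as.integer(round_half_up(m))
}

#' Extract an MS cube from a cranial volume
#'
#' Returns the axis-aligned cube `[c - edge/2, c + edge/2)` on each axis
#' (half-open, 0-based voxel coordinates), with no resampling. A cube that
#' exceeds the cranial grid is an error -- never silently clamped or padded.
#'
#' @param cranial 3D array.
#' @param centroid 0-based voxel coordinates (i, j, k) of the cube centre.
#' @param edge Cube edge length in voxels.
#' @param side `"left"` or `"right"`.
#' @param patient_id Carried into the returned volume.
#' @return An `ms_volume`.
#' @export
extract_ms_volume <- function(cranial, centroid, edge, side = c("left", "right"),
                              patient_id = NA_character_) {
  side <- match.arg(side)
  d <- dim(cranial)
  half <- edge %/% 2L
  start0 <- as.integer(centroid) - half          # 0-based inclusive start
  end0 <- start0 + as.integer(edge)              # 0-based exclusive end
  if (any(start0 < 0L) || any(end0 > d))
    stop(sprintf("crop [%s) exceeds cranial grid %s",
                 paste(sprintf("%d,%d", start0, end0), collapse = " x "),
                 paste(d, collapse = "x")))
  cube <- cranial[start0[1] + seq_len(edge), start0[2] + seq_len(edge),
                  start0[3] + seq_len(edge), drop = FALSE]
  ms_volume(cube, patient_id = patient_id, side = side)
}

#' Harmonize laterality by flipping right MS volumes
#'
#' Reverses the left-right axis (axis 1 of the cube by convention; see
#' `axis`) and relabels the side as left. The flip is an involution.
#'
#' @param volume An `ms_volume`.
#' @param axis Array axis treated as left-right.
#' @return The flipped `ms_volume`.
#' @export
flip_lateral <- function(volume, axis = 1L) {
  stopifnot(inherits(volume, "ms_volume"))
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- rev(seq_len(dim(volume$data)[axis]))
  volume$data <- do.call(`[`, c(list(volume$data), idx, list(drop = FALSE)))
  volume$side <- "left"
  volume
}

#' Min-max normalize a volume to the unit interval
#'
#' Per-volume scaling `(v - min) / (max - min)`; a constant volume maps to
#' all zeros. Non-finite values are an error.
#'
#' @param volume 3D array or `ms_volume`.
#' @return Same type as the input, normalized.
#' @export
normalize_intensity <- function(volume) {
  is_msv <- inherits(volume, "ms_volume")
  v <- if (is_msv) volume$data else volume
  if (any(!is.finite(v))) stop("volume contains non-finite values")
  rng <- range(v)
  v <- if (rng[1] == rng[2]) array(0, dim(v)) else (v - rng[1]) / (rng[2] - rng[1])
  if (is_msv) { volume$data <- v; volume } else v
}

vol_labels <- function(volumes) vapply(volumes, function(v) v$label %||% NA_character_, "")
vol_patients <- function(volumes) vapply(volumes, function(v) v$patient_id, "")

as_volume_list <- function(x) {
  if (inherits(x, "phantom_dataset")) return(lapply(x$labelled, function(s) s$volume))
  lapply(x, function(v) if (inherits(v, "phantom_sample")) v$volume else v)
}

#' Stratified label-fraction subsampling
#'
#' Draws `round_half_up(fraction * n_class)` volumes per class without
#' replacement, keeping the anomaly-to-normal ratio of the full set. Sampling
#' is patient-coherent: volumes of the same patient (within a class) are kept
#' adjacent in the sampling order, and subsets are nested across fractions
#' for a fixed seed (the 10% subset is contained in the 20% subset).
#'
#' @param labelled List of labelled `ms_volume` objects.
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return The subsampled list of volumes.
#' @export
stratified_fraction <- function(labelled, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  labelled <- as_volume_list(labelled)
  if (fraction == 1) return(labelled)
  labs <- vol_labels(labelled)
  if (length(unique(labs)) < 2L)
    stop("both classes must be present for stratified subsampling")
  keep <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(labs))) {
      idx <- which(labs == cl)
      pats <- vol_patients(labelled)[idx]
      ord_pat <- sample(unique(pats))
      ordered <- unlist(lapply(ord_pat, function(p) idx[pats == p]), use.names = FALSE)
      n_take <- as.integer(round_half_up(fraction * length(idx)))
      if (n_take < 1L) stop("fraction leaves class '", cl, "' empty")
      keep <- c(keep, ordered[seq_len(n_take)])
    }
  })
  labelled[sort(keep)]
}

#' A patient-grouped dataset split
#'
#' @param train,validation,test Lists of labelled `ms_volume`s with disjoint
#'   patient ids.
#' @param unlabelled Optional unlabelled pool.
#' @return A `dataset_split`; `normal_train_subset` (the normal-only training
#'   volumes used to fit the autoencoder) is derived automatically.
#' @export
dataset_split <- function(train, validation, test, unlabelled = list()) {
  sets <- list(train = vol_patients(train), validation = vol_patients(validation),
               test = vol_patients(test))
  for (a in 1:2) for (b in (a + 1):3)
    if (length(intersect(sets[[a]], sets[[b]])) > 0L)
      stop("patient ids overlap between ", names(sets)[a], " and ", names(sets)[b])
  structure(list(train = train, validation = validation, test = test,
                 normal_train_subset = train[vol_labels(train) == "normal"],
                 unlabelled = unlabelled),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train=%d (normal %d) val=%d test=%d unlabelled=%d\n",
              length(x$train), length(x$normal_train_subset),
              length(x$validation), length(x$test), length(x$unlabelled)))
  invisible(x)
}

#' Patient-grouped stratified k-fold cross-validation splits
#'
#' Patients (not volumes) are partitioned into `k` folds, stratified by the
#' patient-level label (anomalous if any of the patient's MS volumes is
#' anomalous). Split `i` uses fold `i` as test, the next fold as validation,
#' and the rest as training; the normal-only training subset is derived per
#' split. Both MS volumes of a patient always land in the same partition.
#'
#' @param labelled List of labelled `ms_volume`s.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param unlabelled Optional unlabelled pool attached to every split.
#' @return List of `k` `dataset_split` objects.
#' @export
make_cv_folds <- function(labelled, k = 5L, seed = 1L, unlabelled = list()) {
  labelled <- as_volume_list(labelled)
  if (k < 2L) stop("k must be at least 2")
  pats <- vol_patients(labelled)
  labs <- vol_labels(labelled)
  pat_label <- tapply(labs == "anomalous", pats, any)
  upat <- names(pat_label)
  if (length(upat) < k) stop("fewer patients than folds")
  fold_of <- setNames(integer(length(upat)), upat)
  with_seed(seed, {
    cursor <- 0L  # continue the round-robin across strata to balance fold sizes
    for (stratum in c(FALSE, TRUE)) {
      ps <- sample(upat[pat_label == stratum])
      if (length(ps) > 0L) {
        fold_of[ps] <- (cursor + seq_along(ps) - 1L) %% k + 1L
        cursor <- (cursor + length(ps)) %% k
      }
    }
  })
  lapply(seq_len(k), function(i) {
    test_p <- upat[fold_of == i]
    val_p <- upat[fold_of == (i %% k) + 1L]
    train_p <- setdiff(upat, c(test_p, val_p))
    dataset_split(train = labelled[pats %in% train_p],
                  validation = labelled[pats %in% val_p],
                  test = labelled[pats %in% test_p],
                  unlabelled = unlabelled)
  })
}
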