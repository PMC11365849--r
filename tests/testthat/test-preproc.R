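test_that("mean_centroid averages and rounds half away from zero", {
  expect_identical(mean_centroid(list(c(10, 10, 10))), c(10L, 10L, 10L))
  expect_identical(mean_centroid(list(c(10, 20, 30), c(20, 30, 40))), c(15L, 25L, 35L))
  expect_identical(mean_centroid(list(c(1, 1, 1), c(2, 2, 2))), c(2L, 2L, 2L))  # .5 up
  expect_error(mean_centroid(list()), "at least one")
  # oracle: independent per-axis mean over 20 random centroids
  set.seed(4)
  cs <- lapply(1:20, function(i) sample(0:200, 3))
  m <- sapply(1:3, function(ax) mean(vapply(cs, `[`, 0, ax)))
  expect_identical(mean_centroid(cs), as.integer(sign(m) * floor(abs(m) + 0.5)))
})

test_that("extract_ms_volume crops the half-open centred cube without resampling", {
  set.seed(1)
  cranial <- array(runif(64^3), c(64, 64, 64))
  whole <- extract_ms_volume(cranial, c(32, 32, 32), 64L)
  expect_equal(whole$data, cranial)
  crop <- extract_ms_volume(cranial, c(16, 20, 24), 8L)
  # crop voxel (0,0,0) is cranial voxel (c - edge/2) in 0-based coordinates
  expect_identical(crop$data[1, 1, 1], cranial[16 - 4 + 1, 20 - 4 + 1, 24 - 4 + 1])
  expect_identical(dim(crop$data), c(8L, 8L, 8L))
  expect_error(extract_ms_volume(cranial, c(5, 32, 32), 64L), "exceeds")
  expect_error(extract_ms_volume(cranial, c(62, 32, 32), 8L), "exceeds")
})

test_that("flip_lateral is an involution that mirrors the first axis", {
  set.seed(2)
  v <- ms_volume(array(runif(4^3), c(4, 4, 4)), side = "right")
  expect_equal(flip_lateral(flip_lateral(v))$data, v$data)
  expect_identical(flip_lateral(v)$side, "left")
  marked <- ms_volume(array(0, c(6, 4, 4)))
  marked$data[1, 2, 3] <- 1
  expect_identical(which(flip_lateral(marked)$data == 1, arr.ind = TRUE)[1, ],
                   c(dim1 = 6L, dim2 = 2L, dim3 = 3L))
  sym <- ms_volume(array(rep(c(1, 2, 2, 1), each = 1), c(4, 1, 1)))
  expect_equal(flip_lateral(sym)$data, sym$data)
})

test_that("normalize_intensity min-max scales with defined degenerate case", {
  expect_equal(sort(unique(as.vector(normalize_intensity(array(c(2, 4), c(2, 1, 1)))))),
               c(0, 1))
  expect_equal(normalize_intensity(array(7, c(3, 3, 3))), array(0, c(3, 3, 3)))
  set.seed(3)
  v <- normalize_intensity(array(rnorm(4^3), c(4, 4, 4)))
  expect_equal(range(v), c(0, 1))
  bad <- array(1, c(2, 2, 2)); bad[1] <- NaN
  expect_error(normalize_intensity(bad), "non-finite")
})

test_that("preprocessing chain is deterministic and order-stable", {
  set.seed(5)
  cranial <- array(runif(32^3), c(32, 32, 32))
  run <- function() {
    v <- extract_ms_volume(cranial, c(16, 16, 16), 16L, side = "right")
    normalize_intensity(flip_lateral(v))$data
  }
  expect_identical(run(), run())
})

test_that("stratified_fraction reproduces the documented class counts", {
  vols <- stub_volumes(708, 487)
  sub <- stratified_fraction(vols, 0.1, seed = 1L)
  labs <- vapply(sub, function(v) v$label, "")
  expect_identical(sum(labs == "normal"), 71L)
  expect_identical(sum(labs == "anomalous"), 49L)
})

test_that("stratified_fraction keeps ratio, nests across fractions, validates input", {
  vols <- stub_volumes(40, 30)
  expect_identical(stratified_fraction(vols, 1), vols)
  full_ratio <- 30 / 70
  for (s in 1:20) {
    sub <- stratified_fraction(vols, 0.3, seed = s)
    labs <- vapply(sub, function(v) v$label, "")
    # recount: within one sample of the full-set ratio
    expect_lte(abs(sum(labs == "anomalous") - full_ratio * length(sub)), 1)
  }
  ids <- function(x) vapply(x, function(v) v$patient_id, "")
  expect_true(all(ids(stratified_fraction(vols, 0.1, seed = 3L)) %in%
                    ids(stratified_fraction(vols, 0.2, seed = 3L))))
  expect_error(stratified_fraction(vols, 0), "\\(0, 1\\]")
  expect_error(stratified_fraction(vols, 1.2), "\\(0, 1\\]")
  expect_error(stratified_fraction(stub_volumes(5, 0), 0.5), "both classes")
})

test_that("make_cv_folds partitions patients exactly once with stratification", {
  vols <- stub_volumes(6, 4)
  folds <- make_cv_folds(vols, k = 5L, seed = 2L)
  expect_length(folds, 5L)
  test_pats <- unlist(lapply(folds, function(f)
    unique(vapply(f$test, function(v) v$patient_id, ""))))
  expect_identical(sort(test_pats),
                   sort(vapply(vols, function(v) v$patient_id, "")))
  for (f in folds) {
    expect_length(unique(vapply(f$test, function(v) v$patient_id, "")), 2L)
    expect_true(all(vapply(f$normal_train_subset, function(v) v$label, "") == "normal"))
  }
  expect_error(make_cv_folds(stub_volumes(2, 1), k = 5L), "fewer patients")
})

test_that("both volumes of a patient always land in the same partition", {
  vols <- stub_volumes(8, 0, two_sided_patients = TRUE)
  for (i in seq_along(vols)) if (i %% 3 == 0) vols[[i]]$label <- "anomalous"
  folds <- make_cv_folds(vols, k = 4L, seed = 3L)
  for (f in folds) {
    part_of <- c(setNames(rep("train", length(f$train)),
                          vapply(f$train, function(v) v$patient_id, "")),
                 setNames(rep("val", length(f$validation)),
                          vapply(f$validation, function(v) v$patient_id, "")),
                 setNames(rep("test", length(f$test)),
                          vapply(f$test, function(v) v$patient_id, "")))
    tab <- tapply(part_of, names(part_of), function(x) length(unique(x)))
    expect_true(all(tab == 1L))
  }
})

test_that("dataset_split rejects patient leakage", {
  vols <- stub_volumes(4, 2)
  expect_error(dataset_split(vols[1:3], vols[3:4], vols[5:6]), "overlap")
})
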