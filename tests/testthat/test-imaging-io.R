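test_that("NIfTI write/read round-trips voxel values exactly", {
  set.seed(11)
  arr <- matrix(runif(64 * 64), 64, 64)
  path <- withr::local_tempfile(fileext = ".nii")
  write_volume(arr, path)
  ch <- load_volume(path, "t1")
  expect_identical(dim(ch), c(64L, 64L))
  expect_equal(as.vector(ch), as.vector(arr), tolerance = 0)
  expect_identical(attr(ch, "channel_name"), "t1")
})

test_that("channels with mismatched shapes refuse to assemble", {
  a <- matrix(0, 4, 4); b <- matrix(0, 4, 5)
  expect_error(mp_image(t1 = a, t2 = b), class = "tcf_shape_error")
  expect_error(mp_image(t1 = a, t1 = a), class = "tcf_spec_error")
})

test_that("min-max normalization maps endpoints, is idempotent and monotone", {
  img <- mp_image(ch = array(c(2, 4, 6), dim = c(3, 1)))
  out <- normalize_channels(img)
  expect_equal(as.vector(out$channels$ch), c(0, 0.5, 1))
  expect_true(all(out$normalized))

  unit <- mp_image(ch = array(c(0, 0.25, 1), dim = c(3, 1)))
  expect_equal(as.vector(normalize_channels(unit)$channels$ch), c(0, 0.25, 1))

  set.seed(5)
  rnd <- mp_image(ch = matrix(rnorm(100), 10, 10))
  once <- normalize_channels(rnd)
  twice <- normalize_channels(once)
  expect_equal(once$channels$ch, twice$channels$ch)
  expect_identical(order(as.vector(rnd$channels$ch)),
                   order(as.vector(once$channels$ch)))
  expect_true(all(once$channels$ch >= 0 & once$channels$ch <= 1))
})

test_that("constant channels are rejected by name", {
  img <- mp_image(flat = matrix(3, 4, 4))
  expect_error(normalize_channels(img), "flat",
               class = "tcf_degenerate_channel_error")
})

test_that("largest-extent slice selection matches a brute-force scan", {
  # sphere of radius 5 centered on slice 10 in a 24-cube
  d <- c(24L, 24L, 24L)
  arr <- array(FALSE, d)
  for (s in 1:24) {
    r2 <- 25 - (s - 10)^2
    if (r2 < 0) next
    arr[, , s] <- outer((1:24 - 12)^2, (1:24 - 12)^2, `+`) <= r2
  }
  mask <- roi_mask(arr)
  expect_identical(select_largest_slice(mask, axis = 3), 10L)

  # brute force: per-slice max pairwise distance
  ext <- vapply(1:24, function(s) {
    pts <- which(arr[, , s], arr.ind = TRUE)
    if (nrow(pts) < 2) return(if (nrow(pts) == 1) 0 else -Inf)
    max(dist(pts))
  }, numeric(1))
  expect_identical(select_largest_slice(mask, axis = 3),
                   which.max(ext))

  # single nonzero slice and tie toward the lower index
  one <- array(FALSE, d); one[10:12, 10:12, 7] <- TRUE
  expect_identical(select_largest_slice(roi_mask(one), axis = 3), 7L)
  two <- array(FALSE, d)
  two[10:12, 10, 4] <- TRUE; two[10:12, 10, 9] <- TRUE
  expect_identical(select_largest_slice(roi_mask(two), axis = 3), 4L)

  expect_error(select_largest_slice(roi_mask(array(FALSE, d)), axis = 3),
               class = "tcf_empty_roi_error")
})

test_that("signature extraction sizes, seeding and preconditions behave", {
  set.seed(7)
  img <- normalize_channels(mp_image(a = matrix(runif(900), 30, 30),
                                     b = matrix(runif(900), 30, 30),
                                     c = matrix(runif(900), 30, 30)))
  m <- matrix(FALSE, 30, 30); m[5:7, 5:7] <- TRUE; m[5, 7] <- FALSE
  mask <- roi_mask(m)  # 8 voxels
  sig <- extract_signatures(img, mask, subsample_cap = 100)
  expect_identical(sig$n_voxels, 8L)
  expect_identical(sig$D, 3L)
  expect_false(any(duplicated(sig$coords)))
  expect_true(all(sig$features >= 0 & sig$features <= 1))

  big <- roi_mask(matrix(TRUE, 30, 30))  # 900 voxels
  s1 <- extract_signatures(img, big, subsample_cap = 200, seed = 42)
  s2 <- extract_signatures(img, big, subsample_cap = 200, seed = 42)
  s3 <- extract_signatures(img, big, subsample_cap = 200, seed = 43)
  expect_identical(s1$coords, s2$coords)
  expect_identical(nrow(s3$coords), 200L)
  expect_false(identical(s1$coords, s3$coords))
  expect_true(s1$provenance$subsampled)

  raw <- mp_image(a = matrix(runif(900), 30, 30))
  expect_error(extract_signatures(raw, mask), class = "tcf_precondition_error")
  empty <- roi_mask(matrix(FALSE, 30, 30))
  expect_error(extract_signatures(img, empty), class = "tcf_empty_roi_error")
})

test_that("extracted count is always min(mask count, cap)", {
  set.seed(9)
  img <- normalize_channels(mp_image(a = matrix(runif(400), 20, 20)))
  for (cap in c(5L, 50L, 500L)) {
    m <- matrix(runif(400) < 0.3, 20, 20)
    if (sum(m) < 2) next
    sig <- extract_signatures(img, roi_mask(m), subsample_cap = cap, seed = 1)
    expect_identical(sig$n_voxels, min(sum(m), cap))
  }
})

test_that("include_xy appends scaled coordinate channels", {
  img <- normalize_channels(mp_image(a = matrix(runif(100), 10, 10)))
  mask <- roi_mask(matrix(TRUE, 10, 10))
  sig <- extract_signatures(img, mask, include_xy = TRUE)
  expect_identical(sig$D, 3L)
  expect_true(all(sig$features[, 2:3] >= 0 & sig$features[, 2:3] <= 1))
})
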