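# phantom generator: determinism, geometry against the pixel-membership
# oracle, augmentation invariants, dataset packaging

test_that("generation is deterministic and leaves the caller's RNG alone", {
  sp <- phantom_spec(size = 48, seed = 7)
  s1 <- generate_phantom(sp, 3)
  s2 <- generate_phantom(sp, 3)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  set.seed(123); r1 <- runif(3)
  set.seed(123); invisible(generate_phantom(sp, 1)); r2 <- runif(3)
  expect_identical(r1, r2)
  # different ids differ
  expect_false(identical(generate_phantom(sp, 4)$mask, s1$mask))
})

test_that("a noise-free centred disc covers exactly the brute-force pixel count", {
  # one structure, forced circular: equal axes via degenerate range
  sp <- phantom_spec(size = 64, n_structures = 1, noise_sd = 0,
                     intensity_jitter = 0, seed = 5,
                     axes_min = 0.2, axes_max = 0.2, center_margin = 0.5)
  s <- generate_phantom(sp, 1)
  r <- 0.2 * 64
  cx <- 0.5 * 64; cy <- 0.5 * 64  # margin 0.5 pins the centre
  count <- 0
  for (i in 1:64) for (j in 1:64) {
    if ((i - cx)^2 + (j - cy)^2 <= r^2) count <- count + 1
  }
  expect_equal(sum(s$mask == 1), count)
  # noise-free image carries exactly two intensity levels
  expect_equal(sort(unique(as.vector(s$image))),
               c(sp$background, sp$intensities[1]))
})

test_that("zero structures give pure-noise background images", {
  sp <- phantom_spec(size = 32, n_structures = 0, seed = 2)
  s <- generate_phantom(sp, 1)
  expect_true(all(s$mask == 0))
  expect_true(all(s$image >= 0 & s$image <= 1))
  expect_gt(stats::sd(s$image), 0)
})

test_that("degenerate ellipse axes are rejected", {
  expect_error(phantom_spec(axes_min = 0), "degenerate")
  expect_error(phantom_spec(axes_min = 0.2, axes_max = 0.1), "degenerate")
})

test_that("augmentation is a rigid relabelling: counts preserved, flips involutive", {
  sp <- phantom_spec(size = 32, seed = 9)
  s <- generate_phantom(sp, 2)
  for (sd in 1:5) {
    a <- augment(s, sd)
    expect_identical(table(a$mask), table(s$mask))
    expect_identical(sort(unique(as.vector(a$image))),
                     sort(unique(as.vector(s$image))))
  }
  # explicit double horizontal flip is the identity
  hflip <- function(m) m[, rev(seq_len(ncol(m)))]
  expect_identical(hflip(hflip(s$mask)), s$mask)
  # a 90-degree rotation moves an off-centre blob centroid as computed
  # independently from the coordinate transform
  msk <- s$mask
  rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  rmsk <- rot90(msk)
  for (k in sort(unique(as.vector(msk)))[-1]) {
    pts <- which(msk == k, arr.ind = TRUE)
    cen <- colMeans(pts)
    rpts <- which(rmsk == k, arr.ind = TRUE)
    n <- nrow(msk)
    # (i, j) -> (n + 1 - j, i) under this rotation
    expect_equal(colMeans(rpts), unname(c(n + 1 - cen[2], cen[1])),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("class frequencies match the geometric expectation over many draws", {
  # one structure placed so it can never clip the border or occlude:
  # E[area fraction] = pi * E[a] * E[b] with a, b ~ U(min, max) independent
  sp1 <- phantom_spec(size = 32, n_structures = 1, seed = 31,
                      axes_min = 0.08, axes_max = 0.15, center_margin = 0.3)
  n_samp <- 100
  fg <- vapply(seq_len(n_samp), function(i)
    mean(generate_phantom(sp1, i)$mask == 1), numeric(1))
  mean_axis <- (0.08 + 0.15) / 2
  analytic <- pi * mean_axis^2
  expect_gt(mean(fg), analytic * 0.8)
  expect_lt(mean(fg), analytic * 1.2)

  # default multi-structure mix: union below the sum of parts (overlap /
  # clipping), above the largest single structure; all classes usually seen
  sp <- phantom_spec(size = 32, seed = 31)
  fg <- vapply(seq_len(n_samp), function(i)
    mean(generate_phantom(sp, i)$mask > 0), numeric(1))
  upper <- sum(pi * ((sp$axes_min + sp$axes_max) / 2)^2)
  lower <- pi * ((sp$axes_min[1] + sp$axes_max[1]) / 2)^2
  expect_lt(mean(fg), upper)
  expect_gt(mean(fg), lower)
  vis <- rowMeans(vapply(seq_len(n_samp), function(i) {
    m <- generate_phantom(sp, i)$mask
    vapply(seq_len(sp$n_structures), function(k) any(m == k), logical(1))
  }, logical(sp$n_structures)))
  expect_true(all(vis > 0.8))
})

test_that("dataset building writes disjoint splits that reload exactly", {
  sp <- phantom_spec(size = 32, seed = 11)
  d <- tempfile("phantomds")
  mf <- build_phantom_dataset(sp, 8, 2, 2, d)
  expect_length(list.files(d), 13)  # 12 samples + manifest
  ids <- mf$ids
  expect_length(intersect(ids$train, ids$val), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$val, ids$test), 0)
  ds <- load_phantom_dataset(d)
  expect_identical(ds$train[[3]]$mask, generate_phantom(sp, 3)$mask)
  expect_identical(ds$test[[1]]$image, generate_phantom(sp, 11)$image)
  # collision with a non-empty directory is refused
  expect_error(build_phantom_dataset(sp, 1, 1, 1, d), "not empty")
  # regeneration into a fresh directory is identical
  d2 <- tempfile("phantomds")
  build_phantom_dataset(sp, 8, 2, 2, d2)
  ds2 <- load_phantom_dataset(d2)
  expect_identical(ds$train[[1]]$image, ds2$train[[1]]$image)
  unlink(c(d, d2), recursive = TRUE)
})

test_that("PNG and NIfTI export produce readable files", {
  skip_if_not_installed("png")
  sp <- phantom_spec(size = 16, seed = 3)
  s <- generate_phantom(sp, 1)
  fi <- tempfile(fileext = ".png"); fm <- tempfile(fileext = ".png")
  export_phantom_png(s, fi, fm)
  expect_true(file.exists(fi) && file.exists(fm))
  img <- png::readPNG(fi)
  expect_equal(dim(img), c(16, 16))
  skip_if_not_installed("RNifti")
  ni <- tempfile(fileext = ".nii.gz"); nm <- tempfile(fileext = ".nii.gz")
  export_phantom_nifti(s, ni, nm)
  expect_equal(dim(RNifti::readNifti(ni))[1:2], c(16, 16))
})
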