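# Seeded multi-organ phantom generator.
#
# Each phantom slice contains several smooth elliptical structures of
# distinct mean intensity on a noisy darker background - a stand-in for
# multi-organ CT/MRI slices with exactly known ground truth. Structure k
# always keeps intensity band k (small per-sample jitter), so class identity
# is learnable from appearance across samples; later structures occlude
# earlier ones where they overlap, and the mask records the visible pixels.

#' Phantom specification
#'
#' Defines the population a phantom dataset is drawn from. The default mix
#' emulates multi-organ contrast: one large "liver-like" structure, medium
#' organs, and a small low-contrast "pancreas-like" one, so small-structure
#' segmentation is exercised. All geometry is in fractions of the image
#' size; identical `seed` + spec reproduce samples bit-exactly.
#'
#' @param size image edge length in pixels.
#' @param n_structures number of foreground classes (0 = pure noise images).
#' @param intensities mean intensity per structure in \[0, 1\] (recycled /
#'   defaulted to an even spread over 0.35..0.95).
#' @param axes_min,axes_max per-structure semi-axis range as a fraction of
#'   `size` (recycled; defaults shrink from large to small structures).
#' @param center_margin structures are centred inside
#'   `[margin, 1 - margin] * size`.
#' @param background background mean intensity.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param intensity_jitter half-width of the per-sample uniform jitter of
#'   each structure's mean intensity.
#' @param seed master seed of the generator.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(size = 64L, n_structures = 4L,
                         intensities = NULL,
                         axes_min = NULL, axes_max = NULL,
                         center_margin = 0.22,
                         background = 0.1, noise_sd = 0.05,
                         intensity_jitter = 0.03, seed = 1L) {
  n <- as.integer(n_structures)
  if (n > 0) {
    if (is.null(intensities)) {
      intensities <- seq(0.35, 0.95, length.out = max(n, 2L))[seq_len(n)]
    }
    intensities <- rep_len(intensities, n)
    if (is.null(axes_min)) {
      axes_min <- seq(0.16, 0.05, length.out = max(n, 2L))[seq_len(n)]
    }
    if (is.null(axes_max)) {
      axes_max <- seq(0.26, 0.09, length.out = max(n, 2L))[seq_len(n)]
    }
    axes_min <- rep_len(axes_min, n)
    axes_max <- rep_len(axes_max, n)
    if (any(axes_min <= 0) || any(axes_max < axes_min)) {
      stop("degenerate ellipse axes: need 0 < axes_min <= axes_max")
    }
    stopifnot(all(intensities >= 0), all(intensities <= 1))
  } else {
    intensities <- numeric(0); axes_min <- numeric(0); axes_max <- numeric(0)
  }
  structure(list(size = as.integer(size), n_structures = n,
                 intensities = intensities,
                 axes_min = axes_min, axes_max = axes_max,
                 center_margin = center_margin, background = background,
                 noise_sd = noise_sd, intensity_jitter = intensity_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# deterministic per-stream seed derivation (kept well below 2^31)
derive_seed <- function(master, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(master) %% 100003) * 7919 + h %% 99991) %% 2147483647L
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# logical membership mask of a rotated ellipse on the pixel-centre grid
.ellipse_mask <- function(size, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(size), times = size), size, size)  # row coord
  ys <- matrix(rep(seq_len(size), each = size), size, size)   # col coord
  dx <- xs - cx; dy <- ys - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

#' Generate one phantom sample
#'
#' Deterministic given `spec` and `id`: structure centres, axes, rotations,
#' intensity jitter and pixel noise are all drawn from a seed derived from
#' `spec$seed` and `id`. The mask assigns class `k` to exactly the visible
#' pixels of structure `k` (later structures occlude earlier ones).
#'
#' @param spec a [phantom_spec()].
#' @param id sample index (varies the draw under the same spec).
#' @return a `phantom_sample`: list with `image` (`1 x H x W`, values in
#'   \[0, 1\]), `mask` (`H x W` integer, 0 = background), `id`, `occluded`
#'   (ids of structures fully hidden by later ones), and the generating
#'   `spec`.
#' @export
generate_phantom <- function(spec, id = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_structures
  sz <- spec$size
  .with_seed(derive_seed(spec$seed, paste0("sample", id)), {
    mask <- matrix(0L, sz, sz)
    intens <- matrix(spec$background, sz, sz)
    occluded <- integer(0)
    for (k in seq_len(n)) {
      margin <- spec$center_margin * sz
      cx <- stats::runif(1, margin, sz - margin)
      cy <- stats::runif(1, margin, sz - margin)
      a <- stats::runif(1, spec$axes_min[k], spec$axes_max[k]) * sz
      b <- stats::runif(1, spec$axes_min[k], spec$axes_max[k]) * sz
      theta <- stats::runif(1, 0, pi)
      mu <- spec$intensities[k] +
        stats::runif(1, -spec$intensity_jitter, spec$intensity_jitter)
      mem <- .ellipse_mask(sz, cx, cy, a, b, theta)
      mask[mem] <- k
      intens[mem] <- mu
    }
    for (k in seq_len(n)) if (!any(mask == k)) occluded <- c(occluded, k)
    img <- intens + stats::rnorm(sz * sz, sd = spec$noise_sd)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = array(img, c(1L, sz, sz)), mask = mask,
                   id = as.integer(id), occluded = occluded, spec = spec),
              class = "phantom_sample")
  })
}

#' Random flip / right-angle rotation augmentation
#'
#' Applies (independently, each with probability 1/2) a horizontal and a
#' vertical flip, plus a uniformly drawn rotation by a multiple of 90
#' degrees, identically to image and mask; rigid transforms, so per-class
#' pixel counts are preserved.
#'
#' @param sample a `phantom_sample`.
#' @param seed seed of the augmentation draw.
#' @return the augmented `phantom_sample`.
#' @export
augment <- function(sample, seed = 1L) {
  .with_seed(seed, {
    img <- sample$image[1, , ]
    msk <- sample$mask
    if (stats::runif(1) < 0.5) { img <- img[, rev(seq_len(ncol(img)))]
                                 msk <- msk[, rev(seq_len(ncol(msk)))] }
    if (stats::runif(1) < 0.5) { img <- img[rev(seq_len(nrow(img))), ]
                                 msk <- msk[rev(seq_len(nrow(msk))), ] }
    k <- sample.int(4L, 1L) - 1L
    rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
    for (i in seq_len(k)) { img <- rot90(img); msk <- rot90(msk) }
    out <- sample
    out$image <- array(img, c(1L, dim(img)))
    out$mask <- msk
    out
  })
}

#' Build a phantom dataset on disk
#'
#' Generates disjoint train / validation / test splits (sample ids are
#' consecutive and non-overlapping across splits) and writes each sample
#' plus a JSON manifest recording the spec and seeds, so the dataset can be
#' reloaded - or regenerated - exactly.
#'
#' @param spec a [phantom_spec()].
#' @param n_train,n_val,n_test split sizes.
#' @param dir target directory; must not already contain files.
#' @return the manifest list, invisibly.
#' @export
build_phantom_dataset <- function(spec, n_train, n_val, n_test, dir) {
  if (dir.exists(dir) && length(list.files(dir)) > 0) {
    stop("target directory ", dir, " exists and is not empty")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- list(train = seq_len(n_train),
              val = n_train + seq_len(n_val),
              test = n_train + n_val + seq_len(n_test))
  files <- list()
  for (split in names(ids)) {
    files[[split]] <- vapply(ids[[split]], function(i) {
      s <- generate_phantom(spec, i)
      f <- file.path(dir, sprintf("%s_%04d.rds", split, i))
      saveRDS(s, f)
      basename(f)
    }, character(1))
  }
  manifest <- list(spec = unclass(spec), ids = ids, files = files,
                   created = "phantom dataset")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a phantom dataset written by [build_phantom_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `train`, `val`, `test` (lists of `phantom_sample`) and
#'   `manifest`.
#' @export
load_phantom_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  out <- list(manifest = mf)
  for (split in c("train", "val", "test")) {
    out[[split]] <- lapply(mf$files[[split]], function(f)
      readRDS(file.path(dir, f)))
  }
  out
}

#' Generate a list of phantom samples in memory
#'
#' @param spec a [phantom_spec()].
#' @param ids integer sample ids.
#' @return list of `phantom_sample`.
#' @export
phantom_batch <- function(spec, ids) {
  lapply(ids, function(i) generate_phantom(spec, i))
}

#' Export a phantom as PNG (8-bit image + paletted-style mask)
#'
#' @param sample a `phantom_sample`.
#' @param image_path,mask_path output files; the mask is written with class
#'   ids scaled into the grey range for inspection.
#' @return invisible `NULL`. Requires the `png` package.
#' @export
export_phantom_png <- function(sample, image_path, mask_path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  png::writePNG(sample$image[1, , ], image_path)
  k <- max(1L, max(sample$mask))
  png::writePNG(sample$mask / k, mask_path)
  invisible(NULL)
}

#' Export a phantom as NIfTI (image + mask volumes)
#'
#' @param sample a `phantom_sample`.
#' @param image_path,mask_path output `.nii.gz` files. Requires `RNifti`.
#' @return invisible `NULL`.
#' @export
export_phantom_nifti <- function(sample, image_path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the 'RNifti' package is required for NIfTI export")
  }
  RNifti::writeNifti(RNifti::asNifti(sample$image[1, , ]), image_path)
  RNifti::writeNifti(RNifti::asNifti(sample$mask), mask_path)
  invisible(NULL)
}
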