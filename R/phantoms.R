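# Ground-truthed synthetic phantoms emulating the three data regimes the
# toolkit targets: high-contrast multi-region volumes (microCT-like),
# low-SNR volumes with blob organelles and thin tubes (cryoET-like), and
# medium-SNR volumes with many varied blobs (cryoSXT-like). Fully
# deterministic under the seed.

ellipsoid_mask <- function(d, center, radii) {
  z <- slice.index(array(0, d), 1) - center[1]
  y <- slice.index(array(0, d), 2) - center[2]
  x <- slice.index(array(0, d), 3) - center[3]
  (z / radii[1])^2 + (y / radii[2])^2 + (x / radii[3])^2 <= 1
}

tube_mask <- function(d, point, direction, radius) {
  u <- direction / sqrt(sum(direction^2))
  z <- slice.index(array(0, d), 1) - point[1]
  y <- slice.index(array(0, d), 2) - point[2]
  x <- slice.index(array(0, d), 3) - point[3]
  t <- z * u[1] + y * u[2] + x * u[3]
  (z - t * u[1])^2 + (y - t * u[2])^2 + (x - t * u[3])^2 <= radius^2
}

#' Multi-region phantom (microCT-like)
#'
#' Ground-truthed volume with `n_regions` regions of distinct mean
#' intensity plus Gaussian noise. Layout `"nested"` places concentric
#' ellipsoids (background = region 1, means `0, contrast, 2*contrast, ...`);
#' `"slabs"` splits the volume into parallel slabs along y (a step phantom;
#' `n_regions = 2` gives the classic two-phase step).
#'
#' @param size cube edge in voxels (>= 8).
#' @param n_regions number of regions (>= 2).
#' @param contrast intensity step between consecutive region means.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed; identical seeds give identical phantoms.
#' @param layout `"nested"` or `"slabs"`.
#' @return a `phantom`: `volume`, integer `truth` (1..n_regions), `objects`
#'   (generative parameters), `seed`, `noise_sd`, `class_means`.
#' @export
make_multiregion <- function(size = 64, n_regions = 4, contrast = 1,
                             noise_sd = 0.1, seed = 1, layout = "nested") {
  if (size < 8) stop("size must be >= 8")
  if (n_regions < 2) stop("n_regions must be >= 2")
  layout <- match.arg(layout, c("nested", "slabs"))
  set.seed(seed)
  d <- rep(size, 3)
  truth <- array(1L, d)
  objects <- list()
  if (layout == "nested") {
    ctr <- rep((size + 1) / 2, 3)
    fracs <- seq(0.42, 0.14, length.out = n_regions - 1)
    for (k in seq_len(n_regions - 1)) {
      r <- fracs[k] * size
      m <- ellipsoid_mask(d, ctr, rep(r, 3))
      truth[m] <- k + 1L
      objects[[k]] <- list(type = "ellipsoid", center = ctr,
                           radii = rep(r, 3), region = k + 1L)
    }
  } else {
    cuts <- round(seq(0, size, length.out = n_regions + 1))
    yi <- slice.index(truth, 2)
    for (k in seq_len(n_regions)) {
      truth[yi > cuts[k] & yi <= cuts[k + 1]] <- k
      objects[[k]] <- list(type = "slab", y0 = cuts[k] + 1, y1 = cuts[k + 1],
                           region = k)
    }
  }
  means <- (seq_len(n_regions) - 1) * contrast
  vol <- array(means[truth], d)
  if (noise_sd > 0) vol <- vol + rnorm(length(vol), 0, noise_sd)
  structure(list(volume = vol, truth = truth, objects = objects,
                 seed = seed, noise_sd = noise_sd, class_means = means,
                 params = list(size = size, n_regions = n_regions,
                               contrast = contrast, layout = layout)),
            class = "phantom")
}

#' Organelle-cell phantom (cryoET / cryoSXT-like)
#'
#' Ellipsoidal "organelle" blobs of varied size and intensity and thin
#' tubes (radius 1-2 voxels, microtubule-like) over a smooth background
#' gradient, with Gaussian noise set by the requested signal-to-noise ratio
#' (SNR = mean foreground contrast / noise sd). Object placement uses
#' rejection sampling with a 2-voxel gap so every blob and tube is a
#' separate connected component in the truth. An optional anisotropic blur
#' along z coarsely emulates missing-wedge elongation (off by default).
#'
#' @param size cube edge in voxels (>= 16).
#' @param n_blobs,n_tubes object counts.
#' @param snr requested signal-to-noise ratio (> 0).
#' @param seed RNG seed.
#' @param bg_gradient amplitude of the linear background gradient along y.
#' @param wedge_blur_z sigma of the optional z blur (0 = off).
#' @return a `phantom`; truth ids: 1 = background, blobs `2..n_blobs+1`,
#'   tubes `n_blobs+2..`.
#' @export
make_organelle_cell <- function(size = 64, n_blobs = 10, n_tubes = 2,
                                snr = 3, seed = 1, bg_gradient = 0.2,
                                wedge_blur_z = 0) {
  if (size < 16) stop("size must be >= 16")
  if (snr <= 0) stop("snr must be > 0")
  set.seed(seed)
  d <- rep(size, 3)
  truth <- array(1L, d)
  fg_guard <- array(FALSE, d) # occupied + 2-voxel gap
  signal <- array(0, d)
  # symmetric gradient along y, zero mean
  signal <- signal + bg_gradient *
    (slice.index(signal, 2) - (size + 1) / 2) / size
  objects <- list()
  rmax <- max(3, round(size / 10))
  oid <- 1L
  for (b in seq_len(n_blobs)) {
    placed <- FALSE
    for (try in 1:200) {
      radii <- runif(3, 3, rmax)
      ctr <- runif(3, rmax + 2, size - rmax - 1)
      guard <- ellipsoid_mask(d, ctr, radii + 2)
      if (any(guard & fg_guard)) next
      m <- ellipsoid_mask(d, ctr, radii)
      intensity <- runif(1, 0.8, 1.2)
      signal[m] <- intensity
      oid <- oid + 1L
      truth[m] <- oid
      fg_guard <- fg_guard | guard
      objects[[length(objects) + 1]] <-
        list(type = "blob", center = ctr, radii = radii,
             intensity = intensity, region = oid)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place blob ", b,
                      "; reduce n_blobs or increase size")
  }
  for (tb in seq_len(n_tubes)) {
    placed <- FALSE
    for (try in 1:200) {
      pt <- runif(3, size * 0.25, size * 0.75)
      dir <- rnorm(3)
      radius <- runif(1, 1, 2)
      guard <- tube_mask(d, pt, dir, radius + 2)
      if (any(guard & fg_guard)) next
      m <- tube_mask(d, pt, dir, radius)
      intensity <- runif(1, 0.8, 1.2)
      signal[m] <- intensity
      oid <- oid + 1L
      truth[m] <- oid
      fg_guard <- fg_guard | guard
      objects[[length(objects) + 1]] <-
        list(type = "tube", point = pt, direction = dir, radius = radius,
             intensity = intensity, region = oid)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place tube ", tb)
  }
  fg <- truth > 1L
  mean_contrast <- mean(signal[fg] - bg_gradient *
                          (slice.index(signal, 2)[fg] - (size + 1) / 2) /
                          size)
  noise_sd <- mean_contrast / snr
  vol <- signal + rnorm(length(signal), 0, noise_sd)
  if (wedge_blur_z > 0) # axial blur only: coarse missing-wedge emulation
    vol <- conv_axis(vol, gaussian_kernel(wedge_blur_z), 1, "reflect")
  structure(list(volume = vol, truth = truth, objects = objects,
                 seed = seed, noise_sd = noise_sd, snr = snr,
                 params = list(size = size, n_blobs = n_blobs,
                               n_tubes = n_tubes, snr = snr,
                               bg_gradient = bg_gradient,
                               wedge_blur_z = wedge_blur_z)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("phantom ", paste(dim(x$volume), collapse = "x"), ", ",
      length(unique(as.integer(x$truth))), " truth classes, noise sd ",
      signif(x$noise_sd, 3), ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Estimate the SNR of a phantom from its volume and truth
#'
#' Foreground contrast is the difference of mean intensity between
#' foreground and background voxels; the noise sd is estimated from
#' first differences along z inside the background (insensitive to the
#' smooth in-plane gradient).
#'
#' @param phantom a `phantom` (or any list with `volume` and `truth`).
#' @return estimated SNR (scalar).
#' @export
estimate_snr <- function(phantom) {
  vol <- phantom$volume; truth <- phantom$truth
  fg <- truth > 1
  contrast <- mean(vol[fg]) - mean(vol[!fg])
  dz <- vol[-1, , ] - vol[-dim(vol)[1], , ]
  bgz <- (!fg)[-1, , ] & (!fg)[-dim(vol)[1], , ]
  noise <- sd(dz[bgz]) / sqrt(2)
  contrast / noise
}

#' Write a phantom to disk in all supported formats
#'
#' Emits the volume as HDF5, MRC (float32) and TIFF, and the truth labels
#' as HDF5 and MRC (int16), for I/O round-trip testing.
#'
#' @param phantom a `phantom`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("hdf5", "mrc", "tiff")`.
#' @return named character vector of files written.
#' @export
write_fixtures <- function(phantom, dir, formats = c("hdf5", "mrc",
                                                     "tiff")) {
  stopifnot(inherits(phantom, "phantom"))
  formats <- match.arg(formats, FORMATS, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character(0)
  for (f in formats) {
    ext <- switch(f, hdf5 = "h5", mrc = "mrc", tiff = "tif")
    p <- file.path(dir, paste0("phantom.", ext))
    write_volume_as(phantom$volume, p, f)
    out[f] <- p
  }
  if ("hdf5" %in% formats) {
    p <- file.path(dir, "truth.h5")
    write_hdf5_volume(phantom$truth, p)
    out["truth_hdf5"] <- p
  }
  if ("mrc" %in% formats) {
    p <- file.path(dir, "truth.mrc")
    write_mrc(phantom$truth, p, mode = 1)
    out["truth_mrc"] <- p
  }
  out
}
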