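#' Multichannel 3D voxel image
#'
#' A thin container for confocal-style z-stacks: named 3D intensity arrays
#' sharing one shape, plus the physical voxel size. The voxel size is
#' anisotropic by default (0.1 x 0.1 um in-plane, 0.3 um z-steps). Array
#' index convention is `[x, y, z]`; the centre of voxel `(i, j, k)` lies at
#' `((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz)` um.
#'
#' @param channels Named list of 3D numeric arrays (e.g. `alpha_tubulin`,
#'   `gamma_tubulin`, `hset`).
#' @param voxel_size Numeric length-3, um per voxel in x, y, z.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(channels, voxel_size = c(0.1, 0.1, 0.3)) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  lapply(dims, function(d) stopifnot(length(d) == 3L))
  if (length(unique(dims)) != 1L)
    stop("all channels must share one shape")
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(channels = channels, voxel_size = voxel_size,
                 dim = dims[[1L]]),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<voxel_image> %dx%dx%d voxels (%.2g x %.2g x %.2g um), channels: %s\n",
              x$dim[1L], x$dim[2L], x$dim[3L],
              x$voxel_size[1L], x$voxel_size[2L], x$voxel_size[3L],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# TIFF stores values in [0,1]; intensities are scaled by this factor on
# write and restored on read (12-bit convention).
.tiff_scale <- 4095

#' Write / read a voxel image as per-channel multi-page TIFF
#'
#' Each channel is written as `<dir>/<channel>.tif` (one page per z-slice,
#' 32-bit float), with voxel size recorded in `<dir>/voxel_size.yaml`.
#'
#' @param image A [voxel_image()]. Intensities must lie in
#'   `[0, 4095]` (the stored 12-bit dynamic range).
#' @param dir Directory (created if needed) holding one TIFF per channel.
#' @return `dir` invisibly (write); a [voxel_image()] (read).
#' @export
write_voxel_image <- function(image, dir) {
  stopifnot(inherits(image, "voxel_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(image$channels)) {
    arr <- image$channels[[ch]]
    if (min(arr) < 0 || max(arr) > .tiff_scale)
      stop("channel '", ch, "' outside storable range [0, ", .tiff_scale, "]")
    slices <- lapply(seq_len(dim(arr)[3L]),
                     function(k) arr[, , k] / .tiff_scale)
    tiff::writeTIFF(slices, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  yaml::write_yaml(list(voxel_size = as.numeric(image$voxel_size)),
                   file.path(dir, "voxel_size.yaml"))
  invisible(dir)
}

#' @rdname write_voxel_image
#' @param channels Channel names to read; `NULL` reads every `*.tif` in
#'   `dir`.
#' @param voxel_size Override for the stored voxel size.
#' @export
read_voxel_image <- function(dir, channels = NULL, voxel_size = NULL) {
  if (is.null(channels)) {
    channels <- sub("\\.tif$", "", basename(
      list.files(dir, pattern = "\\.tif$", full.names = FALSE)))
    if (!length(channels)) stop("no .tif channels found in ", dir)
  }
  arrs <- lapply(channels, function(ch) {
    slices <- tiff::readTIFF(file.path(dir, paste0(ch, ".tif")), all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    arr <- array(0, dim = c(dim(slices[[1L]]), length(slices)))
    for (k in seq_along(slices)) arr[, , k] <- slices[[k]] * .tiff_scale
    arr
  })
  names(arrs) <- channels
  if (is.null(voxel_size)) {
    meta <- file.path(dir, "voxel_size.yaml")
    voxel_size <- if (file.exists(meta)) yaml::read_yaml(meta)$voxel_size
                  else c(0.1, 0.1, 0.3)
  }
  voxel_image(arrs, voxel_size = voxel_size)
}

# 26-connected component labelling by vectorized frontier expansion.
# Returns an integer array of labels (0 = background), labels assigned in
# raster-scan order of each component's first voxel, so labelling is
# deterministic.
label_components_26 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  fg <- which(mask)
  if (!length(fg)) return(labels)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  # linear-index offsets are only valid away from borders; use coordinates
  coord <- arrayInd(fg, d)
  lin_of <- function(xyz) (xyz[, 3L] - 1L) * d[1L] * d[2L] +
    (xyz[, 2L] - 1L) * d[1L] + xyz[, 1L]
  next_label <- 0L
  for (seed in seq_along(fg)) {
    if (labels[fg[seed]] != 0L) next
    next_label <- next_label + 1L
    labels[fg[seed]] <- next_label
    frontier <- coord[seed, , drop = FALSE]
    while (nrow(frontier)) {
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(o)
        sweep(frontier, 2L, off[o, ], "+")))
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) break
      nb <- nb[!duplicated(nb), , drop = FALSE]
      li <- lin_of(nb)
      take <- mask[li] & labels[li] == 0L
      nb <- nb[take, , drop = FALSE]
      if (!nrow(nb)) break
      labels[lin_of(nb)] <- next_label
      frontier <- nb
    }
  }
  labels
}

#' Segment a channel by intensity thresholding
#'
#' Foreground is `intensity >= tau`; objects are 26-connected components
#' with at least `min_voxels` voxels. The same threshold is meant to be
#' applied to every cell of an experiment regardless of genotype. Centroids
#' are intensity-unweighted means of voxel centres, converted to physical
#' um via the (anisotropic) voxel size; volume is voxel count times the
#' voxel volume. The principal axis is the leading eigenvector of the
#' second-moment (covariance) matrix of voxel centres, with its two extreme
#' projection points recorded.
#'
#' @param image A [voxel_image()].
#' @param channel Channel name to segment.
#' @param tau Intensity threshold (inclusive).
#' @param min_voxels Minimum object size in voxels (default 1).
#' @return List of `segmented_object`s (possibly empty), each with fields
#'   `label`, `voxels` (n x 3 integer index matrix), `n_voxels`,
#'   `centroid` (um), `volume` (um^3), `principal_axis` (unit vector, NA
#'   for single-voxel objects), `axis_extreme_points` (2 x 3 um matrix).
#'   Objects are ordered by label (raster-scan discovery order).
#' @export
threshold_segment <- function(image, channel, tau, min_voxels = 1L) {
  stopifnot(inherits(image, "voxel_image"),
            channel %in% names(image$channels), min_voxels >= 1L)
  arr <- image$channels[[channel]]
  labels <- label_components_26(arr >= tau)
  n_lab <- max(labels)
  if (n_lab == 0L) return(list())
  vs <- image$voxel_size
  idx <- which(labels > 0L)
  lab <- labels[idx]
  coord <- arrayInd(idx, dim(arr))
  out <- list()
  for (l in seq_len(n_lab)) {
    vox <- coord[lab == l, , drop = FALSE]
    if (nrow(vox) < min_voxels) next
    centers <- sweep(sweep(vox, 2L, 0.5, "-"), 2L, vs, "*")
    centroid <- colMeans(centers)
    if (nrow(vox) > 1L) {
      cv <- stats::cov(centers)
      ax <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
      ax <- ax / sqrt(sum(ax^2))
      # sign convention: largest-magnitude component positive
      if (ax[which.max(abs(ax))] < 0) ax <- -ax
      proj <- centers %*% ax
      extremes <- centers[c(which.min(proj), which.max(proj)), , drop = FALSE]
    } else {
      ax <- rep(NA_real_, 3L)
      extremes <- rbind(centers, centers)
    }
    out[[length(out) + 1L]] <- structure(
      list(label = l, voxels = vox, n_voxels = nrow(vox),
           voxel_size = vs,
           centroid = centroid,
           volume = nrow(vox) * prod(vs),
           principal_axis = ax,
           axis_extreme_points = extremes),
      class = "segmented_object")
  }
  out
}

#' @export
print.segmented_object <- function(x, ...) {
  cat(sprintf("<segmented_object> label=%d voxels=%d volume=%.3f um^3 centroid=(%.2f, %.2f, %.2f)\n",
              x$label, x$n_voxels, x$volume,
              x$centroid[1L], x$centroid[2L], x$centroid[3L]))
  invisible(x)
}
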