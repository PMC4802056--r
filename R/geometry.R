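#' Fit the spindle axis from two pole objects
#'
#' The axis is the line connecting the two pole centroids. A cell is
#' accepted for angle measurements only when the poles lie within
#' `dz_max` of each other in z (default 1.8 um, i.e. six 0.3-um z-steps),
#' so that the spindle lies close to the imaging plane; the comparison is
#' inclusive.
#'
#' @param pole1,pole2 `segmented_object`s or numeric length-3 centroids
#'   (um).
#' @param dz_max Maximum accepted z-separation of the poles, um.
#' @return An object of class `spindle_model` with fields `pole_centroids`
#'   (2 x 3 um matrix), `axis_direction` (unit vector P1 -> P2),
#'   `z_separation`, `accepted`, and `back_edges` (`NULL` until
#'   [pole_back_edges()] is attached).
#' @export
fit_spindle_axis <- function(pole1, pole2, dz_max = 1.8) {
  as_pt <- function(p) {
    if (inherits(p, "segmented_object")) p$centroid
    else { stopifnot(is.numeric(p), length(p) == 3L); as.numeric(p) }
  }
  p1 <- as_pt(pole1); p2 <- as_pt(pole2)
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("degenerate spindle axis: coincident pole centroids")
  zsep <- abs(p1[3L] - p2[3L])
  structure(list(pole_centroids = rbind(p1, p2),
                 axis_direction = v / nv,
                 z_separation = zsep,
                 accepted = zsep <= dz_max,
                 dz_max = dz_max,
                 back_edges = NULL),
            class = "spindle_model")
}

#' @export
print.spindle_model <- function(x, ...) {
  cat(sprintf("<spindle_model> length=%.2f um, z-separation=%.2f um (%s)\n",
              sqrt(sum((x$pole_centroids[2L, ] - x$pole_centroids[1L, ])^2)),
              x$z_separation,
              if (x$accepted) "accepted" else
                sprintf("rejected: > %.2f um", x$dz_max)))
  invisible(x)
}

#' Locate the back edges of the spindle poles
#'
#' The back edge of each pole is the spindle object's extreme point along
#' the spindle axis ("longest axis points"): the voxel centres attaining
#' the minimum and maximum scalar projection onto the axis direction.
#' Returned in pole order: the edge nearer pole 1 first.
#'
#' @param spindle_object A `segmented_object` covering the whole spindle
#'   (alpha-tubulin staining).
#' @param spindle A `spindle_model`; its axis is used and the back edges
#'   are attached to the returned model. Alternatively pass `axis` alone.
#' @param axis Unit vector; defaults to the spindle model's axis or, if no
#'   model is given, the object's principal axis.
#' @return The updated `spindle_model` (if given), otherwise a 2 x 3 matrix
#'   of back-edge points in um.
#' @export
pole_back_edges <- function(spindle_object, spindle = NULL, axis = NULL) {
  stopifnot(inherits(spindle_object, "segmented_object"))
  if (is.null(axis)) {
    axis <- if (!is.null(spindle)) spindle$axis_direction
            else spindle_object$principal_axis
  }
  if (anyNA(axis)) stop("no usable axis for back-edge extraction")
  axis <- axis / sqrt(sum(axis^2))
  centers <- sweep(sweep(spindle_object$voxels, 2L, 0.5, "-"), 2L,
                   spindle_object$voxel_size, "*")
  proj <- centers %*% axis
  edges <- centers[c(which.min(proj), which.max(proj)), , drop = FALSE]
  if (!is.null(spindle)) {
    # order edges so edges[i, ] is the one nearer pole i
    d1 <- sum((edges[1L, ] - spindle$pole_centroids[1L, ])^2)
    d2 <- sum((edges[2L, ] - spindle$pole_centroids[1L, ])^2)
    if (d2 < d1) edges <- edges[2:1, , drop = FALSE]
    spindle$back_edges <- edges
    return(spindle)
  }
  edges
}

#' Centrosome angle relative to the spindle axis
#'
#' Computed in the xy maximum-projection plane (z is discarded), matching a
#' projection-based measurement workflow. The vertex is the centroid of
#' the nearer pole; the angle is between the outward axis direction (away
#' from the other pole) and the pole-to-centrosome vector, in degrees
#' within `[0, 180]`. Angles are binned at 15 and 30 degrees.
#'
#' @param C Centrosome centroid, numeric length-3 (um).
#' @param spindle An accepted `spindle_model`.
#' @return List with `angle_deg`, `angle_bin` (`"<=15"`, `"15-30"`,
#'   `">30"`), `assigned_pole` (1 or 2), and `flagged` (`TRUE` when the
#'   centrosome coincides with the vertex pole, in which case the angle is
#'   defined as 0).
#' @export
centrosome_angle <- function(C, spindle) {
  stopifnot(inherits(spindle, "spindle_model"), length(C) == 3L)
  if (!spindle$accepted)
    stop("angle undefined: spindle not accepted (z-separation ",
         sprintf("%.2f", spindle$z_separation), " um)")
  P <- spindle$pole_centroids
  dd <- c(sum((C - P[1L, ])^2), sum((C - P[2L, ])^2))
  pole <- which.min(dd)
  other <- 3L - pole
  outward <- (P[pole, 1:2] - P[other, 1:2])
  u <- C[1:2] - P[pole, 1:2]
  nu <- sqrt(sum(u^2)); no <- sqrt(sum(outward^2))
  if (no < 1e-12)
    stop("degenerate axis in xy projection")
  flagged <- nu < 1e-9
  ang <- if (flagged) 0 else {
    cs <- sum(u * outward) / (nu * no)
    acos(max(-1, min(1, cs))) * 180 / pi
  }
  list(angle_deg = ang, angle_bin = angle_bin(ang),
       assigned_pole = pole, flagged = flagged)
}

#' Bin an angle at the 15 and 30 degree cutoffs
#' @param angle_deg Angle(s) in degrees.
#' @return Character vector: `"<=15"`, `"15-30"` or `">30"`.
#' @export
angle_bin <- function(angle_deg) {
  ifelse(angle_deg <= 15, "<=15", ifelse(angle_deg <= 30, "15-30", ">30"))
}

#' Distance from a centrosome to the nearer pole back edge
#'
#' 3D Euclidean distance from the centrosome centroid to the nearer of the
#' two pole back-edge points; the centrosome is assigned to that pole.
#'
#' @param C Centrosome centroid, numeric length-3 (um).
#' @param spindle A `spindle_model` with back edges attached, or a 2 x 3
#'   matrix of back-edge points.
#' @return List with `distance_um` and `assigned_pole` (1 or 2).
#' @export
centrosome_pole_distance <- function(C, spindle) {
  B <- if (inherits(spindle, "spindle_model")) {
    if (is.null(spindle$back_edges))
      stop("spindle model has no back edges; run pole_back_edges() first")
    spindle$back_edges
  } else spindle
  stopifnot(is.matrix(B), nrow(B) == 2L, ncol(B) == 3L, length(C) == 3L)
  d <- c(sqrt(sum((C - B[1L, ])^2)), sqrt(sum((C - B[2L, ])^2)))
  pole <- which.min(d)
  list(distance_um = d[pole], assigned_pole = pole)
}

#' Measure centrosome volume and marker intensity
#'
#' Segments the centrosome marker channel (e.g. gamma-tubulin) and, per
#' object, reports volume and the mean intensity of a measurement channel
#' (e.g. HSET) over the object's voxels. The per-cell summary averages the
#' two largest objects ("averaged across the two centrosomes in each
#' cell"); size ties break toward the lower label. More than two marker
#' objects triggers a warning (debris), a single object is flagged.
#'
#' @param image A [voxel_image()].
#' @param marker Marker channel name defining the centrosomal volumes.
#' @param measure Channel whose mean intensity is reported.
#' @param tau Threshold for the marker channel.
#' @param min_voxels Minimum object size (default 1).
#' @return List with `measures` (data.frame: `label`, `n_voxels`, `volume`,
#'   `mean_intensity`, `centroid.x/y/z`, for the up-to-two selected
#'   objects), `objects` (their `segmented_object`s), `summary` (list:
#'   `volume`, `mean_intensity`, both averaged over the selected objects),
#'   `n_objects` (before selection) and `flagged` (single centrosome).
#' @export
measure_centrosomes <- function(image, marker, measure, tau, min_voxels = 1L) {
  stopifnot(inherits(image, "voxel_image"),
            measure %in% names(image$channels))
  objs <- threshold_segment(image, marker, tau, min_voxels)
  n_all <- length(objs)
  if (n_all == 0L) {
    warning("no centrosome objects found in channel '", marker, "'")
    return(list(measures = data.frame(), objects = list(),
                summary = list(volume = NA_real_, mean_intensity = NA_real_),
                n_objects = 0L, flagged = TRUE))
  }
  if (n_all > 2L)
    warning(n_all, " marker objects found; using the two largest")
  sizes <- vapply(objs, `[[`, integer(1L), "n_voxels")
  keep <- order(-sizes, vapply(objs, `[[`, integer(1L), "label"))[
    seq_len(min(2L, n_all))]
  keep <- sort(keep)
  objs <- objs[keep]
  meas_arr <- image$channels[[measure]]
  d <- dim(meas_arr)
  rows <- lapply(objs, function(o) {
    li <- (o$voxels[, 3L] - 1L) * d[1L] * d[2L] +
      (o$voxels[, 2L] - 1L) * d[1L] + o$voxels[, 1L]
    data.frame(label = o$label, n_voxels = o$n_voxels, volume = o$volume,
               mean_intensity = mean(meas_arr[li]),
               centroid.x = o$centroid[1L], centroid.y = o$centroid[2L],
               centroid.z = o$centroid[3L])
  })
  measures <- do.call(rbind, rows)
  list(measures = measures, objects = objs,
       summary = list(volume = mean(measures$volume),
                      mean_intensity = mean(measures$mean_intensity)),
       n_objects = n_all, flagged = n_all == 1L)
}

#' Classify the mitotic phenotype of a cell
#'
#' Categories, in order of precedence: `multipolar` (more than two spindle
#' poles), `disorganized` (fewer than two poles, or spindle axis rejected
#' or degenerate — unfocussed/monopolar/collapsed spindles), `detached`
#' (any centrosome farther than `d_det` from its pole back edge; one or
#' two centrosomes may be detached), else `normal`. The classification is
#' a pure function of its inputs and is invariant to centrosome order.
#'
#' @param n_poles Number of spindle-pole objects found.
#' @param spindle_ok `TRUE` when a spindle axis was fitted and accepted.
#' @param distances Numeric vector of per-centrosome pole distances (um);
#'   may be empty when no axis exists.
#' @param d_det Detachment threshold in um (default 1.0; an explicit
#'   analysis choice, as "detached" is a qualitative category).
#' @return An object of class `cell_phenotype`: list with `category`,
#'   `n_poles`, `detached_count`, `params_used`.
#' @export
classify_phenotype <- function(n_poles, spindle_ok, distances = numeric(),
                               d_det = 1.0) {
  n_det <- sum(distances > d_det, na.rm = TRUE)
  category <- if (n_poles > 2L) "multipolar"
    else if (n_poles < 2L || !isTRUE(spindle_ok)) "disorganized"
    else if (n_det >= 1L) "detached"
    else "normal"
  structure(list(category = category, n_poles = as.integer(n_poles),
                 detached_count = as.integer(if (category == "detached") n_det else
                   min(n_det, 2L)),
                 params_used = list(d_det = d_det)),
            class = "cell_phenotype")
}

#' @export
print.cell_phenotype <- function(x, ...) {
  cat(sprintf("<cell_phenotype> %s (poles=%d, detached=%d)\n",
              x$category, x$n_poles, x$detached_count))
  invisible(x)
}

#' Analysis parameters for 3D geometry quantification
#'
#' Bundles the channel roles and thresholds applied identically to every
#' cell of an experiment.
#'
#' @param pole_channel Channel segmented at `tau_pole` to find spindle-pole
#'   objects (default `"alpha_tubulin"`).
#' @param spindle_channel Channel segmented at the lower `tau_spindle` to
#'   delimit the whole spindle body for back edges (default
#'   `"alpha_tubulin"`).
#' @param marker_channel Centrosome marker channel (default
#'   `"gamma_tubulin"`).
#' @param measure_channel Channel whose centrosomal mean intensity is
#'   reported (default `"hset"`).
#' @param tau_pole,tau_spindle,tau_marker Intensity thresholds.
#' @param min_voxels Minimum object size in voxels (default 5).
#' @param d_det Detachment threshold, um (default 1.0).
#' @param dz_max Pole z-separation acceptance window, um (default 1.8).
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(pole_channel = "alpha_tubulin",
                            spindle_channel = "alpha_tubulin",
                            marker_channel = "gamma_tubulin",
                            measure_channel = "hset",
                            tau_pole = 200, tau_spindle = 40,
                            tau_marker = 100,
                            min_voxels = 5L, d_det = 1.0, dz_max = 1.8) {
  stopifnot(tau_pole > 0, tau_spindle > 0, tau_marker > 0,
            min_voxels >= 1L, d_det > 0, dz_max > 0)
  structure(list(pole_channel = pole_channel,
                 spindle_channel = spindle_channel,
                 marker_channel = marker_channel,
                 measure_channel = measure_channel,
                 tau_pole = tau_pole, tau_spindle = tau_spindle,
                 tau_marker = tau_marker,
                 min_voxels = as.integer(min_voxels),
                 d_det = d_det, dz_max = dz_max),
            class = "geometry_params")
}

empty_cell_row <- function(cell_id) {
  data.frame(cell_id = cell_id, n_poles = NA_integer_, accepted = NA,
             z_separation = NA_real_,
             volume_1 = NA_real_, intensity_1 = NA_real_,
             angle_1 = NA_real_, bin_1 = NA_character_, d_1 = NA_real_,
             volume_2 = NA_real_, intensity_2 = NA_real_,
             angle_2 = NA_real_, bin_2 = NA_character_, d_2 = NA_real_,
             mean_volume = NA_real_, mean_intensity = NA_real_,
             category = NA_character_, detached_count = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Quantify centrosome-spindle geometry in one cell
#'
#' Runs the full per-cell measurement chain: spindle-pole segmentation and
#' counting, axis fit with z-separation acceptance, whole-spindle back
#' edges, centrosome segmentation/intensity, per-centrosome angle and
#' pole distance, and phenotype classification. Angles and distances are
#' reported only for accepted bipolar cells; the phenotype is always
#' reported.
#'
#' @param image A [voxel_image()].
#' @param params A [geometry_params()].
#' @param cell_id Identifier copied into the output row.
#' @return A one-row data.frame (see [empty columns][quantify_cells] for
#'   the schema): `cell_id, n_poles, accepted, z_separation, volume_i,
#'   intensity_i, angle_i, bin_i, d_i (i = 1, 2), mean_volume,
#'   mean_intensity, category, detached_count`.
#' @export
quantify_cell <- function(image, params = geometry_params(),
                          cell_id = "cell") {
  stopifnot(inherits(image, "voxel_image"),
            inherits(params, "geometry_params"))
  row <- empty_cell_row(cell_id)
  poles <- threshold_segment(image, params$pole_channel, params$tau_pole,
                             params$min_voxels)
  row$n_poles <- length(poles)
  if (length(poles) > 1L) {
    # canonical pole order: ascending centroid x (then y, z), so reported
    # pole/centrosome indices do not depend on raster-scan label order
    cen <- t(vapply(poles, `[[`, numeric(3L), "centroid"))
    poles <- poles[order(cen[, 1L], cen[, 2L], cen[, 3L])]
  }
  cm <- suppressWarnings(
    measure_centrosomes(image, params$marker_channel,
                        params$measure_channel, params$tau_marker,
                        params$min_voxels))
  meas <- cm$measures
  if (nrow(meas)) {
    row$mean_volume <- cm$summary$volume
    row$mean_intensity <- cm$summary$mean_intensity
    meas$d <- NA_real_; meas$angle <- NA_real_
    meas$bin <- NA_character_; meas$pole <- NA_integer_
  }
  spindle <- NULL
  if (length(poles) == 2L) {
    spindle <- tryCatch(
      fit_spindle_axis(poles[[1L]], poles[[2L]], dz_max = params$dz_max),
      error = function(e) NULL)
  }
  distances <- numeric()
  if (!is.null(spindle)) {
    row$accepted <- spindle$accepted
    row$z_separation <- spindle$z_separation
    body <- threshold_segment(image, params$spindle_channel,
                              params$tau_spindle, params$min_voxels)
    if (length(body) && nrow(meas)) {
      sizes <- vapply(body, `[[`, integer(1L), "n_voxels")
      spindle <- pole_back_edges(body[[which.max(sizes)]], spindle)
      for (i in seq_len(nrow(meas))) {
        C <- as.numeric(meas[i, c("centroid.x", "centroid.y", "centroid.z")])
        dist <- centrosome_pole_distance(C, spindle)
        meas$d[i] <- dist$distance_um
        meas$pole[i] <- dist$assigned_pole
        distances <- c(distances, dist$distance_um)
        if (spindle$accepted) {
          ang <- centrosome_angle(C, spindle)
          meas$angle[i] <- ang$angle_deg
          meas$bin[i] <- ang$angle_bin
        }
      }
    }
  } else {
    row$accepted <- FALSE
  }
  if (nrow(meas)) {
    # report centrosomes in pole order where assigned, else by position
    ord <- if (!anyNA(meas$pole) && length(unique(meas$pole)) == nrow(meas))
      order(meas$pole) else order(meas$centroid.x, meas$centroid.y,
                                  meas$centroid.z)
    meas <- meas[ord, , drop = FALSE]
    for (i in seq_len(nrow(meas))) {
      row[[paste0("volume_", i)]] <- meas$volume[i]
      row[[paste0("intensity_", i)]] <- meas$mean_intensity[i]
      row[[paste0("d_", i)]] <- meas$d[i]
      row[[paste0("angle_", i)]] <- meas$angle[i]
      row[[paste0("bin_", i)]] <- meas$bin[i]
    }
  }
  ph <- classify_phenotype(length(poles),
                           !is.null(spindle) && spindle$accepted,
                           distances, d_det = params$d_det)
  row$category <- ph$category
  row$detached_count <- ph$detached_count
  row
}

#' Quantify a collection of cells
#'
#' @param images Named list of [voxel_image()]s, or a character vector of
#'   directories readable by [read_voxel_image()].
#' @param params A [geometry_params()].
#' @return A data.frame with one row per cell (schema as in
#'   [quantify_cell()]).
#' @export
quantify_cells <- function(images, params = geometry_params()) {
  if (is.character(images)) {
    ids <- basename(images)
    rows <- lapply(seq_along(images), function(i)
      quantify_cell(read_voxel_image(images[i]), params, cell_id = ids[i]))
  } else {
    ids <- names(images)
    if (is.null(ids)) ids <- sprintf("cell_%03d", seq_along(images))
    rows <- lapply(seq_along(images), function(i)
      quantify_cell(images[[i]], params, cell_id = ids[i]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
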