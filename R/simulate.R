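#' Parameters for simulating an AP-MS pulldown experiment
#'
#' The generator emulates the structure of a TAP pulldown screen: R bait
#' replicates plus control pulldowns from an untagged wild-type line and
#' from other TAP-tagged bait lines. Three protein classes are planted:
#' genuine bait interactors (bait runs only), sticky background proteins
#' (bait and every control line), and tag-specific binders (every
#' TAP-tagged run, bait and other-bait, but not untagged WT).
#'
#' Unique peptide counts are Poisson with per-class means; each true
#' interactor is independently missed (zeroed) in each replicate with
#' probability `dropout_q`. In `fixed_count_mode` the Poisson draw is
#' replaced by the deterministic mean, so threshold behaviour is exactly
#' predictable. In the runs that define a class's presence (controls for
#' background/tag-specific proteins) counts are zero-truncated, so class
#' membership guarantees detection there. Mascot scores follow
#' `s = mascot_slope * u + N(0, mascot_noise)`, floored at 0.
#'
#' @param n_true,n_background,n_tag_specific Class sizes.
#' @param lambda_true,lambda_bg Mean unique-peptide counts.
#' @param dropout_q Per-replicate probability a true interactor is missed.
#' @param replicates Number of bait replicates R (default 3).
#' @param control_lines List of `list(line_id=, role=, replicates=)`
#'   entries; default one untagged WT line and two other-bait TAP lines,
#'   one run each.
#' @param mascot_slope,mascot_noise Linear Mascot-score model.
#' @param fixed_count_mode Use deterministic counts equal to the class
#'   mean (default `FALSE`).
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `apms_sim_params`.
#' @export
apms_sim_params <- function(n_true = 20L, n_background = 50L,
                            n_tag_specific = 10L,
                            lambda_true = 6, lambda_bg = 3,
                            dropout_q = 0, replicates = 3L,
                            control_lines = list(
                              list(line_id = "WT", role = "control_untagged",
                                   replicates = 1L),
                              list(line_id = "TAP-OTHER1",
                                   role = "control_other_bait",
                                   replicates = 1L),
                              list(line_id = "TAP-OTHER2",
                                   role = "control_other_bait",
                                   replicates = 1L)),
                            mascot_slope = 30, mascot_noise = 10,
                            fixed_count_mode = FALSE, seed = 1L) {
  stopifnot(n_true >= 0L, n_background >= 0L, n_tag_specific >= 0L,
            lambda_true >= 0, lambda_bg >= 0,
            dropout_q >= 0, dropout_q <= 1, replicates >= 1L,
            mascot_slope >= 0, mascot_noise >= 0)
  structure(list(n_true = as.integer(n_true),
                 n_background = as.integer(n_background),
                 n_tag_specific = as.integer(n_tag_specific),
                 lambda_true = lambda_true, lambda_bg = lambda_bg,
                 dropout_q = dropout_q, replicates = as.integer(replicates),
                 control_lines = control_lines,
                 mascot_slope = mascot_slope, mascot_noise = mascot_noise,
                 fixed_count_mode = isTRUE(fixed_count_mode),
                 seed = as.integer(seed)),
            class = "apms_sim_params")
}

sim_mascot <- function(u, params) {
  s <- params$mascot_slope * u + stats::rnorm(length(u), 0, params$mascot_noise)
  ifelse(u > 0L, pmax(0, s), 0)
}

sim_counts <- function(n, lambda, params, truncated = FALSE) {
  if (params$fixed_count_mode) {
    u <- rep(as.integer(round(lambda)), n)
    if (truncated) u <- pmax(1L, u)
    return(u)
  }
  if (truncated) 1L + stats::rpois(n, max(lambda - 1, 0))
  else stats::rpois(n, lambda)
}

#' Simulate an AP-MS experiment with known ground truth
#'
#' @param params An [apms_sim_params()].
#' @return An object of class `apms_simulation`: list with `experiment`
#'   (an [experiment_set()], runs already non-redundant), `truth`
#'   (data.frame `accession`, `class` in
#'   `true_interactor`/`background`/`tag_specific`), and `params`.
#' @seealso [filtered3_recovery_prob()] for the closed-form recovery
#'   probability under dropout.
#' @export
simulate_apms <- function(params = apms_sim_params()) {
  stopifnot(inherits(params, "apms_sim_params"))
  set.seed(params$seed)
  acc_true <- sprintf("INT%04d", seq_len(params$n_true))
  acc_bg <- sprintf("BGD%04d", seq_len(params$n_background))
  acc_tag <- sprintf("TAG%04d", seq_len(params$n_tag_specific))
  truth <- data.frame(
    accession = c(acc_true, acc_bg, acc_tag),
    class = rep(c("true_interactor", "background", "tag_specific"),
                c(params$n_true, params$n_background, params$n_tag_specific)),
    stringsAsFactors = FALSE)
  make_records <- function(acc, u) {
    keep <- u > 0L
    data.frame(accession = acc[keep], gene_symbol = acc[keep],
               unique_peptides = u[keep],
               mascot_score = sim_mascot(u[keep], params),
               stringsAsFactors = FALSE)
  }
  bait_runs <- lapply(seq_len(params$replicates), function(r) {
    u_true <- sim_counts(params$n_true, params$lambda_true, params)
    dropped <- stats::runif(params$n_true) < params$dropout_q
    u_true[dropped] <- 0L
    u_bg <- sim_counts(params$n_background, params$lambda_bg, params)
    u_tag <- sim_counts(params$n_tag_specific, params$lambda_bg, params)
    pulldown_run("BAIT-TAP", "bait", r,
                 make_records(c(acc_true, acc_bg, acc_tag),
                              c(u_true, u_bg, u_tag)))
  })
  control_runs <- list()
  for (line in params$control_lines) {
    for (r in seq_len(line$replicates)) {
      u_bg <- sim_counts(params$n_background, params$lambda_bg, params,
                         truncated = TRUE)
      if (line$role == "control_other_bait") {
        u_tag <- sim_counts(params$n_tag_specific, params$lambda_bg, params,
                            truncated = TRUE)
        rec <- make_records(c(acc_bg, acc_tag), c(u_bg, u_tag))
      } else {
        rec <- make_records(acc_bg, u_bg)
      }
      control_runs[[length(control_runs) + 1L]] <-
        pulldown_run(line$line_id, line$role, r, rec)
    }
  }
  structure(list(
    experiment = experiment_set(bait_runs, control_runs,
                                manifest = list(simulated = TRUE,
                                                seed = params$seed)),
    truth = truth, params = params),
    class = "apms_simulation")
}

#' Write a simulated AP-MS experiment to disk
#'
#' Writes one evidence table per run, a `manifest.yaml` consumable by
#' [read_experiment_manifest()], and `truth.tsv`.
#'
#' @param sim An `apms_simulation`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_apms_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "apms_simulation"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runs <- c(sim$experiment$bait_runs, sim$experiment$control_runs)
  entries <- lapply(runs, function(run) {
    fn <- sprintf("%s_rep%d.tsv", gsub("[^A-Za-z0-9_-]", "_", run$line_id),
                  run$replicate_index)
    write_evidence_table(run, file.path(out_dir, fn))
    list(line_id = run$line_id, role = run$role,
         replicate_index = run$replicate_index, path = fn)
  })
  yaml::write_yaml(list(seed = sim$params$seed, runs = entries),
                   file.path(out_dir, "manifest.yaml"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Closed-form top-tier recovery probability under replicate dropout
#'
#' In `fixed_count_mode` with per-replicate count `count`, a true
#' interactor (absent from all controls) reaches the top tier iff the
#' number of non-dropped replicates — Binomial(R, 1 - q) — meets every
#' presence condition: presence in all `all_replicates`, `min_presence`,
#' and (when `count >= peptide_threshold`) `peptide_threshold_replicates`
#' replicates at threshold. With default thresholds and `R = 3` this is
#' `(1 - q)^3`.
#'
#' @param dropout_q Per-replicate dropout probability.
#' @param count Deterministic per-replicate unique-peptide count.
#' @param params A [filter_params()].
#' @param R Number of bait replicates.
#' @return Probability in `[0, 1]`.
#' @export
filtered3_recovery_prob <- function(dropout_q, count = 6L,
                                    params = filter_params(), R = 3L) {
  if (count < 1L) return(0)
  if (count < params$peptide_threshold && params$peptide_threshold_replicates > 0L)
    return(0)
  need <- max(params$all_replicates, params$min_presence,
              params$peptide_threshold_replicates)
  if (need > R) return(0)
  sum(stats::dbinom(need:R, R, 1 - dropout_q))
}

#' Parameters for simulating voxelized mitotic cells
#'
#' Each synthetic cell is a bipolar spindle rendered into a 3-channel
#' anisotropic voxel grid: an alpha-tubulin channel (Gaussian-profile
#' spindle body connecting two bright pole blobs), a gamma-tubulin channel
#' (two centrosome blobs) and a measurement channel co-located with the
#' centrosomes whose amplitude is scaled by `intensity_ratio` (the
#' genotype effect on centrosomal signal). Gaussian blobs, not a PSF
#' model: the goal is exercising segmentation and geometry, not optical
#' realism.
#'
#' Geometry: poles sit `spindle_length` apart, the axis drawn with a
#' random in-plane azimuth (within `azimuth_max_deg`) and a z-tilt giving
#' a pole z-separation uniform on `[0, z_sep_max]`. The pole "back edge"
#' is defined geometrically at `back_edge_extent` um beyond each pole
#' centroid along the axis; [sim_geometry_params()] derives the matched
#' alpha-tubulin threshold whose iso-surface crosses the axis exactly
#' there, so ground truth is exact in pre-noise coordinates. Centrosomes
#' are attached at their pole (isotropic jitter `attach_jitter`) or, with
#' probability `detached_fraction` per cell, displaced: offset magnitude
#' lognormal(`detach_meanlog`, `detach_sdlog`) truncated at `detach_max`,
#' direction at an angle uniform on [0, 90] degrees from the outward axis
#' in the xy plane (one centrosome, or both with probability
#' `detach_both_prob`). The truth category applies the phenotype rule to
#' the exact coordinates with threshold `d_det`.
#'
#' @param n_cells Number of cells.
#' @param spindle_length Pole-to-pole distance, um (default 8).
#' @param pole_sigma,pole_amp Pole blob Gaussian sigma (um) / amplitude.
#' @param body_sigma,body_amp Spindle-body radial sigma (um) / amplitude.
#' @param back_edge_extent Back-edge distance beyond the pole centroid, um.
#' @param centrosome_sigma,centrosome_amp Centrosome blob sigma / amplitude
#'   (gamma-tubulin channel).
#' @param measure_amp Measurement-channel amplitude at full signal.
#' @param intensity_ratio Genotype scaling of the measurement channel
#'   (rho; 1 = wild-type level).
#' @param detached_fraction Per-cell probability of planted detachment.
#' @param detach_meanlog,detach_sdlog,detach_max Lognormal offset
#'   distribution (um), truncated.
#' @param detach_both_prob Probability both centrosomes detach in a
#'   detached cell.
#' @param attach_jitter Isotropic sd of attached-centrosome placement, um.
#' @param z_sep_max Maximum planted pole z-separation, um.
#' @param azimuth_max_deg Maximum |in-plane axis rotation|, degrees.
#' @param background Uniform background level, all channels.
#' @param noise_sd Gaussian read-noise sd (0 = noiseless).
#' @param poisson_noise Add Poisson shot noise (default `FALSE`).
#' @param voxel_size um per voxel in x, y, z.
#' @param grid Grid shape in voxels (x, y, z).
#' @param d_det Detachment threshold used for the truth category, um.
#' @param planted Optional data.frame with columns `alpha` (deg) and
#'   `offset` (um): explicit placement of centrosome 1 per cell (recycled),
#'   overriding the random detachment model; centrosome 2 stays attached
#'   with no jitter. Used for recovery experiments.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `cell_sim_params`.
#' @export
cell_sim_params <- function(n_cells = 10L, spindle_length = 8,
                            pole_sigma = 0.3, pole_amp = 255,
                            body_sigma = 0.35, body_amp = 80,
                            back_edge_extent = 0.6,
                            centrosome_sigma = 0.3, centrosome_amp = 200,
                            measure_amp = 200, intensity_ratio = 1,
                            detached_fraction = 0,
                            detach_meanlog = log(2), detach_sdlog = 0.25,
                            detach_max = 3.2, detach_both_prob = 0.2,
                            attach_jitter = 0.05,
                            z_sep_max = 1.2, azimuth_max_deg = 15,
                            background = 2, noise_sd = 10,
                            poisson_noise = FALSE,
                            voxel_size = c(0.1, 0.1, 0.3),
                            grid = c(176L, 112L, 24L),
                            d_det = 1.0, planted = NULL, seed = 1L) {
  stopifnot(n_cells >= 1L, spindle_length > 0,
            detached_fraction >= 0, detached_fraction <= 1,
            intensity_ratio > 0, all(voxel_size > 0), all(grid >= 4L),
            noise_sd >= 0, background >= 0, d_det > 0)
  if (!is.null(planted))
    stopifnot(is.data.frame(planted),
              all(c("alpha", "offset") %in% names(planted)))
  structure(as.list(environment()), class = "cell_sim_params")
}

#' Geometry-analysis parameters matched to a cell simulation
#'
#' Derives thresholds consistent with the generator's amplitudes: the
#' pole threshold sits halfway up the pole blob above the local body +
#' background level, the spindle threshold is the exact rendered
#' intensity at the defined back edge (so the segmented spindle ends
#' there, up to voxelization), and the marker threshold is half the
#' centrosome amplitude above background.
#'
#' @param params A [cell_sim_params()].
#' @return A [geometry_params()].
#' @export
sim_geometry_params <- function(params) {
  stopifnot(inherits(params, "cell_sim_params"))
  r2 <- params$back_edge_extent^2
  tau_sp <- params$background +
    params$body_amp * exp(-r2 / (2 * params$body_sigma^2)) +
    params$pole_amp * exp(-r2 / (2 * params$pole_sigma^2))
  geometry_params(
    tau_pole = params$background + params$body_amp + params$pole_amp / 2,
    tau_spindle = tau_sp,
    tau_marker = params$background + params$centrosome_amp / 2,
    min_voxels = 5L, d_det = params$d_det, dz_max = 1.8)
}

# squared distance from every voxel centre to the segment p1-p2,
# returned as an array of the grid shape
dist2_to_segment <- function(xs, ys, zs, p1, p2) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  v <- p2 - p1
  L2 <- sum(v^2)
  wx <- array(xs - p1[1L], dim = c(nx, ny, nz))
  wy <- array(rep(ys - p1[2L], each = nx), dim = c(nx, ny, nz))
  wz <- array(rep(zs - p1[3L], each = nx * ny), dim = c(nx, ny, nz))
  t <- (wx * v[1L] + wy * v[2L] + wz * v[3L]) / L2
  t[t < 0] <- 0; t[t > 1] <- 1
  (wx - t * v[1L])^2 + (wy - t * v[2L])^2 + (wz - t * v[3L])^2
}

# add a Gaussian blob in-place within a 4-sigma window
add_blob <- function(arr, center, sigma, amp, xs, ys, zs) {
  ix <- which(abs(xs - center[1L]) <= 4 * sigma)
  iy <- which(abs(ys - center[2L]) <= 4 * sigma)
  iz <- which(abs(zs - center[3L]) <= 4 * sigma)
  if (!length(ix) || !length(iy) || !length(iz)) return(arr)
  d2 <- outer(outer((xs[ix] - center[1L])^2, (ys[iy] - center[2L])^2, "+"),
              (zs[iz] - center[3L])^2, "+")
  arr[ix, iy, iz] <- arr[ix, iy, iz] + amp * exp(-d2 / (2 * sigma^2))
  arr
}

# draw the exact geometry of every cell; consumes RNG deterministically
plan_cells <- function(params) {
  n <- params$n_cells
  L <- params$spindle_length
  vs <- params$voxel_size
  extent <- params$grid * vs
  center <- extent / 2
  plans <- vector("list", n)
  for (i in seq_len(n)) {
    az <- stats::runif(1, -params$azimuth_max_deg, params$azimuth_max_deg) *
      pi / 180
    zsep <- stats::runif(1, 0, params$z_sep_max)
    cz <- zsep / L
    s <- sqrt(1 - cz^2)
    axis <- c(cos(az) * s, sin(az) * s, cz)
    P <- rbind(center - L / 2 * axis, center + L / 2 * axis)
    B <- rbind(P[1L, ] - params$back_edge_extent * axis,
               P[2L, ] + params$back_edge_extent * axis)
    outward <- rbind(-axis, axis)
    C <- matrix(0, 2L, 3L)
    planted_alpha <- rep(NA_real_, 2L)
    if (!is.null(params$planted)) {
      row <- params$planted[(i - 1L) %% nrow(params$planted) + 1L, ]
      C[1L, ] <- place_centrosome(P[1L, ], outward[1L, ], row$alpha,
                                  row$offset)
      C[2L, ] <- P[2L, ]
      planted_alpha[1L] <- row$alpha
    } else {
      det_cell <- stats::runif(1) < params$detached_fraction
      which_det <- if (!det_cell) integer() else {
        first <- sample(1:2, 1L)
        if (stats::runif(1) < params$detach_both_prob) 1:2 else first
      }
      for (j in 1:2) {
        if (j %in% which_det) {
          off <- min(stats::rlnorm(1, params$detach_meanlog,
                                   params$detach_sdlog), params$detach_max)
          alpha <- stats::runif(1, 0, 90)
          planted_alpha[j] <- alpha
          C[j, ] <- place_centrosome(P[j, ], outward[j, ], alpha, off) +
            stats::rnorm(3, 0, params$attach_jitter)
        } else {
          C[j, ] <- P[j, ] + stats::rnorm(3, 0, params$attach_jitter)
        }
      }
    }
    d_true <- c(sqrt(sum((C[1L, ] - B[1L, ])^2)),
                sqrt(sum((C[2L, ] - B[2L, ])^2)))
    ang_true <- vapply(1:2, function(j) {
      u <- C[j, 1:2] - P[j, 1:2]
      if (sqrt(sum(u^2)) < 1e-12) return(0)
      o <- outward[j, 1:2]
      cs <- sum(u * o) / sqrt(sum(u^2) * sum(o^2))
      acos(max(-1, min(1, cs))) * 180 / pi
    }, numeric(1L))
    category <- classify_phenotype(2L, zsep <= 1.8, d_true,
                                   d_det = params$d_det)
    plans[[i]] <- list(P = P, B = B, C = C, axis = axis, zsep = zsep,
                       d_true = d_true, angle_true = ang_true,
                       planted_alpha = planted_alpha,
                       category = category$category,
                       detached_count = category$detached_count)
  }
  plans
}

# planted placement: angle alpha (deg) from the outward axis direction,
# rotated in the xy plane, at distance offset from the pole centroid
place_centrosome <- function(P, outward, alpha, offset) {
  o <- outward[1:2]
  o <- o / sqrt(sum(o^2))
  perp <- c(-o[2L], o[1L])
  a <- alpha * pi / 180
  P + c(offset * (cos(a) * o + sin(a) * perp), 0)
}

render_cell <- function(params, plan, xs, ys, zs) {
  d2 <- dist2_to_segment(xs, ys, zs, plan$P[1L, ], plan$P[2L, ])
  alpha_ch <- params$body_amp * exp(-d2 / (2 * params$body_sigma^2))
  for (j in 1:2)
    alpha_ch <- add_blob(alpha_ch, plan$P[j, ], params$pole_sigma,
                         params$pole_amp, xs, ys, zs)
  gamma_ch <- array(0, dim = dim(alpha_ch))
  hset_ch <- array(0, dim = dim(alpha_ch))
  for (j in 1:2) {
    gamma_ch <- add_blob(gamma_ch, plan$C[j, ], params$centrosome_sigma,
                         params$centrosome_amp, xs, ys, zs)
    hset_ch <- add_blob(hset_ch, plan$C[j, ], params$centrosome_sigma,
                        params$measure_amp * params$intensity_ratio,
                        xs, ys, zs)
  }
  chans <- list(alpha_tubulin = alpha_ch, gamma_tubulin = gamma_ch,
                hset = hset_ch)
  for (nm in names(chans)) {
    ch <- chans[[nm]] + params$background
    if (params$poisson_noise) ch <- stats::rpois(length(ch), pmax(ch, 0))
    if (params$noise_sd > 0)
      ch <- ch + stats::rnorm(length(ch), 0, params$noise_sd)
    ch[ch < 0] <- 0
    ch[ch > .tiff_scale] <- .tiff_scale
    chans[[nm]] <- array(ch, dim = dim(alpha_ch))
  }
  voxel_image(chans, voxel_size = params$voxel_size)
}

sim_truth_table <- function(plans) {
  do.call(rbind, lapply(seq_along(plans), function(i) {
    p <- plans[[i]]
    data.frame(cell_id = sprintf("cell_%04d", i),
               z_separation = p$zsep,
               d_1 = p$d_true[1L], d_2 = p$d_true[2L],
               angle_1 = p$angle_true[1L], angle_2 = p$angle_true[2L],
               planted_alpha_1 = p$planted_alpha[1L],
               planted_alpha_2 = p$planted_alpha[2L],
               category = p$category, detached_count = p$detached_count,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate voxelized mitotic cells with ground truth
#'
#' @param params A [cell_sim_params()].
#' @param out_dir If non-`NULL`, each cell is written as a TIFF set under
#'   `out_dir/cell_NNNN/` (see [write_voxel_image()]) together with
#'   `truth.tsv` and the matched `geometry.yaml`; images are not kept in
#'   memory. With `out_dir = NULL` the rendered images are returned
#'   (memory scales with `n_cells`; ~9 MB per cell at the default grid).
#' @return An object of class `cell_simulation`: list with `truth`
#'   (exact pre-noise per-cell table: per-centrosome back-edge distances
#'   `d_1/d_2`, axis angles `angle_1/angle_2`, planted angles where
#'   applicable, truth `category`), `images` (named list or `NULL`),
#'   `dirs` (or `NULL`), `geometry` (matched [geometry_params()]),
#'   `params`.
#' @export
simulate_cells <- function(params = cell_sim_params(), out_dir = NULL) {
  stopifnot(inherits(params, "cell_sim_params"))
  set.seed(params$seed)
  vs <- params$voxel_size
  xs <- (seq_len(params$grid[1L]) - 0.5) * vs[1L]
  ys <- (seq_len(params$grid[2L]) - 0.5) * vs[2L]
  zs <- (seq_len(params$grid[3L]) - 0.5) * vs[3L]
  plans <- plan_cells(params)
  check_inside(plans, params)
  truth <- sim_truth_table(plans)
  geometry <- sim_geometry_params(params)
  images <- NULL; dirs <- NULL
  if (is.null(out_dir)) {
    images <- lapply(plans, function(p) render_cell(params, p, xs, ys, zs))
    names(images) <- truth$cell_id
  } else {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    dirs <- file.path(out_dir, truth$cell_id)
    for (i in seq_along(plans))
      write_voxel_image(render_cell(params, plans[[i]], xs, ys, zs), dirs[i])
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(geometry), file.path(out_dir, "geometry.yaml"))
  }
  structure(list(truth = truth, images = images, dirs = dirs,
                 geometry = geometry, params = params),
            class = "cell_simulation")
}

check_inside <- function(plans, params) {
  extent <- params$grid * params$voxel_size
  margin <- 4 * max(params$pole_sigma, params$centrosome_sigma)
  for (i in seq_along(plans)) {
    pts <- rbind(plans[[i]]$P, plans[[i]]$B, plans[[i]]$C)
    if (any(sweep(pts, 2L, extent - margin, ">")) || any(pts < margin))
      stop("planted objects fall outside the grid for cell ", i,
           "; enlarge `grid` or reduce placement parameters")
  }
}

#' Render and quantify simulated cells one at a time
#'
#' Streams through the simulation without holding all images in memory:
#' each cell is rendered, quantified with [quantify_cell()], and
#' discarded. Output is identical to rendering everything first (the
#' random-number stream is consumed in the same order).
#'
#' @param params A [cell_sim_params()].
#' @param geometry A [geometry_params()]; default
#'   [sim_geometry_params()]`(params)`.
#' @return List with `measurements` (per-cell table from
#'   [quantify_cells()]), `truth`, `geometry`, `params`.
#' @export
simulate_quantify_cells <- function(params = cell_sim_params(),
                                    geometry = sim_geometry_params(params)) {
  stopifnot(inherits(params, "cell_sim_params"))
  set.seed(params$seed)
  vs <- params$voxel_size
  xs <- (seq_len(params$grid[1L]) - 0.5) * vs[1L]
  ys <- (seq_len(params$grid[2L]) - 0.5) * vs[2L]
  zs <- (seq_len(params$grid[3L]) - 0.5) * vs[3L]
  plans <- plan_cells(params)
  check_inside(plans, params)
  truth <- sim_truth_table(plans)
  rows <- lapply(seq_along(plans), function(i)
    quantify_cell(render_cell(params, plans[[i]], xs, ys, zs),
                  geometry, cell_id = truth$cell_id[i]))
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  list(measurements = measurements, truth = truth,
       geometry = geometry, params = params)
}
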