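test_that("spindle axis acceptance window on pole z-separation is inclusive", {
  s <- fit_spindle_axis(c(0, 0, 0), c(8, 0, 2.1))
  expect_false(s$accepted)                       # 2.1 um > 1.8 um window
  expect_true(fit_spindle_axis(c(0, 0, 0), c(8, 0, 1.8))$accepted)
  expect_equal(fit_spindle_axis(c(0, 0, 0), c(8, 0, 0))$axis_direction,
               c(1, 0, 0))
  expect_error(fit_spindle_axis(c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("back edges are the extreme axial projections of the spindle object", {
  # axis-aligned slab of voxels from x-index 1..101 at dx = 0.1
  arr <- block_image(dim = c(110L, 8L, 4L), blocks = list(
    list(x = c(1, 101), y = c(3, 5), z = c(2, 3), value = 90)))
  obj <- threshold_segment(voxel_image(list(ch = arr)), "ch", 50)[[1L]]
  edges <- pole_back_edges(obj, axis = c(1, 0, 0))
  expect_equal(edges[1L, 1L], 0.05)   # centre of voxel 1
  expect_equal(edges[2L, 1L], 10.05)  # centre of voxel 101

  # single-voxel object: both edges coincide at the voxel centre
  arr2 <- array(0, c(6, 6, 4)); arr2[3, 3, 2] <- 99
  obj2 <- threshold_segment(voxel_image(list(ch = arr2)), "ch", 50)[[1L]]
  e2 <- pole_back_edges(obj2, axis = c(1, 0, 0))
  expect_equal(e2[1L, ], e2[2L, ])
  expect_equal(e2[1L, ], c(0.25, 0.25, 0.45))
})

test_that("centrosome angles use the xy projection with vertex at the nearer pole", {
  sp <- fit_spindle_axis(c(0, 0, 0), c(8, 0, 0))
  # on the axis beyond the pole -> 0 degrees
  expect_equal(centrosome_angle(c(-2, 0, 0), sp)$angle_deg, 0)
  # perpendicular at the pole -> 90
  expect_equal(centrosome_angle(c(0, 1.5, 0), sp)$angle_deg, 90)
  # coincident with the vertex -> 0, flagged
  a <- centrosome_angle(c(0, 0, 0), sp)
  expect_true(a$flagged); expect_equal(a$angle_deg, 0)
  # z-offset is discarded (projection)
  expect_equal(centrosome_angle(c(-2, 0, 1.2), sp)$angle_deg, 0)
  # assignment to the nearer pole, outward direction away from the other
  a2 <- centrosome_angle(c(9, 1, 0), sp)
  expect_equal(a2$assigned_pole, 2L)
  expect_equal(a2$angle_deg, atan2(1, 1) * 180 / pi)
  expect_error(centrosome_angle(c(0, 1, 0),
                                fit_spindle_axis(c(0, 0, 0), c(8, 0, 3))),
               "not accepted")
})

test_that("planted analytic construction at 25 degrees is recovered to 1e-6", {
  sp <- fit_spindle_axis(c(2, 3, 1), c(9, 4, 1.5))
  out <- (sp$pole_centroids[1L, 1:2] - sp$pole_centroids[2L, 1:2])
  out <- out / sqrt(sum(out^2))
  perp <- c(-out[2L], out[1L])
  theta <- 25 * pi / 180
  C <- c(sp$pole_centroids[1L, 1:2] +
           2.2 * (cos(theta) * out + sin(theta) * perp), 1)
  a <- centrosome_angle(C, sp)
  expect_equal(a$angle_deg, 25, tolerance = 1e-6)
  expect_equal(a$angle_bin, "15-30")
  expect_equal(angle_bin(c(4, 15, 15.01, 30, 30.01)),
               c("<=15", "<=15", "15-30", "15-30", ">30"))
})

test_that("pole distances are 3D Euclidean to the nearer back edge", {
  B <- rbind(c(0, 0, 0), c(8, 0, 0))
  expect_equal(centrosome_pole_distance(c(0, 0, 0), B)$distance_um, 0)
  d <- centrosome_pole_distance(c(0.3, 0.4, 0), B)
  expect_equal(d$distance_um, 0.5)     # 3-4-5 triangle
  expect_equal(d$assigned_pole, 1L)
  expect_equal(centrosome_pole_distance(c(7, 1, 2), B)$assigned_pole, 2L)
})

test_that("coordinate-level angles and distances are rigid-transform invariant", {
  set.seed(9)
  for (i in 1:25) {
    P1 <- runif(3, 0, 5); P2 <- P1 + c(8, runif(2, -1, 1))
    C <- P1 + runif(3, -3, 3)
    B <- rbind(P1 - 0.6 * (P2 - P1) / sqrt(sum((P2 - P1)^2)),
               P2 + 0.6 * (P2 - P1) / sqrt(sum((P2 - P1)^2)))
    d0 <- centrosome_pole_distance(C, B)$distance_um
    # distances: arbitrary 3D rotation + translation
    Rm <- rotation_matrix(runif(3, -1, 1), runif(1, 0, 2 * pi))
    tr <- runif(3, -5, 5)
    mv <- function(p) as.numeric(Rm %*% p + tr)
    d1 <- centrosome_pole_distance(mv(C), rbind(mv(B[1, ]), mv(B[2, ])))$distance_um
    expect_equal(d1, d0, tolerance = 1e-9)
    # angles: rigid motions of the projection plane (rotation about z)
    sp0 <- fit_spindle_axis(P1, P2)
    a0 <- centrosome_angle(C, sp0)$angle_deg
    Rz <- rotation_matrix(c(0, 0, 1), runif(1, 0, 2 * pi))
    mvz <- function(p) as.numeric(Rz %*% p + c(tr[1:2], 0))
    a1 <- centrosome_angle(mvz(C), fit_spindle_axis(mvz(P1), mvz(P2)))$angle_deg
    expect_equal(a1, a0, tolerance = 1e-9)
  }
})

test_that("centrosome measurement averages the two largest marker objects", {
  marker <- block_image(dim = c(30L, 10L, 6L), blocks = list(
    list(x = c(2, 4), y = c(2, 4), z = c(2, 3), value = 200),
    list(x = c(20, 24), y = c(2, 6), z = c(2, 4), value = 200),
    list(x = c(28, 28), y = c(9, 9), z = c(5, 5), value = 200)))  # debris
  measure <- block_image(dim = c(30L, 10L, 6L), base = 7)
  measure[20:24, 2:6, 2:4] <- 20
  img <- voxel_image(list(gamma = marker, hset = measure))
  expect_warning(res <- measure_centrosomes(img, "gamma", "hset", tau = 100),
                 "two largest")
  expect_equal(nrow(res$measures), 2L)
  expect_equal(res$n_objects, 3L)
  # uniform measure over each object -> the two means, averaged
  expect_equal(res$measures$mean_intensity, c(7, 20))
  expect_equal(res$summary$mean_intensity, 13.5)
  expect_equal(res$summary$volume, mean(res$measures$volume))

  # single object is flagged
  img2 <- voxel_image(list(gamma = block_image(dim = c(30L, 10L, 6L),
    blocks = list(list(x = c(2, 4), y = c(2, 4), z = c(2, 3), value = 200))),
    hset = measure))
  res2 <- measure_centrosomes(img2, "gamma", "hset", tau = 100)
  expect_true(res2$flagged)
})

test_that("phenotype classification follows the stated precedence and is order-invariant", {
  expect_equal(classify_phenotype(3L, TRUE, c(9, 9, 9))$category, "multipolar")
  expect_equal(classify_phenotype(1L, FALSE)$category, "disorganized")
  expect_equal(classify_phenotype(2L, FALSE, c(0.1, 0.2))$category,
               "disorganized")    # axis rejected
  det <- classify_phenotype(2L, TRUE, c(0.2, 2.5), d_det = 1.0)
  expect_equal(det$category, "detached")
  expect_equal(det$detached_count, 1L)
  expect_equal(classify_phenotype(2L, TRUE, c(0.1, 0.2))$category, "normal")
  set.seed(3)
  for (i in 1:20) {
    d <- runif(2, 0, 3)
    expect_identical(classify_phenotype(2L, TRUE, d)$category,
                     classify_phenotype(2L, TRUE, rev(d))$category)
  }
})

test_that("quantify_cell produces a coherent per-cell row on a rendered cell", {
  cp <- cell_sim_params(n_cells = 1, noise_sd = 0, background = 0,
                        attach_jitter = 0, detached_fraction = 0, seed = 21)
  res <- simulate_quantify_cells(cp)
  row <- res$measurements
  expect_equal(row$n_poles, 2L)
  expect_true(row$accepted)
  expect_equal(row$category, "normal")
  # per-cell summary is the mean of the two per-centrosome values
  expect_equal(row$mean_intensity, mean(c(row$intensity_1, row$intensity_2)))
  expect_equal(row$mean_volume, mean(c(row$volume_1, row$volume_2)))
  expect_lt(abs(row$z_separation - res$truth$z_separation), 0.15)
})
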