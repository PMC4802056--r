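test_that("AP-MS simulation is seed-deterministic and class structure holds", {
  p <- apms_sim_params(n_true = 8, n_background = 6, n_tag_specific = 4,
                       dropout_q = 0.2, seed = 13)
  s1 <- simulate_apms(p); s2 <- simulate_apms(p)
  expect_identical(s1$experiment, s2$experiment)
  expect_identical(s1$truth, s2$truth)
  # true interactors never appear in control runs
  ctl_acc <- unlist(lapply(s1$experiment$control_runs,
                           function(r) r$records$accession))
  expect_false(any(grepl("^INT", ctl_acc)))
  # tag-specific proteins appear in every other-bait control, never in WT
  for (run in s1$experiment$control_runs) {
    tags <- grep("^TAG", run$records$accession, value = TRUE)
    if (run$role == "control_untagged") expect_length(tags, 0L)
    else expect_length(tags, 4L)
  }
  # background proteins appear in every control run
  for (run in s1$experiment$control_runs)
    expect_length(grep("^BGD", run$records$accession), 6L)
})

test_that("fixed-count simulation is recovered perfectly by the filter cascade", {
  sim <- simulate_apms(apms_sim_params(n_true = 20, lambda_true = 6,
                                       dropout_q = 0, fixed_count_mode = TRUE,
                                       seed = 5))
  ht <- call_hits(flag_control_contaminants(build_hit_matrix(sim$experiment),
                                            sim$experiment))
  truth <- setNames(sim$truth$class, sim$truth$accession)
  f3 <- ht$accession[ht$tier == "filtered3"]
  expect_setequal(f3, sim$truth$accession[sim$truth$class == "true_interactor"])
  # every contaminant class is excluded by construction
  expect_true(all(ht$tier[truth[ht$accession] != "true_interactor"] ==
                    "excluded_control"))
  # peptide vectors are exactly (6, 6, 6) for true interactors
  ints <- ht[ht$accession %in% f3, c("u_1", "u_2", "u_3")]
  expect_true(all(as.matrix(ints) == 6L))
})

test_that("closed-form top-tier recovery probability is correct", {
  expect_equal(filtered3_recovery_prob(0), 1)
  expect_equal(filtered3_recovery_prob(0.2), 0.8^3)
  expect_equal(filtered3_recovery_prob(1), 0)
  # a count below the peptide threshold can never reach the top tier
  expect_equal(filtered3_recovery_prob(0, count = 3), 0)
})

test_that("cell simulation is seed-deterministic including rendered voxels", {
  p <- cell_sim_params(n_cells = 2, grid = c(120L, 80L, 20L),
                       spindle_length = 6, detached_fraction = 0.5, seed = 99)
  s1 <- simulate_cells(p); s2 <- simulate_cells(p)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$images[[1]]$channels, s2$images[[1]]$channels)
  # streaming quantification consumes the same random stream
  q <- simulate_quantify_cells(p)
  expect_identical(q$truth, s1$truth)
})

test_that("rendered cells round-trip through TIFF directories and the pipeline reader", {
  p <- cell_sim_params(n_cells = 2, grid = c(120L, 80L, 20L),
                       spindle_length = 6, seed = 7)
  dir <- withr::local_tempdir()
  sim <- simulate_cells(p, out_dir = dir)
  expect_null(sim$images)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  img <- read_voxel_image(sim$dirs[1L])
  expect_setequal(names(img$channels),
                  c("alpha_tubulin", "gamma_tubulin", "hset"))
  row <- quantify_cell(img, sim$geometry, cell_id = "c1")
  expect_equal(row$n_poles, 2L)
})

test_that("attached construction yields normal cells with near-truth distances", {
  p <- cell_sim_params(n_cells = 4, detached_fraction = 0, attach_jitter = 0,
                       noise_sd = 0, background = 0, seed = 31)
  res <- simulate_quantify_cells(p)
  voxdiag <- sqrt(sum(p$voxel_size^2))
  expect_true(all(res$measurements$category == "normal"))
  expect_true(all(abs(res$measurements$d_1 - res$truth$d_1) <= voxdiag))
  expect_true(all(abs(res$measurements$d_2 - res$truth$d_2) <= voxdiag))
})

test_that("a planted 25-degree, 2-um centrosome is recovered from the rendering", {
  p <- cell_sim_params(n_cells = 1, noise_sd = 0, background = 0,
                       planted = data.frame(alpha = 25, offset = 2),
                       seed = 17)
  res <- simulate_quantify_cells(p)
  expect_equal(res$measurements$bin_1, "15-30")
  expect_lt(abs(res$measurements$angle_1 - 25), 2)
  expect_lt(abs(res$measurements$d_1 - res$truth$d_1),
            sqrt(sum(p$voxel_size^2)))
})

test_that("out-of-grid placement fails with the offending cell named", {
  p <- cell_sim_params(n_cells = 3, grid = c(60L, 40L, 16L),
                       spindle_length = 8, seed = 1)
  expect_error(simulate_cells(p), "cell 1")
})
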