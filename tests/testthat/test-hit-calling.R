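test_that("build_hit_matrix fills absent replicates with zero", {
  u <- rbind(c(3L, 2L, 0L), c(1L, 1L, 1L), c(0L, 0L, 4L))
  ht <- hit_table_from_matrix(u)
  expect_equal(unname(as.matrix(ht[, c("u_1", "u_2", "u_3")])), u)
  ht <- call_hits(ht)
  expect_equal(ht$n, c(2L, 3L, 1L))

  empty <- experiment_set(list(pulldown_run("B", "bait", 1L, data.frame(
    accession = character(), gene_symbol = character(),
    unique_peptides = integer(), mascot_score = numeric()))))
  expect_equal(nrow(build_hit_matrix(empty)), 0L)
})

test_that("a single control peptide excludes regardless of bait evidence", {
  u <- rbind(c(50L, 40L, 30L), c(5L, 4L, 4L))
  ht <- hit_table_from_matrix(u, control_hit = c(TRUE, FALSE))
  ht <- call_hits(ht)
  expect_equal(ht$tier, c("excluded_control", "filtered3"))

  # presence only in an other-bait TAP control line also excludes
  bait <- lapply(1:3, function(r) pulldown_run("BAIT", "bait", r, data.frame(
    accession = "A", gene_symbol = NA, unique_peptides = 10L,
    mascot_score = 300)))
  other <- pulldown_run("TAP-X", "control_other_bait", 1L, data.frame(
    accession = "A", gene_symbol = NA, unique_peptides = 1L,
    mascot_score = 15))
  es <- experiment_set(bait, list(other))
  ht <- call_hits(flag_control_contaminants(build_hit_matrix(es), es))
  expect_equal(ht$tier, "excluded_control")

  # no controls: warning, nothing excluded
  es2 <- experiment_set(bait)
  expect_warning(ht2 <- flag_control_contaminants(build_hit_matrix(es2),
                                                  list()),
                 "no control")
  expect_false(any(ht2$control_hit))
})

test_that("tier assignment follows the replicate-presence and peptide thresholds", {
  u <- rbind(c(5L, 4L, 1L),   # n=3, m=2 -> filtered3
             c(6L, 5L, 0L),   # n=2, m=2 -> filtered2 only
             c(3L, 3L, 3L),   # m=0 at threshold 4 -> below
             c(4L, 0L, 0L))   # n=1 -> below
  ht <- call_hits(hit_table_from_matrix(u))
  expect_equal(tiers_by_index(ht, 4),
               c("filtered3", "filtered2", "below_threshold",
                 "below_threshold"))
})

test_that("tiering matches the independently coded filter transcription exhaustively", {
  grid <- as.matrix(expand.grid(u1 = 0:5, u2 = 0:5, u3 = 0:5))
  for (ctl in c(FALSE, TRUE)) {
    present <- rowSums(grid) > 0   # proteins absent everywhere have no row
    ht <- call_hits(hit_table_from_matrix(grid[present, , drop = FALSE],
                                          control_hit = rep(ctl, sum(present))))
    got <- tiers_by_index(ht, sum(present))
    want <- apply(grid[present, , drop = FALSE], 1L, tier_oracle,
                  control_hit = ctl)
    expect_identical(got, unname(want))
  }
})

test_that("tiering is monotone in the thresholds, nested, and control-dominated", {
  set.seed(101)
  count_sets <- function(ht) {
    c(f2 = sum(ht$tier %in% c("filtered2", "filtered3")),
      f3 = sum(ht$tier == "filtered3"),
      excl = sum(ht$tier == "excluded_control"))
  }
  for (i in 1:60) {
    u <- matrix(rpois(3 * 30, sample(1:5, 1)), ncol = 3)
    ctl <- runif(30) < 0.3
    ht0 <- hit_table_from_matrix(u, control_hit = ctl)
    base <- call_hits(ht0)
    b <- count_sets(base)
    # nesting and control dominance
    expect_true(all(base$tier[base$control_hit] == "excluded_control"))
    expect_lte(b["f3"], b["f2"])
    # raising each threshold never grows the filtered sets
    for (arg in c("min_presence", "peptide_threshold",
                  "peptide_threshold_replicates")) {
      args <- list(); args[[arg]] <- formals(filter_params)[[arg]] + 1L
      stricter <- call_hits(ht0, do.call(filter_params, args))
      expect_lte(count_sets(stricter)["f2"], b[["f2"]])
      expect_lte(count_sets(stricter)["f3"], b[["f3"]])
    }
    # row-order invariance
    perm <- sample(nrow(u))
    ht_perm <- call_hits(hit_table_from_matrix(u[perm, , drop = FALSE],
                                               control_hit = ctl[perm]))
    expect_equal(tiers_by_index(ht_perm, 30),
                 tiers_by_index(base, 30)[perm])
  }
})

test_that("localization shortlist removes only fully excluded categories", {
  u <- rbind(c(5L, 5L, 5L), c(5L, 5L, 5L), c(5L, 5L, 5L), c(5L, 5L, 5L))
  ht <- call_hits(hit_table_from_matrix(u))
  ann <- data.frame(accession = c("P0001", "P0002", "P0003"),
                    category = c("nucleus", "centrosome",
                                 "nucleus; spliceosome"))
  excl <- c("nucleus", "spliceosome", "membrane")
  out <- apply_localization_shortlist(ht, ann, excl)
  expect_setequal(out$accession, c("P0002", "P0004"))  # P0004 unannotated
  expect_equal(out$category[out$accession == "P0004"], "unknown")

  mixed <- data.frame(accession = "P0001", category = "nucleus; centrosome")
  out2 <- apply_localization_shortlist(ht, mixed, excl)
  expect_true("P0001" %in% out2$accession)   # not *limited to* excluded

  # empty excluded set is the identity on rows
  out3 <- apply_localization_shortlist(ht, ann, character())
  expect_equal(out3$accession, ht$accession)
})

test_that("hit tables round-trip through TSV with provenance comments", {
  ht <- call_hits(hit_table_from_matrix(rbind(c(5L, 4L, 1L), c(1L, 0L, 0L))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(ht, path, header = c("test v0", "seed 1"))
  back <- read_hit_table(path)
  expect_equal(back$tier, ht$tier)
  expect_equal(back$u_1, ht$u_1)
  expect_equal(attr(back, "R"), 3L)
})
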