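test_that("evidence tables are read with row-count preserved and validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tgene_symbol\tunique_peptides\tmascot_score",
               "A\tgA\t5\t100.5", "B\tgB\t4\t80", "C\t\t1\t12.25"), path)
  run <- read_evidence_table(path, "BAIT", "bait", 1L)
  expect_s3_class(run, "pulldown_run")
  expect_equal(nrow(run$records), 3L)
  expect_equal(run$records$unique_peptides, c(5L, 4L, 1L))
  expect_equal(run$records$mascot_score, c(100.5, 80, 12.25))

  # empty table with a valid header
  writeLines("accession\tgene_symbol\tunique_peptides\tmascot_score", path)
  expect_equal(nrow(read_evidence_table(path, "BAIT", "bait", 1L)$records), 0L)

  # negative peptide count is rejected with the row number
  writeLines(c("accession\tgene_symbol\tunique_peptides\tmascot_score",
               "A\tgA\t5\t100", "B\tgB\t-2\t80"), path)
  expect_error(read_evidence_table(path, "BAIT", "bait", 1L), "row 2")

  # missing required column is named
  writeLines(c("accession\tgene_symbol\tmascot_score", "A\tgA\t100"), path)
  expect_error(read_evidence_table(path, "BAIT", "bait", 1L),
               "unique_peptides")

  # dialect remapping and comma separation
  writeLines(c("Accession,Gene,# Unique Peptides,Score",
               "A,gA,5,100.5"), path)
  run <- read_evidence_table(path, "BAIT", "bait", 1L,
                             dialect = c(accession = "Accession",
                                         gene_symbol = "Gene",
                                         unique_peptides = "# Unique Peptides",
                                         mascot_score = "Score"))
  expect_equal(run$records$unique_peptides, 5L)
})

test_that("collapse_redundancy takes per-field maxima and is idempotent and order-independent", {
  rec <- data.frame(accession = c("A", "B", "A"),
                    gene_symbol = c(NA, "gB", "gA"),
                    unique_peptides = c(3L, 2L, 5L),
                    mascot_score = c(40, 25, 35))
  run <- pulldown_run("BAIT", "bait", 1L, rec)
  col <- collapse_redundancy(run)
  a <- col$records[col$records$accession == "A", ]
  expect_equal(a$unique_peptides, 5L)   # max of 3, 5
  expect_equal(a$mascot_score, 40)      # max of 40, 35
  expect_equal(a$gene_symbol, "gA")
  expect_identical(collapse_redundancy(col)$records, col$records)

  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:15, 1)
    rec <- data.frame(accession = sample(LETTERS[1:5], n, replace = TRUE),
                      gene_symbol = NA_character_,
                      unique_peptides = sample(0:9, n, replace = TRUE),
                      mascot_score = round(runif(n, 0, 100), 2))
    base <- collapse_redundancy(pulldown_run("B1", "bait", 1L, rec))
    perm <- collapse_redundancy(pulldown_run("B1", "bait", 1L,
                                             rec[sample(n), , drop = FALSE]))
    expect_identical(base$records, perm$records)
  }
})

test_that("write/read round trip is the identity, including unicode symbols", {
  rec <- data.frame(accession = c("Q8N4L1", "P35611"),
                    gene_symbol = c("CDK5RAP2", "α-adducin"),
                    unique_peptides = c(7L, 0L),
                    mascot_score = c(250.125, 0))
  run <- pulldown_run("BAIT", "bait", 2L, rec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_evidence_table(run, path)
  back <- read_evidence_table(path, "BAIT", "bait", 2L)
  expect_identical(back$records, run$records)

  # empty run -> header-only file that reads back empty
  empty <- pulldown_run("BAIT", "bait", 1L, rec[0, ])
  write_evidence_table(empty, path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_evidence_table(path, "BAIT", "bait", 1L)$records), 0L)
})

test_that("experiment_set enforces replicate and control-line invariants", {
  mk <- function(line, role, rep) pulldown_run(line, role, rep, data.frame(
    accession = "A", gene_symbol = NA, unique_peptides = 1L,
    mascot_score = 10))
  b <- lapply(1:3, function(r) mk("BAIT", "bait", r))
  expect_s3_class(experiment_set(b, list(mk("WT", "control_untagged", 1))),
                  "experiment_set")
  expect_error(experiment_set(b[c(1, 2, 2)]), "1..R")
  expect_error(experiment_set(b, list(mk("BAIT", "control_untagged", 1))),
               "disjoint")
  expect_error(experiment_set(list(b[[1]], b[[1]])), "1..R")
})

test_that("manifest read reconstructs a simulated experiment", {
  sim <- simulate_apms(apms_sim_params(n_true = 5, n_background = 4,
                                       n_tag_specific = 2, seed = 42))
  dir <- withr::local_tempdir()
  write_apms_simulation(sim, dir)
  es <- read_experiment_manifest(file.path(dir, "manifest.yaml"))
  expect_equal(es$R, 3L)
  expect_equal(length(es$control_runs), 3L)
  ht1 <- call_hits(flag_control_contaminants(build_hit_matrix(sim$experiment),
                                             sim$experiment))
  ht2 <- call_hits(flag_control_contaminants(build_hit_matrix(es), es))
  expect_equal(ht1$tier, ht2$tier)
  expect_equal(ht1$accession, ht2$accession)
})
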