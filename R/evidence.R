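#' Construct a single pulldown run
#'
#' A pulldown run holds the per-protein identification evidence (unique
#' peptide counts and Mascot scores) from one affinity-purification
#' experiment: either a bait pulldown replicate or a control pulldown
#' (untagged wild-type line, or a different TAP-tagged bait line used to
#' subtract tag-specific binders).
#'
#' @param line_id Cell-line identifier, e.g. `"CEP215-TAP"` or `"WT"`.
#' @param role One of `"bait"`, `"control_untagged"`, `"control_other_bait"`.
#' @param replicate_index Positive integer replicate number within the line.
#' @param records A data.frame with columns `accession`, `gene_symbol`,
#'   `unique_peptides` (non-negative integer), `mascot_score` (non-negative
#'   numeric). `gene_symbol` may be `NA`.
#' @return An object of class `pulldown_run`.
#' @export
pulldown_run <- function(line_id, role, replicate_index, records) {
  role <- match.arg(role, c("bait", "control_untagged", "control_other_bait"))
  stopifnot(is.character(line_id), length(line_id) == 1L, nzchar(line_id))
  replicate_index <- as.integer(replicate_index)
  stopifnot(length(replicate_index) == 1L, !is.na(replicate_index),
            replicate_index >= 1L)
  records <- validate_evidence(records)
  structure(
    list(line_id = line_id, role = role,
         replicate_index = replicate_index, records = records),
    class = "pulldown_run")
}

#' @export
print.pulldown_run <- function(x, ...) {
  cat(sprintf("<pulldown_run> line=%s role=%s replicate=%d proteins=%d\n",
              x$line_id, x$role, x$replicate_index, nrow(x$records)))
  invisible(x)
}

validate_evidence <- function(records) {
  if (!is.data.frame(records))
    stop("evidence records must be a data.frame", call. = FALSE)
  need <- c("accession", "unique_peptides", "mascot_score")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("evidence table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"gene_symbol" %in% names(records)) records$gene_symbol <- NA_character_
  records <- records[, c("accession", "gene_symbol",
                         "unique_peptides", "mascot_score")]
  records$accession <- as.character(records$accession)
  records$gene_symbol <- as.character(records$gene_symbol)
  bad <- which(is.na(records$accession) | !nzchar(records$accession))
  if (length(bad))
    stop("empty accession at row ", bad[1L], call. = FALSE)
  u <- suppressWarnings(as.numeric(records$unique_peptides))
  bad <- which(is.na(u) | u < 0 | u != floor(u))
  if (length(bad))
    stop("unique_peptides must be a non-negative integer; violated at row ",
         bad[1L], " (value '", records$unique_peptides[bad[1L]], "')",
         call. = FALSE)
  records$unique_peptides <- as.integer(u)
  s <- suppressWarnings(as.numeric(records$mascot_score))
  bad <- which(is.na(s) | s < 0)
  if (length(bad))
    stop("mascot_score must be a non-negative number; violated at row ",
         bad[1L], call. = FALSE)
  records$mascot_score <- s
  rownames(records) <- NULL
  records
}

#' Read a protein evidence table from disk
#'
#' Evidence tables are plain tab- or comma-separated text with a header row.
#' Column names are resolved through `dialect`, so exports with different
#' headers (e.g. `"Accession"`, `"# Unique Peptides"`) can be ingested
#' without editing the file.
#'
#' @param path Path to the table.
#' @param line_id,role,replicate_index Run metadata (see [pulldown_run()]).
#' @param dialect Named character vector mapping the canonical names
#'   `accession`, `gene_symbol`, `unique_peptides`, `mascot_score` to the
#'   column names used in the file.
#' @param sep Field separator; `NULL` (default) autodetects tab vs comma
#'   from the header line.
#' @return A [pulldown_run()].
#' @export
read_evidence_table <- function(path, line_id, role, replicate_index,
                                dialect = NULL, sep = NULL) {
  canonical <- c(accession = "accession", gene_symbol = "gene_symbol",
                 unique_peptides = "unique_peptides",
                 mascot_score = "mascot_score")
  if (!is.null(dialect)) canonical[names(dialect)] <- dialect
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  for (canon in c("accession", "unique_peptides", "mascot_score")) {
    if (!canonical[[canon]] %in% names(tab))
      stop("column '", canonical[[canon]], "' (", canon, ") not found in ",
           path, call. = FALSE)
  }
  records <- data.frame(
    accession = tab[[canonical[["accession"]]]],
    gene_symbol = if (canonical[["gene_symbol"]] %in% names(tab))
      tab[[canonical[["gene_symbol"]]]] else NA_character_,
    unique_peptides = tab[[canonical[["unique_peptides"]]]],
    mascot_score = tab[[canonical[["mascot_score"]]]],
    stringsAsFactors = FALSE)
  pulldown_run(line_id, role, replicate_index, records)
}

#' Write a protein evidence table
#'
#' Writes the run's records as UTF-8 tab-separated text with canonical
#' column names. `read_evidence_table(write_evidence_table(run))` is the
#' identity on valid runs.
#'
#' @param run A [pulldown_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(run, path) {
  stopifnot(inherits(run, "pulldown_run"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(run$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Collapse an evidence table to one record per accession
#'
#' Produces a non-redundant protein list. Duplicated accessions are merged
#' by taking, per field, the maximum evidence over the duplicates (peptide
#' count and Mascot score); summing is deliberately avoided as it would
#' double-count shared peptide evidence. The output is sorted by accession,
#' making the operation idempotent and independent of input row order.
#'
#' @param run A [pulldown_run()].
#' @return A [pulldown_run()] with at most one record per accession.
#' @export
collapse_redundancy <- function(run) {
  stopifnot(inherits(run, "pulldown_run"))
  rec <- run$records
  if (nrow(rec) == 0L) return(run)
  first_symbol <- function(g) {
    g <- g[!is.na(g) & nzchar(g)]
    if (length(g)) g[1L] else NA_character_
  }
  sp <- split(seq_len(nrow(rec)), rec$accession)   # split() sorts keys
  out <- data.frame(
    accession = names(sp),
    gene_symbol = vapply(sp, function(i) first_symbol(rec$gene_symbol[i]), ""),
    unique_peptides = vapply(sp, function(i)
      max(rec$unique_peptides[i]), integer(1L)),
    mascot_score = vapply(sp, function(i)
      max(rec$mascot_score[i]), numeric(1L)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  run$records <- out
  run
}

#' Assemble bait and control runs into an experiment set
#'
#' @param bait_runs List of [pulldown_run()] with role `"bait"` from a single
#'   bait line; replicate indices must form `1..R`.
#' @param control_runs List of [pulldown_run()] with control roles. Control
#'   line ids must be disjoint from the bait line.
#' @param manifest Optional named list of provenance metadata.
#' @return An object of class `experiment_set` with element `R`, the number
#'   of bait replicates.
#' @export
experiment_set <- function(bait_runs, control_runs = list(), manifest = list()) {
  stopifnot(is.list(bait_runs), length(bait_runs) >= 1L)
  lapply(bait_runs, function(r) stopifnot(inherits(r, "pulldown_run")))
  lapply(control_runs, function(r) stopifnot(inherits(r, "pulldown_run")))
  roles <- vapply(bait_runs, `[[`, "", "role")
  if (!all(roles == "bait")) stop("bait_runs must all have role 'bait'")
  bait_line <- unique(vapply(bait_runs, `[[`, "", "line_id"))
  if (length(bait_line) != 1L) stop("bait runs must come from a single line")
  idx <- sort(vapply(bait_runs, `[[`, integer(1L), "replicate_index"))
  R <- length(bait_runs)
  if (!identical(idx, seq_len(R)))
    stop("bait replicate indices must form 1..R; got ",
         paste(idx, collapse = ","))
  ctl_roles <- vapply(control_runs, `[[`, "", "role")
  if (any(ctl_roles == "bait")) stop("control_runs may not contain bait runs")
  ctl_lines <- vapply(control_runs, `[[`, "", "line_id")
  if (bait_line %in% ctl_lines)
    stop("control lines must be disjoint from the bait line")
  key <- c(paste0(bait_line, "#", idx),
           paste0(ctl_lines, "#",
                  vapply(control_runs, `[[`, integer(1L), "replicate_index")))
  if (anyDuplicated(key))
    stop("duplicate (line_id, replicate_index) pair: ", key[duplicated(key)][1L])
  ord <- order(vapply(bait_runs, `[[`, integer(1L), "replicate_index"))
  structure(list(bait_runs = bait_runs[ord], control_runs = control_runs,
                 R = R, bait_line = bait_line, manifest = manifest),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf("<experiment_set> bait=%s replicates=%d control_runs=%d\n",
              x$bait_line, x$R, length(x$control_runs)))
  invisible(x)
}

#' Read an experiment manifest and its evidence tables
#'
#' The manifest is a YAML file with a top-level `runs:` list; each entry
#' has `line_id`, `role`, `replicate_index` and `path` (relative paths are
#' resolved against the manifest's directory). All runs are read, collapsed
#' to non-redundant form, and assembled into an [experiment_set()].
#'
#' @param path Path to the manifest YAML.
#' @param collapse Collapse each run with [collapse_redundancy()]
#'   (default `TRUE`).
#' @return An [experiment_set()].
#' @export
read_experiment_manifest <- function(path, collapse = TRUE) {
  man <- yaml::read_yaml(path)
  if (is.null(man$runs) || !length(man$runs))
    stop("manifest has no runs", call. = FALSE)
  base <- dirname(normalizePath(path))
  runs <- lapply(man$runs, function(entry) {
    for (f in c("line_id", "role", "replicate_index", "path"))
      if (is.null(entry[[f]]))
        stop("manifest run entry missing field '", f, "'", call. = FALSE)
    p <- entry$path
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    run <- read_evidence_table(p, entry$line_id, entry$role,
                               entry$replicate_index)
    if (collapse) run <- collapse_redundancy(run) else run
  })
  roles <- vapply(runs, `[[`, "", "role")
  experiment_set(bait_runs = runs[roles == "bait"],
                 control_runs = runs[roles != "bait"],
                 manifest = man[setdiff(names(man), "runs")])
}
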