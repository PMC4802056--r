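#' Filtering thresholds for AP-MS hit calling
#'
#' The cascade mirrors the worksheet workflow used to build tiered
#' interactor lists from TAP pulldown evidence:
#' presence in at least `min_presence` bait replicates, at least
#' `peptide_threshold` unique peptides in at least
#' `peptide_threshold_replicates` replicates ("Filtered_2"), and presence in
#' all `all_replicates` replicates ("Filtered_3"). A protein seen with
#' `control_exclusion_min` or more unique peptides in any single control
#' replicate is excluded outright, whatever its bait evidence.
#'
#' @param min_presence Minimum bait replicates with >= 1 peptide (default 2).
#' @param peptide_threshold Unique-peptide threshold per replicate
#'   (default 4).
#' @param peptide_threshold_replicates Replicates that must meet
#'   `peptide_threshold` (default 2).
#' @param all_replicates Replicates required for the top tier (default 3).
#' @param control_exclusion_min Peptides in a single control replicate that
#'   trigger exclusion (default 1: "even a single unique peptide").
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_presence = 2L, peptide_threshold = 4L,
                          peptide_threshold_replicates = 2L,
                          all_replicates = 3L, control_exclusion_min = 1L) {
  p <- list(min_presence = as.integer(min_presence),
            peptide_threshold = as.integer(peptide_threshold),
            peptide_threshold_replicates = as.integer(peptide_threshold_replicates),
            all_replicates = as.integer(all_replicates),
            control_exclusion_min = as.integer(control_exclusion_min))
  if (any(vapply(p, function(x) is.na(x) || x < 0L, logical(1L))))
    stop("all thresholds must be non-negative integers")
  if (p$min_presence > p$all_replicates)
    stop("min_presence must not exceed all_replicates")
  structure(p, class = "filter_params")
}

hit_tiers <- c("excluded_control", "below_threshold", "filtered2", "filtered3")

#' Build the per-accession peptide/score matrix over bait replicates
#'
#' Every accession seen in at least one bait replicate gets a row; entries
#' for replicates where it was not detected are 0. Rows are sorted by
#' accession so the result is independent of file and row order.
#'
#' @param experiment An [experiment_set()]; bait runs should be collapsed to
#'   non-redundant form (they are collapsed defensively here, which is a
#'   no-op on already-collapsed runs).
#' @return A data.frame of class `hit_table` with columns `accession`,
#'   `gene_symbol`, `u_1..u_R`, `s_1..s_R`, `best_mascot`, `control_hit`
#'   (NA until [flag_control_contaminants()]), `tier` (NA until
#'   [call_hits()]); attribute `R` holds the replicate count.
#' @export
build_hit_matrix <- function(experiment) {
  stopifnot(inherits(experiment, "experiment_set"))
  R <- experiment$R
  runs <- lapply(experiment$bait_runs, collapse_redundancy)
  acc <- sort(unique(unlist(lapply(runs, function(r) r$records$accession))))
  u <- matrix(0L, nrow = length(acc), ncol = R,
              dimnames = list(acc, paste0("u_", seq_len(R))))
  s <- matrix(0, nrow = length(acc), ncol = R,
              dimnames = list(acc, paste0("s_", seq_len(R))))
  sym <- setNames(rep(NA_character_, length(acc)), acc)
  for (run in runs) {
    r <- run$replicate_index
    rec <- run$records
    u[rec$accession, r] <- rec$unique_peptides
    s[rec$accession, r] <- rec$mascot_score
    fill <- is.na(sym[rec$accession]) & !is.na(rec$gene_symbol)
    sym[rec$accession[fill]] <- rec$gene_symbol[fill]
  }
  if (length(acc) == 0L) {
    out <- data.frame(accession = character(), gene_symbol = character(),
                      stringsAsFactors = FALSE)
    for (j in seq_len(R)) out[[paste0("u_", j)]] <- integer()
    for (j in seq_len(R)) out[[paste0("s_", j)]] <- numeric()
    out$best_mascot <- numeric(); out$control_hit <- logical()
    out$tier <- character()
  } else {
    out <- data.frame(accession = acc, gene_symbol = unname(sym),
                      u, s, best_mascot = apply(s, 1L, max),
                      control_hit = NA, tier = NA_character_,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out, R = R, class = c("hit_table", "data.frame"))
}

peptide_matrix <- function(table) {
  R <- attr(table, "R")
  as.matrix(table[, paste0("u_", seq_len(R)), drop = FALSE])
}

#' Flag proteins observed in control pulldowns
#'
#' Marks `control_hit = TRUE` for any accession detected with at least
#' `theta_ctrl` unique peptides in any single replicate of any control line
#' (untagged wild-type, or another TAP-tagged bait). Flagged rows are
#' assigned tier `"excluded_control"` immediately; exclusion is
#' unconditional on the strength of the bait evidence.
#'
#' @param table A `hit_table` from [build_hit_matrix()].
#' @param controls List of control [pulldown_run()]s (any control role), or
#'   an [experiment_set()] whose `control_runs` are used.
#' @param theta_ctrl Peptide count in one control replicate sufficient for
#'   exclusion (default 1).
#' @return The table with `control_hit` filled and excluded tiers set.
#' @export
flag_control_contaminants <- function(table, controls, theta_ctrl = 1L) {
  stopifnot(inherits(table, "hit_table"))
  if (inherits(controls, "experiment_set")) controls <- controls$control_runs
  if (!length(controls)) {
    warning("no control runs supplied; no contaminant exclusions applied")
    table$control_hit <- FALSE
    return(table)
  }
  lapply(controls, function(r) {
    stopifnot(inherits(r, "pulldown_run"))
    if (r$role == "bait") stop("bait run supplied as control")
  })
  seen <- unique(unlist(lapply(controls, function(r)
    r$records$accession[r$records$unique_peptides >= theta_ctrl])))
  table$control_hit <- table$accession %in% seen
  table$tier[table$control_hit] <- "excluded_control"
  table$tier[!table$control_hit & table$tier %in% "excluded_control"] <-
    NA_character_
  table
}

#' Assign filtering tiers to bait-detected proteins
#'
#' A pure function of the peptide matrix, the control flags and the
#' thresholds. With per-replicate counts `u_r`, presence
#' `n = #\{r : u_r >= 1\}` and strong count
#' `m = #\{r : u_r >= peptide_threshold\}`:
#' control-flagged rows are `excluded_control`; otherwise
#' `below_threshold` when `n < min_presence` or
#' `m < peptide_threshold_replicates`; `filtered2` when both hold; and
#' `filtered3` when additionally `n >= all_replicates`. All comparisons are
#' inclusive ("at least", "four or more").
#'
#' @param table A `hit_table` with `control_hit` computed (rows with NA
#'   `control_hit` are treated as not control-flagged, with a warning).
#' @param params A [filter_params()].
#' @return The table with `tier`, `n`, `m` and `best_mascot` columns filled,
#'   sorted by accession.
#' @export
call_hits <- function(table, params = filter_params()) {
  stopifnot(inherits(table, "hit_table"), inherits(params, "filter_params"))
  u <- peptide_matrix(table)
  if (anyNA(table$control_hit)) {
    warning("control_hit not computed for some rows; treating as FALSE")
    table$control_hit[is.na(table$control_hit)] <- FALSE
  }
  n <- rowSums(u >= 1L)
  m <- rowSums(u >= params$peptide_threshold)
  tier <- rep("below_threshold", nrow(table))
  f2 <- n >= params$min_presence & m >= params$peptide_threshold_replicates
  tier[f2] <- "filtered2"
  tier[f2 & n >= params$all_replicates] <- "filtered3"
  tier[table$control_hit] <- "excluded_control"
  table$n <- as.integer(n)
  table$m <- as.integer(m)
  table$tier <- tier
  table[order(table$accession), , drop = FALSE]
}

#' Restrict a tiered hit table by subcellular localization
#'
#' Stands in for the GO-based shortlist step: rather than querying a live
#' annotation database (which would tie results to a database snapshot),
#' the caller supplies an annotation table. Rows whose localization is
#' limited to the excluded categories are removed; proteins without an
#' annotation are retained with category `"unknown"`, never silently
#' dropped. A protein annotated with several categories (separated by `;`
#' or `,`) is removed only if all of them are excluded.
#'
#' @param table A `hit_table`.
#' @param annotations Data.frame with columns `accession`, `category`, or a
#'   named character vector `accession -> category`. `NULL` means no
#'   annotations.
#' @param excluded_categories Character vector, e.g.
#'   `c("nucleus", "spliceosome", "membrane")`.
#' @return The filtered table with a `category` column appended.
#' @export
apply_localization_shortlist <- function(table, annotations = NULL,
                                         excluded_categories = character()) {
  stopifnot(inherits(table, "hit_table"))
  if (is.data.frame(annotations))
    annotations <- setNames(as.character(annotations$category),
                            annotations$accession)
  cat_of <- rep("unknown", nrow(table))
  if (length(annotations)) {
    hit <- table$accession %in% names(annotations)
    cat_of[hit] <- unname(annotations[table$accession[hit]])
  }
  table$category <- cat_of
  if (!length(excluded_categories)) return(table)
  drop <- vapply(cat_of, function(cc) {
    parts <- trimws(strsplit(cc, "[;,]")[[1L]])
    parts <- parts[nzchar(parts)]
    length(parts) > 0L && all(parts %in% excluded_categories) &&
      !identical(parts, "unknown")
  }, logical(1L))
  out <- table[!drop, , drop = FALSE]
  attr(out, "R") <- attr(table, "R")
  class(out) <- class(table)
  out
}

#' Write / read a tiered hit table
#'
#' Tab-separated with columns `accession, gene_symbol, u_1..u_R, s_1..s_R,
#' best_mascot, n, m, control_hit, tier[, category]`. Lines starting with
#' `#` (provenance headers) are ignored on read.
#'
#' @param table A `hit_table`.
#' @param path Output path.
#' @param header Optional character vector of `# `-prefixed header lines.
#' @return `path` invisibly (write); a `hit_table` (read).
#' @export
write_hit_table <- function(table, path, header = NULL) {
  stopifnot(inherits(table, "hit_table"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           quote = "\"", stringsAsFactors = FALSE,
                           check.names = FALSE, encoding = "UTF-8")
  R <- sum(grepl("^u_[0-9]+$", names(tab)))
  if (R == 0L) stop("not a hit table: no u_<r> columns found in ", path)
  tab$control_hit <- as.logical(tab$control_hit)
  structure(tab, R = R, class = c("hit_table", "data.frame"))
}
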