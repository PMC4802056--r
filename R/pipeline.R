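#' Read a pipeline configuration file
#'
#' YAML with known top-level blocks only (unknown keys are rejected so
#' typos fail loudly): `manifest`, `filter`, `annotations`,
#' `exclude_categories`, `known_pairs`, `bait`, `include_filtered2`,
#' `images`, `geometry`, `simulate_apms`, `simulate_cells`, `groups`,
#' `seed`, `out_dir`, `log_level`.
#'
#' @param path YAML path.
#' @return Named list (class `pipeline_config`) with a `config_path`
#'   element recording provenance.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("manifest", "filter", "annotations", "exclude_categories",
             "known_pairs", "bait", "include_filtered2", "images",
             "geometry", "simulate_apms", "simulate_cells", "groups",
             "seed", "out_dir", "log_level")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg$config_path <- normalizePath(path)
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(level, stage, msg, log_level = "info") {
  ranks <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (ranks[[level]] >= ranks[[log_level]])
    message(sprintf("[%s] %s: %s", toupper(level), stage, msg))
}

provenance_header <- function(config, seed = NULL) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(config, cfg_file)
  c(sprintf("spindlekit %s", as.character(utils::packageVersion("spindlekit"))),
    sprintf("config_md5 %s", unname(tools::md5sum(cfg_file))),
    sprintf("seed %s", if (is.null(seed)) "NA" else seed),
    sprintf("date %s", format(Sys.time(), "%Y-%m-%d")))
}

run_stage <- function(stage, log_level, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the AP-MS pipeline: evidence tables to tiered hits and network
#'
#' Stages, in order: read manifest -> collapse redundancy -> build
#' peptide/score matrix -> flag control contaminants -> assign tiers ->
#' localization shortlist -> build network. Intermediate and final tables
#' are written under `out_dir` with a provenance header (package version,
#' config hash, seed).
#'
#' @param config A `pipeline_config`, a path to one, or a named list with
#'   the same keys. Either `manifest` (path) or `simulate_apms`
#'   (parameter list for [apms_sim_params()]) must provide the evidence.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return List with `hits` (tiered `hit_table`), `shortlisted`, `graph`,
#'   `truth` (simulation only), and `paths` of the written artefacts.
#' @export
run_apms_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  log_level <- config$log_level %||% "info"
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(config$simulate_apms)) {
    sp <- do.call(apms_sim_params, config$simulate_apms)
    pipeline_log("info", "simulate",
                 sprintf("simulating AP-MS set (seed %d)", sp$seed), log_level)
    sim <- simulate_apms(sp)
    experiment <- sim$experiment
    truth <- sim$truth
    seed <- sp$seed
  } else if (!is.null(config$manifest)) {
    pipeline_log("info", "read", config$manifest, log_level)
    experiment <- run_stage("read", log_level,
                            read_experiment_manifest(config$manifest))
    seed <- config$seed
  } else stop("config must provide either 'manifest' or 'simulate_apms'")
  header <- provenance_header(unclass(config), seed)
  fp <- do.call(filter_params, config$filter %||% list())
  hits <- run_stage("matrix", log_level, build_hit_matrix(experiment))
  pipeline_log("info", "matrix",
               sprintf("%d proteins over %d replicates", nrow(hits),
                       attr(hits, "R")), log_level)
  hits <- run_stage("control_flag", log_level,
                    flag_control_contaminants(hits, experiment,
                                              fp$control_exclusion_min))
  hits <- run_stage("tier", log_level, call_hits(hits, fp))
  pipeline_log("info", "tier",
               paste(capture_counts(hits$tier), collapse = ", "), log_level)
  annotations <- load_annotations(config$annotations)
  shortlisted <- run_stage("shortlist", log_level,
    apply_localization_shortlist(hits, annotations,
                                 config$exclude_categories %||% character()))
  bait <- config$bait %||% experiment$bait_line
  known_pairs <- load_known_pairs(config$known_pairs)
  graph <- run_stage("network", log_level,
    build_network(shortlisted, bait, annotations, known_pairs,
                  include_filtered2 = isTRUE(config$include_filtered2)))
  paths <- list(hits = file.path(out_dir, "hit_table.tsv"),
                shortlisted = file.path(out_dir, "hit_table_shortlisted.tsv"),
                graphml = file.path(out_dir, "network.graphml"),
                edges = file.path(out_dir, "network_edges.tsv"))
  write_hit_table(hits, paths$hits, header = header)
  write_hit_table(shortlisted, paths$shortlisted, header = header)
  export_graph(graph, "graphml", paths$graphml)
  export_graph(graph, "edge_tsv", paths$edges)
  yaml::write_yaml(list(provenance = header,
                        tiers = as.list(table(hits$tier))),
                   file.path(out_dir, "run_manifest.yaml"))
  list(hits = hits, shortlisted = shortlisted, graph = graph,
       truth = truth, paths = paths)
}

capture_counts <- function(x) {
  tb <- table(x)
  sprintf("%s=%d", names(tb), as.integer(tb))
}

load_annotations <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(utils::read.table(x, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  x
}

load_known_pairs <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(as.matrix(utils::read.table(x, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)[, 1:2]))
  if (is.list(x) && !is.data.frame(x)) return(do.call(rbind, x))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the geometry pipeline: image stacks to phenotype statistics
#'
#' Quantifies each cell with [quantify_cell()] (unreadable images are
#' reported and skipped, not fatal), reports cells excluded by the pole
#' z-separation selection rule, tabulates phenotypes per group, and runs
#' the category-vs-rest Fisher tests plus Wilcoxon tests on the continuous
#' measures. With a single group, counts are emitted and tests skipped
#' with a notice.
#'
#' @param config A `pipeline_config`, path, or named list: `images` (vector
#'   of cell directories for [read_voxel_image()]) or `simulate_cells`
#'   (parameter list for [cell_sim_params()], streamed); `geometry`
#'   (list for [geometry_params()]); `groups` (per-cell group labels, or a
#'   TSV path with columns `cell_id`, `group`).
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return List with `measurements`, `stats` (`phenotype_stats` or `NULL`),
#'   `excluded` (cell ids failing the z-window), `failed` (unreadable
#'   inputs), `truth` (simulation only), `paths`.
#' @export
run_geometry_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  log_level <- config$log_level %||% "info"
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gp <- if (is.null(config$geometry)) NULL
        else do.call(geometry_params, config$geometry)
  truth <- NULL; failed <- character(); seed <- config$seed
  if (!is.null(config$simulate_cells)) {
    cp <- do.call(cell_sim_params, config$simulate_cells)
    seed <- cp$seed
    pipeline_log("info", "simulate",
                 sprintf("simulating %d cells (seed %d)", cp$n_cells, cp$seed),
                 log_level)
    res <- simulate_quantify_cells(cp, geometry = gp %||%
                                     sim_geometry_params(cp))
    measurements <- res$measurements
    truth <- res$truth
  } else if (!is.null(config$images)) {
    gp <- gp %||% geometry_params()
    rows <- list()
    for (p in config$images) {
      row <- tryCatch(
        quantify_cell(read_voxel_image(p), gp, cell_id = basename(p)),
        error = function(e) {
          pipeline_log("error", "quantify",
                       sprintf("%s: %s", p, conditionMessage(e)), log_level)
          NULL
        })
      if (is.null(row)) failed <- c(failed, p) else
        rows[[length(rows) + 1L]] <- row
    }
    if (!length(rows))
      stop("no readable images among ", length(config$images), " inputs")
    measurements <- do.call(rbind, rows)
  } else stop("config must provide either 'images' or 'simulate_cells'")
  excluded <- measurements$cell_id[!is.na(measurements$accepted) &
                                     !measurements$accepted]
  if (length(excluded))
    pipeline_log("info", "select",
                 sprintf("%d cell(s) excluded by the %.1f um pole z-window: %s",
                         length(excluded),
                         (gp %||% geometry_params())$dz_max,
                         paste(excluded, collapse = ", ")), log_level)
  groups <- config$groups
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gtab <- utils::read.table(groups, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    groups <- gtab$group[match(measurements$cell_id, gtab$cell_id)]
  }
  stats_obj <- NULL
  if (!is.null(groups)) {
    measurements$group <- rep_len(groups, nrow(measurements))
    stats_obj <- phenotype_stats(measurements, group = "group",
                                 continuous = c("mean_intensity",
                                                "d_1", "d_2"))
    if (!is.null(stats_obj$note))
      pipeline_log("info", "stats", stats_obj$note, log_level)
  }
  header <- provenance_header(unclass(config), seed)
  paths <- list(measurements = file.path(out_dir, "cell_measurements.tsv"),
                stats = file.path(out_dir, "phenotype_stats.tsv"))
  con <- file(paths$measurements, open = "w", encoding = "UTF-8")
  writeLines(paste0("# ", header), con)
  suppressWarnings(utils::write.table(measurements, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      na = ""))
  close(con)
  if (!is.null(stats_obj))
    write_stats_report(stats_obj, paths$stats, header = header)
  yaml::write_yaml(list(provenance = header, n_cells = nrow(measurements),
                        excluded = as.list(excluded),
                        failed = as.list(failed)),
                   file.path(out_dir, "run_manifest.yaml"))
  list(measurements = measurements, stats = stats_obj, excluded = excluded,
       failed = failed, truth = truth, paths = paths)
}
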