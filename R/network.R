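#' Build a bait-centric interactome graph from a tiered hit table
#'
#' Nodes are the bait plus the retained preys; each prey is connected to the
#' bait by an edge weighted by the prey's best Mascot score across
#' replicates (the rendering convention "the darker the line, the greater
#' the score" is carried as this numeric weight). Preys in the top tier
#' (present in all replicates) get solid edges; two-replicate preys, when
#' requested, get dashed edges, mirroring how borderline interactors are
#' drawn. Previously reported prey-prey interactions are added as
#' unweighted `prior_known` edges, only when both partners are in the node
#' set. The graph is simple: duplicate edges and self-loops cannot occur,
#' and a bait accession appearing among the preys is removed with a
#' warning.
#'
#' @param hits A tiered `hit_table` (after [call_hits()], optionally
#'   shortlisted).
#' @param bait Bait accession (node is always present).
#' @param annotations Optional accession -> localization category map (data
#'   frame with `accession`, `category` or named character vector); nodes
#'   without one get `"unknown"`.
#' @param known_pairs Optional 2-column matrix/data.frame of accession pairs
#'   with previously reported interactions (treated as symmetric).
#' @param include_filtered2 Also include two-replicate (`filtered2`) preys
#'   with dashed edges (default `FALSE`: top tier only).
#' @param bait_label Display label for the bait node (default `bait`).
#' @return An [igraph::graph] with vertex attributes `name`, `label`,
#'   `category`, `tier` and edge attributes `weight`, `style`
#'   (`solid`/`dashed`), `kind` (`bait_prey`/`prior_known`).
#' @export
build_network <- function(hits, bait, annotations = NULL, known_pairs = NULL,
                          include_filtered2 = FALSE, bait_label = bait) {
  stopifnot(inherits(hits, "hit_table"), is.character(bait), nzchar(bait))
  keep_tiers <- if (include_filtered2) c("filtered2", "filtered3") else "filtered3"
  prey <- hits[hits$tier %in% keep_tiers, , drop = FALSE]
  if (bait %in% prey$accession) {
    warning("bait accession '", bait, "' appears among preys; removed")
    prey <- prey[prey$accession != bait, , drop = FALSE]
  }
  if (is.data.frame(annotations))
    annotations <- setNames(as.character(annotations$category),
                            annotations$accession)
  categ <- function(acc) {
    if (!length(annotations)) return(rep("unknown", length(acc)))
    out <- unname(annotations[acc])
    out[is.na(out)] <- "unknown"
    out
  }
  label <- prey$gene_symbol
  label[is.na(label) | !nzchar(label)] <- prey$accession[is.na(label) | !nzchar(label)]
  vertices <- data.frame(
    name = c(bait, prey$accession),
    label = c(bait_label, label),
    category = c("bait", categ(prey$accession)),
    tier = c("bait", prey$tier),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character(), weight = numeric(),
                      style = character(), kind = character(),
                      stringsAsFactors = FALSE)
  if (nrow(prey)) {
    if (any(prey$best_mascot <= 0))
      stop("bait-prey edge weights must be positive; zero best_mascot for ",
           prey$accession[which(prey$best_mascot <= 0)[1L]])
    edges <- data.frame(
      from = bait, to = prey$accession, weight = prey$best_mascot,
      style = ifelse(prey$tier == "filtered2", "dashed", "solid"),
      kind = "bait_prey", stringsAsFactors = FALSE)
  }
  if (!is.null(known_pairs) && NROW(known_pairs)) {
    kp <- as.matrix(known_pairs)[, 1:2, drop = FALSE]
    mode(kp) <- "character"
    both <- kp[, 1L] %in% vertices$name & kp[, 2L] %in% vertices$name &
      kp[, 1L] != kp[, 2L] & kp[, 1L] != bait & kp[, 2L] != bait
    kp <- kp[both, , drop = FALSE]
    if (nrow(kp)) {
      key <- apply(kp, 1L, function(p) paste(sort(p), collapse = "\r"))
      kp <- kp[!duplicated(key), , drop = FALSE]
      edges <- rbind(edges, data.frame(
        from = kp[, 1L], to = kp[, 2L], weight = NA_real_,
        style = "dashed", kind = "prior_known", stringsAsFactors = FALSE))
    }
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Export an interactome graph
#'
#' `graphml` is the canonical interchange format (attribute-preserving,
#' re-importable with [igraph::read_graph()]); `edge_tsv` is a flat
#' tab-separated edge list with columns `source, target, weight, style,
#' kind` (weight empty for `prior_known` edges).
#'
#' @param graph Graph from [build_network()].
#' @param format `"graphml"` or `"edge_tsv"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, format = c("graphml", "edge_tsv"), path) {
  stopifnot(inherits(graph, "igraph"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    out <- data.frame(source = el$from, target = el$to,
                      weight = el$weight, style = el$style, kind = el$kind,
                      stringsAsFactors = FALSE)
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}
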