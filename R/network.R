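## network module: representative selection, thresholded similarity graph,
## components, Cytoscape-friendly export.

#' Greedy longest-first representative clustering (CD-HIT semantics)
#'
#' Re-implements the greedy incremental cluster-assignment rule of CD-HIT
#' over a caller-supplied pairwise identity table: proteins are processed in
#' descending length (ties broken by id); each protein joins the earliest
#' founded cluster whose representative it matches at `>= threshold`
#' identity, else it founds a new cluster. Only the assignment semantics are
#' reproduced, not CD-HIT's short-word heuristics.
#'
#' @param proteins Protein metadata table with `protein_id` and `length`.
#' @param identities Alignment table with `query_id`, `subject_id`,
#'   `pct_identity` (symmetrised internally by max).
#' @param threshold Identity fraction in (0, 1]; default 0.5.
#' @return A list of class `representative_set`: `representative` (named
#'   character, member -> representative), `clusters` (list representative ->
#'   member ids), `threshold`.
#' @export
greedy_identity_clustering <- function(proteins, identities,
                                       threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    config_error("identity threshold must lie in (0, 1], got ", threshold)
  }
  ord <- proteins[order(-length, protein_id), protein_id]
  ## symmetrise by max identity
  sym <- rbind(
    identities[, .(a = query_id, b = subject_id, pct_identity)],
    identities[, .(a = subject_id, b = query_id, pct_identity)]
  )[a != b]
  if (nrow(sym)) {
    sym <- sym[, .(pct_identity = max(pct_identity)), by = .(a, b)]
  }
  nb <- split(setNames(sym$pct_identity, sym$b), sym$a)
  reps <- character()
  assignment <- setNames(character(length(ord)), ord)
  for (p in ord) {
    ids <- nb[[p]]
    hit <- NA_character_
    if (length(reps) && length(ids)) {
      match_pct <- ids[match(reps, names(ids))]
      ok <- which(!is.na(match_pct) & match_pct / 100 >= threshold)
      if (length(ok)) hit <- reps[ok[1L]]   # earliest founded representative
    }
    if (is.na(hit)) {
      reps <- c(reps, p)
      assignment[p] <- p
    } else {
      assignment[p] <- hit
    }
  }
  structure(list(representative = assignment,
                 clusters = split(names(assignment), assignment)[reps],
                 threshold = threshold),
            class = "representative_set")
}

#' Build the thresholded protein-similarity network
#'
#' Nodes are proteins (annotated with phylum and architecture type); an
#' undirected edge connects two proteins whose best directional alignment has
#' e-value at or below `e_threshold` (inclusive). Reciprocal hits collapse to
#' one edge carrying the minimum e-value and maximum bit score. Annotated
#' proteins without any passing edge are kept as singleton nodes.
#'
#' @param edges Alignment table ([read_alignments()] layout; self hits
#'   ignored).
#' @param annotations Table with `protein_id`, `phylum`, `type_label`
#'   covering at least every protein incident to a kept edge; its rows define
#'   the node set.
#' @param e_threshold E-value cut-off, default 1e-15.
#' @return An \pkg{igraph} undirected graph; vertex attributes `phylum`,
#'   `type_label`; edge attributes `e_value`, `bit_score`.
#' @export
build_network <- function(edges, annotations, e_threshold = 1e-15) {
  kept <- edges[query_id != subject_id & e_value <= e_threshold]
  if (nrow(kept)) {
    kept <- kept[, .(query_id, subject_id, e_value, bit_score)]
    kept[, `:=`(a = pmin(query_id, subject_id),
                b = pmax(query_id, subject_id))]
    kept <- kept[, .(e_value = min(e_value), bit_score = max(bit_score)),
                 by = .(a, b)]
    missing <- setdiff(unique(c(kept$a, kept$b)), annotations$protein_id)
    if (length(missing)) {
      stop_mce("build_network: edge endpoint(s) missing from annotations: ",
               paste(head(missing, 10L), collapse = ", "))
    }
  } else {
    kept <- data.table(a = character(), b = character(),
                       e_value = numeric(), bit_score = numeric())
  }
  verts <- unique(annotations[, .(protein_id, phylum, type_label)])
  igraph::graph_from_data_frame(kept, directed = FALSE,
                                vertices = as.data.frame(verts))
}

#' Label connected components and summarise their composition
#'
#' @param graph Graph from [build_network()].
#' @return A list with `membership` (`data.table`: protein_id, component; ids
#'   1..k by descending component size, ties by smallest member id) and
#'   `summary` (per component: size, composition by phylum and by type as
#'   `name:count` strings).
#' @export
connected_component_summary <- function(graph) {
  comp <- igraph::components(graph)
  dt <- data.table(protein_id = igraph::V(graph)$name,
                   raw = comp$membership,
                   phylum = igraph::V(graph)$phylum,
                   type_label = igraph::V(graph)$type_label)
  sizes <- dt[, .(size = .N, min_id = min(protein_id)), by = raw]
  setorder(sizes, -size, min_id)
  sizes[, component := seq_len(.N)]
  dt <- dt[sizes[, .(raw, component)], on = "raw"]
  count_str <- function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = ";")
  }
  summary <- dt[, .(size = .N,
                    by_phylum = count_str(phylum),
                    by_type = count_str(type_label)),
                by = component]
  setorder(summary, component)
  membership <- dt[order(component, protein_id),
                   .(protein_id, component)]
  list(membership = membership, summary = summary)
}

#' Export a similarity network
#'
#' `write_graphml()` writes GraphML (node attributes `phylum`, `type_label`;
#' edge attributes `e_value`, `bit_score`) for Cytoscape; `write_sif()`
#' writes the simple interaction format, one `a pp b` line per edge and a
#' bare id line per isolated node.
#'
#' @param graph Graph from [build_network()].
#' @param path Output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_sif <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  lines <- if (nrow(el)) paste(el[, 1L], "pp", el[, 2L]) else character()
  isolated <- igraph::V(graph)$name[igraph::degree(graph) == 0L]
  writeLines(c(lines, isolated), path)
  invisible(path)
}
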