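#' Select the edges of one tissue from a multi-tissue edge list
#'
#' @param edges Edge-list tibble (`node_a`, `node_b`, `tissue`).
#' @param tissue Tissue label to keep.
#'
#' @return The rows of `edges` with the matching tissue.
#' @export
select_tissue_edges <- function(edges, tissue) {
  available <- unique(edges$tissue)
  if (!tissue %in% available) {
    abort(paste0("tissue '", tissue, "' not present; available: ",
                 paste(available, collapse = ", ")))
  }
  out <- edges[edges$tissue == tissue, ]
  if (nrow(out) == 0L) abort("no edges left after tissue selection")
  out
}

#' Translate gene symbols to numeric IDs
#'
#' @param symbols Character vector of gene symbols.
#' @param id_map ID-map tibble (`symbol`, `entrez_id`).
#'
#' @return A list with `ids` (numeric IDs of the mapped symbols, in input
#'   order) and `unmapped` (symbols absent from the map). Unmapped symbols are
#'   reported, never silently dropped.
#' @export
translate_gene_ids <- function(symbols, id_map) {
  idx <- match(symbols, id_map$symbol)
  list(
    ids = id_map$entrez_id[idx[!is.na(idx)]],
    unmapped = symbols[is.na(idx)]
  )
}

# Build an undirected igraph from an edge-list tibble; vertex names are the
# character form of the numeric node IDs.
edges_to_graph <- function(edges) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$node_a), to = as.character(edges$node_b)),
    directed = FALSE
  )
  g
}

#' Prune an interaction graph
#'
#' Removes self-loops (and collapses multi-edges) and deletes every connected
#' component with fewer than `min_component` nodes. Idempotent.
#'
#' @param g An undirected `igraph` graph.
#' @param min_component Minimum component size to keep (default 5; a
#'   component of exactly `min_component` nodes is kept).
#'
#' @return The pruned graph.
#' @export
prune_graph <- function(g, min_component = 5L) {
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  comp <- igraph::components(g)
  keep <- which(comp$csize[comp$membership] >= min_component)
  g <- igraph::induced_subgraph(g, keep)
  if (igraph::vcount(g) == 0L) abort("pruning removed every node")
  g
}

#' Expand a seed-gene set by breadth-first neighbor lookup
#'
#' Returns every node whose shortest-path distance from any seed node is at
#' most `depth`; seeds themselves are always included.
#'
#' @param g An undirected `igraph` graph.
#' @param seeds Vertex names (character) or numeric node IDs of the seed
#'   genes; seeds absent from the graph are ignored, but at least one must be
#'   present.
#' @param depth Maximum BFS depth (default 3; `depth = 0` returns the seeds
#'   present in the graph).
#'
#' @return Character vector of vertex names within `depth` of the seeds.
#' @export
expand_seed_genes <- function(g, seeds, depth = 3L) {
  if (depth < 0) abort("depth must be >= 0")
  seeds <- as.character(seeds)
  present <- intersect(seeds, igraph::V(g)$name)
  if (length(present) == 0L) abort("no seed gene is present in the graph")
  reached <- igraph::ego(g, order = depth, nodes = present, mode = "all")
  sort(unique(unlist(lapply(reached, function(v) v$name))))
}

#' Graph connectivity diagnostics
#'
#' Reports the bridges of the graph (edges whose removal disconnects a
#' component) and the mean and standard deviation of the normalized
#' betweenness and closeness centralities. Closeness is computed per
#' connected component, so values stay in `[0, 1]` even for disconnected
#' graphs.
#'
#' @param g An undirected `igraph` graph.
#'
#' @return A list with `bridges` (two-column tibble of endpoints),
#'   `betweenness_mean`, `betweenness_sd`, `closeness_mean`, `closeness_sd`,
#'   `n_nodes`, `n_edges`.
#' @export
graph_statistics <- function(g) {
  br <- igraph::bridges(g)
  ends <- igraph::ends(g, br)
  bridges <- tibble::tibble(
    node_a = if (length(br) > 0) ends[, 1] else character(),
    node_b = if (length(br) > 0) ends[, 2] else character()
  )
  btw <- igraph::betweenness(g, normalized = TRUE)
  comp <- igraph::components(g)
  clo <- numeric(igraph::vcount(g))
  names(clo) <- igraph::V(g)$name
  for (cid in seq_len(comp$no)) {
    sub_idx <- which(comp$membership == cid)
    sub <- igraph::induced_subgraph(g, sub_idx)
    clo_sub <- if (igraph::vcount(sub) > 1L) {
      igraph::closeness(sub, normalized = TRUE)
    } else {
      setNames(0, igraph::V(sub)$name)
    }
    clo[names(clo_sub)] <- clo_sub
  }
  list(
    bridges = bridges,
    betweenness_mean = mean(btw), betweenness_sd = sd(btw),
    closeness_mean = mean(clo), closeness_sd = sd(clo),
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g)
  )
}

#' Build the shared patient interactome
#'
#' Composes the graph-construction pipeline: select one tissue's edges,
#' translate the disease-gene symbols to numeric IDs, prune the tissue graph
#' (self-loops, small components), expand the seed set by BFS to the given
#' depth, take the induced subgraph on the expanded node set, and prune
#' again.
#'
#' @param edges Multi-tissue edge-list tibble.
#' @param tissue Tissue to select.
#' @param seed_symbols Gene symbols of the disease-associated seed set.
#' @param id_map ID-map tibble (`symbol`, `entrez_id`).
#' @param depth BFS expansion depth (default 3).
#' @param min_component Minimum component size (default 5).
#'
#' @return A list with `graph` (igraph), `seeds_used` (vertex names of seeds
#'   present pre-expansion) and `unmapped` (symbols missing from the map).
#' @export
build_ppi_graph <- function(edges, tissue, seed_symbols, id_map,
                            depth = 3L, min_component = 5L) {
  tissue_edges <- select_tissue_edges(edges, tissue)
  tr <- translate_gene_ids(seed_symbols, id_map)
  g <- prune_graph(edges_to_graph(tissue_edges), min_component)
  seeds <- intersect(as.character(tr$ids), igraph::V(g)$name)
  if (length(seeds) == 0L) abort("no disease gene maps into the pruned tissue graph")
  expanded <- expand_seed_genes(g, seeds, depth)
  g <- igraph::induced_subgraph(g, expanded)
  g <- prune_graph(g, min_component)
  list(graph = g, seeds_used = seeds, unmapped = tr$unmapped)
}

#' Attribute the shared interactome to each patient
#'
#' Creates one attributed graph per patient: the topology is shared (by
#' reference to the same igraph object); node attributes are the patient's
#' normalized expression of the node's gene; graph attributes are the
#' patient's histology features. Nodes whose genes were filtered out of
#' `expr` can be attributed from `fallback_expr` (the normalized unfiltered
#' matrix).
#'
#' @param g The shared `igraph` topology (vertex names = numeric IDs).
#' @param expr Normalized expression tibble.
#' @param hist Normalized histology tibble, row-aligned with `expr`.
#' @param id_map ID-map tibble translating expression gene symbols to the
#'   graph's numeric IDs.
#' @param fallback_expr Optional normalized unfiltered expression tibble used
#'   for nodes absent from `expr`.
#'
#' @return A list of per-patient lists with elements `patient_id`,
#'   `topology` (the shared igraph), `node_attr` (named numeric vector, one
#'   value per node, in vertex order) and `graph_attr` (named histology
#'   vector).
#' @export
build_patient_graphs <- function(g, expr, hist, id_map, fallback_expr = NULL) {
  assert_aligned(expr, hist, "histology")
  nodes <- igraph::V(g)$name
  sym <- id_map$symbol[match(as.integer(nodes), id_map$entrez_id)]
  x <- expr_to_matrix(expr)
  fb <- if (!is.null(fallback_expr)) expr_to_matrix(fallback_expr) else NULL
  src <- ifelse(sym %in% colnames(x), "primary",
                ifelse(!is.null(fb) & sym %in% colnames(fb), "fallback", NA))
  if (anyNA(sym) || anyNA(src)) {
    missing <- nodes[is.na(sym) | is.na(src)]
    abort(paste0("no expression source for graph node(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  feat <- setdiff(names(hist), "patient_id")
  hmat <- as.matrix(hist[feat])
  purrr::map(seq_len(nrow(x)), function(i) {
    vals <- rep(NA_real_, length(sym))
    vals[src == "primary"] <- x[i, sym[src == "primary"]]
    if (any(src == "fallback")) {
      vals[src == "fallback"] <- fb[i, sym[src == "fallback"]]
    }
    list(
      patient_id = expr$patient_id[i],
      topology = g,
      node_attr = setNames(as.numeric(vals), nodes),
      graph_attr = setNames(as.numeric(hmat[i, ]), feat)
    )
  })
}
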