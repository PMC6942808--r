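#' Map core symptoms to phenotype terms
#'
#' Resolves each core symptom to its phenotype-ontology terms via the
#' symptom-term map, de-duplicating terms shared by several symptoms
#' (e.g. several stool symptoms all mapping to the constipation term).
#' Symptoms with an empty term list (tongue, fur and pulse signs typically
#' have no ontology counterpart) are returned as `unmapped`.
#'
#' @param core core symptoms: a character vector or a `selected_features`
#'   data frame from [extract_core_symptoms()].
#' @param map named list symptom -> term IDs, e.g. from a
#'   [knowledge_base] or [load_reference_fixtures()].
#' @return list with `terms` (sorted unique term IDs), `mapped` and
#'   `unmapped` (symptom names).
#' @export
map_symptoms_to_terms <- function(core, map) {
  symptoms <- if (is.data.frame(core)) core$symptom else as.character(core)
  miss <- setdiff(symptoms, names(map))
  if (length(miss)) {
    stop("symptom(s) absent from the symptom-term map: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  hits <- map[symptoms]
  unmapped <- symptoms[lengths(hits) == 0L]
  list(terms = sort(unique(as.character(unlist(hits, use.names = FALSE)))),
       mapped = setdiff(symptoms, unmapped),
       unmapped = unmapped)
}

#' Genes annotated to a set of phenotype terms
#'
#' Union of the gene symbols annotated to any of the query terms in a
#' flat term-gene annotation table.  Terms missing from the table
#' contribute nothing and are reported via a message.
#'
#' @param terms character vector of term IDs.
#' @param annotations named list term -> gene symbols.
#' @return sorted character vector of gene symbols.
#' @export
genes_for_terms <- function(terms, annotations) {
  if (!length(terms)) return(character())
  absent <- setdiff(terms, names(annotations))
  if (length(absent)) {
    message("term(s) without annotations: ", paste(absent, collapse = ", "))
  }
  sort(unique(unlist(annotations[intersect(terms, names(annotations))],
                     use.names = FALSE)))
}

#' Induce the interaction subgraph on a gene set
#'
#' Builds the undirected simple graph on the query genes from a scored
#' edge list, keeping edges whose combined confidence score reaches
#' `min_score` (default 0.4, the usual medium-confidence convention for
#' STRING-style scores).  Query genes with no surviving interaction are
#' retained as isolated nodes.
#'
#' @param genes character vector of query gene symbols.
#' @param edges data frame with columns `gene_a`, `gene_b`,
#'   `combined_score`, or a [knowledge_base].
#' @param min_score minimum combined score in \[0, 1\].
#' @return an \pkg{igraph} undirected graph with edge attribute `score`.
#' @export
build_interaction_graph <- function(genes, edges, min_score = 0.4) {
  if (inherits(edges, "knowledge_base")) edges <- edges$interaction_edges
  if (any(edges$combined_score < 0 | edges$combined_score > 1)) {
    stop("edge scores must lie in [0, 1]", call. = FALSE)
  }
  genes <- unique(genes)
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes &
    edges$combined_score >= min_score
  e <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$gene_a, to = e$gene_b, score = e$combined_score),
    directed = FALSE,
    vertices = data.frame(name = sort(genes)))
  stopifnot(igraph::ecount(g) == nrow(e))
  g
}

# Lower median: for an even count take the smaller of the two central
# order statistics, so the hub cutoff never falls between integers.
lower_median <- function(x) {
  s <- sort(x)
  unname(s[ceiling(length(s) / 2)])
}

#' Topology summary of an interaction graph
#'
#' Node and edge counts, average degree (2E/N), average local clustering
#' coefficient (per node: the fraction of its neighbour pairs that are
#' connected, 0 for degree < 2, averaged over all nodes) and the median
#' degree under the lower-median convention.
#'
#' @param graph an undirected \pkg{igraph} graph.
#' @return an object of class `topology_stats`: list with `node_count`,
#'   `edge_count`, `average_degree`, `average_local_clustering`,
#'   `median_degree`.
#' @export
graph_topology <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 1L) stop("empty graph", call. = FALSE)
  e <- igraph::ecount(graph)
  deg <- igraph::degree(graph)
  cc <- igraph::transitivity(graph, type = "localundirected",
                             isolates = "zero")
  structure(list(node_count = n, edge_count = e,
                 average_degree = 2 * e / n,
                 average_local_clustering = mean(cc),
                 median_degree = lower_median(deg)),
            class = "topology_stats")
}

#' @export
print.topology_stats <- function(x, ...) {
  cat(sprintf(paste0("Graph: %d nodes, %d edges | avg degree %.1f | ",
                     "avg local clustering %.3f | median degree %d\n"),
              x$node_count, x$edge_count, x$average_degree,
              x$average_local_clustering, x$median_degree))
  invisible(x)
}

#' Median-degree hub filter
#'
#' Selects the nodes whose degree is at least (`strict`: strictly above)
#' `multiplier` times the graph's median degree (lower-median
#' convention).  On a regular graph the non-strict filter with
#' multiplier 2 returns nothing; on a star it returns the centre.
#'
#' @param graph an undirected \pkg{igraph} graph.
#' @param multiplier degree multiplier (default 2).
#' @param strict use a strict inequality? Default `FALSE`.
#' @return character vector of hub gene names (sorted).
#' @export
select_hub_nodes <- function(graph, multiplier = 2, strict = FALSE) {
  if (igraph::vcount(graph) < 1L) stop("empty graph", call. = FALSE)
  deg <- igraph::degree(graph)
  cutoff <- multiplier * lower_median(deg)
  hubs <- if (strict) names(deg)[deg > cutoff] else names(deg)[deg >= cutoff]
  sort(hubs)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests each gene set for over-representation in the query via the
#' hypergeometric upper tail `P(X >= overlap)` with the annotation
#' universe as the population, the (universe-intersected) set as the
#' successes and the query as the draws.  Benjamini-Hochberg q-values are
#' reported alongside the raw p-values; the returned table is sorted by
#' ascending p, filtered at `p < alpha` and truncated to `top_n` rows.
#' The EASE-style conservative variant (overlap decremented by one before
#' taking the tail) is available behind a flag.
#'
#' @param query character vector of query genes (subset of `universe`).
#' @param sets named list of gene sets, or a [knowledge_base] (whose
#'   pathway sets and categories are used).
#' @param universe background gene universe; defaults to
#'   [kb_gene_universe()] when `sets` is a knowledge base.
#' @param alpha raw-p significance cutoff (default 0.05).
#' @param top_n maximum rows returned (default 20).
#' @param categories optional named character of per-set category tags.
#' @param ease use the EASE-style decremented overlap? Default `FALSE`.
#' @return data frame of class `enrichment_table` with columns `set`,
#'   `category`, `overlap`, `set_size`, `query_size`, `universe_size`,
#'   `p_value`, `q_value`.
#' @export
enrich_gene_sets <- function(query, sets, universe = NULL, alpha = 0.05,
                             top_n = 20L, categories = NULL, ease = FALSE) {
  if (inherits(sets, "knowledge_base")) {
    kb <- sets
    sets <- kb$pathway_sets
    categories <- categories %||% kb$pathway_categories
    universe <- universe %||% kb_gene_universe(kb)
  }
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(query)) stop("empty query", call. = FALSE)
  universe <- unique(universe)
  query <- unique(query)
  if (length(setdiff(query, universe))) {
    stop("query genes outside the universe", call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- stats::setNames(rep("other", length(sets)), names(sets))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    k <- length(intersect(members, query))
    k_tail <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(k_tail - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, category = unname(categories[nm]), overlap = k,
               set_size = K, query_size = n, universe_size = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")
  tab <- tab[order(tab$p_value, tab$set), ]
  tab <- tab[tab$p_value < alpha, , drop = FALSE]
  tab <- utils::head(tab, top_n)
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Symptom-to-pathway network analysis in one call
#'
#' Runs the full network-biology stage: map the core symptoms to
#' phenotype terms, retrieve annotated genes, induce the scored
#' interaction subgraph on all retrieved genes, filter hub nodes by the
#' median-degree rule, re-induce and summarize the hub subgraph, and run
#' hypergeometric enrichment of the hub genes against the pathway sets.
#'
#' @param core core symptoms (character or `selected_features`).
#' @param kb a [knowledge_base].
#' @param min_score interaction confidence cutoff (default 0.4).
#' @param multiplier hub degree multiplier (default 2).
#' @param alpha,top_n enrichment reporting controls.
#' @return list with `terms`, `unmapped`, `genes`, `graph`, `hubs`,
#'   `hub_graph`, `topology` (of the hub subgraph), `enrichment`.
#' @export
run_network_analysis <- function(core, kb, min_score = 0.4, multiplier = 2,
                                 alpha = 0.05, top_n = 20L) {
  mapping <- map_symptoms_to_terms(core, kb$symptom_term_map)
  genes <- genes_for_terms(mapping$terms, kb$term_gene_table)
  graph <- build_interaction_graph(genes, kb, min_score = min_score)
  hubs <- select_hub_nodes(graph, multiplier = multiplier)
  hub_graph <- igraph::induced_subgraph(graph, hubs)
  list(terms = mapping$terms, unmapped = mapping$unmapped, genes = genes,
       graph = graph, hubs = hubs, hub_graph = hub_graph,
       topology = if (length(hubs)) graph_topology(hub_graph) else NULL,
       enrichment = if (length(hubs)) {
         enrich_gene_sets(hubs, kb, alpha = alpha, top_n = top_n)
       } else {
         NULL
       })
}
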