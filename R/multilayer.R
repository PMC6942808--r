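#' Assemble the symptom-gene-pathway tripartite network
#'
#' Builds the three-layer network summarizing the biology stage: a
#' symptom-gene edge whenever a hub gene is annotated to at least one
#' phenotype term mapped from that symptom, and a gene-pathway edge
#' whenever a hub gene belongs to a significantly enriched set.  Genes
#' lacking either a symptom edge or a pathway edge are pruned first, then
#' symptoms and pathways left without any edge; the result therefore
#' contains only complete symptom-gene-pathway chains.  Node and edge
#' orderings are lexicographic, so assembly is deterministic and
#' idempotent.
#'
#' @param symptom_term_map named list symptom -> term IDs.
#' @param hub_genes character vector of hub gene symbols.
#' @param term_gene_table named list term -> gene symbols.
#' @param enrichment an `enrichment_table` already filtered to the
#'   significant sets (as returned by [enrich_gene_sets()]).
#' @param pathway_sets named list pathway -> member genes (the sets the
#'   enrichment table refers to).
#' @return an object of class `multilayer_network`: list with `nodes`
#'   (data frame `name`, `layer`) and `edges` (data frame `from`, `to`,
#'   `type` with `maps_to` for symptom-gene and `member_of` for
#'   gene-pathway edges).
#' @export
assemble_tripartite <- function(symptom_term_map, hub_genes,
                                term_gene_table, enrichment, pathway_sets) {
  if (!length(hub_genes)) {
    warning("empty hub set: returning an empty network")
    return(empty_multilayer())
  }
  # symptom -> gene via shared phenotype terms
  sg <- do.call(rbind, lapply(names(symptom_term_map), function(s) {
    terms <- intersect(symptom_term_map[[s]], names(term_gene_table))
    genes <- intersect(unique(unlist(term_gene_table[terms],
                                     use.names = FALSE)), hub_genes)
    if (!length(genes)) return(NULL)
    data.frame(from = s, to = genes, type = "maps_to",
               stringsAsFactors = FALSE)
  }))
  # gene -> enriched pathway via membership
  sig <- if (is.null(enrichment) || !nrow(enrichment)) character() else
    enrichment$set
  gp <- do.call(rbind, lapply(sig, function(pw) {
    genes <- intersect(pathway_sets[[pw]], hub_genes)
    if (!length(genes)) return(NULL)
    data.frame(from = genes, to = pw, type = "member_of",
               stringsAsFactors = FALSE)
  }))
  if (is.null(sg)) sg <- empty_edges()
  if (is.null(gp)) gp <- empty_edges()

  # keep only genes with both a symptom edge and a pathway edge
  both <- intersect(unique(sg$to), unique(gp$from))
  sg <- sg[sg$to %in% both, , drop = FALSE]
  gp <- gp[gp$from %in% both, , drop = FALSE]

  edges <- rbind(sg, gp)
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- rbind(
    data.frame(name = sort(unique(sg$from)), layer = "symptom",
               stringsAsFactors = FALSE),
    data.frame(name = sort(both), layer = "gene", stringsAsFactors = FALSE),
    data.frame(name = sort(unique(gp$to)), layer = "pathway",
               stringsAsFactors = FALSE))
  structure(list(nodes = nodes, edges = edges), class = "multilayer_network")
}

empty_edges <- function() {
  data.frame(from = character(), to = character(), type = character(),
             stringsAsFactors = FALSE)
}

empty_multilayer <- function() {
  structure(list(nodes = data.frame(name = character(), layer = character(),
                                    stringsAsFactors = FALSE),
                 edges = empty_edges()),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  tab <- table(factor(x$nodes$layer,
                      levels = c("symptom", "gene", "pathway")))
  cat(sprintf("Tripartite network: %d symptoms, %d genes, %d pathways; %d edges\n",
              tab[["symptom"]], tab[["gene"]], tab[["pathway"]],
              nrow(x$edges)))
  invisible(x)
}

#' Validate the tripartite layer-partition invariants
#'
#' Checks that edges only link symptom-gene or gene-pathway pairs, that
#' every retained gene touches both layers, and that no symptom or
#' pathway node is isolated.  Called by the assembly tests on every
#' generated network.
#'
#' @param net a `multilayer_network`.
#' @return `TRUE` invisibly, or an error describing the violated
#'   invariant.
#' @export
validate_multilayer <- function(net) {
  layer <- stats::setNames(net$nodes$layer, net$nodes$name)
  e <- net$edges
  if (nrow(e)) {
    from_l <- layer[e$from]
    to_l <- layer[e$to]
    ok <- (from_l == "symptom" & to_l == "gene" & e$type == "maps_to") |
      (from_l == "gene" & to_l == "pathway" & e$type == "member_of")
    if (!all(ok)) stop("edge crossing forbidden layers", call. = FALSE)
  }
  genes <- net$nodes$name[net$nodes$layer == "gene"]
  if (!all(genes %in% e$to[e$type == "maps_to"]) ||
      !all(genes %in% e$from[e$type == "member_of"])) {
    stop("a gene lacks a symptom- or pathway-side edge", call. = FALSE)
  }
  others <- net$nodes$name[net$nodes$layer != "gene"]
  if (!all(others %in% c(e$from, e$to))) {
    stop("isolated symptom or pathway node", call. = FALSE)
  }
  invisible(TRUE)
}

#' Export / import a tripartite network
#'
#' `graphml` writes an XML graph with a `layer` vertex attribute
#' (round-trips exactly through [read_network_graphml()]); `sif` writes
#' simple-interaction lines `source<TAB>maps_to|member_of<TAB>target`;
#' `csv` writes the node table with layer tags.
#'
#' @param net a `multilayer_network`.
#' @param path output file path.
#' @param format one of `"graphml"`, `"sif"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph_multilayer(net), path, format = "graphml")
  } else if (format == "sif") {
    lines <- if (nrow(net$edges)) {
      paste(net$edges$from, net$edges$type, net$edges$to, sep = "\t")
    } else {
      character()
    }
    writeLines(lines, path)
  } else {
    utils::write.csv(net$nodes, path, row.names = FALSE)
  }
  invisible(path)
}

as_igraph_multilayer <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' @rdname export_network
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(name = igraph::V(g)$name, layer = igraph::V(g)$layer,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  layer <- stats::setNames(nodes$layer, nodes$name)
  edges <- if (nrow(el)) {
    swap <- layer[el[, 1]] %in% c("gene", "pathway") &
      !(layer[el[, 1]] == "gene" & layer[el[, 2]] == "pathway")
    data.frame(from = ifelse(swap, el[, 2], el[, 1]),
               to = ifelse(swap, el[, 1], el[, 2]),
               type = igraph::E(g)$type, stringsAsFactors = FALSE)
  } else {
    empty_edges()
  }
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(match(nodes$layer, c("symptom", "gene", "pathway")),
                       nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "multilayer_network")
}
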