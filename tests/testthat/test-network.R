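test_that("symptom-term mapping de-duplicates shared terms and tracks None rows", {
  fx <- load_reference_fixtures()
  core <- names(fx$symptom_term_map)
  res <- map_symptoms_to_terms(core, fx$symptom_term_map)
  expect_length(res$mapped, 12)
  expect_length(res$unmapped, 7)
  expect_equal(length(res$terms), 15)   # distinct published term IDs
  # three stool symptoms collapse onto the single constipation term
  stool <- map_symptoms_to_terms(
    c("Dry stool", "Hard defecation", "Reduced frequency of defecation"),
    fx$symptom_term_map)
  expect_equal(stool$terms, "HP:0002019")
  expect_equal(map_symptoms_to_terms(character(), fx$symptom_term_map)$terms,
               character())
  expect_error(map_symptoms_to_terms("no such symptom", fx$symptom_term_map),
               "no such symptom")
})

test_that("gene retrieval is a union with lookup-oracle equality", {
  ann <- list(T1 = c("A", "B"), T2 = c("B", "C"))
  expect_equal(genes_for_terms(c("T1", "T2"), ann), c("A", "B", "C"))
  expect_equal(genes_for_terms(character(), ann), character())
  expect_message(genes_for_terms(c("T1", "T9"), ann), "T9")

  kb <- generate_knowledge_base(seed = 30)
  terms <- names(kb$term_gene_table)[1:5]
  oracle <- sort(unique(unlist(kb$term_gene_table[terms])))
  expect_equal(genes_for_terms(terms, kb$term_gene_table), oracle)
})

test_that("interaction subgraph induction filters by score and keeps isolates", {
  kb <- tiny_kb()
  g <- build_interaction_graph(c("G1", "G2", "G3"), kb, min_score = 0.4)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)   # the scored triangle
  g2 <- build_interaction_graph(c("G1", "G2", "G3"), kb, min_score = 1.0)
  expect_equal(igraph::ecount(g2), 0)
  expect_equal(igraph::vcount(g2), 3)  # isolated queries retained

  # filter oracle on a generated snapshot
  kb2 <- generate_knowledge_base(seed = 31)
  genes <- kb_gene_universe(kb2)[1:100]
  g3 <- build_interaction_graph(genes, kb2, min_score = 0.5)
  e <- kb2$interaction_edges
  manual <- e[e$gene_a %in% genes & e$gene_b %in% genes &
                e$combined_score >= 0.5, ]
  expect_equal(igraph::ecount(g3), nrow(manual))
  expect_equal(2 * igraph::ecount(g3) / igraph::vcount(g3),
               graph_topology(g3)$average_degree)
})

test_that("topology statistics match hand enumerations and the published identity", {
  # the published hub network: 145 nodes, 1964 edges -> mean degree 27.1
  pairs <- t(utils::combn(145, 2))[1:1964, ]
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  topo <- graph_topology(g)
  expect_equal(round(topo$average_degree, 1), 27.1)

  tri <- igraph::make_full_graph(3)
  t3 <- graph_topology(tri)
  expect_equal(t3$average_degree, 2)
  expect_equal(t3$average_local_clustering, 1)

  path5 <- igraph::make_graph(~ a - b - c - d - e)
  tp <- graph_topology(path5)
  expect_equal(tp$average_local_clustering, 0)
  expect_equal(tp$median_degree, 2)
  expect_equal(tp$average_degree, 8 / 5)
  # lower-median convention on even counts
  star4 <- igraph::make_star(4, mode = "undirected")  # degrees 3,1,1,1
  expect_equal(graph_topology(star4)$median_degree, 1)
  expect_error(graph_topology(igraph::make_empty_graph(0)), "empty")
})

test_that("the median-degree hub filter behaves on canonical graphs", {
  ring <- igraph::make_ring(10)
  igraph::V(ring)$name <- paste0("r", 1:10)
  expect_length(select_hub_nodes(ring), 0)   # regular: d < 2d

  star <- igraph::make_star(10, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("center", paste0("leaf", 1:9))
  expect_equal(select_hub_nodes(star), "center")   # 9 >= 2*1

  # relabeling invariance
  star2 <- igraph::permute(star, c(5, 1:4, 6:10))
  expect_equal(select_hub_nodes(star2), "center")

  # planted hubs with ~10x degree are recovered exactly
  set.seed(7)
  hubs <- paste0("H", 1:10)
  leaves <- paste0("L", 1:60)
  edges <- do.call(rbind, c(
    lapply(hubs, function(h) cbind(h, sample(leaves, 30))),
    list(cbind(leaves[seq(1, 59, 2)], leaves[seq(2, 60, 2)]))))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  expect_equal(select_hub_nodes(g), sort(hubs))
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  # spec-style case: universe 10, set 4, query 3, overlap 2
  universe <- letters[1:10]
  set4 <- letters[1:4]
  query <- c("a", "b", "e")
  tab <- enrich_gene_sets(query, list(S = set4), universe, alpha = 1.01)
  manual <- sum(choose(4, 2:3) * choose(6, 3 - 2:3)) / choose(10, 3)
  expect_equal(tab$p_value, manual, tolerance = 1e-12)

  # exhaustive oracle over all draws, several configurations
  for (cfg in list(c(8, 3, 4), c(12, 5, 6), c(9, 4, 2))) {
    N <- cfg[1]; K <- cfg[2]; n <- cfg[3]
    uni <- paste0("g", seq_len(N))
    set <- uni[seq_len(K)]
    draws <- utils::combn(N, n)
    for (k_obs in 0:min(K, n)) {
      # pick any query with that overlap, if one exists
      q <- c(uni[seq_len(k_obs)], setdiff(uni, set)[seq_len(n - k_obs)])
      if (anyNA(q) || length(unique(q)) < n) next
      p_pkg <- enrich_gene_sets(q, list(S = set), uni,
                                alpha = 1.01)$p_value
      overlap_all <- apply(draws, 2, function(d) sum(uni[d] %in% set))
      expect_equal(p_pkg, mean(overlap_all >= k_obs), tolerance = 1e-12)
    }
  }
})

test_that("enrichment table honors BH ordering, filters and degenerate cases", {
  kb <- generate_knowledge_base(seed = 33)
  hubs <- attr(kb, "planted")$hub_genes
  tab <- enrich_gene_sets(hubs, kb, alpha = 1.01, top_n = 100)
  expect_true(all(diff(tab$p_value) >= 0))
  expect_true(all(tab$q_value >= tab$p_value - 1e-12))
  expect_true(all(diff(tab$q_value) >= -1e-12))
  expect_true(all(tab$overlap <= pmin(tab$set_size, tab$query_size)))

  # query = universe: every draw is forced, p = 1 for every set
  uni <- c("A", "B", "C", "D")
  t2 <- enrich_gene_sets(uni, list(S1 = c("A", "B"), S2 = "D"), uni,
                         alpha = 1.01)
  expect_true(all(t2$p_value == 1))
  # zero overlap is never significant
  t3 <- enrich_gene_sets("A", list(S = c("B", "C")), uni, alpha = 1.01)
  expect_gt(t3$p_value, 0.2)
  # EASE-style decrement is conservative
  t4 <- enrich_gene_sets(c("A", "B"), list(S = c("A", "B")), uni,
                         alpha = 1.01, ease = TRUE)
  t5 <- enrich_gene_sets(c("A", "B"), list(S = c("A", "B")), uni,
                         alpha = 1.01)
  expect_gte(t4$p_value, t5$p_value)
  expect_error(enrich_gene_sets(character(), list(S = "A"), uni), "query")
  expect_error(enrich_gene_sets("A", list(S = "A"), character()), "universe")
  expect_error(enrich_gene_sets("Z", list(S = "A"), uni), "outside")
})

test_that("planted enriched pathways dominate the top ranks across seeds", {
  hits <- vapply(1:50, function(s) {
    kb <- generate_knowledge_base(n_genes = 200, seed = s)
    planted <- attr(kb, "planted")
    tab <- enrich_gene_sets(planted$hub_genes, kb, alpha = 0.05, top_n = 20)
    top <- utils::head(tab$set, length(planted$enriched_pathways))
    mean(top %in% planted$enriched_pathways) >= 0.8
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
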