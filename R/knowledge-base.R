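#' Knowledge-base snapshot
#'
#' Local stand-in for the online resources a symptom-to-pathway analysis
#' queries: a phenotype-term gene annotation table (HPO-style), a scored
#' gene-gene interaction edge list (STRING-style combined scores in
#' \[0, 1\]) and named pathway gene sets (GMT-style), plus the
#' symptom-to-term mapping.  Symptoms may map to no term at all (tongue
#' and pulse signs have no ontology counterpart); such entries are kept
#' with an empty term list.
#'
#' @param symptom_term_map named list: symptom -> character vector of
#'   phenotype term IDs (possibly empty).
#' @param term_gene_table named list: term ID -> character vector of gene
#'   symbols.
#' @param interaction_edges data frame with columns `gene_a`, `gene_b`,
#'   `combined_score`; undirected, no self-loops, no duplicate pairs.
#' @param pathway_sets named list: pathway name -> gene symbols.
#' @param pathway_categories named character vector over the pathway names
#'   with values in `proliferation-type`, `mitochondrial-type`, `other`.
#' @return an object of class `knowledge_base`.
#' @export
knowledge_base <- function(symptom_term_map, term_gene_table,
                           interaction_edges, pathway_sets,
                           pathway_categories = NULL) {
  stopifnot(is.list(symptom_term_map), is.list(term_gene_table),
            is.data.frame(interaction_edges), is.list(pathway_sets))
  need <- c("gene_a", "gene_b", "combined_score")
  if (!all(need %in% names(interaction_edges))) {
    stop("interaction_edges needs columns gene_a, gene_b, combined_score",
         call. = FALSE)
  }
  e <- interaction_edges
  if (any(e$gene_a == e$gene_b)) stop("self-loops not allowed", call. = FALSE)
  if (any(e$combined_score < 0 | e$combined_score > 1)) {
    stop("combined scores must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
  if (anyDuplicated(key)) stop("duplicate interaction pairs", call. = FALSE)
  universe <- union(unlist(term_gene_table, use.names = FALSE),
                    c(e$gene_a, e$gene_b))
  extra <- setdiff(unlist(pathway_sets, use.names = FALSE), universe)
  if (length(extra)) {
    stop("pathway genes outside the gene universe: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(pathway_categories)) {
    pathway_categories <- stats::setNames(
      rep("other", length(pathway_sets)), names(pathway_sets))
  }
  structure(list(symptom_term_map = symptom_term_map,
                 term_gene_table = term_gene_table,
                 interaction_edges = e[need],
                 pathway_sets = pathway_sets,
                 pathway_categories = pathway_categories),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf(paste0("Knowledge base: %d symptoms (%d unmapped), %d terms, ",
                     "%d genes, %d interactions, %d pathway sets\n"),
              length(x$symptom_term_map),
              sum(lengths(x$symptom_term_map) == 0),
              length(x$term_gene_table),
              length(kb_gene_universe(x)),
              nrow(x$interaction_edges),
              length(x$pathway_sets)))
  invisible(x)
}

#' Gene universe of a knowledge base
#'
#' All gene symbols appearing in the annotation table or the interaction
#' edge list; the default enrichment background.
#'
#' @param kb a [knowledge_base].
#' @return sorted character vector of gene symbols.
#' @export
kb_gene_universe <- function(kb) {
  sort(union(unlist(kb$term_gene_table, use.names = FALSE),
             c(kb$interaction_edges$gene_a, kb$interaction_edges$gene_b)))
}

#' Simulate a knowledge-base snapshot with planted structure
#'
#' Builds an interaction graph with a heavy-tailed degree distribution by
#' wiring a small hub set (`hub_fraction` of the genes) to many partners
#' and every other gene to only a few, so that a median-degree hub filter
#' has a non-trivial answer.  Phenotype terms annotate genes with a bias
#' toward hubs; a subset of pathways is enriched for hub genes by
#' `enrichment_factor`-fold oversampling; and a fraction of symptoms maps
#' to no term at all.  The planted hub genes and enriched pathway names are
#' attached as attribute `"planted"` for recovery tests.
#'
#' @param n_genes,n_terms,n_pathways component counts (all >= 1).
#' @param hub_fraction fraction of genes wired as hubs, in (0, 1).
#' @param seed integer seed.
#' @param symptoms symptom names to map; defaults to the 19-symptom core
#'   panel.
#' @param unmapped_fraction fraction of symptoms left without any term.
#' @param enrichment_factor hub oversampling factor for enriched pathways.
#' @param hub_degree,background_degree target degrees for hub and
#'   non-hub genes.
#' @return a [knowledge_base] with attribute `planted` (list with
#'   `hub_genes`, `enriched_pathways`).
#' @export
generate_knowledge_base <- function(n_genes = 300L, n_terms = 30L,
                                    n_pathways = 20L, hub_fraction = 0.05,
                                    seed = 1L,
                                    symptoms = default_symptom_panel()[1:19],
                                    unmapped_fraction = 7 / 19,
                                    enrichment_factor = 4,
                                    hub_degree = max(20L, round(0.25 * n_genes)),
                                    background_degree = 3L) {
  if (n_genes < 1 || n_terms < 1 || n_pathways < 1) {
    stop("component counts must be >= 1", call. = FALSE)
  }
  if (hub_fraction <= 0 || hub_fraction >= 1) {
    stop("hub_fraction must lie in (0, 1)", call. = FALSE)
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  n_hub <- max(1L, round(hub_fraction * n_genes))
  hubs <- genes[seq_len(n_hub)]

  with_seed(seed, {
    # heavy-tailed wiring: hubs attach to many partners, the rest to few
    pairs <- list()
    for (g in genes) {
      deg <- if (g %in% hubs) hub_degree else background_degree
      partners <- sample(setdiff(genes, g), min(deg, n_genes - 1L))
      pairs[[g]] <- cbind(pmin(g, partners), pmax(g, partners))
    }
    ep <- unique(do.call(rbind, pairs))
    edges <- data.frame(gene_a = ep[, 1], gene_b = ep[, 2],
                        combined_score = round(stats::runif(nrow(ep), 0.4, 0.999), 3),
                        stringsAsFactors = FALSE)
    # a sprinkling of low-confidence edges that a 0.4 cutoff should drop
    weak_a <- sample(genes, n_genes, replace = TRUE)
    weak_b <- sample(genes, n_genes, replace = TRUE)
    keep <- weak_a != weak_b
    weak <- data.frame(gene_a = pmin(weak_a[keep], weak_b[keep]),
                       gene_b = pmax(weak_a[keep], weak_b[keep]),
                       combined_score = round(stats::runif(sum(keep), 0.05, 0.39), 3),
                       stringsAsFactors = FALSE)
    key <- function(d) paste(d$gene_a, d$gene_b)
    weak <- weak[!duplicated(key(weak)) & !(key(weak) %in% key(edges)), ]
    edges <- rbind(edges, weak)
    edges <- edges[order(edges$gene_a, edges$gene_b), ]
    rownames(edges) <- NULL

    # term annotations biased toward hubs so symptom queries retrieve them
    w <- ifelse(genes %in% hubs, 5, 1)
    terms <- sprintf("HP:%07d", sample.int(9999999L, n_terms))
    term_gene <- lapply(terms, function(t) {
      size <- 2L + stats::rpois(1L, 8)
      sort(sample(genes, min(size, n_genes), prob = w))
    })
    names(term_gene) <- terms

    # symptom -> term map with deliberate "None" rows
    n_unmapped <- round(unmapped_fraction * length(symptoms))
    unmapped <- if (n_unmapped > 0) {
      sample(symptoms, min(n_unmapped, length(symptoms) - 1L))
    } else {
      character()
    }
    stm <- lapply(symptoms, function(s) {
      if (s %in% unmapped) character() else sort(sample(terms, sample(1:3, 1)))
    })
    names(stm) <- symptoms

    # pathway sets; half are planted hub-enriched
    n_enr <- max(1L, n_pathways %/% 2L)
    pw_names <- sprintf("PW%03d", seq_len(n_pathways))
    base_hub_share <- n_hub / n_genes
    sets <- lapply(seq_len(n_pathways), function(i) {
      size <- sample(10:20, 1)
      if (i <= n_enr) {
        share <- min(0.9, enrichment_factor * base_hub_share)
        n_h <- max(2L, round(share * size))
        sort(c(sample(hubs, min(n_h, n_hub)),
               sample(setdiff(genes, hubs), size - min(n_h, n_hub))))
      } else {
        sort(sample(genes, size))
      }
    })
    names(sets) <- pw_names
    cats <- stats::setNames(rep("other", n_pathways), pw_names)
    cats[seq_len(n_enr)] <- rep(c("proliferation-type", "mitochondrial-type"),
                                length.out = n_enr)

    kb <- knowledge_base(stm, term_gene, edges, sets, cats)
    attr(kb, "planted") <- list(hub_genes = hubs,
                                enriched_pathways = pw_names[seq_len(n_enr)])
    kb
  })
}

#' Write / read a knowledge base as plain-text snapshot files
#'
#' Four files in `dir`: `term_gene.tsv` (term<TAB>gene, one row per
#' annotation), `interactions.tsv` (gene_a<TAB>gene_b<TAB>combined_score),
#' `pathways.gmt` (name<TAB>category<TAB>gene...) and `symptom_terms.tsv`
#' (symptom<TAB>semicolon-joined terms, empty field for unmapped
#' symptoms).  Writing is deterministic, so equal knowledge bases produce
#' byte-identical files.
#'
#' @param kb a [knowledge_base].
#' @param dir directory (created if needed).
#' @return `write_knowledge_base` returns `dir` invisibly;
#'   `read_knowledge_base` returns a [knowledge_base].
#' @export
write_knowledge_base <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tg <- data.frame(
    term = rep(names(kb$term_gene_table), lengths(kb$term_gene_table)),
    gene = unlist(kb$term_gene_table, use.names = FALSE))
  utils::write.table(tg, file.path(dir, "term_gene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(kb$interaction_edges, file.path(dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gmt <- vapply(names(kb$pathway_sets), function(nm) {
    paste(c(nm, kb$pathway_categories[[nm]], kb$pathway_sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(dir, "pathways.gmt"))
  stm <- vapply(names(kb$symptom_term_map), function(s) {
    paste(s, paste(kb$symptom_term_map[[s]], collapse = ";"), sep = "\t")
  }, character(1))
  writeLines(c("symptom\tterms", stm), file.path(dir, "symptom_terms.tsv"))
  invisible(dir)
}

#' @rdname write_knowledge_base
#' @export
read_knowledge_base <- function(dir) {
  tg <- utils::read.delim(file.path(dir, "term_gene.tsv"),
                          stringsAsFactors = FALSE)
  term_gene <- split(tg$gene, tg$term)
  edges <- utils::read.delim(file.path(dir, "interactions.tsv"),
                             stringsAsFactors = FALSE)
  gmt <- read_gmt(file.path(dir, "pathways.gmt"))
  stm <- read_symptom_term_map(file.path(dir, "symptom_terms.tsv"))
  knowledge_base(stm, term_gene, edges, gmt$sets, gmt$categories)
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited gene-set format: set name, description, then the
#' member genes.  The description field is carried through as the set's
#' category tag.
#'
#' @param path GMT file path.
#' @return list with `sets` (named list of gene vectors) and `categories`
#'   (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1L)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), nm)
  cats <- stats::setNames(vapply(parts, `[[`, character(1), 2L), nm)
  list(sets = sets, categories = cats)
}

#' Read a symptom-to-term mapping TSV
#'
#' Two tab-separated columns with a header: symptom and a semicolon-joined
#' term list; a missing or empty second field means the symptom has no
#' ontology counterpart.
#'
#' @param path TSV file path.
#' @return named list: symptom -> character vector of term IDs.
#' @export
read_symptom_term_map <- function(path) {
  lines <- readLines(path)[-1L]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1L)
  stats::setNames(lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2L])) character() else
      unique(strsplit(p[2L], ";", fixed = TRUE)[[1]])
  }), nm)
}
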