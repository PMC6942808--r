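test_that("expert score generator hits degenerate and calibrated targets", {
  # degenerate concentration: every expert gives the full mark
  items4 <- data.frame(item = c("a", "b"), mu = 4, kappa = Inf)
  m <- generate_expert_scores(10, items4, seed = 1)
  expect_true(all(m$scores == 4L))
  expect_equal(item_statistics(m)$full_mark_rate, c(100, 100))

  # calibration: sample means track the requested means across many seeds
  fx <- load_reference_fixtures()
  items <- data.frame(item = fx$delphi_items$item,
                      mu = fx$delphi_items$mean_score)
  mean_of_means <- rowMeans(vapply(1:100, function(s) {
    colMeans(generate_expert_scores(54, items, seed = s)$scores)
  }, numeric(nrow(items))))
  # Monte-Carlo SE of a single item mean over 100x54 draws is ~0.02
  expect_true(max(abs(mean_of_means - items$mu)) < 0.08)
})

test_that("expert score generator is deterministic and validates inputs", {
  items <- data.frame(item = c("a", "b"), mu = c(3.5, 1.2),
                      planted_weak = c(FALSE, TRUE))
  m1 <- generate_expert_scores(20, items, seed = 42)
  m2 <- generate_expert_scores(20, items, seed = 42)
  expect_identical(m1$scores, m2$scores)
  expect_error(generate_expert_scores(1, items, seed = 1), "2 experts")
  expect_error(generate_expert_scores(10, data.frame(mu = 5), seed = 1),
               "\\[0, 4\\]")
  expect_error(generate_expert_scores(10, data.frame(mu = 2, kappa = -1),
                                      seed = 1), "kappa")
  # unreachable mean under heavy uniform mixing
  expect_error(generate_expert_scores(10, data.frame(mu = 3.9, kappa = 0.5),
                                      seed = 1), "unreachable")
})

test_that("planted weak items are removed by the deletion rules", {
  items <- data.frame(item = sprintf("it%02d", 1:20),
                      mu = c(rep(3.4, 15), rep(3.0, 5)),
                      planted_weak = rep(c(FALSE, TRUE), c(15, 5)))
  m <- generate_expert_scores(54, items, seed = 3)
  stats <- item_statistics(m)
  res <- apply_deletion_rules(stats, deletion_thresholds(stats))
  expect_true(all(items$item[items$planted_weak] %in% res$deleted$item))
})

test_that("null cohort model gives coin-flip labels with no association", {
  truth <- synthetic_truth(character(), numeric(), intercept = 0,
                           age_effect = 0)
  sim <- generate_clinical_cohort(n = 4000, symptoms = c("x1", "x2"),
                                  truth = truth, prevalence_target = NULL,
                                  seed = 11)
  prev <- mean(sim$cohort$label == "positive")
  expect_true(abs(prev - 0.5) < 3 * sqrt(0.25 / 4000))
  or <- function(sym) {
    t <- table(sim$cohort[[sym]], sim$cohort$label)
    (t[2, 2] * t[1, 1]) / (t[2, 1] * t[1, 2])
  }
  expect_true(abs(log(or("x1"))) < 0.25)
})

test_that("a planted log-odds of 3 yields an empirical odds ratio near e^3", {
  truth <- synthetic_truth("x1", 3, intercept = -1.5, age_effect = 0)
  sim <- generate_clinical_cohort(n = 50000, symptoms = c("x1", "x2"),
                                  truth = truth, prevalence_target = NULL,
                                  symptom_prevalence = 0.5, seed = 5)
  t <- table(sim$cohort$x1, sim$cohort$label)
  or <- (t[2, 2] * t[1, 1]) / (t[2, 1] * t[1, 2])
  expect_true(abs(log(or) - 3) < 0.15)
})

test_that("default cohort reproduces the motivating prevalence and age pattern", {
  sim <- generate_clinical_cohort(seed = 1)
  n_pos <- sum(sim$cohort$label == "positive")
  # binomial sd around 453 is ~12
  expect_true(abs(n_pos - 453) < 40)
  tab <- crosstab(sim$cohort, "age_group")
  pc <- attr(tab, "percent")
  expect_gt(pc["positive", "3-6"], pc["negative", "3-6"])

  # calibration invariant: mean empirical prevalence over replicates
  prev <- vapply(1:200, function(s) {
    mean(generate_clinical_cohort(n = 660, seed = s)$cohort$label == "positive")
  }, numeric(1))
  se <- stats::sd(prev) / sqrt(length(prev))
  expect_true(abs(mean(prev) - 453 / 660) < 2 * se + 0.002)

  expect_error(generate_clinical_cohort(prevalence_target = 1.2, seed = 1),
               "prevalence_target")
  s2 <- generate_clinical_cohort(seed = 1)
  expect_identical(as.data.frame(sim$cohort), as.data.frame(s2$cohort))
})

test_that("cohort CSV round-trips", {
  sim <- generate_clinical_cohort(n = 50, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(sim$cohort, path)
  back <- read_cohort_csv(path)
  expect_identical(symptom_names(back), symptom_names(sim$cohort))
  expect_equal(symptom_matrix(back), symptom_matrix(sim$cohort))
})

test_that("knowledge-base generator plants recoverable structure", {
  kb <- generate_knowledge_base(seed = 9)
  planted <- attr(kb, "planted")
  g <- build_interaction_graph(kb_gene_universe(kb), kb, min_score = 0.4)
  hubs <- select_hub_nodes(g)
  # planted hubs dominate the degree distribution
  expect_true(all(hubs %in% planted$hub_genes))
  expect_gte(length(hubs), 0.8 * length(planted$hub_genes))

  # closure: every mapped symptom with annotated terms yields genes
  mapped <- names(kb$symptom_term_map)[lengths(kb$symptom_term_map) > 0]
  for (s in mapped) {
    genes <- genes_for_terms(kb$symptom_term_map[[s]], kb$term_gene_table)
    expect_gt(length(genes), 0)
  }
  # pathway genes stay inside the universe (constructor enforces; re-check)
  expect_true(all(unlist(kb$pathway_sets) %in% kb_gene_universe(kb)))
})

test_that("knowledge-base snapshots are deterministic and round-trip", {
  d1 <- file.path(tempdir(), "kb1"); d2 <- file.path(tempdir(), "kb2")
  write_knowledge_base(generate_knowledge_base(seed = 4), d1)
  write_knowledge_base(generate_knowledge_base(seed = 4), d2)
  for (f in c("term_gene.tsv", "interactions.tsv", "pathways.gmt",
              "symptom_terms.tsv")) {
    expect_same_file(file.path(d1, f), file.path(d2, f))
  }
  kb <- generate_knowledge_base(seed = 4)
  back <- read_knowledge_base(d1)
  expect_equal(back$interaction_edges, kb$interaction_edges)
  expect_equal(back$pathway_sets, kb$pathway_sets)
  expect_equal(back$symptom_term_map[order(names(back$symptom_term_map))],
               kb$symptom_term_map[order(names(kb$symptom_term_map))])
  expect_error(generate_knowledge_base(hub_fraction = 1, seed = 1),
               "hub_fraction")
})

test_that("packaged reference fixtures load with the published shape", {
  fx <- load_reference_fixtures()
  expect_equal(nrow(fx$delphi_items), 47)
  halitosis <- fx$delphi_items[fx$delphi_items$item == "Halitosis", ]
  expect_equal(unname(unlist(
    halitosis[c("mean_score", "variable_coefficient", "full_mark_rate")])),
    c(3.69, 0.15, 72.22))
  expect_equal(fx$symptom_term_map[["Vomiting"]], "HP:0002013")
  expect_equal(length(fx$symptom_term_map), 19)
  expect_equal(sum(lengths(fx$symptom_term_map) == 0), 7)
  expect_equal(unname(fx$cohort_counts$age_group["positive", ]), c(250, 203))
  expect_equal(unname(fx$cohort_counts$age_group["negative", ]), c(66, 141))
})
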