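# Small in-code fixtures shared across test files.

# A tiny deterministic cohort: symptom s1 drives the label, s2 and s3 are
# noise; built without RNG so expectations are exact.
tiny_cohort <- function(n = 40L) {
  s1 <- rep(c(1L, 0L), each = n / 2)
  df <- data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    gender = rep(c("male", "female"), length.out = n),
    age_group = rep(c("3-6", "7-14"), length.out = n),
    label = ifelse(s1 == 1L, "positive", "negative"),
    s1 = s1,
    s2 = rep(c(0L, 1L, 0L, 1L), length.out = n),
    s3 = rep(c(1L, 1L, 0L, 0L), length.out = n),
    check.names = FALSE)
  clinical_dataset(df, c("s1", "s2", "s3"))
}

# A hand-wired knowledge base with fully known chains:
#   symA -> T1 -> {G1, G2}; symB -> T2 -> {G2, G3}; symC unmapped.
#   G1-G2-G3 form a scored triangle; P1 = {G1, G2} (enriched-style),
#   P2 = {G4} (disjoint from any query).
tiny_kb <- function() {
  knowledge_base(
    symptom_term_map = list(symA = "HP:0000001", symB = "HP:0000002",
                            symC = character()),
    term_gene_table = list("HP:0000001" = c("G1", "G2"),
                           "HP:0000002" = c("G2", "G3")),
    interaction_edges = data.frame(
      gene_a = c("G1", "G1", "G2", "G3"),
      gene_b = c("G2", "G3", "G3", "G4"),
      combined_score = c(0.9, 0.8, 0.7, 0.95),
      stringsAsFactors = FALSE),
    pathway_sets = list(P1 = c("G1", "G2"), P2 = "G4"),
    pathway_categories = c(P1 = "proliferation-type", P2 = "other"))
}

expect_same_file <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}
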