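# Occurrence/centrality scoring, medoid combination, the reaction-of-
# interest intersection, gene scores, and the drug ranking.

mk_class <- function(extended_ids, all_ids) {
  data.frame(reaction_id = all_ids,
             label = ifelse(all_ids %in% extended_ids, "extended", "none"),
             stringsAsFactors = FALSE)
}

test_that("occurrence selection uses the at-least-half (ceiling) rule", {
  ids <- c("r1", "r2", "r3")
  cls <- list(mk_class(c("r1", "r2"), ids), mk_class("r1", ids),
              mk_class("r1", ids), mk_class(character(0), ids))
  cen <- rep(list(stats::setNames(rep(1 / 3, 3), ids)), 4)
  sc <- score_reactions(cls, cen, reaction_ids = ids)
  # r1 extended in 3/4, r2 in 1/4, threshold ceil(0.5*4) = 2
  expect_identical(sc$occurrence, c(3L, 1L, 0L))
  expect_identical(sc$is_occurrence_selected, c(TRUE, FALSE, FALSE))
  # boundary: exactly half
  cls2 <- list(mk_class("r2", ids), mk_class("r2", ids),
               mk_class(character(0), ids), mk_class(character(0), ids))
  sc2 <- score_reactions(cls2, cen, reaction_ids = ids)
  expect_true(sc2$is_occurrence_selected[sc2$reaction_id == "r2"])
  # odd count: 2 of 5 is below ceil(2.5) = 3
  cls3 <- c(cls2, list(mk_class(character(0), ids)))
  sc3 <- score_reactions(cls3, c(cen, cen[1]), reaction_ids = ids)
  expect_false(sc3$is_occurrence_selected[sc3$reaction_id == "r2"])
})

test_that("topology selection takes the top decile with ties included", {
  ids <- sprintf("r%02d", 1:20)
  cen <- stats::setNames(seq(0.2, 0.01, length.out = 20), ids)
  cen <- cen / sum(cen)
  sc <- score_reactions(list(mk_class(character(0), ids)), list(cen),
                        reaction_ids = ids)
  expect_identical(sc$reaction_id[sc$is_topology_selected],
                   c("r01", "r02"))   # exactly floor(0.1 * 20) = 2
  # ties at the cutoff are included
  cen2 <- stats::setNames(c(5, 5, 5, rep(1, 17)), ids)
  sc2 <- score_reactions(list(mk_class(character(0), ids)), list(cen2),
                         reaction_ids = ids)
  expect_identical(sum(sc2$is_topology_selected), 3L)
})

test_that("centrality sums treat absence from a solution as zero", {
  cls <- list(mk_class(character(0), c("r1", "r2")),
              mk_class(character(0), "r1"))
  cen <- list(stats::setNames(c(0.6, 0.4), c("r1", "r2")),
              stats::setNames(1, "r1"))
  sc <- score_reactions(cls, cen, reaction_ids = c("r1", "r2"))
  expect_equal(sc$centrality, c(1.6, 0.4))
  expect_error(score_reactions(list(), list()), "zero non-redundant")
})

test_that("medoid combination sums scores and ORs flags over the union", {
  s1 <- data.frame(reaction_id = c("a", "b"), occurrence = c(3L, 1L),
                   centrality = c(0.5, 0.1),
                   is_occurrence_selected = c(TRUE, FALSE),
                   is_topology_selected = c(FALSE, TRUE),
                   stringsAsFactors = FALSE)
  s2 <- data.frame(reaction_id = c("a", "c"), occurrence = c(2L, 4L),
                   centrality = c(0.2, 0.9),
                   is_occurrence_selected = c(FALSE, TRUE),
                   is_topology_selected = c(FALSE, FALSE),
                   stringsAsFactors = FALSE)
  cmb <- combine_medoids(s1, s2)
  expect_identical(cmb$reaction_id, c("a", "b", "c"))
  expect_identical(cmb$occurrence, c(5L, 1L, 4L))
  expect_equal(cmb$centrality, c(0.7, 0.1, 0.9))
  expect_identical(cmb$is_occurrence_selected, c(TRUE, FALSE, TRUE))
  expect_identical(cmb$is_topology_selected, c(FALSE, TRUE, FALSE))
})

test_that("reactions of interest equal the brute-force set expression", {
  set.seed(17)
  n <- 50
  ids <- sprintf("r%02d", 1:n)
  genes <- sprintf("g%02d", 1:n)
  m <- metabolic_model(metabolite_ids = "X",
                       reaction_ids = ids,
                       S = matrix(1, 1, n),
                       lower_bound = rep(0, n), upper_bound = rep(1, n),
                       gpr = genes)
  scores <- data.frame(reaction_id = ids,
                       occurrence = sample(0:5, n, replace = TRUE),
                       centrality = runif(n),
                       is_occurrence_selected = sample(c(TRUE, FALSE), n,
                                                       replace = TRUE),
                       is_topology_selected = sample(c(TRUE, FALSE), n,
                                                     replace = TRUE),
                       stringsAsFactors = FALSE)
  essential <- sample(ids, 25)
  upreg <- sample(genes, 25)
  roi <- reactions_of_interest(scores, essential, upreg, m)
  brute <- sort(ids[ids %in% essential &
                      genes %in% upreg &
                      (scores$is_occurrence_selected |
                         scores$is_topology_selected)])
  expect_identical(roi, brute)
  # enlarging any criterion set never shrinks the output
  roi2 <- reactions_of_interest(scores, ids, upreg, m)
  roi3 <- reactions_of_interest(scores, essential, genes, m)
  expect_true(all(roi %in% roi2))
  expect_true(all(roi %in% roi3))
})

test_that("gene scores normalize per component and guard zero columns", {
  ids <- c("r1", "r2", "r3")
  m <- metabolic_model("X", ids, matrix(1, 1, 3), rep(0, 3), rep(1, 3),
                       gpr = c("gA", "gA", "gB"))
  scores <- data.frame(reaction_id = ids, occurrence = c(3L, 1L, 2L),
                       centrality = c(0, 0, 0),
                       is_occurrence_selected = TRUE,
                       is_topology_selected = FALSE,
                       stringsAsFactors = FALSE)
  gs <- gene_scores(ids, scores, m)
  # gA raw occurrence 4 -> norm 1, gB raw 2 -> 0.5; centrality all zero
  expect_equal(gs$occurrence_norm[gs$gene == "gA"], 1)
  expect_equal(gs$occurrence_norm[gs$gene == "gB"], 0.5)
  expect_equal(gs$centrality_norm, c(0, 0))
  expect_true(all(gs$relevance >= 0 & gs$relevance <= 2))

  # single gene, single reaction: both components 1, relevance 2
  m1 <- metabolic_model("X", "r1", matrix(1, 1, 1), 0, 1, gpr = "gA")
  sc1 <- data.frame(reaction_id = "r1", occurrence = 7L, centrality = 0.3,
                    is_occurrence_selected = TRUE,
                    is_topology_selected = TRUE, stringsAsFactors = FALSE)
  gs1 <- gene_scores("r1", sc1, m1)
  expect_equal(gs1$relevance, 2)
  expect_warning(gene_scores(character(0), sc1, m1), "no reactions")
})

test_that("drug relevance sums distinct matched genes and sorts stably", {
  genes <- data.frame(gene = c("gA", "gB"),
                      occurrence_norm = c(1, 0.5),
                      centrality_norm = c(1, 0.3),
                      relevance = c(2, 0.8), stringsAsFactors = FALSE)
  tbl <- data.frame(
    chemical = c("dx", "dx", "dx", "dy", "dz"),
    gene = c("gA", "gB", "gA", "gA", "gZ"),
    interaction_type = c("direct", "direct", "expression_increase",
                         "direct", "predicted"),
    source = c("s1", "s1", "s2", "s1", "s1"), stringsAsFactors = FALSE)
  expect_message(dr <- drug_relevance(tbl, genes), "dropped 1")
  # duplicate (dx, gA) from two sources counted once
  expect_equal(dr$relevance[dr$chemical == "dx"], 2.8)
  expect_identical(dr$n_genes[dr$chemical == "dx"], 2L)
  expect_identical(dr$chemical[1], "dx")   # multi-gene chemical outranks
  expect_false("dz" %in% dr$chemical)      # unmatched-only chemical dropped
  # row order of the interaction table does not matter
  dr2 <- suppressMessages(drug_relevance(tbl[sample(nrow(tbl)), ], genes))
  expect_identical(dr2, dr, ignore_attr = TRUE)
  expect_identical(nrow(drug_relevance(tbl[0, ], genes)), 0L)
})
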