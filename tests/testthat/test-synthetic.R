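# Synthetic fixture generation: planted ground truth must be recoverable.

test_that("generation is deterministic under a fixed seed", {
  a <- generate_toy_model(fixture_spec(seed = 3))
  b <- generate_toy_model(fixture_spec(seed = 3))
  expect_identical(a$truth, b$truth)
  expect_equal(as.matrix(a$model$S), as.matrix(b$model$S))
  ea <- generate_expression(fixture_spec(seed = 3), a)
  eb <- generate_expression(fixture_spec(seed = 3), b)
  expect_identical(ea$expression$values, eb$expression$values)
  expect_identical(ea$differential, eb$differential)
})

test_that("planted choke-point classes are realized at the biomass optimum", {
  toy <- generate_toy_model(fixture_spec())
  s <- solve_weighted_fba(toy$model, c(1, 0, 0))
  expect_equal(s$objective_value, 10)   # pinned at the uptake bound
  net <- reduce_network(toy$model, s)
  # guard: the designed forward direction is realized
  expect_true(all(net$orientation == 1L))
  cl <- classify_choke_points(net)
  tr <- toy$truth[!is.na(toy$truth$planted_class), ]
  got <- cl$label[match(tr$reaction_id, cl$reaction_id)]
  expect_identical(got, tr$planted_class)
})

test_that("planted essentiality truth is recovered by the knockout screen", {
  toy <- generate_toy_model(fixture_spec())
  ess <- essential_reactions(toy$model)
  tr <- toy$truth[!is.na(toy$truth$essential), ]
  expect_identical(tr$reaction_id %in% as.character(ess), tr$essential)
})

test_that("a motif-free spec yields a pure chain, everything essential", {
  spec <- fixture_spec(n_linear_chains = 3, n_parallel_motifs = 0,
                       motifs = c(none = 0, single_consuming = 0,
                                  single_producing = 0, double = 0,
                                  extended = 0))
  toy <- generate_toy_model(spec)
  ess <- essential_reactions(toy$model)
  chain_rxns <- setdiff(toy$model$reaction_ids,
                        c("EX_o2", "atp_syn", "atp_sink", "pi4p_syn",
                          "pi4p_sink"))
  expect_true(all(chain_rxns %in% as.character(ess)))
  # middle chain reactions are extended choke points by construction
  s <- solve_weighted_fba(toy$model, c(1, 0, 0))
  cl <- classify_choke_points(reduce_network(toy$model, s))
  mid <- grep("_chai_chain$", cl$reaction_id, value = TRUE)[2]
  expect_identical(cl$label[cl$reaction_id == mid], "extended")
})

test_that("zero-noise expression recovers k = 2 and the planted profiles", {
  spec <- fixture_spec()
  toy <- generate_toy_model(spec)
  expr <- generate_expression(spec, toy)
  sig <- binarize(expr$expression)
  expect_identical(as.integer(select_k_silhouette(sig, 2:4)), 2L)
  cl <- pam_cluster(sig, 2)
  meds <- list(unname(cl$medoids[, 1]), unname(cl$medoids[, 2]))
  pls <- list(unname(expr$profiles[, "A"]), unname(expr$profiles[, "B"]))
  expect_true((identical(meds[[1]], pls[[1]]) &&
                 identical(meds[[2]], pls[[2]])) ||
                (identical(meds[[1]], pls[[2]]) &&
                   identical(meds[[2]], pls[[1]])))
})

test_that("planted upregulated genes pass the differential thresholds", {
  spec <- fixture_spec()
  toy <- generate_toy_model(spec)
  expr <- generate_expression(spec, toy)
  up <- flag_upregulated(expr$differential)
  expect_identical(up, expr$upregulated)
  expect_true(all(toy$target_genes %in% up))
  # the epsilon-logFC of planted genes clears the 1.5 threshold at zero noise
  expect_true(all(expr$differential$logFC[
    expr$differential$gene %in% expr$upregulated] >= 1.5))
})

test_that("the full pipeline ranks every planted target above non-targets", {
  spec <- fixture_spec()
  toy <- generate_toy_model(spec)
  expr <- generate_expression(spec, toy)
  inter <- generate_interactions(toy, expr)
  res <- suppressMessages(
    run_pipeline(toy$model, expr$expression, expr$differential, inter))
  expect_identical(res$k, 2L)
  # every planted extended + essential + upregulated reaction is recovered
  planted <- toy$truth$reaction_id[toy$truth$is_target]
  expect_true(all(planted %in% res$roi))
  # rank-order property on the gene scores
  tg <- toy$target_genes
  if (any(!res$genes$gene %in% tg)) {
    min_t <- min(res$genes$relevance[res$genes$gene %in% tg])
    max_o <- max(res$genes$relevance[!res$genes$gene %in% tg])
    expect_gt(min_t, max_o)
  }
  expect_true(all(tg %in% res$genes$gene))
  # the planted multi-target chemical tops the drug ranking
  expect_identical(res$drugs$chemical[1], "drug_multi")
})

test_that("fixture files round-trip through the readers", {
  dir <- withr::local_tempdir()
  fx <- write_fixture(fixture_spec(seed = 8), dir)
  m <- load_model(fx$paths$model)
  expect_equal(as.matrix(m$S), as.matrix(fx$toy$model$S))
  expect_identical(m$objective_tags, fx$toy$model$objective_tags)
  E <- read_expression(fx$paths$expression, fx$paths$cohorts)
  expect_equal(E$values, fx$expr$expression$values, tolerance = 1e-9)
  expect_identical(E$cohort, fx$expr$expression$cohort)
  d <- read_differential(fx$paths$differential)
  expect_identical(d$gene, fx$expr$differential$gene)
  i <- read_interactions(fx$paths$interactions)
  expect_identical(nrow(i), nrow(fx$interactions))
})
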