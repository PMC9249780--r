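# Network reduction, choke-point classification, reaction graph, PageRank.

test_that("reduction keeps active reactions and orients reversed ones", {
  m <- chain_model(3)
  fl <- fluxtarget:::flux_distribution(m$reaction_ids, rep(10, 4), 10, "t")
  net <- reduce_network(m, fl)
  expect_identical(net$reaction_ids, m$reaction_ids)
  expect_true(all(net$orientation == 1L))

  # reversible reaction carried at -5: column equals the sign-flipped one
  mr <- metabolic_model(c("A", "B"), c("r1", "r2"),
                        rbind(c(-1, 1), c(1, -1)), c(-5, -5), c(5, 5))
  flr <- fluxtarget:::flux_distribution(mr$reaction_ids, c(-5, 5), 0, "t")
  netr <- reduce_network(mr, flr)
  expect_equal(as.numeric(netr$S[, "r1"]), -as.numeric(mr$S[, "r1"]))
  expect_equal(as.numeric(netr$S[, "r2"]), as.numeric(mr$S[, "r2"]))

  # sub-tolerance flux is dropped, all-zero flux warns and empties
  fl2 <- fluxtarget:::flux_distribution(m$reaction_ids,
                                        c(10, 1e-9, 10, 10), 10, "t")
  expect_identical(setdiff(m$reaction_ids,
                           reduce_network(m, fl2)$reaction_ids), "r1")
  fl0 <- fluxtarget:::flux_distribution(m$reaction_ids, rep(0, 4), 0, "t")
  expect_warning(net0 <- reduce_network(m, fl0), "below tolerance")
  expect_length(net0$reaction_ids, 0)
})

test_that("the five figure motifs classify as planted", {
  expected <- c(none = "none",
                single_consuming = "single_consuming",
                single_producing = "single_producing",
                double = "double",
                extended = "extended")
  for (type in names(expected)) {
    cl <- classify_choke_points(motif_network(type))
    expect_identical(cl$label[cl$reaction_id == "R"],
                     unname(expected[type]), info = type)
  }
  # the double motif is single on both sides without being extended
  cld <- classify_choke_points(motif_network("double"))
  row <- cld[cld$reaction_id == "R", ]
  expect_true(row$is_single_consuming && row$is_single_producing)
})

test_that("extended implies double implies single on both sides", {
  for (seed in 1:40) {
    S <- random_oriented_network(sample(4:12, 1), sample(3:8, 1), seed)
    cl <- classify_choke_points(as_net(S))
    dbl <- cl$label %in% c("double", "extended")
    expect_true(all(cl$is_single_consuming[dbl] &
                      cl$is_single_producing[dbl]))
    expect_true(all(cl$label[cl$is_single_consuming &
                               cl$is_single_producing] %in%
                      c("double", "extended")))
  }
})

test_that("classification matches the brute-force oracle on 200 networks", {
  for (seed in 1:200) {
    S <- random_oriented_network(sample(3:12, 1), sample(2:8, 1),
                                 seed + 1000)
    for (rule in c("all", "exists")) {
      cfg <- analysis_config(extended_rule = rule)
      got <- classify_choke_points(as_net(S), cfg)
      want <- oracle_classify(S, rule)
      expect_identical(stats::setNames(got$label, got$reaction_id),
                       want, info = sprintf("seed %d rule %s", seed, rule))
    }
  }
})

test_that("the exists-rule is at most as strict as the all-rule", {
  for (seed in 1:30) {
    S <- random_oriented_network(sample(4:10, 1), sample(3:7, 1),
                                 seed + 5000)
    all_cl <- classify_choke_points(as_net(S),
                                    analysis_config(extended_rule = "all"))
    ex_cl <- classify_choke_points(as_net(S),
                                   analysis_config(extended_rule = "exists"))
    ext_all <- all_cl$reaction_id[all_cl$label == "extended"]
    ext_ex <- ex_cl$reaction_id[ex_cl$label == "extended"]
    # both label exactly the same reactions as double-or-extended
    expect_identical(sort(c(ext_all,
                            all_cl$reaction_id[all_cl$label == "double"])),
                     sort(c(ext_ex,
                            ex_cl$reaction_id[ex_cl$label == "double"])))
  }
})

test_that("the reaction graph links producers to consumers", {
  m <- chain_model(3)
  fl <- fluxtarget:::flux_distribution(m$reaction_ids, rep(10, 4), 10, "t")
  g <- build_reaction_graph(reduce_network(m, fl))
  el <- igraph::as_edgelist(g)
  expect_identical(nrow(el), 3L)
  expect_true(all(paste(el[, 1], el[, 2]) %in%
                    c("EX_in r1", "r1 r2", "r2 biomass")))

  # two producers of A and one consumer: two edges in, none between producers
  S <- matrix(c(1, 1, -1), 1, 3,
              dimnames = list("A", c("p1", "p2", "c1")))
  g2 <- build_reaction_graph(as_net(S))
  el2 <- igraph::as_edgelist(g2)
  expect_identical(sort(paste(el2[, 1], el2[, 2])), c("p1 c1", "p2 c1"))
})

test_that("graph edges ignore metabolite order and coefficient size", {
  S <- random_oriented_network(8, 6, 77)
  g1 <- build_reaction_graph(as_net(S))
  perm <- sample(nrow(S))
  g2 <- build_reaction_graph(as_net(S[perm, , drop = FALSE]))
  S3 <- S * matrix(sample(1:5, length(S), replace = TRUE), nrow(S))
  g3 <- build_reaction_graph(as_net(S3))
  e <- function(g) sort(apply(igraph::as_edgelist(g), 1, paste,
                              collapse = ">"))
  expect_identical(e(g2), e(g1))
  expect_identical(e(g3), e(g1))
})

test_that("a reversed reaction rewires the graph like a pre-flipped model", {
  mr <- metabolic_model(c("A", "B", "C"), c("r1", "r2", "r3"),
                        rbind(c(1, 0, 0), c(-1, 1, 0), c(0, -1, 1)),
                        c(0, -10, 0), c(10, 0, 10))
  # r2 only runs backwards: C? no, r2: A -> B reversed means B -> A
  flr <- fluxtarget:::flux_distribution(mr$reaction_ids, c(5, -5, 5), 0, "t")
  net <- reduce_network(mr, flr)
  pre <- mr
  pre$S[, "r2"] <- -pre$S[, "r2"]
  flp <- fluxtarget:::flux_distribution(pre$reaction_ids, c(5, 5, 5), 0, "t")
  net_pre <- reduce_network(pre, flp)
  e <- function(n) sort(apply(igraph::as_edgelist(build_reaction_graph(n)),
                              1, paste, collapse = ">"))
  expect_identical(e(net), e(net_pre))
})

test_that("PageRank is uniform on a cycle, sums to one, and is non-negative", {
  S <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"),
                                       c("r1", "r2", "r3")))
  S["A", "r1"] <- -1; S["B", "r1"] <- 1
  S["B", "r2"] <- -1; S["C", "r2"] <- 1
  S["C", "r3"] <- -1; S["A", "r3"] <- 1
  g <- build_reaction_graph(as_net(S))
  pr <- pagerank(g)
  expect_equal(unname(pr), rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_true(all(pr >= 0))
})

test_that("PageRank matches dense power iteration on fixture graphs", {
  # 4-node star: three nodes feeding a hub (a dangling node)
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A["a", "d"] <- A["b", "d"] <- A["c", "d"] <- 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  expect_equal(unname(pagerank(g, 0.85)),
               unname(oracle_pagerank(A, 0.85)), tolerance = 1e-10)
  # random directed graphs including dangling nodes
  for (seed in 1:10) {
    set.seed(seed + 300)
    n <- sample(3:9, 1)
    A <- matrix(rbinom(n * n, 1, 0.3), n, n,
                dimnames = list(sprintf("n%d", 1:n), sprintf("n%d", 1:n)))
    diag(A) <- 0
    g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    expect_equal(unname(pagerank(g, 0.85)),
                 unname(oracle_pagerank(A, 0.85)),
                 tolerance = 1e-9, info = paste("seed", seed))
  }
})
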