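# Simplex-lattice enumeration, weighted FBA, flux-sum minimization,
# deduplication, and essentiality.

test_that("lattice counts follow stars-and-bars for q <= 5, m <= 6", {
  for (q in 2:5) for (m in 1:6) {
    W <- simplex_lattice(q, m)
    expect_identical(nrow(W), as.integer(choose(q + m - 1, m)))
    expect_equal(rowSums(W), rep(1, nrow(W)))
    expect_true(all(abs(W * m - round(W * m)) < 1e-12))
    expect_false(any(duplicated(W)))
  }
})

test_that("the {3,4} design has 15 vectors including the named points", {
  W <- simplex_lattice(3, 4)
  expect_identical(nrow(W), 15L)
  has_row <- function(w) any(apply(W, 1, function(x)
    isTRUE(all.equal(unname(x), w))))
  expect_true(has_row(c(1, 0, 0)))
  expect_true(has_row(c(0, 1, 0)))
  expect_true(has_row(c(0, 0, 1)))
  expect_true(has_row(c(0.25, 0.25, 0.50)))
  expect_identical(nrow(simplex_lattice(2, 2)), 3L)
  expect_equal(unname(simplex_lattice(2, 2)),
               rbind(c(1, 0), c(0.5, 0.5), c(0, 1)))
})

test_that("weighted FBA solves the hand LP and is self-consistent", {
  m <- design_model()
  s <- solve_weighted_fba(m, c(1, 0, 0))
  expect_equal(s$objective_value, 10)    # biomass bounded by uptake
  expect_equal(s$v[match("biomass", m$reaction_ids)], 10)
  # any w: objective equals w . (v_biomass, v_atp, v_pi4p)
  for (w in list(c(0.5, 0.25, 0.25), c(0, 1, 0), c(0.25, 0.25, 0.5))) {
    sw <- solve_weighted_fba(m, w)
    comp <- sw$v[match(c("biomass", "atp_sink", "pi4p_sink"),
                       m$reaction_ids)]
    expect_equal(sw$objective_value, sum(w * comp), tolerance = 1e-8)
    # steady state and oxygen cap hold
    expect_lt(max(abs(as.numeric(as.matrix(m$S) %*% sw$v))), 1e-6)
    expect_lte(sw$v[match("EX_o2", m$reaction_ids)], 2 + 1e-8)
  }
})

test_that("a model without a PI4P route still solves with objective 0", {
  m <- design_model(pi4p_ub = 0)
  s <- solve_weighted_fba(m, c(0, 0, 1))
  expect_equal(s$objective_value, 0)
})

test_that("scalarization is monotone in the biomass component", {
  m <- design_model()
  best <- solve_weighted_fba(m, c(1, 0, 0))
  bio <- match("biomass", m$reaction_ids)
  for (w in list(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5), c(0, 0.5, 0.5))) {
    sw <- solve_weighted_fba(m, w)
    expect_lte(sw$v[bio], best$objective_value + 1e-8)
  }
})

test_that("min-total-flux fixes biomass and matches the chain hand LP", {
  m <- chain_model(3)
  m$objective_tags <- c(biomass = "biomass", atp = "biomass",
                        pi4p = "biomass")
  s <- solve_min_total_flux(m)
  # 4 reactions each carrying the fixed biomass optimum of 10
  expect_equal(s$objective_value, 40)
  expect_equal(unname(s$v), rep(10, 4))
  expect_identical(s$label, "min_total_flux")
})

test_that("min-total-flux silences loops and undercuts the plain optimum", {
  # chain plus a feasible 2-cycle not needed for biomass
  mets <- c("A", "B")
  rxns <- c("EX_in", "r1", "biomass", "loop_f", "loop_b")
  S <- matrix(0, 2, 5, dimnames = list(mets, rxns))
  S["A", "EX_in"] <- 1
  S["A", "r1"] <- -1; S["B", "r1"] <- 1
  S["B", "biomass"] <- -1
  S["A", "loop_f"] <- -1; S["B", "loop_f"] <- 1
  S["A", "loop_b"] <- 1; S["B", "loop_b"] <- -1
  m <- metabolic_model(mets, rxns, S, rep(0, 5), rep(10, 5),
                       objective_tags = c(biomass = "biomass",
                                          atp = "biomass",
                                          pi4p = "biomass"))
  s <- solve_min_total_flux(m)
  expect_equal(s$v[match("loop_f", rxns)], 0)
  expect_equal(s$v[match("loop_b", rxns)], 0)
  plain <- solve_weighted_fba(m, c(1, 0, 0))
  expect_lte(sum(abs(s$v)), sum(abs(plain$v)) + 1e-8)
})

test_that("the full design yields 16 labeled feasible tests", {
  m <- design_model()
  sols <- run_design(m)
  expect_length(sols, 16L)
  expect_true("min_total_flux" %in% names(sols))
  expect_true(all(c("w_1.00_0.00_0.00", "w_0.00_1.00_0.00",
                    "w_0.00_0.00_1.00") %in% names(sols)))
  for (s in sols) {
    expect_lt(max(abs(as.numeric(as.matrix(m$S) %*% s$v))), 1e-6)
    expect_lte(s$v[match("EX_o2", m$reaction_ids)], 2 + 1e-8)
  }
})

test_that("deduplication keeps one of identical and all of distinct", {
  rid <- c("a", "b")
  mk <- function(v, lab) fluxtarget:::flux_distribution(rid, v, 1, lab)
  same <- lapply(1:16, function(i) mk(c(1, 2), paste0("t", i)))
  expect_length(deduplicate_solutions(same, 1e-6), 1L)
  distinct <- list(mk(c(1, 2), "t1"), mk(c(1, 2 + 1e-9), "t2"))
  expect_length(deduplicate_solutions(distinct, 0), 2L)
  expect_length(deduplicate_solutions(distinct, 1e-6), 1L)
  dup <- attr(deduplicate_solutions(distinct, 1e-6), "duplicate_of")
  expect_identical(unname(dup["t2"]), "t1")
  expect_error(deduplicate_solutions(list(mk(c(1, 2), "t1"),
                                          fluxtarget:::flux_distribution(
                                            c("a", "c"), c(1, 2), 1, "t2"))),
               "different reaction sets")
})

test_that("design tests with coinciding optima collapse under dedup", {
  # no ATP/PI4P capacity: every weighting shares the biomass-only optimum
  m <- design_model(atp_ub = 0, pi4p_ub = 0)
  sols <- run_design(m)
  kept <- deduplicate_solutions(sols, 1e-6)
  expect_lt(length(kept), 16L)
})

test_that("essentiality matches the brute-force knockout loop", {
  cfg <- analysis_config()
  # single linear path: every reaction essential at a 100% drop
  m <- chain_model(3)
  ess <- essential_reactions(m, cfg)
  expect_identical(sort(as.character(ess)), sort(m$reaction_ids))
  expect_equal(unname(attr(ess, "drop")), rep(1, 4))

  # redundant parallel paths: neither branch essential
  mp <- parallel_model()
  essp <- essential_reactions(mp, cfg)
  expect_false("p1" %in% essp)
  expect_false("p2" %in% essp)
  expect_true(all(c("EX_in", "biomass") %in% essp))

  # independent brute-force loop on the design model
  md <- design_model()
  essd <- essential_reactions(md, cfg)
  mdc <- fluxtarget:::apply_oxygen_cap(md, cfg)
  obj <- as.numeric(md$reaction_ids == "biomass")
  base <- fluxtarget:::fba_optimize(mdc, obj, TRUE)$value
  for (j in seq_along(md$reaction_ids)) {
    mk <- mdc
    mk$lower_bound[j] <- mk$upper_bound[j] <- 0
    res <- fluxtarget:::fba_optimize(mk, obj, TRUE)
    ko <- if (res$status == "optimal") res$value else 0
    expect_identical(md$reaction_ids[j] %in% essd,
                     (base - ko) / base >= cfg$essentiality_drop,
                     info = md$reaction_ids[j])
  }
})

test_that("essentiality is undefined for a zero baseline", {
  m <- chain_model(3)
  m$upper_bound[1] <- 0
  expect_error(essential_reactions(m), "not positive")
})
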