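# Synthetic fixtures: toy metabolic models with planted choke-point motifs
# and expression datasets with planted clusters and upregulated genes, so
# that every pipeline stage can be exercised against known ground truth.

#' Specification of a synthetic fixture
#'
#' The generated model is a carbon backbone fed by one exchange
#' (`EX_in`, 10 mmol/gDW/h) and drained by a biomass sink, with planted
#' motif blocks spliced in series: linear chain reactions, redundant
#' parallel pairs, and the five choke-point motif shapes (`none`,
#' `single_consuming`, `single_producing`, `double`, `extended`). Capacity
#' limits inside the motif blocks force every planted reaction to be active
#' at any biomass optimum, so the planted classes are realized by the
#' designed forward flux direction. ATP (oxygen-coupled) and PI4P branches
#' plus an oxygen exchange support the three-objective design. Tumor
#' expression is drawn from two planted binary activity profiles; planted
#' upregulated genes get a mean shift of `effect_size` log2 units over
#' normal tissue. `noise_sigma` is the per-entry multiplicative log-normal
#' sigma; the default 0 emulates the idealized noiseless limit in which the
#' mean-based binarization is exact (see the package vignette for why any
#' i.i.d. noise makes a gene-local mean threshold split uniformly active
#' genes).
#'
#' @param n_linear_chains Number of plain chain reactions in the backbone.
#' @param n_parallel_motifs Number of fully redundant parallel pairs
#'   (planted non-essential reactions).
#' @param motifs Named counts for the five planted motif types.
#' @param n_genes Total gene universe (filler genes beyond the model's).
#' @param n_tumor_samples,n_normal_samples Cohort sizes.
#' @param upregulated_fraction Fraction of the gene universe planted as
#'   tumor-upregulated (always includes the target genes).
#' @param effect_size Planted tumor/normal shift in log2 units.
#' @param noise_sigma Log-normal noise sigma (0 = deterministic values).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_linear_chains = 2L,
                         n_parallel_motifs = 1L,
                         motifs = c(none = 1L, single_consuming = 1L,
                                    single_producing = 1L, double = 1L,
                                    extended = 2L),
                         n_genes = 60L,
                         n_tumor_samples = 30L,
                         n_normal_samples = 15L,
                         upregulated_fraction = 0.2,
                         effect_size = 2.5,
                         noise_sigma = 0,
                         seed = 1L) {
  full <- c(none = 0L, single_consuming = 0L, single_producing = 0L,
            double = 0L, extended = 0L)
  full[names(motifs)] <- as.integer(motifs)
  spec <- list(n_linear_chains = as.integer(n_linear_chains),
               n_parallel_motifs = as.integer(n_parallel_motifs),
               motifs = full,
               n_genes = as.integer(n_genes),
               n_tumor_samples = as.integer(n_tumor_samples),
               n_normal_samples = as.integer(n_normal_samples),
               upregulated_fraction = upregulated_fraction,
               effect_size = effect_size,
               noise_sigma = noise_sigma,
               seed = as.integer(seed))
  stopifnot(all(unlist(spec[1:2]) >= 0), all(spec$motifs >= 0),
            spec$n_genes > 0, spec$n_tumor_samples >= 4,
            spec$n_normal_samples >= 2, spec$noise_sigma >= 0,
            spec$effect_size > 0)
  structure(spec, class = "fixture_spec")
}

# internal accumulator for model assembly
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$rxns <- list()
  env$truth <- list()
  env$gene_i <- 0L
  env
}

next_gene <- function(bld) {
  bld$gene_i <- bld$gene_i + 1L
  sprintf("g%04d", bld$gene_i)
}

add_rxn <- function(bld, id, mets, lb = 0, ub = 1000, gpr = "",
                    planted_class = NA_character_, essential = NA,
                    is_target = FALSE) {
  bld$rxns[[id]] <- list(id = id, mets = mets, lb = lb, ub = ub, gpr = gpr)
  bld$truth[[id]] <- data.frame(
    reaction_id = id, planted_class = planted_class, essential = essential,
    gpr = gpr, is_target = is_target, stringsAsFactors = FALSE)
  invisible(bld)
}

# each motif block consumes `inm` and produces `outm`, conserving the
# backbone flux of 10 so the biomass optimum stays pinned at the uptake
# bound regardless of block order
add_block <- function(bld, type, k, inm, outm, with_or_gene) {
  px <- sprintf("b%02d_%s", k, substr(type, 1, 4))
  met <- function(s) paste0(px, "_", s)
  g <- function(target = FALSE) next_gene(bld)
  rule <- function(gene, j) {
    # every third internal reaction gets an isozyme (OR) partner gene
    if (with_or_gene && j %% 3L == 0L) paste(gene, "or", next_gene(bld))
    else gene
  }
  if (type == "chain") {
    add_rxn(bld, paste0(px, "_chain"), c(stats::setNames(-1, inm),
                                         stats::setNames(1, outm)),
            ub = 1000, gpr = rule(g(), k), essential = TRUE)
  } else if (type == "parallel") {
    add_rxn(bld, paste0(px, "_a"), c(stats::setNames(-1, inm),
                                     stats::setNames(1, outm)),
            ub = 1000, gpr = g(), essential = FALSE)
    add_rxn(bld, paste0(px, "_b"), c(stats::setNames(-1, inm),
                                     stats::setNames(1, outm)),
            ub = 1000, gpr = g(), essential = FALSE)
  } else if (type == "none") {
    x <- met("X")
    add_rxn(bld, paste0(px, "_p1"), c(stats::setNames(-1, inm),
                                      stats::setNames(1, x)),
            ub = 6, gpr = rule(g(), 1L))
    add_rxn(bld, paste0(px, "_p2"), c(stats::setNames(-1, inm),
                                      stats::setNames(1, x)),
            ub = 6, gpr = rule(g(), 2L))
    add_rxn(bld, paste0(px, "_focal"), c(stats::setNames(-1, x),
                                         stats::setNames(1, outm)),
            ub = 6, gpr = g(), planted_class = "none", essential = TRUE)
    add_rxn(bld, paste0(px, "_c2"), c(stats::setNames(-1, x),
                                      stats::setNames(1, outm)),
            ub = 6, gpr = rule(g(), 3L))
  } else if (type == "single_consuming") {
    x <- met("X")
    add_rxn(bld, paste0(px, "_a1"), c(stats::setNames(-1, inm),
                                      stats::setNames(1, x)),
            ub = 4, gpr = rule(g(), 1L))
    add_rxn(bld, paste0(px, "_a2"), c(stats::setNames(-1, inm),
                                      stats::setNames(1, x)),
            ub = 4, gpr = rule(g(), 2L))
    add_rxn(bld, paste0(px, "_focal"), c(stats::setNames(-1, x),
                                         stats::setNames(1, outm)),
            ub = 1000, gpr = g(), planted_class = "single_consuming",
            essential = TRUE)
    add_rxn(bld, paste0(px, "_d"), c(stats::setNames(-1, inm),
                                     stats::setNames(1, outm)),
            ub = 2, gpr = rule(g(), 3L))
  } else if (type == "single_producing") {
    x <- met("X")
    add_rxn(bld, paste0(px, "_focal"), c(stats::setNames(-1, inm),
                                         stats::setNames(1, x)),
            ub = 1000, gpr = g(), planted_class = "single_producing",
            essential = TRUE)
    add_rxn(bld, paste0(px, "_c1"), c(stats::setNames(-1, x),
                                      stats::setNames(1, outm)),
            ub = 4, gpr = rule(g(), 1L))
    add_rxn(bld, paste0(px, "_c2"), c(stats::setNames(-1, x),
                                      stats::setNames(1, outm)),
            ub = 4, gpr = rule(g(), 2L))
    add_rxn(bld, paste0(px, "_d"), c(stats::setNames(-1, inm),
                                     stats::setNames(1, outm)),
            ub = 2, gpr = rule(g(), 3L))
  } else if (type == "double") {
    m1 <- met("m1"); m2 <- met("m2"); m3 <- met("m3")
    # p co-produces a byproduct m3 that is also made by q: the upstream
    # producer of m1 is therefore NOT a strict single producer, which
    # keeps the focal reaction a double (not extended) choke point
    add_rxn(bld, paste0(px, "_p"), c(stats::setNames(-1, inm),
                                     stats::setNames(1, m1),
                                     stats::setNames(1, m3)),
            ub = 6, gpr = rule(g(), 1L))
    add_rxn(bld, paste0(px, "_q"), c(stats::setNames(-1, inm),
                                     stats::setNames(1, outm),
                                     stats::setNames(1, m3)),
            ub = 6, gpr = rule(g(), 2L))
    add_rxn(bld, paste0(px, "_focal"), c(stats::setNames(-1, m1),
                                         stats::setNames(1, m2)),
            ub = 1000, gpr = g(), planted_class = "double", essential = TRUE)
    add_rxn(bld, paste0(px, "_e"), stats::setNames(-1, m3),
            ub = 1000, gpr = rule(g(), 3L))
    add_rxn(bld, paste0(px, "_f"), c(stats::setNames(-1, m2),
                                     stats::setNames(1, outm)),
            ub = 1000, gpr = rule(g(), 4L))
  } else if (type == "extended") {
    m1 <- met("m1"); m2 <- met("m2")
    add_rxn(bld, paste0(px, "_p"), c(stats::setNames(-1, inm),
                                     stats::setNames(1, m1)),
            ub = 8, gpr = g())
    tgt <- next_gene(bld)
    add_rxn(bld, paste0(px, "_focal"), c(stats::setNames(-1, m1),
                                         stats::setNames(1, m2)),
            ub = 1000, gpr = tgt, planted_class = "extended",
            essential = TRUE, is_target = TRUE)
    add_rxn(bld, paste0(px, "_f"), c(stats::setNames(-1, m2),
                                     stats::setNames(1, outm)),
            ub = 1000, gpr = g())
    add_rxn(bld, paste0(px, "_d"), c(stats::setNames(-1, inm),
                                     stats::setNames(1, outm)),
            ub = 2, gpr = g())
  } else stop("unknown block type: ", type)
  invisible(bld)
}

#' Generate a toy metabolic model with planted ground truth
#'
#' See [fixture_spec()] for the construction. The returned truth table
#' records, for the designed forward (biomass-maximizing) flux direction,
#' each planted focal reaction's intended choke-point class, the designed
#' essentiality of chain/parallel/focal reactions (`NA` where no claim is
#' made), the GPR, and whether the reaction carries a planted target gene
#' (the extended-choke-point focal reactions).
#'
#' @param spec A `fixture_spec`.
#' @return List with elements `model` (a [metabolic_model()]), `truth`
#'   (per-reaction data.frame) and `target_genes` (character).
#' @export
generate_toy_model <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  bld <- new_builder()
  # deterministic block order: the five motif types, parallels, chains
  blocks <- c(rep("none", spec$motifs[["none"]]),
              rep("single_consuming", spec$motifs[["single_consuming"]]),
              rep("single_producing", spec$motifs[["single_producing"]]),
              rep("double", spec$motifs[["double"]]),
              rep("extended", spec$motifs[["extended"]]),
              rep("parallel", spec$n_parallel_motifs),
              rep("chain", spec$n_linear_chains))
  add_rxn(bld, "EX_in", stats::setNames(1, "C00"), ub = 10,
          essential = TRUE)
  cur <- "C00"
  for (k in seq_along(blocks)) {
    nxt <- sprintf("C%02d", k)
    add_block(bld, blocks[k], k, cur, nxt, with_or_gene = TRUE)
    cur <- nxt
  }
  # objective branches off the final backbone metabolite
  add_rxn(bld, "EX_o2", stats::setNames(1, "O2"), ub = 1000,
          essential = FALSE)
  add_rxn(bld, "atp_syn", c(stats::setNames(-1, cur),
                            stats::setNames(-2, "O2"),
                            stats::setNames(2, "ATP")),
          ub = 1000, gpr = next_gene(bld), essential = FALSE)
  add_rxn(bld, "atp_sink", stats::setNames(-1, "ATP"), ub = 1000,
          essential = FALSE)
  add_rxn(bld, "pi4p_syn", c(stats::setNames(-1, cur),
                             stats::setNames(1, "PI4P")),
          ub = 4, gpr = next_gene(bld), essential = FALSE)
  add_rxn(bld, "pi4p_sink", stats::setNames(-1, "PI4P"), ub = 1000,
          essential = FALSE)
  add_rxn(bld, "biomass", stats::setNames(-1, cur), ub = 1000,
          essential = TRUE)

  rxns <- bld$rxns
  mids <- unique(unlist(lapply(rxns, function(r) names(r$mets))))
  S <- matrix(0, nrow = length(mids), ncol = length(rxns),
              dimnames = list(mids, names(rxns)))
  for (j in seq_along(rxns)) S[names(rxns[[j]]$mets), j] <- rxns[[j]]$mets
  model <- metabolic_model(
    metabolite_ids = mids,
    reaction_ids = names(rxns),
    S = S,
    lower_bound = vapply(rxns, `[[`, numeric(1), "lb"),
    upper_bound = vapply(rxns, `[[`, numeric(1), "ub"),
    gpr = vapply(rxns, `[[`, character(1), "gpr"),
    objective_tags = c(biomass = "biomass", atp = "atp_sink",
                       pi4p = "pi4p_sink", oxygen_uptake = "EX_o2"),
    id = sprintf("synthetic_fixture_seed%d", spec$seed)
  )
  truth <- do.call(rbind, bld$truth)
  rownames(truth) <- NULL
  target_genes <- unlist(lapply(which(truth$is_target), function(i)
    gpr_genes(parse_gpr(truth$gpr[i]))))
  list(model = model, truth = truth,
       target_genes = sort(unique(target_genes)))
}

#' Generate a synthetic expression dataset with planted truth
#'
#' Tumor samples are drawn from two planted binary activity profiles
#' (alternating assignment): all model genes are active in both profiles
#' except the second reaction of each redundant parallel pair, whose gene is
#' switched off in profile B (so the two contextualized models differ);
#' filler genes are active in exactly one profile (even index in A, odd in
#' B), which separates the clusters. Active genes take value 100, inactive
#' 1, each multiplied by log-normal noise `exp(noise_sigma * Z)`. Normal
#' samples take the gene's tumor mean, divided by `2^effect_size` for the
#' planted upregulated genes (the target genes plus filler genes up to
#' `upregulated_fraction` of the universe). A planted differential table is
#' included: logFC from [logfc_table()] and p-values planted at 0 for
#' upregulated genes and 0.5 otherwise (a toy stand-in for a real
#' differential pipeline, which is out of scope).
#'
#' @param spec A `fixture_spec`.
#' @param toy Output of [generate_toy_model()] (model + truth).
#' @return List with `expression` (an [expression_matrix()]), `profiles`
#'   (genes x 2 planted binary profiles), `assignments` (planted cluster
#'   per tumor sample), `upregulated` (planted gene set), and
#'   `differential` (data.frame gene/logFC/pvalue).
#' @export
generate_expression <- function(spec = fixture_spec(),
                                toy = generate_toy_model(spec)) {
  stopifnot(inherits(spec, "fixture_spec"))
  model <- toy$model
  n_model <- length(model$gene_ids)
  n_genes <- max(spec$n_genes, n_model)
  genes <- sprintf("g%04d", seq_len(n_genes))
  stopifnot(all(model$gene_ids %in% genes))
  filler <- setdiff(genes, model$gene_ids)

  # genes of the "_b" reaction of each parallel pair are off in profile B
  par_b <- grepl("_para_b$", toy$truth$reaction_id)
  toggled <- unique(unlist(lapply(toy$truth$gpr[par_b], function(r)
    gpr_genes(parse_gpr(r)))))

  profA <- stats::setNames(rep(0L, n_genes), genes)
  profB <- profA
  profA[model$gene_ids] <- 1L
  profB[model$gene_ids] <- 1L
  profB[toggled] <- 0L
  fi <- seq_along(filler)
  profA[filler[fi %% 2L == 0L]] <- 1L
  profB[filler[fi %% 2L == 1L]] <- 1L
  profiles <- cbind(A = profA, B = profB)

  set.seed(spec$seed)
  nT <- spec$n_tumor_samples
  assignments <- rep(c("A", "B"), length.out = nT)
  tum_base <- ifelse(profiles[, assignments] == 1L, 100, 1)
  noise <- function(n) exp(spec$noise_sigma * stats::rnorm(n))
  tum <- tum_base * matrix(noise(n_genes * nT), n_genes, nT)
  colnames(tum) <- sprintf("T%03d", seq_len(nT))
  rownames(tum) <- genes

  n_up <- max(length(toy$target_genes),
              round(spec$upregulated_fraction * n_genes))
  upregulated <- unique(c(toy$target_genes,
                          filler[seq_len(min(length(filler),
                                             n_up - length(toy$target_genes)))]))
  nN <- spec$n_normal_samples
  tum_mean <- rowMeans(tum)
  nor_base <- ifelse(genes %in% upregulated,
                     tum_mean / 2^spec$effect_size, tum_mean)
  nor <- nor_base * matrix(noise(n_genes * nN), n_genes, nN)
  colnames(nor) <- sprintf("N%03d", seq_len(nN))
  rownames(nor) <- genes

  E <- expression_matrix(cbind(tum, nor),
                         c(rep("tumor", nT), rep("normal", nN)))
  diff_tbl <- logfc_table(E)
  diff_tbl$pvalue <- ifelse(diff_tbl$gene %in% upregulated, 0, 0.5)
  list(expression = E, profiles = profiles,
       assignments = stats::setNames(assignments, colnames(tum)),
       upregulated = sort(upregulated), differential = diff_tbl)
}

#' Generate a planted chemical-gene interaction table
#'
#' Plants one multi-target chemical hitting the first two target genes
#' (`drug_multi`), one single-target chemical (`drug_single`), a dedicated
#' direct inhibitor per target gene (`cpd_<gene>`), and an off-target
#' chemical hitting only filler genes (`drug_offtarget`), so that the
#' expected relevance ranking is known by construction.
#'
#' @param toy Output of [generate_toy_model()].
#' @param expr Output of [generate_expression()].
#' @return data.frame with columns `chemical`, `gene`, `interaction_type`,
#'   `source`.
#' @export
generate_interactions <- function(toy, expr) {
  tg <- toy$target_genes
  stopifnot(length(tg) >= 1L)
  non_scored <- setdiff(expr$upregulated, c(tg, toy$model$gene_ids))
  if (length(non_scored) < 2L)
    non_scored <- c(non_scored, "g9998", "g9999")
  rows <- list(
    data.frame(chemical = "drug_multi", gene = tg[seq_len(min(2, length(tg)))],
               interaction_type = "expression_decrease",
               source = "synthetic_db", stringsAsFactors = FALSE),
    data.frame(chemical = "drug_single", gene = tg[1],
               interaction_type = "direct", source = "synthetic_db",
               stringsAsFactors = FALSE),
    data.frame(chemical = paste0("cpd_", tg), gene = tg,
               interaction_type = "direct", source = "synthetic_db",
               stringsAsFactors = FALSE),
    data.frame(chemical = "drug_offtarget", gene = non_scored[1:2],
               interaction_type = "predicted", source = "synthetic_db",
               stringsAsFactors = FALSE)
  )
  do.call(rbind, rows)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the same plain-text formats the pipeline reads: `model.json`,
#' `expression.tsv`, `cohorts.tsv`, `differential.tsv`,
#' `interactions.tsv`, plus `gene_manifest.tsv` (gene to reaction map) and
#' `reaction_truth.tsv` for test introspection.
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
write_fixture <- function(spec = fixture_spec(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  toy <- generate_toy_model(spec)
  expr <- generate_expression(spec, toy)
  inter <- generate_interactions(toy, expr)
  paths <- list(
    model = file.path(dir, "model.json"),
    expression = file.path(dir, "expression.tsv"),
    cohorts = file.path(dir, "cohorts.tsv"),
    differential = file.path(dir, "differential.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    gene_manifest = file.path(dir, "gene_manifest.tsv"),
    reaction_truth = file.path(dir, "reaction_truth.tsv")
  )
  write_model_json(toy$model, paths$model)
  write_expression(expr$expression, paths$expression, paths$cohorts)
  write_tsv(expr$differential, paths$differential)
  write_tsv(inter, paths$interactions)
  manifest <- do.call(rbind, lapply(seq_along(toy$model$reaction_ids),
    function(j) {
      g <- gpr_genes(toy$model$gpr_ast[[j]])
      if (!length(g)) return(NULL)
      data.frame(gene = g, reaction_id = toy$model$reaction_ids[j],
                 stringsAsFactors = FALSE)
    }))
  write_tsv(manifest, paths$gene_manifest)
  write_tsv(toy$truth, paths$reaction_truth)
  invisible(list(spec = spec, toy = toy, expr = expr,
                 interactions = inter, paths = paths))
}
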