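# End-to-end orchestration: expression -> medoids -> contextualized models
# -> FBA design -> topology -> prioritization -> drug ranking.

#' Analyze one contextualized model
#'
#' Runs the 16-test objective design, deduplicates the optima, reduces the
#' network per non-redundant optimum, classifies choke points, computes
#' reaction PageRank, scores reactions, and screens essentiality.
#'
#' @param model A contextualized (flux-consistent) `metabolic_model` with
#'   objective tags.
#' @param cfg An [analysis_config()].
#' @return List with `solutions` (all 16), `nonredundant`, per-solution
#'   `classifications` and `centralities`, `scores` (from
#'   [score_reactions()]) and `essential`.
#' @export
analyze_model <- function(model, cfg = analysis_config()) {
  solutions <- run_design(model, cfg)
  nonred <- deduplicate_solutions(solutions, cfg$dedup_tol)
  nets <- lapply(nonred, function(s) reduce_network(model, s, cfg$flux_tol))
  keep <- vapply(nets, function(n) length(n$reaction_ids) > 0, logical(1))
  classifications <- lapply(nets[keep], classify_choke_points, cfg = cfg)
  centralities <- lapply(nets[keep], function(n)
    pagerank(build_reaction_graph(n), damping = cfg$damping))
  scores <- score_reactions(classifications, centralities, cfg,
                            reaction_ids = model$reaction_ids)
  essential <- essential_reactions(model, cfg)
  list(solutions = solutions, nonredundant = nonred,
       classifications = classifications, centralities = centralities,
       scores = scores, essential = essential)
}

#' Run the full target-prioritization pipeline
#'
#' The complete workflow: binarize tumor expression, pick the cluster count
#' by silhouette (unless `k` is fixed), cluster with PAM, contextualize the
#' flux-consistent model with each medoid, analyze every contextualized
#' model ([analyze_model()]), combine the per-medoid reaction scores,
#' intersect with essentiality and tumor upregulation, and rank genes and
#' chemicals.
#'
#' @param model A `metabolic_model` with objective tags (the generic model;
#'   it is made flux-consistent internally).
#' @param expression An [expression_matrix()].
#' @param differential data.frame with `gene`, `logFC`, `pvalue`.
#' @param interactions data.frame with `chemical`, `gene` (may be `NULL` to
#'   skip the drug ranking).
#' @param cfg An [analysis_config()].
#' @param seed Integer seed (clustering interface).
#' @param k Fixed number of clusters, or `NULL` to select by silhouette
#'   over `k_range`.
#' @param k_range Candidate cluster counts for the silhouette search.
#' @param outdir Optional directory; when given, the stage outputs are
#'   written as deterministic TSVs (`reaction_scores.tsv`,
#'   `reactions_of_interest.tsv`, `gene_scores.tsv`, `drug_ranking.tsv`,
#'   per-medoid flux tables, choke-point and centrality reports).
#' @return List with all intermediate and final results (see details in the
#'   vignette); key elements: `k`, `medoids`, `per_medoid`, `combined`,
#'   `essential`, `upregulated`, `roi`, `genes`, `drugs`.
#' @export
run_pipeline <- function(model, expression, differential,
                         interactions = NULL, cfg = analysis_config(),
                         seed = 1L, k = NULL, k_range = 2:4,
                         outdir = NULL) {
  consistent <- find_flux_consistent_subnetwork(model, cfg$flux_tol)
  signatures <- binarize(expression, cfg)
  if (is.null(k)) {
    k_range <- k_range[k_range < ncol(signatures)]
    k <- as.integer(select_k_silhouette(signatures, k_range, seed, cfg))
  }
  clust <- pam_cluster(signatures, k, seed, cfg)
  medoid_states <- lapply(seq_len(k), function(i) clust$medoids[, i])
  names(medoid_states) <- colnames(clust$medoids)

  per_medoid <- lapply(medoid_states, function(med) {
    ctx <- contextualize(consistent, med, cfg)
    c(list(model = ctx), analyze_model(ctx, cfg))
  })

  combined <- per_medoid[[1]]$scores
  if (k > 1L)
    for (i in 2:k) combined <- combine_medoids(combined,
                                               per_medoid[[i]]$scores)
  essential <- sort(unique(unlist(lapply(per_medoid, `[[`, "essential"))))
  upregulated <- flag_upregulated(differential, cfg)
  roi <- reactions_of_interest(combined, essential, upregulated, model)
  genes <- gene_scores(roi, combined, model)
  drugs <- if (!is.null(interactions)) drug_relevance(interactions, genes)
           else NULL

  res <- list(cfg = cfg, seed = seed, k = k,
              consistent_model = consistent, signatures = signatures,
              clustering = clust, per_medoid = per_medoid,
              combined = combined, essential = essential,
              upregulated = upregulated, roi = roi, genes = genes,
              drugs = drugs)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_tsv(res$combined, p("reaction_scores.tsv"))
  write_tsv(data.frame(reaction_id = res$roi, stringsAsFactors = FALSE),
            p("reactions_of_interest.tsv"))
  write_tsv(res$genes, p("gene_scores.tsv"))
  if (!is.null(res$drugs)) write_tsv(res$drugs, p("drug_ranking.tsv"))
  write_tsv(data.frame(gene = res$upregulated, stringsAsFactors = FALSE),
            p("upregulated_genes.tsv"))
  write_tsv(data.frame(reaction_id = res$essential,
                       stringsAsFactors = FALSE),
            p("essential_reactions.tsv"))
  for (mn in names(res$per_medoid)) {
    pm <- res$per_medoid[[mn]]
    write_tsv(flux_table(pm$solutions), p(sprintf("fluxes_%s.tsv", mn)))
    cls <- do.call(rbind, lapply(names(pm$classifications), function(lab) {
      df <- pm$classifications[[lab]]
      cbind(test_label = lab, df)
    }))
    if (!is.null(cls)) write_tsv(cls, p(sprintf("chokepoints_%s.tsv", mn)))
    cen <- do.call(rbind, lapply(names(pm$centralities), function(lab) {
      ce <- pm$centralities[[lab]]
      data.frame(test_label = lab, reaction_id = names(ce),
                 score = as.numeric(ce), stringsAsFactors = FALSE)
    }))
    if (!is.null(cen)) write_tsv(cen, p(sprintf("centrality_%s.tsv", mn)))
  }
  invisible(outdir)
}
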