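# Aggregation of per-optimum topology into reaction, gene, and chemical
# rankings.

#' Score reactions by occurrence and summed centrality
#'
#' For one contextualized model: `occurrence` counts the non-redundant
#' optima in which the reaction is classified as an extended choke point;
#' `centrality` sums its PageRank score over the optima (0 when inactive).
#' A reaction is occurrence-selected when
#' `occurrence >= ceiling(occurrence_fraction * n_solutions)` ("at least
#' half" by default) and topology-selected when it ranks within the top
#' `floor(centrality_top_fraction * n_ranked)` reactions by summed
#' centrality, with ties at the cutoff included.
#'
#' @param classifications List of data.frames from
#'   [classify_choke_points()], one per non-redundant optimum.
#' @param centralities List of named numeric vectors from [pagerank()],
#'   aligned with `classifications`.
#' @param cfg An [analysis_config()].
#' @param reaction_ids Optional universe of reactions; defaults to the union
#'   seen across solutions.
#' @return data.frame with columns `reaction_id`, `occurrence`,
#'   `centrality`, `is_occurrence_selected`, `is_topology_selected`, plus
#'   `n_solutions` as an attribute.
#' @export
score_reactions <- function(classifications, centralities,
                            cfg = analysis_config(), reaction_ids = NULL) {
  if (length(classifications) != length(centralities))
    stop("score_reactions: classification and centrality lists must index ",
         "the same solution set")
  n_sol <- length(classifications)
  if (!n_sol) stop("score_reactions: zero non-redundant solutions")
  if (is.null(reaction_ids)) {
    reaction_ids <- sort(unique(c(
      unlist(lapply(classifications, `[[`, "reaction_id")),
      unlist(lapply(centralities, names)))))
  }
  occurrence <- stats::setNames(integer(length(reaction_ids)), reaction_ids)
  centrality <- stats::setNames(numeric(length(reaction_ids)), reaction_ids)
  for (i in seq_len(n_sol)) {
    cl <- classifications[[i]]
    ext <- cl$reaction_id[cl$label == "extended"]
    ext <- intersect(ext, reaction_ids)
    occurrence[ext] <- occurrence[ext] + 1L
    ce <- centralities[[i]]
    common <- intersect(names(ce), reaction_ids)
    centrality[common] <- centrality[common] + ce[common]
  }
  occ_needed <- ceiling(cfg$occurrence_fraction * n_sol)
  is_occ <- occurrence >= occ_needed
  n_top <- floor(cfg$centrality_top_fraction * length(reaction_ids))
  is_top <- rep(FALSE, length(reaction_ids))
  if (n_top >= 1L) {
    cutoff <- sort(centrality, decreasing = TRUE)[n_top]
    is_top <- centrality >= cutoff & centrality > 0
  }
  out <- data.frame(reaction_id = reaction_ids,
                    occurrence = as.integer(occurrence),
                    centrality = as.numeric(centrality),
                    is_occurrence_selected = as.logical(is_occ),
                    is_topology_selected = as.logical(is_top),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_solutions") <- n_sol
  out
}

#' Combine reaction scores from two medoid models
#'
#' Occurrence and centrality are summed per reaction over the medoids where
#' the reaction is present (absent = 0); the selection flags are recomputed
#' as the OR of the per-medoid flags.
#'
#' @param scores_m1,scores_m2 data.frames from [score_reactions()].
#' @return Combined data.frame over the union of reaction sets.
#' @export
combine_medoids <- function(scores_m1, scores_m2) {
  rid <- sort(union(scores_m1$reaction_id, scores_m2$reaction_id))
  pull <- function(df, col, default) {
    v <- stats::setNames(rep(default, length(rid)), rid)
    v[df$reaction_id] <- df[[col]]
    v
  }
  data.frame(
    reaction_id = rid,
    occurrence = as.integer(pull(scores_m1, "occurrence", 0L) +
                            pull(scores_m2, "occurrence", 0L)),
    centrality = as.numeric(pull(scores_m1, "centrality", 0) +
                            pull(scores_m2, "centrality", 0)),
    is_occurrence_selected =
      as.logical(pull(scores_m1, "is_occurrence_selected", FALSE) |
                 pull(scores_m2, "is_occurrence_selected", FALSE)),
    is_topology_selected =
      as.logical(pull(scores_m1, "is_topology_selected", FALSE) |
                 pull(scores_m2, "is_topology_selected", FALSE)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Reactions of interest (Venn intersection)
#'
#' A reaction is of interest when it is (a) essential, (b) carried out by a
#' protein related to at least one tumor-upregulated gene, and (c) either
#' occurrence-selected (recurrent extended choke point) or
#' topology-selected (top-central by PageRank).
#'
#' @param scores Combined data.frame from [combine_medoids()] (or a single
#'   [score_reactions()] output).
#' @param essential Character vector of essential reaction ids (union over
#'   medoid models).
#' @param upregulated Character vector of upregulated gene ids.
#' @param model A `metabolic_model` supplying the GPRs.
#' @return Sorted character vector of reaction ids.
#' @export
reactions_of_interest <- function(scores, essential, upregulated, model) {
  gpr_hit <- vapply(scores$reaction_id, function(r) {
    j <- match(r, model$reaction_ids)
    if (is.na(j)) return(FALSE)
    length(intersect(gpr_genes(model$gpr_ast[[j]]), upregulated)) > 0
  }, logical(1))
  sel <- scores$reaction_id %in% essential &
    gpr_hit &
    (scores$is_occurrence_selected | scores$is_topology_selected)
  sort(scores$reaction_id[sel])
}

#' Gene-level occurrence and centrality scores
#'
#' Maps reaction scores onto genes: a gene's raw occurrence (centrality) is
#' the sum over the reactions of interest whose GPR references it. Each
#' component is then max-normalized to [0, 1] across genes (an all-zero
#' component stays zero), and `relevance` is the sum of the two normalized
#' components (so relevance lies in [0, 2]). Raw sums are retained
#' alongside.
#'
#' @param roi Character vector from [reactions_of_interest()].
#' @param scores Combined reaction score data.frame covering `roi`.
#' @param model A `metabolic_model` supplying the GPRs.
#' @return data.frame with columns `gene`, `occurrence_raw`,
#'   `centrality_raw`, `occurrence_norm`, `centrality_norm`, `relevance`,
#'   sorted by decreasing relevance (ties alphabetically). Empty (with a
#'   warning) when `roi` is empty.
#' @export
gene_scores <- function(roi, scores, model) {
  empty <- data.frame(gene = character(0), occurrence_raw = numeric(0),
                      centrality_raw = numeric(0),
                      occurrence_norm = numeric(0),
                      centrality_norm = numeric(0), relevance = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(roi)) {
    warning("gene_scores: no reactions of interest")
    return(empty)
  }
  sc <- scores[scores$reaction_id %in% roi, , drop = FALSE]
  genes_per_rxn <- lapply(sc$reaction_id, function(r) {
    j <- match(r, model$reaction_ids)
    if (is.na(j)) character(0) else gpr_genes(model$gpr_ast[[j]])
  })
  genes <- sort(unique(unlist(genes_per_rxn)))
  if (!length(genes)) {
    warning("gene_scores: reactions of interest carry no gene annotation")
    return(empty)
  }
  occ <- stats::setNames(numeric(length(genes)), genes)
  cen <- stats::setNames(numeric(length(genes)), genes)
  for (i in seq_along(genes_per_rxn)) {
    g <- genes_per_rxn[[i]]
    occ[g] <- occ[g] + sc$occurrence[i]
    cen[g] <- cen[g] + sc$centrality[i]
  }
  norm <- function(x) if (max(x) > 0) x / max(x) else x
  out <- data.frame(gene = genes,
                    occurrence_raw = as.numeric(occ),
                    centrality_raw = as.numeric(cen),
                    occurrence_norm = as.numeric(norm(occ)),
                    centrality_norm = as.numeric(norm(cen)),
                    stringsAsFactors = FALSE)
  out$relevance <- out$occurrence_norm + out$centrality_norm
  out[order(-out$relevance, out$gene), , drop = FALSE]
}

#' Rank chemicals by summed gene relevance
#'
#' Joins a chemical-gene interaction table (DGIdb/CTD-style snapshot)
#' against the gene scores. Each chemical's relevance is the sum, over its
#' distinct targeted genes that carry a gene score, of
#' `occurrence_norm + centrality_norm`. Interaction direction/type is
#' carried through for reporting but does not weight the score. Gene ids
#' are matched case-sensitively; rows whose gene has no score are dropped
#' (count reported via the `"n_unmatched"` attribute and a message).
#'
#' @param interactions data.frame with columns `chemical`, `gene` and
#'   optionally `interaction_type`, `source`.
#' @param genes data.frame from [gene_scores()].
#' @return data.frame with columns `chemical`, `relevance`, `n_genes`,
#'   `genes` (";"-joined sorted gene list), sorted by decreasing relevance,
#'   ties broken alphabetically by chemical.
#' @export
drug_relevance <- function(interactions, genes) {
  if (!all(c("chemical", "gene") %in% names(interactions)))
    stop("drug_relevance: interactions need 'chemical' and 'gene' columns")
  empty <- data.frame(chemical = character(0), relevance = numeric(0),
                      n_genes = integer(0), genes = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(interactions)) return(empty)
  if (any(!nzchar(interactions$gene)))
    stop("drug_relevance: empty gene id in interaction table")
  pairs <- unique(interactions[, c("chemical", "gene")])
  matched <- pairs$gene %in% genes$gene
  n_unmatched <- sum(!matched)
  if (n_unmatched)
    message("drug_relevance: dropped ", n_unmatched,
            " interaction pair(s) with unscored genes")
  pairs <- pairs[matched, , drop = FALSE]
  if (!nrow(pairs)) return(structure(empty, n_unmatched = n_unmatched))
  rel <- stats::setNames(genes$relevance, genes$gene)
  agg <- split(pairs$gene, pairs$chemical)
  out <- data.frame(
    chemical = names(agg),
    relevance = vapply(agg, function(g) sum(rel[g]), numeric(1)),
    n_genes = vapply(agg, length, integer(1)),
    genes = vapply(agg, function(g) paste(sort(g), collapse = ";"),
                   character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(-out$relevance, out$chemical), , drop = FALSE]
  structure(out, n_unmatched = n_unmatched)
}

#' Read a chemical-gene interaction table
#'
#' Tab-separated with required columns `chemical` and `gene`; optional
#' `interaction_type` (one of `direct`, `expression_increase`,
#' `expression_decrease`, `predicted`) and `source`. Exact duplicate rows
#' are rejected.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_interactions <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chemical", "gene") %in% names(tbl)))
    stop("interaction table must have 'chemical' and 'gene' columns: ", path)
  if (anyDuplicated(tbl))
    stop("interaction table has duplicate rows: ", path)
  tbl
}
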