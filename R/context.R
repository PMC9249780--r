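# Flux-consistent subnetwork extraction and expression-based
# contextualization of a generic model.

#' Extract the flux-consistent subnetwork
#'
#' Returns the maximal subnetwork in which every retained reaction can carry
#' a flux of magnitude at least `tol` in some steady-state solution
#' (`S v = 0`, bounds respected). Consistency is decided by per-reaction flux
#' variability (maximize and minimize each flux; keep the reaction if
#' `max >= tol` or `min <= -tol`); blocked reactions are removed and the test
#' is repeated on the reduced network until a fixed point, which makes the
#' operation idempotent. Metabolites left without any reaction are dropped.
#'
#' @param m A `metabolic_model`.
#' @param tol Positive flux tolerance.
#' @return A `metabolic_model` restricted to consistent reactions. If the
#'   model admits no steady state at all, an empty model is returned with a
#'   warning.
#' @export
find_flux_consistent_subnetwork <- function(m, tol = 1e-6) {
  stopifnot(tol > 0)
  cur <- m
  repeat {
    if (!length(cur$reaction_ids)) break
    fv <- flux_variability(cur)
    if (all(is.na(fv$max))) {
      warning("model admits no steady-state solution; ",
              "returning empty reaction set")
      cur <- subset_reactions(cur, character(0))
      break
    }
    keep <- !is.na(fv$max) & (fv$max >= tol | fv$min <= -tol)
    if (all(keep)) break
    cur <- subset_reactions(cur, cur$reaction_ids[keep])
  }
  cur
}

#' Contextualize a model with a binary activity signature
#'
#' Builds a condition-specific model from a flux-consistent generic model and
#' a per-gene 0/1 activity vector (typically a cluster medoid): reactions
#' whose GPR evaluates to 0 under the signature are removed (reactions with
#' no gene association are always kept), and the flux-consistent subnetwork
#' of the pruned model is extracted so that every surviving reaction can
#' still carry flux. This is a deliberately simple, fully specified
#' contract; it does not reproduce weighted core/non-core extraction schemes
#' such as FASTCORE/rFASTCORMICS.
#'
#' @param m A flux-consistent `metabolic_model`.
#' @param medoid Named 0/1 vector over gene ids (a column of the matrix
#'   returned by [binarize()], or any named vector).
#' @param cfg An [analysis_config()]; uses `flux_tol` and the `missing_gene`
#'   policy.
#' @return A `metabolic_model`; attribute `"provenance"` is a data.frame
#'   recording each removed reaction and the reason
#'   (`gpr_inactive` or `inconsistent`). A warning is raised if the tagged
#'   biomass reaction does not survive.
#' @export
contextualize <- function(m, medoid, cfg = analysis_config()) {
  states <- unlist(medoid)
  if (is.null(names(states)))
    stop("contextualize: medoid must be a named 0/1 vector over genes")
  active <- vapply(seq_along(m$reaction_ids), function(j) {
    evaluate_gpr(m$gpr_ast[[j]], states, missing = cfg$missing_gene) == 1L
  }, logical(1))
  pruned <- subset_reactions(m, m$reaction_ids[active])
  out <- find_flux_consistent_subnetwork(pruned, tol = cfg$flux_tol)
  removed_gpr <- setdiff(m$reaction_ids, pruned$reaction_ids)
  removed_cons <- setdiff(pruned$reaction_ids, out$reaction_ids)
  prov <- data.frame(
    reaction_id = c(removed_gpr, removed_cons),
    reason = c(rep("gpr_inactive", length(removed_gpr)),
               rep("inconsistent", length(removed_cons))),
    stringsAsFactors = FALSE
  )
  if ("biomass" %in% names(m$objective_tags) &&
      !m$objective_tags[["biomass"]] %in% out$reaction_ids)
    warning("contextualize: biomass reaction '",
            m$objective_tags[["biomass"]],
            "' is not flux-consistent in the contextualized model; ",
            "growth objectives will be infeasible")
  attr(out, "provenance") <- prov
  out
}
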