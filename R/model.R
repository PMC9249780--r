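# Genome-scale metabolic model container and validation.
#
# Direction convention (inherited by every downstream module): column j of S
# consumes metabolites with S[i,j] < 0 and produces those with S[i,j] > 0 when
# the flux v_j > 0; negative flux reverses the roles.

#' Construct a metabolic model
#'
#' A genome-scale metabolic model (GSM): a stoichiometric matrix S (rows =
#' metabolites, columns = reactions), per-reaction flux bounds in mmol/gDW/h,
#' gene-protein-reaction rules, and a tag map naming the reactions that play
#' the objective roles (`biomass`, `atp`, `pi4p`) and the oxygen exchange
#' (`oxygen_uptake`).
#'
#' @param metabolite_ids,reaction_ids Unique character vectors.
#' @param S Numeric matrix (or Matrix) with `length(metabolite_ids)` rows and
#'   `length(reaction_ids)` columns.
#' @param lower_bound,upper_bound Per-reaction flux bounds.
#' @param gpr Character vector of GPR rule strings (`""` = no gene
#'   association), recycled if length 1.
#' @param gene_ids Optional character vector; defaults to the union of genes
#'   referenced by the GPRs. Every GPR gene must be included.
#' @param objective_tags Named character vector mapping roles (subset of
#'   `biomass`, `atp`, `pi4p`, `oxygen_uptake`) to reaction ids.
#' @param id Model identifier string.
#' @return Object of class `metabolic_model`.
#' @examples
#' m <- metabolic_model(
#'   metabolite_ids = c("A", "B"),
#'   reaction_ids = c("EX_A", "R1", "DM_B"),
#'   S = cbind(c(1, 0), c(-1, 1), c(0, -1)),
#'   lower_bound = c(0, 0, 0), upper_bound = c(10, 10, 10),
#'   gpr = c("", "g1 or g2", ""),
#'   objective_tags = c(biomass = "DM_B")
#' )
#' @export
metabolic_model <- function(metabolite_ids, reaction_ids, S,
                            lower_bound, upper_bound,
                            gpr = "", gene_ids = NULL,
                            objective_tags = character(0),
                            id = "model") {
  metabolite_ids <- as.character(metabolite_ids)
  reaction_ids <- as.character(reaction_ids)
  S <- Matrix::Matrix(as.matrix(S), sparse = TRUE)
  if (length(gpr) == 1L) gpr <- rep(gpr, length(reaction_ids))
  stopifnot(length(gpr) == length(reaction_ids),
            length(lower_bound) == length(reaction_ids),
            length(upper_bound) == length(reaction_ids))
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  gpr_ast <- lapply(gpr, parse_gpr)
  genes_used <- unique(unlist(lapply(gpr_ast, gpr_genes)))
  if (is.null(gene_ids)) gene_ids <- genes_used
  m <- structure(list(
    id = id,
    metabolite_ids = metabolite_ids,
    reaction_ids = reaction_ids,
    S = S,
    lower_bound = as.numeric(lower_bound),
    upper_bound = as.numeric(upper_bound),
    gpr = gpr,
    gpr_ast = gpr_ast,
    gene_ids = as.character(gene_ids),
    objective_tags = objective_tags
  ), class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: matching dimensions, unique ids,
#' `lower_bound <= upper_bound`, GPR genes covered by `gene_ids`, and
#' objective tags naming existing reactions. Called by the constructor and
#' the file loaders; exported so externally assembled objects can be checked.
#'
#' @param m A `metabolic_model`.
#' @return `m`, invisibly; stops with a validation error otherwise.
#' @export
validate_model <- function(m) {
  if (anyDuplicated(m$metabolite_ids))
    stop("model validation: duplicate metabolite ids: ",
         paste(unique(m$metabolite_ids[duplicated(m$metabolite_ids)]),
               collapse = ", "))
  if (anyDuplicated(m$reaction_ids))
    stop("model validation: duplicate reaction ids: ",
         paste(unique(m$reaction_ids[duplicated(m$reaction_ids)]),
               collapse = ", "))
  if (nrow(m$S) != length(m$metabolite_ids) ||
      ncol(m$S) != length(m$reaction_ids))
    stop("model validation: S dimensions (", nrow(m$S), " x ", ncol(m$S),
         ") do not match id lists")
  bad <- which(m$lower_bound > m$upper_bound)
  if (length(bad))
    stop("model validation: lower_bound > upper_bound for reaction(s): ",
         paste(m$reaction_ids[bad], collapse = ", "))
  genes_used <- unique(unlist(lapply(m$gpr_ast, gpr_genes)))
  missing <- setdiff(genes_used, m$gene_ids)
  if (length(missing))
    stop("model validation: GPR gene(s) not in gene_ids: ",
         paste(missing, collapse = ", "))
  bad_tag <- m$objective_tags[!m$objective_tags %in% m$reaction_ids]
  if (length(bad_tag))
    stop("model validation: objective tag(s) name unknown reaction(s): ",
         paste(names(bad_tag), "=", bad_tag, collapse = ", "))
  invisible(m)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites x %d reactions, %d genes\n",
              x$id, length(x$metabolite_ids), length(x$reaction_ids),
              length(x$gene_ids)))
  if (length(x$objective_tags))
    cat("  tags:", paste(names(x$objective_tags), "=", x$objective_tags,
                         collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a model to a subset of reactions
#'
#' Keeps the named reactions, drops metabolites that no longer participate in
#' any retained reaction, and drops objective tags whose reaction was removed.
#'
#' @param m A `metabolic_model`.
#' @param keep Character vector of reaction ids (order is taken from the
#'   model, not from `keep`).
#' @return A `metabolic_model`.
#' @export
subset_reactions <- function(m, keep) {
  keep <- m$reaction_ids %in% keep
  S <- m$S[, keep, drop = FALSE]
  live_met <- Matrix::rowSums(S != 0) > 0
  tags <- m$objective_tags[m$objective_tags %in% m$reaction_ids[keep]]
  metabolic_model(
    metabolite_ids = m$metabolite_ids[live_met],
    reaction_ids = m$reaction_ids[keep],
    S = S[live_met, , drop = FALSE],
    lower_bound = m$lower_bound[keep],
    upper_bound = m$upper_bound[keep],
    gpr = m$gpr[keep],
    gene_ids = m$gene_ids,
    objective_tags = tags,
    id = m$id
  )
}

reaction_index <- function(m, rid) {
  i <- match(rid, m$reaction_ids)
  if (is.na(i)) stop("unknown reaction id: ", rid)
  i
}

tagged_reaction <- function(m, role) {
  rid <- m$objective_tags[[role]]
  if (is.null(rid))
    stop("model has no '", role, "' objective tag")
  rid
}
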