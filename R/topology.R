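# Topology of one FBA optimum: active-subnetwork reduction, choke-point
# classification (single / double / extended), and reaction-centric
# PageRank on the directed reaction graph.

#' Construct a reduced (active, oriented) network
#'
#' Low-level constructor for a condition-specific network: an oriented
#' stoichiometric matrix over active reactions only, where every column is
#' read in its carried direction (negative coefficients = consumed,
#' positive = produced). Usually produced by [reduce_network()]; exposed so
#' small motif networks can be built directly.
#'
#' @param S Oriented stoichiometric matrix (rows = metabolites, columns =
#'   reactions) with dimnames.
#' @param orientation Optional per-reaction +1/-1 record of the original
#'   flux sign (purely informational; `S` is already oriented).
#' @param label Free-text label (e.g. the source test label).
#' @return Object of class `reduced_network`.
#' @export
reduced_network <- function(S, orientation = NULL, label = "network") {
  dn <- dimnames(as.matrix(S))
  if ((is.null(dn[[1]]) || is.null(dn[[2]])) && length(S))
    stop("reduced_network: S must carry metabolite and reaction dimnames")
  if (is.null(dn[[1]])) dn <- list(character(0), character(0))
  S <- Matrix::Matrix(as.matrix(S), sparse = TRUE)
  dimnames(S) <- dn
  if (is.null(orientation)) orientation <- rep(1L, ncol(S))
  structure(list(
    metabolite_ids = rownames(S),
    reaction_ids = colnames(S),
    S = S,
    orientation = as.integer(orientation),
    label = label
  ), class = "reduced_network")
}

#' @export
print.reduced_network <- function(x, ...) {
  cat(sprintf("<reduced_network> %s: %d metabolites x %d reactions\n",
              x$label, length(x$metabolite_ids), length(x$reaction_ids)))
  invisible(x)
}

#' Reduce a model to the active subnetwork of a flux distribution
#'
#' Retains reactions with `|v| > flux_tol`, flips the stoichiometry of
#' reactions carried in reverse (so the oriented matrix always reads
#' "negative = consumed, positive = produced"), and drops metabolites that
#' participate in no retained reaction.
#'
#' @param m A `metabolic_model`.
#' @param flux A `flux_distribution` over the model's reactions.
#' @param flux_tol Activity threshold.
#' @return A `reduced_network`; empty (with a warning) if no reaction is
#'   active.
#' @export
reduce_network <- function(m, flux, flux_tol = 1e-6) {
  if (!identical(flux$reaction_ids, m$reaction_ids))
    stop("reduce_network: flux distribution does not match model reactions")
  act <- which(abs(flux$v) > flux_tol)
  if (!length(act)) {
    warning("reduce_network: all fluxes below tolerance; empty network")
    S <- matrix(0, 0, 0, dimnames = list(character(0), character(0)))
    return(reduced_network(S, integer(0), label = flux$label))
  }
  sgn <- sign(flux$v[act])
  S <- m$S[, act, drop = FALSE]
  S <- S %*% Matrix::Diagonal(x = sgn)
  colnames(S) <- m$reaction_ids[act]
  live <- Matrix::rowSums(S != 0) > 0
  S <- S[live, , drop = FALSE]
  reduced_network(S, orientation = sgn, label = flux$label)
}

# producers/consumers per metabolite on the oriented matrix (sign only;
# coefficient magnitudes are irrelevant for topology)
incidence_sets <- function(net) {
  S <- as.matrix(net$S)
  prod <- apply(S > 0, 1, function(r) net$reaction_ids[r], simplify = FALSE)
  cons <- apply(S < 0, 1, function(r) net$reaction_ids[r], simplify = FALSE)
  list(producers = prod, consumers = cons)
}

#' Classify choke points in a reduced network
#'
#' Labels every reaction of an oriented active network with the most
#' specific applicable choke-point class:
#' \describe{
#'   \item{single_producing}{the sole producer of some metabolite;}
#'   \item{single_consuming}{the sole consumer of some metabolite;}
#'   \item{double}{both at once;}
#'   \item{extended}{a double choke point "surrounded by" single choke
#'     points: for some witness pair (a metabolite it exclusively consumes,
#'     one it exclusively produces), the neighboring producers of the
#'     consumed metabolite are strict single producers (every metabolite
#'     they produce has them as sole producer) and the neighboring consumers
#'     of the produced metabolite are strict single consumers.}
#' }
#' The quantifier over the neighbor sets is `cfg$extended_rule`: `"all"`
#' (default, the stringent reading) requires every neighbor to qualify,
#' `"exists"` requires at least one (and at least one neighbor on each
#' side). Exchange/boundary reactions participate like any other column.
#'
#' @param net A `reduced_network`.
#' @param cfg An [analysis_config()] (only `extended_rule` is used).
#' @return A data.frame with columns `reaction_id`, `label` (one of `none`,
#'   `single_consuming`, `single_producing`, `double`, `extended`),
#'   `is_single_consuming`, `is_single_producing`, and the witness
#'   metabolites `m_in`/`m_out` for extended choke points.
#' @export
classify_choke_points <- function(net, cfg = analysis_config()) {
  n <- length(net$reaction_ids)
  if (!n) stop("classify_choke_points: empty network")
  inc <- incidence_sets(net)
  S <- as.matrix(net$S)
  rid <- net$reaction_ids

  prod_sets <- inc$producers  # per metabolite
  cons_sets <- inc$consumers

  sole_prod_of <- lapply(rid, function(r)
    names(prod_sets)[vapply(prod_sets, function(p) identical(p, r),
                            logical(1))])
  names(sole_prod_of) <- rid
  sole_cons_of <- lapply(rid, function(r)
    names(cons_sets)[vapply(cons_sets, function(p) identical(p, r),
                            logical(1))])
  names(sole_cons_of) <- rid

  is_sp <- vapply(sole_prod_of, function(x) length(x) > 0, logical(1))
  is_sc <- vapply(sole_cons_of, function(x) length(x) > 0, logical(1))

  # strict single producer: produces >= 1 metabolite and is the sole
  # producer of every metabolite it produces (mirror for consumers)
  products_of <- lapply(seq_len(n), function(j) rownames(S)[S[, j] > 0])
  substrates_of <- lapply(seq_len(n), function(j) rownames(S)[S[, j] < 0])
  names(products_of) <- names(substrates_of) <- rid
  strict_sp <- vapply(rid, function(r) {
    ps <- products_of[[r]]
    length(ps) > 0 && all(vapply(ps, function(mx)
      identical(prod_sets[[mx]], r), logical(1)))
  }, logical(1))
  strict_sc <- vapply(rid, function(r) {
    ss <- substrates_of[[r]]
    length(ss) > 0 && all(vapply(ss, function(mx)
      identical(cons_sets[[mx]], r), logical(1)))
  }, logical(1))

  quantifier <- if (cfg$extended_rule == "all") {
    function(nbrs, ok) all(ok[nbrs])           # vacuously true when empty
  } else {
    function(nbrs, ok) length(nbrs) > 0 && any(ok[nbrs])
  }

  label <- rep("none", n)
  m_in <- m_out <- rep(NA_character_, n)
  for (j in seq_len(n)) {
    r <- rid[j]
    if (is_sp[j] && is_sc[j]) {
      label[j] <- "double"
      # extended: search witness pairs
      found <- FALSE
      for (mi in sole_cons_of[[r]]) {
        up_ok <- quantifier(setdiff(prod_sets[[mi]], r), strict_sp)
        if (!up_ok) next
        for (mo in sole_prod_of[[r]]) {
          dn_ok <- quantifier(setdiff(cons_sets[[mo]], r), strict_sc)
          if (dn_ok) {
            label[j] <- "extended"
            m_in[j] <- mi; m_out[j] <- mo
            found <- TRUE
            break
          }
        }
        if (found) break
      }
    } else if (is_sc[j]) {
      label[j] <- "single_consuming"
    } else if (is_sp[j]) {
      label[j] <- "single_producing"
    }
  }
  data.frame(reaction_id = rid, label = label,
             is_single_consuming = is_sc, is_single_producing = is_sp,
             m_in = m_in, m_out = m_out,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the directed reaction graph of a reduced network
#'
#' Reactions become nodes; a directed edge i -> j exists iff some metabolite
#' is produced by i and consumed by j in the oriented network (the
#' reaction-centric counterpart of the metabolite graph, obtained from the
#' transposed incidence structure). Node order is the sorted reaction id.
#'
#' @param net A `reduced_network`.
#' @return An [igraph::graph] with vertex names; the adjacency matrix is
#'   available via `igraph::as_adjacency_matrix()`.
#' @export
build_reaction_graph <- function(net) {
  if (!length(net$reaction_ids))
    stop("build_reaction_graph: empty network")
  rid <- sort(net$reaction_ids)
  S <- as.matrix(net$S)[, rid, drop = FALSE]
  P <- S > 0
  C <- S < 0
  # edge i->j iff exists m: P[m,i] & C[m,j]
  A <- (t(P) %*% C) > 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  g
}

#' Reaction-centric PageRank
#'
#' Standard PageRank with uniform teleportation on the directed reaction
#' graph; dangling nodes redistribute their mass uniformly. Scores are
#' non-negative and sum to 1.
#'
#' @param graph An igraph object from [build_reaction_graph()].
#' @param damping Damping factor (default 0.85).
#' @param tol Convergence tolerance.
#' @return Named numeric vector of centrality scores.
#' @export
pagerank <- function(graph, damping = 0.85, tol = 1e-12) {
  stopifnot(igraph::vcount(graph) >= 1L)
  pr <- igraph::page_rank(graph, damping = damping,
                          algo = "prpack")$vector
  pr
}
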