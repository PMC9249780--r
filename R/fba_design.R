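# Multi-objective FBA design: simplex-lattice weight enumeration, weighted
# global criterion scalarization, flux-sum minimization, deduplication of
# optima, and reaction essentiality.

#' Simplex lattice design \{q, m\}
#'
#' Enumerates all q-component mixture weight vectors whose entries are
#' non-negative integer multiples of 1/m summing to 1, in deterministic
#' lexicographic order (first component varying slowest, descending).
#' The count is `choose(q + m - 1, m)`; for \{3, 4\} this yields the 15
#' weight vectors of the published design.
#'
#' @param q Number of mixture components (objectives), >= 2.
#' @param m Lattice resolution, >= 1.
#' @return Numeric matrix with `choose(q + m - 1, m)` rows and `q` columns,
#'   each row summing to 1.
#' @examples
#' simplex_lattice(3, 4)  # 15 rows
#' @export
simplex_lattice <- function(q = 3, m = 4) {
  q <- as.integer(q); m <- as.integer(m)
  stopifnot(q >= 2L, m >= 1L)
  compositions <- function(total, parts) {
    if (parts == 1L) return(matrix(total, nrow = 1L))
    out <- NULL
    for (k in total:0) {
      rest <- compositions(total - k, parts - 1L)
      out <- rbind(out, cbind(k, rest))
    }
    out
  }
  w <- compositions(m, q) / m
  dimnames(w) <- NULL
  colnames(w) <- if (q == 3L) c("w_biomass", "w_atp", "w_pi4p")
                 else paste0("w", seq_len(q))
  w
}

flux_distribution <- function(reaction_ids, v, objective_value, label,
                              weights = NULL) {
  structure(list(reaction_ids = reaction_ids, v = as.numeric(v),
                 objective_value = objective_value, label = label,
                 weights = weights),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> %s: objective %.6g, %d reactions (%d active)\n",
              x$label, x$objective_value, length(x$v), sum(abs(x$v) > 1e-9)))
  invisible(x)
}

objective_vector <- function(m, w) {
  roles <- c("biomass", "atp", "pi4p")
  obj <- numeric(length(m$reaction_ids))
  for (k in seq_along(roles)) {
    if (w[k] != 0) {
      j <- reaction_index(m, tagged_reaction(m, roles[k]))
      obj[j] <- obj[j] + w[k]
    }
  }
  obj
}

weight_label <- function(w) sprintf("w_%.2f_%.2f_%.2f", w[1], w[2], w[3])

#' Solve one weighted-objective FBA problem
#'
#' Scalarizes the three-objective problem (biomass, ATP, PI4P production) by
#' the weighted global criterion method -- maximize
#' `w1*v_biomass + w2*v_atp + w3*v_pi4p` -- subject to steady state, the
#' model bounds, and the oxygen uptake cap from `cfg`.
#'
#' @param m A `metabolic_model` with `biomass`, `atp` and `pi4p` objective
#'   tags (an `oxygen_uptake` tag enables the uptake cap).
#' @param w Numeric weight vector of length 3 (a row of [simplex_lattice()]).
#' @param cfg An [analysis_config()].
#' @return A `flux_distribution` whose `objective_value` is the attained
#'   maximum of the weighted sum.
#' @export
solve_weighted_fba <- function(m, w, cfg = analysis_config()) {
  w <- as.numeric(w)
  stopifnot(length(w) == 3L, all(w >= 0))
  mc <- apply_oxygen_cap(m, cfg)
  obj <- objective_vector(mc, w)
  if (any(obj > 0 & !is.finite(mc$upper_bound)))
    stop("solve_weighted_fba: objective reaction with infinite upper bound; ",
         "the problem would be unbounded")
  res <- fba_optimize(mc, obj, maximize = TRUE)
  if (res$status != "optimal")
    stop("solve_weighted_fba: LP infeasible under steady state, bounds and ",
         "oxygen cap (weights ", weight_label(w), ")")
  flux_distribution(m$reaction_ids, res$v, res$value,
                    label = weight_label(w), weights = w)
}

#' Minimize the total flux at fixed biomass
#'
#' The extra design point complementing the 15 weighted problems: minimizes
#' the sum of absolute fluxes. Because the unanchored problem has the
#' trivial all-zero optimum, the default follows the parsimonious-FBA
#' convention and first fixes the biomass flux at its single-objective
#' maximum (`cfg$min_flux_anchor = "biomass"`); with `"none"` the degenerate
#' unanchored problem is solved and flagged. Absolute values are handled by
#' splitting each flux into two non-negative variables.
#'
#' @param m A tagged `metabolic_model`.
#' @param cfg An [analysis_config()].
#' @return A `flux_distribution` labeled `"min_total_flux"`, with
#'   `objective_value` the minimal total flux sum.
#' @export
solve_min_total_flux <- function(m, cfg = analysis_config()) {
  mc <- apply_oxygen_cap(m, cfg)
  lb <- mc$lower_bound; ub <- mc$upper_bound
  if (cfg$min_flux_anchor == "biomass") {
    bio <- reaction_index(mc, tagged_reaction(mc, "biomass"))
    base <- fba_optimize(mc, {o <- numeric(length(lb)); o[bio] <- 1; o},
                         maximize = TRUE)
    if (base$status != "optimal")
      stop("solve_min_total_flux: biomass maximization infeasible")
    lb[bio] <- ub[bio] <- base$value
  }
  n <- length(lb)
  # |v| via flux splitting v = p - q (p, q >= 0); only reversible columns
  # need the negative part
  rev_j <- which(lb < 0)
  p_lb <- pmax(lb, 0); p_ub <- pmax(ub, 0)
  q_lb <- pmax(-ub, 0)[rev_j]; q_ub <- pmax(-lb, 0)[rev_j]
  Sm <- as.matrix(mc$S)
  S2 <- cbind(Sm, -Sm[, rev_j, drop = FALSE])
  res <- solve_lp(rep(1, n + length(rev_j)), S2, c(p_lb, q_lb),
                  c(p_ub, q_ub), maximize = FALSE)
  if (res$status != "optimal")
    stop("solve_min_total_flux: LP infeasible")
  v <- res$v[seq_len(n)]
  v[rev_j] <- v[rev_j] - res$v[n + seq_along(rev_j)]
  out <- flux_distribution(m$reaction_ids, v, res$value,
                           label = "min_total_flux")
  if (cfg$min_flux_anchor == "none") attr(out, "degenerate") <- TRUE
  out
}

#' Run the full objective design
#'
#' Solves the `choose(q+m-1, m)` simplex-lattice weighted problems (15 for
#' the default \{3,4\} design) plus the flux-sum minimization, for 16 tests
#' in total. Labels are deterministic: `w_<w1>_<w2>_<w3>` and
#' `"min_total_flux"`.
#'
#' @param m A tagged `metabolic_model`.
#' @param cfg An [analysis_config()].
#' @return Named list of `flux_distribution` objects, one per test.
#' @export
run_design <- function(m, cfg = analysis_config()) {
  W <- simplex_lattice(cfg$lattice_q, cfg$lattice_m)
  if (cfg$lattice_q != 3L)
    stop("run_design: only the three-objective design is supported ",
         "(lattice_q = 3)")
  sols <- lapply(seq_len(nrow(W)), function(i)
    solve_weighted_fba(m, W[i, ], cfg))
  sols <- c(sols, list(solve_min_total_flux(m, cfg)))
  names(sols) <- vapply(sols, `[[`, character(1), "label")
  sols
}

#' Deduplicate optimal flux distributions
#'
#' Several design points typically attain the same optimum. Greedy
#' deduplication in input order: a solution is redundant if its flux vector
#' is within L-infinity distance `dedup_tol` of an already kept one.
#'
#' @param solutions List of `flux_distribution` over a common reaction set.
#' @param dedup_tol Non-negative tolerance.
#' @return The kept (non-redundant) sublist; attribute `"duplicate_of"` maps
#'   each dropped label to the kept label it matched.
#' @export
deduplicate_solutions <- function(solutions, dedup_tol = 1e-6) {
  stopifnot(length(solutions) >= 1L)
  rid <- solutions[[1]]$reaction_ids
  for (s in solutions)
    if (!identical(s$reaction_ids, rid))
      stop("deduplicate_solutions: solutions cover different reaction sets")
  kept <- list()
  dup <- character(0)
  for (s in solutions) {
    match_lab <- NULL
    for (k in kept) {
      if (max(abs(s$v - k$v)) <= dedup_tol) { match_lab <- k$label; break }
    }
    if (is.null(match_lab)) kept[[length(kept) + 1L]] <- s
    else dup[s$label] <- match_lab
  }
  names(kept) <- vapply(kept, `[[`, character(1), "label")
  attr(kept, "duplicate_of") <- dup
  kept
}

#' Essential reactions under the biomass objective
#'
#' A reaction is essential when forcing its flux to zero reduces the optimal
#' biomass flux by at least `cfg$essentiality_drop` (5% by default). Each
#' reaction is knocked out in turn (`lb = ub = 0`), biomass is re-maximized
#' under the oxygen cap, and bounds are restored. A knockout that makes the
#' LP infeasible counts as a 100% reduction.
#'
#' @param m A `metabolic_model` with a `biomass` tag and a strictly positive
#'   baseline biomass optimum (otherwise an error: essentiality undefined).
#' @param cfg An [analysis_config()].
#' @return Character vector of essential reaction ids (model order);
#'   attribute `"drop"` holds the per-reaction fractional reduction.
#' @export
essential_reactions <- function(m, cfg = analysis_config()) {
  mc <- apply_oxygen_cap(m, cfg)
  bio <- reaction_index(mc, tagged_reaction(mc, "biomass"))
  obj <- numeric(length(mc$reaction_ids)); obj[bio] <- 1
  base <- fba_optimize(mc, obj, maximize = TRUE)
  if (base$status != "optimal" || base$value <= cfg$flux_tol)
    stop("essential_reactions: baseline biomass optimum is not positive; ",
         "essentiality undefined")
  drop_frac <- vapply(seq_along(mc$reaction_ids), function(j) {
    mk <- mc
    mk$lower_bound[j] <- 0
    mk$upper_bound[j] <- 0
    res <- fba_optimize(mk, obj, maximize = TRUE)
    ko <- if (res$status == "optimal") res$value else 0
    (base$value - ko) / base$value
  }, numeric(1))
  names(drop_frac) <- mc$reaction_ids
  out <- mc$reaction_ids[drop_frac >= cfg$essentiality_drop]
  attr(out, "drop") <- drop_frac
  out
}
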