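# Internal linear-programming layer for flux balance analysis.
#
# All FBA problems are maximize/minimize c'v subject to S v = 0,
# lb <= v <= ub, plus optional extra inequality rows E v <= f. They are
# shifted to non-negative variables x = v - lb, put in standard equality
# form with box/inequality slacks, and solved by the package's two-phase
# simplex (lp_simplex).

LP_BIG <- 1e6  # stand-in for infinite bounds; models are expected finite

solve_lp <- function(obj, S, lb, ub, ineq_A = NULL, ineq_b = NULL,
                     maximize = TRUE, eps = 1e-10) {
  n <- length(obj)
  stopifnot(ncol(S) == n, length(lb) == n, length(ub) == n)
  lb <- pmax(lb, -LP_BIG)
  ub <- pmin(ub, LP_BIG)
  if (any(lb > ub)) return(list(status = "infeasible", value = NA_real_,
                                v = rep(NA_real_, n)))
  S <- as.matrix(S)
  if (!is.null(ineq_A)) ineq_A <- matrix(ineq_A, ncol = n)
  # presolve: variables with a zero-width box are constants; eliminating
  # them keeps the simplex phase-1 basis well formed
  fixed <- (ub - lb) <= 0
  if (any(fixed)) {
    v_full <- numeric(n)
    v_full[fixed] <- lb[fixed]
    d_eq <- as.numeric(-S[, fixed, drop = FALSE] %*% lb[fixed])
    if (!all(fixed)) {
      sub <- solve_lp2(obj[!fixed], S[, !fixed, drop = FALSE], d_eq,
                       lb[!fixed], ub[!fixed],
                       if (is.null(ineq_A)) NULL
                       else ineq_A[, !fixed, drop = FALSE],
                       if (is.null(ineq_b)) NULL
                       else as.numeric(ineq_b) -
                         as.numeric(ineq_A[, fixed, drop = FALSE] %*%
                                      lb[fixed]),
                       maximize, eps)
      if (sub$status != "optimal")
        return(list(status = sub$status, value = NA_real_,
                    v = rep(NA_real_, n)))
      v_full[!fixed] <- sub$v
    } else {
      feas_eq <- all(abs(d_eq) <= 1e-9)
      feas_in <- is.null(ineq_A) ||
        all(as.numeric(ineq_A %*% v_full) <= as.numeric(ineq_b) + 1e-9)
      if (!feas_eq || !feas_in)
        return(list(status = "infeasible", value = NA_real_,
                    v = rep(NA_real_, n)))
    }
    return(list(status = "optimal", value = sum(obj * v_full), v = v_full))
  }
  solve_lp2(obj, S, rep(0, nrow(S)), lb, ub, ineq_A, ineq_b, maximize, eps)
}

# core: optimize c'v s.t. S v = d, lb <= v <= ub (strictly lb < ub),
# ineq_A v <= ineq_b; shifted to the standard form consumed by lp_simplex
solve_lp2 <- function(obj, S, d, lb, ub, ineq_A, ineq_b, maximize, eps) {
  n <- length(obj)
  me <- nrow(S)
  mi <- if (is.null(ineq_A)) 0L else nrow(ineq_A)
  ncols <- n + n + mi                 # x, box slacks, inequality slacks
  # equality rows: S x = d - S lb
  b_eq <- d - as.numeric(S %*% lb)
  A <- matrix(0, me + n + mi, ncols)
  b <- numeric(me + n + mi)
  A[seq_len(me), seq_len(n)] <- S
  b[seq_len(me)] <- b_eq
  flip <- which(b < 0)
  if (length(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
  }
  basis0 <- rep(NA_integer_, me + n + mi)
  # box rows: x_j + s_j = ub_j - lb_j (rhs >= 0, slack starts basic)
  for (j in seq_len(n)) {
    A[me + j, j] <- 1
    A[me + j, n + j] <- 1
    b[me + j] <- ub[j] - lb[j]
    basis0[me + j] <- n + j
  }
  # inequality rows: E x + t = f - E lb
  if (mi) {
    rhs <- as.numeric(ineq_b) - as.numeric(ineq_A %*% lb)
    for (k in seq_len(mi)) {
      i <- me + n + k
      if (rhs[k] >= 0) {
        A[i, seq_len(n)] <- ineq_A[k, ]
        A[i, n + n + k] <- 1
        b[i] <- rhs[k]
        basis0[i] <- n + n + k
      } else {
        A[i, seq_len(n)] <- -ineq_A[k, ]
        A[i, n + n + k] <- -1
        b[i] <- -rhs[k]
      }
    }
  }
  cost <- c(if (maximize) -obj else obj, rep(0, n + mi))
  res <- lp_simplex(cost, A, b, basis0 = basis0)
  if (res$status == "maxit")
    stop("internal LP solver exceeded its iteration budget")
  if (res$status != "optimal")
    return(list(status = if (res$status == "unbounded") "unbounded"
                else "infeasible",
                value = NA_real_, v = rep(NA_real_, n)))
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", value = sum(obj * v), v = v)
}

# Apply the oxygen uptake cap (cfg$oxygen_ub) to a copy of the model's
# bounds. The tagged oxygen exchange is inspected: if it produces the oxygen
# species into the network (import-positive convention), uptake is the
# positive direction and the cap tightens the upper bound; if it consumes it
# (export-positive convention, uptake = negative flux), the cap tightens the
# lower bound at -oxygen_ub. Models without an oxygen_uptake tag are
# returned unchanged.
apply_oxygen_cap <- function(m, cfg) {
  if (!"oxygen_uptake" %in% names(m$objective_tags)) return(m)
  j <- reaction_index(m, tagged_reaction(m, "oxygen_uptake"))
  col <- m$S[, j]
  nz <- which(col != 0)
  if (!length(nz)) return(m)
  # exchange reactions touch a single species; for multi-species columns the
  # dominant (largest magnitude) coefficient decides the direction
  sgn <- sign(as.numeric(col[nz[which.max(abs(as.numeric(col[nz])))]]))
  if (sgn > 0) {
    m$upper_bound[j] <- min(m$upper_bound[j], cfg$oxygen_ub)
  } else {
    m$lower_bound[j] <- max(m$lower_bound[j], -cfg$oxygen_ub)
  }
  if (m$lower_bound[j] > m$upper_bound[j])
    stop("oxygen cap makes reaction '", m$reaction_ids[j], "' bounds empty")
  m
}

# Maximize (or minimize) a linear objective over the model's flux cone.
fba_optimize <- function(m, obj, maximize = TRUE) {
  solve_lp(obj, m$S, m$lower_bound, m$upper_bound, maximize = maximize)
}

#' Flux variability of individual reactions
#'
#' For each requested reaction, maximizes and minimizes its flux subject to
#' steady state (`S v = 0`) and the model bounds. This is the oracle notion
#' of flux consistency: a reaction is consistent at tolerance `tol` iff its
#' maximum is `>= tol` or its minimum is `<= -tol`.
#'
#' @param m A `metabolic_model`.
#' @param reactions Reaction ids (default: all).
#' @return A data.frame with columns `reaction_id`, `min`, `max`. Infeasible
#'   models yield `NA` ranges.
#' @export
flux_variability <- function(m, reactions = m$reaction_ids) {
  idx <- match(reactions, m$reaction_ids)
  if (anyNA(idx)) stop("flux_variability: unknown reaction id(s)")
  n <- length(m$reaction_ids)
  lo <- hi <- numeric(length(idx))
  for (k in seq_along(idx)) {
    obj <- numeric(n); obj[idx[k]] <- 1
    up <- fba_optimize(m, obj, maximize = TRUE)
    dn <- fba_optimize(m, obj, maximize = FALSE)
    hi[k] <- if (up$status == "optimal") up$value else NA_real_
    lo[k] <- if (dn$status == "optimal") dn$value else NA_real_
  }
  data.frame(reaction_id = reactions, min = lo, max = hi,
             stringsAsFactors = FALSE)
}
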