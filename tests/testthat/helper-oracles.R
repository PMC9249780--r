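# Independent oracles used across the suite. These deliberately share no
# code with the package implementation paths they check.

# --- LP by brute-force vertex enumeration (tiny problems only) -------------
# maximize obj'v s.t. S v = 0, lb <= v <= ub, by enumerating candidate
# vertices: fix (n - rank) variables at a bound in all ways, solve the
# equality system for the rest, keep feasible points.
oracle_lp_max <- function(obj, S, lb, ub) {
  S <- as.matrix(S)
  n <- length(obj)
  rk <- qr(S)$rank
  nfix <- n - rk
  best <- -Inf
  if (nfix == 0L) {
    v <- tryCatch(qr.solve(S, rep(0, nrow(S))), error = function(e) NULL)
    if (!is.null(v) && all(v >= lb - 1e-8) && all(v <= ub + 1e-8))
      best <- sum(obj * v)
    return(best)
  }
  combos <- utils::combn(n, nfix)
  for (ci in seq_len(ncol(combos))) {
    fixv <- combos[, ci]
    rest <- setdiff(seq_len(n), fixv)
    A <- S[, rest, drop = FALSE]
    if (qr(A)$rank < length(rest)) next
    for (pat in 0:(2^nfix - 1)) {
      at_ub <- bitwAnd(bitwShiftR(pat, seq_len(nfix) - 1L), 1L) == 1L
      vals <- ifelse(at_ub, ub[fixv], lb[fixv])
      rhs <- -S[, fixv, drop = FALSE] %*% vals
      sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(n); v[fixv] <- vals; v[rest] <- sol
      if (all(v >= lb - 1e-8) && all(v <= ub + 1e-8) &&
          max(abs(S %*% v)) < 1e-8)
        best <- max(best, sum(obj * v))
    }
  }
  best
}

# per-reaction FVA by the enumeration oracle (models of <= ~12 reactions)
oracle_fva <- function(m) {
  S <- as.matrix(m$S)
  n <- ncol(S)
  t(vapply(seq_len(n), function(j) {
    o <- numeric(n); o[j] <- 1
    c(min = -oracle_lp_max(-o, S, m$lower_bound, m$upper_bound),
      max = oracle_lp_max(o, S, m$lower_bound, m$upper_bound))
  }, c(min = 0, max = 0)))
}

oracle_consistent_ids <- function(m, tol = 1e-6) {
  fv <- oracle_fva(m)
  m$reaction_ids[is.finite(fv[, "max"]) &
                   (fv[, "max"] >= tol | fv[, "min"] <= -tol)]
}

# --- dense PageRank power iteration ----------------------------------------
oracle_pagerank <- function(A, damping = 0.85, tol = 1e-14,
                            maxit = 100000L) {
  A <- as.matrix(A)
  n <- nrow(A)
  out_deg <- rowSums(A)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (out_deg[i] > 0) P[i, ] <- A[i, ] / out_deg[i]
    else P[i, ] <- 1 / n   # dangling: uniform redistribution
  }
  x <- rep(1 / n, n)
  for (it in seq_len(maxit)) {
    x_new <- damping * as.numeric(t(P) %*% x) + (1 - damping) / n
    if (sum(abs(x_new - x)) < tol) break
    x <- x_new
  }
  stats::setNames(x_new, rownames(A))
}

# --- brute-force choke-point classification --------------------------------
# straight re-statement of the rules with explicit loops over the
# (metabolite, reaction) incidence pairs of an oriented matrix
oracle_classify <- function(S, rule = "all") {
  S <- as.matrix(S)
  mets <- rownames(S); rxns <- colnames(S)
  producers <- function(mx) rxns[S[mx, ] > 0]
  consumers <- function(mx) rxns[S[mx, ] < 0]
  is_sp <- function(r) any(vapply(mets, function(mx)
    length(producers(mx)) == 1 && producers(mx) == r, logical(1)))
  is_sc <- function(r) any(vapply(mets, function(mx)
    length(consumers(mx)) == 1 && consumers(mx) == r, logical(1)))
  strict_sp <- function(r) {
    prods <- mets[S[, r] > 0]
    length(prods) > 0 && all(vapply(prods, function(mx)
      length(producers(mx)) == 1 && producers(mx) == r, logical(1)))
  }
  strict_sc <- function(r) {
    subs <- mets[S[, r] < 0]
    length(subs) > 0 && all(vapply(subs, function(mx)
      length(consumers(mx)) == 1 && consumers(mx) == r, logical(1)))
  }
  quant <- function(nbrs, test) {
    if (rule == "all") all(vapply(nbrs, test, logical(1)))
    else length(nbrs) > 0 && any(vapply(nbrs, test, logical(1)))
  }
  vapply(rxns, function(r) {
    sp <- is_sp(r); sc <- is_sc(r)
    if (!sp || !sc) {
      if (sc) return("single_consuming")
      if (sp) return("single_producing")
      return("none")
    }
    wit_in <- mets[vapply(mets, function(mx)
      length(consumers(mx)) == 1 && consumers(mx) == r, logical(1))]
    wit_out <- mets[vapply(mets, function(mx)
      length(producers(mx)) == 1 && producers(mx) == r, logical(1))]
    for (mi in wit_in) {
      if (!quant(setdiff(producers(mi), r), strict_sp)) next
      for (mo in wit_out) {
        if (quant(setdiff(consumers(mo), r), strict_sc))
          return("extended")
      }
    }
    "double"
  }, character(1))
}

# --- brute-force PAM objective over all medoid pairs -----------------------
oracle_pam2_objective <- function(signatures) {
  d <- as.matrix(stats::dist(t(signatures), method = "manhattan"))
  n <- ncol(signatures)
  best <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    obj <- sum(pmin(d[, i], d[, j]))
    best <- min(best, obj)
  }
  best
}

# random oriented network generator for property tests
random_oriented_network <- function(n_rxn, n_met, seed) {
  set.seed(seed)
  repeat {
    S <- matrix(0, n_met, n_rxn,
                dimnames = list(sprintf("m%02d", 1:n_met),
                                sprintf("r%02d", 1:n_rxn)))
    for (j in seq_len(n_rxn)) {
      k <- sample(1:min(3, n_met), 1)
      rows <- sample(n_met, k)
      S[rows, j] <- sample(c(-1, 1), k, replace = TRUE)
    }
    live <- rowSums(S != 0) > 0
    S <- S[live, , drop = FALSE]
    if (nrow(S) >= 1) return(S)
  }
}
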