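# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# The flux balance problems solved here are small (tens of variables) but
# highly degenerate, which trips the textbook implementations available in
# the R ecosystem; Bland's rule guarantees finite termination at the cost
# of speed, which is irrelevant at this scale.
#
# lp_simplex solves: minimize cost' x  subject to  A x = b, x >= 0,
# with b >= 0 required (callers flip row signs). Returns the optimum, a
# solution vector, and a status flag.

lp_simplex <- function(cost, A, b, basis0 = NULL, eps = 1e-9,
                       maxit = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cost) == n, length(b) == m, all(b >= 0))
  if (is.null(maxit)) maxit <- 2000L + 40L * (n + m)

  # phase 1: artificial variables on rows without a supplied basic column
  if (is.null(basis0)) basis0 <- rep(NA_integer_, m)
  art_rows <- which(is.na(basis0))
  n_art <- length(art_rows)
  Tb <- cbind(A, matrix(0, m, n_art), b, deparse.level = 0)
  for (k in seq_along(art_rows)) Tb[art_rows[k], n + k] <- 1
  basis <- basis0
  basis[art_rows] <- n + seq_len(n_art)
  ncols <- n + n_art
  rhs_col <- ncols + 1L

  run_phase <- function(Tb, basis, cost_full, allowed) {
    # reduced cost row: r = cost - cost_B' Tb
    cb <- cost_full[basis]
    r <- cost_full[seq_len(ncols)] - as.numeric(cb %*% Tb[, seq_len(ncols),
                                                          drop = FALSE])
    fin <- function(status) {
      val <- as.numeric(cost_full[basis] %*% Tb[, rhs_col])
      list(Tb = Tb, basis = basis, val = val, status = status)
    }
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) return(fin("maxit"))
      enter <- 0L
      for (j in seq_len(ncols)) {        # Bland: smallest eligible index
        if (allowed[j] && r[j] < -eps) { enter <- j; break }
      }
      if (enter == 0L) return(fin("optimal"))
      col <- Tb[, enter]
      rows <- which(col > eps)
      if (!length(rows)) return(fin("unbounded"))
      ratios <- Tb[rows, rhs_col] / col[rows]
      best <- min(ratios)
      cand <- rows[ratios <= best + eps]
      leave <- cand[which.min(basis[cand])]   # Bland on ties
      # pivot
      piv <- Tb[leave, enter]
      Tb[leave, ] <- Tb[leave, ] / piv
      for (i in seq_len(m)) {
        if (i != leave && abs(Tb[i, enter]) > 0) {
          Tb[i, ] <- Tb[i, ] - Tb[i, enter] * Tb[leave, ]
        }
      }
      r <- r - r[enter] * Tb[leave, seq_len(ncols)]
      basis[leave] <- enter
    }
  }

  if (n_art) {
    cost1 <- c(rep(0, n), rep(1, n_art))
    ph1 <- run_phase(Tb, basis, cost1, allowed = rep(TRUE, ncols))
    if (ph1$status != "optimal" || ph1$val > 1e-7)
      return(list(status = if (ph1$status == "maxit") "maxit"
                  else "infeasible",
                  value = NA_real_, x = rep(NA_real_, n)))
    Tb <- ph1$Tb; basis <- ph1$basis
    # drive residual artificials out of the (degenerate) basis
    for (i in which(basis > n)) {
      piv_j <- 0L
      for (j in seq_len(n)) {
        if (abs(Tb[i, j]) > eps && !(j %in% basis)) { piv_j <- j; break }
      }
      if (piv_j == 0L) {
        Tb[i, ] <- 0   # redundant row
        next
      }
      piv <- Tb[i, piv_j]
      Tb[i, ] <- Tb[i, ] / piv
      for (k in seq_len(m)) if (k != i && abs(Tb[k, piv_j]) > 0)
        Tb[k, ] <- Tb[k, ] - Tb[k, piv_j] * Tb[i, ]
      basis[i] <- piv_j
    }
  }

  allowed2 <- c(rep(TRUE, n), rep(FALSE, n_art))
  cost2 <- c(cost, rep(0, n_art))
  ph2 <- run_phase(Tb, basis, cost2, allowed = allowed2)
  if (ph2$status != "optimal")
    return(list(status = ph2$status, value = NA_real_,
                x = rep(NA_real_, n)))
  x <- numeric(n)
  live <- ph2$basis <= n
  x[ph2$basis[live]] <- ph2$Tb[live, rhs_col]
  list(status = "optimal", value = sum(cost * x), x = x)
}
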