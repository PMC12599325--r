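# Dense two-phase simplex with Bland's rule for the box-constrained
# equality-form linear programs of flux balance analysis:
#
#   maximise  obj' x   subject to   Aeq x = beq,  0 <= x <= upper
#
# Sized for toy stoichiometric models (tens of variables). Bland's
# smallest-index rule guarantees termination on the highly degenerate
# (zero right-hand side) bases these problems produce.

simplex_box_lp <- function(Aeq, beq, upper, obj, tol = 1e-9) {
  m <- nrow(Aeq)
  n <- ncol(Aeq)
  stopifnot(length(beq) == m, length(upper) == n, length(obj) == n,
            all(is.finite(upper)), all(upper >= 0))
  neg <- beq < 0
  Aeq[neg, ] <- -Aeq[neg, , drop = FALSE]
  beq[neg] <- -beq[neg]
  scale <- max(1, abs(Aeq), abs(beq), upper)
  eps <- tol * scale

  # tableau columns: x (n) | bound slacks s (n) | artificials a (m)
  nr <- m + n
  nc <- 2L * n + m
  TT <- matrix(0, nr, nc)
  TT[seq_len(m), seq_len(n)] <- Aeq
  rhs <- c(beq, upper)
  for (k in seq_len(n)) {
    TT[m + k, k] <- 1
    TT[m + k, n + k] <- 1
  }
  for (i in seq_len(m)) TT[i, 2L * n + i] <- 1
  basis <- c(2L * n + seq_len(m), n + seq_len(n))

  pivot <- function(i, j) {
    prow <- TT[i, ] / TT[i, j]
    prhs <- rhs[i] / TT[i, j]
    colj <- TT[, j]
    TT <<- TT - outer(colj, prow)
    rhs <<- rhs - colj * prhs
    TT[i, ] <<- prow
    rhs[i] <<- prhs
    basis[i] <<- j
  }

  iterate <- function(cost, forbid) {
    repeat {
      red <- cost - as.numeric(cost[basis] %*% TT)
      red[basis] <- 0
      red[forbid] <- -Inf
      ent <- which(red > eps)
      if (!length(ent)) return("optimal")
      j <- min(ent) # Bland: smallest entering index
      col <- TT[, j]
      pos <- which(col > eps)
      if (!length(pos)) return("unbounded")
      ratios <- rhs[pos] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + eps]
      i <- cand[which.min(basis[cand])] # Bland: smallest leaving index
      pivot(i, j)
    }
  }

  # phase 1: drive the artificials to zero
  cost1 <- c(rep(0, 2L * n), rep(-1, m))
  st <- iterate(cost1, forbid = integer(0))
  if (st != "optimal") stop("phase-1 simplex failed") # cannot happen: bounded
  if (sum(rhs[basis > 2L * n]) > eps * max(1, m)) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                value = NA_real_))
  }
  # pivot lingering zero-level artificials out of the basis
  for (i in which(basis > 2L * n)) {
    j <- which(abs(TT[i, seq_len(2L * n)]) > eps)
    if (length(j)) pivot(i, min(j))
    # otherwise the row is redundant; the artificial stays at zero
  }

  # phase 2: the real objective, artificials locked out
  cost2 <- c(obj, rep(0, n + m))
  st <- iterate(cost2, forbid = 2L * n + seq_len(m))
  if (st == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n),
                value = NA_real_))
  }
  x <- numeric(nc)
  x[basis] <- rhs
  x <- pmin(pmax(x[seq_len(n)], 0), upper) # clip solver noise
  list(status = "optimal", x = x, value = sum(obj * x))
}
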