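# Dense two-phase primal simplex with variable bounds.
#
# Solves   max/min  c'v   s.t.  Aeq v = beq,  Ain v <= bin,  lb <= v <= ub
# with finite bounds. Problems in this package are small (tens to a few
# hundred variables), so a tableau method with Bland's anti-cycling rule is
# robust and fast enough; feasibility tolerance 1e-9.

#' Solve a small dense linear program
#'
#' @param obj Objective coefficients.
#' @param Aeq,beq Equality constraints (`Aeq v = beq`); may be `NULL`.
#' @param Ain,bin Inequality constraints (`Ain v <= bin`); may be `NULL`.
#' @param lb,ub Finite variable bounds.
#' @param maximize Maximize (default) or minimize.
#' @param tol Feasibility/pivot tolerance.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective` and `x`.
#' @export
solveLP <- function(obj, Aeq = NULL, beq = NULL, Ain = NULL, bin = NULL,
                    lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("bounds must be finite")
  if (any(lb > ub + tol)) return(list(status = "infeasible",
                                      objective = NA_real_, x = NULL))
  if (is.null(Aeq)) { Aeq <- matrix(0, 0, n); beq <- numeric(0) }
  if (is.null(Ain)) { Ain <- matrix(0, 0, n); bin <- numeric(0) }
  Aeq <- matrix(Aeq, ncol = n); Ain <- matrix(Ain, ncol = n)

  # shift to x = v - lb >= 0
  u <- ub - lb
  beq2 <- beq - as.vector(Aeq %*% lb)
  bin2 <- bin - as.vector(Ain %*% lb)

  # rows: equalities, inequalities (slack), upper bounds (slack)
  bounded <- which(u < Inf)
  A <- rbind(Aeq, Ain)
  rhs <- c(beq2, bin2)
  type <- c(rep("eq", nrow(Aeq)), rep("le", nrow(Ain)))
  if (length(bounded)) {
    Ub <- matrix(0, length(bounded), n)
    Ub[cbind(seq_along(bounded), bounded)] <- 1
    A <- rbind(A, Ub)
    rhs <- c(rhs, u[bounded])
    type <- c(type, rep("le", length(bounded)))
  }
  m <- nrow(A)
  nslack <- sum(type == "le")
  # build columns: x (n) | slacks (nslack) | artificials (added as needed)
  Tb <- cbind(A, matrix(0, m, nslack))
  sidx <- 0L
  slack_col <- integer(m)
  for (i in seq_len(m)) if (type[i] == "le") {
    sidx <- sidx + 1L
    Tb[i, n + sidx] <- 1
    slack_col[i] <- n + sidx
  }
  # normalize rhs >= 0
  neg <- rhs < 0
  Tb[neg, ] <- -Tb[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]
  # basis: slack if its coefficient survived as +1, else artificial
  basis <- integer(m)
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (slack_col[i] > 0 && Tb[i, slack_col[i]] > 0) {
      basis[i] <- slack_col[i]
    } else {
      Tb <- cbind(Tb, 0)
      Tb[i, ncol(Tb)] <- 1
      basis[i] <- ncol(Tb)
      art_cols <- c(art_cols, ncol(Tb))
    }
  }
  N <- ncol(Tb)

  pivot <- function(Tb, rhs, basis, cost, tol) {
    # minimize cost'x with Bland's rule; returns updated state
    repeat {
      # reduced costs: cost - cost_B' B^-1 A, maintained by elimination:
      cb <- cost[basis]
      red <- cost - as.vector(cb %*% Tb)
      enter <- which(red < -tol)
      if (!length(enter)) return(list(Tb = Tb, rhs = rhs, basis = basis,
                                      status = "optimal"))
      e <- min(enter)
      col <- Tb[, e]
      ok <- which(col > tol)
      if (!length(ok)) return(list(Tb = Tb, rhs = rhs, basis = basis,
                                   status = "unbounded"))
      ratio <- rhs[ok] / col[ok]
      cand <- ok[ratio <= min(ratio) + tol]
      l <- cand[which.min(basis[cand])]
      piv <- Tb[l, e]
      Tb[l, ] <- Tb[l, ] / piv
      rhs[l] <- rhs[l] / piv
      f <- Tb[, e]; f[l] <- 0
      Tb <- Tb - outer(f, Tb[l, ])
      rhs <- rhs - f * rhs[l]
      basis[l] <- e
    }
  }

  # eliminate basic columns from the working tableau first
  for (i in seq_len(m)) {
    piv <- Tb[i, basis[i]]
    Tb[i, ] <- Tb[i, ] / piv
    rhs[i] <- rhs[i] / piv
  }

  # phase 1
  if (length(art_cols)) {
    cost1 <- numeric(N)
    cost1[art_cols] <- 1
    r1 <- pivot(Tb, rhs, basis, cost1, tol)
    if (r1$status != "optimal")
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    Tb <- r1$Tb; rhs <- r1$rhs; basis <- r1$basis
    if (sum(rhs[basis %in% art_cols]) > 1e-7)
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    # pivot lingering zero-level artificials out where possible
    for (i in which(basis %in% art_cols)) {
      cand <- which(abs(Tb[i, seq_len(n + nslack)]) > tol)
      if (length(cand)) {
        e <- cand[1]
        piv <- Tb[i, e]
        Tb[i, ] <- Tb[i, ] / piv
        rhs[i] <- rhs[i] / piv
        for (j in seq_len(m)) if (j != i && abs(Tb[j, e]) > 0) {
          f <- Tb[j, e]
          Tb[j, ] <- Tb[j, ] - f * Tb[i, ]
          rhs[j] <- rhs[j] - f * rhs[i]
        }
        basis[i] <- e
      }
    }
    # forbid artificials from re-entering
    Tb[, art_cols] <- 0
  }

  # phase 2
  cost2 <- numeric(N)
  cost2[seq_len(n)] <- if (maximize) -obj else obj
  r2 <- pivot(Tb, rhs, basis, cost2, tol)
  if (r2$status == "unbounded")
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  x <- numeric(N)
  x[r2$basis] <- r2$rhs
  v <- x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), x = v)
}
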