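## Dense two-phase revised simplex with Bland's anti-cycling rule.
##
## Written for the small, fully dense flux programs this package solves
## (about 60 equality rows and 110 columns after splitting reversible
## fluxes): deterministic, no randomized perturbation, explicit basis
## re-factorization at every iteration.  Bland's rule guarantees finite
## termination on the degenerate vertices that flux cones produce.

## min c'x  s.t.  A x = b, x >= 0.  A must have full row rank; b may have
## any signs (rows are flipped internally).
## Returns list(x, value, status) with status in
## {"optimal", "infeasible", "unbounded"}.
simplex_std <- function(cc, A, b, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A)
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 2000L + 50L * (n + m)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  ## phase 1: artificial identity basis
  A1 <- cbind(A, diag(m))
  basis <- n + seq_len(m)
  run_phase <- function(cost, basis, allowed) {
    for (it in seq_len(max_iter)) {
      B <- A1[, basis, drop = FALSE]
      xB <- solve(B, b)
      y <- solve(t(B), cost[basis])
      ## Bland: entering = smallest allowed nonbasic index with d_j < -tol
      enter <- 0L
      for (j in allowed) {
        if (j %in% basis) next
        dj <- cost[j] - sum(y * A1[, j])
        if (dj < -tol) { enter <- j; break }
      }
      if (enter == 0L)
        return(list(basis = basis, xB = xB, status = "optimal"))
      w <- solve(B, A1[, enter])
      cand <- which(w > tol)
      if (!length(cand))
        return(list(basis = basis, xB = xB, status = "unbounded"))
      ratios <- xB[cand] / w[cand]
      rmin <- min(ratios)
      ties <- cand[ratios <= rmin + tol * (1 + abs(rmin))]
      leave_row <- ties[which.min(basis[ties])]   # Bland tie-break
      basis[leave_row] <- enter
    }
    stop("simplex iteration limit reached")
  }

  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(cost1, basis, seq_len(n + m))
  feas_val <- sum(cost1[ph1$basis] * ph1$xB)
  ## threshold well below the smallest meaningful bound displacement
  ## (1e-7) but far above phase-1 roundoff (~1e-13)
  if (feas_val > 1e-10 * max(1, max(abs(b))))
    return(list(x = NULL, value = NA_real_, status = "infeasible"))
  basis <- ph1$basis
  ## pivot remaining (degenerate) artificials out of the basis
  art_rows <- which(basis > n)
  if (length(art_rows)) {
    B <- A1[, basis, drop = FALSE]
    for (r in art_rows) {
      W <- solve(B, A1[, seq_len(n), drop = FALSE])
      j <- which(abs(W[r, ]) > 1e-8 & !(seq_len(n) %in% basis))
      if (length(j)) {
        basis[r] <- j[1]
        B <- A1[, basis, drop = FALSE]
      }
    }
  }
  if (any(basis > n)) {
    ## rows whose artificial cannot be pivoted out are redundant; keep the
    ## artificial pinned at zero by leaving its unit cost in phase 2
    cost2 <- c(cc, rep(1e6, m))
  } else {
    cost2 <- c(cc, rep(0, m))
  }
  ph2 <- run_phase(cost2, basis, seq_len(n))
  if (ph2$status == "unbounded")
    return(list(x = NULL, value = NA_real_, status = "unbounded"))
  x <- numeric(n)
  keep <- ph2$basis <= n
  x[ph2$basis[keep]] <- ph2$xB[keep]
  list(x = x, value = sum(cc * x), status = "optimal")
}

## General-form wrapper:
## max/min obj'v  s.t.  Aeq v = beq, Age v >= bge, v_i >= 0 for i in
## nonneg, remaining coordinates free.
lp_dense <- function(obj, Aeq = NULL, beq = NULL, Age = NULL, bge = NULL,
                     nonneg = integer(0), maximize = TRUE) {
  n <- length(obj)
  free <- setdiff(seq_len(n), nonneg)
  expand <- function(M) {
    if (is.null(M)) return(NULL)
    cbind(M, -M[, free, drop = FALSE])
  }
  nslack <- if (is.null(Age)) 0L else nrow(Age)
  A <- rbind(
    if (!is.null(Aeq))
      cbind(expand(Aeq), matrix(0, nrow(Aeq), nslack)) else NULL,
    if (!is.null(Age))
      cbind(expand(Age), -diag(nslack)) else NULL)
  b <- c(beq, bge)
  cc <- c(obj, -obj[free], rep(0, ncol(A) - n - length(free)))
  if (maximize) cc <- -cc
  res <- simplex_std(cc, A, b)
  if (res$status != "optimal")
    return(list(v = NULL, value = NA_real_, status = res$status))
  v <- res$x[seq_len(n)]
  if (length(free)) v <- replace(v, free,
                                 v[free] - res$x[n + seq_along(free)])
  list(v = unname(v), value = sum(obj * v), status = "optimal")
}
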