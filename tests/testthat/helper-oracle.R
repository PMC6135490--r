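# Independent oracle for the constrained least-squares core: Dykstra's
# alternating-projection algorithm for the projection of a point onto the
# intersection of an affine subspace (S v = 0) and a box (bounds).  With
# strictly positive weights the weighted problem is an unweighted
# projection in u = sqrt(w) * v coordinates.  The algorithm shares no code
# or ideas with the package's null-space active-set solver.
dykstra_lsei <- function(S, v0, weights, lower, upper,
                         max_iter = 200000L, tol = 1e-12) {
  stopifnot(all(weights > 0))
  wh <- sqrt(weights)
  A <- t(t(S) / wh)           # S %*% diag(1/wh)
  ## projector onto null(A): I - pinv(A) A
  svA <- svd(A)
  pos <- svA$d > max(dim(A)) * max(svA$d, 0) * 1e-12
  Vr <- svA$v[, pos, drop = FALSE]
  proj_null <- function(u) u - Vr %*% crossprod(Vr, u)
  lo <- lower * wh
  hi <- upper * wh
  u <- wh * v0
  p_inc <- q_inc <- numeric(length(u))
  for (it in seq_len(max_iter)) {
    y <- proj_null(u + p_inc)
    p_inc <- u + p_inc - y
    u_new <- pmin(pmax(y + q_inc, lo), hi)
    q_inc <- y + q_inc - u_new
    if (max(abs(u_new - u)) < tol && it > 10L) {
      u <- u_new
      break
    }
    u <- u_new
  }
  as.numeric(proj_null(u)) / wh   # final affine projection for exactness
}
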