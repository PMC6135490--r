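## The Lsei-FBA core: least squares with equality (mass balance) and
## inequality (irreversibility, displacement bounds) constraints.
##
## The program  min sum_i w_i (v_i - v0_i)^2  s.t.  S v = 0,  lb <= v <= ub
## is solved in the null space of S: writing v = Z y with Z an orthonormal
## basis of null(S), the equalities disappear and a primal active-set
## iteration handles the bounds.  All linear algebra is dense SVD/QR; the
## iteration is deterministic (no randomized starts, Bland-style smallest-
## index tie-breaking), so re-solves reproduce bit-identical certificates.

null_basis <- function(S, tol_factor = 1e-11) {
  if (nrow(S) == 0L) return(diag(ncol(S)))
  sv <- svd(S, nu = 0, nv = ncol(S))
  tol <- max(dim(S)) * max(sv$d, 0) * tol_factor
  rk <- sum(sv$d > tol)
  if (rk >= ncol(S)) matrix(0, ncol(S), 0) else
    sv$v[, (rk + 1):ncol(S), drop = FALSE]
}

## Moore-Penrose least-squares solve, min-norm on flat directions.
pinv_solve <- function(A, b, tol_factor = 1e-11) {
  if (ncol(A) == 0L) return(numeric(0))
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d, 0) * tol_factor
  pos <- sv$d > tol
  if (!any(pos)) return(numeric(ncol(A)))
  sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*% b) /
                                   sv$d[pos])
}

#' Assemble a constrained least-squares flux problem
#'
#' @param S A \code{stoich_matrix} (or plain numeric matrix with reaction
#'   columns) encoding the steady-state equalities \code{S v = 0}.
#' @param v0 Target flux vector (the fold-change-scaled healthy fluxes).
#' @param weights Non-negative per-reaction weights of the squared
#'   deviations; defaults to 1 everywhere.
#' @param irreversible Character vector of reaction ids (or integer
#'   indices) constrained to \code{v >= 0}.
#' @param lower,upper Optional named numeric vectors of extra per-reaction
#'   bounds (used by the displacement uniqueness certificate).
#' @return An object of class \code{lsei_problem} with the null-space basis
#'   of \code{S} precomputed.
#' @export
lsei_problem <- function(S, v0, weights = NULL, irreversible = integer(0),
                         lower = NULL, upper = NULL) {
  if (inherits(S, "stoich_matrix")) {
    ids <- S$col_index
    S <- S$S
  } else {
    ids <- colnames(S)
    if (is.null(ids)) ids <- as.character(seq_len(ncol(S)))
  }
  n <- ncol(S)
  if (length(v0) != n) stop("v0 length does not match reaction count")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length does not match reactions")
  if (any(weights < 0)) stop("weights must be non-negative")
  irr <- if (is.character(irreversible)) match(irreversible, ids) else
    as.integer(irreversible)
  if (anyNA(irr)) stop("unknown irreversible reaction id(s)")
  lb <- rep(-Inf, n)
  lb[irr] <- 0
  ub <- rep(Inf, n)
  apply_named <- function(base, extra, f) {
    if (is.null(extra)) return(base)
    idx <- match(names(extra), ids)
    if (anyNA(idx)) stop("bound names reference unknown reactions")
    base[idx] <- f(base[idx], unname(extra))
    base
  }
  lb <- apply_named(lb, lower, pmax)
  ub <- apply_named(ub, upper, pmin)
  structure(list(S = S, ids = ids, v0 = as.numeric(v0),
                 weights = as.numeric(weights), irr = irr,
                 lower = lb, upper = ub, Z = null_basis(S)),
            class = "lsei_problem")
}

## Feasible point of { G y >= h } via the phase-1 simplex.
feasible_point <- function(G, h) {
  if (nrow(G) == 0L) return(numeric(ncol(G)))
  res <- lp_dense(numeric(ncol(G)), Age = G, bge = h, maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  res$v
}

## Primal active-set solver for  min ||C y - d||^2  s.t.  G y >= h.
## Returns list(y, iterations, kkt_residual) or NULL when infeasible.
lsi_active_set <- function(C, d, G, h, tol = 1e-10, max_iter = NULL) {
  k <- ncol(C)
  if (k == 0L) return(list(y = numeric(0), iterations = 0L,
                           kkt_residual = 0))
  m <- nrow(G)
  if (is.null(max_iter)) max_iter <- 100L + 20L * (m + k)
  y <- if (m > 0L && any(G %*% numeric(k) - h < -tol)) {
    fp <- feasible_point(G, h)
    if (is.null(fp)) return(NULL)
    fp
  } else numeric(k)
  active <- integer(0)
  for (it in seq_len(max_iter)) {
    GA <- G[active, , drop = FALSE]
    N <- if (length(active)) null_basis(GA) else diag(k)
    if (ncol(N) == 0L) {
      y_new <- y
    } else {
      z <- pinv_solve(C %*% N, d - C %*% y)
      y_new <- y + as.numeric(N %*% z)
    }
    step <- y_new - y
    if (sqrt(sum(step^2)) <= tol * (1 + sqrt(sum(y^2)))) {
      ## stationary on the working set: check multipliers
      grad <- 2 * as.numeric(crossprod(C, C %*% y - d))
      if (!length(active)) {
        resid <- sqrt(sum(grad^2))
        return(list(y = y, iterations = it, kkt_residual = resid))
      }
      lam <- as.numeric(pinv_solve(t(GA), grad))
      resid <- sqrt(sum((as.numeric(t(GA) %*% lam) - grad)^2))
      neg <- which(lam < -1e-9)
      if (!length(neg))
        return(list(y = y, iterations = it, kkt_residual = resid))
      drop_i <- neg[which.min(lam[neg])]
      active <- active[-drop_i]
      next
    }
    ## ratio test against inactive constraints
    alpha <- 1
    block <- 0L
    if (m > 0L) {
      inactive <- setdiff(seq_len(m), active)
      for (i in inactive) {
        gi_step <- sum(G[i, ] * step)
        if (gi_step < -tol) {
          slack <- sum(G[i, ] * y) - h[i]
          ai <- max(0, slack / (-gi_step))
          if (ai < alpha - 1e-14 || (abs(ai - alpha) <= 1e-14 && block > i)) {
            alpha <- min(alpha, ai)
            block <- i
          }
        }
      }
    }
    y <- y + alpha * step
    if (alpha < 1 && block > 0L) active <- sort(c(active, block))
  }
  stop("active-set iteration limit reached")
}

#' Solve the constrained least-squares flux problem
#'
#' Minimizes the weighted sum of squared deviations from the target flux
#' vector subject to steady-state balance and the problem's bounds
#' (non-negativity of irreversible reactions plus any extra bounds).  The
#' zero vector is feasible for the standard problem, so the program is
#' always satisfiable unless extra bounds exclude the whole cone.
#'
#' @param p An \code{lsei_problem}.
#' @param v0 Optional replacement target vector (the cached null-space
#'   basis is reused; used heavily by the permutation test).
#' @return An \code{lsei_solution}: list with the flux vector \code{v}
#'   (named), \code{ssq}, \code{balance_residual}, \code{kkt_residual} and
#'   \code{iterations}.  \code{NULL} is never returned; an infeasible bound
#'   set raises an error (callers probing displaced bounds catch it).
#' @export
solve_lsei <- function(p, v0 = NULL) {
  stopifnot(inherits(p, "lsei_problem"))
  if (!is.null(v0)) p$v0 <- as.numeric(v0)
  n <- length(p$ids)
  Z <- p$Z
  wh <- sqrt(p$weights)
  C <- Z * wh   # diag(wh) %*% Z, row scaling
  d <- wh * p$v0
  rows <- list()
  h <- numeric(0)
  fin_l <- which(is.finite(p$lower))
  fin_u <- which(is.finite(p$upper))
  G <- rbind(Z[fin_l, , drop = FALSE], -Z[fin_u, , drop = FALSE])
  h <- c(p$lower[fin_l], -p$upper[fin_u])
  res <- lsi_active_set(C, d, G, h)
  if (is.null(res))
    stop("LSEI problem infeasible under the supplied bounds")
  v <- as.numeric(Z %*% res$y)
  names(v) <- p$ids
  structure(list(
    v = v,
    ssq = sum(p$weights * (v - p$v0)^2),
    balance_residual = if (nrow(p$S)) max(abs(p$S %*% v)) else 0,
    kkt_residual = res$kkt_residual,
    iterations = res$iterations,
    problem = p), class = "lsei_solution")
}

#' @export
print.lsei_solution <- function(x, ...) {
  cat("lsei_solution: ssq =", format(x$ssq, digits = 8),
      "| balance residual =", format(x$balance_residual, digits = 3),
      "| KKT residual =", format(x$kkt_residual, digits = 3), "\n")
  if (!is.null(x$uniqueness))
    cat("uniqueness certificate:",
        if (isTRUE(attr(x$uniqueness, "unique"))) "unique" else
          "NOT unique", "\n")
  invisible(x)
}

#' Displacement uniqueness certificate
#'
#' For every reaction the solver is re-run twice with the reaction's flux
#' forced below (upper bound) and above (lower bound) the solution value by
#' a small displacement, \code{max(rel * |v_i|, abs_floor)}.  The solution
#' is certified unique when every such perturbed minimal cost exceeds the
#' original \code{ssq} by more than \code{gap} (displacements that are
#' infeasible, e.g. pushing an irreversible zero flux negative, count as
#' infinitely costly).
#'
#' @param p The \code{lsei_problem} that produced \code{sol}.
#' @param sol The \code{lsei_solution} to certify.
#' @param rel Relative displacement (default 1e-5, i.e. 0.00001 times the
#'   flux value: a flux of 0.193846 is displaced by 1.93846e-6).
#' @param abs_floor Absolute displacement floor so zero fluxes are also
#'   displaced (default 1e-7).
#' @param gap Strictness margin on the cost increase (default 1e-16).  A
#'   displacement of size \code{d} can raise a strictly convex cost by as
#'   little as order \code{d^2} (1e-14 for a floor displacement), so the
#'   margin must sit between that and the solver's numerical noise in
#'   \code{ssq} (around 1e-20); margins at or above 1e-12 would misreport
#'   genuinely unique solutions with small fluxes as non-unique.
#' @return A data.frame (class \code{uniqueness_report}) with per-reaction
#'   \code{ssq_low}, \code{ssq_high}, \code{displacement}; attribute
#'   \code{unique} carries the verdict.
#' @export
uniqueness_test <- function(p, sol, rel = 1e-5, abs_floor = 1e-7,
                            gap = 1e-16) {
  n <- length(p$ids)
  ssq0 <- sol$ssq
  disp <- pmax(rel * abs(sol$v), abs_floor)
  ssq_low <- ssq_high <- numeric(n)
  probe <- function(extra_lower, extra_upper) {
    q <- p
    if (!is.null(extra_lower)) {
      i <- match(names(extra_lower), q$ids)
      q$lower[i] <- pmax(q$lower[i], extra_lower)
    }
    if (!is.null(extra_upper)) {
      i <- match(names(extra_upper), q$ids)
      q$upper[i] <- pmin(q$upper[i], extra_upper)
    }
    if (any(q$lower > q$upper + 1e-15)) return(Inf)
    s <- tryCatch(solve_lsei(q), error = function(e) NULL)
    if (is.null(s)) Inf else s$ssq
  }
  for (i in seq_len(n)) {
    id <- p$ids[i]
    ssq_low[i] <- probe(NULL, stats::setNames(sol$v[i] - disp[i], id))
    ssq_high[i] <- probe(stats::setNames(sol$v[i] + disp[i], id), NULL)
  }
  rep <- data.frame(id = p$ids, displacement = disp,
                    ssq_low = ssq_low, ssq_high = ssq_high,
                    stringsAsFactors = FALSE)
  attr(rep, "unique") <- all(ssq_low > ssq0 + gap & ssq_high > ssq0 + gap)
  attr(rep, "ssq") <- ssq0
  class(rep) <- c("uniqueness_report", "data.frame")
  rep
}

#' Is a displacement report a uniqueness certificate?
#' @param report A \code{uniqueness_report}.
#' @return Logical.
#' @export
lsei_unique <- function(report) isTRUE(attr(report, "unique"))

#' Predict the diseased flux distribution from fold changes
#'
#' Implements the disease stage of Lsei-FBA: the target vector is the
#' healthy flux scaled per reaction by its expression fold change; the
#' prediction is its weighted least-squares projection onto the
#' steady-state cone (balance equalities plus forward-only irreversible
#' reactions).  No exchange rates are fixed: diseased uptake and release
#' rates are outputs.
#'
#' @param net The metabolic network.
#' @param healthy Healthy \code{flux_distribution} (from
#'   \code{\link{solve_fba}}).
#' @param fcs A \code{fold_change_map} from
#'   \code{\link{reaction_fold_changes}}.
#' @param weights_policy \code{"coverage"} (default): weight 1 for
#'   gene-covered reactions, 0 for reactions without expression evidence,
#'   whose fluxes are then set purely by network balance;
#'   \code{"uniform"}: weight 1 everywhere.
#' @param uniqueness Attach the displacement uniqueness certificate
#'   (default TRUE).
#' @return An \code{lsei_solution} with provenance fields: a per-reaction
#'   \code{table} (healthy flux, fold change, target, prediction, delta),
#'   \code{totals} from \code{\link{derived_totals}}, and optionally
#'   \code{uniqueness}.
#' @export
predict_disease_fluxes <- function(net, healthy, fcs,
                                   weights_policy = c("coverage", "uniform"),
                                   uniqueness = TRUE) {
  weights_policy <- match.arg(weights_policy)
  sm <- build_stoich_matrix(net)
  v0 <- initial_flux_estimate(healthy, fcs)
  w <- if (weights_policy == "coverage")
    as.numeric(fcs$coverage[sm$col_index] > 0) else rep(1, ncol(sm$S))
  p <- lsei_problem(sm, v0 = v0[sm$col_index], weights = w,
                    irreversible = irreversible_ids(net))
  sol <- solve_lsei(p)
  hv <- healthy$values[sm$col_index]
  tab <- data.frame(
    reaction_id = sm$col_index,
    subsystem = net$reactions$subsystem,
    healthy_flux = unname(hv),
    fold_change = unname(fcs$reaction_fc[sm$col_index]),
    n_genes = unname(fcs$coverage[sm$col_index]),
    v0 = unname(v0[sm$col_index]),
    predicted_flux = unname(sol$v),
    delta = unname(sol$v - hv),
    delta_percent = ifelse(hv != 0, 100 * (sol$v - hv) / hv, NA_real_),
    stringsAsFactors = FALSE)
  sol$table <- tab
  sol$weights_policy <- weights_policy
  sol$totals <- derived_totals(sol$v, net)
  if (uniqueness) sol$uniqueness <- uniqueness_test(p, sol)
  sol$provenance <- "diseased_LSEI"
  sol
}

#' Write a per-study prediction table
#'
#' @param sol An \code{lsei_solution} from
#'   \code{\link{predict_disease_fluxes}}.
#' @param path Output path (tab-delimited; \code{#}-prefixed header records
#'   the weight policy).
#' @return \code{path}, invisibly.
#' @export
write_prediction <- function(sol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# lsei-fba prediction; weights_policy=",
                    sol$weights_policy,
                    "; ssq=", format(sol$ssq, digits = 10),
                    "; units=umol/g wet brain/min"), con)
  utils::write.table(sol$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
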