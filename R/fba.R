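## Healthy-state flux balance analysis: linear programming under measured
## exchange rates and flux-ratio constraints, plus flux variability analysis.

#' Flux constraint set for the healthy state
#'
#' @param fixed_exchanges Named numeric vector: reaction id -> fixed rate
#'   (micromol/g/min; positive = uptake, negative = release).
#' @param ratio_constraints data.frame with columns \code{numerator},
#'   \code{reference}, \code{fraction}, each row encoding
#'   \code{v[numerator] - fraction * v[reference] = 0}.
#' @param objective_reaction Reaction id whose flux the LP maximizes.
#' @return An object of class \code{flux_constraints}.
#' @export
flux_constraints <- function(fixed_exchanges, ratio_constraints,
                             objective_reaction) {
  stopifnot(is.numeric(fixed_exchanges), !is.null(names(fixed_exchanges)))
  stopifnot(all(c("numerator", "reference", "fraction") %in%
                  names(ratio_constraints)))
  if (any(ratio_constraints$fraction <= 0 | ratio_constraints$fraction > 1))
    stop("ratio fractions must lie in (0, 1]")
  structure(list(fixed_exchanges = fixed_exchanges,
                 ratio_constraints = ratio_constraints,
                 objective_reaction = objective_reaction),
            class = "flux_constraints")
}

#' @export
print.flux_constraints <- function(x, ...) {
  cat("flux_constraints:", length(x$fixed_exchanges), "fixed exchanges,",
      nrow(x$ratio_constraints), "flux ratios; objective:",
      x$objective_reaction, "\n")
  invisible(x)
}

#' Measured constraints for the healthy elderly human brain
#'
#' Glucose uptake fixed at 0.203 and lactate, glutamine and pyruvate
#' release at 0.0092, 0.011 and 0.0024 micromol/g wet brain/min; pentose
#' phosphate pathway flux at 6.9\% of the hexokinase (glycolytic) flux;
#' pyruvate carboxylase, glutamine-glutamate cycling (glutaminase) and GABA
#' shunt (glutamate decarboxylase) fluxes at 13\%, 62\% and 32\% of the
#' glucose uptake; objective: maximize mitochondrial ATP synthase flux.
#'
#' @return A \code{flux_constraints} object.
#' @export
default_constraints <- function() {
  path <- system.file("extdata", "healthy_constraints.tsv",
                      package = PKG_NAME, mustWork = TRUE)
  read_constraints(path)
}

#' Read a constraint file
#'
#' Tab-delimited with columns \code{reaction_id}, \code{type} (one of
#' fixed/ratio/objective), \code{value} and \code{reference_id} (ratio rows
#' only).
#'
#' @param path File path.
#' @return A \code{flux_constraints} object.
#' @export
read_constraints <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  fixed <- tab[tab$type == "fixed", ]
  ratios <- tab[tab$type == "ratio", ]
  obj <- tab[tab$type == "objective", ]
  if (nrow(obj) != 1L) stop("constraint file must name exactly one objective")
  flux_constraints(
    fixed_exchanges = stats::setNames(fixed$value, fixed$reaction_id),
    ratio_constraints = data.frame(numerator = ratios$reaction_id,
                                   reference = ratios$reference_id,
                                   fraction = ratios$value,
                                   stringsAsFactors = FALSE),
    objective_reaction = obj$reaction_id)
}

check_constraint_refs <- function(net, cons) {
  ids <- net$reactions$id
  refs <- c(names(cons$fixed_exchanges), cons$ratio_constraints$numerator,
            cons$ratio_constraints$reference, cons$objective_reaction)
  unknown <- setdiff(refs, ids)
  if (length(unknown))
    stop("constraints reference unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  invisible(TRUE)
}

## ---- generic dense LP over a flux space ------------------------------------

## Solves max/min obj'v subject to A v = b, v_i >= 0 for i in nonneg,
## other coordinates free.  Free coordinates are split into positive and
## negative parts for the two-phase simplex in boot::simplex.
## Returns list(v, value, status) with status one of "optimal",
## "infeasible", "unbounded".
lp_flux <- function(obj, A, b, nonneg, maximize = TRUE) {
  ## drop linearly dependent equality rows (conserved moieties make the
  ## balance system row-rank-deficient); consistency of the dropped rows is
  ## re-checked against the full system by the callers
  qrA <- qr(t(A), tol = 1e-10)
  indep <- sort(qrA$pivot[seq_len(qrA$rank)])
  res <- lp_dense(obj, Aeq = A[indep, , drop = FALSE], beq = b[indep],
                  nonneg = nonneg, maximize = maximize)
  if (res$status == "optimal" &&
      max(abs(A %*% res$v - b)) > 1e-8 * max(1, max(abs(b)))) {
    ## the dropped (linearly dependent) rows are inconsistent with the
    ## kept ones: the full system has no solution
    return(list(v = NULL, value = NA_real_, status = "infeasible"))
  }
  res
}

## Assemble the equality system for a constrained FBA problem:
## balance rows (S v = 0), fixed-exchange rows, ratio rows.
fba_equalities <- function(net, cons) {
  sm <- build_stoich_matrix(net)
  ids <- sm$col_index
  n <- length(ids)
  rows <- list(sm$S)
  b <- rep(0, nrow(sm$S))
  labels <- paste0("balance:", sm$row_index)
  for (rid in names(cons$fixed_exchanges)) {
    row <- rep(0, n)
    row[match(rid, ids)] <- 1
    rows <- c(rows, list(matrix(row, nrow = 1)))
    b <- c(b, cons$fixed_exchanges[[rid]])
    labels <- c(labels, paste0("fixed:", rid))
  }
  rc <- cons$ratio_constraints
  for (i in seq_len(nrow(rc))) {
    row <- rep(0, n)
    row[match(rc$numerator[i], ids)] <- 1
    row[match(rc$reference[i], ids)] <- -rc$fraction[i]
    rows <- c(rows, list(matrix(row, nrow = 1)))
    b <- c(b, 0)
    labels <- c(labels, paste0("ratio:", rc$numerator[i]))
  }
  A <- do.call(rbind, rows)
  rownames(A) <- labels
  list(A = A, b = b, ids = ids,
       nonneg = which(ids %in% irreversible_ids(net)))
}

## Greedy deletion filter: returns a (near-)irreducible infeasible subset of
## the named (fixed/ratio) constraints, keeping balance rows as core.
infeasible_subset <- function(obj, eq, maximize) {
  named <- grep("^(fixed|ratio):", rownames(eq$A))
  keep <- named
  for (i in named) {
    trial <- setdiff(keep, i)
    sel <- sort(c(setdiff(seq_len(nrow(eq$A)), named), trial))
    st <- lp_flux(obj, eq$A[sel, , drop = FALSE], eq$b[sel], eq$nonneg,
                  maximize)$status
    if (st == "infeasible") keep <- trial
  }
  rownames(eq$A)[keep]
}

#' Solve the healthy-state flux balance problem
#'
#' Maximizes the objective reaction's flux subject to steady-state balance
#' of all internal metabolites, the fixed exchange rates, the flux-ratio
#' equalities, non-negativity of irreversible reactions, and free reversible
#' reactions.
#'
#' @param net A validated \code{metabolic_network}.
#' @param cons A \code{flux_constraints} object.
#' @return A \code{flux_distribution}: list with \code{values} (named flux
#'   vector), \code{provenance = "healthy_LP"} and \code{objective_value}.
#' @export
solve_fba <- function(net, cons) {
  check_constraint_refs(net, cons)
  eq <- fba_equalities(net, cons)
  obj <- as.numeric(eq$ids == cons$objective_reaction)
  res <- lp_flux(obj, eq$A, eq$b, eq$nonneg, maximize = TRUE)
  if (res$status == "infeasible")
    stop("FBA problem is infeasible; irreducible infeasible constraint ",
         "subset: ", paste(infeasible_subset(obj, eq, TRUE), collapse = ", "))
  if (res$status != "optimal")
    stop("FBA problem is ", res$status,
         " (an unbounded problem indicates a missing bound or leak)")
  v <- stats::setNames(res$v, eq$ids)
  resid <- max(abs(eq$A %*% res$v - eq$b))
  if (resid > 1e-8)
    stop("LP solution violates constraints (residual ", format(resid), ")")
  flux_distribution(v, provenance = "healthy_LP",
                    objective_value = res$value)
}

#' Flux distribution container
#'
#' @param values Named numeric vector of per-reaction fluxes
#'   (micromol/g/min).
#' @param provenance \code{"healthy_LP"} or \code{"diseased_LSEI"}.
#' @param objective_value Scalar objective at the solution.
#' @return An object of class \code{flux_distribution}.
#' @export
flux_distribution <- function(values, provenance = c("healthy_LP",
                                                     "diseased_LSEI"),
                              objective_value = NA_real_) {
  provenance <- match.arg(provenance)
  structure(list(values = values, provenance = provenance,
                 objective_value = objective_value),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("flux_distribution (", x$provenance, "): ", length(x$values),
      " reactions, objective = ", format(x$objective_value, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis at a fixed objective
#'
#' For every reaction, minimizes and maximizes its flux over the feasible
#' set with the objective pinned to \code{at_objective}.  The solution is
#' certified unique when every (max - min) span is at most \code{tol}.
#' Internally the equality system is reduced to its null space, so only
#' reactions with genuine degrees of freedom require LP solves.
#'
#' @param net A validated \code{metabolic_network}.
#' @param cons A \code{flux_constraints}.
#' @param at_objective Objective value at which to probe (usually the
#'   optimum from \code{\link{solve_fba}}).
#' @param tol Span tolerance for declaring uniqueness (default 1e-6).
#' @return An \code{fva_report}: data.frame with columns \code{id},
#'   \code{min}, \code{max}, \code{span}, plus attribute \code{unique}.
#' @export
flux_variability <- function(net, cons, at_objective, tol = 1e-6) {
  check_constraint_refs(net, cons)
  eq <- fba_equalities(net, cons)
  obj_row <- as.numeric(eq$ids == cons$objective_reaction)
  A <- rbind(eq$A, objective = obj_row)
  b <- c(eq$b, at_objective)
  ## particular solution + null-space basis of the pinned equality system
  n <- length(eq$ids)
  sv <- svd(A, nu = nrow(A), nv = n)
  rk <- sum(sv$d > max(dim(A)) * max(sv$d) * 1e-12)
  vp <- sv$v[, seq_len(rk), drop = FALSE] %*%
    ((t(sv$u[, seq_len(rk), drop = FALSE]) %*% b) / sv$d[seq_len(rk)])
  if (max(abs(A %*% vp - b)) > 1e-7)
    stop("no flux vector attains the requested objective value")
  Z <- if (rk < n) sv$v[, (rk + 1):n, drop = FALSE] else
    matrix(0, n, 0)
  k <- ncol(Z)
  vmin <- vmax <- as.numeric(vp)
  if (k > 0) {
    ## feasibility in reduced space: (vp + Z y)_i >= 0 for irreversible i
    Gi <- Z[eq$nonneg, , drop = FALSE]
    hi <- -vp[eq$nonneg]
    for (i in seq_len(n)) {
      zi <- Z[i, ]
      if (sqrt(sum(zi^2)) < 1e-11) next
      for (dir in c(-1, 1)) {
        res <- lp_dense(dir * zi, Age = Gi, bge = hi, maximize = TRUE)
        if (res$status != "optimal")
          stop("FVA subproblem for reaction '", eq$ids[i],
               "' did not solve (status ", res$status, ")")
        val <- vp[i] + dir * res$value
        if (dir > 0) vmax[i] <- val else vmin[i] <- val
      }
    }
  }
  rep <- data.frame(id = eq$ids, min = vmin, max = vmax,
                    span = vmax - vmin, stringsAsFactors = FALSE)
  attr(rep, "unique") <- all(rep$span <= tol)
  attr(rep, "at_objective") <- at_objective
  class(rep) <- c("fva_report", "data.frame")
  rep
}

#' Is an FVA report a uniqueness certificate?
#' @param report An \code{fva_report}.
#' @return Logical: TRUE when all spans were within tolerance.
#' @export
fva_unique <- function(report) isTRUE(attr(report, "unique"))

#' Derived whole-tissue totals from a flux distribution
#'
#' Summaries reported alongside a solution of the packaged brain model:
#' mitochondrial ATP production (ATP synthase flux), mitochondrial ATP
#' export (adenine nucleotide translocase), oxygen uptake, carbon dioxide
#' release, net lactate release, and the oxygen:glucose and ATP:glucose
#' uptake ratios (0 when glucose uptake is 0).
#'
#' @param v A \code{flux_distribution} (or named flux vector).
#' @param net The network the fluxes belong to.
#' @return Named list of totals.
#' @export
derived_totals <- function(v, net) {
  x <- if (inherits(v, "flux_distribution")) v$values else v
  g <- function(id) if (id %in% names(x)) unname(x[[id]]) else 0
  glc <- g("GLCt1r")
  atp <- g("ATPS4mi")
  o2 <- g("O2t")
  list(
    atp_mito = atp,
    atp_export = g("ATPtm"),
    o2_uptake = o2,
    co2_release = g("CO2t"),        # written cytosol -> blood
    lactate_release = -g("L_LACt2r"),  # uptake-positive convention
    o2_glucose_ratio = if (glc != 0) o2 / glc else 0,
    atp_glucose_ratio = if (glc != 0) atp / glc else 0)
}
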