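## Significance machinery: dependent flux sets, cross-study t-tests,
## per-study label-permutation p-values, Fisher meta-analysis,
## Holm-Bonferroni family-wise error control.

#' Partition reactions into fully coupled (dependent) sets
#'
#' Reactions in an unbranched sequence carry identical flux at steady
#' state, so their predictions are completely dependent and are tested
#' once per set.  Coupling is detected structurally: two reactions are
#' fully coupled with ratio +/-1 exactly when their coordinate rows in a
#' null-space basis of S are equal up to sign; the grouping is then
#' verified on random interior points of the null space so that reactions
#' whose healthy fluxes merely coincide numerically are not merged.
#'
#' @param net A \code{metabolic_network}.
#' @param healthy Healthy \code{flux_distribution} (used for the
#'   equal-|flux| sanity check recorded in the result).
#' @param n_check Number of random null-space points for verification
#'   (default 50).
#' @param seed Seed for the verification points (default 1).
#' @return A \code{reaction_set_partition}: list with \code{sets} (list of
#'   reaction-id groups), \code{n_sets}, and \code{representatives} (first
#'   member of each set).
#' @export
dependent_sets <- function(net, healthy = NULL, n_check = 50L, seed = 1L) {
  sm <- build_stoich_matrix(net)
  Z <- null_basis(sm$S)
  n <- ncol(sm$S)
  ids <- sm$col_index
  norms <- sqrt(rowSums(Z^2))
  ## random interior points for verification
  rng <- local({
    set.seed(seed)
    matrix(stats::rnorm(ncol(Z) * n_check), ncol(Z), n_check)
  })
  V <- Z %*% rng   # n x n_check flux values spanning the null space
  assigned <- rep(NA_integer_, n)
  next_set <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    next_set <- next_set + 1L
    assigned[i] <- next_set
    if (norms[i] < 1e-10) {
      ## structurally blocked reaction: zero everywhere, its own set
      next
    }
    for (j in seq_len(n)) {
      if (!is.na(assigned[j]) || norms[j] < 1e-10) next
      same <- max(abs(Z[j, ] - Z[i, ])) < 1e-8
      opp <- max(abs(Z[j, ] + Z[i, ])) < 1e-8
      if ((same || opp) &&
          max(abs(abs(V[j, ]) - abs(V[i, ]))) < 1e-8 * (1 + max(abs(V[i, ]))))
        assigned[j] <- next_set
    }
  }
  sets <- split(ids, assigned)
  names(sets) <- paste0("set", seq_along(sets))
  part <- structure(list(
    sets = sets, n_sets = length(sets),
    representatives = vapply(sets, `[`, character(1), 1)),
    class = "reaction_set_partition")
  if (!is.null(healthy)) {
    hv <- if (inherits(healthy, "flux_distribution")) healthy$values else
      healthy
    spread <- vapply(sets, function(s) diff(range(abs(hv[s]))), numeric(1))
    part$max_abs_flux_spread <- max(spread)
  }
  part
}

#' @export
print.reaction_set_partition <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("reaction_set_partition:", x$n_sets, "independent sets (",
      sum(sizes > 1), "multi-reaction );",
      "largest set size", max(sizes), "\n")
  invisible(x)
}

#' One-sample t-tests of predicted fluxes across studies
#'
#' For one representative reaction per dependent set, tests the per-study
#' diseased predictions against the healthy flux (two-sided one-sample
#' t-test).  Sets with zero variance across studies cannot be tested and
#' are flagged degenerate, with p reported as 1 when every prediction
#' equals the healthy value and 0 otherwise.
#'
#' @param predictions Numeric matrix of predicted fluxes, reactions x
#'   studies (rownames = reaction ids), or a list of named flux vectors.
#' @param healthy Healthy \code{flux_distribution} (or named vector).
#' @param partition A \code{reaction_set_partition}.
#' @return data.frame with one row per set: representative id, members,
#'   n studies, mean delta, t, p, degenerate flag.
#' @export
ttest_across_studies <- function(predictions, healthy, partition) {
  if (is.list(predictions) && !is.matrix(predictions))
    predictions <- do.call(cbind, predictions)
  if (ncol(predictions) < 2L) stop("need at least two studies")
  hv <- if (inherits(healthy, "flux_distribution")) healthy$values else
    healthy
  reps <- partition$representatives
  out <- data.frame(set = names(partition$sets),
                    representative = unname(reps),
                    members = vapply(partition$sets, paste, character(1),
                                     collapse = ";"),
                    n = ncol(predictions),
                    mean_delta = NA_real_, t = NA_real_, p = NA_real_,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(reps)) {
    x <- predictions[reps[k], ]
    mu <- hv[[reps[k]]]
    out$mean_delta[k] <- mean(x) - mu
    if (stats::sd(x) < 1e-14) {
      out$degenerate[k] <- TRUE
      out$t[k] <- if (abs(mean(x) - mu) < 1e-14) 0 else Inf
      out$p[k] <- if (abs(mean(x) - mu) < 1e-14) 1 else 0
    } else {
      tt <- stats::t.test(x, mu = mu)
      out$t[k] <- unname(tt$statistic)
      out$p[k] <- tt$p.value
    }
  }
  out
}

#' Label-permutation significance test for one study
#'
#' The observed statistic per reaction is the difference between the
#' diseased prediction under the true labeling and the healthy flux.  The
#' sample group labels are then permuted (group sizes preserved) and the
#' entire fold-change + least-squares pipeline is re-run per permutation.
#' Two-tailed p-values use the add-one estimator
#' \code{(1 + #\{|delta_perm| >= |delta_obs|\}) / (n_perm + 1)}; when the
#' number of distinct relabelings is at most \code{n_perm} they are
#' enumerated exhaustively instead and the p-value is the exact fraction.
#'
#' @param study An \code{expression_study} (>= 2 samples per group).
#' @param net The metabolic network.
#' @param healthy Healthy \code{flux_distribution}.
#' @param n_perm Number of permutations (default 1e5 as in desk use;
#'   reduce for quick runs).
#' @param seed RNG seed for the permutation draws.
#' @param weights_policy See \code{\link{predict_disease_fluxes}}.
#' @return A \code{permutation_result}: data.frame of per-reaction
#'   observed delta and two-tailed p; attributes record study id, seed,
#'   n_perm and whether enumeration was exhaustive.
#' @export
permutation_test <- function(study, net, healthy, n_perm = 100000L,
                             seed = 1L,
                             weights_policy = c("coverage", "uniform")) {
  weights_policy <- match.arg(weights_policy)
  groups <- study$groups
  n_c <- sum(groups == "control")
  n_p <- sum(groups == "patient")
  if (n_c < 2L || n_p < 2L)
    stop("permutation test needs at least two samples per group")
  sm <- build_stoich_matrix(net)
  hv <- healthy$values[sm$col_index]
  predict_v <- function(labels) {
    st <- study
    st$groups <- labels
    fcs <- reaction_fold_changes(gene_fold_changes(st), net)
    v0 <- initial_flux_estimate(healthy, fcs)[sm$col_index]
    solve_lsei(base_problem, v0 = v0)$v
  }
  gene_cov <- reaction_fold_changes(
    stats::setNames(rep(1, nrow(study$matrix)), rownames(study$matrix)),
    net)$coverage
  w <- if (weights_policy == "coverage")
    as.numeric(gene_cov[sm$col_index] > 0) else rep(1, ncol(sm$S))
  base_problem <- lsei_problem(sm, v0 = hv, weights = w,
                               irreversible = irreversible_ids(net))
  obs <- predict_v(groups) - hv
  n_total <- length(groups)
  n_distinct <- choose(n_total, n_c)
  exhaustive <- n_distinct <= n_perm
  exceed <- integer(length(obs))
  if (exhaustive) {
    combos <- utils::combn(n_total, n_c)
    n_used <- ncol(combos)
    for (k in seq_len(n_used)) {
      lab <- rep("patient", n_total)
      lab[combos[, k]] <- "control"
      d <- predict_v(lab) - hv
      exceed <- exceed + (abs(d) >= abs(obs) - 1e-12)
    }
    p <- exceed / n_used
  } else {
    set.seed(seed)
    n_used <- n_perm
    for (k in seq_len(n_perm)) {
      lab <- sample(groups)
      d <- predict_v(lab) - hv
      exceed <- exceed + (abs(d) >= abs(obs) - 1e-12)
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  res <- data.frame(reaction_id = sm$col_index, observed_delta = unname(obs),
                    p = unname(p), stringsAsFactors = FALSE)
  attr(res, "study_id") <- study$study_id
  attr(res, "n_perm") <- n_used
  attr(res, "seed") <- seed
  attr(res, "exhaustive") <- exhaustive
  class(res) <- c("permutation_result", "data.frame")
  res
}

#' Fisher's method for combining per-study p-values
#'
#' \code{X = -2 sum(log p)} compared against a chi-square distribution
#' with \code{2k} degrees of freedom, one combination per reaction set.
#'
#' @param p_per_study A named list: one numeric vector of per-study
#'   p-values per reaction set (all in (0, 1]; exact zeros are rejected --
#'   use add-one permutation p-values).
#' @return A \code{meta_result} data.frame: set, k, X, df, combined p.
#' @export
fisher_meta <- function(p_per_study) {
  if (!length(p_per_study)) stop("no p-values supplied")
  out <- data.frame(set = names(p_per_study),
                    k = lengths(p_per_study),
                    X = NA_real_, df = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(p_per_study)) {
    p <- p_per_study[[i]]
    if (any(p <= 0))
      stop("p-value of 0 in set '", out$set[i],
           "': use add-one permutation p-values")
    if (any(p > 1)) stop("p-values must lie in (0, 1]")
    X <- -2 * sum(log(p))
    df <- 2 * length(p)
    out$X[i] <- X
    out$df[i] <- df
    out$p[i] <- stats::pchisq(X, df = df, lower.tail = FALSE)
  }
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Holm-Bonferroni step-down family-wise error control
#'
#' Sorts the p-values ascending and rejects while
#' \code{p_(j) <= alpha / (m - j + 1)}; the rank-1 threshold
#' \code{alpha / m} is reported (0.05 / 31 = 0.0016 for 31 sets).
#'
#' @param pvals Named numeric vector of per-set p-values.
#' @param alpha Family-wise error rate (default 0.05).
#' @return data.frame with p, rank, step-down threshold and rejection
#'   flag per set; attributes \code{rank1_threshold} and \code{alpha}.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  m <- length(pvals)
  ord <- order(pvals)
  thresh <- alpha / (m - seq_len(m) + 1)
  rejected <- logical(m)
  for (j in seq_len(m)) {
    if (pvals[ord[j]] <= thresh[j]) rejected[ord[j]] <- TRUE else break
  }
  out <- data.frame(set = if (is.null(names(pvals)))
    as.character(seq_len(m)) else names(pvals),
    p = unname(pvals), stringsAsFactors = FALSE)
  out$rank <- match(seq_len(m), ord)
  out$threshold <- thresh[out$rank]
  out$rejected <- rejected
  attr(out, "rank1_threshold") <- alpha / m
  attr(out, "alpha") <- alpha
  out
}
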