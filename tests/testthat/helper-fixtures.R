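# Programmatic fixtures: toy networks and a cached copy of the packaged
# model with its healthy solution (computed once per test run).

toy_chain_net <- function() {
  mets <- data.frame(
    id = c("A_e", "A_c", "B_c", "B_e"),
    name = c("A", "A", "B", "B"),
    compartment = c("extracellular", "cytosolic", "cytosolic",
                    "extracellular"),
    exchanged = c(TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("EX_A", "T_A", "CONV", "T_B"),
    name = c("A supply", "A uptake", "A to B", "B release"),
    reversible = c(TRUE, TRUE, FALSE, TRUE),
    subsystem = c("exchange", "transport", "core", "transport"),
    stringsAsFactors = FALSE)
  rx$stoichiometry <- I(list(
    c(A_e = 1),
    c(A_e = -1, A_c = 1),
    c(A_c = -1, B_c = 1),
    c(B_c = -1, B_e = 1)))
  rx$genes <- I(list(character(0), c("TA1"), c("CV1", "CV2"), c("TB1")))
  metabolic_network(mets, rx)
}

# Two parallel identical irreversible paths between the uptake and release
# steps; the path reactions carry no genes (weight 0 under the coverage
# policy), so the split between them is a flat direction of the
# least-squares cost.
toy_parallel_net <- function() {
  mets <- data.frame(
    id = c("A_e", "A_c", "B_c", "B_e"),
    name = c("A", "A", "B", "B"),
    compartment = c("extracellular", "cytosolic", "cytosolic",
                    "extracellular"),
    exchanged = c(TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("T_A", "P1", "P2", "T_B"),
    name = c("A uptake", "path 1", "path 2", "B release"),
    reversible = c(TRUE, FALSE, FALSE, TRUE),
    subsystem = c("transport", "core", "core", "transport"),
    stringsAsFactors = FALSE)
  rx$stoichiometry <- I(list(
    c(A_e = -1, A_c = 1),
    c(A_c = -1, B_c = 1),
    c(A_c = -1, B_c = 1),
    c(B_c = -1, B_e = 1)))
  rx$genes <- I(list(c("TA1"), character(0), character(0), c("TB1")))
  metabolic_network(mets, rx)
}

# Random small flux problems for oracle cross-checks: random sparse
# stoichiometry, random positive weights, random target vector, random
# irreversible subset.
rand_lsei_problem <- function(seed) {
  set.seed(seed)
  n_m <- sample(2:5, 1)
  n_r <- sample(4:12, 1)
  repeat {
    S <- matrix(0, n_m, n_r)
    for (j in seq_len(n_r)) {
      k <- sample(1:min(3, n_m), 1)
      rows <- sample(n_m, k)
      S[rows, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    }
    if (all(rowSums(S != 0) > 0)) break
  }
  colnames(S) <- paste0("r", seq_len(n_r))
  irr <- which(stats::runif(n_r) < 0.5)
  w <- stats::runif(n_r, 0.2, 2)
  v0 <- stats::rnorm(n_r)
  lsei_problem(S, v0 = v0, weights = w, irreversible = irr)
}

the_cache <- new.env(parent = emptyenv())

cached_brain <- function() {
  if (is.null(the_cache$net)) {
    the_cache$net <- default_brain_network()
    the_cache$cons <- default_constraints()
    the_cache$healthy <- solve_fba(the_cache$net, the_cache$cons)
  }
  list(net = the_cache$net, cons = the_cache$cons,
       healthy = the_cache$healthy)
}
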