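test_that("dependent sets group unbranched chains on the packaged model", {
  b <- cached_brain()
  part <- dependent_sets(b$net, b$healthy)
  find_set <- function(id) {
    hits <- which(vapply(part$sets, function(s) id %in% s, logical(1)))
    names(part$sets)[hits]
  }
  ## glucose transport and hexokinase are fully coupled
  expect_identical(find_set("GLCt1r"), find_set("HEX1"))
  ## the lower glycolytic chain forms one set
  expect_identical(find_set("PGK"), find_set("PGM"))
  expect_identical(find_set("PGM"), find_set("ENO"))
  expect_identical(find_set("ENO"), find_set("PYK"))
  ## branch points separate sets
  expect_false(identical(find_set("HEX1"), find_set("PFK")))
  ## healthy |flux| is constant within every set
  expect_lt(part$max_abs_flux_spread, 1e-9)
  ## partition covers every reaction exactly once
  expect_setequal(unlist(part$sets), b$net$reactions$id)
  expect_identical(anyDuplicated(unlist(part$sets)), 0L)
})

test_that("a linear chain collapses to a single dependent set", {
  toy <- toy_chain_net()
  part <- dependent_sets(toy)
  sizes <- lengths(part$sets)
  ## EX_A touches only the unbalanced boundary pool, so it is uncoupled;
  ## the three chain reactions form one set
  expect_identical(max(sizes), 3L)
  expect_setequal(part$sets[[which.max(sizes)]], c("T_A", "CONV", "T_B"))
})

test_that("cross-study t-tests flag degenerate sets and pass identities", {
  b <- cached_brain()
  part <- dependent_sets(b$net, b$healthy)
  hv <- b$healthy$values
  ## all studies identical to healthy: t = 0, p = 1
  preds <- cbind(hv, hv, hv, hv)
  rownames(preds) <- names(hv)
  tt <- ttest_across_studies(preds, b$healthy, part)
  expect_true(all(tt$degenerate))
  expect_true(all(tt$p == 1))
  expect_true(all(tt$t == 0))
  ## constant shifted predictions: zero variance, flagged, p = 0
  preds2 <- preds * 0.9
  tt2 <- ttest_across_studies(preds2, b$healthy, part)
  moved <- abs(tt2$mean_delta) > 1e-12
  expect_true(all(tt2$degenerate[moved]))
  expect_true(all(tt2$p[moved] == 0))
  ## noisy predictions give finite t and p in (0, 1)
  set.seed(5)
  preds3 <- preds + matrix(rnorm(length(preds), 0, 0.01), nrow(preds))
  tt3 <- ttest_across_studies(preds3, b$healthy, part)
  expect_true(all(tt3$p > 0 & tt3$p < 1))
  expect_false(any(tt3$degenerate))
})

test_that("permutation p-values are exact ones for a patient group copying
          the controls", {
  b <- cached_brain()
  cfg <- synthetic_config(n_control = 3, n_patient = 3, noise_sd = 0.3,
                          seed = 21L)
  gen <- generate_study(cfg, b$net)
  m <- gen$study$matrix
  m[, 4:6] <- m[, 1:3]   # patients are an exact copy of controls
  st <- expression_study(m, gen$study$groups, "copy")
  pr <- permutation_test(st, gen$net, b$healthy, n_perm = 99, seed = 2L)
  expect_true(attr(pr, "exhaustive"))   # choose(6,3) = 20 relabelings
  expect_true(all(abs(pr$observed_delta) < 1e-10))
  expect_true(all(pr$p == 1))
})

test_that("permutation p-values respect the add-one lower bound and are
          seed-stable in distribution", {
  b <- cached_brain()
  prof <- feasible_disease_profile(b$net, b$healthy,
                                   pattern = c(oxphos = 0.8))
  cfg <- synthetic_config(n_control = 8, n_patient = 8, noise_sd = 0.2,
                          true_reaction_fc = prof$true_reaction_fc,
                          seed = 31L)
  gen <- generate_study(cfg, b$net)
  n_perm <- 199L
  p1 <- permutation_test(gen$study, gen$net, b$healthy, n_perm = n_perm,
                         seed = 10L)
  p2 <- permutation_test(gen$study, gen$net, b$healthy, n_perm = n_perm,
                         seed = 20L)
  expect_true(all(p1$p >= 1 / (n_perm + 1)))
  expect_true(all(p1$p <= 1))
  ## 4 sigma of the difference of two independent estimates of the same
  ## permutation p-value, plus the add-one discreteness
  pbar <- (p1$p + p2$p) / 2
  tol <- 4 * sqrt(2 * pmax(pbar * (1 - pbar), 1 / n_perm) / n_perm)
  expect_true(all(abs(p1$p - p2$p) <= tol + 2 / (n_perm + 1)))
  ## identical seeds reproduce identical p-values
  p1b <- permutation_test(gen$study, gen$net, b$healthy, n_perm = n_perm,
                          seed = 10L)
  expect_identical(p1$p, p1b$p)
})

test_that("Fisher combination matches the chi-square tail", {
  ## all ones
  m1 <- fisher_meta(list(s1 = c(1, 1, 1)))
  expect_equal(m1$X, 0)
  expect_equal(m1$p, 1)
  ## two studies at 0.05: X = -4 log(0.05) = 11.98, df 4
  ## frozen from the closed form: upper chi-square tail at df 4 is
  ## (1 + X/2) exp(-X/2) with X = -4 log(0.05) = 11.982929
  m2 <- fisher_meta(list(s = c(0.05, 0.05)))
  expect_equal(m2$X, 11.982929, tolerance = 1e-6)
  expect_identical(m2$df, 4)
  expect_equal(m2$p, 0.01747866, tolerance = 1e-7)
  expect_equal(m2$p, (1 + m2$X / 2) * exp(-m2$X / 2), tolerance = 1e-12)
  ## single study: combined p equals the input
  for (p in c(0.01, 0.2, 0.9))
    expect_equal(fisher_meta(list(s = p))$p, p, tolerance = 1e-12)
  ## statistic is additive over disjoint study subsets
  set.seed(6)
  ps <- runif(6, 0.01, 1)
  expect_equal(fisher_meta(list(a = ps))$X,
               fisher_meta(list(a = ps[1:2]))$X +
                 fisher_meta(list(a = ps[3:6]))$X, tolerance = 1e-12)
  expect_error(fisher_meta(list(a = c(0.5, 0))), "add-one")
})

test_that("Holm-Bonferroni step-down matches the hand execution and
          p.adjust", {
  ## 31 sets: rank-1 threshold 0.05/31
  p31 <- stats::setNames(rep(0.5, 31), paste0("s", 1:31))
  h31 <- holm_bonferroni(p31)
  expect_equal(attr(h31, "rank1_threshold"), 0.05 / 31)
  expect_equal(round(attr(h31, "rank1_threshold"), 4), 0.0016)
  expect_false(any(h31$rejected))
  ## hand-executed case: all three rejected step by step
  h3 <- holm_bonferroni(c(a = 0.001, b = 0.02, c = 0.03))
  expect_true(all(h3$rejected))
  expect_equal(sort(h3$threshold), c(0.05 / 3, 0.05 / 2, 0.05),
               tolerance = 1e-12)
  ## the step-down stops at the first failure
  h_stop <- holm_bonferroni(c(a = 0.001, b = 0.04, c = 0.041))
  expect_identical(h_stop$rejected, c(TRUE, FALSE, FALSE))
  ## m = 1 reduces to a plain alpha-level test
  expect_true(holm_bonferroni(c(x = 0.049))$rejected)
  expect_false(holm_bonferroni(c(x = 0.051))$rejected)
  ## agreement with stats::p.adjust on random vectors
  set.seed(7)
  for (k in 1:5) {
    p <- runif(sample(3:12, 1))^2
    names(p) <- paste0("t", seq_along(p))
    mine <- holm_bonferroni(p, alpha = 0.05)
    ref <- stats::p.adjust(p, method = "holm") <= 0.05
    expect_identical(mine$rejected, unname(ref))
  }
})
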