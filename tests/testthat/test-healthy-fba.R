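test_that("default constraints carry the measured rates and ratios", {
  cons <- default_constraints()
  expect_equal(cons$fixed_exchanges[["GLCt1r"]], 0.203)
  expect_equal(cons$fixed_exchanges[["L_LACt2r"]], -0.0092)
  expect_equal(cons$fixed_exchanges[["GLNt"]], -0.011)
  expect_equal(cons$fixed_exchanges[["PYRt2r"]], -0.0024)
  rc <- cons$ratio_constraints
  expect_equal(rc$fraction[rc$numerator == "PPP_OX"], 0.069)
  expect_identical(rc$reference[rc$numerator == "PPP_OX"], "HEX1")
  expect_equal(rc$fraction[rc$numerator == "PCm"], 0.13)
  expect_equal(rc$fraction[rc$numerator == "GLUNm"], 0.62)
  expect_equal(rc$fraction[rc$numerator == "GLUDC"], 0.32)
  expect_identical(cons$objective_reaction, "ATPS4mi")
})

test_that("solve_fba matches the closed-form solution on a toy chain", {
  toy <- toy_chain_net()
  cons <- flux_constraints(
    fixed_exchanges = c(T_A = 2),
    ratio_constraints = data.frame(numerator = character(0),
                                   reference = character(0),
                                   fraction = numeric(0)),
    objective_reaction = "T_B")
  sol <- solve_fba(toy, cons)
  ## balance forces every chain reaction to the fixed uptake; EX_A is the
  ## unconstrained boundary supply of the exchanged pool
  expect_equal(unname(sol$values[c("T_A", "CONV", "T_B")]), c(2, 2, 2),
               tolerance = 1e-9)
  expect_equal(sol$objective_value, 2, tolerance = 1e-9)
})

test_that("healthy LP satisfies balance, fixed rates and ratios to
          tolerance", {
  b <- cached_brain()
  sm <- build_stoich_matrix(b$net)
  v <- b$healthy$values
  expect_lt(max(abs(sm$S %*% v)), 1e-8)
  for (id in names(b$cons$fixed_exchanges))
    expect_equal(v[[id]], b$cons$fixed_exchanges[[id]], tolerance = 1e-9)
  rc <- b$cons$ratio_constraints
  for (i in seq_len(nrow(rc)))
    expect_equal(v[[rc$numerator[i]]],
                 rc$fraction[i] * v[[rc$reference[i]]], tolerance = 1e-9)
  expect_true(all(v[irreversible_ids(b$net)] >= -1e-10))
  expect_equal(b$healthy$objective_value, v[["ATPS4mi"]])
})

test_that("optimal flux vector scales linearly with the exchange rates", {
  b <- cached_brain()
  for (alpha in c(0.5, 2)) {
    cons <- b$cons
    cons$fixed_exchanges <- alpha * cons$fixed_exchanges
    sol <- solve_fba(b$net, cons)
    expect_equal(sol$values, alpha * b$healthy$values, tolerance = 1e-7)
    expect_equal(sol$objective_value,
                 alpha * b$healthy$objective_value, tolerance = 1e-7)
  }
})

test_that("a closed network is optimal at zero flux", {
  b <- cached_brain()
  cons <- flux_constraints(
    fixed_exchanges = stats::setNames(
      rep(0, length(b$cons$fixed_exchanges)),
      names(b$cons$fixed_exchanges)),
    ratio_constraints = data.frame(numerator = character(0),
                                   reference = character(0),
                                   fraction = numeric(0)),
    objective_reaction = "ATPS4mi")
  sol <- solve_fba(b$net, cons)
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
  expect_lt(max(abs(sol$values)), 1e-8)
})

test_that("FVA certifies uniqueness on the packaged model and brackets the
          optimum", {
  b <- cached_brain()
  fva <- flux_variability(b$net, b$cons, b$healthy$objective_value)
  expect_true(fva_unique(fva))
  expect_lte(max(fva$span), 1e-6)
  expect_true(all(fva$min <= b$healthy$values + 1e-7))
  expect_true(all(fva$max >= b$healthy$values - 1e-7))
})

test_that("FVA exposes the alternative optima of parallel identical paths", {
  toy <- toy_parallel_net()
  cons <- flux_constraints(
    fixed_exchanges = c(T_A = 1),
    ratio_constraints = data.frame(numerator = character(0),
                                   reference = character(0),
                                   fraction = numeric(0)),
    objective_reaction = "T_B")
  sol <- solve_fba(toy, cons)
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)
  fva <- flux_variability(toy, cons, sol$objective_value)
  expect_false(fva_unique(fva))
  ## each path reaction can carry anything from 0 to the full path flux
  expect_equal(fva$span[fva$id == "P1"], 1, tolerance = 1e-7)
  expect_equal(fva$span[fva$id == "P2"], 1, tolerance = 1e-7)
  expect_lt(fva$span[fva$id == "T_B"], 1e-9)
})

test_that("infeasible constraint sets report a small conflicting subset", {
  toy <- toy_chain_net()
  cons <- flux_constraints(
    fixed_exchanges = c(T_A = 2, T_B = 1),   # chain cannot split flux
    ratio_constraints = data.frame(numerator = character(0),
                                   reference = character(0),
                                   fraction = numeric(0)),
    objective_reaction = "T_B")
  expect_error(solve_fba(toy, cons), "infeasible")
  err <- tryCatch(solve_fba(toy, cons), error = conditionMessage)
  expect_match(err, "fixed:T_A")
  expect_match(err, "fixed:T_B")
})

test_that("derived totals summarise the healthy solution and degenerate
          inputs", {
  b <- cached_brain()
  tot <- derived_totals(b$healthy, b$net)
  expect_equal(tot$atp_mito, b$healthy$objective_value)
  expect_gt(tot$o2_glucose_ratio, 5.0)
  expect_lt(tot$o2_glucose_ratio, 6.0)
  expect_equal(tot$lactate_release, 0.0092, tolerance = 1e-9)
  zero <- flux_distribution(
    stats::setNames(rep(0, nrow(b$net$reactions)), b$net$reactions$id),
    "healthy_LP", 0)
  zt <- derived_totals(zero, b$net)
  expect_true(all(unlist(zt) == 0))
})
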