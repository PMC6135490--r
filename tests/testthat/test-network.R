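test_that("the packaged brain model loads, validates and has 69 reactions", {
  net <- cached_brain()$net
  expect_s3_class(net, "metabolic_network")
  expect_identical(nrow(net$reactions), 69L)
  expect_setequal(unique(net$metabolites$compartment),
                  c("extracellular", "cytosolic", "mitochondrial"))
  ## matrix protons balanced, cytosolic protons not
  expect_false(net$metabolites$exchanged[net$metabolites$id == "h_m"])
  expect_true(net$metabolites$exchanged[net$metabolites$id == "h_c"])
  ## ETC complexes carry mitochondrially encoded gene symbols
  rx <- net$reactions
  ci_genes <- rx$genes[[which(rx$id == "NADH2_u10mi")]]
  expect_true(all(c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6") %in%
                    ci_genes))
  expect_true("CYTB" %in% rx$genes[[which(rx$id == "CYOR_u10mi")]])
  expect_true(all(c("COX1", "COX2", "COX3") %in%
                    rx$genes[[which(rx$id == "CYOOm3i")]]))
  expect_true(all(c("ATP6", "ATP8") %in%
                    rx$genes[[which(rx$id == "ATPS4mi")]]))
  ## glycerol-phosphate shuttle present and irreversible
  expect_false(rx$reversible[rx$id == "G3PD2"])
  expect_false(rx$reversible[rx$id == "G3PDm"])
})

test_that("equation parsing handles coefficients, arrows and errors", {
  st <- lseifba:::parse_equation("2 h_m + nadh_m -> 4 h_c + nad_m", "x")
  expect_identical(st[["h_m"]], -2)
  expect_identical(st[["h_c"]], 4)
  expect_identical(st[["nadh_m"]], -1)
  rev_st <- lseifba:::parse_equation("a_c <=> b_c", "x")
  expect_identical(unname(rev_st[c("a_c", "b_c")]), c(-1, 1))
  expect_error(lseifba:::parse_equation("2x a_c -> b_c", "RXN_BAD"),
               "RXN_BAD")
  expect_error(lseifba:::parse_equation("a_c b_c c_c -> d_c", "RXN_BAD"),
               "RXN_BAD")
})

test_that("validation rejects undefined metabolites and bad compartments", {
  net <- toy_chain_net()
  broken <- net
  broken$reactions$stoichiometry[[3]] <- c(A_c = -1, xyz_c = 1)
  expect_error(validate_network(broken), "xyz_c")
  bad_comp <- net
  bad_comp$metabolites$compartment[2] <- "nucleus"
  expect_error(validate_network(bad_comp), "nucleus")
  dangling <- net
  dangling$reactions$stoichiometry[[1]] <- c(A_c = 1)  # pseudo-reaction on
  expect_error(validate_network(dangling), "internal")  # a balanced species
})

test_that("tabular and json round trips are lossless field by field", {
  net <- cached_brain()$net
  dir <- withr::local_tempdir()
  tpath <- file.path(dir, "model.tsv")
  write_network(net, tpath, format = "tabular")
  back <- load_network(tpath, format = "tabular")
  expect_identical(back$reactions$id, net$reactions$id)
  expect_identical(back$reactions$reversible, net$reactions$reversible)
  expect_identical(back$reactions$subsystem, net$reactions$subsystem)
  expect_identical(unclass(back$reactions$genes),
                   unclass(net$reactions$genes))
  for (i in seq_len(nrow(net$reactions))) {
    a <- net$reactions$stoichiometry[[i]]
    b <- back$reactions$stoichiometry[[i]]
    expect_equal(b[sort(names(b))], a[sort(names(a))],
                 tolerance = 1e-15)
  }
  expect_identical(back$metabolites$exchanged, net$metabolites$exchanged)
  jpath <- file.path(dir, "model.json")
  write_network(net, jpath, format = "json")
  jback <- load_network(jpath, format = "json")
  expect_identical(jback$reactions$id, net$reactions$id)
  expect_equal(jback$reactions$stoichiometry[[10]],
               net$reactions$stoichiometry[[10]], tolerance = 1e-15)
  expect_identical(jback$metabolites$compartment,
                   net$metabolites$compartment)
})

test_that("stoichiometric matrix covers internal metabolites only and is
          order-stable", {
  toy <- toy_chain_net()
  sm <- build_stoich_matrix(toy)
  expect_identical(dim(sm$S), c(2L, 4L))
  expect_setequal(sm$row_index, c("A_c", "B_c"))
  expect_identical(sm$col_index, toy$reactions$id)
  expect_equal(unname(sm$S["A_c", ]), c(0, 1, -1, 0))
  ## permuting reaction order only permutes columns
  perm <- c(3L, 1L, 4L, 2L)
  toy2 <- toy
  toy2$reactions <- toy$reactions[perm, ]
  sm2 <- build_stoich_matrix(toy2)
  expect_identical(sm2$col_index, sm$col_index[perm])
  expect_equal(sm2$S[sm$row_index, sm$col_index], sm$S)
})

test_that("packaged model is structurally consistent", {
  b <- cached_brain()
  sm <- build_stoich_matrix(b$net)
  expect_false(any(rowSums(sm$S != 0) == 0))   # no all-zero internal rows
  ## every internal metabolite is producible and consumable once
  ## reversibility is taken into account
  rev_flags <- b$net$reactions$reversible
  producible <- apply(sm$S, 1, function(r)
    any(r > 0) || any(r != 0 & rev_flags))
  consumable <- apply(sm$S, 1, function(r)
    any(r < 0) || any(r != 0 & rev_flags))
  expect_true(all(producible))
  expect_true(all(consumable))
  ## irreversible set matches the reversibility column
  expect_setequal(irreversible_ids(b$net),
                  b$net$reactions$id[!b$net$reactions$reversible])
})

test_that("SBML export round-trips, including degenerate inputs", {
  dir <- withr::local_tempdir()
  toy <- toy_chain_net()
  path <- file.path(dir, "toy.xml")
  export_sbml(toy, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  expect_length(xml2::xml_find_all(doc, ".//s:reaction", ns), 4L)
  expect_length(xml2::xml_find_all(doc, ".//s:species", ns), 4L)
  expect_length(xml2::xml_find_all(doc, ".//s:compartment", ns), 2L)
  back <- read_sbml(path)
  expect_identical(back$reactions$id, toy$reactions$id)
  expect_identical(back$reactions$reversible, toy$reactions$reversible)
  expect_identical(unclass(back$reactions$genes),
                   unclass(toy$reactions$genes))
  expect_equal(back$reactions$stoichiometry[[2]],
               toy$reactions$stoichiometry[[2]])
  expect_identical(back$metabolites$exchanged, toy$metabolites$exchanged)
  ## empty network
  empty <- structure(list(
    metabolites = toy$metabolites[0, ],
    reactions = toy$reactions[0, ]), class = "metabolic_network")
  epath <- file.path(dir, "empty.xml")
  export_sbml(empty, epath)
  eback <- read_sbml(epath)
  expect_identical(nrow(eback$reactions), 0L)
  ## packaged model round trip
  b <- cached_brain()
  bpath <- file.path(dir, "brain.xml")
  export_sbml(b$net, bpath)
  bback <- read_sbml(bpath)
  expect_identical(bback$reactions$id, b$net$reactions$id)
  expect_equal(build_stoich_matrix(bback)$S, build_stoich_matrix(b$net)$S)
})
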