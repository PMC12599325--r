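test_that("FBA solves toy models to their hand optima", {
  lin <- toy_linear_model()
  sol <- fba_optimize(lin)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 10)
  expect_equal(unname(sol$fluxes), rep(10, 3))

  # zero uptake bound: biomass zero
  sol0 <- fba_optimize(set_reaction_bounds(lin, "EX_A", 0, 0))
  expect_equal(sol0$objective, 0)

  # parallel routes: objective unique even though the split is not
  par <- toy_parallel_model()
  solp <- fba_optimize(par)
  expect_equal(solp$objective, 10)
  expect_equal(unname(solp$fluxes["r1"] + solp$fluxes["r2"]), 10)

  # branched model: 10 A -> 20 D at the optimum
  br <- toy_branched_model()
  solb <- fba_optimize(br)
  expect_equal(solb$objective, 20)

  # forcing flux through an infeasible constraint is reported
  bad <- set_reaction_bounds(toy_linear_model(), "r1", 50, 60)
  expect_equal(fba_optimize(bad)$status, "infeasible")
})

test_that("essentiality follows the re-optimisation rule", {
  lin <- toy_linear_model()
  expect_setequal(essential_for_optimum(lin),
                  c("EX_A", "r1", "BIOMASS"))

  # equal-capacity parallel routes, each able to carry the demand:
  # neither branch is essential
  par <- toy_parallel_model(uptake = 10, cap1 = 10, cap2 = 10)
  ess <- essential_for_optimum(par)
  expect_false("r1" %in% ess)
  expect_false("r2" %in% ess)
  expect_true(all(c("EX_A", "BIOMASS") %in% ess))

  # capacities 9 and 1 against demand 10: losing either branch costs
  # 90% and 10% respectively, both above the 1% threshold
  par2 <- toy_parallel_model(uptake = 10, cap1 = 9, cap2 = 1)
  ess2 <- essential_for_optimum(par2)
  expect_true(all(c("r1", "r2") %in% ess2))
  # with a 15% threshold only the big branch remains essential
  ess3 <- essential_for_optimum(par2, threshold = 0.15)
  expect_true("r1" %in% ess3)
  expect_false("r2" %in% ess3)

  # monotone in the threshold: larger thresholds never add reactions
  for (m in list(lin, par2, toy_branched_model())) {
    e_small <- essential_for_optimum(m, 0.01)
    e_large <- essential_for_optimum(m, 0.2)
    expect_true(all(e_large %in% e_small))
  }

  # zero baseline growth: empty set with a warning
  dead <- set_reaction_bounds(lin, "EX_A", 0, 0)
  expect_warning(e <- essential_for_optimum(dead), "zero")
  expect_equal(e, character(0))
})

test_that("carbon by-product counts match hand enumeration", {
  lin <- toy_linear_model()
  sol <- fba_optimize(lin)
  ess <- essential_for_optimum(lin)
  bp <- count_carbon_byproducts(lin, sol$fluxes, ess)
  expect_equal(bp$byproducts, "B")
  expect_equal(bp$count, 1L)

  # branched model: essential active reactions are EX_A, v1, v2 and
  # BIOMASS; their carbon metabolites are A, B, D; A is the source
  br <- toy_branched_model()
  solb <- fba_optimize(br)
  essb <- essential_for_optimum(br)
  expect_setequal(essb, c("EX_A", "v1", "v2", "BIOMASS"))
  bpb <- count_carbon_byproducts(br, solb$fluxes, essb)
  expect_setequal(bpb$byproducts, c("B", "D"))
  expect_equal(bpb$count, 2L)

  # only source and biomass active: count 0
  direct <- metabolic_model(
    metabolites = data.frame(id = "A", carbon = 6),
    reactions = list(
      list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = 10),
      list(id = "BIOMASS", stoich = c(A = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS", supplied_source = "A")
  sd0 <- fba_optimize(direct)
  bp0 <- count_carbon_byproducts(direct, sd0$fluxes,
                                 essential_for_optimum(direct))
  expect_equal(bp0$count, 0L)
})

test_that("by-product counts are invariant to ordering and scaling", {
  br <- toy_branched_model()
  count_of <- function(m) {
    sol <- fba_optimize(m)
    count_carbon_byproducts(m, sol$fluxes, essential_for_optimum(m))$count
  }
  base_count <- count_of(br)

  # reverse the reaction list
  rxns <- lapply(rev(br$reaction_ids), function(r) {
    st <- br$S[, r]
    list(id = r, stoich = st[st != 0], lb = unname(br$lb[r]),
         ub = unname(br$ub[r]))
  })
  rev_model <- metabolic_model(br$metabolites, rxns, br$biomass,
                               br$supplied_source)
  expect_equal(count_of(rev_model), base_count)

  # scale one reaction's stoichiometry by 4 with compensating bounds
  rxns2 <- lapply(br$reaction_ids, function(r) {
    st <- br$S[, r]
    sc <- if (r == "v2") 4 else 1
    list(id = r, stoich = sc * st[st != 0], lb = unname(br$lb[r]) / sc,
         ub = unname(br$ub[r]) / sc)
  })
  sc_model <- metabolic_model(br$metabolites, rxns2, br$biomass,
                              br$supplied_source)
  expect_equal(fba_optimize(sc_model)$objective, 20)
  expect_equal(count_of(sc_model), base_count)
})

test_that("models round-trip through JSON and load from SBML", {
  br <- toy_branched_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_metabolic_model(br, f)
  back <- read_metabolic_model(f)
  expect_equal(back$metabolites, br$metabolites)
  expect_equal(back$S[, back$reaction_ids], br$S[, br$reaction_ids])
  expect_equal(back$lb, br$lb)
  expect_equal(fba_optimize(back)$objective, 20)

  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    ' xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    ' level="3" version="1">',
    '<model id="mini">',
    '<listOfParameters>',
    '<parameter id="zero" value="0"/><parameter id="ten" value="10"/>',
    '<parameter id="big" value="1000"/>',
    '</listOfParameters>',
    '<listOfSpecies>',
    '<species id="A" fbc:chemicalFormula="C6H12O6"/>',
    '<species id="B" fbc:chemicalFormula="C3H4O3"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="EX_A" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ten">',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="r1" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>',
    '</reaction>',
    '<reaction id="GROW" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">',
    '<listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    '<fbc:listOfFluxObjectives>',
    '<fbc:fluxObjective fbc:reaction="GROW" fbc:coefficient="1"/>',
    '</fbc:listOfFluxObjectives>',
    '</fbc:objective>',
    '</fbc:listOfObjectives>',
    '</model></sbml>')
  fs <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, fs)
  m <- read_metabolic_model(fs)
  expect_equal(m$biomass, "GROW")
  expect_equal(m$supplied_source, "A")
  expect_equal(m$metabolites$carbon, c(6, 3))
  expect_equal(fba_optimize(m)$objective, 20)
})

test_that("by-product / theta-rank correlations per species", {
  reports <- data.frame(
    species = rep(c("sp1", "sp2", "sp3"), each = 4),
    source = rep(c("Glucose", "Ribose", "Acetate", "Uridine"), 3),
    count = c(1, 2, 3, 4, # increasing with theta rank
              4, 4, 4, 4, # constant: skipped
              4, 3, 2, 1))
  tb <- data.frame(env = c("Glucose", "Ribose", "Acetate", "Uridine"),
                   theta_bar = c(-30, -10, 10, 40))
  res <- byproduct_theta_correlation(reports, tb)
  expect_equal(res$rho[res$species == "sp1"], 1)
  expect_true(res$skipped[res$species == "sp2"])
  expect_equal(res$rho[res$species == "sp3"], -1)
  # restricting to verified growth drops sources
  grown <- data.frame(species = "sp1",
                      source = c("Glucose", "Ribose"))
  res2 <- byproduct_theta_correlation(reports[reports$species == "sp1", ],
                                      tb, grown = grown)
  expect_true(res2$skipped)
  expect_match(res2$reason, "too few")
})
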