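# Model I/O: JSON and SBML round-trips, shipped fixtures, flux tables.

test_that("JSON round-trip is lossless for S, bounds and objective", {
  m <- core_acetate_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path, format = "json")
  m2 <- read_model_json(path)
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_equal(m2$S[m$metabolites$id, ], m$S)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_equal(m2$reactions$objective_coefficient,
               m$reactions$objective_coefficient)
})

test_that("SBML round-trip is lossless, including via JSON", {
  m <- core_acetate_model()
  p_sbml <- withr::local_tempfile(fileext = ".xml")
  p_json <- withr::local_tempfile(fileext = ".json")
  p_sbml2 <- withr::local_tempfile(fileext = ".xml")
  write_model(m, p_sbml, format = "sbml")
  m2 <- read_sbml(p_sbml)
  expect_equal(m2$S[m$metabolites$id, ], m$S)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$objective_coefficient,
               m$reactions$objective_coefficient)
  # sbml -> json -> sbml preserves every coefficient
  write_model(m2, p_json, format = "json")
  m3 <- read_model_json(p_json)
  write_model(m3, p_sbml2, format = "sbml")
  m4 <- read_sbml(p_sbml2)
  expect_equal(m4$S[m$metabolites$id, ], m$S)
  expect_equal(m4$reactions$upper_bound, m$reactions$upper_bound)
})

test_that("shipped fixture files equal the in-code generators", {
  m <- core_acetate_model()
  js <- read_model_json(system.file("extdata", "core_acetate.json",
                                    package = "cofswap"))
  xb <- read_sbml(system.file("extdata", "core_acetate.xml",
                              package = "cofswap"))
  expect_equal(js$S[m$metabolites$id, ], m$S)
  expect_equal(xb$S[m$metabolites$id, ], m$S)
  expect_equal(js$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(xb$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(nrow(js$reactions), nrow(m$reactions))
})

test_that("malformed XML and missing bounds raise parse errors", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><listOfReact", bad)
  expect_error(read_sbml(bad))
  nobounds <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" level=\"3\" version=\"1\">",
    "  <model id=\"m\">",
    "    <listOfSpecies><species id=\"A\" compartment=\"c\"/></listOfSpecies>",
    "    <listOfReactions><reaction id=\"R1\"><listOfReactants>",
    "      <speciesReference species=\"A\" stoichiometry=\"1\"/>",
    "    </listOfReactants></reaction></listOfReactions>",
    "  </model>",
    "</sbml>"), nobounds)
  expect_error(read_sbml(nobounds), "R1")
})

test_that("an empty-objective model writes all-zero objective weights", {
  m <- cofswap:::toy_chain_model()
  m$reactions$objective_coefficient <- 0
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path, format = "json")
  m2 <- read_model_json(path)
  expect_true(all(m2$reactions$objective_coefficient == 0))
})

test_that("flux tables normalize by the acetate uptake rate, sign-preserving", {
  fluxes <- stats::setNames(c(-7.88, 7.88, 4.65), c("EX_ac_e", "UPT", "ICDHyr"))
  dist <- flux_distribution(fluxes, 0, "optimal")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_flux_table(dist, path, qac = 7.88)
  tab <- utils::read.delim(path)
  expect_identical(names(tab), c("reaction_id", "flux", "pct_of_qac"))
  expect_equal(tab$pct_of_qac[tab$reaction_id == "UPT"], 100)
  expect_equal(tab$pct_of_qac[tab$reaction_id == "EX_ac_e"], -100)
  expect_equal(round(tab$pct_of_qac[tab$reaction_id == "ICDHyr"], 1), 59.0)
})

test_that("flux range tables keep min <= max in every row", {
  m <- cofswap:::toy_chain_model()
  fr <- fva(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_flux_table(fr, path, qac = 10)
  tab <- utils::read.delim(path)
  expect_true(all(tab$min_flux <= tab$max_flux + 1e-9))
})

test_that("exchange-id dialects are interchangeable", {
  m <- core_acetate_model()
  expect_identical(reaction_index(m, "EX_ac(e)"),
                   reaction_index(m, "EX_ac_e"))
  expect_identical(reaction_index(m, "EX_o2(e)"),
                   reaction_index(m, "EX_o2_e"))
})

test_that("model invariants are enforced at construction", {
  m <- cofswap:::toy_chain_model()
  bad <- m
  bad$reactions$lower_bound[1] <- 5
  bad$reactions$upper_bound[1] <- -5
  expect_error(validate_model(bad), "lower bound exceeds")
  expect_error(set_bounds(m, "CONV", lb = 2, ub = 1), "lower bound")
})
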