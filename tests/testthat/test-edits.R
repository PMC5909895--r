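# Cofactor swapping, knockouts, irreversibility and strain preparation.

test_that("swap fraction 0 leaves the model unchanged", {
  m <- core_acetate_model()
  m2 <- swap_cofactor(m, "ICDHyr", 0)
  expect_equal(m2$S, m$S)
})

test_that("full swap interchanges the NADP+/NADPH coefficients onto NAD+/NADH", {
  m <- core_acetate_model()
  m2 <- swap_cofactor(m, "ICDHyr", 1)
  k <- reaction_index(m, "ICDHyr")
  expect_equal(m2$S["nadp", k], 0)
  expect_equal(m2$S["nadph", k], 0)
  expect_equal(m2$S["nad", k], m$S["nadp", k])
  expect_equal(m2$S["nadh", k], m$S["nadph", k])
  # non-cofactor rows untouched
  others <- setdiff(rownames(m$S), c("nadp", "nadph", "nad", "nadh"))
  expect_equal(m2$S[others, k], m$S[others, k])
})

test_that("half swap splits each pair and conserves summed coefficients", {
  m <- core_acetate_model()
  k <- reaction_index(m, "ICDHyr")
  m2 <- swap_cofactor(m, "ICDHyr", 0.5)
  expect_equal(m2$S["nadp", k], -0.5)
  expect_equal(m2$S["nadh", k], 0.5)
  expect_equal(m2$S["nadp", k] + m2$S["nad", k],
               m$S["nadp", k] + m$S["nad", k])
})

test_that("cofactor coefficient sums are conserved for random fractions", {
  m <- core_acetate_model()
  k <- reaction_index(m, "ICDHyr")
  set.seed(7)
  for (f in runif(100)) {
    m2 <- swap_cofactor(m, "ICDHyr", f)
    expect_equal(m2$S["nadp", k] + m2$S["nad", k],
                 m$S["nadp", k] + m$S["nad", k], tolerance = 1e-12)
    expect_equal(m2$S["nadph", k] + m2$S["nadh", k],
                 m$S["nadph", k] + m$S["nadh", k], tolerance = 1e-12)
    expect_equal(abs(m2$S["nadp", k]) + abs(m2$S["nad", k]), 1,
                 tolerance = 1e-12)
  }
})

test_that("repeated swaps are expressed from the pristine model", {
  m <- core_acetate_model()
  direct <- swap_cofactor(m, "ICDHyr", 0.7)
  chained <- swap_cofactor(swap_cofactor(m, "ICDHyr", 0.3), "ICDHyr", 0.7)
  expect_equal(chained$S, direct$S)
})

test_that("swap validates its inputs", {
  m <- core_acetate_model()
  expect_error(swap_cofactor(m, "ICDHyr", 1.2), "\\[0, 1\\]")
  expect_error(swap_cofactor(m, "FUM", 0.5), "no NADP")
  expect_error(swap_cofactor(m, "NOPE", 0.5), "unknown reaction")
})

test_that("knockout zeroes both bounds and silences the reaction in FVA", {
  m <- core_acetate_model()
  strains <- table1_strains()
  prep <- prep_strain(knockout(m, "THD2pp"), strains$wild_type)
  r <- get_range(fva(prep, "THD2pp"), "THD2pp")
  expect_equal(unname(r), c(0, 0))
  # already-zero reaction unchanged
  m2 <- knockout(m, "THD2pp")
  expect_equal(knockout(m2, "THD2pp")$reactions, m2$reactions)
  expect_error(knockout(m, "NOPE"), "unknown reaction")
})

test_that("knocking out biomass forces zero growth", {
  m <- knockout(core_acetate_model(), "BIOMASS_core")
  sol <- fba(m, "BIOMASS_core", "max")
  expect_equal(sol$objective, 0, tolerance = 1e-12)
})

test_that("make_irreversible clamps the lower bound at zero only", {
  m <- core_acetate_model()
  k <- reaction_index(m, "POR5")
  expect_equal(m$reactions$lower_bound[k], -1000)
  m2 <- make_irreversible(m, "POR5")
  expect_equal(m2$reactions$lower_bound[k], 0)
  expect_equal(m2$reactions$upper_bound[k],
               m$reactions$upper_bound[k])
  expect_equal(make_irreversible(m2, "POR5")$reactions,
               m2$reactions)
  # no feasible flux is negative afterwards
  prep <- prep_strain(m2, table1_strains()$wild_type)
  expect_gte(get_range(fva(prep, "POR5"), "POR5")[["min"]], -1e-9)
})

test_that("apply_strain composes the edits and fixes the measured rates", {
  m <- core_acetate_model()
  strains <- table1_strains()
  wt <- apply_strain(m, strains$wild_type)
  k_ac <- reaction_index(wt, "EX_ac_e")
  expect_equal(wt$reactions$lower_bound[k_ac], -7.88)
  expect_equal(wt$reactions$upper_bound[k_ac], -7.88)
  k_bio <- reaction_index(wt, "BIOMASS_core")
  expect_equal(wt$reactions$lower_bound[k_bio], 0.196)
  expect_equal(wt$reactions$lower_bound[reaction_index(wt, "POR5")], 0)

  dm <- apply_strain(m, strains$icd_nad_dpntab)
  expect_equal(dm$S["nadh", reaction_index(dm, "ICDHyr")], 1)
  expect_equal(dm$reactions$upper_bound[reaction_index(dm, "THD2pp")], 0)
  expect_equal(dm$reactions$lower_bound[reaction_index(dm, "EX_ac_e")], -7)
})

test_that("apply_strain is idempotent for fixed constraints", {
  m <- core_acetate_model()
  cons <- table1_strains()$icd_nad
  once <- apply_strain(m, cons)
  twice <- apply_strain(once, cons)
  expect_equal(twice$S, once$S)
  expect_equal(twice$reactions, once$reactions)
})

test_that("the packaged strain table carries the measured physiology", {
  st <- table1_strains()
  expect_length(st, 4)
  expect_equal(st$wild_type$mu, 0.196)
  expect_equal(st$wild_type$qac, 7.88)
  expect_equal(st$icd_nad$swap_fraction, 1)
  expect_false(st$dpntab$pntab_present)
  expect_equal(st$icd_nad_dpntab$mu, 0.1203)
  expect_error(strain_constraints("x", mu = -1, qac = 5), "mu > 0")
})
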