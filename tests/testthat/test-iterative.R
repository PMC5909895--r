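# Alternate-optima enumeration, selection, thresholding and the full
# iterative procedure.

test_that("sum-of-squares selection is minimal and stable under ties", {
  mk <- function(v) flux_distribution(stats::setNames(v, paste0("R", seq_along(v))),
                                      0, "optimal")
  a <- mk(c(1, 1, 0)); b <- mk(c(1, 0, 1)); d <- mk(c(2, 0, 0))
  sel <- min_sum_squares_select(list(a, b, d))
  expect_identical(sel$fluxes, a$fluxes)       # tie with b, first wins
  expect_identical(min_sum_squares_select(list(d))$fluxes, d$fluxes)
  z <- mk(c(0, 0, 0))
  expect_identical(min_sum_squares_select(list(d, z, a))$fluxes, z$fluxes)
  expect_error(min_sum_squares_select(list()), "empty")
})

test_that("a unique optimum enumerates to a single solution", {
  m <- cofswap:::toy_chain_model()
  res <- enumerate_alternate_optima(m, "SINK", n = 10)
  expect_length(res$solutions, 1)
  expect_true(res$exhausted)
  expect_equal(res$solutions[[1]]$objective, 10, tolerance = 1e-6)
})

test_that("parallel equivalent paths give exactly k support-distinct optima", {
  for (k in c(1, 2, 5)) {
    m <- degenerate_optima_model(k)
    res <- enumerate_alternate_optima(m, "SINK", n = 400)
    expect_length(res$solutions, k)
    expect_true(res$exhausted)
    for (s in res$solutions) {
      expect_equal(s$objective, 10, tolerance = 1e-6)
    }
    supports <- lapply(res$solutions, function(s)
      sort(names(which(abs(s$fluxes) > 1e-6))))
    expect_identical(length(unique(supports)), as.integer(k))
  }
})

test_that("sum-of-squares selection prefers the shortest parallel route", {
  m <- degenerate_optima_model(3, lengths = c(3L, 1L, 2L))
  res <- enumerate_alternate_optima(m, "SINK", n = 400)
  expect_length(res$solutions, 3)
  sel <- min_sum_squares_select(res$solutions)
  expect_gt(abs(get_flux(sel, "PATH2_1")), 1e-6)
  expect_lt(abs(get_flux(sel, "PATH1_1")), 1e-6)
})

test_that("sub-threshold fluxes get pinned, loop reactions stay free", {
  m <- loopy_toy_model()
  v <- stats::setNames(c(-10, 10, 1000, 1000, 1000, 10), reaction_ids(m))
  dist <- flux_distribution(v, 10, "optimal")
  m2 <- fix_subthreshold_fluxes(m, dist, 500)
  rx <- m2$reactions
  expect_equal(rx$lower_bound[rx$id == "CONV"], 10)
  expect_equal(rx$upper_bound[rx$id == "CONV"], 10)
  expect_equal(rx$lower_bound[rx$id == "LOOP1"], -1000)  # kept free
  expect_equal(rx$upper_bound[rx$id == "LOOP1"], 1000)
  # all-below-threshold distribution pins everything
  v2 <- stats::setNames(c(-10, 10, 3, 3, 3, 10), reaction_ids(m))
  m3 <- fix_subthreshold_fluxes(m, flux_distribution(v2, 10, "optimal"), 500)
  expect_equal(m3$reactions$lower_bound, m3$reactions$upper_bound)
})

test_that("thresholding uses flux magnitude, not sign", {
  m <- loopy_toy_model()
  v <- stats::setNames(c(-10, 10, -600, -600, -600, 10), reaction_ids(m))
  m2 <- fix_subthreshold_fluxes(m, flux_distribution(v, 10, "optimal"), 500)
  rx <- m2$reactions
  expect_equal(rx$lower_bound[rx$id == "LOOP1"], -1000)
  expect_equal(rx$lower_bound[rx$id == "EX_A"], -10)
  expect_equal(rx$upper_bound[rx$id == "EX_A"], -10)
})

test_that("the internal cycle can carry bound-magnitude flux yet ends at zero", {
  m <- loopy_toy_model()
  fr <- fva(set_bounds(m, "SINK", lb = 10, ub = 10))
  expect_equal(unname(get_range(fr, "LOOP1")), c(-1000, 1000),
               tolerance = 1e-9)
  res <- enumerate_alternate_optima(m, "SINK", n = 50)
  sel <- min_sum_squares_select(res$solutions)
  expect_equal(get_flux(sel, "SINK"), 10, tolerance = 1e-6)
  expect_lt(abs(get_flux(sel, "LOOP1")), 1e-6)
  expect_lt(abs(get_flux(sel, "LOOP2")), 1e-6)
})

test_that("the full procedure equals plain FBA when the optimum is unique", {
  # chain network dressed with the reactions the procedure manipulates
  m <- cofswap:::build_model("unique_opt", list(
    EX_ac_e = cofswap:::rxn(c(A = -1), lb = -10, ub = -10),
    EX_o2_e = cofswap:::rxn(c(o2_e = -1), lb = -1000, ub = 0),
    O2X     = cofswap:::rxn(c(o2_e = -1, A = -1, atp = 1)),
    BIOMASS = cofswap:::rxn(c(atp = -2), lb = 0.5, ub = 0.5),
    ATPM    = cofswap:::rxn(c(atp = -1), lb = 3.15)
  ))
  plain <- fba(set_bounds(m, "ATPM", lb = 0, ub = 50), "ATPM", "max")
  it <- iterative_optimize(m)
  expect_equal(it$fluxes, plain$fluxes, tolerance = 1e-9)
  prov <- attr(it, "provenance")
  expect_equal(prov$atpm_final, prov$atpm_max, tolerance = 1e-9)
  expect_equal(prov$n_optima_first, 1L)
})

test_that("two identical runs of the procedure are bit-identical", {
  m <- core_acetate_model()
  cons <- table1_strains()$wild_type
  cfg <- iter_opt_config(n_optima = 5)
  r1 <- iterative_optimize(m, cons, config = cfg)
  r2 <- iterative_optimize(m, cons, config = cfg)
  expect_identical(r1$fluxes, r2$fluxes)
})

test_that("the final distribution respects every constraint and the step-2 optimum", {
  m <- core_acetate_model()
  cons <- table1_strains()$icd_nad
  cfg <- iter_opt_config(n_optima = 5)
  it <- iterative_optimize(m, cons, config = cfg)
  prov <- attr(it, "provenance")
  expect_equal(get_flux(it, "ATPM"), prov$atpm_max, tolerance = 1e-5)
  prep <- apply_strain(m, cons)
  v <- it$fluxes[prep$reactions$id]
  expect_lt(max(abs(prep$S %*% v)), 1e-6)
  expect_equal(get_flux(it, "EX_ac_e"), -cons$qac, tolerance = 1e-9)
  expect_equal(get_flux(it, "BIOMASS_core"), cons$mu, tolerance = 1e-9)
  expect_equal(get_flux(it, "EX_o2_e"), prov$o2_min, tolerance = 1e-9)
})

test_that("infeasible constraints name the failing step", {
  m <- core_acetate_model()
  cons <- strain_constraints("impossible", mu = 5, qac = 7.88)
  expect_error(iterative_optimize(m, cons), "step 2")
})
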