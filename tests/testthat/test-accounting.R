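# Net turnover, ATP allocation, cofactor sources, partition, swap scan.

test_that("net turnover halves agree on random steady-state flux vectors", {
  m <- core_acetate_model()
  set.seed(31)
  for (trial in 1:20) {
    v <- random_steady_state(m)
    dist <- flux_distribution(stats::setNames(v, reaction_ids(m)), 0,
                              "optimal")
    for (met in sample(metabolite_ids(m), 5)) {
      nt <- net_turnover(m, dist, met)
      pos <- sum(nt$terms[nt$terms > 0])
      neg <- -sum(nt$terms[nt$terms < 0])
      expect_equal(pos, neg, tolerance = 1e-6)
      expect_equal(nt$phi, pos, tolerance = 1e-6)
      expect_gte(nt$phi, 0)
    }
  }
})

test_that("turnover arithmetic on a two-reaction producer/consumer pair", {
  m <- cofswap:::toy_chain_model()
  v <- stats::setNames(c(-2, 2, 2), reaction_ids(m))
  dist <- flux_distribution(v, 2, "optimal")
  expect_equal(net_turnover(m, dist, "B")$phi, 2)
  # untouched metabolite
  v0 <- stats::setNames(c(0, 0, 0), reaction_ids(m))
  expect_equal(net_turnover(m, flux_distribution(v0, 0, "optimal"), "A")$phi, 0)
  expect_error(net_turnover(m, dist, "nonexistent"), "unknown metabolite")
})

test_that("cycle flux inflates turnover and the iterative procedure removes it", {
  m <- loopy_toy_model()
  loopy <- stats::setNames(c(-10, 10, 1000, 1000, 1000, 10),
                           reaction_ids(m))
  inflated <- net_turnover(m, flux_distribution(loopy, 10, "optimal"), "C")
  expect_equal(inflated$phi, 1000)
  res <- enumerate_alternate_optima(set_bounds(m, "SINK", lb = 10, ub = 10),
                                    "SINK", n = 20)
  sel <- min_sum_squares_select(res$solutions)
  clean <- net_turnover(m, sel, "C")
  expect_lt(clean$phi, 1e-6)
})

test_that("ATP allocation splits total turnover into maintenance and growth", {
  m <- core_acetate_model()
  strains <- table1_strains()
  wt <- fba(prep_strain(m, strains$wild_type), "ATPM", "max")
  al <- atp_allocation(m, wt)
  expect_equal(al$total, al$atpm + al$atp_growth, tolerance = 1e-9)
  expect_equal(al$total, net_turnover(m, wt, "atp")$phi, tolerance = 1e-9)
  expect_gte(al$atp_growth, 0)
  expect_gte(al$atpm, 0)
  # swapped strains allocate more ATP to maintenance
  ic <- fba(prep_strain(m, strains$icd_nad), "ATPM", "max")
  expect_gt(atp_allocation(m, ic)$atpm, al$atpm)
})

test_that("cofactor source breakdowns list producers only and reconstruct totals", {
  m <- core_acetate_model()
  strains <- table1_strains()
  wt <- fba(prep_strain(m, strains$wild_type), "ATPM", "max")
  nadph <- cofactor_sources(m, wt, "NADPH", qac = strains$wild_type$qac)
  nadh <- cofactor_sources(m, wt, "NADH", qac = strains$wild_type$qac)
  expect_true(all(nadph$sources$flux > 0))
  expect_equal(nadph$total, sum(nadph$sources$flux), tolerance = 1e-12)
  expect_equal(nadph$sources$pct_of_qac,
               100 * nadph$sources$flux / strains$wild_type$qac)
  # the soluble transhydrogenase consumes NADPH and produces NADH in the
  # wild type, so it must appear on exactly one ledger
  expect_false("NADTRHD" %in% nadph$sources$reaction_id)
  expect_true("NADTRHD" %in% nadh$sources$reaction_id)
  # ICDH produces NADPH in the wild type
  expect_true("ICDHyr" %in% nadph$sources$reaction_id)

  # per-term reconstruction against net turnover contributions
  nt <- net_turnover(m, wt, "nadph")
  pos <- nt$terms[nt$terms > 1e-9]
  expect_equal(sort(unname(pos)), sort(nadph$sources$flux),
               tolerance = 1e-9)
})

test_that("a zero-flux transhydrogenase is absent from the breakdown", {
  m <- core_acetate_model()
  ic <- fba(prep_strain(m, table1_strains()$icd_nad), "ATPM", "max")
  expect_lt(abs(get_flux(ic, "NADTRHD")), 1e-9)
  nadh <- cofactor_sources(m, ic, "NADH", qac = 8)
  expect_false("NADTRHD" %in% nadh$sources$reaction_id)
})

test_that("isocitrate partition fractions are complementary and consistent", {
  v <- stats::setNames(c(2, 2), c("ICL", "ICDHyr"))
  eq <- isocitrate_partition(flux_distribution(v, 0, "optimal"))
  expect_equal(eq$p_icl, 0.5)
  expect_equal(eq$ratio, 1)
  set.seed(5)
  for (trial in 1:25) {
    v <- stats::setNames(runif(2, 0.01, 10), c("ICL", "ICDHyr"))
    pr <- isocitrate_partition(flux_distribution(v, 0, "optimal"))
    expect_equal(pr$p_icl + pr$p_icdh, 1, tolerance = 1e-12)
    expect_equal(pr$ratio, pr$p_icdh / pr$p_icl, tolerance = 1e-9)
  }
  z <- stats::setNames(c(0, 0), c("ICL", "ICDHyr"))
  expect_error(isocitrate_partition(flux_distribution(z, 0, "optimal")),
               "undefined")
})

test_that("partition of the optimal distribution lies within the FVA partition range", {
  m <- core_acetate_model()
  cons <- table1_strains()$wild_type
  prep <- prep_strain(m, cons)
  sol <- fba(prep, "ATPM", "max")
  part <- isocitrate_partition(sol)
  prep2 <- set_bounds(prep, "ATPM", lb = sol$objective, ub = 50)
  fr <- as.data.frame(fva(prep2, c("ICL", "ICDHyr")))
  tot <- get_flux(sol, "ICL") + get_flux(sol, "ICDHyr")
  p_lo <- fr$min_flux[fr$reaction_id == "ICL"] / tot
  p_hi <- fr$max_flux[fr$reaction_id == "ICL"] / tot
  expect_gte(part$p_icl, p_lo - 1e-6)
  expect_lte(part$p_icl, p_hi + 1e-6)
})

test_that("swap scan at fraction zero equals the unswapped strain", {
  m <- core_acetate_model()
  cons <- table1_strains()$icd_nad
  sc <- swap_scan(m, cons, fractions = c(0, 1))
  cons0 <- cons
  cons0$swap_fraction <- 0
  direct <- fba(prep_strain(m, cons0), "ATPM", "max")
  expect_equal(sc$atpm[1], direct$objective, tolerance = 1e-9)
  expect_true(all(sc$status == "optimal"))
  # full swap matches the strain's own preparation
  direct1 <- fba(prep_strain(m, cons), "ATPM", "max")
  expect_equal(sc$atpm[2], direct1$objective, tolerance = 1e-9)
})
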