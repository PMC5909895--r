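# Packaged synthetic networks. These are hand-solvable fixtures that
# reproduce the structural features the analyses rely on: the isocitrate
# bifurcation with an NADP+-specific dehydrogenase, the glyoxylate shunt,
# both transhydrogenases, an ATP drain, internal loops and degenerate
# optima. They test mechanisms, not genome-scale magnitudes.

# Build a model from a list of reactions given as
# list(id = list(mets = c(met = coef, ...), lb = , ub = , obj = )).
build_model <- function(id, reactions, compartments = NULL) {
  met_ids <- unique(unlist(lapply(reactions, function(r) names(r$mets))))
  comp <- vapply(met_ids, function(m) {
    if (!is.null(compartments) && m %in% names(compartments))
      compartments[[m]] else if (grepl("_e$", m)) "e" else "c"
  }, "")
  S <- matrix(0, length(met_ids), length(reactions),
              dimnames = list(met_ids, names(reactions)))
  for (k in seq_along(reactions)) {
    S[names(reactions[[k]]$mets), k] <- reactions[[k]]$mets
  }
  rx <- data.frame(
    id = names(reactions),
    name = names(reactions),
    lower_bound = vapply(reactions, function(r) r$lb %||% 0, 0),
    upper_bound = vapply(reactions, function(r) r$ub %||% 1000, 0),
    objective_coefficient = vapply(reactions, function(r) r$obj %||% 0, 0),
    stringsAsFactors = FALSE
  )
  metabolic_model(id = id,
                  metabolites = data.frame(id = met_ids, name = met_ids,
                                           compartment = comp,
                                           stringsAsFactors = FALSE),
                  reactions = rx, S = S)
}

rxn <- function(mets, lb = 0, ub = 1000, obj = 0) {
  list(mets = mets, lb = lb, ub = ub, obj = obj)
}

#' Core acetate network
#'
#' A condensed, hand-solvable model of E. coli acetate metabolism:
#' acetate activation, TCA cycle with the NADP+-specific isocitrate
#' dehydrogenase, glyoxylate shunt (ICL + malate synthase), gluconeogenesis
#' and pentose-phosphate lumps, both malic enzymes, the PntAB and UdhA
#' transhydrogenases, pyruvate:ferredoxin oxidoreductase with its
#' flavodoxin/NADPH reductase partner, oxidative phosphorylation lumps, an
#' ATP-maintenance drain and a biomass reaction consuming precursors, ATP
#' and NADPH. The fumarase isozyme pair (FUM/FUMB) provides both an
#' internal loop able to carry arbitrary circulating flux and a
#' degenerate-optimum structure. Without edits, the reversible POR5 permits
#' spurious carbon fixation so growth survives an ICL shutdown; making
#' POR5 irreversible (the standard strain preparation) restores glyoxylate
#' shunt essentiality.
#'
#' Biomass precursor, ATP and NADPH coefficients are mmol per gDW, chosen
#' in the physiological range for E. coli, so biomass flux is in h^-1.
#'
#' @return A [metabolic_model()].
#' @export
core_acetate_model <- function() {
  build_model("core_acetate", list(
    EX_ac_e  = rxn(c(ac_e = -1), lb = -1000, ub = 1000),
    EX_o2_e  = rxn(c(o2_e = -1), lb = -1000, ub = 0),
    EX_co2_e = rxn(c(co2_e = -1), lb = -1000, ub = 1000),
    O2t      = rxn(c(o2_e = -1, o2 = 1)),
    CO2t     = rxn(c(co2 = -1, co2_e = 1), lb = -1000),
    ACS      = rxn(c(ac_e = -1, atp = -2, accoa = 1, adp = 2)),
    CS_ACONT = rxn(c(accoa = -1, oaa = -1, icit = 1)),
    ICDHyr   = rxn(c(icit = -1, nadp = -1, akg = 1, co2 = 1, nadph = 1),
                   lb = -1000),
    ICL      = rxn(c(icit = -1, glx = 1, succ = 1)),
    MALS     = rxn(c(accoa = -1, glx = -1, mal = 1)),
    AKGDH    = rxn(c(akg = -1, nad = -1, adp = -1, succ = 1, co2 = 1,
                     nadh = 1, atp = 1)),
    SUCDi    = rxn(c(succ = -1, fum = 1, fadh2 = 1)),
    FUM      = rxn(c(fum = -1, mal = 1), lb = -1000),
    FUMB     = rxn(c(fum = -1, mal = 1), lb = -1000),
    MDH      = rxn(c(mal = -1, nad = -1, oaa = 1, nadh = 1), lb = -1000),
    ME1      = rxn(c(mal = -1, nad = -1, pyr = 1, co2 = 1, nadh = 1)),
    ME2      = rxn(c(mal = -1, nadp = -1, pyr = 1, co2 = 1, nadph = 1)),
    PDH      = rxn(c(pyr = -1, nad = -1, accoa = 1, co2 = 1, nadh = 1)),
    POR5     = rxn(c(pyr = -1, fdox = -1, accoa = 1, co2 = 1, fdred = 1),
                   lb = -1000),
    FLDR     = rxn(c(nadph = -1, fdox = -1, fdred = 1, nadp = 1)),
    PPS      = rxn(c(pyr = -1, atp = -2, pep = 1, adp = 2)),
    PPC      = rxn(c(pep = -1, co2 = -1, oaa = 1)),
    PCK      = rxn(c(oaa = -1, atp = -1, pep = 1, co2 = 1, adp = 1)),
    GLUCONEO = rxn(c(pep = -2, atp = -2, nadh = -2, g6p = 1, adp = 2,
                     nad = 2)),
    G6PDH2r  = rxn(c(g6p = -1, nadp = -1, p6g = 1, nadph = 1)),
    GND      = rxn(c(p6g = -1, nadp = -1, ru5p = 1, co2 = 1, nadph = 1)),
    PPP_NONOX = rxn(c(g6p = -1, ru5p = 1.2)),
    THD2pp   = rxn(c(nadh = -1, nadp = -1, atp = -0.25, nad = 1,
                     nadph = 1, adp = 0.25)),
    NADTRHD  = rxn(c(nadph = -1, nad = -1, nadp = 1, nadh = 1)),
    NADH16   = rxn(c(nadh = -1, o2 = -0.5, adp = -2, nad = 1, atp = 2)),
    FADH2O   = rxn(c(fadh2 = -1, o2 = -0.5, adp = -1, atp = 1)),
    ATPM     = rxn(c(atp = -1, adp = 1), lb = 3.15),
    BIOMASS_core = rxn(c(accoa = -2.4, oaa = -1.8, akg = -1.1, pep = -0.7,
                         pyr = -2.8, g6p = -0.2, ru5p = -0.9,
                         nadph = -12, atp = -50, nadp = 12, adp = 50),
                       obj = 1)
  ))
}

#' Reference values for the core acetate network
#'
#' Frozen optima for the packaged core network under standard preparation
#' (POR5 irreversible, maintenance released to 0-50), derived with an
#' independent solver and kept as the fixture's sidecar. Values are exact
#' to the stated digits.
#'
#' @return A named list: `wt_biomass_max` (maximal growth rate at the
#'   wild-type acetate uptake 7.88 with maintenance at its default floor),
#'   `wt_atpm_max` (maximal maintenance flux, released to 0-50, with
#'   wild-type growth 0.196 and uptake fixed), `swap_biomass_max` (maximal
#'   growth after full cofactor swap, wild-type uptake), and
#'   `icdnad_atpm_max` (maximal maintenance flux under full swap with the
#'   swapped strain's measured growth 0.135 and uptake 8.0).
#' @export
core_acetate_reference <- function() {
  list(
    qac_wt = 7.88,
    mu_wt = 0.196,
    wt_biomass_max = 0.221313941825476,
    wt_atpm_max = 8.1976,
    swap_biomass_max = 0.218790282597914,
    icdnad_atpm_max = 20.7705
  )
}

#' Internal-loop toy network
#'
#' A linear uptake-conversion-sink pathway with a superimposed
#' three-reaction reversible cycle (B -> C -> D -> B) that can circulate
#' arbitrary flux without affecting any exchange. Naive FBA leaves the
#' cycle flux undetermined up to the bound magnitude; the iterative
#' procedure's sparse enumeration returns the loop-free solution (uptake
#' and sink at 10, cycle at 0).
#'
#' @return A [metabolic_model()].
#' @export
loopy_toy_model <- function() {
  build_model("loopy_toy", list(
    EX_A  = rxn(c(A = -1), lb = -10, ub = 0),
    CONV  = rxn(c(A = -1, B = 1)),
    LOOP1 = rxn(c(B = -1, C = 1), lb = -1000),
    LOOP2 = rxn(c(C = -1, D = 1), lb = -1000),
    LOOP3 = rxn(c(D = -1, B = 1), lb = -1000),
    SINK  = rxn(c(B = -1), obj = 1)
  ))
}

#' Parallel-path degenerate-optimum network
#'
#' `k` stoichiometrically equivalent routes from a fixed substrate uptake
#' to a sink, giving exactly `k` support-distinct optimal flux
#' distributions. Path `i` consists of `lengths[i]` serial reactions, so
#' unequal lengths let the sum-of-squares selection prefer the shortest
#' route.
#'
#' @param k number of parallel routes.
#' @param lengths integer vector (length `k`) of reactions per route.
#' @return A [metabolic_model()].
#' @export
degenerate_optima_model <- function(k, lengths = rep(1L, k)) {
  stopifnot(k >= 1, length(lengths) == k, all(lengths >= 1))
  rxns <- list(EX_A = rxn(c(A = -1), lb = -10, ub = -10))
  for (i in seq_len(k)) {
    prev <- "A"
    for (s in seq_len(lengths[i])) {
      nxt <- if (s == lengths[i]) "B" else sprintf("P%d_%d", i, s)
      mets <- c(-1, 1)
      names(mets) <- c(prev, nxt)
      rxns[[sprintf("PATH%d_%d", i, s)]] <- rxn(mets)
      prev <- nxt
    }
  }
  rxns$SINK <- rxn(c(B = -1), obj = 1)
  build_model(sprintf("degenerate_%d", k), rxns)
}

# Minimal chain with a unique optimum: uptake (<=10) -> conversion -> sink.
# Used to check that the full iterative procedure collapses to plain FBA
# when the optimum is unique.
toy_chain_model <- function() {
  build_model("toy_chain", list(
    EX_A = rxn(c(A = -1), lb = -10, ub = 0),
    CONV = rxn(c(A = -1, B = 1)),
    SINK = rxn(c(B = -1), obj = 1)
  ))
}

# One-dimensional feasible segment: v_in = v_out in [0, 10]. The sampling
# chain should be uniform on it.
segment_model <- function(upper = 10) {
  build_model("segment", list(
    IN  = rxn(c(m = 1), lb = 0, ub = upper),
    OUT = rxn(c(m = -1), lb = 0, ub = upper, obj = 1)
  ))
}
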