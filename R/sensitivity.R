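# Sensitivity analyses: robustness curves, partition-constrained FBA at the
# isocitrate branch point, and the phenotype phase plane.

#' Robustness analysis
#'
#' Fixes a control reaction at each grid value (`lb = ub = value`) and
#' re-optimizes the objective. Infeasible grid points are reported with
#' status `"infeasible"`, never dropped.
#'
#' @param model a `metabolic_model`.
#' @param control_reaction reaction fixed along the grid.
#' @param values numeric grid of fixed values.
#' @param objective_reaction reaction to optimize at each point.
#' @param sense `"max"` or `"min"`.
#' @return Data frame with columns `value`, `objective`, `status`.
#' @export
robustness <- function(model, control_reaction, values, objective_reaction,
                       sense = "max") {
  out <- data.frame(value = values, objective = NA_real_,
                    status = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(values)) {
    m <- set_bounds(model, control_reaction, lb = values[i], ub = values[i])
    sol <- fba(m, objective_reaction, sense = sense)
    out$objective[i] <- sol$objective
    out$status[i] <- sol$status
  }
  out
}

#' FBA with a fixed isocitrate branch-point partition
#'
#' Adds the single equality row `v_ICL - p * (v_ICL + v_ICDH) = 0`, i.e.
#' fixes the fraction `p` of isocitrate-consuming flux routed through
#' isocitrate lyase, and optimizes the objective. The constraint lives only
#' in the solve; the model is not modified.
#'
#' @param model a `metabolic_model`.
#' @param p partition fraction toward ICL in `[0, 1]`.
#' @param objective reaction to optimize.
#' @param sense `"max"` or `"min"`.
#' @param icl,icdh reaction ids of the two branches.
#' @return A [flux_distribution()].
#' @export
partition_constrained_fba <- function(model, p, objective, sense = "max",
                                      icl = "ICL", icdh = "ICDHyr") {
  if (p < 0 || p > 1) stop("partition fraction must lie in [0, 1]")
  n <- nrow(model$reactions)
  row <- matrix(0, 1, n)
  row[1, reaction_index(model, icl)] <- 1 - p
  row[1, reaction_index(model, icdh)] <- -p
  fba(model, objective, sense = sense, extra_rows = row, extra_rhs = 0)
}

#' Phenotype phase plane over isocitrate production and branch partition
#'
#' For every combination of isocitrate production rate (the aconitase flux,
#' equal to `v_ICL + v_ICDH` at steady state) and ICL partition `p`, biomass
#' is maximized and reported as a yield (`mu / qac`, gDW per mmol acetate).
#' The maintenance reaction is expected to have been lower-bounded at its
#' strain optimum beforehand (see [iterative_optimize()]); this function
#' does not change bounds. Infeasible cells carry `NA` yield and their
#' status.
#'
#' @param model a `metabolic_model` already carrying strain bounds.
#' @param iso_values grid of isocitrate production rates.
#' @param p_values grid of ICL partition fractions in `[0, 1]`.
#' @param qac acetate uptake rate used to convert growth rate to yield.
#' @param objective biomass reaction id (`NULL` to auto-detect).
#' @param icl,icdh branch reaction ids.
#' @return Long-format data frame `(iso_production, p, growth, yield,
#'   status)`.
#' @export
phase_plane <- function(model, iso_values, p_values, qac,
                        objective = NULL, icl = "ICL", icdh = "ICDHyr") {
  if (is.null(objective)) objective <- find_biomass(model)
  n <- nrow(model$reactions)
  i_icl <- reaction_index(model, icl)
  i_icdh <- reaction_index(model, icdh)
  grid <- expand.grid(iso_production = iso_values, p = p_values)
  grid$growth <- NA_real_
  grid$yield <- NA_real_
  grid$status <- NA_character_
  for (g in seq_len(nrow(grid))) {
    rows <- matrix(0, 2, n)
    rows[1, c(i_icl, i_icdh)] <- 1                 # total isocitrate flux
    rows[2, i_icl] <- 1 - grid$p[g]                # partition equality
    rows[2, i_icdh] <- -grid$p[g]
    sol <- fba(model, objective, sense = "max", extra_rows = rows,
               extra_rhs = c(grid$iso_production[g], 0))
    grid$status[g] <- sol$status
    if (sol$status == "optimal") {
      grid$growth[g] <- sol$objective
      grid$yield[g] <- sol$objective / qac
    }
  }
  grid
}
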