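# The iterative optimization procedure: ATP-yield maximization, oxygen
# minimization, MILP enumeration of alternate optima, minimum-sum-of-squares
# selection and sub-threshold flux fixing, yielding a unique optimal flux
# distribution per strain.

#' Configuration for the iterative optimization
#'
#' @param atpm_release bounds (lower, upper) to which the maintenance
#'   reaction is released before ATP-yield maximization, in
#'   mmol x gDW^-1 x h^-1.
#' @param n_optima number of alternate optima enumerated per MILP stage.
#' @param loop_threshold flux magnitude below which reactions are fixed
#'   after the first selection (mmol x gDW^-1 x h^-1); reactions at or
#'   above it keep their bounds so re-optimization can shrink loop fluxes.
#' @param obj_tol relative tolerance defining the optimal face in the MILP.
#' @param support_tol flux magnitude counted as "active".
#' @param time_limit seconds allowed per MILP integer-cut solve.
#' @param max_nodes branch-and-bound node cap per MILP solve.
#' @param atpm_reaction,o2_exchange reaction ids.
#' @return A list of class `iter_opt_config`.
#' @export
iter_opt_config <- function(atpm_release = c(0, 50), n_optima = 400L,
                            loop_threshold = 500, obj_tol = 1e-6,
                            support_tol = 1e-6, time_limit = 60,
                            max_nodes = 50000L,
                            atpm_reaction = "ATPM",
                            o2_exchange = "EX_o2_e") {
  stopifnot(n_optima >= 1, loop_threshold > 0)
  structure(list(atpm_release = atpm_release, n_optima = as.integer(n_optima),
                 loop_threshold = loop_threshold, obj_tol = obj_tol,
                 support_tol = support_tol, time_limit = time_limit,
                 max_nodes = max_nodes, atpm_reaction = atpm_reaction,
                 o2_exchange = o2_exchange),
            class = "iter_opt_config")
}

#' Select the flux distribution minimizing the sum of squared velocities
#'
#' Among enumerated optima, returns the one with smallest `sum(v_i^2)`;
#' ties break stably to the earliest element.
#'
#' @param solutions non-empty list of [flux_distribution()] objects.
#' @return The selected `flux_distribution`.
#' @export
min_sum_squares_select <- function(solutions) {
  if (length(solutions) == 0) stop("empty solution list")
  ss <- vapply(solutions, function(s) sum(s$fluxes^2), 0)
  solutions[[which.min(ss)]]
}

#' Fix sub-threshold fluxes
#'
#' Every reaction whose flux magnitude in `dist` is below `threshold` gets
#' `lb = ub = flux`; reactions at or above the threshold keep their
#' original bounds, so a later re-optimization can shrink internal-loop
#' fluxes.
#'
#' @param model a `metabolic_model`.
#' @param dist a [flux_distribution()] valid for `model`.
#' @param threshold flux magnitude cut-off (mmol x gDW^-1 x h^-1).
#' @return The modified model.
#' @export
fix_subthreshold_fluxes <- function(model, dist, threshold) {
  stopifnot(inherits(dist, "flux_distribution"),
            length(dist$fluxes) == nrow(model$reactions))
  v <- dist$fluxes[model$reactions$id]
  fix <- abs(v) < threshold
  model$reactions$lower_bound[fix] <- v[fix]
  model$reactions$upper_bound[fix] <- v[fix]
  model$reactions$reversible <- model$reactions$lower_bound < 0
  model
}

#' Iterative optimization of a strain model
#'
#' Executes the full procedure on a model already carrying (or given) the
#' strain's physiological constraints: (1) release the maintenance reaction
#' to `atpm_release`; (2) maximize it by LP; (3) set the maximum as its
#' lower bound; (4) minimize the oxygen uptake magnitude; (5) fix the
#' oxygen exchange at that minimum; (6-7) enumerate up to `n_optima`
#' ATP-optimal flux distributions by MILP; (8) select the one minimizing
#' the sum of squared velocities; (9) fix all sub-threshold fluxes; (10)
#' re-enumerate; (11) select again. The returned distribution carries a
#' `provenance` attribute recording every intermediate objective value.
#'
#' @param model a `metabolic_model`.
#' @param constraints optional [strain_constraints()]; when supplied,
#'   [apply_strain()] is called first.
#' @param config an [iter_opt_config()].
#' @param ... passed to [apply_strain()].
#' @return A [flux_distribution()] with a `provenance` attribute.
#' @export
iterative_optimize <- function(model, constraints = NULL,
                               config = iter_opt_config(), ...) {
  if (!is.null(constraints)) model <- apply_strain(model, constraints, ...)
  prov <- list()
  step <- function(k, what) paste0("step ", k, " (", what, ")")

  # 1. release ATPM
  model <- set_bounds(model, config$atpm_reaction,
                      lb = config$atpm_release[1],
                      ub = config$atpm_release[2])
  # 2. maximize ATPM
  sol2 <- fba(model, config$atpm_reaction, sense = "max")
  if (sol2$status != "optimal") {
    stop("infeasible at ", step(2, "ATP-yield maximization"), ": status ",
         sol2$status)
  }
  prov$atpm_max <- sol2$objective
  # 3. constrain ATPM lower bound at its maximum
  model <- set_bounds(model, config$atpm_reaction, lb = sol2$objective)
  # 4. minimize oxygen uptake magnitude (maximize the negative exchange
  #    flux toward zero)
  sol4 <- fba(model, config$o2_exchange, sense = "max")
  if (sol4$status != "optimal") {
    stop("infeasible at ", step(4, "oxygen minimization"), ": status ",
         sol4$status)
  }
  prov$o2_min <- sol4$objective
  # 5. fix oxygen exchange
  model <- set_bounds(model, config$o2_exchange, lb = sol4$objective,
                      ub = sol4$objective)
  # 6-7. enumerate ATP-optimal alternate optima
  enum1 <- enumerate_alternate_optima(model, config$atpm_reaction,
                                      n = config$n_optima, sense = "max",
                                      config = config)
  if (length(enum1$solutions) == 0) {
    stop("infeasible at ", step(7, "first MILP enumeration"))
  }
  prov$n_optima_first <- length(enum1$solutions)
  prov$exhausted_first <- enum1$exhausted
  # 8. min sum-of-squares selection
  sel1 <- min_sum_squares_select(enum1$solutions)
  prov$sumsq_first <- sum(sel1$fluxes^2)
  # 9. fix sub-threshold fluxes
  model9 <- fix_subthreshold_fluxes(model, sel1, config$loop_threshold)
  # 10. re-enumerate
  enum2 <- enumerate_alternate_optima(model9, config$atpm_reaction,
                                      n = config$n_optima, sense = "max",
                                      config = config)
  if (length(enum2$solutions) == 0) {
    stop("infeasible at ", step(10, "second MILP enumeration"))
  }
  prov$n_optima_second <- length(enum2$solutions)
  prov$exhausted_second <- enum2$exhausted
  # 11. final selection
  sel2 <- min_sum_squares_select(enum2$solutions)
  prov$sumsq_final <- sum(sel2$fluxes^2)
  prov$atpm_final <- get_flux(sel2, config$atpm_reaction)
  prov$warnings <- stats::na.omit(c(enum1$warning, enum2$warning))

  out <- flux_distribution(sel2$fluxes, prov$atpm_final, "optimal",
                           config$atpm_reaction)
  attr(out, "provenance") <- prov
  out
}
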