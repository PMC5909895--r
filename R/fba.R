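# Flux balance analysis and flux variability analysis.

#' Flux distribution object
#'
#' @param fluxes named numeric vector, one flux per model reaction.
#' @param objective objective value at the optimum.
#' @param status solver status.
#' @param objective_reaction id of the optimized reaction (if single).
#' @return An object of class `flux_distribution`.
#' @export
flux_distribution <- function(fluxes, objective, status,
                              objective_reaction = NA_character_) {
  structure(list(fluxes = fluxes, objective = objective, status = status,
                 objective_reaction = objective_reaction),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("Flux distribution (", x$status, ")\n", sep = "")
  if (!is.na(x$objective_reaction)) {
    cat("  objective ", x$objective_reaction, " = ", format(x$objective),
        "\n", sep = "")
  } else {
    cat("  objective =", format(x$objective), "\n")
  }
  if (!is.null(x$fluxes)) {
    act <- sum(abs(x$fluxes) > 1e-9)
    cat("  ", act, " of ", length(x$fluxes), " reactions carry flux\n",
        sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.flux_distribution <- function(x, ...) {
  data.frame(reaction_id = names(x$fluxes), flux = unname(x$fluxes),
             stringsAsFactors = FALSE)
}

#' @export
summary.flux_distribution <- function(object, ...) {
  print(object)
  if (!is.null(object$fluxes)) {
    top <- sort(abs(object$fluxes), decreasing = TRUE)
    top <- top[top > 1e-9][seq_len(min(10, sum(top > 1e-9)))]
    cat("  largest |flux|:\n")
    for (id in names(top)) {
      cat(sprintf("    %-12s %10.4f\n", id, object$fluxes[id]))
    }
  }
  invisible(object)
}

#' Retrieve one flux from a distribution
#'
#' @param dist a `flux_distribution`.
#' @param id reaction id (either exchange dialect).
#' @return The flux value.
#' @export
get_flux <- function(dist, id) {
  ids <- names(dist$fluxes)
  i <- match(id, ids)
  if (is.na(i)) i <- match(normalize_rxn_id(id), normalize_rxn_id(ids))
  if (is.na(i)) stop("unknown reaction id: ", id)
  unname(dist$fluxes[i])
}

# Assemble the LP data for a model, optionally with extra equality rows.
model_lp <- function(model, extra_rows = NULL, extra_rhs = NULL) {
  A <- model$S
  b <- rep(0, nrow(A))
  if (!is.null(extra_rows)) {
    A <- rbind(A, extra_rows)
    b <- c(b, extra_rhs)
  }
  list(A = A, b = b,
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound)
}

#' Flux balance analysis
#'
#' Solves the steady-state linear program `S v = 0`, `lb <= v <= ub`,
#' optimizing a single reaction (or the model's stored objective vector).
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimize; `NULL` uses the model's
#'   objective vector.
#' @param sense `"max"` or `"min"`.
#' @param extra_rows,extra_rhs optional additional equality rows over the
#'   flux vector (used by the partition and phase-plane analyses).
#' @return A [flux_distribution()].
#' @export
fba <- function(model, objective = NULL, sense = c("max", "min"),
                extra_rows = NULL, extra_rhs = NULL) {
  sense <- match.arg(sense)
  lp <- model_lp(model, extra_rows, extra_rhs)
  if (is.null(objective)) {
    c_obj <- model$reactions$objective_coefficient
    obj_id <- NA_character_
    nz <- which(c_obj != 0)
    if (length(nz) == 1) obj_id <- model$reactions$id[nz]
  } else {
    k <- reaction_index(model, objective)
    c_obj <- numeric(nrow(model$reactions))
    c_obj[k] <- 1
    obj_id <- model$reactions$id[k]
  }
  res <- solve_lp(lp$A, lp$b, c_obj, lp$lb, lp$ub, sense = sense)
  if (res$status != "optimal") {
    return(flux_distribution(NULL, NA_real_, res$status, obj_id))
  }
  flux_distribution(stats::setNames(res$x, model$reactions$id),
                    res$objective, "optimal", obj_id)
}

#' Flux range object
#'
#' @param ranges data frame with columns `reaction_id`, `min_flux`,
#'   `max_flux`.
#' @return An object of class `flux_range`.
#' @export
flux_range <- function(ranges) {
  stopifnot(all(ranges$min_flux <= ranges$max_flux + 1e-6, na.rm = TRUE))
  structure(list(ranges = ranges), class = "flux_range")
}

#' @export
print.flux_range <- function(x, ...) {
  cat("Flux ranges for", nrow(x$ranges), "reactions\n")
  fixed <- sum(x$ranges$max_flux - x$ranges$min_flux < 1e-9)
  cat("  ", fixed, " reactions fully determined\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.flux_range <- function(x, ...) x$ranges

#' Retrieve one range from a flux_range
#'
#' @param fr a `flux_range`.
#' @param id reaction id.
#' @return Numeric `c(min, max)`.
#' @export
get_range <- function(fr, id) {
  ids <- fr$ranges$reaction_id
  i <- match(id, ids)
  if (is.na(i)) i <- match(normalize_rxn_id(id), normalize_rxn_id(ids))
  if (is.na(i)) stop("unknown reaction id: ", id)
  c(min = fr$ranges$min_flux[i], max = fr$ranges$max_flux[i])
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to all current model
#' constraints. Errors out before any per-reaction solve if the model is
#' infeasible.
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to analyze (`NULL` for all).
#' @return A [flux_range()].
#' @export
fva <- function(model, reactions = NULL) {
  lp <- model_lp(model)
  n <- nrow(model$reactions)
  feas <- solve_lp(lp$A, lp$b, numeric(n), lp$lb, lp$ub, sense = "min")
  if (feas$status != "optimal") {
    stop("model is infeasible under current constraints; FVA aborted")
  }
  if (is.null(reactions)) reactions <- model$reactions$id
  idx <- vapply(reactions, function(id) reaction_index(model, id), 0L)
  mins <- maxs <- numeric(length(idx))
  for (j in seq_along(idx)) {
    c_obj <- numeric(n)
    c_obj[idx[j]] <- 1
    lo <- solve_lp(lp$A, lp$b, c_obj, lp$lb, lp$ub, sense = "min")
    hi <- solve_lp(lp$A, lp$b, c_obj, lp$lb, lp$ub, sense = "max")
    mins[j] <- if (lo$status == "optimal") lo$objective else NA_real_
    maxs[j] <- if (hi$status == "optimal") hi$objective else NA_real_
  }
  flux_range(data.frame(reaction_id = model$reactions$id[idx],
                        min_flux = pmin(mins, maxs),
                        max_flux = pmax(mins, maxs),
                        stringsAsFactors = FALSE))
}
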