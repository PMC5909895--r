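# Core in-memory representation of a stoichiometric network.

#' Construct a metabolic model
#'
#' A `metabolic_model` holds the stoichiometric matrix `S` (metabolites x
#' reactions), per-reaction flux bounds in mmol x gDW^-1 x h^-1 (biomass in
#' h^-1 by model convention) and a linear objective vector. It is the
#' container on which every analysis in the package operates.
#'
#' @param id model identifier.
#' @param metabolites data frame with columns `id`, `name`, `compartment`.
#' @param reactions data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `objective_coefficient`.
#' @param S numeric matrix, rows in the order of `metabolites$id`, columns
#'   in the order of `reactions$id`.
#' @param gene_rules optional named character vector of gene-reaction
#'   associations keyed by reaction id.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, S,
                            gene_rules = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$objective_coefficient)) {
    reactions$objective_coefficient <- 0
  }
  S <- as.matrix(S)
  rownames(S) <- metabolites$id
  colnames(S) <- reactions$id
  reactions$reversible <- reactions$lower_bound < 0
  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions, S = S,
         gene_rules = gene_rules, swap_backup = list()),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks bound ordering, id uniqueness and matrix conformity; stops with an
#' informative error on the first violation.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  if (anyDuplicated(rx$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rx$id[duplicated(rx$id)]), collapse = ", "))
  }
  if (anyDuplicated(model$metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(model$metabolites$id[duplicated(model$metabolites$id)]),
               collapse = ", "))
  }
  bad <- rx$lower_bound > rx$upper_bound
  if (any(bad)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(rx$id[bad], collapse = ", "))
  }
  if (nrow(model$S) != nrow(model$metabolites) ||
      ncol(model$S) != nrow(rx)) {
    stop("stoichiometric matrix dimensions do not match metabolite/",
         "reaction lists")
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", x$id, "\n")
  cat("  metabolites:", nrow(x$metabolites), "\n")
  cat("  reactions:  ", nrow(x$reactions),
      sprintf("(%d reversible)", sum(x$reactions$reversible)), "\n")
  obj <- which(x$reactions$objective_coefficient != 0)
  if (length(obj)) {
    cat("  objective:  ",
        paste(sprintf("%g %s", x$reactions$objective_coefficient[obj],
                      x$reactions$id[obj]), collapse = " + "), "\n")
  }
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  print(object)
  ex <- grepl("^EX_", object$reactions$id)
  cat("  exchanges:  ", sum(ex), "\n")
  cat("  S entries:  ", sum(object$S != 0), "nonzero\n")
  invisible(object)
}

# Normalize exchange-reaction id dialects: "EX_ac(e)" -> "EX_ac_e".
normalize_rxn_id <- function(id) {
  gsub("\\(([A-Za-z0-9]+)\\)$", "_\\1", id)
}

#' Locate a reaction, tolerating exchange-id dialects
#'
#' Accepts both `EX_ac(e)` and `EX_ac_e` spellings.
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param required error (`TRUE`) or return `NA` when absent.
#' @return Integer column index of the reaction.
#' @export
reaction_index <- function(model, id, required = TRUE) {
  ids <- model$reactions$id
  i <- match(id, ids)
  if (is.na(i)) i <- match(normalize_rxn_id(id), normalize_rxn_id(ids))
  if (is.na(i) && required) {
    stop("unknown reaction id: ", id)
  }
  i
}

metabolite_index <- function(model, id, required = TRUE) {
  i <- match(id, model$metabolites$id)
  if (is.na(i) && required) stop("unknown metabolite id: ", id)
  i
}

#' Set flux bounds on a reaction
#'
#' @param model a `metabolic_model`.
#' @param id reaction id (either exchange dialect).
#' @param lb,ub new bounds; `NULL` leaves the respective bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- reaction_index(model, id)
  if (!is.null(lb)) model$reactions$lower_bound[i] <- lb
  if (!is.null(ub)) model$reactions$upper_bound[i] <- ub
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i]) {
    stop("lower bound exceeds upper bound for reaction: ", id)
  }
  model$reactions$reversible[i] <- model$reactions$lower_bound[i] < 0
  model
}

#' Set the linear objective
#'
#' Replaces the objective vector with weight 1 (or `coefficient`) on a
#' single reaction.
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param coefficient objective weight.
#' @return The modified model.
#' @export
set_objective <- function(model, id, coefficient = 1) {
  i <- reaction_index(model, id)
  model$reactions$objective_coefficient <- 0
  model$reactions$objective_coefficient[i] <- coefficient
  model
}

#' @rdname reaction_index
#' @export
reaction_ids <- function(model) model$reactions$id

#' @rdname reaction_index
#' @export
metabolite_ids <- function(model) model$metabolites$id
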