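# Genetic/constraint edits: fractional cofactor swapping of ICDH, reaction
# knockouts, irreversibility, and the per-strain physiological constraints.

#' Physiological constraints for one strain
#'
#' Bundles the measured growth rate and acetate uptake rate with the genetic
#' edits that define a strain: the fraction of ICDH cofactor swapping
#' (NADP+/NADPH moved onto NAD+/NADH) and the presence of the PntAB
#' transhydrogenase.
#'
#' @param strain strain label.
#' @param mu growth rate (h^-1), > 0.
#' @param qac acetate uptake rate (mmol x gDW^-1 x h^-1), > 0.
#' @param swap_fraction fraction of ICDH cofactor swapping in `[0, 1]`.
#' @param pntab_present logical; `FALSE` adds a THD2pp knockout.
#' @param knockouts additional reaction ids to knock out.
#' @return An object of class `strain_constraints`.
#' @export
strain_constraints <- function(strain, mu, qac, swap_fraction = 0,
                               pntab_present = TRUE,
                               knockouts = character()) {
  stopifnot(mu > 0, qac > 0,
            swap_fraction >= 0, swap_fraction <= 1)
  structure(list(strain = strain, mu = mu, qac = qac,
                 swap_fraction = swap_fraction,
                 pntab_present = pntab_present,
                 knockouts = knockouts),
            class = "strain_constraints")
}

#' @export
print.strain_constraints <- function(x, ...) {
  cat(sprintf(
    "Strain %s: mu = %g h^-1, Qac = %g mmol/gDW/h, swap = %g%%, PntAB %s\n",
    x$strain, x$mu, x$qac, 100 * x$swap_fraction,
    if (x$pntab_present) "present" else "absent"))
  invisible(x)
}

#' The four measured strains
#'
#' Growth rates and acetate uptake rates measured during exponential growth
#' on acetate for the wild type, the PntAB deletion, the NAD+-specific ICDH
#' strain and the double mutant, shipped as a packaged JSON config.
#'
#' @return A named list of [strain_constraints()] objects.
#' @export
table1_strains <- function() {
  path <- system.file("extdata", "table1_strains.json", package = "cofswap")
  raw <- jsonlite::read_json(path)
  out <- lapply(raw, function(s) {
    strain_constraints(strain = s$strain, mu = s$mu, qac = s$qac,
                       swap_fraction = s$swap_fraction,
                       pntab_present = s$pntab_present,
                       knockouts = unlist(s$knockouts) %||% character())
  })
  stats::setNames(out, vapply(out, `[[`, "", "strain"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fractionally swap the cofactor specificity of a reaction
#'
#' For the original NADP+ coefficient `a` and NADPH coefficient `b`, sets
#' NADP+ to `(1 - fraction) * a`, NADPH to `(1 - fraction) * b`, and adds
#' `fraction * a` / `fraction * b` to the NAD+ / NADH coefficients. All
#' other coefficients are untouched. The swap is always expressed relative
#' to the pristine stoichiometry: repeated calls replace, rather than
#' compound, the previous fraction.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction carrying the NADP+/NADPH pair (default the
#'   isocitrate dehydrogenase id `ICDHyr`).
#' @param fraction swap fraction in `[0, 1]`.
#' @param cofactors named list giving the metabolite ids of `nadp`, `nadph`,
#'   `nad`, `nadh`; defaults auto-detect common suffixed variants.
#' @return The modified model.
#' @export
swap_cofactor <- function(model, reaction_id = "ICDHyr", fraction,
                          cofactors = NULL) {
  if (fraction < 0 || fraction > 1) {
    stop("swap fraction must lie in [0, 1], got ", fraction)
  }
  k <- reaction_index(model, reaction_id)
  cof <- resolve_cofactor_ids(model, cofactors)

  key <- model$reactions$id[k]
  if (!is.null(model$swap_backup[[key]])) {
    # restore pristine coefficients before re-applying
    orig <- model$swap_backup[[key]]
    model$S[names(orig), k] <- orig
  } else {
    ids <- unlist(cof)
    model$swap_backup[[key]] <- stats::setNames(model$S[ids, k], ids)
  }

  a <- model$S[cof$nadp, k]
  b <- model$S[cof$nadph, k]
  if (a == 0 && b == 0) {
    stop("reaction ", key, " carries no NADP+/NADPH coefficients to swap")
  }
  model$S[cof$nadp, k] <- (1 - fraction) * a
  model$S[cof$nadph, k] <- (1 - fraction) * b
  model$S[cof$nad, k] <- model$S[cof$nad, k] + fraction * a
  model$S[cof$nadh, k] <- model$S[cof$nadh, k] + fraction * b
  model
}

resolve_cofactor_ids <- function(model, cofactors = NULL) {
  if (!is.null(cofactors)) return(cofactors)
  pick <- function(base) {
    cands <- c(base, paste0(base, "_c"), paste0(base, "[c]"))
    hit <- cands[cands %in% model$metabolites$id]
    if (length(hit) == 0) stop("cofactor metabolite not found: ", base)
    hit[1]
  }
  list(nadp = pick("nadp"), nadph = pick("nadph"),
       nad = pick("nad"), nadh = pick("nadh"))
}

#' Knock out reactions
#'
#' Models a gene deletion by zeroing the lower and upper bounds of the
#' listed reactions.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids character vector of reaction ids.
#' @return The modified model.
#' @export
knockout <- function(model, reaction_ids) {
  for (id in reaction_ids) {
    i <- reaction_index(model, id)
    model$reactions$lower_bound[i] <- 0
    model$reactions$upper_bound[i] <- 0
    model$reactions$reversible[i] <- FALSE
  }
  model
}

#' Make a reaction irreversible
#'
#' Raises the lower bound to zero (used for the pyruvate:ferredoxin
#' oxidoreductase POR5, whose reverse direction would otherwise permit
#' spurious carbon fixation).
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction id.
#' @return The modified model.
#' @export
make_irreversible <- function(model, reaction_id) {
  i <- reaction_index(model, reaction_id)
  model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i], 0)
  model$reactions$reversible[i] <- model$reactions$lower_bound[i] < 0
  model
}

#' Apply a strain's edits and physiological constraints to a model
#'
#' Edits are applied in a fixed order for reproducibility: cofactor swap,
#' knockouts (including THD2pp when PntAB is absent), POR5 irreversibility,
#' then bounds. Acetate uptake is fixed as an equality
#' (`lb = ub = -qac`) and the biomass reaction's lower bound is set to the
#' measured growth rate. Applying the same constraints twice is idempotent.
#'
#' @param model a `metabolic_model`.
#' @param constraints a [strain_constraints()] object.
#' @param acetate_exchange,biomass_reaction,icdh_reaction,pntab_reaction,por5_reaction
#'   reaction ids; defaults follow BiGG conventions.
#' @param fix_growth fix growth as an equality (`lb = ub = mu`) instead of a
#'   lower bound only.
#' @return The modified model.
#' @export
apply_strain <- function(model, constraints,
                         acetate_exchange = "EX_ac_e",
                         biomass_reaction = NULL,
                         icdh_reaction = "ICDHyr",
                         pntab_reaction = "THD2pp",
                         por5_reaction = "POR5",
                         fix_growth = TRUE) {
  stopifnot(inherits(constraints, "strain_constraints"))
  if (is.null(biomass_reaction)) biomass_reaction <- find_biomass(model)

  if (constraints$swap_fraction > 0 ||
      !is.null(model$swap_backup[[icdh_reaction]])) {
    model <- swap_cofactor(model, icdh_reaction, constraints$swap_fraction)
  }
  kos <- constraints$knockouts
  if (!constraints$pntab_present) kos <- union(kos, pntab_reaction)
  if (length(kos)) model <- knockout(model, kos)
  if (!is.na(reaction_index(model, por5_reaction, required = FALSE))) {
    model <- make_irreversible(model, por5_reaction)
  }
  model <- set_bounds(model, acetate_exchange,
                      lb = -constraints$qac, ub = -constraints$qac)
  model <- set_bounds(model, biomass_reaction, lb = constraints$mu,
                      ub = if (fix_growth) constraints$mu else NULL)
  model
}

find_biomass <- function(model) {
  hits <- grep("BIOMASS", model$reactions$id, ignore.case = TRUE,
               value = TRUE)
  if (length(hits) == 0) stop("no biomass reaction found; pass ",
                              "biomass_reaction explicitly")
  hits[1]
}
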