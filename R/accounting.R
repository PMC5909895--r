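# Derived quantities from a flux distribution: net metabolite turnover,
# ATP allocation, cofactor source breakdowns, isocitrate branch-point
# partition, and the cofactor-swap scan.

#' Net flux of production/consumption of a metabolite
#'
#' At steady state the production and consumption of a metabolite balance,
#' and the net turnover is
#' `phi_i = 1/2 * sum_j | S(i,j) * v_j |`,
#' equal to both the summed positive terms and the negated summed negative
#' terms.
#'
#' @param model a `metabolic_model`.
#' @param dist a [flux_distribution()].
#' @param metabolite_id metabolite of interest.
#' @return A list with `phi`, and `terms`: the per-reaction signed
#'   contributions `S(i,j) * v_j` (nonzero entries only).
#' @export
net_turnover <- function(model, dist, metabolite_id) {
  i <- metabolite_index(model, metabolite_id)
  v <- dist$fluxes[model$reactions$id]
  terms <- model$S[i, ] * v
  nz <- terms[abs(terms) > 1e-12]
  list(phi = sum(abs(terms)) / 2, terms = nz)
}

#' ATP allocation: maintenance versus growth-associated production
#'
#' Splits the total ATP turnover into the non-growth-associated maintenance
#' flux (the ATPM reaction) and the remainder, the growth-associated ATP
#' (which includes growth-associated maintenance and pathway costs such as
#' gluconeogenesis).
#'
#' @param model a `metabolic_model`.
#' @param dist a [flux_distribution()].
#' @param atp_metabolite id of the ATP species.
#' @param atpm_reaction id of the maintenance reaction.
#' @return A list with `atpm`, `atp_growth`, `total` (all in
#'   mmol x gDW^-1 x h^-1); `total = atpm + atp_growth`.
#' @export
atp_allocation <- function(model, dist, atp_metabolite = "atp",
                           atpm_reaction = "ATPM") {
  total <- net_turnover(model, dist, atp_metabolite)$phi
  atpm <- get_flux(dist, atpm_reaction)
  list(atpm = atpm, atp_growth = total - atpm, total = total)
}

#' Per-reaction sources of NADPH or NADH production
#'
#' Lists every reaction that produces the reduced cofactor
#' (`S(i,j) * v_j > 0` for the reduced species) with its production flux
#' and its percentage of the acetate uptake rate. Consumption is excluded;
#' a transhydrogenase therefore appears as a producer of one cofactor and
#' not the other.
#'
#' @param model a `metabolic_model`.
#' @param dist a [flux_distribution()].
#' @param cofactor `"NADPH"` or `"NADH"`.
#' @param qac acetate uptake rate for percentage normalization.
#' @param metabolite_id override the reduced-species metabolite id.
#' @return A list of class `cofactor_breakdown` with `cofactor`, `sources`
#'   (data frame `reaction_id`, `flux`, `pct_of_qac`) and `total`.
#' @export
cofactor_sources <- function(model, dist, cofactor = c("NADPH", "NADH"),
                             qac, metabolite_id = NULL) {
  cofactor <- match.arg(cofactor)
  if (is.null(metabolite_id)) {
    base <- if (cofactor == "NADPH") "nadph" else "nadh"
    cands <- c(base, paste0(base, "_c"))
    metabolite_id <- cands[cands %in% model$metabolites$id][1]
    if (is.na(metabolite_id)) stop("cofactor metabolite not found: ", base)
  }
  i <- metabolite_index(model, metabolite_id)
  v <- dist$fluxes[model$reactions$id]
  terms <- model$S[i, ] * v
  prod <- terms[terms > 1e-9]
  sources <- data.frame(reaction_id = names(prod), flux = unname(prod),
                        pct_of_qac = 100 * unname(prod) / qac,
                        stringsAsFactors = FALSE)
  sources <- sources[order(-sources$flux), , drop = FALSE]
  structure(list(cofactor = cofactor, sources = sources,
                 total = sum(prod), qac = qac),
            class = "cofactor_breakdown")
}

#' @export
print.cofactor_breakdown <- function(x, ...) {
  cat(sprintf("%s production: %.4f mmol/gDW/h (%.1f%% of Qac)\n",
              x$cofactor, x$total, 100 * x$total / x$qac))
  for (r in seq_len(nrow(x$sources))) {
    cat(sprintf("  %-12s %8.4f  (%5.1f%%)\n", x$sources$reaction_id[r],
                x$sources$flux[r], x$sources$pct_of_qac[r]))
  }
  invisible(x)
}

#' Partition of flux at the isocitrate branch point
#'
#' @param dist a [flux_distribution()].
#' @param icl,icdh branch reaction ids.
#' @return A list with `p_icl`, `p_icdh` (fractions of the total
#'   isocitrate-consuming flux) and `ratio` (`v_ICDH / v_ICL`, `Inf` when
#'   ICL carries no flux).
#' @export
isocitrate_partition <- function(dist, icl = "ICL", icdh = "ICDHyr") {
  v_icl <- get_flux(dist, icl)
  v_icdh <- get_flux(dist, icdh)
  total <- v_icl + v_icdh
  if (total <= 1e-12) {
    stop("isocitrate partition undefined: v_ICL + v_ICDH <= 0")
  }
  p_icl <- v_icl / total
  list(p_icl = p_icl, p_icdh = 1 - p_icl,
       ratio = if (abs(v_icl) > 1e-12) v_icdh / v_icl else Inf)
}

#' Scan the effect of fractional cofactor swapping
#'
#' For each swap fraction the pristine model is re-edited, the strain's
#' physiological constraints applied, the maintenance flux maximized, and
#' the tracked fluxes recorded.
#'
#' @param model pristine `metabolic_model`.
#' @param constraints [strain_constraints()] supplying mu and Qac (its own
#'   `swap_fraction` is ignored in favor of the grid).
#' @param fractions numeric grid in `[0, 1]`.
#' @param track reaction ids to record (missing ones are skipped).
#' @param atpm_release maintenance release bounds used before maximizing.
#' @param ... passed to [apply_strain()].
#' @return Data frame with one row per fraction: `fraction`, `atpm`,
#'   one column per tracked reaction, `status`.
#' @export
swap_scan <- function(model, constraints, fractions = seq(0, 1, by = 0.1),
                      track = c("ICDHyr", "ICL", "THD2pp", "NADTRHD"),
                      atpm_release = c(0, 50), ...) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  track <- track[!is.na(vapply(track, function(id)
    reaction_index(model, id, required = FALSE), 0L))]
  out <- data.frame(fraction = fractions, atpm = NA_real_)
  for (id in track) out[[id]] <- NA_real_
  out$status <- NA_character_
  for (i in seq_along(fractions)) {
    cons <- constraints
    cons$swap_fraction <- fractions[i]
    m <- apply_strain(model, cons, ...)
    m <- set_bounds(m, "ATPM", lb = atpm_release[1], ub = atpm_release[2])
    sol <- fba(m, "ATPM", sense = "max")
    out$status[i] <- sol$status
    if (sol$status == "optimal") {
      out$atpm[i] <- sol$objective
      for (id in track) out[[id]][i] <- get_flux(sol, id)
    }
  }
  out
}
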