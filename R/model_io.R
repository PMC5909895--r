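# Model input/output: SBML L3-FBC (and L2 with kinetic-law bound
# parameters), a JSON dialect used as the repo-internal canonical fixture
# format, and delimited flux tables.

#' Read a metabolic model from SBML
#'
#' Supports SBML Level 3 with the FBC flux-bounds package and Level 2 files
#' carrying `LOWER_BOUND`/`UPPER_BOUND`/`OBJECTIVE_COEFFICIENT` kinetic-law
#' parameters.
#'
#' @param path path to an SBML file.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model_node, "xml_missing")) stop("no <model> element in ", path)
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE
  )[!boundary, , drop = FALSE]

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(
    vapply(xml2::xml_attr(params, "value"), parse_sbml_double, numeric(1)),
    xml2::xml_attr(params, "id")
  )

  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  n <- length(rnodes)
  if (n == 0) stop("no reactions in ", path)
  rid <- xml2::xml_attr(rnodes, "id")
  rname <- ifelse(is.na(xml2::xml_attr(rnodes, "name")), rid,
                  xml2::xml_attr(rnodes, "name"))
  rev_attr <- xml2::xml_attr(rnodes, "reversible")
  lb <- ub <- rep(NA_real_, n)
  obj <- rep(0, n)
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, rid))

  for (k in seq_len(n)) {
    node <- rnodes[[k]]
    for (ref in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      s <- xml2::xml_attr(ref, "species")
      if (s %in% mets$id) {
        S[s, k] <- S[s, k] - parse_sbml_double(xml2::xml_attr(ref, "stoichiometry"))
      }
    }
    for (ref in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      s <- xml2::xml_attr(ref, "species")
      if (s %in% mets$id) {
        S[s, k] <- S[s, k] + parse_sbml_double(xml2::xml_attr(ref, "stoichiometry"))
      }
    }
    # L3/FBC: bounds are parameter references on the reaction element.
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(pval)) lb[k] <- pval[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(pval)) ub[k] <- pval[[ub_ref]]
    # L2: kinetic-law local parameters.
    if (is.na(lb[k]) || is.na(ub[k])) {
      kl <- xml2::xml_find_all(node, ".//parameter")
      kid <- xml2::xml_attr(kl, "id")
      kv <- vapply(xml2::xml_attr(kl, "value"), parse_sbml_double, numeric(1))
      if (is.na(lb[k]) && "LOWER_BOUND" %in% kid) {
        lb[k] <- kv[match("LOWER_BOUND", kid)]
      }
      if (is.na(ub[k]) && "UPPER_BOUND" %in% kid) {
        ub[k] <- kv[match("UPPER_BOUND", kid)]
      }
      if ("OBJECTIVE_COEFFICIENT" %in% kid) {
        obj[k] <- kv[match("OBJECTIVE_COEFFICIENT", kid)]
      }
    }
    if (is.na(lb[k]) || is.na(ub[k])) {
      # Last resort: SBML reversibility attribute with default magnitudes.
      if (!is.na(rev_attr[k])) {
        if (is.na(lb[k])) lb[k] <- if (rev_attr[k] %in% c("true", "1")) -1000 else 0
        if (is.na(ub[k])) ub[k] <- 1000
      } else {
        stop("missing flux bounds for reaction: ", rid[k])
      }
    }
  }

  # FBC objective (prefixed elements survive namespace stripping, so match
  # on local names).
  fobj <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  if (length(fobj)) {
    obj <- rep(0, n)
    fr <- xml2::xml_attr(fobj, "reaction")
    fc <- vapply(xml2::xml_attr(fobj, "coefficient"), parse_sbml_double,
                 numeric(1))
    obj[match(fr, rid)] <- fc
  }

  metabolic_model(
    id = model_id,
    metabolites = mets,
    reactions = data.frame(id = rid, name = rname, lower_bound = lb,
                           upper_bound = ub, objective_coefficient = obj,
                           stringsAsFactors = FALSE),
    S = S
  )
}

parse_sbml_double <- function(x) {
  if (is.na(x)) return(NA_real_)
  if (x %in% c("INF", "inf", "Infinity")) return(Inf)
  if (x %in% c("-INF", "-inf", "-Infinity")) return(-Inf)
  as.numeric(x)
}

#' Write a metabolic model to SBML or JSON
#'
#' Lossless for the stoichiometric matrix, bounds and objective; SBML output
#' is Level 3 Version 1 with the FBC v2 package.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"sbml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("sbml", "json")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "json") write_model_json(model, path) else
    write_model_sbml(model, path)
  invisible(path)
}

write_model_json <- function(model, path) {
  rx <- model$reactions
  reactions <- lapply(seq_len(nrow(rx)), function(k) {
    coefs <- model$S[, k]
    coefs <- coefs[coefs != 0]
    list(
      id = rx$id[k], name = rx$name[k],
      lower_bound = rx$lower_bound[k], upper_bound = rx$upper_bound[k],
      objective_coefficient = rx$objective_coefficient[k],
      metabolites = as.list(coefs)
    )
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    as.list(model$metabolites[i, c("id", "name", "compartment")])
  })
  obj <- list(id = model$id, metabolites = mets, reactions = reactions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Read a metabolic model from the package JSON dialect
#'
#' @param path path to a JSON model file written by [write_model()].
#' @return A [metabolic_model()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(obj$metabolites, function(m) {
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "c" else
                 m$compartment,
               stringsAsFactors = FALSE)
  }))
  n <- length(obj$reactions)
  rx <- do.call(rbind, lapply(obj$reactions, function(r) {
    data.frame(id = r$id,
               name = if (is.null(r$name)) r$id else r$name,
               lower_bound = as.numeric(r$lower_bound),
               upper_bound = as.numeric(r$upper_bound),
               objective_coefficient =
                 if (is.null(r$objective_coefficient)) 0 else
                   as.numeric(r$objective_coefficient),
               stringsAsFactors = FALSE)
  }))
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, rx$id))
  for (k in seq_len(n)) {
    for (met in names(obj$reactions[[k]]$metabolites)) {
      S[met, k] <- as.numeric(obj$reactions[[k]]$metabolites[[met]])
    }
  }
  metabolic_model(id = if (is.null(obj$id)) "model" else obj$id,
                  metabolites = mets, reactions = rx, S = S)
}

write_model_sbml <- function(model, path) {
  num <- function(x) {
    if (is.infinite(x)) (if (x > 0) "INF" else "-INF") else
      format(x, digits = 17, scientific = FALSE)
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  rx <- model$reactions
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">", esc(model$id)),
    "    <listOfCompartments>"
  )
  for (cp in unique(model$metabolites$compartment)) {
    lines <- c(lines, sprintf(
      "      <compartment id=\"%s\" constant=\"true\"/>", esc(cp)))
  }
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    lines <- c(lines, sprintf(
      paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
             "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
             "constant=\"false\"/>"),
      esc(m$id), esc(m$name), esc(m$compartment)))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (k in seq_len(nrow(rx))) {
    lines <- c(lines,
      sprintf("      <parameter id=\"lb_%s\" value=\"%s\" constant=\"true\"/>",
              rx$id[k], num(rx$lower_bound[k])),
      sprintf("      <parameter id=\"ub_%s\" value=\"%s\" constant=\"true\"/>",
              rx$id[k], num(rx$upper_bound[k])))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (k in seq_len(nrow(rx))) {
    coefs <- model$S[, k]
    reac <- which(coefs < 0)
    prod <- which(coefs > 0)
    lines <- c(lines, sprintf(
      paste0("      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\" ",
             "fast=\"false\" fbc:lowerFluxBound=\"lb_%s\" ",
             "fbc:upperFluxBound=\"ub_%s\">"),
      rx$id[k], esc(rx$name[k]),
      if (rx$lower_bound[k] < 0) "true" else "false", rx$id[k], rx$id[k]))
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>")
      for (i in reac) {
        lines <- c(lines, sprintf(
          paste0("          <speciesReference species=\"%s\" ",
                 "stoichiometry=\"%s\" constant=\"true\"/>"),
          model$metabolites$id[i], num(-coefs[i])))
      }
      lines <- c(lines, "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>")
      for (i in prod) {
        lines <- c(lines, sprintf(
          paste0("          <speciesReference species=\"%s\" ",
                 "stoichiometry=\"%s\" constant=\"true\"/>"),
          model$metabolites$id[i], num(coefs[i])))
      }
      lines <- c(lines, "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  obj <- which(rx$objective_coefficient != 0)
  lines <- c(lines,
    "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
    "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
    "        <fbc:listOfFluxObjectives>")
  for (k in obj) {
    lines <- c(lines, sprintf(
      paste0("          <fbc:fluxObjective fbc:reaction=\"%s\" ",
             "fbc:coefficient=\"%s\"/>"),
      rx$id[k], num(rx$objective_coefficient[k])))
  }
  lines <- c(lines,
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>",
    "</sbml>")
  writeLines(lines, path)
}

#' Write a flux table
#'
#' One row per reaction. For a [flux_distribution] the columns are
#' `reaction_id`, `flux` and, when `qac` is supplied, `pct_of_qac`
#' (sign-preserving `100 * flux / qac`). For a [flux_range] the flux column
#' is replaced by `min_flux`/`max_flux`.
#'
#' @param x a `flux_distribution` or `flux_range`.
#' @param path output path.
#' @param qac acetate uptake rate used for percentage normalization
#'   (optional).
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(x, path, qac = NULL, sep = "\t") {
  if (inherits(x, "flux_distribution")) {
    df <- data.frame(reaction_id = names(x$fluxes), flux = unname(x$fluxes),
                     stringsAsFactors = FALSE)
    if (!is.null(qac)) df$pct_of_qac <- 100 * df$flux / qac
  } else if (inherits(x, "flux_range")) {
    df <- as.data.frame(x)
    if (!is.null(qac)) {
      df$min_pct_of_qac <- 100 * df$min_flux / qac
      df$max_pct_of_qac <- 100 * df$max_flux / qac
    }
  } else {
    stop("x must be a flux_distribution or flux_range")
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
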