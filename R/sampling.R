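# Sub-optimal flux-space characterization by artificially centered
# hit-and-run (ACHR) sampling.

#' Sample a model's current flux polytope by ACHR
#'
#' Draws steady-state flux vectors from `{v : S v = 0, lb <= v <= ub}`
#' with an artificially centered hit-and-run chain. Warmup points are the
#' flux-variability extreme solutions (min and max of every reaction), so
#' chain directions lie in the null space of `S` and iterates stay on
#' `S v = 0` exactly; bound violations are prevented by the step-size
#' limits. The chain moves one stored point per step toward a direction
#' drawn from a random stored point and the running center.
#'
#' @param model a `metabolic_model`; its current bounds define the
#'   polytope.
#' @param n_samples number of samples to retain.
#' @param seed integer seed; the run is reproducible given it.
#' @param thin chain steps between retained samples.
#' @return An object of class `flux_samples`.
#' @export
achr_sample <- function(model, n_samples, seed = 1L, thin = 100L) {
  nr <- nrow(model$reactions)
  lp <- model_lp(model)
  feas <- solve_lp(lp$A, lp$b, numeric(nr), lp$lb, lp$ub)
  if (feas$status != "optimal") {
    stop("sampling constraints are infeasible (status ", feas$status, ")")
  }

  # Warmup: FVA extreme points.
  warm <- matrix(NA_real_, 2L * nr, nr)
  for (j in seq_len(nr)) {
    c_obj <- numeric(nr)
    c_obj[j] <- 1
    lo <- solve_lp(lp$A, lp$b, c_obj, lp$lb, lp$ub, sense = "min")
    hi <- solve_lp(lp$A, lp$b, c_obj, lp$lb, lp$ub, sense = "max")
    warm[2L * j - 1L, ] <- if (lo$status == "optimal") lo$x else feas$x
    warm[2L * j, ] <- if (hi$status == "optimal") hi$x else feas$x
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  pts <- warm
  npts <- nrow(pts)
  center <- colMeans(pts)
  samples <- matrix(NA_real_, n_samples, nr,
                    dimnames = list(NULL, model$reactions$id))
  spread <- max(abs(sweep(pts, 2, center)))
  if (spread < 1e-9) {
    # Degenerate polytope (single point): every sample is that point.
    samples[] <- rep(center, each = n_samples)
    return(structure(list(samples = samples, seed = seed, thin = thin,
                          n_warmup = npts, strain = model$id,
                          growth_fraction = NA_real_),
                     class = "flux_samples"))
  }
  lb <- lp$lb
  ub <- lp$ub
  collected <- 0L
  iter <- 0L
  dir_tol <- 1e-10
  while (collected < n_samples) {
    iter <- iter + 1L
    k <- sample.int(npts, 1L)
    u <- pts[k, ] - center
    nu <- sqrt(sum(u^2))
    if (nu < dir_tol) next
    u <- u / nu
    x <- pts[k, ]
    tmin <- -Inf
    tmax <- Inf
    for (j in seq_len(nr)) {
      if (u[j] > dir_tol) {
        tmax <- min(tmax, (ub[j] - x[j]) / u[j])
        tmin <- max(tmin, (lb[j] - x[j]) / u[j])
      } else if (u[j] < -dir_tol) {
        tmax <- min(tmax, (lb[j] - x[j]) / u[j])
        tmin <- max(tmin, (ub[j] - x[j]) / u[j])
      }
    }
    if (!is.finite(tmin)) tmin <- -1e6
    if (!is.finite(tmax)) tmax <- 1e6
    if (tmax < tmin) next                        # numerically stuck point
    t_step <- stats::runif(1, tmin, tmax)
    x_new <- x + t_step * u
    x_new <- pmin(pmax(x_new, lb), ub)
    center <- center + (x_new - pts[k, ]) / npts
    pts[k, ] <- x_new
    if (iter %% thin == 0L) {
      collected <- collected + 1L
      samples[collected, ] <- x_new
    }
  }

  structure(list(samples = samples, seed = seed, thin = thin,
                 n_warmup = npts, strain = model$id,
                 growth_fraction = NA_real_),
            class = "flux_samples")
}

#' Sample the sub-optimal flux polytope of a strain
#'
#' Applies the strain's edits, constrains growth to at least
#' `growth_fraction` of the measured rate (and at most the measured rate),
#' fixes acetate uptake, releases the maintenance reaction (growth, not
#' energy, defines sub-optimality), and samples with [achr_sample()].
#'
#' @param model a pristine `metabolic_model`.
#' @param constraints a [strain_constraints()] object.
#' @param growth_fraction fraction of the measured growth rate used as the
#'   biomass lower bound (default 0.9).
#' @param n_samples number of samples; default twice the reaction count.
#' @param seed integer seed.
#' @param thin chain steps between retained samples.
#' @param atpm_release bounds to which the maintenance reaction is
#'   released during sampling.
#' @param ... passed to [apply_strain()].
#' @return An object of class `flux_samples`: list with `samples`
#'   (n_samples x reactions matrix), `seed`, `thin`, `n_warmup`, `strain`,
#'   `growth_fraction`.
#' @export
sample_fluxes <- function(model, constraints, growth_fraction = 0.9,
                          n_samples = NULL, seed = 1L, thin = 100L,
                          atpm_release = c(0, 50), ...) {
  stopifnot(inherits(constraints, "strain_constraints"))
  model <- apply_strain(model, constraints, fix_growth = FALSE, ...)
  bio <- find_biomass(model)
  model <- set_bounds(model, bio, lb = growth_fraction * constraints$mu,
                      ub = constraints$mu)
  if (!is.na(reaction_index(model, "ATPM", required = FALSE))) {
    model <- set_bounds(model, "ATPM", lb = atpm_release[1],
                        ub = atpm_release[2])
  }
  if (is.null(n_samples)) n_samples <- 2L * nrow(model$reactions)
  out <- achr_sample(model, n_samples, seed = seed, thin = thin)
  out$strain <- constraints$strain
  out$growth_fraction <- growth_fraction
  out
}

#' @export
print.flux_samples <- function(x, ...) {
  cat("Flux samples:", nrow(x$samples), "points x", ncol(x$samples),
      "reactions\n")
  cat("  strain:", x$strain, " seed:", x$seed, " thin:", x$thin,
      " growth fraction:", x$growth_fraction, "\n")
  invisible(x)
}

#' Filter samples by an upper bound on one reaction
#'
#' Keeps the rows whose flux through `reaction_id` does not exceed
#' `upper_bound` (used to study sub-optimal scenarios, e.g. restricting
#' PntAB to 75% of its optimal flux). Warns when the filter empties the
#' set.
#'
#' @param samples a `flux_samples` object.
#' @param reaction_id reaction to filter on.
#' @param upper_bound maximum retained flux.
#' @return A filtered `flux_samples` object.
#' @export
filter_samples <- function(samples, reaction_id, upper_bound) {
  stopifnot(inherits(samples, "flux_samples"))
  ids <- colnames(samples$samples)
  j <- match(reaction_id, ids)
  if (is.na(j)) j <- match(normalize_rxn_id(reaction_id),
                           normalize_rxn_id(ids))
  if (is.na(j)) stop("unknown reaction id: ", reaction_id)
  keep <- samples$samples[, j] <= upper_bound
  if (!any(keep)) {
    warning("filter removed every sample (upper bound below the sampled ",
            "minimum)")
  }
  samples$samples <- samples$samples[keep, , drop = FALSE]
  samples
}

#' Histogram of sampled fluxes for one reaction
#'
#' @param samples a `flux_samples` object.
#' @param reaction_id reaction of interest.
#' @param bins number of bins.
#' @return A list with `breaks`, `counts`, `mids` and `mode` (midpoint of
#'   the highest-count bin; ties resolve to the lowest bin).
#' @export
flux_histogram <- function(samples, reaction_id, bins = 30L) {
  stopifnot(inherits(samples, "flux_samples"),
            nrow(samples$samples) > 0)
  ids <- colnames(samples$samples)
  j <- match(reaction_id, ids)
  if (is.na(j)) j <- match(normalize_rxn_id(reaction_id),
                           normalize_rxn_id(ids))
  if (is.na(j)) stop("unknown reaction id: ", reaction_id)
  v <- samples$samples[, j]
  rng <- range(v)
  if (diff(rng) < 1e-12) {
    return(list(breaks = c(rng[1] - 0.5, rng[1] + 0.5),
                counts = length(v), mids = rng[1], mode = rng[1]))
  }
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = bins + 1),
                      plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       mode = h$mids[which.max(h$counts)])
}
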