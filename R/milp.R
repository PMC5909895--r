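# Mixed-integer LP by depth-first branch and bound over the package's
# bounded-variable simplex. Only binary variables are needed here (reaction
# activation indicators for alternate-optima enumeration).

# Minimizes c_obj. int_idx are indices restricted to {lb_i, ..., ub_i}
# integers (binaries in practice). Deterministic: fixed branching order
# (most fractional, ties by lowest index; zero branch explored first).
solve_milp <- function(A, b, c_obj, lb, ub, int_idx,
                       max_nodes = 50000L, time_limit = Inf,
                       int_tol = 1e-6) {
  t0 <- Sys.time()
  best_x <- NULL
  best_obj <- Inf
  # stack of nodes: list(lb, ub)
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  limit_hit <- FALSE
  while (length(stack) > 0) {
    nodes <- nodes + 1L
    if (nodes > max_nodes ||
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit) {
      limit_hit <- TRUE
      break
    }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- solve_lp(A, b, c_obj, node$lb, node$ub, sense = "min")
    if (rel$status != "optimal") next
    if (rel$objective >= best_obj - 1e-9) next
    frac <- abs(rel$x[int_idx] - round(rel$x[int_idx]))
    if (all(frac <= int_tol)) {
      best_obj <- rel$objective
      best_x <- rel$x
      best_x[int_idx] <- round(best_x[int_idx])
      next
    }
    j <- int_idx[which.max(frac)]
    down <- node
    down$ub[j] <- floor(rel$x[j])
    up <- node
    up$lb[j] <- ceiling(rel$x[j])
    # depth-first, zero/floor branch explored first
    stack[[length(stack) + 1L]] <- up
    stack[[length(stack) + 1L]] <- down
  }
  if (!is.null(best_x)) {
    list(status = if (limit_hit) "optimal_partial" else "optimal",
         x = best_x, objective = best_obj, nodes = nodes)
  } else {
    list(status = if (limit_hit) "limit" else "infeasible",
         x = NULL, objective = NA_real_, nodes = nodes)
  }
}

#' Enumerate alternate optimal flux distributions by MILP
#'
#' Recursive integer-cut enumeration of support-distinct optima of a flux
#' balance objective. Each reaction gets a binary activation variable `y_i`
#' linked to its flux by its own bounds (`lb_i * y_i <= v_i <= ub_i * y_i`);
#' the objective value is constrained to the LP optimum, the MILP minimizes
#' the number of active reactions, and after each solution an integer cut
#' forces at least one previously active reaction to zero. Solutions
#' therefore appear in discovery order, sparsest support first, and no
#' support repeats or contains an earlier one.
#'
#' @param model a `metabolic_model`.
#' @param objective_reaction reaction whose optimum defines the optimal
#'   face.
#' @param n maximum number of optima to return.
#' @param sense `"max"` or `"min"` for the defining objective.
#' @param config an [iter_opt_config()] (tolerances, time limit).
#' @return A list with `solutions` (list of [flux_distribution()]),
#'   `exhausted` (`TRUE` when fewer than `n` support-distinct optima
#'   exist) and `warning` (`NA` or a time/node-limit note).
#' @export
enumerate_alternate_optima <- function(model, objective_reaction, n,
                                       sense = "max",
                                       config = iter_opt_config()) {
  base <- fba(model, objective_reaction, sense = sense)
  if (base$status != "optimal") {
    stop("cannot enumerate optima: base FBA status ", base$status)
  }
  z_star <- base$objective
  nr <- nrow(model$reactions)
  lbv <- model$reactions$lower_bound
  ubv <- model$reactions$upper_bound
  bigM <- 1000

  # Column layout: v (nr) | y (nr) | slacks (appended as rows are built).
  fixed_zero <- lbv == 0 & ubv == 0
  always_on <- lbv == ubv & lbv != 0
  link_idx <- which(!fixed_zero)

  rows <- list()
  rhs <- numeric(0)
  slack_bounds <- list()
  n_slack <- 0L
  add_row <- function(vcoef, ycoef, srange, rv) {
    n_slack <<- n_slack + 1L
    rows[[length(rows) + 1L]] <<- list(v = vcoef, y = ycoef, s = n_slack)
    rhs <<- c(rhs, rv)
    slack_bounds[[n_slack]] <<- srange
  }

  for (i in link_idx) {
    Mu <- if (is.finite(ubv[i])) max(ubv[i], 0) else bigM
    Ml <- if (is.finite(lbv[i])) min(lbv[i], 0) else -bigM
    # v_i - Mu * y_i <= 0
    vc <- numeric(nr); vc[i] <- 1
    yc <- numeric(nr); yc[i] <- -Mu
    add_row(vc, yc, c(0, Inf), 0)       # + slack = 0 with slack >= 0 means <= 0
    # v_i - Ml * y_i >= 0  ->  -(v_i - Ml y_i) <= 0
    vc2 <- numeric(nr); vc2[i] <- -1
    yc2 <- numeric(nr); yc2[i] <- Ml
    add_row(vc2, yc2, c(0, Inf), 0)
  }
  # objective optimality: c'v within tolerance of z*
  tol_abs <- config$obj_tol * (1 + abs(z_star))
  cvec <- numeric(nr)
  cvec[reaction_index(model, objective_reaction)] <- 1
  if (sense == "max") {
    add_row(cvec, numeric(nr), c(0, tol_abs), z_star)   # c'v + s = z*
  } else {
    add_row(-cvec, numeric(nr), c(0, tol_abs), -z_star)
  }

  build_lp <- function(cuts) {
    all_rows <- rows
    all_rhs <- rhs
    sb <- slack_bounds
    ns <- n_slack
    for (cut in cuts) {
      ns <- ns + 1L
      yc <- numeric(nr); yc[cut] <- 1
      all_rows[[length(all_rows) + 1L]] <- list(v = numeric(nr), y = yc,
                                                s = ns)
      all_rhs <- c(all_rhs, length(cut) - 1)
      sb[[ns]] <- c(0, Inf)
    }
    m_extra <- length(all_rows)
    ncol_tot <- 2L * nr + ns
    A <- matrix(0, nrow(model$S) + m_extra, ncol_tot)
    A[seq_len(nrow(model$S)), seq_len(nr)] <- model$S
    for (r in seq_len(m_extra)) {
      A[nrow(model$S) + r, seq_len(nr)] <- all_rows[[r]]$v
      A[nrow(model$S) + r, nr + seq_len(nr)] <- all_rows[[r]]$y
      A[nrow(model$S) + r, 2L * nr + all_rows[[r]]$s] <- 1
    }
    b <- c(rep(0, nrow(model$S)), all_rhs)
    ylb <- ifelse(fixed_zero, 0, ifelse(always_on, 1, 0))
    yub <- ifelse(fixed_zero, 0, 1)
    slb <- vapply(sb[seq_len(ns)], `[`, 0, 1)
    sub <- vapply(sb[seq_len(ns)], `[`, 0, 2)
    list(A = A, b = b,
         lb = c(lbv, ylb, slb), ub = c(ubv, yub, sub),
         c_obj = c(numeric(nr), rep(1, nr), numeric(ns)),
         int_idx = nr + seq_len(nr))
  }

  solutions <- list()
  cuts <- list()
  exhausted <- FALSE
  warn <- NA_character_
  while (length(solutions) < n) {
    lp <- build_lp(cuts)
    res <- solve_milp(lp$A, lp$b, lp$c_obj, lp$lb, lp$ub, lp$int_idx,
                      max_nodes = config$max_nodes,
                      time_limit = config$time_limit)
    if (res$status == "limit") {
      warn <- "MILP node/time limit reached; enumeration is partial"
      break
    }
    if (res$status == "infeasible") {
      exhausted <- TRUE
      break
    }
    if (res$status == "optimal_partial") {
      warn <- "MILP node/time limit reached during a cut; solution kept"
    }
    v <- res$x[seq_len(nr)]
    support <- which(abs(v) > config$support_tol)
    solutions[[length(solutions) + 1L]] <- flux_distribution(
      stats::setNames(v, model$reactions$id),
      unname(sum(cvec * v)), "optimal", objective_reaction)
    if (length(support) == 0) {
      exhausted <- TRUE
      break
    }
    cuts[[length(cuts) + 1L]] <- support
  }
  if (length(solutions) == n) {
    # n requested and found; exhaustion status unknown without one more
    # solve, leave FALSE.
    exhausted <- FALSE
  }
  list(solutions = solutions, exhausted = exhausted, warning = warn)
}
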