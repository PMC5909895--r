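# Independent oracles used across the suite.

# Brute-force LP oracle: enumerates every candidate vertex of
# {A x = b, lb <= x <= ub} by choosing basic column sets and assigning each
# nonbasic variable to a finite bound. Exponential; only for tiny problems.
lp_vertex_oracle <- function(A, b, c_obj, lb, ub, sense = "min",
                             tol = 1e-7) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  best <- NULL
  best_obj <- if (sense == "min") Inf else -Inf
  for (basis in utils::combn(n, m, simplify = FALSE)) {
    Bm <- A[, basis, drop = FALSE]
    if (abs(det(Bm)) < 1e-10) next
    nb <- setdiff(seq_len(n), basis)
    opts <- lapply(nb, function(j) {
      v <- c(if (is.finite(lb[j])) lb[j], if (is.finite(ub[j])) ub[j])
      if (length(v) == 0) 0 else unique(v)
    })
    grid <- if (length(opts)) expand.grid(opts) else data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      xn <- as.numeric(grid[g, ])
      xB <- solve(Bm, b - if (length(nb))
        A[, nb, drop = FALSE] %*% xn else 0)
      x <- numeric(n)
      x[basis] <- xB
      if (length(nb)) x[nb] <- xn
      if (all(x >= lb - tol) && all(x <= ub + tol)) {
        obj <- sum(c_obj * x)
        if ((sense == "min" && obj < best_obj - 1e-12) ||
            (sense == "max" && obj > best_obj + 1e-12)) {
          best_obj <- obj
          best <- x
        }
      }
    }
  }
  list(objective = best_obj, x = best)
}

# Random small LP with a guaranteed feasible point and full-row-rank
# constraints (so the vertex oracle always finds a basic solution).
random_lp <- function() {
  repeat {
    m <- sample(1:3, 1)
    n <- m + sample(1:3, 1)
    A <- matrix(sample(-3:3, m * n, replace = TRUE), m, n)
    if (qr(A)$rank == m) break
  }
  x0 <- round(runif(n, -5, 5), 1)
  list(A = A, b = as.vector(A %*% x0),
       lb = x0 - round(runif(n, 0, 6), 1),
       ub = x0 + round(runif(n, 0, 6), 1),
       c_obj = sample(-5:5, n, replace = TRUE),
       sense = sample(c("min", "max"), 1))
}

# Random steady-state flux vector: a bounded combination of null-space
# basis vectors of the stoichiometric matrix.
random_steady_state <- function(model, scale = 5) {
  ns <- null_space(model$S)
  if (ncol(ns) == 0) return(numeric(ncol(model$S)))
  as.vector(ns %*% runif(ncol(ns), -scale, scale))
}

null_space <- function(A) {
  s <- svd(A, nu = 0, nv = ncol(A))
  keep <- s$d < max(dim(A)) * max(s$d, 0) * .Machine$double.eps * 100
  nkeep <- sum(keep) + ncol(A) - length(s$d)
  if (nkeep == 0) return(matrix(0, ncol(A), 0))
  s$v[, (ncol(A) - nkeep + 1):ncol(A), drop = FALSE]
}

# Strain model preparation used by several suites: edits applied, growth
# and uptake fixed, maintenance released.
prep_strain <- function(model, constraints, release = c(0, 50)) {
  m <- apply_strain(model, constraints)
  set_bounds(m, "ATPM", lb = release[1], ub = release[2])
}
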