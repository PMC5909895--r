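# Dense two-phase simplex for bounded-variable linear programs.
#
# Solves   min/max  c'x   s.t.  A x = b,  lb <= x <= ub
# with lb/ub possibly infinite. Written for the problem sizes of this
# package (stoichiometric fixtures and MILP node relaxations, tens to a few
# hundred columns); every basis system is solved densely.

#' Solve a bounded-variable linear program
#'
#' Two-phase primal simplex over general bounds. Used internally by
#' [fba()], [fva()] and the MILP branch-and-bound; exported because the
#' test suite cross-checks it against an independent vertex-enumeration
#' oracle.
#'
#' @param A constraint matrix (equality rows).
#' @param b right-hand side vector, one entry per row of `A`.
#' @param c_obj objective coefficient vector, one entry per column of `A`.
#' @param lb,ub lower/upper variable bounds (may be `-Inf`/`Inf`).
#' @param sense `"min"` or `"max"`.
#' @param tol pivot tolerance.
#' @param max_iter pivot limit before giving up.
#'
#' @return A list with elements `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"` or `"iteration_limit"`), `x` (primal solution, `NULL`
#'   unless optimal) and `objective` (in the requested sense).
#' @export
solve_lp <- function(A, b, c_obj, lb, ub, sense = c("min", "max"),
                     tol = 1e-9, max_iter = 20000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(c_obj) == n,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  cc <- if (sense == "max") -c_obj else c_obj
  res <- simplex_bounded(A, b, cc, lb, ub, tol = tol, max_iter = max_iter)
  if (res$status == "optimal") {
    list(status = "optimal", x = res$x, objective = sum(c_obj * res$x))
  } else {
    list(status = res$status, x = NULL, objective = NA_real_)
  }
}

# Internal engine: minimizes cc'x subject to A x = b, lb <= x <= ub.
# Classic bounded-variable simplex with artificial columns for phase 1,
# Dantzig pricing switching to Bland's rule under sustained degeneracy.
simplex_bounded <- function(A, b, cc, lb, ub, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)

  x <- numeric(n)
  vstat <- character(n)                 # "lb", "ub", "free" (nonbasic), "basic"
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      x[j] <- lb[j]; vstat[j] <- "lb"
    } else if (is.finite(ub[j])) {
      x[j] <- ub[j]; vstat[j] <- "ub"
    } else {
      x[j] <- 0; vstat[j] <- "free"
    }
  }

  r <- b - as.vector(A %*% x)
  art_sign <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(art_sign, nrow = m))
  state <- list(
    lb = c(lb, rep(0, m)),
    ub = c(ub, rep(Inf, m)),
    x = c(x, abs(r)),
    vstat = c(vstat, rep("basic", m)),
    basis = n + seq_len(m)
  )

  run_phase <- function(st, cvec, phase) {
    lball <- st$lb; uball <- st$ub
    xall <- st$x; vstat <- st$vstat; basis <- st$basis
    iter <- 0L
    degen_run <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        return(list(status = "iteration_limit"))
      }
      Bmat <- Aall[, basis, drop = FALSE]
      nb <- which(vstat != "basic")
      rhs <- b - as.vector(Aall[, nb, drop = FALSE] %*% xall[nb])
      xB <- tryCatch(solve(Bmat, rhs), error = function(e) NULL)
      if (is.null(xB)) return(list(status = "singular"))
      xall[basis] <- xB
      y <- tryCatch(solve(t(Bmat), cvec[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular"))
      d <- cvec[nb] - as.vector(crossprod(Aall[, nb, drop = FALSE], y))

      movable <- uball[nb] - lball[nb] > tol
      elig_up <- movable & d < -tol & (vstat[nb] %in% c("lb", "free"))
      elig_dn <- movable & d > tol & (vstat[nb] %in% c("ub", "free"))
      cand <- which(elig_up | elig_dn)
      if (length(cand) == 0L) {
        return(list(status = "optimal", x = xall, vstat = vstat,
                    basis = basis))
      }
      use_bland <- degen_run > 200L
      pick <- if (use_bland) cand[which.min(nb[cand])] else
        cand[which.max(abs(d[cand]))]
      q <- nb[pick]
      sigma <- if (elig_up[pick]) 1 else -1

      w <- solve(Bmat, Aall[, q])
      dB <- -sigma * w                   # movement of basic vars per unit t

      caps <- rep(Inf, m)
      cap_to <- character(m)
      for (k in seq_len(m)) {
        i <- basis[k]
        if (dB[k] > tol && is.finite(uball[i])) {
          caps[k] <- (uball[i] - xall[i]) / dB[k]; cap_to[k] <- "ub"
        } else if (dB[k] < -tol && is.finite(lball[i])) {
          caps[k] <- (lball[i] - xall[i]) / dB[k]; cap_to[k] <- "lb"
        }
      }
      span <- uball[q] - lball[q]
      t_max <- min(caps, span)
      if (!is.finite(t_max)) {
        if (phase == 1L) return(list(status = "singular"))
        return(list(status = "unbounded"))
      }
      t_max <- max(t_max, 0)
      degen_run <- if (t_max <= tol) degen_run + 1L else 0L

      if (is.finite(span) && span <= t_max + tol &&
          !any(caps < span - tol)) {
        # Bound flip: entering variable crosses to its other bound.
        xall[q] <- if (sigma > 0) uball[q] else lball[q]
        xall[basis] <- xall[basis] + dB * span
        vstat[q] <- if (sigma > 0) "ub" else "lb"
      } else {
        block <- which(caps <= t_max + tol)
        # Deterministic anti-cycling tie-break: smallest variable index.
        k_out <- block[which.min(basis[block])]
        i_out <- basis[k_out]
        xall[q] <- xall[q] + sigma * t_max
        xall[basis] <- xall[basis] + dB * t_max
        vstat[i_out] <- cap_to[k_out]
        xall[i_out] <- if (cap_to[k_out] == "ub") uball[i_out] else
          lball[i_out]
        basis[k_out] <- q
        vstat[q] <- "basic"
      }
    }
  }

  ph1 <- run_phase(state, c(rep(0, n), rep(1, m)), phase = 1L)
  if (ph1$status != "optimal") {
    return(list(status = if (ph1$status == "unbounded") "singular" else
      ph1$status, x = NULL))
  }
  if (sum(abs(ph1$x[n + seq_len(m)])) > 1e-7) {
    return(list(status = "infeasible", x = NULL))
  }

  state2 <- list(
    lb = c(lb, rep(0, m)),
    ub = c(ub, rep(0, m)),                 # artificials pinned at zero
    x = ph1$x,
    vstat = ph1$vstat,
    basis = ph1$basis
  )
  state2$x[n + seq_len(m)] <- 0
  nonbasic_art <- n + which(state2$vstat[n + seq_len(m)] != "basic")
  state2$vstat[nonbasic_art] <- "lb"
  ph2 <- run_phase(state2, c(cc, rep(0, m)), phase = 2L)
  if (ph2$status == "optimal") {
    list(status = "optimal", x = ph2$x[seq_len(n)])
  } else {
    list(status = ph2$status, x = NULL)
  }
}
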