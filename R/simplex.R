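# Bounded-variable revised simplex with explicit basis inverse.
#
# Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
# and returns the optimal primal solution together with the row duals
# (shadow prices) and reduced costs needed for sensitivity reporting.
# Two phases: phase 1 drives signed artificial variables to zero, phase 2
# optimizes the true objective with the artificials fixed at zero. The
# basis inverse is updated by rank-one pivots and refactorized periodically
# for numerical stability; Dantzig pricing with a Bland's-rule fallback
# guarantees termination on degenerate problems.

SOLVER_TOL <- 1e-9

#' Solve a bounded linear program
#'
#' @param obj Objective coefficients, length `n`.
#' @param A Constraint matrix (`m x n`), equality rows `A x = b`.
#' @param b Right-hand side, length `m`.
#' @param lb,ub Variable bounds, length `n`; `Inf`/`-Inf` permitted only
#'   where the problem is otherwise bounded.
#' @param maximize Logical; direction of optimization.
#' @param tol Solver feasibility/optimality tolerance.
#' @return A list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `x`, `objective`, `row_duals` (length `m`,
#'   d(objective)/d(b_i) in the problem's own sense), `reduced_costs`
#'   (length `n`, d(objective)/d(active bound)) and `iterations`.
#' @export
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE, tol = SOLVER_TOL) {
  n <- length(obj)
  A <- matrix(as.numeric(A), nrow = length(b), ncol = n)
  m <- nrow(A)
  if (any(lb > ub))
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                row_duals = NULL, reduced_costs = NULL, iterations = 0L))
  sense <- if (maximize) 1 else -1
  cc <- sense * as.numeric(obj)

  if (m == 0L) {  # box-only problem: each variable sits at its best bound
    x <- ifelse(cc > 0, ub, lb)
    x[cc == 0] <- pmin(pmax(0, lb[cc == 0]), ub[cc == 0])
    if (any(!is.finite(x)))
      return(list(status = "unbounded", x = NULL, objective = NA_real_,
                  row_duals = numeric(0), reduced_costs = NULL,
                  iterations = 0L))
    return(list(status = "optimal", x = x, objective = sum(obj * x),
                row_duals = numeric(0), reduced_costs = as.numeric(obj),
                iterations = 0L))
  }

  # augmented problem: n structural + m signed artificial columns
  nv <- n + m
  # nonbasic start: each structural variable at its finite bound nearest 0
  x0 <- ifelse(is.finite(lb) & (abs(lb) <= abs(ub) | !is.finite(ub)), lb,
               ifelse(is.finite(ub), ub, 0))
  r <- b - drop(A %*% x0)
  s <- ifelse(r >= 0, 1, -1)
  Aa <- cbind(A, diag(s, nrow = m))
  lba <- c(lb, rep(0, m))
  uba <- c(ub, rep(Inf, m))
  x <- c(x0, abs(r))
  vstat <- c(ifelse(x0 == lb, 1L, 2L), rep(0L, m))  # 0 basic, 1 at lb, 2 at ub
  basis <- n + seq_len(m)
  Binv <- diag(1 / s, nrow = m)  # inverse of diag(s)

  # phase 1: maximize -(sum of artificials)
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- simplex_iterate(c1, Aa, b, lba, uba, basis, vstat, x, Binv, tol)
  if (ph1$status == "iteration_limit")
    stop("simplex iteration limit exceeded in phase 1")
  infeas <- sum(ph1$x[n + seq_len(m)])
  if (infeas > 1e-7)
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                row_duals = NULL, reduced_costs = NULL,
                iterations = ph1$iterations))

  # fix artificials at zero; basic zero-valued artificials on redundant rows
  # may stay basic, pinned by their bounds
  uba[n + seq_len(m)] <- 0
  x[n + seq_len(m)] <- 0
  ph1$x[n + seq_len(m)] <- 0

  c2 <- c(cc, rep(0, m))
  ph2 <- simplex_iterate(c2, Aa, b, lba, uba, ph1$basis, ph1$vstat, ph1$x,
                         ph1$Binv, tol)
  if (ph2$status == "iteration_limit")
    stop("simplex iteration limit exceeded in phase 2")
  total_iter <- ph1$iterations + ph2$iterations
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objective = NA_real_,
                row_duals = NULL, reduced_costs = NULL,
                iterations = total_iter))

  xs <- ph2$x[seq_len(n)]
  # duals in the internal (maximize) sense, then mapped to the true sense:
  # z_true = sense * z_int, so d z_true / d b = sense * y_int
  y <- ph2$y
  d <- ph2$d[seq_len(n)]
  list(status = "optimal", x = xs, objective = sum(obj * xs),
       row_duals = sense * y, reduced_costs = sense * d,
       iterations = total_iter)
}

# Core pivoting loop (always maximizes `cc`). Returns updated basis state.
simplex_iterate <- function(cc, Aa, b, lba, uba, basis, vstat, x, Binv, tol) {
  m <- nrow(Aa)
  nv <- ncol(Aa)
  max_iter <- 50L * nv + 1000L
  bland_after <- 10L * nv + 200L
  refactor_every <- 60L
  since_refactor <- 0L
  free_range <- (uba - lba) > tol  # fixed variables never enter

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      return(list(status = "iteration_limit", iterations = iter, basis = basis,
                  vstat = vstat, x = x, Binv = Binv, y = NULL, d = NULL))

    cB <- cc[basis]
    y <- drop(crossprod(Binv, cB))
    d <- cc - drop(y %*% Aa)

    cand <- which((vstat == 1L & d > tol) | (vstat == 2L & d < -tol))
    cand <- cand[free_range[cand]]
    if (length(cand) == 0L) {
      return(list(status = "optimal", iterations = iter - 1L, basis = basis,
                  vstat = vstat, x = x, Binv = Binv, y = y, d = d))
    }
    e <- if (iter > bland_after) min(cand) else cand[which.max(abs(d[cand]))]

    w <- drop(Binv %*% Aa[, e])
    dir <- if (vstat[e] == 1L) 1 else -1  # movement off the active bound
    delta <- dir * w                       # x_B changes by -t * delta
    xB <- x[basis]

    # ratio test against basic-variable bounds; basic variable i blocks at
    # its lower bound when delta_i > 0 and at its upper bound when < 0
    pos <- which(delta > tol)
    neg <- which(delta < -tol)
    cand_rows <- c(pos, neg)
    cand_to <- c(rep(1L, length(pos)), rep(2L, length(neg)))
    cand_ratio <- c((xB[pos] - lba[basis[pos]]) / delta[pos],
                    (xB[neg] - uba[basis[neg]]) / delta[neg])
    cand_ratio <- pmax(cand_ratio, 0)  # clip tiny negative degeneracy
    t_best <- uba[e] - lba[e]          # bound-flip distance (may be Inf)
    leave <- 0L                        # 0 = bound flip
    leave_to <- 0L
    if (length(cand_rows)) {
      t_min <- min(cand_ratio)
      if (t_min <= t_best) {
        ties <- which(cand_ratio <= t_min + 1e-12)
        k <- ties[which.max(abs(delta[cand_rows[ties]]))]  # stablest pivot
        t_best <- cand_ratio[k]
        leave <- cand_rows[k]
        leave_to <- cand_to[k]
      }
    }

    if (!is.finite(t_best))
      return(list(status = "unbounded", iterations = iter, basis = basis,
                  vstat = vstat, x = x, Binv = Binv, y = y, d = d))

    if (leave == 0L) {                     # nonbasic bound flip
      x[e] <- if (vstat[e] == 1L) uba[e] else lba[e]
      vstat[e] <- 3L - vstat[e]
      x[basis] <- xB - t_best * delta
      next
    }

    # pivot: e enters, basis[leave] exits to one of its bounds
    lv <- basis[leave]
    x[basis] <- xB - t_best * delta
    x[e] <- x[e] + dir * t_best
    x[lv] <- if (leave_to == 1L) lba[lv] else uba[lv]
    vstat[lv] <- leave_to
    vstat[e] <- 0L
    basis[leave] <- e

    piv <- w[leave]
    Binv[leave, ] <- Binv[leave, ] / piv
    other <- setdiff(seq_len(m), leave)
    if (length(other))
      Binv[other, ] <- Binv[other, ] - outer(w[other], Binv[leave, ])

    since_refactor <- since_refactor + 1L
    if (since_refactor >= refactor_every) {
      Binv <- solve(Aa[, basis, drop = FALSE])
      nonb <- setdiff(seq_len(nv), basis)
      x[basis] <- drop(Binv %*% (b - Aa[, nonb, drop = FALSE] %*% x[nonb]))
      since_refactor <- 0L
    }
  }
}
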