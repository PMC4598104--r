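# Internal LP layer.
#
# All optimization in the package funnels through solve_lp(): maximize (or
# minimize) obj'v subject to S v = 0, lb <= v <= ub and optional coupling
# rows A v <= b. Coupling rows get bounded slack variables, so the problem
# handed to the solver is equality-form with box bounds.
#
# The solver is a dense two-phase primal simplex for bounded variables
# using Bland's smallest-index rule throughout, which guarantees
# termination without cycling and is fully deterministic (no RNG, no
# tie-breaking randomness). Problems in this package are small (tens of
# variables), so dense refactorization each iteration is cheap and
# numerically transparent.

solve_lp <- function(model, obj, maximize = TRUE) {
  lb <- unname(model$lb); ub <- unname(model$ub)
  if (!all(is.finite(lb)) || !all(is.finite(ub)))
    stop("solve_lp requires finite flux bounds on every reaction")
  A <- as.matrix(model$S)
  b <- rep(0, nrow(A))
  cc <- obj
  l <- lb; u <- ub
  if (!is.null(model$coupling)) {
    C <- model$coupling$A
    d <- model$coupling$b
    # slack s = d - C v; finite range from the box bounds of v
    lo_Cv <- as.vector(pmin(C, 0) %*% ub + pmax(C, 0) %*% lb)
    ns <- nrow(C)
    A <- rbind(cbind(A, matrix(0, nrow(A), ns)),
               cbind(C, diag(ns)))
    b <- c(b, d)
    cc <- c(cc, rep(0, ns))
    l <- c(l, rep(0, ns))
    u <- c(u, pmax(d - lo_Cv, 0))
  }
  res <- simplex_bounded(cc, A, b, l, u, maximize = maximize)
  if (res$status != "optimal")
    return(list(status = res$status, v = NULL, objective = NA_real_))
  v <- stats::setNames(res$x[seq_along(lb)], model$rxns)
  list(status = "optimal", v = v, objective = sum(obj * v))
}

# Two-phase bounded-variable primal simplex, Bland's rule.
# maximize cc'x  s.t.  A x = b,  l <= x <= u  (l, u finite).
simplex_bounded <- function(cc, A, b, l, u, maximize = TRUE,
                            tol = 1e-9, max_iter = 20000L) {
  if (!maximize) cc <- -cc
  m <- nrow(A); n <- ncol(A)
  if (any(l > u + tol)) return(list(status = "infeasible", x = NULL))
  u <- pmax(u, l)
  # start with every structural variable at the bound nearer zero
  x <- ifelse(abs(l) <= abs(u), l, u)
  at_upper <- abs(l) > abs(u)
  r0 <- b - as.vector(A %*% x)
  sgn <- ifelse(r0 >= 0, 1, -1)
  Af <- cbind(A, diag(sgn, m))
  lf <- c(l, rep(0, m))
  uf <- c(u, abs(r0))
  xf <- c(x, abs(r0))
  at_upper <- c(at_upper, rep(FALSE, m))
  basis <- (n + 1):(n + m)
  phase1 <- c(rep(0, n), rep(-1, m))
  st <- simplex_core(phase1, Af, lf, uf, xf, at_upper, basis, tol, max_iter)
  if (st$status != "optimal") return(list(status = st$status, x = NULL))
  if (sum(st$x[(n + 1):(n + m)]) > 1e-7)
    return(list(status = "infeasible", x = NULL))
  # pin artificials at zero and optimize the real objective
  uf2 <- uf; uf2[(n + 1):(n + m)] <- 0
  xf2 <- st$x; xf2[(n + 1):(n + m)] <- 0
  st2 <- simplex_core(c(cc, rep(0, m)), Af, lf, uf2, xf2,
                      st$at_upper, st$basis, tol, max_iter)
  if (st2$status != "optimal") return(list(status = st2$status, x = NULL))
  list(status = "optimal", x = st2$x[seq_len(n)],
       objective = sum(cc * st2$x[seq_len(n)]) * if (maximize) 1 else -1)
}

simplex_core <- function(obj, A, l, u, x, at_upper, basis, tol, max_iter) {
  ntot <- ncol(A)
  in_basis <- logical(ntot); in_basis[basis] <- TRUE
  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), obj[basis]), error = function(e) NULL)
    if (is.null(y)) return(list(status = "singular_basis"))
    nonbasic <- which(!in_basis)
    r <- obj[nonbasic] - as.vector(crossprod(A[, nonbasic, drop = FALSE], y))
    movable <- u[nonbasic] - l[nonbasic] > tol
    enter_up <- movable & !at_upper[nonbasic] & r > tol
    enter_dn <- movable & at_upper[nonbasic] & r < -tol
    cand <- nonbasic[enter_up | enter_dn]
    if (!length(cand))
      return(list(status = "optimal", x = x, basis = basis, at_upper = at_upper))
    j <- min(cand)                         # Bland
    dir <- if (at_upper[j]) -1 else 1
    d <- solve(B, A[, j])                  # basic change rate: -dir * d
    rate <- -dir * d
    t_best <- u[j] - l[j]                  # entering variable flips bound
    leave <- j
    for (k in seq_along(basis)) {
      bi <- basis[k]
      if (rate[k] > tol) {
        tk <- (u[bi] - x[bi]) / rate[k]
      } else if (rate[k] < -tol) {
        tk <- (x[bi] - l[bi]) / (-rate[k])
      } else next
      if (tk < t_best - tol || (tk < t_best + tol && bi < leave)) {
        t_best <- tk
        leave <- bi
      }
    }
    t_best <- max(t_best, 0)
    x[j] <- x[j] + dir * t_best
    x[basis] <- x[basis] + rate * t_best
    x <- pmin(pmax(x, l), u)               # sweep numerical dust
    if (leave == j) {
      at_upper[j] <- !at_upper[j]
    } else {
      k <- which(basis == leave)
      basis[k] <- j
      in_basis[j] <- TRUE
      in_basis[leave] <- FALSE
      at_upper[leave] <- abs(x[leave] - u[leave]) < abs(x[leave] - l[leave])
    }
  }
  list(status = "iteration_limit")
}

check_feasible <- function(model, v, tol = 1e-6) {
  bal <- max(abs(as.vector(model$S %*% v)))
  bnd <- max(c(model$lb - v, v - model$ub, 0))
  cpl <- if (is.null(model$coupling)) 0 else
    max(c(as.vector(model$coupling$A %*% v) - model$coupling$b, 0))
  max(bal, bnd, cpl) <= tol
}
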