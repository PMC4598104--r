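# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: LP values come from exhaustive vertex
# enumeration, rank correlations from a direct average-rank formula, and
# polytope marginals from rejection sampling over the bounding box.

# All vertices of {v : S v = 0, lb <= v <= ub}: fix every size-d subset of
# variables at lower or upper bounds (d = null dimension), solve for the
# rest, keep feasible solutions.
enum_vertices <- function(model, tol = 1e-8) {
  S <- as.matrix(model$S)
  n <- ncol(S)
  lb <- unname(model$lb); ub <- unname(model$ub)
  r <- qr(S)$rank
  d <- n - r
  verts <- list()
  if (d == 0) stop("no degrees of freedom to enumerate")
  for (fix_idx in utils::combn(n, d, simplify = FALSE)) {
    free_idx <- setdiff(seq_len(n), fix_idx)
    A <- S[, free_idx, drop = FALSE]
    if (qr(A)$rank < length(free_idx)) next
    for (pat in 0:(2^d - 1)) {
      at_ub <- bitwAnd(pat, 2^(seq_len(d) - 1)) > 0
      vfix <- ifelse(at_ub, ub[fix_idx], lb[fix_idx])
      rhs <- -S[, fix_idx, drop = FALSE] %*% vfix
      sol <- qr.solve(A, rhs)
      v <- numeric(n)
      v[fix_idx] <- vfix
      v[free_idx] <- sol
      if (max(abs(S %*% v)) > tol) next
      if (all(v >= lb - tol & v <= ub + tol))
        verts[[length(verts) + 1]] <- v
    }
  }
  if (!length(verts)) stop("polytope has no vertices (infeasible?)")
  out <- do.call(rbind, verts)
  colnames(out) <- model$rxns
  out
}

enum_lp_max <- function(model, objective_rxn) {
  V <- enum_vertices(model)
  max(V[, objective_rxn])
}

enum_fva <- function(model, reactions) {
  V <- enum_vertices(model)
  data.frame(reaction = reactions,
             v_min = apply(V[, reactions, drop = FALSE], 2, min),
             v_max = apply(V[, reactions, drop = FALSE], 2, max),
             row.names = NULL)
}

# Direct average-rank implementation of Spearman's rho (no rank(); no cor()).
brute_spearman <- function(x, y) {
  avg_rank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Rejection sampler over the bounding box of the free coordinates of a
# polytope {sum(out) <= cap, 0 <= out_i <= ub_i}; used for marginal
# comparisons on the small test polytopes.
rejection_simplex <- function(n, ubs, cap, seed) {
  withr::with_seed(seed, {
    out <- matrix(NA_real_, 0, length(ubs))
    while (nrow(out) < n) {
      m <- 4 * n
      draw <- sapply(ubs, function(u) stats::runif(m, 0, u))
      keep <- rowSums(draw) <= cap
      out <- rbind(out, draw[keep, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  })
}

# Closed-form FBA optimum of the minicore network with glucose, oxygen,
# ethanol and glycerol exchange fixed (defaults yields 0.07/0.010/0.003,
# ethanol+co2 yield 0.8 per fermented glucose, 2 O2 per respired glucose).
minicore_growth <- function(g, o2, eth, gly,
                            y_resp = 0.07, y_ferm = 0.010, y_gly = 0.003) {
  R <- g - eth / 0.8 - gly / 0.8
  if (R < -1e-9) return(NA_real_)
  R <- max(R, 0)
  y_resp * min(R, o2 / 2) + (y_ferm / 0.8) * eth + (y_gly / 0.8) * gly
}

# Hand-built physiological constraints with known coefficients.
manual_constraints <- function(alpha_oxy_low = 1.0, beta_l_oxy = -0.1,
                               beta_u_oxy = 0.1,
                               alpha_oxy_high = -0.2, beta_l_oxy_high = 9,
                               beta_u_oxy_high = 10,
                               alpha_eth = 0.6, beta_l_eth = -0.5,
                               beta_u_eth = 0.5,
                               alpha_gly_l = 0.05, alpha_gly_u = 0.1,
                               transition = 4, o2_floor = 0.016) {
  structure(list(
    o2_low = list(alpha = alpha_oxy_low, beta_l = beta_l_oxy,
                  beta_u = beta_u_oxy, r_squared = NA, n = NA),
    o2_high = list(alpha = alpha_oxy_high, beta_l = beta_l_oxy_high,
                   beta_u = beta_u_oxy_high, r_squared = NA, n = NA),
    ethanol = list(alpha = alpha_eth, beta_l = beta_l_eth,
                   beta_u = beta_u_eth, r_squared = NA, n = NA),
    glycerol = list(alpha_l = alpha_gly_l, alpha_u = alpha_gly_u, n = NA),
    transition = transition, o2_floor = o2_floor, coverage = NA),
    class = "phys_constraints")
}

# Small flux polytopes reused by sampling tests.
triangle_model <- function(cap = 10, ub_out = 6) {
  S <- matrix(c(1, -1, -1), 1, 3,
              dimnames = list("A", c("in", "out1", "out2")))
  stoichiometric_model("triangle", S, lb = c(0, 0, 0),
                       ub = c(cap, ub_out, ub_out), objective = "in")
}

simplex3_model <- function(cap = 9, ub_out = 4) {
  S <- matrix(c(1, -1, -1, -1), 1, 4,
              dimnames = list("A", c("in", "o1", "o2", "o3")))
  stoichiometric_model("simplex3", S, lb = rep(0, 4),
                       ub = c(cap, rep(ub_out, 3)), objective = "in")
}
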