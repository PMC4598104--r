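#' Flux balance analysis
#'
#' Maximizes the objective-reaction flux (biomass growth) over the
#' steady-state polytope \code{\{v : S v = 0, lb <= v <= ub\}}, plus any
#' coupling inequalities attached to the model. Any optimal vertex is
#' acceptable; contracts in this package are on the objective value and
#' feasibility, never on a unique flux vector.
#'
#' @param model a \code{stoich_model}.
#' @param tol feasibility tolerance used to verify the returned solution.
#' @return a \code{flux_distribution}: list with \code{fluxes} (named
#'   vector), \code{objective} and \code{status}.
#' @export
fba <- function(model, tol = 1e-6) {
  obj <- as.numeric(model$rxns == model$objective)
  res <- solve_lp(model, obj, maximize = TRUE)
  if (res$status == "infeasible")
    stop("FBA infeasible: the constraints conflict (model '", model$id, "')",
         call. = FALSE)
  if (res$status != "optimal")
    stop("LP did not converge on model '", model$id, "'", call. = FALSE)
  if (!check_feasible(model, res$v, tol))
    stop("LP solution violates constraints beyond tolerance ", tol)
  structure(list(fluxes = res$v, objective = res$objective, status = res$status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> objective =", format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' LP-exact minimum and maximum of each listed reaction flux over the
#' constraint polytope (no objective fixing). Used both as an analysis tool
#' and as the deterministic oracle that sampled flux extremes must respect.
#'
#' @param model a \code{stoich_model}.
#' @param reactions reaction ids; default all.
#' @return data.frame with columns \code{reaction}, \code{v_min},
#'   \code{v_max}.
#' @export
fva <- function(model, reactions = NULL) {
  if (is.null(reactions)) reactions <- model$rxns
  unknown <- setdiff(reactions, model$rxns)
  if (length(unknown)) stop("unknown reaction(s): ", paste(unknown, collapse = ", "))
  out <- data.frame(reaction = reactions, v_min = NA_real_, v_max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reactions)) {
    obj <- as.numeric(model$rxns == reactions[i])
    lo <- solve_lp(model, obj, maximize = FALSE)
    hi <- solve_lp(model, obj, maximize = TRUE)
    if (lo$status == "infeasible" || hi$status == "infeasible")
      stop("FVA infeasible on model '", model$id, "'", call. = FALSE)
    out$v_min[i] <- lo$objective
    out$v_max[i] <- hi$objective
  }
  out
}

#' Apply physiological exchange constraints to a model
#'
#' Imposes the fitted glucose-dependent bound bands for oxygen uptake,
#' ethanol production and glycerol secretion on the model's mapped exchange
#' reactions. Two modes:
#' \describe{
#'   \item{fixed glucose}{\code{glucose} a single value: the glucose
#'     exchange is fixed and each band is evaluated at that uptake rate,
#'     giving numeric lb/ub on the three exchanges.}
#'   \item{window}{\code{glucose} a length-2 interval (e.g. \code{c(18,
#'     20)}): the glucose exchange is bounded to the window and four
#'     coupling inequalities per phenotype tie the exchange flux to the
#'     glucose flux, \code{alpha*v_glu + beta_l <= v_phen <= alpha*v_glu +
#'     beta_u}.}
#' }
#' In both modes the oxygen lower bound is floored at
#' \code{constraints$o2_floor} (default 0.016 mmol gDW^-1 h^-1, a minimal
#' respiration requirement), band lower bounds are clamped at 0, and any
#' mapped alternative carbon uptakes (roles \code{"fructose"},
#' \code{"ethanol_uptake"}) are fixed to 0.
#'
#' All mapped exchange reactions must carry non-negative flux in their
#' physiological direction (uptake positive for glucose/oxygen, secretion
#' positive for ethanol/glycerol); the toy generators follow this
#' convention.
#'
#' @param model a \code{stoich_model} with exchange roles mapped.
#' @param constraints a \code{phys_constraints} object from
#'   [build_constraints()].
#' @param glucose a single uptake rate or a length-2 window
#'   (mmol gDW^-1 h^-1).
#' @return the constrained model.
#' @export
apply_constraints <- function(model, constraints, glucose) {
  stopifnot(inherits(constraints, "phys_constraints"))
  if (!length(model$exchanges))
    stop("model has no exchange-role mapping; cannot apply constraints")
  glc <- role_rxn(model, "glucose")
  for (role in c("fructose", "ethanol_uptake")) {
    id <- role_rxn(model, role, required = FALSE)
    if (!is.null(id)) model <- set_bounds(model, id, lb = 0, ub = 0)
  }
  if (length(glucose) == 1) {
    if (glucose < 0) stop("glucose uptake must be non-negative")
    model <- set_bounds(model, glc, lb = glucose, ub = glucose)
    bands <- evaluate_bounds(constraints, glucose)
    for (role in c("oxygen", "ethanol", "glycerol")) {
      id <- role_rxn(model, role, required = FALSE)
      if (is.null(id)) next
      lo <- bands[[role]][1]; hi <- bands[[role]][2]
      if (role == "oxygen") {
        lo <- max(lo, constraints$o2_floor)
        hi <- max(hi, lo)
      }
      model <- set_bounds(model, id, lb = lo, ub = hi)
    }
    return(model)
  }
  if (length(glucose) != 2 || glucose[1] > glucose[2])
    stop("glucose must be a single value or an increasing length-2 window")
  tm <- constraints$transition
  if (glucose[1] < tm && glucose[2] > tm)
    stop("glucose window straddles the metabolic transition at ", tm,
         "; the oxygen band is regime-specific")
  model <- set_bounds(model, glc, lb = glucose[1], ub = glucose[2])
  o2b <- if (glucose[2] <= tm) constraints$o2_low else constraints$o2_high
  n <- length(model$rxns)
  rows <- list(); rhs <- numeric(0)
  add_band <- function(phen_id, alpha, beta_l, beta_u) {
    r_up <- numeric(n); r_up[match(phen_id, model$rxns)] <- 1
    r_up[match(glc, model$rxns)] <- -alpha
    r_lo <- -r_up
    rows[[length(rows) + 1]] <<- r_up; rhs <<- c(rhs, beta_u)   # v - a*glu <= b_u
    rows[[length(rows) + 1]] <<- r_lo; rhs <<- c(rhs, -beta_l)  # a*glu - v <= -b_l
  }
  o2 <- role_rxn(model, "oxygen", required = FALSE)
  if (!is.null(o2)) {
    add_band(o2, o2b$alpha, o2b$beta_l, o2b$beta_u)
    model$lb[o2] <- max(model$lb[o2], constraints$o2_floor)
  }
  eth <- role_rxn(model, "ethanol", required = FALSE)
  if (!is.null(eth)) {
    add_band(eth, constraints$ethanol$alpha,
             constraints$ethanol$beta_l, constraints$ethanol$beta_u)
    model$lb[eth] <- max(model$lb[eth], 0)
  }
  gly <- role_rxn(model, "glycerol", required = FALSE)
  if (!is.null(gly)) {
    # glycerol band passes through the origin with two slopes:
    # alpha_l * v_glu <= v_gly <= alpha_u * v_glu
    r_up <- numeric(n); r_up[match(gly, model$rxns)] <- 1
    r_up[match(glc, model$rxns)] <- -constraints$glycerol$alpha_u
    r_lo <- numeric(n); r_lo[match(gly, model$rxns)] <- -1
    r_lo[match(glc, model$rxns)] <- constraints$glycerol$alpha_l
    rows[[length(rows) + 1]] <- r_up; rhs <- c(rhs, 0)
    rows[[length(rows) + 1]] <- r_lo; rhs <- c(rhs, 0)
    model$lb[gly] <- max(model$lb[gly], 0)
  }
  A <- do.call(rbind, rows)
  colnames(A) <- model$rxns
  if (!is.null(model$coupling)) {
    A <- rbind(model$coupling$A, A)
    rhs <- c(model$coupling$b, rhs)
  }
  model$coupling <- list(A = A, b = rhs)
  model
}

#' Single-reaction deletion screen
#'
#' Iteratively forces each reaction's flux to zero, reruns FBA, and labels
#' the reaction by the knockout growth rate: \code{essential} if growth
#' drops to (numerically) zero, \code{nonessential} if growth is unchanged
#' within a relative tolerance, \code{partial} otherwise. The exact
#' "growth = 0" / "growth = wild type" dichotomy is not exhaustive under LP
#' numerics, hence the tolerances and the third label; \code{partial}
#' reactions are excluded from essential/non-essential groupings downstream.
#'
#' @param model a \code{stoich_model}; its unconstrained optimum must be
#'   positive.
#' @param tol_abs absolute growth below which a knockout is essential.
#' @param tol_rel relative deviation from wild-type growth below which a
#'   knockout is non-essential.
#' @return data.frame with \code{reaction}, \code{growth}, \code{label}.
#' @export
single_deletions <- function(model, tol_abs = 1e-6, tol_rel = 1e-3) {
  v_ori <- fba(model)$objective
  if (v_ori <= tol_abs)
    stop("wild-type growth is zero; essentiality screen undefined")
  out <- data.frame(reaction = model$rxns, growth = NA_real_,
                    label = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(model$rxns)) {
    ko <- model
    ko$lb[i] <- 0; ko$ub[i] <- 0
    g <- tryCatch(fba(ko)$objective, error = function(e) 0)
    out$growth[i] <- g
    out$label[i] <- if (g <= tol_abs) "essential"
      else if (abs(g - v_ori) <= tol_rel * v_ori) "nonessential"
      else "partial"
  }
  attr(out, "v_ori") <- v_ori
  out
}

#' Reaction eligibility filter for flux statistics
#'
#' Flags the reactions admissible for per-reaction flux statistics and the
#' gene-level correlation analyses. Excluded are: (a) reactions on
#' internal (thermodynamically infeasible) loops, detected as internal
#' reactions still able to carry flux when every exchange reaction is
#' closed; (b) reactions whose gene rule is not a single gene — isozymes
#' (an \code{or} rule), enzyme complexes (an \code{and} rule) and
#' gene-less reactions — so that a one gene-one reaction mapping holds;
#' (c) bi-directional reactions (\code{lb < 0}).
#'
#' @param model a \code{stoich_model} with gene rules.
#' @param tol flux magnitude above which a closed-exchange reaction counts
#'   as loop-carrying.
#' @return data.frame with \code{reaction}, \code{eligible},
#'   \code{reason} (\code{"ok"}, \code{"loop"}, \code{"isozyme"},
#'   \code{"complex"}, \code{"no_gene"}, \code{"reversible"}).
#' @export
eligible_reactions <- function(model, tol = 1e-6) {
  closed <- model
  ex <- which(model$is_exchange)
  closed$lb[ex] <- 0; closed$ub[ex] <- 0
  internal <- model$rxns[!model$is_exchange]
  loops <- character(0)
  if (length(internal)) {
    rng <- fva(closed, internal)
    loops <- rng$reaction[pmax(abs(rng$v_min), abs(rng$v_max)) > tol]
  }
  reason <- vapply(model$rxns, function(r) {
    if (r %in% loops) return("loop")
    rule <- trimws(model$gene_rules[r])
    if (!nzchar(rule)) return("no_gene")
    if (grepl("\\bor\\b", rule, ignore.case = TRUE)) return("isozyme")
    if (grepl("\\band\\b", rule, ignore.case = TRUE)) return("complex")
    if (model$lb[r] < 0) return("reversible")
    "ok"
  }, "")
  data.frame(reaction = model$rxns, eligible = reason == "ok",
             reason = unname(reason), row.names = NULL, stringsAsFactors = FALSE)
}
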