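#' Predict the growth-rate envelope over a glucose grid
#'
#' At each glucose uptake rate on the grid, the oxygen, ethanol and
#' glycerol exchange rates are drawn uniformly and independently within
#' their physiological bands, fixed, and FBA maximizes growth. Draw
#' combinations incompatible with steady state are discarded (and
#' counted). The largest and smallest optimum over accepted draws give the
#' upper and lower growth bound at that glucose value.
#'
#' @param model a \code{stoich_model} with exchange roles mapped.
#' @param constraints a \code{phys_constraints}.
#' @param grid glucose uptake grid (mmol gDW^-1 h^-1); default 0 to 24 in
#'   steps of 0.1.
#' @param n_draws uniform band draws per grid point.
#' @param seed integer seed.
#' @return data.frame of class \code{growth_envelope} with columns
#'   \code{glucose}, \code{v_min}, \code{v_max}, \code{n_accepted},
#'   \code{n_draws}; grid points where every draw was infeasible carry
#'   \code{NA} bounds.
#' @export
predict_envelope <- function(model, constraints, grid = seq(0, 24, by = 0.1),
                             n_draws = 10000, seed = 1L) {
  stopifnot(inherits(constraints, "phys_constraints"), n_draws >= 1)
  roles <- intersect(c("oxygen", "ethanol", "glycerol"), names(model$exchanges))
  out <- data.frame(glucose = grid, v_min = NA_real_, v_max = NA_real_,
                    n_accepted = 0L, n_draws = as.integer(n_draws))
  withr::with_seed(seed, {
    for (gi in seq_along(grid)) {
      g <- grid[gi]
      base <- apply_constraints(model, constraints, g)
      draws <- matrix(NA_real_, n_draws, length(roles),
                      dimnames = list(NULL, roles))
      for (role in roles) {
        id <- role_rxn(base, role)
        draws[, role] <- stats::runif(n_draws, base$lb[id], base$ub[id])
      }
      vals <- rep(NA_real_, n_draws)
      for (k in seq_len(n_draws)) {
        m <- base
        for (role in roles) {
          id <- role_rxn(m, role)
          m$lb[id] <- m$ub[id] <- draws[k, role]
        }
        vals[k] <- tryCatch(fba(m)$objective, error = function(e) NA_real_)
      }
      ok <- is.finite(vals)
      out$n_accepted[gi] <- sum(ok)
      if (any(ok)) {
        out$v_min[gi] <- min(vals[ok])
        out$v_max[gi] <- max(vals[ok])
      }
    }
  })
  structure(out, class = c("growth_envelope", "data.frame"),
            seed = seed, n_draws = n_draws)
}

#' Piecewise-linear fit of an envelope curve
#'
#' Splits the glucose grid at the given breakpoints and fits ordinary
#' least squares to the upper and lower envelope curve on each segment,
#' yielding linear bound equations for the growth rate.
#'
#' @param envelope a \code{growth_envelope}.
#' @param breakpoints glucose values partitioning the grid; each must lie
#'   inside the grid range. Use [find_breakpoint()] for a data-driven
#'   kink.
#' @return data.frame with one row per segment and curve:
#'   \code{curve} (\code{"upper"}/\code{"lower"}), \code{from}, \code{to},
#'   \code{alpha} (slope), \code{beta} (intercept), \code{r_squared},
#'   \code{n}.
#' @export
fit_segments <- function(envelope, breakpoints = 4) {
  g <- envelope$glucose
  if (any(breakpoints <= min(g)) || any(breakpoints >= max(g)))
    stop("breakpoints must lie strictly inside the glucose grid")
  edges <- c(min(g), sort(breakpoints), max(g))
  rows <- list()
  for (curve in c("upper", "lower")) {
    y_all <- if (curve == "upper") envelope$v_max else envelope$v_min
    for (s in seq_len(length(edges) - 1)) {
      sel <- g >= edges[s] & g <= edges[s + 1] & is.finite(y_all)
      if (sum(sel) < 2)
        stop("segment [", edges[s], ", ", edges[s + 1], "] has fewer than 2 points")
      fit <- stats::lm(y_all[sel] ~ g[sel])
      r2 <- suppressWarnings(summary(fit)$r.squared)
      rows[[length(rows) + 1]] <- data.frame(
        curve = curve, from = edges[s], to = edges[s + 1],
        alpha = unname(stats::coef(fit)[2]), beta = unname(stats::coef(fit)[1]),
        r_squared = if (is.nan(r2)) 1 else r2, n = sum(sel))
    }
  }
  do.call(rbind, rows)
}

#' Locate a single kink by exhaustive two-segment search
#'
#' Scans every interior grid point as a candidate breakpoint, fits two
#' ordinary least-squares segments, and returns the candidate minimizing
#' the total sum of squared errors.
#'
#' @param x,y numeric vectors (e.g. glucose grid and an envelope curve).
#' @param min_points minimum points per segment.
#' @return the breakpoint (an element of \code{x}).
#' @export
find_breakpoint <- function(x, y, min_points = 3) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  ord <- order(x); x <- x[ord]; y <- y[ord]
  n <- length(x)
  if (n < 2 * min_points) stop("too few points for a two-segment fit")
  sse <- function(xx, yy) {
    f <- stats::lm(yy ~ xx)
    sum(stats::resid(f)^2)
  }
  cand <- seq(min_points, n - min_points)
  total <- vapply(cand, function(i)
    sse(x[1:i], y[1:i]) + sse(x[(i + 1):n], y[(i + 1):n]), 0)
  x[cand[which.min(total)]]
}

#' Fraction of observations inside the predicted envelope
#'
#' Linearly interpolates the envelope bounds at each record's glucose
#' uptake rate and counts the records whose growth rate lies between
#' them. Records outside the grid range are skipped and counted.
#'
#' @param records flux-phenotype data.frame with \code{v_glu} and
#'   \code{growth_rate}.
#' @param envelope a \code{growth_envelope}.
#' @param tol numeric slack.
#' @return list with \code{fraction}, \code{n_inside}, \code{n_tested},
#'   \code{n_skipped}.
#' @export
fraction_within <- function(records, envelope, tol = 1e-9) {
  ok <- is.finite(records$v_glu) & is.finite(records$growth_rate)
  d <- records[ok, , drop = FALSE]
  grid_ok <- is.finite(envelope$v_min) & is.finite(envelope$v_max)
  gg <- envelope$glucose[grid_ok]
  in_range <- d$v_glu >= min(gg) & d$v_glu <= max(gg)
  skipped <- sum(!in_range) + sum(!ok)
  d <- d[in_range, , drop = FALSE]
  if (nrow(d) == 0)
    return(list(fraction = NA_real_, n_inside = 0L, n_tested = 0L,
                n_skipped = skipped))
  lo <- stats::approx(gg, envelope$v_min[grid_ok], xout = d$v_glu)$y
  hi <- stats::approx(gg, envelope$v_max[grid_ok], xout = d$v_glu)$y
  inside <- d$growth_rate >= lo - tol & d$growth_rate <= hi + tol
  list(fraction = mean(inside), n_inside = sum(inside),
       n_tested = nrow(d), n_skipped = skipped)
}
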