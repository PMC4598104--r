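FLUX_TABLE_COLS <- c("study_id", "v_glu", "v_o2", "v_co2", "rq",
                     "v_eth", "v_gly", "growth_rate")

#' Read a flux-phenotype table
#'
#' Reads a CSV of steady-state chemostat observations: one row per
#' observation, columns \code{study_id, v_glu, v_o2, v_co2, rq, v_eth,
#' v_gly, growth_rate} (rates in mmol gDW^-1 h^-1, growth in h^-1). Any
#' column other than \code{study_id} and \code{v_glu} may be absent;
#' empty cells become \code{NA}, never 0.
#'
#' @param path CSV file path.
#' @return a validated data.frame of flux-phenotype records.
#' @export
read_flux_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(df), FLUX_TABLE_COLS)
  if (length(unknown))
    stop("unknown column(s) in flux table: ", paste(unknown, collapse = ", "))
  if (!all(c("study_id", "v_glu") %in% names(df)))
    stop("flux table must contain study_id and v_glu columns")
  for (col in setdiff(FLUX_TABLE_COLS, c("study_id", names(df))))
    df[[col]] <- NA_real_
  for (col in setdiff(FLUX_TABLE_COLS, "study_id")) {
    if (!is.numeric(df[[col]]))
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0 & col != "rq")
    if (length(bad))
      stop("negative rate in column '", col, "' at row ", bad[1])
  }
  df[FLUX_TABLE_COLS]
}

#' Classify the metabolic state from the glucose uptake rate
#'
#' Below (and at) the transition marker of 4 mmol gDW^-1 h^-1 the cell is
#' predominantly respiring; above it, fermenting (Crabtree/overflow
#' regime). The boundary value is assigned to respiration.
#'
#' @param v_glu glucose uptake rate(s), non-negative.
#' @param transition transition marker (mmol gDW^-1 h^-1).
#' @return character vector, \code{"respiration"} or
#'   \code{"fermentation"}.
#' @export
classify_state <- function(v_glu, transition = 4) {
  if (any(v_glu < 0, na.rm = TRUE)) stop("glucose uptake must be non-negative")
  ifelse(v_glu <= transition, "respiration", "fermentation")
}

regime_filter <- function(records, regime, transition = 4) {
  switch(regime,
         low = records[records$v_glu <= transition, , drop = FALSE],
         high = records[records$v_glu > transition, , drop = FALSE],
         full = records,
         stop("regime must be 'low', 'high' or 'full'"))
}

#' Fit a phenotype-vs-glucose slope
#'
#' Ordinary least-squares fit of a flux phenotype against glucose uptake,
#' restricted to one glucose regime. Records missing either variable are
#' excluded from this fit only.
#'
#' @param records flux-phenotype data.frame.
#' @param phenotype one of \code{"v_o2"}, \code{"v_co2"}, \code{"v_eth"},
#'   \code{"v_gly"}, \code{"growth_rate"}.
#' @param regime \code{"low"} (v_glu <= transition), \code{"high"}
#'   (v_glu > transition) or \code{"full"}.
#' @param transition regime boundary.
#' @return list with \code{alpha} (slope), \code{intercept},
#'   \code{r_squared}, \code{n}.
#' @export
fit_slope <- function(records, phenotype, regime = "full", transition = 4) {
  if (!phenotype %in% setdiff(FLUX_TABLE_COLS, c("study_id", "v_glu")))
    stop("unknown phenotype: ", phenotype)
  d <- regime_filter(records, regime, transition)
  d <- d[is.finite(d$v_glu) & is.finite(d[[phenotype]]), , drop = FALSE]
  if (nrow(d) < 2)
    stop("fewer than 2 usable points for ", phenotype, " in regime '", regime, "'")
  if (stats::var(d$v_glu) == 0)
    stop("zero variance in glucose uptake; slope undefined")
  fit <- stats::lm(d[[phenotype]] ~ d$v_glu)
  co <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are fine here
  list(alpha = unname(co[2]), intercept = unname(co[1]),
       r_squared = r2, n = nrow(d))
}

#' Leave-one-study-out slope validation
#'
#' Refits the phenotype slope with each elementary dataset (study) left
#' out in turn, guarding the regression against publication bias from any
#' single source. Dispersion is the maximum relative deviation of the
#' leave-one-out slopes from the all-data slope.
#'
#' @inheritParams fit_slope
#' @return list of class \code{loe_report}: \code{slopes} and
#'   \code{r_squared} (named per left-out study), \code{alpha_all},
#'   \code{dispersion}.
#' @export
loe_validation <- function(records, phenotype, regime = "full", transition = 4) {
  studies <- unique(records$study_id)
  if (length(studies) < 2)
    stop("leave-one-study-out validation needs at least 2 studies")
  all_fit <- fit_slope(records, phenotype, regime, transition)
  slopes <- r2 <- stats::setNames(numeric(length(studies)), studies)
  for (s in studies) {
    f <- fit_slope(records[records$study_id != s, , drop = FALSE],
                   phenotype, regime, transition)
    slopes[s] <- f$alpha
    r2[s] <- f$r_squared
  }
  disp <- if (all_fit$alpha == 0) max(abs(slopes - all_fit$alpha)) else
    max(abs(slopes - all_fit$alpha) / abs(all_fit$alpha))
  structure(list(slopes = slopes, r_squared = r2,
                 alpha_all = all_fit$alpha, dispersion = disp),
            class = "loe_report")
}

#' Calibrate band offsets around a fixed slope
#'
#' With the slope \code{alpha} held fixed, chooses offsets
#' \code{beta_l <= beta_u} from the order statistics of the residuals
#' \code{r = y - alpha * v_glu} so that the band
#' \code{[alpha*v_glu + beta_l, alpha*v_glu + beta_u]} contains at least
#' the requested fraction of points: the \code{floor(n*(1-coverage)/2)}
#' most extreme residuals on each side are left outside. This replaces
#' setting offsets by visual inspection with a deterministic rule that
#' preserves the coverage target.
#'
#' @param records flux-phenotype data.frame.
#' @param phenotype phenotype column.
#' @param alpha fixed slope.
#' @param regime,transition glucose regime restriction (see
#'   [fit_slope()]).
#' @param coverage target fraction of points inside the band, in (0, 1].
#' @return list with \code{beta_l}, \code{beta_u}, \code{n}.
#' @export
calibrate_offsets <- function(records, phenotype, alpha, regime = "full",
                              transition = 4, coverage = 0.90) {
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  d <- regime_filter(records, regime, transition)
  d <- d[is.finite(d$v_glu) & is.finite(d[[phenotype]]), , drop = FALSE]
  if (nrow(d) < 1) stop("no usable points for offset calibration")
  r <- sort(d[[phenotype]] - alpha * d$v_glu)
  n <- length(r)
  k <- floor(n * (1 - coverage) / 2)
  list(beta_l = r[k + 1], beta_u = r[n - k], n = n)
}

#' Build physiological constraints from a flux-phenotype table
#'
#' Fits the full set of glucose-uptake-dependent linear bound bands:
#' oxygen uptake separately per metabolic regime (positive slope below the
#' transition, typically negative above), ethanol production over the full
#' glucose range, and a glycerol band through the origin whose two slopes
#' are coverage order-statistics of the per-point ratio
#' \code{v_gly / v_glu}. Offsets come from [calibrate_offsets()]; band
#' lower edges are clamped at 0 downstream (rates are non-negative).
#'
#' @param records flux-phenotype data.frame spanning both glucose regimes.
#' @param coverage target band coverage.
#' @param transition regime boundary (mmol gDW^-1 h^-1).
#' @param o2_floor minimal oxygen uptake imposed when bands dip below it
#'   (applied by [apply_constraints()]).
#' @return object of class \code{phys_constraints} with components
#'   \code{o2_low}, \code{o2_high}, \code{ethanol} (each
#'   \code{alpha/beta_l/beta_u/r_squared/n}), \code{glycerol}
#'   (\code{alpha_l/alpha_u/n}), \code{transition}, \code{o2_floor},
#'   \code{coverage}.
#' @export
build_constraints <- function(records, coverage = 0.90, transition = 4,
                              o2_floor = 0.016) {
  band <- function(phenotype, regime) {
    f <- fit_slope(records, phenotype, regime, transition)
    off <- calibrate_offsets(records, phenotype, f$alpha, regime,
                             transition, coverage)
    list(alpha = f$alpha, beta_l = off$beta_l, beta_u = off$beta_u,
         r_squared = f$r_squared, n = f$n)
  }
  o2_low <- band("v_o2", "low")
  o2_high <- band("v_o2", "high")
  eth <- band("v_eth", "full")
  d <- records[is.finite(records$v_glu) & is.finite(records$v_gly) &
                 records$v_glu > 0, , drop = FALSE]
  if (nrow(d) < 2) stop("fewer than 2 usable glycerol points")
  ratio <- sort(d$v_gly / d$v_glu)
  k <- floor(length(ratio) * (1 - coverage) / 2)
  gly <- list(alpha_l = ratio[k + 1], alpha_u = ratio[length(ratio) - k],
              n = length(ratio))
  structure(list(o2_low = o2_low, o2_high = o2_high, ethanol = eth,
                 glycerol = gly, transition = transition,
                 o2_floor = o2_floor, coverage = coverage),
            class = "phys_constraints")
}

#' @export
print.phys_constraints <- function(x, ...) {
  fmt <- function(b) sprintf("alpha=%.4f  beta=[%.4f, %.4f]  R2=%.3f (n=%d)",
                             b$alpha, b$beta_l, b$beta_u, b$r_squared, b$n)
  cat("<phys_constraints>  transition =", x$transition, "mmol/gDW/h\n")
  cat("  O2  (low) :", fmt(x$o2_low), "\n")
  cat("  O2  (high):", fmt(x$o2_high), "\n")
  cat("  ethanol   :", fmt(x$ethanol), "\n")
  cat(sprintf("  glycerol  : alpha=[%.4f, %.4f] (n=%d), through origin\n",
              x$glycerol$alpha_l, x$glycerol$alpha_u, x$glycerol$n))
  invisible(x)
}

#' Evaluate the bound bands at a glucose uptake rate
#'
#' @param constraints a \code{phys_constraints}.
#' @param v_glu glucose uptake rate (single value).
#' @return list of length-2 \code{c(lb, ub)} vectors for \code{oxygen},
#'   \code{ethanol}, \code{glycerol}; lower edges clamped at 0.
#' @export
evaluate_bounds <- function(constraints, v_glu) {
  stopifnot(length(v_glu) == 1, v_glu >= 0)
  b <- if (v_glu <= constraints$transition) constraints$o2_low else constraints$o2_high
  clamp <- function(lo, hi) c(max(lo, 0), max(hi, 0))
  list(oxygen = clamp(b$alpha * v_glu + b$beta_l, b$alpha * v_glu + b$beta_u),
       ethanol = clamp(constraints$ethanol$alpha * v_glu + constraints$ethanol$beta_l,
                       constraints$ethanol$alpha * v_glu + constraints$ethanol$beta_u),
       glycerol = clamp(constraints$glycerol$alpha_l * v_glu,
                        constraints$glycerol$alpha_u * v_glu))
}

#' Empirical coverage of the fitted bands
#'
#' Fraction of records whose present phenotypes (oxygen by regime,
#' ethanol, glycerol) all lie inside their bands at the record's glucose
#' uptake rate.
#'
#' @param constraints a \code{phys_constraints}.
#' @param records flux-phenotype data.frame.
#' @param phenotypes which bands to test; default all three jointly. The
#'   per-band calibration guarantee (coverage >= target) applies to each
#'   band separately, so pass a single phenotype to check it.
#' @param tol numeric slack when testing band membership.
#' @return fraction in \code{[0, 1]}; \code{NA} (with a warning) for an
#'   empty record set.
#' @export
band_coverage <- function(constraints, records,
                          phenotypes = c("oxygen", "ethanol", "glycerol"),
                          tol = 1e-9) {
  phenotypes <- match.arg(phenotypes, several.ok = TRUE)
  if (nrow(records) == 0) {
    warning("empty record set: coverage undefined")
    return(NA_real_)
  }
  col_of <- c(oxygen = "v_o2", ethanol = "v_eth", glycerol = "v_gly")
  inside <- vapply(seq_len(nrow(records)), function(i) {
    g <- records$v_glu[i]
    if (!is.finite(g)) return(NA)
    bb <- evaluate_bounds(constraints, g)
    ok <- TRUE
    for (ph in phenotypes) {
      val <- records[[col_of[[ph]]]][i]
      if (is.finite(val) && (val < bb[[ph]][1] - tol || val > bb[[ph]][2] + tol))
        ok <- FALSE
    }
    ok
  }, NA)
  mean(inside, na.rm = TRUE)
}
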