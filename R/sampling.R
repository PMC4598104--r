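# Null-space parameterization of the steady-state flux polytope.
#
# Fixed reactions (lb == ub) are folded into the equality system together
# with S v = 0, so the chain moves only in genuinely free directions:
#   v = v0 + N t,   N an orthonormal null-space basis of the equalities,
# and the bounds plus coupling rows become inequalities G t <= h.
flux_polytope <- function(model, tol = 1e-9) {
  n <- length(model$rxns)
  Sd <- as.matrix(model$S)
  fixed <- which(model$ub - model$lb <= tol)
  E <- Sd
  f <- rep(0, nrow(Sd))
  if (length(fixed)) {
    I <- matrix(0, length(fixed), n)
    I[cbind(seq_along(fixed), fixed)] <- 1
    E <- rbind(E, I)
    f <- c(f, (model$lb[fixed] + model$ub[fixed]) / 2)
  }
  sv <- svd(E, nu = nrow(E), nv = n)
  r <- sum(sv$d > max(dim(E)) * max(sv$d) * 1e-12)
  # particular solution via pseudoinverse
  dinv <- ifelse(sv$d[seq_len(r)] > 0, 1 / sv$d[seq_len(r)], 0)
  v0 <- sv$v[, seq_len(r), drop = FALSE] %*%
    (dinv * crossprod(sv$u[, seq_len(r), drop = FALSE], f))
  v0 <- as.numeric(v0)
  N <- sv$v[, setdiff(seq_len(n), seq_len(r)), drop = FALSE]
  d <- ncol(N)
  free <- setdiff(seq_len(n), fixed)
  G <- NULL; h <- NULL
  if (d > 0) {
    Gl <- list(); hl <- list()
    for (i in free) {
      Gl[[length(Gl) + 1]] <- N[i, ]; hl[[length(hl) + 1]] <- model$ub[i] - v0[i]
      Gl[[length(Gl) + 1]] <- -N[i, ]; hl[[length(hl) + 1]] <- v0[i] - model$lb[i]
    }
    if (!is.null(model$coupling)) {
      AN <- model$coupling$A %*% N
      res <- model$coupling$b - as.vector(model$coupling$A %*% v0)
      for (k in seq_len(nrow(AN))) {
        Gl[[length(Gl) + 1]] <- AN[k, ]; hl[[length(hl) + 1]] <- res[k]
      }
    }
    G <- do.call(rbind, Gl)
    h <- unlist(hl)
    norms <- sqrt(rowSums(G^2))
    keep <- norms > tol
    if (any(!keep) && any(h[!keep] < -tol))
      stop("polytope is infeasible (contradictory fixed constraints)")
    G <- G[keep, , drop = FALSE]; h <- h[keep]
  }
  list(v0 = v0, N = N, G = G, h = h, dim = d, n = n)
}

# Warm-up points: FVA-style vertices of the polytope (LP solutions
# maximizing/minimizing each free reaction), mapped to t-space.
polytope_warmup <- function(model, poly) {
  pts <- list()
  for (i in seq_len(poly$n)) {
    if (abs(model$ub[i] - model$lb[i]) <= 1e-9) next
    obj <- numeric(poly$n); obj[i] <- 1
    for (dir in c(FALSE, TRUE)) {
      res <- solve_lp(model, obj, maximize = dir)
      if (res$status == "infeasible")
        stop("sampling polytope is infeasible (model '", model$id, "')")
      if (res$status == "optimal")
        pts[[length(pts) + 1]] <- res$v
    }
  }
  if (!length(pts)) stop("no warm-up points could be generated")
  V <- do.call(rbind, pts)
  sweep(V, 2, poly$v0) %*% poly$N   # rows are t-coordinates
}

#' Uniformly sample the steady-state flux polytope
#'
#' Asymptotically uniform samples over
#' \code{\{v : S v = 0, lb <= v <= ub, A v <= b\}} via an
#' artificial-centering hit-and-run chain run in the null-space
#' parameterization of the equality constraints. Directions are drawn
#' through previously visited points relative to the running center, which
#' adapts the step distribution to elongated polytopes — the de-facto
#' standard chain for this model class. Every retained sample is verified
#' feasible within \code{tol}.
#'
#' @param model a \code{stoich_model} (finite bounds; optional coupling).
#' @param n_samples number of retained flux distributions.
#' @param seed integer seed; the chain is reproducible under it.
#' @param settings list: \code{burnin} discarded leading steps (default
#'   1000), \code{thin} chain steps per retained sample (default 1).
#' @param tol feasibility tolerance for sample verification.
#' @return object of class \code{sample_ensemble}: list with
#'   \code{samples} (n_samples x reactions matrix), \code{model_id},
#'   \code{seed}, \code{settings}, \code{dim} (polytope dimension).
#'   A zero-dimensional polytope returns its single point replicated,
#'   with a warning.
#' @export
sample_space <- function(model, n_samples, seed = 1L,
                         settings = list(), tol = 1e-6) {
  stopifnot(n_samples >= 1)
  burnin <- if (is.null(settings$burnin)) 1000L else as.integer(settings$burnin)
  thin <- if (is.null(settings$thin)) 1L else as.integer(settings$thin)
  poly <- flux_polytope(model)
  if (poly$dim == 0) {
    if (!check_feasible(model, poly$v0, tol))
      stop("polytope is infeasible")
    warning("zero-dimensional polytope: returning its single point")
    M <- matrix(rep(poly$v0, each = n_samples), n_samples, poly$n,
                dimnames = list(NULL, model$rxns))
    return(structure(list(samples = M, model_id = model$id, seed = seed,
                          settings = list(burnin = burnin, thin = thin),
                          dim = 0L),
                     class = "sample_ensemble"))
  }
  warm <- polytope_warmup(model, poly)
  G <- poly$G; h <- poly$h
  d <- poly$dim
  withr::with_seed(seed, {
    n_steps <- burnin + n_samples * thin
    pool <- matrix(NA_real_, nrow(warm) + n_samples, d)
    pool[seq_len(nrow(warm)), ] <- warm
    n_pool <- nrow(warm)
    center <- colMeans(warm)
    x <- center
    # nudge the start strictly inside if it sits on a face
    gx <- as.vector(G %*% x)
    T_out <- matrix(NA_real_, n_samples, d)
    kept <- 0L
    for (step in seq_len(n_steps)) {
      dir <- pool[sample.int(n_pool, 1), ] - center
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-12) {
        dir <- stats::rnorm(d)
        nd <- sqrt(sum(dir^2))
      }
      dir <- dir / nd
      gd <- as.vector(G %*% dir)
      slack <- h - gx
      lam_max <- Inf; lam_min <- -Inf
      pos <- gd > 1e-12; neg <- gd < -1e-12
      if (any(pos)) lam_max <- min(slack[pos] / gd[pos])
      if (any(neg)) lam_min <- max(slack[neg] / gd[neg])
      if (!is.finite(lam_max) || !is.finite(lam_min) || lam_max < lam_min) {
        lam <- 0
      } else {
        lam <- stats::runif(1, lam_min, lam_max)
      }
      x <- x + lam * dir
      gx <- gx + lam * gd
      # periodically recompute gx to stop drift
      if (step %% 5000L == 0L) gx <- as.vector(G %*% x)
      if (step > burnin && (step - burnin) %% thin == 0L) {
        kept <- kept + 1L
        T_out[kept, ] <- x
        n_pool <- n_pool + 1L
        pool[n_pool, ] <- x
      }
      center <- center + (x - center) / (step + nrow(warm))
    }
  })
  V <- sweep(T_out %*% t(poly$N), 2, poly$v0, "+")
  colnames(V) <- model$rxns
  viol <- vapply(seq_len(nrow(V)), function(i) {
    v <- V[i, ]
    max(c(model$lb - v, v - model$ub,
          if (is.null(model$coupling)) 0 else
            as.vector(model$coupling$A %*% v) - model$coupling$b, 0))
  }, 0)
  if (max(viol) > tol)
    warning("worst sample constraint violation ", format(max(viol)),
            " exceeds tolerance ", tol)
  structure(list(samples = V, model_id = model$id, seed = seed,
                 settings = list(burnin = burnin, thin = thin), dim = d),
            class = "sample_ensemble")
}

#' @export
print.sample_ensemble <- function(x, ...) {
  cat("<sample_ensemble> ", nrow(x$samples), " samples x ",
      ncol(x$samples), " reactions (polytope dim ", x$dim, ", seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Trimmed per-reaction flux extremes
#'
#' For each reaction independently, discards the lowest and highest
#' \code{trim} fraction of sampled flux values
#' (\code{floor(n * trim)} values on each side) and returns the extremes
#' of the remainder.
#'
#' @param ensemble a \code{sample_ensemble} or a samples matrix.
#' @param trim fraction trimmed per tail, in \code{[0, 0.5)}; the default
#'   0.05 discards the top and bottom 5 percent.
#' @return data.frame with \code{reaction}, \code{v_min}, \code{v_max}.
#' @export
trimmed_extremes <- function(ensemble, trim = 0.05) {
  if (inherits(ensemble, "sample_ensemble")) ensemble <- ensemble$samples
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  n <- nrow(ensemble)
  k <- floor(n * trim)
  if (n - 2 * k < 1) stop("trimming removes every sample")
  ext <- apply(ensemble, 2, function(col) {
    s <- sort(col)
    c(s[k + 1], s[n - k])
  })
  data.frame(reaction = colnames(ensemble), v_min = ext[1, ], v_max = ext[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-reaction flux statistics: AF, FF and FCS
#'
#' From trimmed flux extremes of the constrained (shrunken) space, and
#' optionally of the original space, computes per reaction:
#' \describe{
#'   \item{AF}{average flux \code{|(v_max + v_min) / 2|}.}
#'   \item{FF}{flux fluctuation
#'     \code{|(v_max - v_min) / ((v_max + v_min) / 2)|}, the range
#'     relative to the average; flagged undefined when AF is below
#'     \code{af_tol}.}
#'   \item{FCS}{flux constraint strength
#'     \code{|(v_max - v_min) / (v_max_ori - v_min_ori)|}, the constrained
#'     range relative to the original range; small values mean the
#'     physiological bands constrain the reaction strongly. Flagged
#'     undefined when the original range is below \code{range_tol}.}
#' }
#'
#' @param extremes trimmed extremes of the constrained space
#'   (data.frame from [trimmed_extremes()]).
#' @param extremes_original trimmed extremes of the original space, same
#'   reactions; \code{NULL} skips FCS.
#' @param af_tol AF below which FF is undefined.
#' @param range_tol original range below which FCS is undefined.
#' @return data.frame with \code{reaction}, \code{v_min}, \code{v_max},
#'   \code{af}, \code{ff}, \code{ff_defined}, and (when the original
#'   space is supplied) \code{v_min_ori}, \code{v_max_ori}, \code{fcs},
#'   \code{fcs_defined}.
#' @export
compute_statistics <- function(extremes, extremes_original = NULL,
                               af_tol = 1e-9, range_tol = 1e-9) {
  out <- extremes[c("reaction", "v_min", "v_max")]
  mid <- (out$v_max + out$v_min) / 2
  rng <- out$v_max - out$v_min
  out$af <- abs(mid)
  out$ff_defined <- out$af >= af_tol
  out$ff <- ifelse(out$ff_defined, abs(rng / mid), NA_real_)
  if (!is.null(extremes_original)) {
    if (!identical(sort(extremes_original$reaction), sort(out$reaction)))
      stop("constrained and original extremes cover different reactions")
    ori <- extremes_original[match(out$reaction, extremes_original$reaction), ]
    out$v_min_ori <- ori$v_min
    out$v_max_ori <- ori$v_max
    rng_ori <- out$v_max_ori - out$v_min_ori
    out$fcs_defined <- rng_ori >= range_tol
    out$fcs <- ifelse(out$fcs_defined, abs(rng / rng_ori), NA_real_)
  }
  out
}

#' Shrunken-space sampling pipeline
#'
#' End-to-end stage: applies the physiological bands in window mode
#' (glucose uptake fluctuating within \code{window}), samples the
#' shrunken and the original solution space at equal depth, trims, and
#' computes AF/FF/FCS for the model's eligible reactions. The original
#' space retains the glucose window but not the three phenotype bands, so
#' FCS isolates the bands' effect.
#'
#' @param model a \code{stoich_model} with exchange roles mapped.
#' @param constraints a \code{phys_constraints}.
#' @param window glucose uptake window (mmol gDW^-1 h^-1).
#' @param n_samples samples per space.
#' @param trim per-tail trim fraction.
#' @param seed integer seed (the original space uses \code{seed + 1}).
#' @param settings sampler settings, see [sample_space()].
#' @param eligible_only drop ineligible reactions from the result
#'   (default) or keep them flagged.
#' @return data.frame of per-reaction statistics (see
#'   [compute_statistics()]) with \code{eligible} and \code{reason}
#'   columns; provenance (window, n_samples, trim, seed) in attributes.
#' @export
run_shrunken_pipeline <- function(model, constraints, window = c(18, 20),
                                  n_samples = 500000, trim = 0.05, seed = 1L,
                                  settings = list(), eligible_only = TRUE) {
  constrained <- apply_constraints(model, constraints, window)
  original <- model
  glc <- role_rxn(model, "glucose")
  original <- set_bounds(original, glc, lb = window[1], ub = window[2])
  for (role in c("fructose", "ethanol_uptake")) {
    id <- role_rxn(original, role, required = FALSE)
    if (!is.null(id)) original <- set_bounds(original, id, lb = 0, ub = 0)
  }
  elig <- eligible_reactions(model)
  ens_c <- sample_space(constrained, n_samples, seed = seed, settings = settings)
  ens_o <- sample_space(original, n_samples, seed = seed + 1L, settings = settings)
  stats_df <- compute_statistics(trimmed_extremes(ens_c, trim),
                                 trimmed_extremes(ens_o, trim))
  stats_df <- merge(stats_df, elig, by = "reaction", sort = FALSE)
  if (eligible_only)
    stats_df <- stats_df[stats_df$eligible, , drop = FALSE]
  rownames(stats_df) <- NULL
  structure(stats_df, window = window, n_samples = n_samples,
            trim = trim, seed = seed)
}
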