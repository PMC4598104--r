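#' Mean-normalize and average expression datasets
#'
#' Each dataset is divided by its own mean, then genes are averaged over
#' the datasets in which they appear — the consensus value used for
#' protein abundance, mRNA level and expression noise when several
#' genome-wide measurements are available.
#'
#' @param datasets list of named numeric vectors (gene -> value).
#' @return named numeric vector of per-gene consensus values.
#' @export
normalize_average <- function(datasets) {
  if (!length(datasets)) stop("at least one dataset is required")
  normed <- lapply(datasets, function(d) {
    d <- d[is.finite(d)]
    m <- mean(d)
    if (!is.finite(m) || m == 0) stop("dataset with zero or undefined mean")
    d / m
  })
  genes <- unique(unlist(lapply(normed, names)))
  if (is.null(genes)) stop("datasets must be named by gene")
  vals <- vapply(genes, function(g) {
    x <- unlist(lapply(normed, function(d) unname(d[g])))
    mean(x, na.rm = TRUE)
  }, 0)
  stats::setNames(vals, genes)
}

#' Select dosage-sensitive reaction (DSR) genes
#'
#' Genes whose protein abundance differs strongly between minimal (SD)
#' and rich (YEPD) media, \code{|log2(sd / yepd)| > cutoff}, are taken to
#' mark enzyme-dosage-sensitive reactions.
#'
#' @param expr data.frame with columns \code{gene}, \code{yepd},
#'   \code{sd} (positive abundances).
#' @param cutoff log2-ratio threshold (default 1; 0.5 and 0.7 are common
#'   sensitivity checks).
#' @return character vector of DSR gene ids.
#' @export
select_dsr <- function(expr, cutoff = 1.0) {
  if (cutoff < 0) stop("cutoff must be non-negative")
  ok <- is.finite(expr$yepd) & is.finite(expr$sd)
  d <- expr[ok, , drop = FALSE]
  if (any(d$yepd <= 0) || any(d$sd <= 0))
    stop("abundances must be positive for the log-ratio filter")
  d$gene[abs(log2(d$sd / d$yepd)) > cutoff]
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The p-value uses the
#' t-approximation for larger samples and exact enumeration over all rank
#' permutations (two-sided) for small ones (\code{n <= exact_max_n};
#' enumeration beyond n = 8 is disproportionate, see the methods
#' vignette).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param exact_max_n largest n for which the exact permutation p-value
#'   is computed.
#' @return list of class \code{correlation_result}: \code{rho}, \code{p},
#'   \code{n}, \code{method}.
#' @export
spearman_cor <- function(x, y, exact_max_n = 8) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite values")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero rank variance; correlation undefined")
  rho <- stats::cor(rx, ry)
  if (n <= exact_max_n) {
    perms <- all_permutations(n)
    # rho is affine in sum(rx * ry_perm) for fixed rank multisets
    sums <- as.vector(perms_to_sums(perms, rx, ry))
    obs <- sum(rx * ry)
    mu <- n * mean(rx) * mean(ry)
    p <- mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p = p, n = n, method = method),
            class = "correlation_result")
}

perms_to_sums <- function(perms, rx, ry) {
  # sum over i of rx[i] * ry[perm[i]] for every permutation, vectorized
  matrix(ry[perms], nrow(perms), ncol(perms)) %*% rx
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f  (p = %.4g, n = %d, %s)\n",
              x$rho, x$p, x$n, x$method))
  invisible(x)
}

#' Flux-fluctuation vs expression-noise correlation battery
#'
#' Joins per-reaction flux statistics to gene-level expression data
#' through a one gene-one reaction map and computes the Spearman
#' correlations of the analysis: FF vs DM for all mapped genes, for DSR
#' genes, and for DSR genes split by reaction essentiality (essential /
#' non-essential groups); plus AF vs mRNA level and AF vs protein
#' abundance. Genes mapped to reactions with undefined FF are dropped
#' (reported in the \code{n_dropped_ff} attribute); groups with fewer
#' than 3 genes are reported as skipped.
#'
#' @param stats per-reaction statistics (from
#'   [run_shrunken_pipeline()] or [compute_statistics()]).
#' @param expr gene-level data.frame with \code{gene}, \code{yepd},
#'   \code{sd}, \code{mrna}, \code{dm}.
#' @param map data.frame with \code{gene}, \code{reaction} and
#'   optionally \code{essentiality} (labels from [single_deletions()]);
#'   must be one-to-one.
#' @param dsr_cutoff log2-ratio cutoff for DSR selection.
#' @return data.frame with one row per analysis: \code{analysis},
#'   \code{rho}, \code{p}, \code{n}, \code{skipped}.
#' @export
ff_dm_analysis <- function(stats, expr, map, dsr_cutoff = 1.0) {
  if (anyDuplicated(map$gene) || anyDuplicated(map$reaction))
    stop("gene-reaction map must be one-to-one")
  d <- merge(map, stats, by = "reaction")
  d <- merge(d, expr, by = "gene")
  n_dropped <- sum(!d$ff_defined | !is.finite(d$ff))
  dff <- d[d$ff_defined & is.finite(d$ff), , drop = FALSE]
  dsr <- select_dsr(expr, dsr_cutoff)
  groups <- list(ff_dm_all = dff,
                 ff_dm_dsr = dff[dff$gene %in% dsr, , drop = FALSE])
  if ("essentiality" %in% names(map)) {
    groups$ff_dm_dsr_er <- dff[dff$gene %in% dsr &
                                 dff$essentiality == "essential", , drop = FALSE]
    groups$ff_dm_dsr_ner <- dff[dff$gene %in% dsr &
                                  dff$essentiality == "nonessential", , drop = FALSE]
  }
  rows <- list()
  add <- function(name, x, y) {
    ok <- sum(is.finite(x) & is.finite(y))
    if (ok < 3) {
      rows[[length(rows) + 1]] <<- data.frame(
        analysis = name, rho = NA_real_, p = NA_real_, n = ok, skipped = TRUE)
    } else {
      r <- spearman_cor(x, y)
      rows[[length(rows) + 1]] <<- data.frame(
        analysis = name, rho = r$rho, p = r$p, n = r$n, skipped = FALSE)
    }
  }
  for (nm in names(groups)) add(nm, groups[[nm]]$ff, groups[[nm]]$dm)
  add("af_mrna", d$af, d$mrna)
  protein <- normalize_average(list(stats::setNames(d$yepd, d$gene),
                                    stats::setNames(d$sd, d$gene)))
  add("af_protein", d$af, unname(protein[d$gene]))
  out <- do.call(rbind, rows)
  attr(out, "n_dropped_ff") <- n_dropped
  attr(out, "dsr_cutoff") <- dsr_cutoff
  out
}

#' Permutation test for a two-group mean difference
#'
#' The observed statistic is \code{mean(group1) - mean(group2)} under the
#' true labels (the first \code{group_sizes[1]} values form group 1). The
#' null distribution is built by shuffling the values and re-splitting
#' into the same group sizes \code{n_perm} times; reported are the null
#' mean and standard deviation, a z-score, and the two-sided empirical
#' p-value with add-one correction \code{(b + 1) / (n_perm + 1)}.
#'
#' @param values numeric vector, group 1 first.
#' @param group_sizes two positive integers summing to
#'   \code{length(values)}.
#' @param n_perm number of random relabelings (default 10000; 100000 for
#'   a high-resolution null).
#' @param seed integer seed.
#' @return list of class \code{permutation_result}: \code{observed},
#'   \code{null_mean}, \code{null_sd}, \code{z}, \code{p},
#'   \code{n_perm}, \code{seed}.
#' @export
permutation_difference_test <- function(values, group_sizes, n_perm = 10000,
                                        seed = 1L) {
  if (length(group_sizes) != 2 || any(group_sizes < 1))
    stop("group_sizes must be two positive counts")
  n <- length(values)
  if (sum(group_sizes) != n)
    stop("group sizes must sum to the number of values")
  n1 <- group_sizes[1]
  observed <- mean(values[seq_len(n1)]) - mean(values[-seq_len(n1)])
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, n1)
      mean(values[idx]) - mean(values[-idx])
    }, 0)
  })
  sdn <- stats::sd(null)
  z <- if (sdn > 0) (observed - mean(null)) / sdn else Inf * sign(observed)
  p <- (1 + sum(abs(null) >= abs(observed) - 1e-12)) / (n_perm + 1)
  structure(list(observed = observed, null_mean = mean(null), null_sd = sdn,
                 z = z, p = p, n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("observed diff = %.4f, null sd = %.4f, z = %.2f, p = %.4g (%d permutations)\n",
              x$observed, x$null_sd, x$z, x$p, x$n_perm))
  invisible(x)
}

#' Histogram of flux constraint strength
#'
#' Bins defined-FCS values into half-open bins
#' \code{[k*w, (k+1)*w)} and reports the fraction of reactions in the
#' first bin — the strongly constrained share of the network.
#'
#' @param stats per-reaction statistics with an \code{fcs} column.
#' @param bin_width positive bin width (default 0.1).
#' @return list with \code{breaks}, \code{counts}, \code{n},
#'   \code{first_bin_fraction}.
#' @export
fcs_histogram <- function(stats, bin_width = 0.1) {
  if (bin_width <= 0) stop("bin_width must be positive")
  v <- stats$fcs
  if (!is.null(stats$fcs_defined)) v <- v[stats$fcs_defined]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no defined FCS values")
  k <- floor(v / bin_width)
  kmax <- max(k)
  counts <- tabulate(k + 1L, nbins = kmax + 1L)
  list(breaks = seq(0, (kmax + 1) * bin_width, by = bin_width),
       counts = counts, n = length(v),
       first_bin_fraction = counts[1] / length(v))
}
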