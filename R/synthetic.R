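#' Configuration for the synthetic flux-phenotype generator
#'
#' Defines the ground-truth piecewise-linear phenotype relations and noise
#' levels used by [generate_flux_dataset()]. The defaults emulate aerobic
#' glucose-limited chemostat physiology of budding yeast: below the
#' respiro-fermentative transition (glucose uptake 4 mmol gDW^-1 h^-1)
#' oxygen uptake rises with glucose uptake; above it oxygen declines
#' gently while ethanol overflow grows linearly; glycerol secretion is
#' proportional to glucose uptake throughout. CO2 production is oxygen
#' uptake plus ethanol production (respiratory CO2 plus fermentative CO2,
#' giving a respiratory quotient of 1 under pure respiration), and growth
#' rate follows a two-regime yield line.
#'
#' @param n_studies number of synthetic studies (elementary datasets).
#' @param points_per_study observations per study.
#' @param glucose_range sampling interval for glucose uptake
#'   (mmol gDW^-1 h^-1), within \code{[0, 30]}.
#' @param alpha_oxy_low,intercept_oxy_low oxygen-vs-glucose line below the
#'   transition.
#' @param alpha_oxy_high,intercept_oxy_high oxygen line above the
#'   transition.
#' @param alpha_eth,intercept_eth ethanol-vs-glucose line (single slope
#'   over the full range).
#' @param alpha_gly,intercept_gly glycerol-vs-glucose line.
#' @param growth_yield_low growth slope (h^-1 per unit uptake) below the
#'   transition; above it growth is
#'   \code{growth_yield_low*transition + growth_slope_high*(v_glu - transition)}.
#' @param growth_slope_high fermentative growth slope.
#' @param noise_sd named vector of Gaussian noise standard deviations for
#'   \code{o2}, \code{co2}, \code{eth}, \code{gly}, \code{growth} (same
#'   units as the rates). Noise is truncated at 0 by resampling: rates are
#'   non-negative.
#' @param transition glucose uptake separating the two regimes.
#' @param clamp_below_transition if \code{TRUE}, ethanol and glycerol means
#'   are set to 0 below the transition (respiratory regime) instead of
#'   following their lines.
#' @param seed integer seed.
#' @return a \code{synthetic_flux_config}.
#' @export
synthetic_flux_config <- function(n_studies = 8, points_per_study = 12,
                                  glucose_range = c(0, 24),
                                  alpha_oxy_low = 2.0, intercept_oxy_low = 0.5,
                                  alpha_oxy_high = -0.2, intercept_oxy_high = 9.3,
                                  alpha_eth = 0.6, intercept_eth = 0,
                                  alpha_gly = 0.08, intercept_gly = 0,
                                  growth_yield_low = 0.06, growth_slope_high = 0.005,
                                  noise_sd = c(o2 = 0.8, co2 = 0.8, eth = 1.0,
                                               gly = 0.25, growth = 0.015),
                                  transition = 4,
                                  clamp_below_transition = TRUE,
                                  seed = 1L) {
  if (n_studies < 1 || points_per_study < 1)
    stop("n_studies and points_per_study must be positive")
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  if (glucose_range[1] < 0 || glucose_range[2] > 30 ||
      glucose_range[1] >= glucose_range[2])
    stop("glucose_range must be an increasing interval within [0, 30]")
  need <- c("o2", "co2", "eth", "gly", "growth")
  sd_full <- stats::setNames(rep(0, 5), need)
  sd_full[names(noise_sd)] <- noise_sd
  structure(list(n_studies = as.integer(n_studies),
                 points_per_study = as.integer(points_per_study),
                 glucose_range = glucose_range,
                 alpha_oxy_low = alpha_oxy_low, intercept_oxy_low = intercept_oxy_low,
                 alpha_oxy_high = alpha_oxy_high, intercept_oxy_high = intercept_oxy_high,
                 alpha_eth = alpha_eth, intercept_eth = intercept_eth,
                 alpha_gly = alpha_gly, intercept_gly = intercept_gly,
                 growth_yield_low = growth_yield_low,
                 growth_slope_high = growth_slope_high,
                 noise_sd = sd_full, transition = transition,
                 clamp_below_transition = clamp_below_transition,
                 seed = as.integer(seed)),
            class = "synthetic_flux_config")
}

# Gaussian noise truncated at zero by resampling (rates are non-negative)
trunc_noise <- function(mean, sd) {
  if (sd == 0) return(mean)
  x <- stats::rnorm(length(mean), mean, sd)
  bad <- which(x < 0)
  guard <- 0
  while (length(bad) && guard < 1000) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] < 0]
    guard <- guard + 1
  }
  x[x < 0] <- 0
  x
}

#' Generate a synthetic flux-phenotype table
#'
#' Draws multi-study chemostat observations from the piecewise-linear
#' ground truth in \code{config}, with truncated-Gaussian measurement
#' noise. The respiratory quotient is computed exactly as
#' \code{v_co2 / v_o2} from the noisy rates, so it is definitionally
#' consistent with the table. Reproducible under the config seed.
#'
#' @param config a \code{synthetic_flux_config}.
#' @return data.frame with columns \code{study_id}, \code{v_glu},
#'   \code{v_o2}, \code{v_co2}, \code{rq}, \code{v_eth}, \code{v_gly},
#'   \code{growth_rate}.
#' @export
generate_flux_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_flux_config"))
  withr::with_seed(config$seed, {
    n <- config$n_studies * config$points_per_study
    study <- rep(sprintf("study%02d", seq_len(config$n_studies)),
                 each = config$points_per_study)
    g <- stats::runif(n, config$glucose_range[1], config$glucose_range[2])
    low <- g <= config$transition
    mu_o2 <- ifelse(low,
                    config$alpha_oxy_low * g + config$intercept_oxy_low,
                    config$alpha_oxy_high * g + config$intercept_oxy_high)
    mu_eth <- config$alpha_eth * g + config$intercept_eth
    mu_gly <- config$alpha_gly * g + config$intercept_gly
    if (config$clamp_below_transition) {
      mu_eth[low] <- 0
      mu_gly[low] <- 0
    }
    mu_eth <- pmax(mu_eth, 0)
    mu_gly <- pmax(mu_gly, 0)
    mu_o2 <- pmax(mu_o2, 0)
    tm <- config$transition
    mu_gro <- ifelse(low, config$growth_yield_low * g,
                     config$growth_yield_low * tm +
                       config$growth_slope_high * (g - tm))
    v_o2 <- trunc_noise(mu_o2, config$noise_sd[["o2"]])
    v_eth <- trunc_noise(mu_eth, config$noise_sd[["eth"]])
    v_gly <- trunc_noise(mu_gly, config$noise_sd[["gly"]])
    v_co2 <- trunc_noise(v_o2 + v_eth, config$noise_sd[["co2"]])
    growth <- trunc_noise(mu_gro, config$noise_sd[["growth"]])
    data.frame(study_id = study, v_glu = g, v_o2 = v_o2, v_co2 = v_co2,
               rq = ifelse(v_o2 > 0, v_co2 / v_o2, NA_real_),
               v_eth = v_eth, v_gly = v_gly, growth_rate = growth,
               stringsAsFactors = FALSE)
  })
}

#' Generate a toy stoichiometric model
#'
#' Small hand-checkable networks used throughout testing and the worked
#' examples (stand-ins for a genome-scale reconstruction):
#' \describe{
#'   \item{chain}{a linear pathway glucose -> A -> B -> biomass; the LP
#'     optimum equals the glucose uptake bound and every reaction is
#'     essential.}
#'   \item{parallel}{two redundant routes from glucose to biomass; either
#'     branch can be deleted without changing the optimum.}
#'   \item{minicore}{a miniature central-carbon network with exchange
#'     reactions for glucose, oxygen, co2, ethanol, glycerol and biomass,
#'     a high-yield respiratory reaction (needs 2 O2 per glucose, biomass
#'     yield \code{yield_resp}), a low-yield fermentative reaction
#'     (0.8 ethanol + 0.8 co2 per glucose, yield \code{yield_ferm}), a
#'     glycerol branch, and a glucose-burning maintenance reaction that
#'     gives the network the slack a genome-scale model has. The LP
#'     optimum is computable by hand: with oxygen unlimited all glucose is
#'     respired, so max growth = \code{yield_resp * ub_glucose}.}
#' }
#'
#' @param preset \code{"chain"}, \code{"parallel"} or \code{"minicore"}.
#' @param ub_glucose glucose uptake upper bound (mmol gDW^-1 h^-1).
#' @param n_internal chain length (chain preset only).
#' @param yield_resp,yield_ferm,yield_gly biomass yields per unit glucose
#'   routed through each minicore branch (h^-1 per mmol gDW^-1 h^-1).
#' @return a \code{stoich_model}.
#' @export
generate_toy_model <- function(preset = c("chain", "parallel", "minicore"),
                               ub_glucose = 10, n_internal = 3,
                               yield_resp = 0.07, yield_ferm = 0.010,
                               yield_gly = 0.003) {
  preset <- match.arg(preset)
  big <- 1000
  if (preset == "chain") {
    if (n_internal < 1) stop("chain needs at least one internal reaction")
    mets <- paste0("M", seq_len(n_internal))
    rxns <- c("EX_glc", paste0("R", seq_len(n_internal - 1)), "EX_bio")
    if (n_internal == 1) rxns <- c("EX_glc", "EX_bio")
    S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
    S["M1", "EX_glc"] <- 1
    if (n_internal > 1)
      for (i in seq_len(n_internal - 1)) {
        S[paste0("M", i), paste0("R", i)] <- -1
        S[paste0("M", i + 1), paste0("R", i)] <- 1
      }
    S[paste0("M", n_internal), "EX_bio"] <- -1
    rules <- stats::setNames(paste0("gc", seq_along(rxns)), rxns)
    rules[c("EX_glc", "EX_bio")] <- ""
    return(stoichiometric_model(
      "toy_chain", S, lb = rep(0, length(rxns)),
      ub = c(ub_glucose, rep(big, length(rxns) - 1)),
      objective = "EX_bio", gene_rules = rules,
      exchanges = c(glucose = "EX_glc", biomass = "EX_bio")))
  }
  if (preset == "parallel") {
    mets <- c("G", "B")
    rxns <- c("EX_glc", "R_a", "R_b", "EX_bio")
    S <- matrix(0, 2, 4, dimnames = list(mets, rxns))
    S["G", "EX_glc"] <- 1
    S["G", "R_a"] <- -1; S["B", "R_a"] <- 1
    S["G", "R_b"] <- -1; S["B", "R_b"] <- 1
    S["B", "EX_bio"] <- -1
    return(stoichiometric_model(
      "toy_parallel", S, lb = rep(0, 4), ub = c(ub_glucose, big, big, big),
      objective = "EX_bio",
      gene_rules = c(R_a = "ga", R_b = "gb"),
      exchanges = c(glucose = "EX_glc", biomass = "EX_bio")))
  }
  # minicore
  mets <- c("G", "O", "C", "E", "Y", "B")
  rxns <- c("EX_glc", "EX_o2", "EX_co2", "EX_eth", "EX_gly", "EX_bio",
            "R_resp", "R_ferm", "R_glyp", "R_maint", "R_aox")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["G", "EX_glc"] <- 1
  S["O", "EX_o2"] <- 1
  S["C", "EX_co2"] <- -1
  S["E", "EX_eth"] <- -1
  S["Y", "EX_gly"] <- -1
  S["B", "EX_bio"] <- -1
  S[, "R_resp"] <- c(-1, -2, 2, 0, 0, yield_resp)
  S[, "R_ferm"] <- c(-1, 0, 0.8, 0.8, 0, yield_ferm)
  S[, "R_glyp"] <- c(-1, 0, 0, 0, 0.8, yield_gly)
  S["G", "R_maint"] <- -1
  S["O", "R_aox"] <- -1
  lb <- rep(0, length(rxns))
  ub <- c(ub_glucose, rep(big, length(rxns) - 1))
  rules <- c(R_resp = "g_resp", R_ferm = "g_ferm", R_glyp = "g_gly",
             R_maint = "gm1 or gm2", R_aox = "g_aox")
  is_ex <- grepl("^EX_", rxns)
  stoichiometric_model("toy_minicore", S, lb, ub, objective = "EX_bio",
                       gene_rules = rules,
                       exchanges = c(glucose = "EX_glc", oxygen = "EX_o2",
                                     co2 = "EX_co2", ethanol = "EX_eth",
                                     glycerol = "EX_gly", biomass = "EX_bio"),
                       is_exchange = is_ex)
}

#' Configuration for the synthetic expression/noise generator
#'
#' @param n_genes number of genes; must match the length of the flux
#'   fluctuation vector passed to [generate_expression_data()].
#' @param planted_rho target Spearman correlation between flux fluctuation
#'   and expression noise (DM) in the generating process, in \code{[-1, 1]}.
#' @param dsr_fraction fraction of genes constructed as dosage-sensitive
#'   (|log2(SD/YEPD)| > 1); exactly \code{round(n_genes * dsr_fraction)}
#'   genes pass the cutoff-1 filter.
#' @param mrna_rho planted Spearman correlation between flux fluctuation
#'   and mRNA level (loose by default; mRNA is carried for the
#'   flux-vs-expression analyses).
#' @param abundance_meanlog,abundance_sdlog log-normal parameters for
#'   protein abundance in rich medium (arbitrary units).
#' @param seed integer seed.
#' @return a \code{synthetic_expression_config}.
#' @export
synthetic_expression_config <- function(n_genes, planted_rho = 0.6,
                                        dsr_fraction = 1.0, mrna_rho = 0.3,
                                        abundance_meanlog = log(1000),
                                        abundance_sdlog = 1,
                                        seed = 1L) {
  if (abs(planted_rho) > 1) stop("|planted_rho| must be <= 1")
  if (dsr_fraction < 0 || dsr_fraction > 1) stop("dsr_fraction must be in [0, 1]")
  if (n_genes < 1) stop("n_genes must be positive")
  structure(list(n_genes = as.integer(n_genes), planted_rho = planted_rho,
                 dsr_fraction = dsr_fraction, mrna_rho = mrna_rho,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog, seed = as.integer(seed)),
            class = "synthetic_expression_config")
}

# Gaussian-copula rank construction: z1 is a deterministic normal-score
# transform of x (preserving its ranks), z2 = r*z1 + sqrt(1-r^2)*eps with
# r = 2*sin(pi*rho_s/6), the Pearson correlation whose bivariate-normal
# copula has Spearman correlation rho_s.
copula_partner <- function(x, rho_s) {
  n <- length(x)
  u <- (rank(x, ties.method = "average") - 0.5) / n
  z1 <- stats::qnorm(u)
  r <- 2 * sin(pi * rho_s / 6)
  r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
}

#' Generate a synthetic expression/noise dataset
#'
#' Builds a gene-level table whose DM (distance-to-median expression
#' noise) values follow a monotone transform of the supplied flux
#' fluctuation values plus calibrated noise, so that the Spearman
#' correlation of the generating process equals \code{planted_rho}
#' (Gaussian-copula construction). A \code{dsr_fraction} subset of genes
#' is made dosage-sensitive: their minimal/rich-medium abundance ratio
#' satisfies |log2(SD/YEPD)| > 1, all other genes < 1.
#'
#' @param ff_values per-gene non-negative flux fluctuation values.
#' @param config a \code{synthetic_expression_config} with
#'   \code{n_genes == length(ff_values)}.
#' @return data.frame with columns \code{gene}, \code{yepd}, \code{sd}
#'   (protein abundance in rich/minimal medium), \code{mrna}, \code{dm},
#'   plus a logical \code{dsr_truth} column marking the constructed
#'   dosage-sensitive genes.
#' @export
generate_expression_data <- function(ff_values, config) {
  stopifnot(inherits(config, "synthetic_expression_config"))
  if (any(!is.finite(ff_values)) || any(ff_values < 0))
    stop("ff_values must be finite and non-negative")
  n <- config$n_genes
  if (length(ff_values) != n)
    stop("length(ff_values) must equal config$n_genes")
  withr::with_seed(config$seed, {
    dm <- 0.5 * copula_partner(ff_values, config$planted_rho)
    mrna <- exp(copula_partner(ff_values, config$mrna_rho))
    yepd <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
    k <- round(n * config$dsr_fraction)
    dsr <- rep(FALSE, n)
    dsr[sample.int(n, k)] <- TRUE
    lr <- numeric(n)
    if (k > 0)
      lr[dsr] <- sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 1.2, 3)
    lr[!dsr] <- sample(c(-1, 1), n - k, replace = TRUE) * stats::runif(n - k, 0, 0.8)
    data.frame(gene = sprintf("gene%04d", seq_len(n)),
               yepd = yepd, sd = yepd * 2^lr, mrna = mrna, dm = dm,
               dsr_truth = dsr, stringsAsFactors = FALSE)
  })
}
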