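write_flux_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

test_that("flux tables are read with typed records and missing values", {
  df <- data.frame(study_id = c("s1", "s1", "s2"),
                   v_glu = c(1, 2, 3), v_o2 = c(2.5, 4.5, 6.5),
                   v_co2 = c(2.5, 4.5, 6.5), rq = c(1, 1, 1),
                   v_eth = c(0, 0, 0.5), v_gly = c(0.1, NA, 0.3),
                   growth_rate = c(0.06, 0.12, 0.18))
  got <- read_flux_table(write_flux_csv(df))
  expect_equal(nrow(got), 3)
  expect_true(is.na(got$v_gly[2]))
  expect_equal(got$v_o2, df$v_o2)
})

test_that("invalid flux tables are rejected naming the offender", {
  df <- data.frame(study_id = "s1", v_glu = -1, v_o2 = 1)
  expect_error(read_flux_table(write_flux_csv(df)), "v_glu.*row 1")
  df2 <- data.frame(study_id = "s1", v_glu = 1, oxygen = 2)
  expect_error(read_flux_table(write_flux_csv(df2)), "unknown column")
})

test_that("metabolic state classification uses the 4 mmol transition", {
  expect_equal(classify_state(3.9), "respiration")
  expect_equal(classify_state(4.1), "fermentation")
  expect_equal(classify_state(4.0), "respiration")   # boundary convention
  expect_equal(classify_state(c(0, 10)), c("respiration", "fermentation"))
  expect_error(classify_state(-0.5), "non-negative")
})

test_that("slope fitting matches the closed-form least-squares oracle", {
  rec <- data.frame(study_id = "s", v_glu = c(1, 2, 4),
                    v_o2 = NA, v_co2 = NA, rq = NA,
                    v_eth = c(0.5, 1.0, 2.0), v_gly = NA, growth_rate = NA)
  f <- fit_slope(rec, "v_eth", "full")
  expect_equal(f$alpha, 0.5, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # noisy data vs independently coded normal equations
  d <- generate_flux_dataset(synthetic_flux_config(
    n_studies = 10, points_per_study = 20, glucose_range = c(5, 24),
    noise_sd = c(eth = 0.1), clamp_below_transition = FALSE, seed = 21))
  f2 <- fit_slope(d, "v_eth", "full")
  x <- d$v_glu; y <- d$v_eth
  alpha_oracle <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  expect_equal(f2$alpha, alpha_oracle, tolerance = 1e-10)
  expect_equal(f2$intercept, mean(y) - alpha_oracle * mean(x),
               tolerance = 1e-10)

  rec$v_eth <- 2
  expect_equal(fit_slope(rec, "v_eth", "full")$alpha, 0, tolerance = 1e-12)
  expect_error(fit_slope(rec[1, ], "v_eth", "full"), "fewer than 2")
})

test_that("slope estimates are unbiased over repeated noisy datasets", {
  alphas <- vapply(1:100, function(s) {
    d <- generate_flux_dataset(synthetic_flux_config(
      n_studies = 10, points_per_study = 20, glucose_range = c(5, 24),
      alpha_eth = 0.6, noise_sd = c(eth = 1.0),
      clamp_below_transition = FALSE, seed = s))
    fit_slope(d, "v_eth", "full")$alpha
  }, 0)
  mc_se <- stats::sd(alphas) / sqrt(length(alphas))
  expect_lt(abs(mean(alphas) - 0.6), 3 * mc_se + 1e-3)
})

test_that("leave-one-study-out reports one slope per study", {
  d <- generate_flux_dataset(synthetic_flux_config(n_studies = 5, seed = 2))
  rep <- loe_validation(d, "v_eth", "full")
  expect_length(rep$slopes, 5)
  expect_named(rep$slopes, unique(d$study_id))
  expect_error(loe_validation(d[d$study_id == "study01", ], "v_eth"),
               "at least 2 studies")

  d0 <- generate_flux_dataset(synthetic_flux_config(
    n_studies = 5, noise_sd = c(o2 = 0, co2 = 0, eth = 0, gly = 0, growth = 0),
    clamp_below_transition = FALSE, seed = 2))
  rep0 <- loe_validation(d0, "v_eth", "full")
  expect_equal(unname(rep0$slopes), rep(rep0$alpha_all, 5), tolerance = 1e-9)
  expect_lt(rep0$dispersion, 1e-9)
})

test_that("omitting a planted outlier study moves the slope the most", {
  d <- generate_flux_dataset(synthetic_flux_config(
    n_studies = 6, points_per_study = 15, noise_sd = c(eth = 0.2),
    clamp_below_transition = FALSE, seed = 8))
  out <- d$study_id == "study03"
  d$v_eth[out] <- d$v_eth[out] + 2.5 * d$v_glu[out]   # corrupt one study
  rep <- loe_validation(d, "v_eth", "full")
  dev <- abs(rep$slopes - rep$alpha_all)
  expect_equal(names(which.max(dev)), "study03")
})

test_that("offset calibration follows the order-statistics rule", {
  rec <- data.frame(study_id = "s", v_glu = rep(0, 5),
                    v_o2 = NA, v_co2 = NA, rq = NA,
                    v_eth = c(-2, -1, 0, 1, 2), v_gly = NA, growth_rate = NA)
  off <- calibrate_offsets(rec, "v_eth", alpha = 0, coverage = 1.0)
  expect_equal(c(off$beta_l, off$beta_u), c(-2, 2))

  d0 <- generate_flux_dataset(synthetic_flux_config(
    noise_sd = c(o2 = 0, co2 = 0, eth = 0, gly = 0, growth = 0),
    alpha_eth = 0.5, intercept_eth = 0.3, clamp_below_transition = FALSE,
    seed = 4))
  off0 <- calibrate_offsets(d0, "v_eth", alpha = 0.5)
  expect_equal(off0$beta_l, off0$beta_u, tolerance = 1e-12)
  expect_equal(off0$beta_l, 0.3, tolerance = 1e-12)

  expect_error(calibrate_offsets(rec, "v_eth", 0, coverage = 0), "coverage")
})

test_that("calibrated bands reach the requested coverage, brute-force counted", {
  d <- generate_flux_dataset(synthetic_flux_config(
    n_studies = 10, points_per_study = 100, seed = 31))
  pc <- build_constraints(d, coverage = 0.90)
  for (ph in c("oxygen", "ethanol", "glycerol")) {
    cov <- band_coverage(pc, d, ph)
    expect_gte(cov, 0.90)
  }
  # independent brute-force count for the ethanol band
  inside <- d$v_eth >= pmax(pc$ethanol$alpha * d$v_glu + pc$ethanol$beta_l, 0) - 1e-9 &
    d$v_eth <= pmax(pc$ethanol$alpha * d$v_glu + pc$ethanol$beta_u, 0) + 1e-9
  expect_equal(band_coverage(pc, d, "ethanol"), mean(inside), tolerance = 1e-12)
})

test_that("zero-noise data recovers the configured band coefficients exactly", {
  d0 <- generate_flux_dataset(synthetic_flux_config(
    n_studies = 8, points_per_study = 30,
    noise_sd = c(o2 = 0, co2 = 0, eth = 0, gly = 0, growth = 0),
    clamp_below_transition = FALSE, seed = 17))
  pc <- build_constraints(d0)
  expect_equal(pc$o2_low$alpha, 2.0, tolerance = 1e-9)
  expect_equal(pc$o2_low$beta_l, 0.5, tolerance = 1e-9)
  expect_equal(pc$o2_high$alpha, -0.2, tolerance = 1e-9)
  expect_equal(pc$ethanol$alpha, 0.6, tolerance = 1e-9)
  expect_equal(pc$glycerol$alpha_l, 0.08, tolerance = 1e-9)
  expect_equal(pc$glycerol$alpha_u, 0.08, tolerance = 1e-9)
  expect_lt(pc$o2_high$alpha, 0)   # sign preserved from the generating truth
})

test_that("band ordering lower <= upper holds across the glucose range", {
  d <- generate_flux_dataset(synthetic_flux_config(seed = 12))
  pc <- build_constraints(d)
  for (g in seq(0, 24, by = 0.25)) {
    b <- evaluate_bounds(pc, g)
    for (ph in names(b)) expect_lte(b[[ph]][1], b[[ph]][2] + 1e-12)
  }
})

test_that("coverage of an empty or censored record set is handled", {
  d <- generate_flux_dataset(synthetic_flux_config(seed = 12))
  pc <- build_constraints(d)
  expect_warning(res <- band_coverage(pc, d[0, ]), "empty")
  expect_true(is.na(res))
  # hand-built 10-point set with exactly one point outside
  d10 <- data.frame(study_id = "h", v_glu = rep(10, 10),
                    v_o2 = NA, v_co2 = NA, rq = NA,
                    v_eth = rep(pc$ethanol$alpha * 10, 10),
                    v_gly = NA, growth_rate = NA)
  d10$v_eth[1] <- 1000
  expect_equal(band_coverage(pc, d10, "ethanol"), 0.9, tolerance = 1e-12)
})
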