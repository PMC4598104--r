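test_that("FBA on toy models matches hand values and vertex enumeration", {
  chain <- generate_toy_model("chain", ub_glucose = 10)
  expect_equal(fba(chain)$objective, 10)

  parallel <- generate_toy_model("parallel", ub_glucose = 10)
  expect_equal(fba(parallel)$objective, 10)

  mini <- generate_toy_model("minicore", ub_glucose = 24)
  obj <- fba(mini)$objective
  expect_equal(obj, 0.07 * 24, tolerance = 1e-10)
  expect_equal(obj, enum_lp_max(mini, "EX_bio"), tolerance = 1e-8)
})

test_that("FBA solutions satisfy mass balance and bounds", {
  mini <- generate_toy_model("minicore", ub_glucose = 24)
  sol <- fba(mini)
  expect_lt(max(abs(as.vector(mini$S %*% sol$fluxes))), 1e-6)
  expect_true(all(sol$fluxes >= mini$lb - 1e-6))
  expect_true(all(sol$fluxes <= mini$ub + 1e-6))
})

test_that("FBA signals infeasibility on conflicting constraints", {
  mini <- generate_toy_model("minicore")
  # force ethanol production above what bounded glucose can supply
  mini <- set_bounds(mini, "EX_glc", lb = 0, ub = 1)
  mini <- set_bounds(mini, "EX_eth", lb = 5, ub = 5)
  expect_error(fba(mini), "infeasible")
  expect_error(stoichiometric_model("bad",
                                    matrix(1, 1, 1, dimnames = list("A", "R")),
                                    lb = 2, ub = 1, objective = "R"),
               "lb > ub")
})

test_that("FVA matches vertex enumeration and brackets the FBA optimum", {
  mini <- generate_toy_model("minicore", ub_glucose = 24)
  rxns <- c("R_resp", "R_ferm", "R_glyp", "EX_o2", "EX_bio")
  got <- fva(mini, rxns)
  ref <- enum_fva(mini, rxns)
  expect_equal(got$v_min, ref$v_min, tolerance = 1e-8)
  expect_equal(got$v_max, ref$v_max, tolerance = 1e-8)

  opt <- fba(mini)$fluxes[rxns]
  expect_true(all(opt >= got$v_min - 1e-6 & opt <= got$v_max + 1e-6))
})

test_that("FVA returns the point range for a fixed reaction", {
  mini <- generate_toy_model("minicore", ub_glucose = 24)
  mini <- set_bounds(mini, "EX_gly", lb = 5, ub = 5)
  rng <- fva(mini, "EX_gly")
  expect_equal(rng$v_min, 5, tolerance = 1e-9)
  expect_equal(rng$v_max, 5, tolerance = 1e-9)

  chain <- generate_toy_model("chain", ub_glucose = 10)
  internal <- fva(chain, "R1")
  expect_equal(c(internal$v_min, internal$v_max), c(0, 10), tolerance = 1e-8)
})

test_that("deleting a zero-variability reaction leaves the optimum unchanged", {
  mini <- generate_toy_model("minicore", ub_glucose = 24)
  # with unlimited O2 the fermentation branch is never forced: check a
  # reaction whose FVA range is pinned to zero stays deletable
  mini2 <- set_bounds(mini, "EX_eth", lb = 0, ub = 0)
  rng <- fva(mini2, "R_ferm")
  expect_equal(rng$v_max, 0, tolerance = 1e-9)
  base <- fba(mini2)$objective
  ko <- set_bounds(mini2, "R_ferm", lb = 0, ub = 0)
  expect_equal(fba(ko)$objective, base, tolerance = 1e-8)
})

test_that("fixed-glucose constraints substitute band values directly", {
  mini <- generate_toy_model("minicore")
  pc <- manual_constraints(alpha_oxy_low = 1.0, beta_l_oxy = -0.1,
                           beta_u_oxy = 0.1)
  m <- apply_constraints(mini, pc, glucose = 2)
  expect_equal(unname(m$lb["EX_glc"]), 2)
  expect_equal(unname(m$ub["EX_glc"]), 2)
  expect_equal(unname(m$lb["EX_o2"]), 1.9)
  expect_equal(unname(m$ub["EX_o2"]), 2.1)
  expect_equal(unname(m$lb["EX_eth"]), 0.6 * 2 - 0.5)
  expect_equal(unname(m$ub["EX_gly"]), 0.1 * 2)
})

test_that("oxygen lower bound is floored at the minimal respiration rate", {
  mini <- generate_toy_model("minicore")
  pc <- manual_constraints(alpha_oxy_low = 0.01, beta_l_oxy = -0.015,
                           beta_u_oxy = 2)
  m <- apply_constraints(mini, pc, glucose = 2)   # band lb = 0.005
  expect_equal(unname(m$lb["EX_o2"]), 0.016)
})

test_that("window-mode coupling inequalities hold for every sampled point", {
  mini <- generate_toy_model("minicore", ub_glucose = 24)
  pc <- manual_constraints(alpha_oxy_high = -0.2, beta_l_oxy_high = 8,
                           beta_u_oxy_high = 10.6,
                           beta_l_eth = -1.5, beta_u_eth = 2)
  m <- apply_constraints(mini, pc, glucose = c(18, 20))
  ens <- sample_space(m, 500, seed = 42, settings = list(burnin = 200))
  V <- ens$samples
  g <- V[, "EX_glc"]
  expect_true(all(g >= 18 - 1e-6 & g <= 20 + 1e-6))
  expect_true(all(V[, "EX_o2"] >= -0.2 * g + 8 - 1e-6))
  expect_true(all(V[, "EX_o2"] <= -0.2 * g + 10.6 + 1e-6))
  expect_true(all(V[, "EX_eth"] >= 0.6 * g - 1.5 - 1e-6))
  expect_true(all(V[, "EX_eth"] <= 0.6 * g + 2 + 1e-6))
  expect_true(all(V[, "EX_gly"] >= 0.05 * g - 1e-6))
  expect_true(all(V[, "EX_gly"] <= 0.1 * g + 1e-6))
})

test_that("window straddling the metabolic transition is rejected", {
  mini <- generate_toy_model("minicore")
  pc <- manual_constraints()
  expect_error(apply_constraints(mini, pc, glucose = c(3, 5)), "transition")
})

test_that("single deletions label chain, parallel and branched networks", {
  chain <- generate_toy_model("chain", ub_glucose = 10)
  del <- single_deletions(chain)
  expect_true(all(del$label == "essential"))

  parallel <- generate_toy_model("parallel")
  del <- single_deletions(parallel)
  expect_equal(del$label[del$reaction %in% c("R_a", "R_b")],
               c("nonessential", "nonessential"))

  # minicore: fermentation is a lower-yield alternative to respiration,
  # so knocking out respiration leaves partial growth
  mini <- generate_toy_model("minicore", ub_glucose = 24)
  del <- single_deletions(mini)
  lab <- setNames(del$label, del$reaction)
  expect_equal(unname(lab["R_resp"]), "partial")
  expect_equal(unname(lab["EX_bio"]), "essential")
  expect_equal(unname(lab["R_ferm"]), "nonessential")
  expect_equal(unname(lab["R_maint"]), "nonessential")
})

test_that("eligibility excludes isozymes, complexes, reversibles and loops", {
  mini <- generate_toy_model("minicore")
  el <- eligible_reactions(mini)
  rs <- setNames(el$reason, el$reaction)
  expect_equal(unname(rs["R_maint"]), "isozyme")   # "gm1 or gm2"
  expect_true(all(rs[c("R_resp", "R_ferm", "R_glyp", "R_aox")] == "ok"))
  expect_true(all(rs[grep("^EX_", names(rs))] == "no_gene"))

  # reversible and complex rules
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("in", "out")))
  m2 <- stoichiometric_model("rv", S, lb = c(-10, 0), ub = c(10, 10),
                             objective = "out",
                             gene_rules = c(`in` = "g1", out = "g2 and g3"))
  el2 <- eligible_reactions(m2)
  expect_equal(el2$reason[el2$reaction == "in"], "reversible")
  expect_equal(el2$reason[el2$reaction == "out"], "complex")

  # a two-reaction internal cycle is flagged by closed-exchange FVA
  S3 <- matrix(0, 2, 4, dimnames = list(c("A", "B"),
                                        c("EX_in", "EX_out", "fwd", "back")))
  S3["A", "EX_in"] <- 1; S3["B", "EX_out"] <- -1
  S3["A", "fwd"] <- -1; S3["B", "fwd"] <- 1
  S3["B", "back"] <- -1; S3["A", "back"] <- 1
  loopy <- stoichiometric_model("loopy", S3, lb = rep(0, 4),
                                ub = c(10, 10, 1000, 1000),
                                objective = "EX_out",
                                gene_rules = c(fwd = "gf", back = "gb"))
  el3 <- eligible_reactions(loopy)
  expect_equal(el3$reason[el3$reaction %in% c("fwd", "back")],
               c("loop", "loop"))
})
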