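test_that("formula parsing and degree of reduction match hand counts", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("C4H7O2"), c(C = 4, H = 7, O = 2))
  expect_equal(parse_formula("H"), c(C = 0, H = 1, O = 0))
  expect_error(parse_formula("C6N2"), "unsupported element")

  sp <- species_table()
  expect_equal(sp["glucose", "gamma"], 24)
  expect_equal(sp["butyrate", "gamma"], 20)
  expect_equal(sp["acetate", "gamma"], 8)
  expect_equal(sp["H2", "gamma"], 2)
  expect_equal(sp["CO2", "gamma"], 0)
  expect_equal(sp["H2O", "gamma"], 0)
  expect_equal(sp["H+", "gamma"], 0)
})

test_that("balance family equals the hand-derived closed form across b", {
  for (b in seq(0, 2, by = 0.05)) {
    bal <- build_balance_family(b)
    oracle <- oracle_family(b)
    oracle <- oracle[abs(oracle) > 0 | names(oracle) == "glucose"]
    expect_equal(coef(bal)[names(oracle)], oracle, tolerance = 1e-12,
                 info = paste("b =", b))
  }
})

test_that("family members are elementally and electronically balanced", {
  for (b in seq(0, 2, by = 0.1)) {
    chk <- balance_check(build_balance_family(b))
    expect_true(attr(chk, "ok"), info = paste("b =", b))
    resid <- oracle_residuals(as.list(coef(build_balance_family(b))))
    expect_true(all(abs(resid) < 1e-9))
  }
})

test_that("butyrate yields outside [0, 2] are rejected", {
  expect_error(build_balance_family(-0.1), "\\[0, 2\\]")
  expect_error(build_balance_family(2.3), "\\[0, 2\\]")
})

test_that("balance_check reports per-element residuals of broken reactions", {
  bal <- build_balance_family(1)
  cf <- coef(bal)
  cf["H2"] <- cf["H2"] + 1
  chk <- balance_check(fermentation_balance(cf))
  expect_false(attr(chk, "ok"))
  expect_equal(unname(chk["H"]), 2)
  expect_equal(unname(chk["electron"]), 2)
  expect_equal(unname(chk["C"]), 0)

  homolactate <- fermentation_balance(c(glucose = -1, lactate = 2, `H+` = 2))
  expect_true(attr(balance_check(homolactate), "ok"))

  expect_error(fermentation_balance(c(glucose = -1, pyruvate = 2)),
               "unknown species")
})

test_that("homolactate flux solution: 2 ATP, no hydrogenase flux", {
  sol <- solve_fluxes(branch_params(lactate_fraction = 1))
  expect_true(sol$feasible)
  expect_equal(sol$atp_glycolysis, 2)
  expect_equal(sol$nadh_glycolysis, 2)
  expect_equal(sol$atp_yield, 2)
  expect_equal(unname(sol$fluxes["hydrogenase"]), 0)
  expect_equal(unname(coef(sol$net_balance)["lactate"]), 2)
})

test_that("pure butyrate fermentation matches the b = 1 family member", {
  sol <- solve_fluxes(branch_params(lactate_fraction = 0, pfl_fraction = 0,
                                    butyrate_fraction = 1,
                                    rnf_atp_per_fd = 0.5))
  expect_true(sol$feasible)
  expect_equal(unname(sol$fluxes["rnf"]), 1)
  expect_equal(unname(sol$fluxes["hydrogenase"]), 2)
  expect_equal(sol$atp_yield, 3 + 0.5)
  fam <- coef(build_balance_family(1))
  net <- coef(sol$net_balance)
  for (nm in union(names(fam), names(net))) {
    a <- if (nm %in% names(fam)) fam[[nm]] else 0
    b <- if (nm %in% names(net)) net[[nm]] else 0
    expect_equal(a, b, tolerance = 1e-12, info = nm)
  }
})

test_that("NADH balance infeasibility is reported, not patched", {
  sol <- solve_fluxes(branch_params(butyrate_fraction = 0))
  expect_false(sol$feasible)
  expect_equal(sol$violated, "NADH")
  expect_error(net_acetate_sign(sol), "infeasible")

  ok <- solve_fluxes(branch_params(butyrate_fraction = 0,
                                   allow_nadh_to_h2 = TRUE))
  expect_true(ok$feasible)
  expect_equal(unname(ok$fluxes["nadh_to_h2"]), 2)
})

test_that("flux net balance reproduces the family whenever lactate and PFL are off", {
  for (beta in seq(0, 1, by = 0.1)) {
    sol <- solve_fluxes(branch_params(butyrate_fraction = beta,
                                      allow_nadh_to_h2 = TRUE))
    expect_true(sol$feasible)
    b <- unname(coef(sol$net_balance)["butyrate"])
    if (is.na(b)) b <- 0
    expect_equal(b, beta, tolerance = 1e-12)
    fam <- coef(build_balance_family(beta))
    net <- coef(sol$net_balance)
    for (nm in union(names(fam), names(net))) {
      a <- if (nm %in% names(fam)) fam[[nm]] else 0
      v <- if (nm %in% names(net)) net[[nm]] else 0
      expect_equal(a, v, tolerance = 1e-9,
                   info = paste("beta =", beta, nm))
    }
  }
})

test_that("ATP yield is non-increasing in the lactate fraction", {
  for (beta in c(0.3, 0.7, 1)) {
    atp <- vapply(seq(0, 1, by = 0.05), function(lam) {
      solve_fluxes(branch_params(lactate_fraction = lam,
                                 butyrate_fraction = beta,
                                 allow_nadh_to_h2 = TRUE))$atp_yield
    }, numeric(1))
    expect_true(all(diff(atp) <= 1e-12), info = paste("beta =", beta))
  }
})

test_that("internal metabolites are conserved for random branch parameters", {
  S <- flux_stoichiometry()
  set.seed(42)
  n_feasible <- 0
  for (i in 1:1000) {
    params <- branch_params(lactate_fraction = runif(1),
                            pfl_fraction = runif(1),
                            butyrate_fraction = runif(1),
                            rnf_atp_per_fd = runif(1, 0, 1),
                            allow_nadh_to_h2 = runif(1) < 0.5)
    sol <- solve_fluxes(params)
    if (!sol$feasible) next
    n_feasible <- n_feasible + 1
    resid <- S[, names(sol$fluxes)] %*% sol$fluxes
    expect_true(max(abs(resid)) < 1e-9)
    expect_true(all(sol$fluxes >= -1e-12))
    expect_true(attr(balance_check(sol$net_balance), "ok"))
  }
  expect_gt(n_feasible, 500)
})

test_that("net acetate sign crosses from product to substrate at b = 1", {
  expect_equal(net_acetate_sign(build_balance_family(0.5)), "product")
  expect_equal(net_acetate_sign(build_balance_family(1)), "zero")
  expect_equal(net_acetate_sign(build_balance_family(1.5)), "substrate")
  sol <- solve_fluxes(branch_params(butyrate_fraction = 0.5,
                                    allow_nadh_to_h2 = TRUE))
  expect_equal(net_acetate_sign(sol), "product")
})

test_that("balances render, serialize and add correctly", {
  bal <- build_balance_family(1)
  expect_match(reaction_string(bal), "glucose -> butyrate \\+ 2 CO2 \\+ 2 H2")
  path <- withr::local_tempfile(fileext = ".csv")
  write_balance(bal, path)
  again <- read_balance(path)
  expect_equal(sort(names(coef(again))), sort(names(coef(bal))))
  expect_equal(coef(again)[names(coef(bal))], coef(bal))

  doubled <- bal + bal
  expect_equal(unname(coef(doubled)["glucose"]), -2)
  expect_true(attr(balance_check(doubled), "ok"))
})
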