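test_that("the 5-species toy satisfies detailed balance against a root-finding oracle", {
  toy <- make_toy_reversible_5species()
  rre <- build_rre(toy$network)
  cs <- condition_set(T = profile_fixed(300), t_end = 300, tau_r = 50)
  c0 <- c(A = 1, B = 0.8)
  sim <- sim_params(c0 = c0, rtol = 1e-11, atol = 1e-15)
  sol <- solve_continuous(rre, cs, toy$calculator, sim)
  cf <- sol$conc[nrow(sol$conc), ]

  # detailed-balance ratios equal k_i / k_-i
  expect_equal(unname(cf["C"] / (cf["A"] * cf["B"])), 2 / 1, tolerance = 1e-5)
  expect_equal(unname(cf["D"] / cf["C"]), 1 / 0.5, tolerance = 1e-5)
  expect_equal(unname(cf["E"] / (cf["D"] * cf["A"])), 1.5 / 0.75, tolerance = 1e-5)

  # independent oracle: solve the equilibrium equations (3 detailed-balance
  # conditions + 2 conservation laws) by direct minimisation
  obj <- function(logc) {
    c_ <- exp(logc)
    names(c_) <- c("A", "B", "C", "D", "E")
    r <- c(
      c_["C"] - 2 * c_["A"] * c_["B"],
      c_["D"] - 2 * c_["C"],
      c_["E"] - 2 * c_["D"] * c_["A"],
      (c_["A"] + c_["C"] + c_["D"] + 2 * c_["E"]) - 1,        # X total
      (c_["B"] + c_["C"] + c_["D"] + c_["E"]) - 0.8           # Y total
    )
    sum(r^2)
  }
  opt <- stats::optim(log(rep(0.2, 5)), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))
  oracle <- exp(opt$par)
  expect_lt(opt$value, 1e-10)   # residual ~3e-7 -> oracle well inside 1e-5
  expect_equal(unname(cf), unname(oracle), tolerance = 1e-5)
})

test_that("the irreversible toy conserves what it converts", {
  toy <- make_toy_reversible_5species(km1 = 0, km2 = 0, km3 = 0)
  expect_length(toy$network$reactions, 3)
  rre <- build_rre(toy$network)
  cs <- condition_set(T = profile_fixed(300), t_end = 50, tau_r = 10)
  sim <- sim_params(c0 = c(A = 1, B = 0.6), rtol = 1e-10, atol = 1e-14)
  sol <- solve_continuous(rre, cs, toy$calculator, sim)
  cf <- sol$conc[nrow(sol$conc), ]
  # consumed A + B reappears in C, D, E per stoichiometry (element totals)
  expect_lt(max(sol$element_drift), 1e-6)
  expect_equal(unname(cf["A"] + cf["C"] + cf["D"] + 2 * cf["E"]), 1, tolerance = 1e-6)
})

test_that("scaling all rates by 10 and time by 1/10 leaves trajectories unchanged", {
  base <- make_toy_reversible_5species()
  fast <- make_toy_reversible_5species(k1 = 20, k2 = 10, k3 = 15,
                                       km1 = 10, km2 = 5, km3 = 7.5)
  rre <- build_rre(base$network)
  c0 <- c(A = 1, B = 0.8)
  s_base <- solve_continuous(rre, condition_set(T = profile_fixed(300), t_end = 40,
                                                tau_r = 10),
                             base$calculator,
                             sim_params(c0 = c0, rtol = 1e-11, atol = 1e-15, n_out = 41L))
  s_fast <- solve_continuous(rre, condition_set(T = profile_fixed(300), t_end = 4,
                                                tau_r = 1),
                             fast$calculator,
                             sim_params(c0 = c0, rtol = 1e-11, atol = 1e-15, n_out = 41L))
  expect_equal(s_fast$conc, s_base$conc, tolerance = 1e-7)
})

test_that("the surrogate assigns finite parameters to every C/H reaction", {
  net <- make_ethane_core_network()
  tab <- make_hydrocarbon_surrogate_rates(net)
  expect_identical(nrow(tab), n_reactions(net))
  expect_true(all(is.finite(tab$Ea)) && all(tab$Ea >= 0))
  expect_true(all(tab$A > 0))
  # table lookups and conventions
  expect_equal(tab$Ea[tab$key == "CC>>[CH3].[CH3]"], 348e3)
  expect_equal(tab$Ea[tab$key == "[CH3].[CH3]>>CC"], 0)

  # totality over a freshly sampled network
  ex <- explore_direct(chem_system(list("CC")),
                       direct_explore_params(radius = 6, maxiters = 4,
                                             rxn_convergence_threshold = 4,
                                             parallel_runs = 1), seed = 11)
  tab2 <- suppressWarnings(make_hydrocarbon_surrogate_rates(ex$network))
  expect_identical(nrow(tab2), n_reactions(ex$network))
  expect_true(all(is.finite(tab2$Ea)) && all(tab2$A > 0))
})

test_that("the ethane double-ramp demo shows net decomposition at peak temperature", {
  net <- make_ethane_core_network()
  dr <- profile_double_ramp(300, 70, -70, 0, 10, 15, 25)
  cs <- condition_set(T = dr, t_end = 30, tau_r = 0.1)
  sim <- sim_params(c0 = c(CC = 1), rtol = 1e-10, atol = 1e-14, n_out = 301L)
  sol <- solve_discrete(build_rre(net), cs, surrogate_calculator_factory()(net), sim)
  i_peak <- which.min(abs(sol$times - 12.5))
  expect_lt(sol$conc[i_peak, "CC"], sol$conc[1, "CC"])
  expect_lt(max(sol$element_drift), 1e-6)
})

test_that("random stiff networks are reproducible and exercise stiff solvers", {
  a <- make_random_stiff_crn(20, 40, 8, seed = 3)
  b <- make_random_stiff_crn(20, 40, 8, seed = 3)
  expect_identical(network_keys(a$network), network_keys(b$network))
  expect_identical(a$k, b$k)

  # span 0: all rate constants equal
  flat <- make_random_stiff_crn(10, 12, 0, seed = 5)
  expect_true(all(flat$k == flat$k[1]))

  # the BDF-family solver completes; a fixed-step explicit RK integrator at
  # the same budget cannot resolve the fast modes
  rre <- build_rre(a$network)
  cs <- condition_set(T = profile_fixed(300), t_end = 5, tau_r = 1)
  c0 <- stats::setNames(1, "S01")
  stiff <- solve_continuous(rre, cs, a$calculator,
                            sim_params(c0 = c0, rtol = 1e-8, atol = 1e-12))
  expect_lt(max(stiff$element_drift), 1e-6)
  rk <- tryCatch(
    suppressWarnings(solve_continuous(rre, cs, a$calculator,
                     sim_params(c0 = c0, rtol = 1e-8, atol = 1e-12, solver = "rk4"))),
    error = function(e) NULL)
  failed <- is.null(rk) || any(!is.finite(rk$conc)) || max(rk$element_drift) > 1e-6
  expect_true(failed)
})
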