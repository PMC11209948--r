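toy_ab <- function(k1 = 2, km1 = 1) {
  sp <- list(A = abstract_species("A", c(X = 1)), B = abstract_species("B", c(X = 1)))
  net <- reaction_network()
  net <- add_reactions(net, list(reaction("A", "B"), reaction("B", "A")), sp)$net
  list(net = net, calc = calc_static(c(k1, km1)))
}

test_that("build_rre assembles mass-action stoichiometry and Jacobian", {
  sp <- list(A = abstract_species("A", c(X = 1)), B = abstract_species("B", c(X = 1)))
  net <- add_reactions(reaction_network(), list(reaction("A", "B")), sp)$net
  rre <- build_rre(net)
  k <- 3
  expect_equal(rre$rhs(0, c(A = 2, B = 0), k), c(-6, 6))
  expect_equal(unname(rre$jac(0, c(A = 2, B = 0), k)),
               rbind(c(-3, 0), c(3, 0)))

  # A + A -> B carries the stoichiometric factor 2
  spb <- list(A = abstract_species("A", c(X = 1)), B = abstract_species("B", c(X = 2)))
  net2 <- add_reactions(reaction_network(), list(reaction(c("A", "A"), "B")), spb)$net
  rre2 <- build_rre(net2)
  kk <- 5
  cA <- 0.7
  expect_equal(rre2$rhs(0, c(A = cA, B = 0), kk)[1], -2 * kk * cA^2)
  # ... and the rate law itself is quadratic
  expect_equal(rre2$rates_of(c(A = cA, B = 0), kk), kk * cA^2)

  bad <- list(reaction("A", "Z"))
  expect_error(build_rre(add_reactions(reaction_network(), bad,
                                       c(sp, list(Z = abstract_species("Z", c(X = 1)))))$net),
               NA)  # Z defined: fine
})

test_that("the analytic Jacobian matches finite differences on a random toy network", {
  set.seed(14)
  toy <- make_toy_reversible_5species(k1 = 1.7, k2 = 0.6, k3 = 2.2,
                                      km1 = 0.9, km2 = 1.3, km3 = 0.4)
  rre <- build_rre(toy$network)
  k <- unname(toy$k)
  conc <- runif(5, 0.1, 2)
  names(conc) <- rre$species
  J <- rre$jac(0, conc, k)
  h <- 1e-6
  Jfd <- matrix(0, 5, 5)
  for (m in 1:5) {
    cp <- conc; cp[m] <- cp[m] + h
    cm_ <- conc; cm_[m] <- cm_[m] - h
    Jfd[, m] <- (rre$rhs(0, cp, k) - rre$rhs(0, cm_, k)) / (2 * h)
  }
  expect_lt(max(abs(J - Jfd)), 1e-6)
})

test_that("A<=>B relaxes to the closed-form equilibrium", {
  toy <- toy_ab(2, 1)
  rre <- build_rre(toy$net)
  cs <- condition_set(T = profile_fixed(300), t_end = 30, tau_r = 1)
  sim <- sim_params(c0 = c(A = 1), rtol = 1e-10, atol = 1e-14)
  sol <- solve_continuous(rre, cs, toy$calc, sim)
  cf <- sol$conc[nrow(sol$conc), ]
  expect_equal(unname(cf["A"]), 1 / 3, tolerance = 1e-6)
  expect_equal(unname(cf["B"]), 2 / 3, tolerance = 1e-6)
  # steady state: vanishing time derivative at t_end
  expect_lt(max(abs(rre$rhs(0, cf, c(2, 1)))), 1e-8 * max(cf))
  # c_max bookkeeping equals the max over the output grid
  expect_equal(sol$c_max, apply(sol$conc, 2, max))
})

test_that("a time-dependent first-order decay matches its quadrature solution", {
  # A -> B with Arrhenius k(T(t)) on a linear temperature ramp:
  # c_A(t) = exp(-Int_0^t k(T(s)) ds), evaluated by adaptive quadrature
  sp <- list(A = abstract_species("A", c(X = 1)), B = abstract_species("B", c(X = 1)))
  net <- add_reactions(reaction_network(), list(reaction("A", "B")), sp)$net
  rre <- build_rre(net)
  Ea <- 40e3; A <- 200
  calc <- calc_arrhenius(arrhenius_params(Ea, A))
  ramp <- profile_linear(300, 900, 60)      # 10 s ramp
  cs <- condition_set(T = ramp, t_end = 10, tau_r = 0.1)
  sim <- sim_params(c0 = c(A = 1), rtol = 1e-11, atol = 1e-15, n_out = 21L)
  sol <- solve_continuous(rre, cs, calc, sim)
  kT <- function(s) A * exp(-Ea / (8.314462618 * (300 + 60 * s)))
  for (tq in c(2.5, 5, 10)) {
    expected <- exp(-stats::integrate(kT, 0, tq, rel.tol = 1e-12)$value)
    got <- sol$conc[which.min(abs(sol$times - tq)), "A"]
    expect_equal(unname(got), expected, tolerance = 1e-6)
  }
})

test_that("discrete rate updates converge to the continuous solution", {
  toy <- toy_ab()
  rre <- build_rre(toy$net)
  calc <- calc_arrhenius(arrhenius_params(Ea = c(60e3, 65e3), A = c(5e3, 1e3)))
  dr <- profile_double_ramp(300, 70, -70, 0, 10, 15, 25)
  sim <- sim_params(c0 = c(A = 1), rtol = 1e-10, atol = 1e-14, n_out = 61L)
  cont <- solve_continuous(rre, condition_set(T = dr, t_end = 30, tau_r = 1),
                           calc, sim)
  final_c <- cont$conc[nrow(cont$conc), ]
  devs <- vapply(c(100, 300, 1000), function(nstop) {
    cs <- condition_set(T = dr, t_end = 30, tau_r = 30 / nstop)
    disc <- solve_discrete(rre, cs, calc, sim)
    final_d <- disc$conc[nrow(disc$conc), ]
    max(abs(final_d - final_c) / pmax(abs(final_c), 1e-12))
  }, 0)
  expect_lt(devs[3], 1e-3)
  # shrinking tau_r never increases the deviation (within solver noise)
  expect_true(all(diff(devs) <= 1e-12))

  # constant conditions: both formalisms agree to solver tolerance
  cs_fix <- condition_set(T = profile_fixed(800), t_end = 5, tau_r = 0.5)
  c1 <- solve_continuous(rre, cs_fix, calc, sim)
  c2 <- solve_discrete(rre, cs_fix, calc, sim)
  expect_equal(c2$conc[nrow(c2$conc), ], c1$conc[nrow(c1$conc), ], tolerance = 1e-8)
})

test_that("with coarse rate updates each inter-stop span relaxes to a static steady state", {
  toy <- toy_ab()
  rre <- build_rre(toy$net)
  calc <- calc_arrhenius(arrhenius_params(Ea = c(30e3, 45e3), A = c(1e7, 5e8)))
  ramp <- profile_linear(300, 900, 120)     # 5 s ramp
  cs <- condition_set(T = ramp, t_end = 5, tau_r = 2.5)   # very coarse
  sim <- sim_params(c0 = c(A = 1), rtol = 1e-10, atol = 1e-14, n_out = 401L)
  sol <- solve_discrete(rre, cs, calc, sim)
  # just before the t = 2.5 stop, the trajectory sits at the static-k
  # steady state of the segment-opening rates (T at t = 0)
  k_seg <- arrhenius_k(arrhenius_params(c(30e3, 45e3), c(1e7, 5e8)), 300)
  eqA <- k_seg[2] / (k_seg[1] + k_seg[2])
  before_stop <- sol$conc[max(which(sol$times < 2.5)), "A"]
  expect_equal(unname(before_stop), unname(eqA), tolerance = 1e-4)
})

test_that("chunked accumulation reproduces the unchunked solution", {
  toy <- toy_ab()
  rre <- build_rre(toy$net)
  calc <- calc_arrhenius(arrhenius_params(Ea = c(60e3, 65e3), A = c(5e3, 1e3)))
  dr <- profile_double_ramp(300, 70, -70, 0, 10, 15, 25)
  cs <- condition_set(T = dr, t_end = 30, tau_r = 0.1)
  rtol <- 1e-10
  sim1 <- sim_params(c0 = c(A = 1), rtol = rtol, atol = 1e-14, n_out = 31L)
  unchunked <- solve_discrete(rre, cs, calc, sim1)
  # one chunk spanning the whole run equals the unchunked call
  sim_one <- sim_params(c0 = c(A = 1), rtol = rtol, atol = 1e-14, n_out = 31L,
                        tau_c = 30)
  one <- solve_discrete(rre, cs, calc, sim_one)
  expect_equal(one$conc[nrow(one$conc), ], unchunked$conc[nrow(unchunked$conc), ],
               tolerance = 1e-12)
  # ten chunks agree within 10 * rtol
  sim10 <- sim_params(c0 = c(A = 1), rtol = rtol, atol = 1e-14, n_out = 31L,
                      tau_c = 3)
  ten <- solve_discrete(rre, cs, calc, sim10)
  expect_equal(ten$conc[nrow(ten$conc), ], unchunked$conc[nrow(unchunked$conc), ],
               tolerance = 10 * rtol)
  # concentrations are continuous across chunk boundaries (strictly increasing grid)
  expect_true(all(diff(ten$times) > 0))
})

test_that("the global-to-local stop mapping is exact", {
  tau_c <- 0.25
  m <- chunk_local_time(2.5 * tau_c, tau_c)
  expect_identical(m$n_c, 2L)
  expect_equal(m$t_local, 0.5 * tau_c)
  # identity holds exactly for a batch of awkward times
  ts <- c(0, 0.1, 0.25, 0.3749999, 1.75, 10)
  mm <- chunk_local_time(ts, tau_c)
  expect_identical(mm$n_c * tau_c + mm$t_local, ts)
})

test_that("pruning removes only sub-precision reactions and is solution-safe", {
  rtol <- 1e-8
  t_end <- 10
  sp <- list(A = abstract_species("A", c(X = 1)), B = abstract_species("B", c(X = 1)),
             C = abstract_species("C", c(X = 1)), Dd = abstract_species("Dd", c(X = 1)))
  net <- reaction_network()
  net <- add_reactions(net, list(reaction("A", "B"), reaction("B", "A"),
                                 reaction("B", "C"), reaction("B", "Dd")), sp)$net
  # c_max_prune defaults to 2 * c0 = 2; engineered rates around the threshold
  k_cut <- rtol / (2 * t_end)
  k <- c(2, 1, 0.1 * k_cut, 10 * k_cut)
  calc <- calc_static(k)
  cs <- condition_set(T = profile_fixed(300), t_end = t_end, tau_r = 1)
  sim <- sim_params(c0 = c(A = 1), rtol = rtol, atol = 1e-14)
  pruned <- prune_slow(net, calc, cs, sim)
  expect_identical(attr(pruned, "pruned_keys"), "B>>C")
  expect_setequal(network_keys(pruned), c("A>>B", "B>>A", "B>>Dd"))

  # a zero-rate reaction is always pruned
  calc0 <- calc_static(c(2, 1, 0, 10 * k_cut))
  expect_true("B>>C" %in% attr(prune_slow(net, calc0, cs, sim), "pruned_keys"))

  # retained species' final concentrations shift by < 10 * rtol
  full_rre <- build_rre(net)
  sol_full <- solve_continuous(full_rre, cs, calc, sim)
  pruned_rre <- build_rre(pruned)
  calc_p <- calc_static(k[match(network_keys(pruned),
                                vapply(net$reactions, `[[`, "", "key"))])
  # align rates to the pruned network's reaction order
  keys_p <- vapply(pruned$reactions, `[[`, "", "key")
  calc_p <- calc_static(k[match(keys_p, vapply(net$reactions, `[[`, "", "key"))])
  sol_p <- solve_continuous(pruned_rre, cs, calc_p, sim)
  for (s in pruned_rre$species) {
    a <- sol_full$conc[nrow(sol_full$conc), s]
    b <- sol_p$conc[nrow(sol_p$conc), s]
    expect_lt(abs(a - b) / max(abs(a), 1e-12), 10 * rtol)
  }
})

test_that("solutions respect conservation and non-negativity", {
  toy <- make_toy_reversible_5species()
  rre <- build_rre(toy$network)
  cs <- condition_set(T = profile_fixed(300), t_end = 100, tau_r = 10)
  sim <- sim_params(c0 = c(A = 1, B = 0.8), rtol = 1e-10, atol = 1e-14)
  sol <- solve_continuous(rre, cs, toy$calculator, sim)
  expect_lt(max(sol$element_drift), 1e-6)
  expect_gte(min(sol$conc), -sim$atol)
  expect_true(all(diff(sol$times) > 0))
})

test_that("solution tables and plots are well-formed", {
  toy <- toy_ab()
  rre <- build_rre(toy$net)
  cs <- condition_set(T = profile_fixed(400), t_end = 2, tau_r = 0.2)
  sim <- sim_params(c0 = c(A = 1), rtol = 1e-8, atol = 1e-12, n_out = 11L)
  sol <- solve_continuous(rre, cs, toy$calc, sim)
  td <- tidy(sol)
  expect_identical(nrow(td), 2L * 11L)
  expect_named(td, c("time", "species", "conc"))
  gl <- glance(sol)
  expect_identical(gl$n_species, 2L)
  p <- autoplot(sol)
  expect_s3_class(p, "ggplot")
  pc <- plot_conditions(solve_profiles(cs))
  expect_s3_class(pc, "ggplot")
  path <- withr::local_tempfile(fileext = ".csv")
  write_solution(sol, path)
  df <- utils::read.csv(path, check.names = FALSE)
  expect_named(df, c("time", "A", "B", "cond_T"))
})
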