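test_that("direct exploration of H2 converges to the enumerable network", {
  sys <- chem_system(list("[H][H]"))
  ex <- explore_direct(sys, direct_explore_params(radius = 10, maxiters = 50,
                                                  rxn_convergence_threshold = 3,
                                                  parallel_runs = 2),
                       seed = 1)
  expect_true(ex$converged)
  expect_identical(n_species(ex$network), 2L)
  expect_identical(n_reactions(ex$network), 2L)
  expect_setequal(network_keys(ex$network),
                  c("[H][H]>>[H].[H]", "[H].[H]>>[H][H]"))
  # the convergence counter is threshold x runs x radius when every step lands
  expect_identical(ex$reactions_sampled_without_change, 3L * 2L * 10L)
  # per-iteration records audit the convergence narrative
  expect_identical(tail(ex$records$new_reactions, 3), rep(0L, 3))
})

test_that("maxiters = 1 returns an unconverged snapshot", {
  sys <- chem_system(list("[H][H]"))
  ex <- explore_direct(sys, direct_explore_params(radius = 2, maxiters = 1,
                                                  rxn_convergence_threshold = 5,
                                                  parallel_runs = 1),
                       seed = 3)
  expect_false(ex$converged)
  expect_identical(nrow(ex$records), 1L)
})

test_that("select_seeds applies a strict cutoff", {
  expect_identical(select_seeds(c(A = 0.05, B = 0.01), 0.02), "A")
  expect_setequal(select_seeds(c(A = 0.05, B = 0.01, Z = 0), 0), c("A", "B"))
  # ties at exactly c_select are excluded
  expect_identical(select_seeds(c(A = 0.02, B = 0.05), 0.02), "B")
})

test_that("the reaction filter removes everything touching oversized species", {
  keys <- c("[CH3].CCCC>>CCCCC.[H]",      # produces a C5 chain
            "CCCCC>>[CH3].CCC[CH2]",      # consumes the C5 chain
            "CC>>[CH3].[CH3]")            # within the cap
  ids <- unique(unlist(strsplit(unlist(strsplit(keys, ">>", fixed = TRUE)),
                                ".", fixed = TRUE)))
  defs <- stats::setNames(lapply(ids, parse_smiles), ids)
  net <- crnkit:::network_from_keys(keys, defs)

  filtered <- apply_rxfilter(net, rx_filter(4))
  expect_identical(network_keys(filtered), "CC>>[CH3].[CH3]")
  # closure: the filtered network references no filtered-out species
  expect_false("CCCCC" %in% names(filtered$species))
  expect_setequal(attr(filtered, "filtered_keys"),
                  setdiff(network_keys(net), "CC>>[CH3].[CH3]"))

  # a network already within the cap is untouched
  eth <- make_ethane_core_network()
  expect_identical(network_keys(apply_rxfilter(eth, rx_filter(4))),
                   network_keys(eth))
})

test_that("iterative exploration with permissive c_select matches direct exploration", {
  cs <- condition_set(T = profile_fixed(2000), t_end = 0.01, tau_r = 0.001)
  sim <- sim_params(c0 = c("[H][H]" = 1), rtol = 1e-8, atol = 1e-12, n_out = 101L)
  params <- iterative_explore_params(seed_conc = 1e-9,
                                     max_levels = 6, level_maxiters = 20,
                                     level_threshold = 3, level_mechanisms = 2,
                                     filter = NULL)
  ex <- explore_iterative(list("[H][H]"), params, conditions = cs,
                          calculator_factory = surrogate_calculator_factory(),
                          sim = sim, seed = 5)
  expect_true(ex$converged)
  direct <- explore_direct(chem_system(list("[H][H]")),
                           direct_explore_params(radius = 10, maxiters = 50,
                                                 rxn_convergence_threshold = 3,
                                                 parallel_runs = 2), seed = 1)
  oracle <- enumerate_network(chem_system(list("[H][H]")))
  expect_identical(network_keys(ex$network), network_keys(direct$network))
  expect_identical(network_keys(ex$network), network_keys(oracle))
})

test_that("seeds can leave and re-enter the seed system across levels", {
  # scripted per-level c_max: [H] falls below the cutoff at level 2 and
  # re-enters at level 3
  script <- list(
    c("[H][H]" = 1, "[H]" = 0.5),
    c("[H][H]" = 1, "[H]" = 1e-6),
    c("[H][H]" = 1, "[H]" = 0.5),
    c("[H][H]" = 1, "[H]" = 0.5),
    c("[H][H]" = 1, "[H]" = 0.5)
  )
  params <- iterative_explore_params(seed_conc = 0.01, max_levels = 5,
                                     level_maxiters = 5, level_threshold = 2,
                                     level_mechanisms = 1, filter = NULL)
  ex <- explore_iterative(list("[H][H]"), params, seed = 7,
                          simulate_fn = function(net, level) script[[level]])
  seeds_by_level <- ex$records$seeds
  expect_true("[H]" %in% seeds_by_level[[1]])
  expect_false("[H]" %in% seeds_by_level[[2]])
  expect_true("[H]" %in% seeds_by_level[[3]])
  expect_true(ex$converged)
})

test_that("an empty seed system terminates with an under-exploration warning", {
  params <- iterative_explore_params(seed_conc = 10, max_levels = 4,
                                     level_maxiters = 5, level_threshold = 2,
                                     level_mechanisms = 1, filter = NULL)
  expect_warning(
    ex <- explore_iterative(list("[H][H]"), params, seed = 2,
                            simulate_fn = function(net, level)
                              c("[H][H]" = 1, "[H]" = 0.1)),
    "under-explored")
  expect_identical(ex$levels, 1L)
  expect_false(ex$converged)
  expect_true(ex$empty_seed_stop)
})

test_that("networks deduplicate idempotently and serialize round-trip", {
  net <- make_ethane_core_network()
  n0 <- n_reactions(net)
  res <- add_reactions(net, net$reactions[1], net$species)
  expect_identical(res$n_new, 0L)
  expect_identical(network_keys(res$net), network_keys(net))

  path <- withr::local_tempfile(fileext = ".txt")
  write_network(net, path)
  net2 <- read_network(path)
  expect_identical(network_keys(net2), network_keys(net))
  expect_identical(sort(names(net2$species)), sort(names(net$species)))
  expect_identical(net2$provenance$level, net$provenance$level)

  # tidy/glance views
  td <- tidy(net)
  expect_identical(nrow(td), n0)
  expect_identical(glance(net)$n_reactions, n0)
})
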