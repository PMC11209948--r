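#' Direct-exploration parameters
#'
#' @param radius mechanism length n_r per sampler run.
#' @param maxiters iteration cap.
#' @param rxn_convergence_threshold consecutive iterations without a new
#'   reaction required to declare convergence.
#' @param parallel_runs independent sampler executions per iteration (each
#'   with its own derived RNG seed).
#' @param max_attempts sampler retries per step.
#' @return Object of class `crn_direct_params`.
#' @export
direct_explore_params <- function(radius = 100L, maxiters = 1000L,
                                  rxn_convergence_threshold = 5L,
                                  parallel_runs = 6L, max_attempts = 100L) {
  stopifnot(radius >= 1, maxiters >= 1, rxn_convergence_threshold >= 1,
            parallel_runs >= 1, max_attempts >= 1)
  structure(
    list(radius = as.integer(radius), maxiters = as.integer(maxiters),
         rxn_convergence_threshold = as.integer(rxn_convergence_threshold),
         parallel_runs = as.integer(parallel_runs),
         max_attempts = as.integer(max_attempts)),
    class = "crn_direct_params"
  )
}

# Collect species definitions for a batch of reactions by parsing their
# canonical SMILES back into graphs.
species_defs_for <- function(reactions) {
  ids <- unique(unlist(lapply(reactions, function(r) c(r$reactants, r$products))))
  defs <- lapply(ids, function(id) tryCatch(parse_smiles(id), error = function(e) NULL))
  names(defs) <- ids
  defs
}

derive_seed <- function(base, iter, run, runs_per_iter) {
  (as.integer(base) * 7919L + (iter - 1L) * runs_per_iter + run) %% 2147483546L + 1L
}

#' Direct (brute-force) network exploration
#'
#' Repeatedly samples mechanisms of length `radius` from the initial system
#' (`parallel_runs` sampler executions per iteration) and adds every
#' extracted reaction -- and its reverse -- to the growing network, until
#' `rxn_convergence_threshold` consecutive iterations add nothing new (or
#' `maxiters` is hit, in which case the result is flagged unconverged).
#' Reactions whose species cannot be canonicalised are logged and discarded.
#'
#' @param init a [chem_system()] of starting molecules.
#' @param params a [direct_explore_params()].
#' @param lib a [move_library()].
#' @param valence,forbidden,radii,grp,refiner sampler dependencies.
#' @param seed integer base seed; every sampler run uses a seed derived from
#'   it, so the whole exploration is reproducible.
#' @return Object of class `crn_exploration`: `network`, `converged`,
#'   `records` (per-iteration tibble), and
#'   `reactions_sampled_without_change` -- the number of reactions sampled
#'   during the consecutive no-change iterations that triggered convergence.
#' @export
explore_direct <- function(init, params = direct_explore_params(),
                           lib = default_move_library(),
                           valence = valence_constraints(), forbidden = NULL,
                           radii = covalent_radii(), grp = grp_params(),
                           refiner = refiner_hook(), seed = 1L) {
  net <- reaction_network()
  consec <- 0L
  sampled_without_change <- 0L
  converged <- FALSE
  records <- list()
  for (iter in seq_len(params$maxiters)) {
    n_new_iter <- 0L
    steps_iter <- 0L
    for (run in seq_len(params$parallel_runs)) {
      sp <- sampler_params(n_r = params$radius, n_m = 1L,
                           max_attempts = params$max_attempts,
                           rng_seed = derive_seed(seed, iter, run, params$parallel_runs))
      mech <- run_segds(init, lib, sp, valence, forbidden, radii, grp, refiner)[[1]]
      steps_iter <- steps_iter + length(mech$steps)
      rxns <- extract_reactions(mech)
      rxns <- c(rxns, lapply(rxns, reverse_reaction))
      defs <- species_defs_for(rxns)
      ok <- vapply(rxns, function(r)
        all(!vapply(defs[c(r$reactants, r$products)], is.null, TRUE)), TRUE)
      if (any(!ok)) {
        warning("discarding ", sum(!ok), " reaction(s) with uncanonicalizable species",
                call. = FALSE)
      }
      res <- add_reactions(net, rxns[ok], defs, level = 0L, iteration = iter)
      net <- res$net
      n_new_iter <- n_new_iter + res$n_new
    }
    if (n_new_iter == 0L) {
      consec <- consec + 1L
      sampled_without_change <- sampled_without_change + steps_iter
    } else {
      consec <- 0L
      sampled_without_change <- 0L
    }
    records[[iter]] <- tibble::tibble(
      iteration = iter, new_reactions = n_new_iter,
      reactions_sampled = steps_iter,
      cumulative_reactions = n_reactions(net))
    if (consec >= params$rxn_convergence_threshold) { converged <- TRUE; break }
  }
  structure(
    list(network = net, converged = converged,
         records = dplyr::bind_rows(records),
         reactions_sampled_without_change = sampled_without_change),
    class = "crn_exploration"
  )
}

#' @export
print.crn_exploration <- function(x, ...) {
  cat("<crn_exploration> ", n_species(x$network), " species, ",
      n_reactions(x$network), " reactions (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}

#' Reaction filter for the simulated copy of a network
#'
#' Default predicate: species with more than `max_carbons` carbon atoms are
#' disallowed; any reaction touching a disallowed species is removed from
#' the simulated network (a species that cannot be produced cannot be
#' consumed either).  Custom predicates replace the carbon rule.
#'
#' @param max_carbons carbon cap per species (default 4).
#' @param predicate optional `function(crn_species) -> logical` (TRUE =
#'   keep); overrides `max_carbons`.
#' @return Object of class `crn_rxfilter`.
#' @export
rx_filter <- function(max_carbons = 4L, predicate = NULL) {
  if (is.null(predicate)) {
    predicate <- function(sp) {
      f <- sp$formula
      (if ("C" %in% names(f)) f[["C"]] else 0L) <= max_carbons
    }
  }
  structure(list(predicate = predicate, max_carbons = max_carbons),
            class = "crn_rxfilter")
}

#' Apply a reaction filter to a network
#'
#' Returns the simulated copy: reactions involving disallowed species are
#' removed (and with them any species left orphaned).  The removed reaction
#' keys and their provenance rows are retained in attributes
#' `"filtered_keys"` / `"filtered_provenance"` so raising the cap later does
#' not require resampling.
#'
#' @param net a `crn_network`.
#' @param filter a [rx_filter()]; `NULL` returns `net` unchanged.
#' @return A filtered `crn_network`.
#' @export
apply_rxfilter <- function(net, filter) {
  if (is.null(filter)) return(net)
  bad <- names(net$species)[!vapply(net$species, filter$predicate, TRUE)]
  if (!length(bad)) return(net)
  keep <- vapply(net$reactions, function(r)
    !any(c(r$reactants, r$products) %in% bad), TRUE)
  out <- reaction_network()
  for (i in which(keep)) {
    out <- add_reactions(out, net$reactions[i], net$species,
                         level = net$provenance$level[i],
                         iteration = net$provenance$iteration[i])$net
  }
  attr(out, "filtered_keys") <- net$reaction_keys[!keep]
  attr(out, "filtered_provenance") <- net$provenance[!keep, ]
  out
}

#' Select seed species from a kinetic solution
#'
#' Seeds are exactly the species whose maximum concentration over the whole
#' simulation strictly exceeds `c_select` (ties at the cutoff are excluded).
#'
#' @param solution a `crn_solution`, or a named numeric vector of per-species
#'   maximum concentrations.
#' @param c_select concentration cutoff (mol dm^-3).
#' @return Character vector of seed species ids (sorted).
#' @export
select_seeds <- function(solution, c_select) {
  c_max <- if (inherits(solution, "crn_solution")) solution$c_max else solution
  stopifnot(is.numeric(c_max), !is.null(names(c_max)))
  sort(names(c_max)[c_max > c_select])
}

#' Iterative-exploration parameters
#'
#' @param seed_conc seed selection cutoff c_select (mol dm^-3, > 0).
#' @param seed_convergence_threshold consecutive levels with an unchanged
#'   seed system required for convergence (default 2).
#' @param max_levels level cap.
#' @param level_maxiters,level_threshold,level_mechanisms,max_attempts level
#'   sampling controls: per level, each seed subsystem is sampled with
#'   radius-1 mechanisms (`level_mechanisms` per subsystem per iteration)
#'   until `level_threshold` consecutive iterations add no new reaction.
#' @param filter a [rx_filter()] applied to the simulated copy each level
#'   (`NULL` disables filtering).
#' @return Object of class `crn_iterative_params`.
#' @export
iterative_explore_params <- function(seed_conc, seed_convergence_threshold = 2L,
                                     max_levels = 12L, level_maxiters = 60L,
                                     level_threshold = 5L, level_mechanisms = 2L,
                                     max_attempts = 100L, filter = rx_filter()) {
  stopifnot(seed_conc > 0, seed_convergence_threshold >= 1, max_levels >= 1,
            level_maxiters >= 1, level_threshold >= 1, level_mechanisms >= 1)
  structure(
    list(seed_conc = seed_conc,
         seed_convergence_threshold = as.integer(seed_convergence_threshold),
         max_levels = as.integer(max_levels),
         level_maxiters = as.integer(level_maxiters),
         level_threshold = as.integer(level_threshold),
         level_mechanisms = as.integer(level_mechanisms),
         max_attempts = as.integer(max_attempts),
         filter = filter),
    class = "crn_iterative_params"
  )
}

# Seed systems for one level: every seed alone (unimolecular applications)
# plus every unordered seed pair including self-pairs (bimolecular).
seed_systems <- function(seeds, species_by_id) {
  out <- list()
  for (s in seeds) out[[length(out) + 1L]] <- chem_system(species_by_id[s])
  if (length(seeds)) {
    for (a in seq_along(seeds)) {
      for (b in a:length(seeds)) {
        out[[length(out) + 1L]] <- chem_system(species_by_id[c(seeds[a], seeds[b])])
      }
    }
  }
  out
}

#' Iterative (kinetics-guided) network exploration
#'
#' Levels of radius-1 sampling around the current seed system, each followed
#' by a kinetic simulation (discrete rate-update formalism) of the
#' filter-reduced cumulative network; species whose maximum concentration
#' exceeds `seed_conc` become the next level's seeds.  Exploration converges
#' when the seed system is unchanged for `seed_convergence_threshold`
#' consecutive levels; an empty seed system terminates with an
#' under-exploration warning.
#'
#' @param init_species list of starting `crn_species` (or SMILES strings).
#' @param params an [iterative_explore_params()].
#' @param conditions a [condition_set()] for the per-level simulations.
#' @param calculator_factory `function(crn_network) -> crn_calculator`
#'   assigning rate parameters to a network's reactions (in network order);
#'   e.g. [surrogate_calculator_factory()].
#' @param sim a [sim_params()] (initial concentrations, tolerances).
#' @param lib,valence,forbidden,radii,grp,refiner sampler dependencies.
#' @param seed integer base seed.
#' @param simulate_fn optional override of the per-level simulation,
#'   `function(net, level) -> crn_solution` (or a named c_max vector);
#'   injectable for testing the seed bookkeeping in isolation.
#' @return Object of class `crn_exploration` with per-level `records`
#'   (tibble: level, new reactions, seed system, c_max) and `levels` count.
#' @export
explore_iterative <- function(init_species, params, conditions = NULL,
                              calculator_factory = NULL, sim = NULL,
                              lib = default_move_library(),
                              valence = valence_constraints(), forbidden = NULL,
                              radii = covalent_radii(), grp = grp_params(),
                              refiner = refiner_hook(), seed = 1L,
                              simulate_fn = NULL) {
  stopifnot(inherits(params, "crn_iterative_params"))
  init_species <- lapply(init_species, function(s) if (is.character(s)) parse_smiles(s) else s)
  species_pool <- stats::setNames(init_species,
                                  vapply(init_species, `[[`, "", "smiles"))
  if (is.null(simulate_fn)) {
    if (is.null(conditions) || is.null(calculator_factory) || is.null(sim)) {
      stop("supply `conditions`, `calculator_factory` and `sim` (or a `simulate_fn`)",
           call. = FALSE)
    }
    simulate_fn <- function(net, level) {
      sim_net <- apply_rxfilter(net, params$filter)
      if (!n_reactions(sim_net)) return(stats::setNames(numeric(0), character(0)))
      rre <- build_rre(sim_net)
      calc <- calculator_factory(sim_net)
      solve_discrete(rre, conditions, calc, sim)
    }
  }
  net <- reaction_network()
  seeds <- sort(names(species_pool))
  seed_consec <- 0L
  converged <- FALSE
  records <- list()
  warned_empty <- FALSE
  for (level in seq_len(params$max_levels)) {
    systems <- seed_systems(seeds, species_pool)
    consec <- 0L
    n_new_level <- 0L
    for (iter in seq_len(params$level_maxiters)) {
      n_new_iter <- 0L
      for (si in seq_along(systems)) {
        sp <- sampler_params(n_r = 1L, n_m = params$level_mechanisms,
                             max_attempts = params$max_attempts,
                             rng_seed = derive_seed(seed + level * 131L, iter, si,
                                                    length(systems)))
        mechs <- run_segds(systems[[si]], lib, sp, valence, forbidden,
                           radii, grp, refiner)
        rxns <- unlist(lapply(mechs, extract_reactions), recursive = FALSE)
        rxns <- c(rxns, lapply(rxns, reverse_reaction))
        defs <- species_defs_for(rxns)
        ok <- vapply(rxns, function(r)
          all(!vapply(defs[c(r$reactants, r$products)], is.null, TRUE)), TRUE)
        res <- add_reactions(net, rxns[ok], defs, level = level, iteration = iter)
        net <- res$net
        n_new_iter <- n_new_iter + res$n_new
      }
      n_new_level <- n_new_level + n_new_iter
      consec <- if (n_new_iter == 0L) consec + 1L else 0L
      if (consec >= params$level_threshold) break
    }
    # refresh the pool with any newly discovered species
    for (id in names(net$species)) {
      if (is.null(species_pool[[id]])) species_pool[[id]] <- net$species[[id]]
    }
    sol <- simulate_fn(net, level)
    c_max <- if (inherits(sol, "crn_solution")) sol$c_max else sol
    new_seeds <- select_seeds(c_max, params$seed_conc)
    records[[level]] <- tibble::tibble(
      level = level, new_reactions = n_new_level,
      seeds = list(new_seeds), c_max = list(c_max),
      cumulative_reactions = n_reactions(net))
    if (!length(new_seeds)) {
      warning("empty seed system at level ", level,
              ": c_select exceeds every attained c_max; network may be under-explored",
              call. = FALSE)
      warned_empty <- TRUE
      break
    }
    if (identical(new_seeds, seeds)) {
      seed_consec <- seed_consec + 1L
    } else {
      seed_consec <- 0L
    }
    seeds <- new_seeds
    if (seed_consec >= params$seed_convergence_threshold) { converged <- TRUE; break }
  }
  structure(
    list(network = net, converged = converged,
         records = dplyr::bind_rows(records),
         levels = length(records), empty_seed_stop = warned_empty),
    class = "crn_exploration"
  )
}

#' Brute-force enumeration of the reachable reaction space
#'
#' Deterministic oracle for small systems: breadth-first closure over all
#' valid move applications starting from the initial system state, recording
#' every state-changing reaction (and, through its reverse states, every
#' reverse reaction reachable the same way).  Only feasible for enumerable
#' chemistries (a handful of atoms); used to validate the stochastic
#' explorers.
#'
#' @param init a [chem_system()].
#' @param lib a [move_library()].
#' @param valence,forbidden,radii sampler dependencies (no geometry stage:
#'   enumeration happens at the graph level).
#' @param max_states safety cap on visited states.
#' @return A `crn_network` of every reachable reaction.
#' @export
enumerate_network <- function(init, lib = default_move_library(),
                              valence = valence_constraints(), forbidden = NULL,
                              radii = covalent_radii(), max_states = 5000L) {
  asm <- assemble_system(init, radii = radii)
  elements <- asm$geometry$elements
  net <- reaction_network()
  seen <- character(0)
  queue <- list(asm$cm)
  while (length(queue)) {
    cm <- queue[[1]]; queue <- queue[-1]
    state <- sort(state_species(cm, elements, valence))
    key <- paste(state, collapse = ".")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (length(seen) > max_states) stop("state space exceeds max_states", call. = FALSE)
    for (move in lib$moves) {
      for (asg in enumerate_applications(cm, elements, move, valence, forbidden)) {
        res <- apply_move(cm, elements, move, asg, valence, forbidden)
        if (!res$accepted) next
        comp_old <- cm_components(cm); comp_new <- cm_components(res$cm)
        if (length(unique(comp_old[asg])) > 2L || length(unique(comp_new[asg])) > 2L) next
        state2 <- tryCatch(sort(state_species(res$cm, elements, valence)),
                           crn_canonicalization_error = function(e) NULL)
        if (is.null(state2)) next
        rxn <- diff_states(state, state2)
        if (is.null(rxn) || identical(rxn, "beyond-bimolecular")) {
          next
        }
        defs <- species_defs_for(list(rxn))
        net <- add_reactions(net, list(rxn), defs)$net
        k2 <- paste(state2, collapse = ".")
        if (!(k2 %in% seen)) queue[[length(queue) + 1L]] <- res$cm
      }
    }
  }
  net
}
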