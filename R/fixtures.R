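#' Toy reversible 5-species network
#'
#' Five abstract species A--E linked by three reversible reactions
#' (`A+B <-> C`, `C <-> D`, `D+A <-> E`) with configurable forward/backward
#' mass-action rate constants.  Element balance uses two abstract elements
#' (A = X, B = Y, C and D = XY isomers, E = X2Y).  The canonical small test
#' system for equilibrium, detailed balance and solver checks.
#'
#' @param k1,k2,k3 forward rate constants.
#' @param km1,km2,km3 backward rate constants (set to 0 for an irreversible
#'   variant; zero-rate reactions are dropped from the network).
#' @return List: `network` (`crn_network`), `k` (named rate vector in
#'   network order), `calculator` (a static [calculator()]).
#' @export
make_toy_reversible_5species <- function(k1 = 2, k2 = 1, k3 = 1.5,
                                         km1 = 1, km2 = 0.5, km3 = 0.75) {
  sp <- list(
    A = abstract_species("A", c(X = 1)),
    B = abstract_species("B", c(Y = 1)),
    C = abstract_species("C", c(X = 1, Y = 1)),
    D = abstract_species("D", c(X = 1, Y = 1)),
    E = abstract_species("E", c(X = 2, Y = 1))
  )
  defs <- list(
    list(key = c("A.B", "C"), k = k1), list(key = c("C", "A.B"), k = km1),
    list(key = c("C", "D"), k = k2),  list(key = c("D", "C"), k = km2),
    list(key = c("A.D", "E"), k = k3), list(key = c("E", "A.D"), k = km3)
  )
  net <- reaction_network()
  k <- numeric(0)
  for (d in defs) {
    if (d$k <= 0) next
    rxn <- reaction(strsplit(d$key[1], ".", fixed = TRUE)[[1]],
                    strsplit(d$key[2], ".", fixed = TRUE)[[1]])
    net <- add_reactions(net, list(rxn), sp)$net
    k <- c(k, stats::setNames(d$k, rxn$key))
  }
  rre_mol <- vapply(net$reactions, function(r) length(r$reactants), 0L)
  list(network = net, k = k,
       calculator = calc_static(unname(k), molecularity = rre_mol))
}

#' Mean bond energy table for the hydrocarbon surrogate
#'
#' Average single-bond dissociation energies (J/mol) used by the surrogate
#' kinetic parameter generator.  A deliberately small, synthetic stand-in
#' for a trained activation-energy model: adequate for demonstration
#' chemistry, not for quantitative kinetics.
#'
#' @return Named numeric vector (`"C-C"`, `"C-H"`, `"H-H"`).
#' @export
bond_energy_table <- function() {
  c("C-C" = 348e3, "C-H" = 413e3, "H-H" = 436e3)
}

# Count bonds by element-pair type in a species graph, e.g. c("C-C"=1,"C-H"=6).
bond_type_counts <- function(sp) {
  if (is.null(sp$graph)) return(integer(0))
  cm <- sp$graph
  el <- sp$elements
  idx <- which(cm == 1L & upper.tri(cm), arr.ind = TRUE)
  if (!nrow(idx)) return(integer(0))
  types <- apply(idx, 1, function(ij) paste(sort(c(el[ij[1]], el[ij[2]])), collapse = "-"))
  tab <- table(types)
  stats::setNames(as.integer(tab), names(tab))
}

side_bond_counts <- function(ids, species_by_id) {
  tot <- integer(0)
  for (s in ids) {
    b <- bond_type_counts(species_by_id[[s]])
    for (nm in names(b)) tot[nm] <- (if (nm %in% names(tot)) tot[[nm]] else 0L) + b[[nm]]
  }
  tot
}

#' Surrogate kinetic parameters for C/H networks
#'
#' Assigns every reaction in a hydrocarbon network a finite (Ea, A) pair
#' from simple structural rules -- a synthetic stand-in for a trained
#' activation-energy model, usable only for demonstrations:
#' \itemize{
#'   \item homolysis (1 reactant, 2 products): Ea = mean bond energy of the
#'     broken bond type, A = `A_uni`;
#'   \item recombination (2 reactants, 1 product): barrierless, Ea = 0,
#'     A = `A_bi`;
#'   \item transfer / exchange and isomerisation: Evans--Polanyi rule
#'     `Ea = max(0, E0 + alpha_ep * dH)` with `dH` the bond-energy change;
#'   \item unrecognised shapes: fallback `Ea_fallback` with a warning.
#' }
#'
#' @param net a `crn_network` of C/H species with graphs.
#' @param bonds a [bond_energy_table()].
#' @param A_uni,A_bi prefactors for uni-/bimolecular reactions (s^-1,
#'   dm^3 mol^-1 s^-1).
#' @param E0,alpha_ep Evans--Polanyi intercept (J/mol) and slope.
#' @param Ea_fallback fallback activation energy (J/mol).
#' @return Tibble: `key`, `Ea`, `A`, `molecularity`, `class` (one row per
#'   reaction, in network order).
#' @export
make_hydrocarbon_surrogate_rates <- function(net, bonds = bond_energy_table(),
                                             A_uni = 1e15, A_bi = 1e10,
                                             E0 = 50e3, alpha_ep = 0.5,
                                             Ea_fallback = 150e3) {
  rows <- lapply(net$reactions, function(rxn) {
    nr <- length(rxn$reactants); np <- length(rxn$products)
    br <- side_bond_counts(rxn$reactants, net$species)
    bp <- side_bond_counts(rxn$products, net$species)
    all_t <- union(names(br), names(bp))
    get <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0L
    diff <- stats::setNames(
      vapply(all_t, function(nm) get(br, nm) - get(bp, nm), 0L), all_t)
    broken <- diff[diff > 0]; formed <- -diff[diff < 0]
    be <- function(counts) sum(vapply(names(counts), function(nm) {
      if (!nm %in% names(bonds)) return(NA_real_)
      bonds[[nm]] * counts[[nm]]
    }, 0))
    dH <- be(broken) - be(formed)   # positive = net bond breaking
    cls <- if (nr == 1L && np == 2L && sum(broken) == 1L && sum(formed) == 0L) {
      "homolysis"
    } else if (nr == 2L && np == 1L && sum(formed) == 1L && sum(broken) == 0L) {
      "recombination"
    } else if (sum(broken) >= 1L && sum(formed) >= 1L) {
      "transfer"
    } else {
      "unclassified"
    }
    Ea <- switch(cls,
      homolysis = if (names(broken) %in% names(bonds)) bonds[[names(broken)]] else NA_real_,
      recombination = 0,
      transfer = max(0, E0 + alpha_ep * dH),
      unclassified = NA_real_)
    if (is.null(Ea) || is.na(Ea)) {
      warning("unrecognised reaction class for ", rxn$key,
              "; using fallback Ea", call. = FALSE)
      Ea <- Ea_fallback
      cls <- "fallback"
    }
    tibble::tibble(key = rxn$key, Ea = Ea,
                   A = if (nr == 2L) A_bi else A_uni,
                   molecularity = nr, class = cls)
  })
  dplyr::bind_rows(rows)
}

#' Calculator factory backed by the hydrocarbon surrogate
#'
#' For use with [explore_iterative()]: maps any C/H network to an Arrhenius
#' calculator parameterised by [make_hydrocarbon_surrogate_rates()].
#'
#' @inheritParams make_hydrocarbon_surrogate_rates
#' @param diffusion optional [diffusion_model()] for capping bimolecular
#'   rates.
#' @return `function(crn_network) -> crn_calculator`.
#' @export
surrogate_calculator_factory <- function(bonds = bond_energy_table(),
                                         A_uni = 1e15, A_bi = 1e10,
                                         E0 = 50e3, alpha_ep = 0.5,
                                         Ea_fallback = 150e3, diffusion = NULL) {
  function(net) {
    tab <- suppressWarnings(
      make_hydrocarbon_surrogate_rates(net, bonds, A_uni, A_bi, E0, alpha_ep,
                                       Ea_fallback))
    calc_arrhenius(arrhenius_params(tab$Ea, tab$A),
                   molecularity = tab$molecularity, diffusion = diffusion)
  }
}

#' Hand-built ethane pyrolysis core network
#'
#' A small fixed C/H network for demo simulations without running an
#' exploration: ethane homolysis, methane and hydrogen radical chemistry,
#' and H abstraction, all reversible.
#'
#' @return A `crn_network`.
#' @export
make_ethane_core_network <- function() {
  keys <- c(
    "CC>>[CH3].[CH3]", "[CH3].[CH3]>>CC",
    "C>>[CH3].[H]", "[CH3].[H]>>C",
    "[H][H]>>[H].[H]", "[H].[H]>>[H][H]",
    "CC.[H]>>C.[CH3]", "C.[CH3]>>CC.[H]"
  )
  ids <- unique(unlist(strsplit(unlist(strsplit(keys, ">>", fixed = TRUE)), ".", fixed = TRUE)))
  defs <- stats::setNames(lapply(ids, parse_smiles), ids)
  network_from_keys(keys, defs)
}

#' Random stiff abstract network
#'
#' A connected random unimolecular isomerisation network over `n_species`
#' single-element species with log-uniform rate constants spanning
#' `k_span_decades` orders of magnitude -- the standard stress fixture for
#' stiff-solver behaviour.  Fully reproducible by seed.
#'
#' @param n_species number of species (>= 2).
#' @param n_reactions number of directed reactions (>= n_species - 1).
#' @param k_span_decades width of the log10 rate-constant span (>= 0).
#' @param seed integer seed.
#' @return List: `network`, `k` (rate vector), `calculator`.
#' @export
make_random_stiff_crn <- function(n_species = 20L, n_reactions = 40L,
                                  k_span_decades = 6, seed = 1L) {
  stopifnot(n_species >= 2, n_reactions >= n_species - 1L, k_span_decades >= 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n_species))
  sp <- stats::setNames(lapply(ids, function(i) abstract_species(i, c(X = 1))), ids)
  # spanning tree first (connectivity), then random extra edges
  edges <- list()
  for (i in 2:n_species) edges[[i - 1L]] <- c(sample.int(i - 1L, 1L), i)
  while (length(edges) < n_reactions) {
    e <- sample.int(n_species, 2L)
    edges[[length(edges) + 1L]] <- e
  }
  edges <- edges[seq_len(n_reactions)]
  net <- reaction_network()
  kept <- logical(length(edges))
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    rxn <- reaction(ids[e[1]], ids[e[2]])
    if (rxn$key %in% net$reaction_keys) next
    net <- add_reactions(net, list(rxn), sp)$net
    kept[i] <- TRUE
  }
  nr <- n_reactions(net)
  k <- 10^stats::runif(nr, 0, k_span_decades)
  list(network = net, k = k,
       calculator = calc_static(k, molecularity = rep(1L, nr)))
}
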