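#' Sampler parameters for single-ended graph-driven sampling
#'
#' @param n_r reactions per mechanism (the exploration "radius").
#' @param n_m mechanisms per run.
#' @param max_attempts move retries per mechanism step before the mechanism
#'   is truncated (default 100).
#' @param rng_seed integer seed making the run reproducible.
#' @return Object of class `crn_sampler_params`.
#' @export
sampler_params <- function(n_r = 1L, n_m = 1L, max_attempts = 100L, rng_seed = 1L) {
  stopifnot(n_r >= 1, n_m >= 1, max_attempts >= 1)
  structure(
    list(n_r = as.integer(n_r), n_m = as.integer(n_m),
         max_attempts = as.integer(max_attempts), rng_seed = as.integer(rng_seed)),
    class = "crn_sampler_params"
  )
}

#' A directional elementary reaction
#'
#' Species multisets are stored as sorted canonical-SMILES character vectors
#' (repeats encode multiplicity).  The identity key is direction-specific:
#' `"reactants>>products"` with each side dot-joined in sorted order.
#'
#' @param reactants,products character vectors of canonical SMILES (repeats
#'   allowed) or lists of `crn_species`.
#' @param species optional named list of `crn_species` carrying element
#'   counts for balance checking (required when SMILES strings alone are
#'   given for species that cannot be parsed, e.g. abstract fixture species).
#' @return Object of class `crn_reaction`.
#' @export
reaction <- function(reactants, products, species = NULL) {
  side <- function(x) {
    if (is.list(x)) x <- vapply(x, `[[`, "", "smiles")
    sort(as.character(x))
  }
  r <- side(reactants); p <- side(products)
  if (length(r) < 1L || length(p) < 1L) stop("both sides must be nonempty", call. = FALSE)
  if (length(r) > 2L || length(p) > 2L) {
    stop("reactions beyond bimolecular are not modelled", call. = FALSE)
  }
  if (identical(r, p)) stop("reactants and products are identical", call. = FALSE)
  structure(
    list(reactants = r, products = p,
         key = paste0(paste(r, collapse = "."), ">>", paste(p, collapse = "."))),
    class = "crn_reaction"
  )
}

#' @export
print.crn_reaction <- function(x, ...) { cat(x$key, "\n"); invisible(x) }

reverse_reaction <- function(rxn) reaction(rxn$products, rxn$reactants)

# Element balance of a reaction given a lookup of species objects by SMILES.
reaction_balanced <- function(rxn, species_by_id) {
  count_side <- function(side) {
    tot <- integer(0)
    for (s in side) {
      f <- species_by_id[[s]]$formula
      for (el in names(f)) tot[el] <- (if (el %in% names(tot)) tot[[el]] else 0L) + f[[el]]
    }
    tot[order(names(tot))]
  }
  identical(count_side(rxn$reactants), count_side(rxn$products))
}

#' Run single-ended graph-driven sampling
#'
#' Repeats the cycle sample-move -> validate -> embed geometry -> re-perceive
#' for `n_r` steps per mechanism and `n_m` mechanisms, starting from the
#' combined connectivity matrix of the input system.  A sampled move is
#' applied at a uniformly drawn valid slot assignment; moves that violate
#' valence limits, forbidden patterns, the bimolecular cap, or whose
#' geometry round-trip changes the connectivity are rejected and resampled
#' (rejections never consume radius).  After `max_attempts` consecutive
#' rejections the mechanism terminates early.
#'
#' @param system a [chem_system()].
#' @param lib a [move_library()].
#' @param params a [sampler_params()].
#' @param valence a [valence_constraints()] table.
#' @param forbidden optional [forbidden_patterns()].
#' @param radii a [covalent_radii()] table.
#' @param grp a [grp_params()].
#' @param refiner a [refiner_hook()].
#' @return List of mechanisms (class `crn_mechanism`); each holds `steps`, a
#'   list of `list(state_before, state_after, reaction, attempts)` where the
#'   states are sorted SMILES vectors, plus the per-step geometries.
#' @export
run_segds <- function(system, lib, params = sampler_params(),
                      valence = valence_constraints(), forbidden = NULL,
                      radii = covalent_radii(), grp = grp_params(),
                      refiner = refiner_hook()) {
  stopifnot(inherits(system, "crn_system"), inherits(lib, "crn_move_library"))
  asm <- assemble_system(system, radii = radii, grp = grp)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(params$rng_seed)
  mechanisms <- vector("list", params$n_m)
  for (m in seq_len(params$n_m)) {
    mechanisms[[m]] <- sample_mechanism(asm, lib, params, valence, forbidden,
                                        radii, grp, refiner)
  }
  mechanisms
}

state_species <- function(cm, elements, valence) {
  comp <- cm_components(cm)
  vapply(seq_len(max(comp)), function(k) {
    idx <- which(comp == k)
    graph_to_smiles(cm[idx, idx, drop = FALSE], elements[idx], valence)
  }, "")
}

sample_mechanism <- function(asm, lib, params, valence, forbidden, radii, grp, refiner) {
  cm <- asm$cm
  geom <- asm$geometry
  elements <- geom$elements
  steps <- list()
  total_attempts <- 0L
  for (step in seq_len(params$n_r)) {
    placed <- FALSE
    attempts <- 0L
    state_before <- sort(state_species(cm, elements, valence))
    while (attempts < params$max_attempts && !placed) {
      attempts <- attempts + 1L
      move <- sample_move(lib)
      apps <- enumerate_applications(cm, elements, move, valence, forbidden)
      if (!length(apps)) next
      asg <- apps[[sample.int(length(apps), 1L)]]
      res <- apply_move(cm, elements, move, asg, valence, forbidden)
      if (!res$accepted) next
      # molecularity cap: the slots may touch at most two molecules on each side
      comp_old <- cm_components(cm)
      comp_new <- cm_components(res$cm)
      if (length(unique(comp_old[asg])) > 2L || length(unique(comp_new[asg])) > 2L) next
      state_after <- tryCatch(sort(state_species(res$cm, elements, valence)),
                              crn_canonicalization_error = function(e) NULL)
      if (is.null(state_after)) next   # unrationalizable species: reject move
      rxn <- diff_states(state_before, state_after)
      if (identical(rxn, "beyond-bimolecular")) next
      opt <- optimize_to_graph(geom, res$cm, radii, grp, refiner)
      if (!opt$ok) next
      cm <- res$cm
      geom <- opt$geometry
      steps[[length(steps) + 1L]] <- list(
        state_before = state_before,
        state_after = state_after,
        reaction = rxn,        # NULL when the multiset did not change
        move = move$name,
        attempts = attempts,
        geometry = geom
      )
      placed <- TRUE
    }
    total_attempts <- total_attempts + attempts
    if (!placed) break   # attempts exhausted: truncate the mechanism
  }
  structure(list(steps = steps, n_r = params$n_r, attempts = total_attempts),
            class = "crn_mechanism")
}

# Multiset difference between two sorted SMILES states -> crn_reaction or
# NULL when nothing changed.
diff_states <- function(before, after) {
  all_ids <- unique(c(before, after))
  nb <- vapply(all_ids, function(s) sum(before == s), 0L)
  na <- vapply(all_ids, function(s) sum(after == s), 0L)
  d <- na - nb
  reactants <- rep(all_ids[d < 0], -d[d < 0])
  products <- rep(all_ids[d > 0], d[d > 0])
  if (!length(reactants) && !length(products)) return(NULL)
  if (!length(reactants) || !length(products)) {
    stop("internal consistency error: one-sided multiset diff", call. = FALSE)
  }
  if (length(reactants) > 2L || length(products) > 2L) return("beyond-bimolecular")
  reaction(reactants, products)
}

#' Extract stoichiometric reactions from a mechanism
#'
#' Diffs the species multisets across each step, dropping spectators; steps
#' whose multisets did not change (e.g. an atom transfer producing the
#' identical species multiset) are discarded.
#'
#' @param mech a `crn_mechanism` from [run_segds()].
#' @return List of `crn_reaction`.
#' @export
extract_reactions <- function(mech) {
  stopifnot(inherits(mech, "crn_mechanism"))
  out <- list()
  for (st in mech$steps) {
    if (!is.null(st$reaction)) out[[length(out) + 1L]] <- st$reaction
  }
  out
}

#' Write a mechanism as reaction SMILES
#'
#' One `reactants>>products` line per state-changing step.
#'
#' @param mech a `crn_mechanism`.
#' @param path optional file; when `NULL` the lines are returned.
#' @export
write_mechanism <- function(mech, path = NULL) {
  lines <- vapply(extract_reactions(mech), `[[`, "", "key")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}
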