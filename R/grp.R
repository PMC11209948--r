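#' Parameters of the graph restraining potential
#'
#' The GRP is a pairwise empirical potential whose minimum basin is exactly
#' the set of coordinates realising a target connectivity matrix: bonded
#' pairs sit in a flat-bottom well below `(1 - margin)` of the bond-perception
#' cutoff (with a short-range core wall so fragments cannot collapse),
#' non-bonded pairs are pushed beyond `(1 + margin)` of the cutoff, and a
#' molecular term keeps centroids of distinct molecules at least `d_mol`
#' apart so no spurious inter-molecular bonds form.
#'
#' @param k_bond force constant of the bonded wells (energy / A^2).
#' @param k_rep force constant of the non-bonded repulsion (energy / A^2).
#' @param k_mol force constant of the inter-molecular centroid term.
#' @param margin fractional well offset delta in (0, 1); default 0.1.
#' @param core fraction of the cutoff below which bonded pairs hit the inner
#'   wall (default 0.4, well under any physical bond length).
#' @param d_mol centroid separation threshold in Angstrom (default 4).
#' @param max_iter optimizer iteration cap.
#' @param grad_tol gradient convergence tolerance.
#' @return Object of class `crn_grp_params`.
#' @export
grp_params <- function(k_bond = 50, k_rep = 50, k_mol = 10,
                       margin = 0.1, core = 0.4, d_mol = 4,
                       max_iter = 500L, grad_tol = 1e-8) {
  stopifnot(k_bond > 0, k_rep > 0, k_mol > 0,
            margin > 0, margin < 1, core > 0, core < 1 - margin,
            d_mol > 0, max_iter >= 1, grad_tol > 0)
  structure(
    list(k_bond = k_bond, k_rep = k_rep, k_mol = k_mol,
         margin = margin, core = core, d_mol = d_mol,
         max_iter = as.integer(max_iter), grad_tol = grad_tol),
    class = "crn_grp_params"
  )
}

#' Graph restraining potential energy and gradient
#'
#' @param coords numeric N x 3 coordinate matrix (Angstrom).
#' @param target target connectivity matrix (N x N, 0/1).
#' @param elements element symbols.
#' @param radii a [covalent_radii()] table (defines the cutoffs the wells are
#'   keyed to).
#' @param params a [grp_params()].
#' @return List with `energy` (scalar >= 0) and `gradient` (N x 3 matrix,
#'   the exact analytic derivative of the implemented energy).
#' @export
grp_energy <- function(coords, target, elements, radii = covalent_radii(),
                       params = grp_params()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  check_cm(target, n)
  cut <- bond_cutoffs(elements, radii)
  comp <- cm_components(target)
  e <- 0
  grad <- matrix(0, n, 3)
  add_pair <- function(i, j, k, d0, side) {
    # side +1: penalise d > d0 ; side -1: penalise d < d0
    dv <- coords[i, ] - coords[j, ]
    d <- sqrt(sum(dv^2))
    gap <- side * (d - d0)
    if (gap > 0) {
      e <<- e + 0.5 * k * gap^2
      if (d > 1e-12) {
        gv <- k * gap * side * dv / d
        grad[i, ] <<- grad[i, ] + gv
        grad[j, ] <<- grad[j, ] - gv
      }
    }
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cij <- cut[i, j]
      if (target[i, j] == 1L) {
        add_pair(i, j, params$k_bond, (1 - params$margin) * cij, +1)
        add_pair(i, j, params$k_bond, params$core * cij, -1)
      } else {
        add_pair(i, j, params$k_rep, (1 + params$margin) * cij, -1)
      }
    }
  }
  nmol <- max(comp)
  if (nmol > 1L) {
    cent <- t(vapply(seq_len(nmol), function(k) colMeans(coords[comp == k, , drop = FALSE]),
                     numeric(3)))
    sizes <- tabulate(comp, nmol)
    for (a in seq_len(nmol - 1L)) {
      for (b in (a + 1L):nmol) {
        dv <- cent[a, ] - cent[b, ]
        d <- sqrt(sum(dv^2))
        gap <- params$d_mol - d
        if (gap > 0) {
          e <- e + 0.5 * params$k_mol * gap^2
          if (d > 1e-12) {
            gv <- -params$k_mol * gap * dv / d
            grad[comp == a, ] <- grad[comp == a, ] +
              matrix(gv / sizes[a], sizes[a], 3, byrow = TRUE)
            grad[comp == b, ] <- grad[comp == b, ] -
              matrix(gv / sizes[b], sizes[b], 3, byrow = TRUE)
          }
        }
      }
    }
  }
  list(energy = e, gradient = grad)
}

# Deterministic pseudo-jitter (no RNG): breaks exact symmetries such as
# collinear placements without compromising reproducibility.
det_jitter <- function(n, scale = 1e-3) {
  idx <- seq_len(n * 3)
  matrix(sin(idx * 12.9898) * scale, n, 3)
}

#' Pluggable geometry refiner hook
#'
#' Stands in for an external electronic-structure re-optimisation stage: any
#' callable mapping a geometry to a geometry with the same atom count.  The
#' default is the identity.
#'
#' @param fn function `crn_geometry -> crn_geometry`.
#' @return The function, validated and classed.
#' @export
refiner_hook <- function(fn = identity) {
  stopifnot(is.function(fn))
  structure(fn, class = c("crn_refiner", "function"))
}

#' Optimise a geometry onto a target connectivity matrix
#'
#' Minimises the GRP from the start coordinates (after displacing
#' newly-separated fragments along their former bond axes), re-perceives
#' bonding, applies the refiner hook, and re-perceives again.  If either
#' stage yields a connectivity differing from the target -- or the optimizer
#' fails to reach the zero-energy basin -- a mismatch is reported instead of
#' a wrong geometry.
#'
#' @param start a [geometry()] with the same atom count as `target`.
#' @param target target connectivity matrix.
#' @param radii a [covalent_radii()] table.
#' @param params a [grp_params()].
#' @param refiner a [refiner_hook()].
#' @return List: `ok` (logical), `geometry` (on success), `reason` (on
#'   mismatch).
#' @export
optimize_to_graph <- function(start, target, radii = covalent_radii(),
                              params = grp_params(), refiner = refiner_hook()) {
  stopifnot(inherits(start, "crn_geometry"))
  n <- length(start$elements)
  check_cm(target, n)
  coords <- start$coords
  cm0 <- connectivity_from_geometry(start, radii)
  cut <- bond_cutoffs(start$elements, radii)
  comp <- cm_components(target)
  # Separate fragments along former bond axes before minimisation.
  broken <- which(cm0 == 1L & target == 0L, arr.ind = TRUE)
  broken <- broken[broken[, 1] < broken[, 2], , drop = FALSE]
  if (nrow(broken)) {
    for (r in seq_len(nrow(broken))) {
      i <- broken[r, 1]; j <- broken[r, 2]
      if (comp[i] == comp[j]) next
      axis <- coords[j, ] - coords[i, ]
      nrm <- sqrt(sum(axis^2))
      axis <- if (nrm > 1e-9) axis / nrm else c(1, 0, 0)
      mol_j <- comp == comp[j]
      coords[mol_j, ] <- coords[mol_j, ] +
        matrix(axis * 1.5 * cut[i, j], sum(mol_j), 3, byrow = TRUE)
    }
  }
  coords <- coords + det_jitter(n, 1e-3)
  fn <- function(x) grp_energy(matrix(x, n, 3), target, start$elements, radii, params)$energy
  gr <- function(x) as.vector(grp_energy(matrix(x, n, 3), target, start$elements, radii, params)$gradient)
  opt <- stats::optim(as.vector(coords), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = params$max_iter,
                                     factr = 1e3, pgtol = params$grad_tol))
  out <- geometry(start$elements, matrix(opt$par, n, 3), start$comment)
  perceived <- connectivity_from_geometry(out, radii)
  if (!all(perceived == target)) {
    return(list(ok = FALSE, reason = "GRP minimisation did not realise the target connectivity"))
  }
  refined <- refiner(out)
  if (!inherits(refined, "crn_geometry") ||
      length(refined$elements) != n) {
    return(list(ok = FALSE, reason = "refiner returned an inconsistent geometry"))
  }
  perceived2 <- connectivity_from_geometry(refined, radii)
  if (!all(perceived2 == target)) {
    return(list(ok = FALSE, reason = "refiner changed the connectivity"))
  }
  list(ok = TRUE, geometry = refined)
}

#' Embed a species graph in 3D
#'
#' Deterministic embedding used for seed systems and fixtures: classical
#' multidimensional scaling of graph distances scaled by a typical bond
#' length provides start coordinates, which are then relaxed under the GRP.
#'
#' @param species a `crn_species` (or SMILES string).
#' @param radii a [covalent_radii()] table.
#' @param params a [grp_params()].
#' @return A `crn_geometry` realising the species graph.
#' @export
geometry_from_graph <- function(species, radii = covalent_radii(),
                                params = grp_params()) {
  if (is.character(species)) species <- parse_smiles(species)
  cm <- species$graph
  el <- species$elements
  n <- nrow(cm)
  if (n == 1L) return(geometry(el, matrix(0, 1, 3)))
  g <- igraph::graph_from_adjacency_matrix(cm, mode = "undirected")
  d <- igraph::distances(g) * 1.2
  # planar/linear graphs legitimately have < 3 positive eigenvalues here
  xy <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = min(3L, n - 1L)))
  coords <- matrix(0, n, 3)
  coords[, seq_len(ncol(xy))] <- xy
  coords <- coords + det_jitter(n, 0.05)
  res <- optimize_to_graph(geometry(el, coords), cm, radii, params)
  if (!res$ok) {
    # fall back to a second, larger deterministic perturbation
    res <- optimize_to_graph(geometry(el, coords + det_jitter(n, 0.3)), cm, radii, params)
  }
  if (!res$ok) stop("could not embed species graph for ", species$smiles, call. = FALSE)
  res$geometry
}
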