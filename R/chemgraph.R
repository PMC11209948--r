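#' Molecular geometry
#'
#' A bare container for element symbols plus Cartesian coordinates in
#' Angstrom.  Everything downstream (bond perception, the graph restraining
#' potential, XYZ round trips) works on this object.
#'
#' @param elements character vector of element symbols (length N >= 1).
#' @param coords numeric N x 3 matrix of coordinates (Angstrom).
#' @param comment optional comment string carried through XYZ output.
#' @return Object of class `crn_geometry`.
#' @export
geometry <- function(elements, coords, comment = "") {
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  if (length(elements) < 1L) stop("geometry needs at least one atom", call. = FALSE)
  if (!is.numeric(coords) || ncol(coords) != 3L || nrow(coords) != length(elements)) {
    stop("`coords` must be a numeric N x 3 matrix matching `elements`", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  dimnames(coords) <- NULL
  structure(
    list(elements = elements, coords = coords, comment = as.character(comment)[1]),
    class = "crn_geometry"
  )
}

#' @export
print.crn_geometry <- function(x, ...) {
  cat("<crn_geometry> ", length(x$elements), " atoms: ",
      paste(format_formula(table_formula(x$elements)), collapse = ""), "\n", sep = "")
  invisible(x)
}

table_formula <- function(elements) {
  tab <- table(elements)
  stats::setNames(as.integer(tab), names(tab))
}

# Hill-ish deterministic formula string, e.g. c(C=2, H=6) -> "C2H6"
format_formula <- function(counts) {
  ord <- order(match(names(counts), c("C", "H")), names(counts), na.last = TRUE)
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

#' Read / write XYZ files
#'
#' Standard XYZ: first line atom count, second line comment, then one
#' `element x y z` row per atom.  Multiple concatenated frames are supported
#' on read; a list of geometries writes multiple frames.
#'
#' @param path file path.
#' @return `read_xyz()` returns a `crn_geometry` (or a list of them when the
#'   file holds several frames); `write_xyz()` returns `path` invisibly.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ: bad atom count at line ", i, call. = FALSE)
    if (i + 1L + n > length(lines)) stop("malformed XYZ: truncated frame", call. = FALSE)
    comment <- lines[i + 1L]
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    el <- vapply(rows, `[[`, "", 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- geometry(el, xyz, comment)
    i <- i + 2L + n
  }
  if (length(frames) == 1L) frames[[1L]] else frames
}

#' @rdname read_xyz
#' @param geom a `crn_geometry` or list of them.
#' @export
write_xyz <- function(geom, path) {
  frames <- if (inherits(geom, "crn_geometry")) list(geom) else geom
  out <- unlist(lapply(frames, function(g) {
    c(length(g$elements), g$comment,
      sprintf("%-3s %18.10f %18.10f %18.10f",
              g$elements, g$coords[, 1], g$coords[, 2], g$coords[, 3]))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Pairwise bond cutoffs for a set of elements
#'
#' @param elements character vector of element symbols.
#' @param radii a [covalent_radii()] table.
#' @return N x N matrix of cutoff distances `alpha * (R_i + R_j)` (Angstrom).
#' @export
bond_cutoffs <- function(elements, radii = covalent_radii()) {
  unknown <- setdiff(unique(elements), names(radii$radius_by_element))
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  r <- radii$radius_by_element[elements]
  radii$alpha * outer(r, r, `+`)
}

#' Perceive the connectivity matrix of a geometry
#'
#' Atoms i and j (i != j) are bonded iff their Euclidean distance is strictly
#' below `alpha * (R_i + R_j)`.  Bond orders are not modelled: the matrix is
#' binary, symmetric, zero on the diagonal.
#'
#' @param geom a [geometry()].
#' @param radii a [covalent_radii()] table.
#' @return Integer N x N connectivity matrix (0/1).
#' @examples
#' g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' connectivity_from_geometry(g)
#' @export
connectivity_from_geometry <- function(geom, radii = covalent_radii()) {
  stopifnot(inherits(geom, "crn_geometry"))
  cut <- bond_cutoffs(geom$elements, radii)
  d <- as.matrix(stats::dist(geom$coords))
  cm <- (d < cut) * 1L
  diag(cm) <- 0L
  storage.mode(cm) <- "integer"
  dimnames(cm) <- NULL
  cm
}

check_cm <- function(cm, n = NULL) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stop("connectivity matrix must be square", call. = FALSE)
  if (!is.null(n) && nrow(cm) != n) stop("connectivity matrix size does not match geometry", call. = FALSE)
  if (any(cm != t(cm))) stop("connectivity matrix must be symmetric", call. = FALSE)
  if (any(diag(cm) != 0)) stop("connectivity matrix must have zero diagonal", call. = FALSE)
  if (!all(cm %in% c(0L, 1L))) stop("connectivity matrix entries must be 0/1", call. = FALSE)
  invisible(TRUE)
}

# Connected components of a 0/1 adjacency matrix; returns integer membership.
cm_components <- function(cm) {
  n <- nrow(cm)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- which(cm[v, ] == 1L)
      stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  comp
}

#' Split a system into its molecules
#'
#' Extracts the connected components of a connectivity matrix, returning one
#' species (plus its sub-geometry, when coordinates are supplied) per
#' molecule.
#'
#' @param cm connectivity matrix of the combined system.
#' @param geom optional [geometry()] consistent with `cm`; when supplied each
#'   component carries its own coordinates.
#' @param elements element symbols; defaults to `geom$elements`.
#' @param valence a [valence_constraints()] table used for canonical ids.
#' @return List with one entry per component: `list(species =, geometry =,
#'   atoms = <original atom indices>)`.
#' @export
split_molecules <- function(cm, geom = NULL, elements = NULL,
                            valence = valence_constraints()) {
  if (is.null(elements)) {
    if (is.null(geom)) stop("need `geom` or `elements`", call. = FALSE)
    elements <- geom$elements
  }
  check_cm(cm, length(elements))
  comp <- cm_components(cm)
  lapply(seq_len(max(comp)), function(k) {
    idx <- which(comp == k)
    sp <- canonical_species(cm[idx, idx, drop = FALSE], elements[idx], valence = valence)
    gsub <- if (!is.null(geom)) geometry(elements[idx], geom$coords[idx, , drop = FALSE]) else NULL
    list(species = sp, geometry = gsub, atoms = idx)
  })
}

#' A chemical system: species with multiplicities
#'
#' @param species list of `crn_species` (or SMILES strings, parsed on the
#'   fly), possibly with repeats to express multiplicity.
#' @param geometries optional list of per-molecule geometries (same length).
#' @return Object of class `crn_system`.
#' @export
chem_system <- function(species, geometries = NULL) {
  species <- lapply(species, function(s) {
    if (is.character(s)) parse_smiles(s) else s
  })
  if (!all(vapply(species, inherits, TRUE, "crn_species"))) {
    stop("`species` must be crn_species objects or SMILES strings", call. = FALSE)
  }
  if (!is.null(geometries) && length(geometries) != length(species)) {
    stop("`geometries` must match `species` in length", call. = FALSE)
  }
  structure(list(species = species, geometries = geometries), class = "crn_system")
}

#' @export
print.crn_system <- function(x, ...) {
  ids <- vapply(x$species, `[[`, "", "smiles")
  cat("<crn_system> ", paste(ids, collapse = " + "), "\n", sep = "")
  invisible(x)
}

# Combined geometry + CM + elements for a system; molecules are laid out on a
# line with >= `gap` Angstrom between bounding spheres so no spurious bonds
# appear.  Missing geometries are embedded from the species graph.
assemble_system <- function(system, radii = covalent_radii(),
                            grp = grp_params(), gap = 4) {
  geoms <- vector("list", length(system$species))
  for (i in seq_along(system$species)) {
    g <- if (!is.null(system$geometries)) system$geometries[[i]] else NULL
    if (is.null(g)) {
      g <- geometry_from_graph(system$species[[i]], radii = radii, params = grp)
    }
    geoms[[i]] <- g
  }
  offset <- 0
  coords <- NULL
  elements <- character(0)
  mol_of <- integer(0)
  for (i in seq_along(geoms)) {
    xyz <- geoms[[i]]$coords
    xyz <- sweep(xyz, 2, colMeans(xyz))
    half <- max(sqrt(rowSums(xyz^2)), 0)
    offset <- offset + half
    xyz[, 1] <- xyz[, 1] + offset
    offset <- offset + half + gap
    coords <- rbind(coords, xyz)
    elements <- c(elements, geoms[[i]]$elements)
    mol_of <- c(mol_of, rep.int(i, nrow(xyz)))
  }
  geom <- geometry(elements, coords)
  list(geometry = geom,
       cm = connectivity_from_geometry(geom, radii),
       molecule = mol_of)
}
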