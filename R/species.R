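#' Canonical species identity
#'
#' Turns one connected molecular fragment (binary connectivity + element
#' labels) into a species object whose `smiles` field is a canonical,
#' hydrogen-folded SMILES string.  Canonicalisation rests on igraph's BLISS
#' canonical permutation of the hydrogen-folded skeleton with vertices
#' coloured by (element, attached-H count), so isomorphic fragments map to
#' identical strings and non-isomorphic fragments (at the connectivity level)
#' to distinct ones.  Radical centres are implied by valence deficit and
#' rendered as bracket atoms, e.g. `[CH3]`; bond orders, charges and
#' stereochemistry are outside the model.
#'
#' @param cm connectivity matrix of the fragment (must be connected).
#' @param elements element symbols, one per row of `cm`.
#' @param valence a [valence_constraints()] table; an atom whose degree
#'   exceeds its entry cannot be rationalised into SMILES and raises a
#'   condition of class `crn_canonicalization_error` (the sampler catches
#'   this and rejects the offending move).
#' @return Object of class `crn_species`: `smiles`, `formula` (named element
#'   counts), `elements`, `graph` (the input connectivity matrix).
#' @examples
#' cm <- matrix(0L, 5, 5); cm[1, 2:5] <- cm[2:5, 1] <- 1L
#' canonical_species(cm, c("C", "H", "H", "H", "H"))$smiles  # "C"
#' @export
canonical_species <- function(cm, elements, valence = valence_constraints()) {
  check_cm(cm, length(elements))
  comp <- cm_components(cm)
  if (max(comp) != 1L) {
    stop("fragment must be connected; use split_molecules() first", call. = FALSE)
  }
  smiles <- graph_to_smiles(cm, elements, valence)
  structure(
    list(
      smiles = smiles,
      formula = table_formula(elements),
      elements = elements,
      graph = cm
    ),
    class = "crn_species"
  )
}

#' @export
print.crn_species <- function(x, ...) {
  cat("<crn_species> ", x$smiles, " (", format_formula(x$formula), ")\n", sep = "")
  invisible(x)
}

#' @export
format.crn_species <- function(x, ...) x$smiles

canon_error <- function(msg) {
  rlang::abort(msg, class = "crn_canonicalization_error")
}

# Organic-subset symbols that may be written without brackets when their
# implicit-H reading reproduces the exact H count.
.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.smiles_cache <- new.env(parent = emptyenv())

# Canonical SMILES writer for connectivity-level graphs (single bonds only).
# Memoised on (elements, cm, valence): system states repeat heavily during
# sampling, and canonical ids are pure functions of the labelled graph.
graph_to_smiles <- function(cm, elements, valence = valence_constraints()) {
  key <- paste(c(elements, cm, unclass(valence)), collapse = "|")
  hit <- .smiles_cache[[key]]
  if (!is.null(hit)) {
    if (inherits(hit, "condition")) stop(hit)
    return(hit)
  }
  val <- tryCatch(graph_to_smiles_impl(cm, elements, valence),
                  crn_canonicalization_error = function(e) e)
  .smiles_cache[[key]] <- val
  if (inherits(val, "condition")) stop(val)
  val
}

graph_to_smiles_impl <- function(cm, elements, valence = valence_constraints()) {
  n <- length(elements)
  deg <- rowSums(cm)
  vmax <- unclass(valence)[elements]
  bad <- which(!is.na(vmax) & deg > vmax)
  if (length(bad)) {
    canon_error(sprintf(
      "atom %d (%s) has degree %d exceeding its maximum valence %d",
      bad[1], elements[bad[1]], deg[bad[1]], vmax[bad[1]]))
  }
  # Fold hydrogens bonded to exactly one heavy atom.
  is_h <- elements == "H"
  heavy_nb <- function(i) which(cm[i, ] == 1L & !is_h)
  foldable <- is_h & deg == 1L & vapply(seq_len(n), function(i) length(heavy_nb(i)) == 1L, TRUE)
  keep <- which(!foldable)
  nH <- vapply(keep, function(i) sum(cm[i, ] == 1L & foldable), 0L)
  skel <- cm[keep, keep, drop = FALSE]
  el <- elements[keep]
  m <- length(keep)
  if (m == 1L) {
    return(atom_token(el[1], nH[1], 0L, valence))
  }
  lab <- paste(el, nH)
  colors <- match(lab, sort(unique(lab)))
  g <- igraph::graph_from_adjacency_matrix(skel, mode = "undirected")
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  # perm[i] = canonical index of vertex i; build inverse ordering
  ord <- order(perm)
  skel <- skel[ord, ord, drop = FALSE]
  el <- el[ord]
  nH <- nH[ord]
  write_smiles_component(skel, el, nH, valence)
}

atom_token <- function(sym, nH, shown_bonds, valence) {
  defv <- unclass(valence)[sym]
  plain_ok <- sym %in% .organic_subset && !is.na(defv) &&
    (shown_bonds + nH) == defv
  if (plain_ok) return(sym)
  paste0("[", sym,
         if (nH > 0L) paste0("H", if (nH > 1L) nH else ""),
         "]")
}

# Deterministic SMILES emission over a canonical-ordered skeleton: DFS from
# vertex 1, neighbours in ascending canonical index, back edges as ring
# closures numbered in discovery order.
write_smiles_component <- function(adj, el, nH, valence) {
  m <- nrow(adj)
  visited <- rep(FALSE, m)
  children <- vector("list", m)
  back_at <- vector("list", m)   # ring digits per vertex, in emission order
  ring_n <- 0L
  open_ring <- list()            # key "u-v" -> digit
  dfs <- function(v, p) {
    visited[v] <<- TRUE
    for (u in which(adj[v, ] == 1L)) {
      if (!is.na(p) && u == p) next
      if (visited[u]) {
        key <- paste(min(u, v), max(u, v), sep = "-")
        if (is.null(open_ring[[key]])) {
          ring_n <<- ring_n + 1L
          open_ring[[key]] <<- ring_n
          back_at[[u]] <<- c(back_at[[u]], ring_n)
          back_at[[v]] <<- c(back_at[[v]], ring_n)
        }
      } else {
        children[[v]] <<- c(children[[v]], u)
        dfs(u, v)
      }
    }
  }
  # Start at the canonically-first vertex of minimum degree: deterministic on
  # the canonical form, and yields conventional strings (CCC, not C(C)C).
  start <- which(rowSums(adj) == min(rowSums(adj)))[1]
  dfs(start, NA_integer_)
  ring_digit <- function(k) if (k <= 9L) as.character(k) else paste0("%", k)
  emit <- function(v) {
    shown <- sum(adj[v, ])   # heavy neighbours + ring bonds all shown
    tok <- atom_token(el[v], nH[v], shown, valence)
    rings <- paste(vapply(sort(back_at[[v]]), ring_digit, ""), collapse = "")
    kids <- children[[v]]
    if (length(kids) == 0L) return(paste0(tok, rings))
    parts <- vapply(kids, emit, "")
    paste0(tok, rings,
           if (length(parts) > 1L)
             paste0(paste0("(", parts[-length(parts)], ")", collapse = ""))
           else "",
           parts[length(parts)])
  }
  emit(start)
}

#' Parse a (subset) SMILES string into species
#'
#' Supports the connectivity-level subset this package emits: organic-subset
#' atoms with implicit hydrogens, bracket atoms with explicit H counts (and
#' implied radical centres), branches, ring closures (including `%nn`), and
#' dot-separated components.  Bond-order symbols (`=`, `#`, `:`) are
#' rejected: bonding here is binary.
#'
#' @param smiles a SMILES string.
#' @param valence a [valence_constraints()] table for implicit-H filling.
#' @return A `crn_species` for a single component, or a list of them when
#'   the string contains dots.
#' @examples
#' parse_smiles("CC")$formula
#' @export
parse_smiles <- function(smiles, valence = valence_constraints()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  comps <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  comps <- comps[nzchar(comps)]
  if (length(comps) == 0L) stop("empty SMILES", call. = FALSE)
  out <- lapply(comps, parse_smiles_component, valence = valence)
  if (length(out) == 1L) out[[1]] else out
}

parse_smiles_component <- function(s, valence) {
  chars <- strsplit(s, "")[[1]]
  atoms <- character(0)       # element of each atom
  explicitH <- integer(0)     # NA = organic-subset implicit fill
  bonds <- list()
  prev_stack <- integer(0)
  prev <- NA_integer_
  ring_open <- list()
  i <- 1L
  add_atom <- function(sym, nH) {
    atoms[[length(atoms) + 1L]] <<- sym
    explicitH[[length(atoms)]] <<- nH
    id <- length(atoms)
    if (!is.na(prev)) bonds[[length(bonds) + 1L]] <<- c(prev, id)
    prev <<- id
    id
  }
  close_ring <- function(num) {
    key <- as.character(num)
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- prev
    } else {
      bonds[[length(bonds) + 1L]] <<- c(ring_open[[key]], prev)
      ring_open[[key]] <<- NULL
    }
  }
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      prev_stack <- c(prev_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(prev_stack)) stop("unbalanced ')' in SMILES", call. = FALSE)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (ch == "[") {
      j <- which(chars == "]" & seq_len(n) > i)[1]
      if (is.na(j)) stop("unterminated bracket atom", call. = FALSE)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      mm <- regmatches(body, regexec("^([A-Z][a-z]?)(H([0-9]+)?)?$", body))[[1]]
      if (length(mm) == 0L) stop("unsupported bracket atom: [", body, "]", call. = FALSE)
      sym <- mm[2]
      nH <- if (nzchar(mm[3])) { if (nzchar(mm[4])) as.integer(mm[4]) else 1L } else 0L
      add_atom(sym, nH)
      i <- j + 1L
    } else if (ch == "%") {
      num <- as.integer(paste(chars[(i + 1L):(i + 2L)], collapse = ""))
      close_ring(num); i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch)); i <- i + 1L
    } else if (ch == "-") {
      i <- i + 1L                       # explicit single bond: no-op
    } else if (ch %in% c("=", "#", ":", "/", "\\", "+", "@")) {
      stop("unsupported SMILES feature '", ch, "': only single-bond connectivity is modelled",
           call. = FALSE)
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, NA_integer_); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, NA_integer_); i <- i + 1L
      } else {
        stop("unsupported SMILES token at '", ch, "'", call. = FALSE)
      }
    }
  }
  if (length(ring_open)) stop("unclosed ring bond in SMILES", call. = FALSE)
  n_heavy <- length(atoms)
  deg <- integer(n_heavy)
  for (b in bonds) { deg[b[1]] <- deg[b[1]] + 1L; deg[b[2]] <- deg[b[2]] + 1L }
  nH <- explicitH
  for (a in seq_len(n_heavy)) {
    if (is.na(nH[a])) {
      defv <- unclass(valence)[atoms[a]]
      if (is.na(defv)) stop("no default valence for element ", atoms[a], call. = FALSE)
      nH[a] <- max(defv - deg[a], 0L)
    }
  }
  n_tot <- n_heavy + sum(nH)
  el <- c(atoms, rep("H", sum(nH)))
  cm <- matrix(0L, n_tot, n_tot)
  for (b in bonds) { cm[b[1], b[2]] <- cm[b[2], b[1]] <- 1L }
  hidx <- n_heavy
  for (a in seq_len(n_heavy)) {
    if (nH[a] > 0L) {
      for (k in seq_len(nH[a])) {
        hidx <- hidx + 1L
        cm[a, hidx] <- cm[hidx, a] <- 1L
      }
    }
  }
  canonical_species(cm, el, valence = valence)
}

#' Canonical id of a multi-molecule state
#'
#' Sorted component SMILES joined with dots; used as the dedup key for
#' system states and reaction sides.
#'
#' @param species list of `crn_species`.
#' @return A single string.
#' @export
system_smiles <- function(species) {
  paste(sort(vapply(species, `[[`, "", "smiles")), collapse = ".")
}
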