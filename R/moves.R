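#' Define a graph move
#'
#' A graph move is a templated edit of the connectivity matrix over `k`
#' abstract atom slots: an ordered set of bond deltas (+1 make, -1 break)
#' between slot pairs, optional per-slot element whitelists, and a relative
#' selection weight.
#'
#' @param name label for the move.
#' @param k number of atom slots (>= 2).
#' @param deltas data frame (or matrix) with columns `i`, `j`, `delta`; each
#'   row changes the bond between slots `i` and `j` by `delta` in {-1, +1}.
#' @param allowed_elements list of length `k`; each entry a character vector
#'   of allowed elements for that slot (`character(0)` = any element).
#' @param weight relative selection probability (>= 0, finite).
#' @return Object of class `crn_move`.
#' @export
graph_move <- function(name, k, deltas, allowed_elements = NULL, weight = 1) {
  deltas <- as.data.frame(deltas)
  names(deltas) <- c("i", "j", "delta")
  k <- as.integer(k)
  if (k < 2L) stop("a move needs at least 2 slots", call. = FALSE)
  if (nrow(deltas) < 1L) stop("a move needs at least one bond delta", call. = FALSE)
  if (!all(deltas$delta %in% c(-1L, 1L))) stop("deltas must be +1 or -1", call. = FALSE)
  if (any(deltas$i == deltas$j) || any(deltas$i > k) || any(deltas$j > k) ||
      any(deltas$i < 1L) || any(deltas$j < 1L)) {
    stop("delta slots must be distinct indices in 1..k", call. = FALSE)
  }
  key <- paste(pmin(deltas$i, deltas$j), pmax(deltas$i, deltas$j))
  if (anyDuplicated(key)) stop("no slot pair may be repeated in deltas", call. = FALSE)
  if (is.null(allowed_elements)) allowed_elements <- rep(list(character(0)), k)
  if (length(allowed_elements) != k) {
    stop("`allowed_elements` must have one entry per slot", call. = FALSE)
  }
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) || weight < 0) {
    stop("`weight` must be a finite non-negative number", call. = FALSE)
  }
  structure(
    list(name = name, k = k,
         deltas = data.frame(i = as.integer(deltas$i), j = as.integer(deltas$j),
                             delta = as.integer(deltas$delta)),
         allowed_elements = allowed_elements, weight = weight),
    class = "crn_move"
  )
}

#' Bundle graph moves into a library
#'
#' @param ... `crn_move` objects (or a single list of them).
#' @return Object of class `crn_move_library`.
#' @export
move_library <- function(...) {
  moves <- list(...)
  if (length(moves) == 1L && !inherits(moves[[1]], "crn_move")) moves <- moves[[1]]
  if (!length(moves) || !all(vapply(moves, inherits, TRUE, "crn_move"))) {
    stop("a move library is built from crn_move objects", call. = FALSE)
  }
  w <- vapply(moves, `[[`, 0, "weight")
  if (sum(w) <= 0) stop("total move weight must be positive", call. = FALSE)
  structure(list(moves = moves), class = "crn_move_library")
}

#' The default 2-/3-atom move library
#'
#' Spans the elementary reaction classes of single-bond chemistry: bond
#' formation (2-slot, +1), homolytic bond cleavage (2-slot, -1), atom
#' transfer (3-slot: break 1-2, make 2-3) and concerted exchange (3-slot:
#' break 1-2, make 1-3).  All weights default to 1; users can define
#' arbitrary moves via [graph_move()] or a library file.
#'
#' @param weights optional named numeric vector overriding per-move weights.
#' @return A `crn_move_library`.
#' @export
default_move_library <- function(weights = NULL) {
  mv <- list(
    graph_move("bond-formation", 2, data.frame(i = 1, j = 2, delta = 1)),
    graph_move("bond-cleavage", 2, data.frame(i = 1, j = 2, delta = -1)),
    graph_move("atom-transfer", 3, data.frame(i = c(1, 2), j = c(2, 3), delta = c(-1, 1))),
    graph_move("concerted-exchange", 3, data.frame(i = c(1, 1), j = c(2, 3), delta = c(-1, 1)))
  )
  if (!is.null(weights)) {
    for (nm in names(weights)) {
      hit <- which(vapply(mv, `[[`, "", "name") == nm)
      if (!length(hit)) stop("unknown move in `weights`: ", nm, call. = FALSE)
      mv[[hit]]$weight <- weights[[nm]]
    }
  }
  move_library(mv)
}

#' Sample a move from a library
#'
#' Move m is drawn with probability `weight(m) / sum(weights)` using the
#' current RNG stream.
#'
#' @param lib a [move_library()].
#' @return A `crn_move`.
#' @export
sample_move <- function(lib) {
  stopifnot(inherits(lib, "crn_move_library"))
  w <- vapply(lib$moves, `[[`, 0, "weight")
  lib$moves[[sample.int(length(w), 1L, prob = w)]]
}

# Slot automorphisms of a move: permutations of 1..k mapping the delta set
# (and element whitelists) onto themselves.  Used to deduplicate symmetric
# slot assignments.  k <= 4 in practice, so brute force is fine.
move_slot_symmetries <- function(move) {
  k <- move$k
  perms <- permutations_of(k)
  key0 <- delta_key(move$deltas)
  keep <- vapply(perms, function(p) {
    d <- move$deltas
    d$i <- p[d$i]; d$j <- p[d$j]
    identical(delta_key(d), key0) &&
      all(vapply(seq_len(k), function(s)
        identical(move$allowed_elements[[s]], move$allowed_elements[[p[s]]]), TRUE))
  }, TRUE)
  perms[keep]
}

delta_key <- function(d) {
  a <- pmin(d$i, d$j); b <- pmax(d$i, d$j)
  ord <- order(a, b)
  paste(a[ord], b[ord], d$delta[ord], collapse = ";")
}

permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in permutations_of(k - 1L)) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

slot_elements_ok <- function(move, elements, assignment) {
  for (s in seq_len(move$k)) {
    allowed <- move$allowed_elements[[s]]
    if (length(allowed) && !(elements[assignment[s]] %in% allowed)) return(FALSE)
  }
  TRUE
}

deltas_applicable <- function(move, cm, assignment) {
  for (r in seq_len(nrow(move$deltas))) {
    a <- assignment[move$deltas$i[r]]
    b <- assignment[move$deltas$j[r]]
    bond <- cm[a, b]
    if (move$deltas$delta[r] > 0L && bond != 0L) return(FALSE)
    if (move$deltas$delta[r] < 0L && bond != 1L) return(FALSE)
  }
  TRUE
}

#' Apply a graph move to a connectivity matrix
#'
#' Applies the move's bond deltas at the given slot assignment, then runs the
#' validity checks: per-atom valence limits and forbidden-pattern screening.
#' The input matrix is never modified; a failed check returns a rejection so
#' the sampler can restore state and resample.
#'
#' @param cm connectivity matrix.
#' @param elements element symbols for the atoms of `cm`.
#' @param move a [graph_move()].
#' @param assignment integer vector of length `move$k`: the atom index bound
#'   to each slot (all distinct).
#' @param valence a [valence_constraints()] table.
#' @param forbidden a [forbidden_patterns()] object or `NULL`.
#' @return List with `accepted` (logical); on success `cm` holds the new
#'   matrix, on rejection `reason` says which check failed.
#' @examples
#' eth <- parse_smiles("CC")
#' brk <- default_move_library()$moves[[2]]
#' res <- apply_move(eth$graph, eth$elements, brk, c(1, 2))
#' res$accepted
#' @export
apply_move <- function(cm, elements, move, assignment,
                       valence = valence_constraints(), forbidden = NULL) {
  assignment <- as.integer(assignment)
  if (length(assignment) != move$k || anyDuplicated(assignment) ||
      any(assignment < 1L) || any(assignment > nrow(cm))) {
    return(list(accepted = FALSE, reason = "invalid slot assignment"))
  }
  if (!slot_elements_ok(move, elements, assignment)) {
    return(list(accepted = FALSE, reason = "element whitelist"))
  }
  if (!deltas_applicable(move, cm, assignment)) {
    return(list(accepted = FALSE, reason = "delta precondition"))
  }
  new_cm <- cm
  for (r in seq_len(nrow(move$deltas))) {
    a <- assignment[move$deltas$i[r]]
    b <- assignment[move$deltas$j[r]]
    new_cm[a, b] <- new_cm[b, a] <- new_cm[a, b] + move$deltas$delta[r]
  }
  deg <- rowSums(new_cm)
  vmax <- unclass(valence)[elements]
  if (any(!is.na(vmax) & deg > vmax)) {
    return(list(accepted = FALSE, reason = "valence violation"))
  }
  if (!is.null(forbidden) && has_forbidden_pattern(new_cm, elements, forbidden)) {
    return(list(accepted = FALSE, reason = "forbidden pattern"))
  }
  list(accepted = TRUE, cm = new_cm)
}

#' Forbidden bonding patterns
#'
#' Small element-labelled graphs whose occurrence as a subgraph disqualifies
#' a candidate connectivity matrix (VF2 subgraph isomorphism on element
#' colours).
#'
#' @param patterns list of `list(cm =, elements =)` entries (or
#'   `crn_species` objects).
#' @return Object of class `crn_forbidden`.
#' @export
forbidden_patterns <- function(patterns) {
  patterns <- lapply(patterns, function(p) {
    if (inherits(p, "crn_species")) p <- list(cm = p$graph, elements = p$elements)
    stopifnot(is.matrix(p$cm), length(p$elements) == nrow(p$cm), nrow(p$cm) >= 1L)
    p
  })
  if (!length(patterns)) stop("need at least one pattern", call. = FALSE)
  structure(list(patterns = patterns), class = "crn_forbidden")
}

has_forbidden_pattern <- function(cm, elements, forbidden) {
  g <- igraph::graph_from_adjacency_matrix(cm, mode = "undirected")
  all_el <- unique(c(elements, unlist(lapply(forbidden$patterns, `[[`, "elements"))))
  for (p in forbidden$patterns) {
    gp <- igraph::graph_from_adjacency_matrix(p$cm, mode = "undirected")
    hit <- igraph::subgraph_isomorphic(
      gp, g, method = "vf2",
      vertex.color1 = match(elements, all_el),    # target colours
      vertex.color2 = match(p$elements, all_el)   # pattern colours
    )
    if (hit) return(TRUE)
  }
  FALSE
}

#' Enumerate all valid applications of a move
#'
#' Exhaustively lists the slot assignments for which [apply_move()] would
#' succeed, deduplicated up to the move's internal slot symmetries.  This is
#' the deterministic backbone of both the sampling step (a uniform draw over
#' valid applications) and the brute-force exploration oracle.
#'
#' @inheritParams apply_move
#' @return List of integer assignments (possibly empty).
#' @export
enumerate_applications <- function(cm, elements, move,
                                   valence = valence_constraints(),
                                   forbidden = NULL) {
  n <- nrow(cm)
  if (n < move$k) return(list())
  syms <- move_slot_symmetries(move)
  seen <- character(0)
  out <- list()
  idx <- seq_len(n)
  grid <- as.matrix(do.call(expand.grid, rep(list(idx), move$k)))
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    if (anyDuplicated(asg)) next
    canon <- min(vapply(syms, function(p) paste(asg[p], collapse = ","), ""))
    if (canon %in% seen) next
    res <- apply_move(cm, elements, move, asg, valence, forbidden)
    if (res$accepted) {
      seen <- c(seen, canon)
      out[[length(out) + 1L]] <- asg
    }
  }
  out
}

#' Read / write a move-library file
#'
#' Plain-text schema, one YAML document with a `moves` list; each record has
#' `name`, `slots`, `deltas` (list of `[i, j, delta]` triples),
#' `allowed_elements` (list of per-slot element vectors, empty = any) and
#' `weight`.
#'
#' @param path file path.
#' @return `read_move_library()` returns a `crn_move_library`;
#'   `write_move_library()` returns `path` invisibly.
#' @export
read_move_library <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$moves)) stop("move-library file must contain a `moves` list", call. = FALSE)
  moves <- lapply(doc$moves, function(m) {
    d <- do.call(rbind, m$deltas)
    ae <- lapply(m$allowed_elements %||% rep(list(list()), m$slots),
                 function(x) as.character(unlist(x)))
    graph_move(m$name, m$slots, data.frame(i = d[, 1], j = d[, 2], delta = d[, 3]),
               allowed_elements = ae, weight = m$weight %||% 1)
  })
  move_library(moves)
}

#' @rdname read_move_library
#' @param lib a `crn_move_library`.
#' @export
write_move_library <- function(lib, path) {
  doc <- list(moves = lapply(lib$moves, function(m) {
    list(
      name = m$name,
      slots = m$k,
      deltas = lapply(seq_len(nrow(m$deltas)),
                      function(r) as.list(unname(unlist(m$deltas[r, ])))),
      allowed_elements = lapply(m$allowed_elements, as.list),
      weight = m$weight
    )
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
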