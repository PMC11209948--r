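#' An empty reaction network
#'
#' A CRN holds an ordered unique species table and an ordered unique
#' directional reaction table with provenance tags (exploration level and
#' iteration).  Reactions are deduplicated by their direction-specific key.
#'
#' @return Object of class `crn_network`.
#' @export
reaction_network <- function() {
  structure(
    list(
      species = list(),                      # named list: smiles -> crn_species
      reactions = list(),                    # list of crn_reaction
      reaction_keys = character(0),
      provenance = tibble::tibble(key = character(0), level = integer(0),
                                  iteration = integer(0))
    ),
    class = "crn_network"
  )
}

#' @export
print.crn_network <- function(x, ...) {
  cat("<crn_network> ", length(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Number of species / reactions in a network
#' @param net a `crn_network`.
#' @return Integer.
#' @export
n_species <- function(net) length(net$species)

#' @rdname n_species
#' @export
n_reactions <- function(net) length(net$reactions)

#' Add reactions (and their species) to a network
#'
#' Deduplication is idempotent: re-adding an existing reaction leaves the
#' network unchanged.  Every reaction must be element-balanced against the
#' species definitions; an unbalanced reaction is a hard error, never a
#' tolerance.
#'
#' @param net a [reaction_network()].
#' @param reactions list of `crn_reaction`.
#' @param species named list of `crn_species` (by canonical SMILES) covering
#'   any species new to the network.
#' @param level,iteration provenance tags.
#' @return List `list(net, n_new)`: the updated network and how many
#'   reactions were actually new.
#' @export
add_reactions <- function(net, reactions, species, level = 0L, iteration = 0L) {
  stopifnot(inherits(net, "crn_network"))
  n_new <- 0L
  for (rxn in reactions) {
    if (rxn$key %in% net$reaction_keys) next
    ids <- c(rxn$reactants, rxn$products)
    for (id in unique(ids)) {
      if (is.null(net$species[[id]])) {
        sp <- species[[id]]
        if (is.null(sp)) stop("no species definition supplied for ", id, call. = FALSE)
        net$species[[id]] <- sp
      }
    }
    if (!reaction_balanced(rxn, net$species)) {
      stop("unbalanced reaction: ", rxn$key, call. = FALSE)
    }
    net$reactions[[length(net$reactions) + 1L]] <- rxn
    net$reaction_keys <- c(net$reaction_keys, rxn$key)
    net$provenance <- dplyr::bind_rows(
      net$provenance,
      tibble::tibble(key = rxn$key, level = as.integer(level),
                     iteration = as.integer(iteration)))
    n_new <- n_new + 1L
  }
  list(net = net, n_new = n_new)
}

#' Tabular views of a network
#'
#' `tidy()` returns the reaction table (one row per directional reaction,
#' with provenance); `glance()` a one-row summary.
#'
#' @param x a `crn_network`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy crn_network
#' @export
tidy.crn_network <- function(x, ...) {
  if (!length(x$reactions)) {
    return(tibble::tibble(key = character(0), reactants = list(),
                          products = list(), level = integer(0),
                          iteration = integer(0)))
  }
  tibble::tibble(
    key = vapply(x$reactions, `[[`, "", "key"),
    reactants = lapply(x$reactions, `[[`, "reactants"),
    products = lapply(x$reactions, `[[`, "products"),
    level = x$provenance$level,
    iteration = x$provenance$iteration
  )
}

#' @rdname tidy.crn_network
#' @method glance crn_network
#' @export
glance.crn_network <- function(x, ...) {
  tibble::tibble(n_species = n_species(x), n_reactions = n_reactions(x))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Species table of a network
#'
#' @param net a `crn_network`.
#' @return Tibble with `smiles` and `formula` (list column of named counts).
#' @export
species_table <- function(net) {
  tibble::tibble(
    smiles = names(net$species),
    formula = lapply(net$species, `[[`, "formula")
  )
}

#' Serialize / read a network as structured text
#'
#' Plain-text format: a `[species]` section (one canonical SMILES per line;
#' abstract species append `TAB formula` as `El:count` pairs) and a
#' `[reactions]` section (one `reactants>>products TAB level TAB iteration`
#' line each).  Round-trip stable.
#'
#' @param net a `crn_network`.
#' @param path file path.
#' @export
write_network <- function(net, path) {
  sp_lines <- vapply(names(net$species), function(id) {
    sp <- net$species[[id]]
    f <- sp$formula
    paste0(id, "\t", paste0(names(f), ":", f, collapse = ","))
  }, "")
  rx_lines <- vapply(seq_along(net$reactions), function(i) {
    paste0(net$reactions[[i]]$key, "\t",
           net$provenance$level[i], "\t", net$provenance$iteration[i])
  }, "")
  writeLines(c("[species]", sp_lines, "[reactions]", rx_lines), path)
  invisible(path)
}

#' @rdname write_network
#' @param parse_graphs when `TRUE` (default) species whose SMILES parses are
#'   given full graphs; failures fall back to formula-only abstract species.
#' @export
read_network <- function(path, parse_graphs = TRUE) {
  lines <- readLines(path)
  isec <- which(lines %in% c("[species]", "[reactions]"))
  sp_lines <- lines[seq(isec[1] + 1L, isec[2] - 1L)]
  rx_lines <- if (isec[2] < length(lines)) lines[seq(isec[2] + 1L, length(lines))] else character(0)
  sp_lines <- sp_lines[nzchar(sp_lines)]
  rx_lines <- rx_lines[nzchar(rx_lines)]
  species <- list()
  for (sl in sp_lines) {
    parts <- strsplit(sl, "\t", fixed = TRUE)[[1]]
    id <- parts[1]
    f_pairs <- strsplit(strsplit(parts[2], ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    formula <- stats::setNames(as.integer(vapply(f_pairs, `[[`, "", 2L)),
                               vapply(f_pairs, `[[`, "", 1L))
    sp <- NULL
    if (parse_graphs) sp <- tryCatch(parse_smiles(id), error = function(e) NULL)
    if (is.null(sp) || inherits(sp, "list")) sp <- abstract_species(id, formula)
    species[[id]] <- sp
  }
  net <- reaction_network()
  for (rl in rx_lines) {
    parts <- strsplit(rl, "\t", fixed = TRUE)[[1]]
    sides <- strsplit(parts[1], ">>", fixed = TRUE)[[1]]
    rxn <- reaction(strsplit(sides[1], ".", fixed = TRUE)[[1]],
                    strsplit(sides[2], ".", fixed = TRUE)[[1]])
    net <- add_reactions(net, list(rxn), species,
                         level = as.integer(parts[2]),
                         iteration = as.integer(parts[3]))$net
  }
  # keep species that appear in no reaction, too
  for (id in names(species)) if (is.null(net$species[[id]])) net$species[[id]] <- species[[id]]
  net
}

#' An abstract (graph-free) species
#'
#' Used by toy fixtures whose species are labels with element counts rather
#' than molecular graphs.
#'
#' @param id label (acts as the canonical id).
#' @param formula named integer vector of element counts.
#' @return A `crn_species` without a graph.
#' @export
abstract_species <- function(id, formula) {
  structure(
    list(smiles = id, formula = stats::setNames(as.integer(formula), names(formula)),
         elements = rep(names(formula), formula), graph = NULL),
    class = "crn_species"
  )
}

# Build a network straight from reaction SMILES strings + a species lookup;
# convenience for fixtures and tests.
network_from_keys <- function(keys, species, level = 0L) {
  net <- reaction_network()
  for (k in keys) {
    sides <- strsplit(k, ">>", fixed = TRUE)[[1]]
    rxn <- reaction(strsplit(sides[1], ".", fixed = TRUE)[[1]],
                    strsplit(sides[2], ".", fixed = TRUE)[[1]])
    net <- add_reactions(net, list(rxn), species, level = level)$net
  }
  net
}
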