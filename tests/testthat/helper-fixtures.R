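# Shared fixtures and independent oracles, all built in code.

# Ideal staggered ethane: r_CC = 1.54 A, r_CH = 1.09 A, tetrahedral-ish cones.
ideal_ethane <- function() {
  rcc <- 1.54
  rch <- 1.09
  ax <- 0.3337          # cos of the C-C-H cone half-angle complement
  eq <- 0.9428          # sin
  h1 <- t(sapply(0:2, function(k) {
    phi <- k * 2 * pi / 3
    c(-rch * ax, rch * eq * cos(phi), rch * eq * sin(phi))
  }))
  h2 <- t(sapply(0:2, function(k) {
    phi <- pi / 3 + k * 2 * pi / 3
    c(rcc + rch * ax, rch * eq * cos(phi), rch * eq * sin(phi))
  }))
  geometry(c("C", "C", rep("H", 6)), rbind(c(0, 0, 0), c(rcc, 0, 0), h1, h2))
}

# Random connected element-labelled graph with valence-respecting degrees.
# Grows a random tree over heavy atoms, optionally adds an extra edge, then
# fills remaining valence with hydrogens (randomly leaving radical sites).
random_molecule_graph <- function(n_heavy, extra_edge = FALSE, full_h = FALSE) {
  elems <- sample(c("C", "C", "C", "O", "N"), n_heavy, replace = TRUE)
  vmax <- unclass(valence_constraints())[elems]
  adj <- matrix(0L, n_heavy, n_heavy)
  if (n_heavy > 1L) {
    for (i in 2:n_heavy) {
      cand <- which(rowSums(adj)[seq_len(i - 1L)] < vmax[seq_len(i - 1L)])
      if (!length(cand)) return(NULL)
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      adj[p, i] <- adj[i, p] <- 1L
    }
  }
  if (extra_edge && n_heavy >= 3L) {
    deg <- rowSums(adj)
    free <- which(deg < vmax)
    if (length(free) >= 2L) {
      pair <- sample(free, 2L)
      if (adj[pair[1], pair[2]] == 0L) {
        adj[pair[1], pair[2]] <- adj[pair[2], pair[1]] <- 1L
      }
    }
  }
  deg <- rowSums(adj)
  nH <- vmax - deg
  if (!full_h) nH <- vapply(nH, function(k) if (k > 0L) sample(0:k, 1L) else 0L, 0L)
  n <- n_heavy + sum(nH)
  cm <- matrix(0L, n, n)
  cm[seq_len(n_heavy), seq_len(n_heavy)] <- adj
  el <- c(elems, rep("H", sum(nH)))
  at <- n_heavy
  for (a in seq_len(n_heavy)) {
    if (nH[a] > 0L) for (k in seq_len(nH[a])) {
      at <- at + 1L
      cm[a, at] <- cm[at, a] <- 1L
    }
  }
  list(cm = cm, elements = el)
}

# Brute-force labelled-graph isomorphism by permutation search (independent
# of igraph); feasible for n <= 8.
brute_force_isomorphic <- function(cm1, el1, cm2, el2) {
  n <- length(el1)
  if (length(el2) != n) return(FALSE)
  if (!identical(sort(el1), sort(el2))) return(FALSE)
  if (sum(cm1) != sum(cm2)) return(FALSE)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  for (p in perms(seq_len(n))) {
    if (!identical(el1, el2[p])) next
    if (identical(cm1, cm2[p, p])) return(TRUE)
  }
  FALSE
}

# A break-bond-only move library (all weight on cleavage).
cleavage_only_library <- function() {
  move_library(list(graph_move("bond-cleavage", 2,
                               data.frame(i = 1, j = 2, delta = -1))))
}

# Reaction-key set of a network, for oracle comparisons.
network_keys <- function(net) sort(vapply(net$reactions, `[[`, "", "key"))

# Total element counts of one reaction side, from a network's species table.
side_formula <- function(ids, species_by_id) {
  tot <- integer(0)
  for (s in ids) {
    f <- species_by_id[[s]]$formula
    for (el in names(f)) tot[el] <- (if (el %in% names(tot)) tot[[el]] else 0L) + f[[el]]
  }
  tot[order(names(tot))]
}
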