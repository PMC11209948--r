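#' Simulation parameters
#'
#' @param t_end global simulation time (s, > 0); defaults to the
#'   ConditionSet's `t_end` at solve time when `NULL`.
#' @param c0 named numeric vector of initial concentrations (mol dm^-3);
#'   species not named start at zero.
#' @param rtol,atol solver relative / absolute tolerances.
#' @param tau_c chunk length (s) for multitime-scale accumulation, or `NULL`
#'   to disable chunking.
#' @param c_max_prune concentration bound used by [prune_slow()]; `NULL`
#'   defaults to 2x the total initial concentration.
#' @param n_out number of output grid points.
#' @param solver deSolve method name (default `"lsode"`, an implicit
#'   BDF-family multistep stiff integrator used with the analytic Jacobian).
#' @return Object of class `crn_sim_params`.
#' @export
sim_params <- function(t_end = NULL, c0, rtol = 1e-8, atol = 1e-12,
                       tau_c = NULL, c_max_prune = NULL, n_out = 201L,
                       solver = "lsode") {
  stopifnot(is.numeric(c0), !is.null(names(c0)), all(c0 >= 0), rtol > 0, atol > 0)
  if (!is.null(t_end)) stopifnot(t_end > 0)
  if (!is.null(tau_c)) stopifnot(tau_c > 0)
  structure(
    list(t_end = t_end, c0 = c0, rtol = rtol, atol = atol, tau_c = tau_c,
         c_max_prune = c_max_prune, n_out = as.integer(n_out), solver = solver),
    class = "crn_sim_params"
  )
}

#' Build the mass-action reaction rate equation system
#'
#' Translates a deduplicated network into sparse reactant / product
#' stoichiometry (nu^- / nu^+), a vectorised mass-action right-hand side
#' `dc/dt = (nu^+ - nu^-)^T (k * prod c^nu^-)` with parametric rate-constant
#' slots, and the exact analytic Jacobian assembled from the nonzero
#' stoichiometric couplings.
#'
#' @param net a `crn_network`.
#' @return Object of class `crn_rre`: species ids, `nu_minus` / `nu_plus`
#'   (reactions x species), `S` (species x reactions net stoichiometry),
#'   `rhs(t, c, k)` and `jac(t, c, k)` functions, and per-reaction
#'   `molecularity`.
#' @export
build_rre <- function(net) {
  stopifnot(inherits(net, "crn_network"))
  species <- names(net$species)
  ns <- length(species)
  nr <- length(net$reactions)
  nu_minus <- matrix(0L, nr, ns, dimnames = list(NULL, species))
  nu_plus <- matrix(0L, nr, ns, dimnames = list(NULL, species))
  for (i in seq_len(nr)) {
    rxn <- net$reactions[[i]]
    for (s in rxn$reactants) {
      if (!s %in% species) stop("reaction references unknown species ", s, call. = FALSE)
      nu_minus[i, s] <- nu_minus[i, s] + 1L
    }
    for (s in rxn$products) {
      if (!s %in% species) stop("reaction references unknown species ", s, call. = FALSE)
      nu_plus[i, s] <- nu_plus[i, s] + 1L
    }
  }
  S <- t(nu_plus - nu_minus)      # species x reactions
  # per-reaction reactant index/power lists for fast mass-action evaluation
  r_idx <- lapply(seq_len(nr), function(i) which(nu_minus[i, ] > 0L))
  r_pow <- lapply(seq_len(nr), function(i) nu_minus[i, r_idx[[i]]])
  molecularity <- vapply(seq_len(nr), function(i) sum(nu_minus[i, ]), 0L)
  rates_of <- function(conc, k) {
    r <- k
    for (i in seq_len(nr)) {
      r[i] <- r[i] * prod(conc[r_idx[[i]]]^r_pow[[i]])
    }
    r
  }
  rhs <- function(t, conc, k) as.vector(S %*% rates_of(conc, k))
  jac <- function(t, conc, k) {
    dR <- matrix(0, nr, ns)
    for (i in seq_len(nr)) {
      idx <- r_idx[[i]]; pw <- r_pow[[i]]
      for (m in seq_along(idx)) {
        others <- prod(conc[idx[-m]]^pw[-m])
        dR[i, idx[m]] <- k[i] * pw[m] * conc[idx[m]]^(pw[m] - 1L) * others
      }
    }
    S %*% dR
  }
  structure(
    list(species = species, nu_minus = nu_minus, nu_plus = nu_plus, S = S,
         rhs = rhs, jac = jac, rates_of = rates_of,
         molecularity = molecularity,
         formulas = lapply(net$species, `[[`, "formula")),
    class = "crn_rre"
  )
}

rre_y0 <- function(rre, sim) {
  y0 <- stats::setNames(rep(0, length(rre$species)), rre$species)
  known <- intersect(names(sim$c0), rre$species)
  y0[known] <- sim$c0[known]
  y0
}

solve_segment <- function(rre, y0, times, kfun, sim) {
  # kfun: function(t) -> rate vector (constant within a discrete segment)
  out <- deSolve::ode(
    y = y0, times = times,
    func = function(t, y, parms) list(rre$rhs(t, y, kfun(t))),
    parms = NULL,
    jacfunc = function(t, y, parms) rre$jac(t, y, kfun(t)),
    jactype = "fullusr",
    method = sim$solver, rtol = sim$rtol, atol = sim$atol, maxsteps = 100000
  )
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    stop("ODE integration failed (istate ", istate[1],
         "); the system may be too stiff for solver '", sim$solver, "'",
         call. = FALSE)
  }
  out
}

finalize_solution <- function(rre, times, conc, csol, formalism) {
  colnames(conc) <- rre$species
  cond <- NULL
  if (!is.null(csol)) {
    cond <- vapply(csol$names, function(nm) csol$fns[[nm]](times), numeric(length(times)))
    cond <- matrix(cond, nrow = length(times),
                   dimnames = list(NULL, csol$names))
  }
  # element conservation drift over the run
  els <- unique(unlist(lapply(rre$formulas, names)))
  el_tot <- vapply(els, function(el) {
    w <- vapply(rre$formulas, function(f) if (el %in% names(f)) f[[el]] else 0L, 0L)
    as.vector(conc %*% w)
  }, numeric(length(times)))
  el_tot <- matrix(el_tot, nrow = length(times), dimnames = list(NULL, els))
  drift <- apply(el_tot, 2, function(x) {
    if (!all(is.finite(x))) return(Inf)     # a diverged integration
    if (max(abs(x)) < 1e-300) 0 else (max(x) - min(x)) / max(abs(x))
  })
  structure(
    list(times = times, conc = conc, conditions = cond,
         c_max = apply(conc, 2, max), element_drift = drift,
         formalism = formalism),
    class = "crn_solution"
  )
}

#' @export
print.crn_solution <- function(x, ...) {
  cat("<crn_solution> ", length(x$times), " time points, ",
      ncol(x$conc), " species (", x$formalism, " formalism)\n", sep = "")
  invisible(x)
}

#' Tidy a kinetic solution
#'
#' Long tibble of `time`, `species`, `conc`; `glance()` summarises the run.
#'
#' @param x a `crn_solution`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy crn_solution
#' @export
tidy.crn_solution <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, ncol(x$conc)),
    species = rep(colnames(x$conc), each = length(x$times)),
    conc = as.vector(x$conc)
  )
}

#' @rdname tidy.crn_solution
#' @method glance crn_solution
#' @export
glance.crn_solution <- function(x, ...) {
  tibble::tibble(
    n_species = ncol(x$conc), n_times = length(x$times),
    t_end = max(x$times), max_element_drift = max(c(x$element_drift, 0)),
    formalism = x$formalism
  )
}

#' Plot concentration-time profiles
#'
#' @param object a `crn_solution`.
#' @param species optional subset of species to show.
#' @param log_conc log-scale the concentration axis.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot crn_solution
#' @export
autoplot.crn_solution <- function(object, species = NULL, log_conc = FALSE, ...) {
  df <- tidy(object)
  if (!is.null(species)) df <- df[df$species %in% species, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$conc,
                                        colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(c ~ (mol ~ dm^-3)),
                  colour = NULL)
  if (log_conc) p <- p + ggplot2::scale_y_log10()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot solved condition profiles
#'
#' @param csol a [solve_profiles()] result.
#' @param n number of plot points.
#' @return A ggplot of each condition over the timespan.
#' @export
plot_conditions <- function(csol, n = 500L) {
  t <- seq(0, csol$t_end, length.out = n)
  df <- dplyr::bind_rows(lapply(csol$names, function(nm) {
    tibble::tibble(time = t, value = csol$fns[[nm]](t), condition = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Solve the RRE with continuously variable rate constants
#'
#' The right-hand side evaluates the calculator at the instantaneous
#' condition values on every integrator step, so rates evolve continuously
#' with the conditions (stiff implicit multistep integration with the
#' analytic Jacobian).
#'
#' @param rre a [build_rre()] system.
#' @param cs a [condition_set()].
#' @param calc a [calculator()] for the network's reactions.
#' @param sim a [sim_params()].
#' @return A `crn_solution`.
#' @export
solve_continuous <- function(rre, cs, calc, sim) {
  csol <- solve_profiles(cs)
  check_calculator_conditions(calc, csol)
  t_end <- sim$t_end %||% cs$t_end
  if (!is.null(sim$tau_c)) {
    return(solve_chunked(solve_continuous_span, rre, cs, calc, sim, csol, t_end,
                         formalism = "continuous-chunked"))
  }
  times <- seq(0, t_end, length.out = sim$n_out)
  out <- solve_span(rre, rre_y0(rre, sim), times, csol, calc, sim)
  finalize_solution(rre, out[, 1], out[, -1, drop = FALSE], csol, "continuous")
}

solve_span <- function(rre, y0, times, csol, calc, sim, t_offset = 0) {
  kfun <- function(t) calc_rates_at(calc, csol, t + t_offset)
  solve_segment(rre, y0, times, kfun, sim)
}

solve_continuous_span <- function(rre, y0, times, csol, calc, sim, cs, t_offset) {
  solve_span(rre, y0, times, csol, calc, sim, t_offset)
}

#' Solve the RRE with discretely updated rate constants
#'
#' Precomputes the rate matrix `K_precalc` at the global stop grid from the
#' solved condition profiles, then integrates piecewise between consecutive
#' stops: at each stop the parametric rate vector is replaced by the
#' matching `K_precalc` column and the solver restarts cleanly at the
#' discontinuity (the integrator always lands exactly on each stop).
#'
#' @inheritParams solve_continuous
#' @return A `crn_solution`.
#' @export
solve_discrete <- function(rre, cs, calc, sim) {
  csol <- solve_profiles(cs)
  check_calculator_conditions(calc, csol)
  t_end <- sim$t_end %||% cs$t_end
  if (!is.null(sim$tau_c)) {
    return(solve_chunked(solve_discrete_span, rre, cs, calc, sim, csol, t_end,
                         formalism = "discrete-chunked"))
  }
  out <- solve_discrete_span(rre, rre_y0(rre, sim), NULL, csol, calc, sim, cs,
                             t_offset = 0, t_span = t_end,
                             n_out = sim$n_out)
  finalize_solution(rre, out[, 1], out[, -1, drop = FALSE], csol, "discrete")
}

# Piecewise integration between stops over a (possibly chunk-local) span.
# Global time = t_offset + local time; stops are taken from the global grid
# and mapped into the local span.
solve_discrete_span <- function(rre, y0, times, csol, calc, sim, cs,
                                t_offset = 0, t_span = NULL, n_out = NULL) {
  if (is.null(t_span)) t_span <- max(times)
  gstops <- make_tstops(cs)
  tol <- max(cs$t_end, 1) * 1e-12
  local_stops <- gstops[gstops > t_offset + tol & gstops < t_offset + t_span - tol] - t_offset
  bounds <- sort(unique(c(0, local_stops, t_span)))
  grid <- if (is.null(times)) seq(0, t_span, length.out = n_out %||% sim$n_out) else times
  K_at <- function(t_local) calc_rates_at(calc, csol, t_offset + t_local)
  acc_t <- numeric(0)
  acc_c <- NULL
  y <- y0
  for (b in seq_len(length(bounds) - 1L)) {
    a <- bounds[b]; z <- bounds[b + 1L]
    k_seg <- K_at(a)     # rates fixed at the segment-opening stop
    seg_times <- sort(unique(c(a, grid[grid > a + tol & grid < z - tol], z)))
    out <- solve_segment(rre, y, seg_times, function(t) k_seg, sim)
    y <- out[nrow(out), -1]
    keep <- if (b == 1L) seq_len(nrow(out)) else seq(2L, nrow(out))
    acc_t <- c(acc_t, out[keep, 1])
    acc_c <- rbind(acc_c, out[keep, -1, drop = FALSE])
  }
  cbind(acc_t, acc_c)
}

#' Chunked (multitime-scale) solution
#'
#' Splits the global timespan into chunks of length `tau_c`; the inner
#' solver restarts each chunk at local time zero from the previous chunk's
#' final concentrations, so time-step accumulation happens against the small
#' local time rather than the large global one (the bookkeeping identity
#' `t_global = n_c * tau_c + t_local` holds exactly at every boundary, and
#' global stops are mapped to local stops by subtracting `n_c * tau_c`).
#' Called automatically by [solve_continuous()] / [solve_discrete()] when
#' `sim$tau_c` is set.
#'
#' @keywords internal
solve_chunked <- function(span_solver, rre, cs, calc, sim, csol, t_end, formalism) {
  tau_c <- sim$tau_c
  y <- rre_y0(rre, sim)
  n_c <- 0L
  acc_t <- numeric(0)
  acc_c <- NULL
  grid <- seq(0, t_end, length.out = sim$n_out)
  tol <- max(t_end, 1) * 1e-12
  while (n_c * tau_c < t_end - tol) {
    t0 <- n_c * tau_c
    t1 <- min((n_c + 1L) * tau_c, t_end)
    span <- t1 - t0
    local_grid <- sort(unique(c(0, grid[grid > t0 + tol & grid < t1 - tol] - t0, span)))
    out <- if (identical(span_solver, solve_discrete_span)) {
      solve_discrete_span(rre, y, local_grid, csol, calc, sim, cs,
                          t_offset = t0, t_span = span)
    } else {
      span_solver(rre, y, local_grid, csol, calc, sim, cs, t_offset = t0)
    }
    stopifnot(abs((n_c * tau_c + out[nrow(out), 1]) - t1) <= 1e-9 * max(t1, 1))
    y <- out[nrow(out), -1]
    keep <- if (n_c == 0L) seq_len(nrow(out)) else seq(2L, nrow(out))
    acc_t <- c(acc_t, out[keep, 1] + t0)
    acc_c <- rbind(acc_c, out[keep, -1, drop = FALSE])
    n_c <- n_c + 1L
  }
  finalize_solution(rre, acc_t, acc_c, csol, formalism)
}

#' Map a global time onto the chunked local timespan
#'
#' The bookkeeping identity of chunked time accumulation:
#' `t_global = n_c * tau_c + t_local` with `n_c = floor(t_global / tau_c)`.
#' Global rate-update stops are converted to chunk-local stops with this
#' mapping (a stop falling exactly on a chunk boundary belongs to the start
#' of the later chunk, where it deduplicates with the restart point).
#'
#' @param t_global global time(s), >= 0.
#' @param tau_c chunk length (> 0).
#' @return List with integer `n_c` and numeric `t_local` (both vectorised);
#'   `n_c * tau_c + t_local` reproduces `t_global` exactly.
#' @export
chunk_local_time <- function(t_global, tau_c) {
  stopifnot(all(t_global >= 0), tau_c > 0)
  n_c <- floor(t_global / tau_c)
  list(n_c = as.integer(n_c), t_local = t_global - n_c * tau_c)
}

#' Prune reactions too slow to matter
#'
#' Removes reaction i iff its maximum possible rate over the whole run can
#' never move any concentration by more than the solver's precision:
#' `k_i^max * c_max_prune^order * t_end < rtol`, where `k_i^max` is the rate
#' constant at the most favourable condition values attained anywhere in the
#' profile and `order` is the reaction's molecularity.
#'
#' @param net a `crn_network`.
#' @param calc a [calculator()] for `net`'s reactions (in network order).
#' @param cs a [condition_set()].
#' @param sim a [sim_params()]; `c_max_prune` defaults to twice the total
#'   initial concentration.
#' @return The reduced `crn_network` (attribute `"pruned_keys"` lists the
#'   removed reactions).
#' @export
prune_slow <- function(net, calc, cs, sim) {
  csol <- solve_profiles(cs)
  check_calculator_conditions(calc, csol)
  t_end <- sim$t_end %||% cs$t_end
  c_max <- sim$c_max_prune %||% (2 * sum(sim$c0))
  rre <- build_rre(net)
  # max rate constant over the condition profile (dense scan incl. stops)
  scan <- sort(unique(c(seq(0, t_end, length.out = 512L), make_tstops(cs))))
  k_max <- rep(0, length(net$reactions))
  for (t in scan) k_max <- pmax(k_max, calc_rates_at(calc, csol, t))
  keep <- k_max * c_max^rre$molecularity * t_end >= sim$rtol
  pruned <- reaction_network()
  sp <- net$species
  for (i in which(keep)) {
    pruned <- add_reactions(pruned, net$reactions[i], sp,
                            level = net$provenance$level[i],
                            iteration = net$provenance$iteration[i])$net
  }
  attr(pruned, "pruned_keys") <- vapply(net$reactions[!keep], `[[`, "", "key")
  pruned
}

#' Write a kinetic solution as delimited text
#'
#' Time column plus one column per species (canonical SMILES); condition
#' traces appended as additional columns prefixed `cond_`.
#'
#' @param sol a `crn_solution`.
#' @param path output CSV path.
#' @export
write_solution <- function(sol, path) {
  df <- data.frame(time = sol$times, sol$conc, check.names = FALSE)
  if (!is.null(sol$conditions)) {
    cond <- sol$conditions
    colnames(cond) <- paste0("cond_", colnames(cond))
    df <- cbind(df, cond)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
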