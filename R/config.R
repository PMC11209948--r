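#' Load and validate a run configuration
#'
#' YAML configuration with blocks mirroring the package's parameter objects:
#' exactly one of `direct_explore` / `iterative_explore`, plus `system`,
#' `conditions`, `calculator` and `simulation` blocks, and top-level `seed`.
#' Unknown keys are rejected with their location; defaults are filled for
#' absent optional fields.
#'
#' @param path YAML file path.
#' @return Object of class `crn_config`: validated blocks ready to hand to
#'   [run_config()].
#' @export
load_config <- function(path) {
  doc <- yaml::read_yaml(path)
  allowed_top <- c("direct_explore", "iterative_explore", "system", "conditions",
                   "calculator", "simulation", "seed", "log_level")
  unknown <- setdiff(names(doc), allowed_top)
  if (length(unknown)) {
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  modes <- intersect(c("direct_explore", "iterative_explore"), names(doc))
  if (length(modes) > 1L) {
    stop("config must contain at most one exploration mode, found: ",
         paste(modes, collapse = " and "), call. = FALSE)
  }
  check_block <- function(block, allowed, where) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown)) {
      stop("unknown key(s) in `", where, "`: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    block
  }
  explore <- NULL
  mode <- if (length(modes)) modes else NA_character_
  if (identical(mode, "direct_explore")) {
    b <- check_block(doc$direct_explore,
                     c("radius", "maxiters", "rxn_convergence_threshold",
                       "parallel_runs", "max_attempts"), "direct_explore")
    explore <- direct_explore_params(
      radius = b$radius %||% 100L, maxiters = b$maxiters %||% 1000L,
      rxn_convergence_threshold = b$rxn_convergence_threshold %||% 5L,
      parallel_runs = b$parallel_runs %||% 1L,
      max_attempts = b$max_attempts %||% 100L)
  } else if (identical(mode, "iterative_explore")) {
    b <- check_block(doc$iterative_explore,
                     c("seed_conc", "seed_convergence_threshold", "max_levels",
                       "level_maxiters", "level_threshold", "level_mechanisms",
                       "max_attempts", "max_carbons"), "iterative_explore")
    if (is.null(b$seed_conc)) stop("iterative_explore needs `seed_conc`", call. = FALSE)
    explore <- iterative_explore_params(
      seed_conc = b$seed_conc,
      seed_convergence_threshold = b$seed_convergence_threshold %||% 2L,
      max_levels = b$max_levels %||% 12L,
      level_maxiters = b$level_maxiters %||% 60L,
      level_threshold = b$level_threshold %||% 5L,
      level_mechanisms = b$level_mechanisms %||% 2L,
      max_attempts = b$max_attempts %||% 100L,
      filter = rx_filter(b$max_carbons %||% 4L))
  }
  sys_block <- check_block(doc$system %||% list(), c("smiles", "concentrations"),
                           "system")
  conditions <- NULL
  if (!is.null(doc$conditions)) {
    cb <- check_block(doc$conditions, c("t_end", "tau_r", "profiles"), "conditions")
    if (is.null(cb$t_end)) stop("`conditions` needs `t_end`", call. = FALSE)
    profiles <- lapply(cb$profiles, function(p) {
      p <- check_block(p, c("type", "value", "X_start", "X_end", "rate",
                            "r1", "r2", "t_r1_start", "t_r1_end",
                            "t_r2_start", "t_r2_end", "units"), "profiles")
      switch(p$type,
        fixed = profile_fixed(p$value, units = p$units %||% ""),
        linear = profile_linear(p$X_start, p$X_end, p$rate, units = p$units %||% ""),
        double_ramp = profile_double_ramp(
          p$X_start, p$r1, p$r2, p$t_r1_start, p$t_r1_end,
          p$t_r2_start, p$t_r2_end, units = p$units %||% ""),
        stop("unknown profile type: ", p$type, call. = FALSE))
    })
    conditions <- condition_set(profiles, t_end = cb$t_end,
                                tau_r = cb$tau_r %||% (cb$t_end / 100))
  }
  calc_block <- NULL
  if (!is.null(doc$calculator)) {
    calc_block <- check_block(doc$calculator,
                              c("type", "rate_table", "A_uni", "A_bi", "E0",
                                "alpha_ep", "Ea_fallback"), "calculator")
  }
  sim <- NULL
  if (!is.null(doc$simulation)) {
    sb <- check_block(doc$simulation,
                      c("rtol", "abstol", "tau_c", "c_max_prune", "n_out",
                        "solver", "formalism"), "simulation")
    c0 <- unlist(sys_block$concentrations %||% list())
    if (is.null(c0)) c0 <- stats::setNames(numeric(0), character(0))
    sim <- sim_params(c0 = c0, rtol = sb$rtol %||% 1e-8,
                      atol = sb$abstol %||% 1e-12, tau_c = sb$tau_c,
                      c_max_prune = sb$c_max_prune, n_out = sb$n_out %||% 201L,
                      solver = sb$solver %||% "lsode")
    attr(sim, "formalism") <- sb$formalism %||% "discrete"
  }
  structure(
    list(mode = mode, explore = explore, system_smiles = sys_block$smiles,
         conditions = conditions, calculator = calc_block, sim = sim,
         seed = as.integer(doc$seed %||% 1L),
         log_level = doc$log_level %||% "info"),
    class = "crn_config"
  )
}

#' Dump a configuration back to YAML
#'
#' Round-trip partner of [load_config()] for the blocks it materialises.
#'
#' @param config a `crn_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  doc <- list()
  if (identical(config$mode, "direct_explore")) {
    e <- config$explore
    doc$direct_explore <- list(
      radius = e$radius, maxiters = e$maxiters,
      rxn_convergence_threshold = e$rxn_convergence_threshold,
      parallel_runs = e$parallel_runs, max_attempts = e$max_attempts)
  } else if (identical(config$mode, "iterative_explore")) {
    e <- config$explore
    doc$iterative_explore <- list(
      seed_conc = e$seed_conc,
      seed_convergence_threshold = e$seed_convergence_threshold,
      max_levels = e$max_levels, level_maxiters = e$level_maxiters,
      level_threshold = e$level_threshold, level_mechanisms = e$level_mechanisms,
      max_attempts = e$max_attempts,
      max_carbons = e$filter$max_carbons)
  }
  if (!is.null(config$system_smiles)) {
    doc$system <- list(smiles = config$system_smiles)
    if (!is.null(config$sim) && length(config$sim$c0)) {
      doc$system$concentrations <- as.list(config$sim$c0)
    }
  }
  if (!is.null(config$conditions)) {
    cs <- config$conditions
    doc$conditions <- list(
      t_end = cs$t_end, tau_r = cs$tau_r,
      profiles = lapply(cs$profiles, function(p) {
        if (inherits(p, "crn_profile_fixed")) {
          list(type = "fixed", value = p$value, units = p$units)
        } else if (inherits(p, "crn_profile_linear")) {
          list(type = "linear", X_start = p$X_start, X_end = p$X_end,
               rate = p$rate, units = p$units)
        } else if (inherits(p, "crn_profile_double_ramp")) {
          list(type = "double_ramp", X_start = p$X_start, r1 = p$r1, r2 = p$r2,
               t_r1_start = p$t_r1_start, t_r1_end = p$t_r1_end,
               t_r2_start = p$t_r2_start, t_r2_end = p$t_r2_end, units = p$units)
        } else {
          stop("cannot serialize a function-backed profile", call. = FALSE)
        }
      }))
  }
  if (!is.null(config$calculator)) doc$calculator <- config$calculator
  if (!is.null(config$sim)) {
    doc$simulation <- list(rtol = config$sim$rtol, abstol = config$sim$atol,
                           n_out = config$sim$n_out, solver = config$sim$solver,
                           formalism = attr(config$sim, "formalism") %||% "discrete")
    if (!is.null(config$sim$tau_c)) doc$simulation$tau_c <- config$sim$tau_c
    if (!is.null(config$sim$c_max_prune)) doc$simulation$c_max_prune <- config$sim$c_max_prune
  }
  doc$seed <- config$seed
  doc$log_level <- config$log_level
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read / write per-reaction rate parameter tables
#'
#' Tab-separated text keyed by reaction SMILES, columns `key`, `Ea`, `A`
#' (and optionally `molecularity`).
#'
#' @param path file path.
#' @return `read_rate_table()` returns a tibble.
#' @export
read_rate_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("key", "Ea", "A")
  if (!all(need %in% names(df))) {
    stop("rate table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_rate_table
#' @param tab tibble/data.frame with at least `key`, `Ea`, `A`.
#' @export
write_rate_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Arrhenius calculator from a rate table, aligned to a network
#'
#' @param net a `crn_network`.
#' @param tab a rate table (see [read_rate_table()]).
#' @param diffusion optional [diffusion_model()].
#' @return A `crn_calculator` whose rate vector follows the network's
#'   reaction order.
#' @export
calculator_from_table <- function(net, tab, diffusion = NULL) {
  keys <- vapply(net$reactions, `[[`, "", "key")
  idx <- match(keys, tab$key)
  if (anyNA(idx)) {
    stop("rate table is missing reaction(s): ",
         paste(utils::head(keys[is.na(idx)], 5L), collapse = ", "), call. = FALSE)
  }
  mol <- vapply(net$reactions, function(r) length(r$reactants), 0L)
  calc_arrhenius(arrhenius_params(tab$Ea[idx], tab$A[idx]),
                 molecularity = mol, diffusion = diffusion)
}

#' Run a loaded configuration end to end
#'
#' Dispatches on the config's exploration mode (or straight to simulation
#' when a network file is given), writing plain-text artifacts into
#' `out_dir`: `network.txt`, `rates.tsv`, `solution.csv`, `conditions.csv`
#' and `records.csv`.
#'
#' @param config a `crn_config` from [load_config()].
#' @param out_dir output directory (created if absent).
#' @param network optional pre-explored `crn_network` (for simulate-only
#'   runs).
#' @return Invisibly, a list with the produced objects.
#' @export
run_config <- function(config, out_dir, network = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  produced <- list()
  net <- network
  if (identical(config$mode, "direct_explore")) {
    init <- chem_system(as.list(config$system_smiles))
    ex <- explore_direct(init, config$explore, seed = config$seed)
    net <- ex$network
    utils::write.csv(ex$records, file.path(out_dir, "records.csv"), row.names = FALSE)
    produced$exploration <- ex
  } else if (identical(config$mode, "iterative_explore")) {
    fac <- surrogate_calculator_factory(
      A_uni = config$calculator$A_uni %||% 1e15,
      A_bi = config$calculator$A_bi %||% 1e10)
    ex <- explore_iterative(as.list(config$system_smiles), config$explore,
                            conditions = config$conditions,
                            calculator_factory = fac, sim = config$sim,
                            seed = config$seed)
    net <- ex$network
    rec <- ex$records
    rec$seeds <- vapply(rec$seeds, paste, "", collapse = ";")
    rec$c_max <- vapply(rec$c_max, function(x) paste(names(x), signif(x, 6),
                                                     sep = "=", collapse = ";"), "")
    utils::write.csv(rec, file.path(out_dir, "records.csv"), row.names = FALSE)
    produced$exploration <- ex
  }
  if (!is.null(net)) {
    write_network(net, file.path(out_dir, "network.txt"))
    produced$network <- net
  }
  if (!is.null(net) && !is.null(config$conditions) && !is.null(config$sim) &&
      n_reactions(net) > 0L) {
    calc <- if (!is.null(config$calculator$rate_table)) {
      calculator_from_table(net, read_rate_table(config$calculator$rate_table))
    } else {
      surrogate_calculator_factory(
        A_uni = config$calculator$A_uni %||% 1e15,
        A_bi = config$calculator$A_bi %||% 1e10)(net)
    }
    formalism <- attr(config$sim, "formalism") %||% "discrete"
    rre <- build_rre(net)
    sol <- if (identical(formalism, "continuous")) {
      solve_continuous(rre, config$conditions, calc, config$sim)
    } else {
      solve_discrete(rre, config$conditions, calc, config$sim)
    }
    write_solution(sol, file.path(out_dir, "solution.csv"))
    produced$solution <- sol
  }
  if (!is.null(config$conditions)) {
    csol <- solve_profiles(config$conditions)
    t <- seq(0, config$conditions$t_end, length.out = 501L)
    df <- data.frame(time = t)
    for (nm in csol$names) df[[nm]] <- csol$fns[[nm]](t)
    utils::write.csv(df, file.path(out_dir, "conditions.csv"), row.names = FALSE)
    produced$conditions <- csol
  }
  invisible(produced)
}
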