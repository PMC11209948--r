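#' Arrhenius rate constants
#'
#' `k_i = A_i * exp(-Ea_i / (R * T))`, vectorised over reactions.
#'
#' @param params an [arrhenius_params()].
#' @param T temperature in K (> 0).
#' @return Numeric vector of rate constants (units of A: s^-1 for
#'   unimolecular reactions, dm^3 mol^-1 s^-1 for bimolecular).
#' @examples
#' p <- arrhenius_params(Ea = 50e3, A = 1e13)
#' arrhenius_k(p, 1000)   # ~2.44e10
#' @export
arrhenius_k <- function(params, T) {
  if (!is.numeric(T) || any(T <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  params$A * exp(-params$Ea / (crn_constants$R * T))
}

#' Per-reaction Arrhenius parameters
#'
#' @param Ea activation energies (J/mol), one per reaction.
#' @param A prefactors (> 0), one per reaction.
#' @return Object of class `crn_arrhenius_params`.
#' @export
arrhenius_params <- function(Ea, A) {
  stopifnot(length(Ea) == length(A), all(is.finite(Ea)), all(A > 0))
  structure(list(Ea = as.numeric(Ea), A = as.numeric(A)),
            class = "crn_arrhenius_params")
}

#' Collision-theory rate constant for a bimolecular reaction
#'
#' `k = N_A * sigma * sqrt(8 kB T / (pi mu)) * exp(-Ea / (R T))` with
#' `sigma = pi (r_A + r_B)^2`, converted to dm^3 mol^-1 s^-1.  Unimolecular
#' reactions have no collision step and are rejected: supply prefactor-based
#' rates for those.
#'
#' @param cp a [collision_params()].
#' @param reactants character vector of the two reactant species ids
#'   (a single id given twice for self-collision).
#' @param Ea activation energy (J/mol).
#' @param T temperature (K, > 0).
#' @return Rate constant in dm^3 mol^-1 s^-1.
#' @export
collision_k <- function(cp, reactants, Ea, T) {
  if (any(T <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  if (length(reactants) != 2L) {
    stop("collision theory applies to bimolecular reactions only", call. = FALSE)
  }
  a <- reactants[1]; b <- reactants[2]
  for (s in c(a, b)) {
    if (is.null(cp$radius[[s]]) || is.null(cp$molar_mass[[s]])) {
      stop("no collision parameters for species ", s, call. = FALSE)
    }
  }
  sigma <- pi * (cp$radius[[a]] + cp$radius[[b]])^2          # m^2
  mA <- cp$molar_mass[[a]] / crn_constants$N_A               # kg per molecule
  mB <- cp$molar_mass[[b]] / crn_constants$N_A
  mu <- mA * mB / (mA + mB)
  v <- sqrt(8 * crn_constants$kB * T / (pi * mu))            # m/s
  k_m3 <- crn_constants$N_A * sigma * v * exp(-Ea / (crn_constants$R * T))
  k_m3 * 1e3                                                 # m^3 -> dm^3
}

#' Collision parameters: per-species hard-sphere radii and molar masses
#'
#' @param radius named numeric, hard-sphere radius per species (m).
#' @param molar_mass named numeric, molar mass per species (kg/mol).
#' @return Object of class `crn_collision_params`.
#' @export
collision_params <- function(radius, molar_mass) {
  stopifnot(all(unlist(radius) > 0), all(unlist(molar_mass) > 0))
  structure(list(radius = as.list(radius), molar_mass = as.list(molar_mass)),
            class = "crn_collision_params")
}

#' Diffusion-limited rate capping
#'
#' In a fluid the encounter frequency bounds any bimolecular rate:
#' `k_D = 8RT / (3 eta(T))` (Smoluchowski form, converted to
#' dm^3 mol^-1 s^-1) and partial diffusion control combines the calculated
#' and diffusion rates harmonically, `k_r = (1/k_calc + 1/k_D)^-1`, giving a
#' smooth transition with `k_r <= min(k_calc, k_D)`.  The cap is applied
#' exactly once per rate evaluation and never to unimolecular reactions.
#'
#' @param k_calc calculated rate constant(s), >= 0 (dm^3 mol^-1 s^-1).
#' @param T temperature (K).
#' @param dm a [diffusion_model()]; a disabled model returns `k_calc`
#'   unchanged.
#' @return Capped rate constant(s) `k_r`.
#' @export
diffusion_limit <- function(k_calc, T, dm) {
  stopifnot(all(k_calc >= 0))
  if (is.null(dm) || !dm$enabled) return(k_calc)
  k_D <- diffusion_kD(T, dm)
  ifelse(k_calc == 0, 0, 1 / (1 / k_calc + 1 / k_D))
}

#' @rdname diffusion_limit
#' @export
diffusion_kD <- function(T, dm) {
  eta <- dm$eta(T)
  if (any(eta <= 0)) stop("viscosity must be positive", call. = FALSE)
  8 * crn_constants$R * T / (3 * eta) * 1e3    # m^3 -> dm^3
}

#' Diffusion model
#'
#' @param eta viscosity function of temperature (Pa s); default is water-like
#'   `1e-3` Pa s independent of T.
#' @param enabled logical; a disabled model is an identity cap.
#' @return Object of class `crn_diffusion_model`.
#' @export
diffusion_model <- function(eta = function(T) rep(1e-3, length(T)), enabled = TRUE) {
  stopifnot(is.function(eta))
  structure(list(eta = eta, enabled = isTRUE(enabled)), class = "crn_diffusion_model")
}

#' Kinetic calculators
#'
#' A calculator declares the condition names it consumes and maps their
#' instantaneous values to a rate-constant vector (one entry per reaction).
#' Simulating with a ConditionSet that lacks a declared condition fails
#' before integration starts.
#'
#' @param conditions character vector of condition names (e.g. `"T"`).
#' @param fn function `(cond_values: named list) -> numeric rate vector`.
#' @param n_reactions length of the rate vector the calculator emits.
#' @param molecularity integer vector (1 or 2) per reaction; bimolecular
#'   entries are eligible for diffusion capping.
#' @param diffusion optional [diffusion_model()] applied (once) to
#'   bimolecular rates.
#' @return Object of class `crn_calculator`.
#' @export
calculator <- function(conditions, fn, n_reactions, molecularity = NULL,
                       diffusion = NULL) {
  stopifnot(is.character(conditions), is.function(fn), n_reactions >= 0)
  if (is.null(molecularity)) molecularity <- rep(1L, n_reactions)
  stopifnot(length(molecularity) == n_reactions, all(molecularity %in% c(1L, 2L)))
  structure(
    list(conditions = conditions, fn = fn, n_reactions = as.integer(n_reactions),
         molecularity = as.integer(molecularity), diffusion = diffusion),
    class = "crn_calculator"
  )
}

#' @rdname calculator
#' @param params an [arrhenius_params()] (one Ea, A pair per reaction).
#' @export
calc_arrhenius <- function(params, molecularity = NULL, diffusion = NULL) {
  n <- length(params$Ea)
  calculator(
    conditions = "T",
    fn = function(cond) arrhenius_k(params, cond$T),
    n_reactions = n, molecularity = molecularity, diffusion = diffusion
  )
}

#' @rdname calculator
#' @param k fixed rate-constant vector for a condition-independent
#'   calculator (static kinetics).
#' @export
calc_static <- function(k, molecularity = NULL, diffusion = NULL) {
  k <- as.numeric(k)
  calculator(
    conditions = character(0),
    fn = function(cond) k,
    n_reactions = length(k), molecularity = molecularity, diffusion = diffusion
  )
}

check_calculator_conditions <- function(calc, csol) {
  missing <- setdiff(calc$conditions, csol$names)
  if (length(missing)) {
    stop("calculator requires condition(s) not in the ConditionSet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Evaluate a calculator at time t (with optional single-application
# diffusion capping of bimolecular entries).
calc_rates_at <- function(calc, csol, t) {
  vals <- condition_values_at(csol, t)
  k <- calc$fn(vals)
  if (length(k) != calc$n_reactions) {
    stop("calculator returned ", length(k), " rates for ", calc$n_reactions,
         " reactions", call. = FALSE)
  }
  if (!is.null(calc$diffusion) && calc$diffusion$enabled && !is.null(vals$T)) {
    bi <- calc$molecularity == 2L
    k[bi] <- diffusion_limit(k[bi], vals$T, calc$diffusion)
  }
  k
}

#' Precompute the rate matrix for the discrete formalism
#'
#' Evaluates the calculator at the condition values interpolated at each
#' global stop time, forming the reactions x stops matrix `K_precalc`;
#' diffusion capping (if configured on the calculator) is applied per entry.
#'
#' @param calc a [calculator()].
#' @param csol a [solve_profiles()] result containing every condition the
#'   calculator declares.
#' @param tstops numeric vector of stop times (from [make_tstops()]).
#' @return Object of class `crn_rate_matrix`: `K` (reactions x stops),
#'   `tstops`.
#' @export
precalculate_rates <- function(calc, csol, tstops) {
  check_calculator_conditions(calc, csol)
  K <- vapply(tstops, function(t) calc_rates_at(calc, csol, t),
              numeric(calc$n_reactions))
  K <- matrix(K, nrow = calc$n_reactions)
  if (any(!is.finite(K)) || any(K < 0)) {
    stop("precalculated rates must be finite and non-negative", call. = FALSE)
  }
  structure(list(K = K, tstops = tstops), class = "crn_rate_matrix")
}
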