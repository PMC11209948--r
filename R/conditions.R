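#' Condition profiles
#'
#' Experimental conditions (temperature, pressure, ...) enter a simulation
#' through named profiles of three kinds: fixed (constant value), direct
#' (an explicit function of time) and gradient (a rate-of-change function
#' integrated from an initial value).  Profiles are agnostic to the quantity
#' they represent; `units` is an annotation only.
#'
#' @param value constant value (finite).
#' @param units free-text units annotation.
#' @return A `crn_profile` object of the respective variant.
#' @export
profile_fixed <- function(value, units = "") {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(variant = "fixed", value = value, units = units),
            class = c("crn_profile_fixed", "crn_profile"))
}

#' @rdname profile_fixed
#' @param f function of time returning the condition value; treated as
#'   variable over the whole timespan (no numerical constancy sniffing of
#'   black-box functions).
#' @export
profile_direct <- function(f, units = "") {
  stopifnot(is.function(f))
  structure(list(variant = "direct", f = f, units = units),
            class = c("crn_profile_direct", "crn_profile"))
}

#' @rdname profile_fixed
#' @param X_start,X_end start and end values of a linear direct profile.
#' @param rate signed rate of change (units/s, nonzero); the profile holds
#'   `X_end` for `t > (X_end - X_start) / rate`.
#' @export
profile_linear <- function(X_start, X_end, rate, units = "") {
  stopifnot(is.finite(X_start), is.finite(X_end), is.finite(rate), rate != 0)
  t_prof <- (X_end - X_start) / rate
  if (t_prof < 0) stop("`rate` must point from X_start toward X_end", call. = FALSE)
  structure(list(variant = "direct", X_start = X_start, X_end = X_end,
                 rate = rate, t_end_profile = t_prof, units = units,
                 f = function(t) ifelse(t < t_prof, X_start + rate * t, X_end)),
            class = c("crn_profile_linear", "crn_profile_direct", "crn_profile"))
}

#' @rdname profile_fixed
#' @param g gradient function of time (units/s).
#' @param initial initial value the gradient is integrated from.
#' @export
profile_gradient <- function(g, initial, units = "") {
  stopifnot(is.function(g), is.finite(initial))
  structure(list(variant = "gradient", g = g, initial = initial, units = units),
            class = c("crn_profile_gradient", "crn_profile"))
}

#' Double-ramp gradient profile
#'
#' Two linear ramps separated by plateaus: gradient `r1` on
#' `[t_r1_start, t_r1_end]`, `r2` on `[t_r2_start, t_r2_end]`, zero
#' elsewhere.  The workhorse profile for heat-then-cool temperature
#' programs; with balanced ramps (`r1 * ramp1 == -r2 * ramp2`) the profile
#' returns exactly to `X_start`.
#'
#' @param X_start initial value.
#' @param r1,r2 ramp gradients (units/s).
#' @param t_r1_start,t_r1_end,t_r2_start,t_r2_end ramp boundary times (s),
#'   non-decreasing.
#' @param units annotation.
#' @return A gradient-variant `crn_profile`.
#' @export
profile_double_ramp <- function(X_start, r1, r2,
                                t_r1_start, t_r1_end, t_r2_start, t_r2_end,
                                units = "") {
  ts <- c(t_r1_start, t_r1_end, t_r2_start, t_r2_end)
  stopifnot(all(is.finite(ts)), all(diff(ts) >= 0), t_r1_start >= 0)
  g <- function(t) {
    ifelse(t >= t_r1_start & t < t_r1_end, r1,
           ifelse(t >= t_r2_start & t < t_r2_end, r2, 0))
  }
  structure(list(variant = "gradient", g = g, initial = X_start,
                 X_start = X_start, r1 = r1, r2 = r2,
                 t_r1_start = t_r1_start, t_r1_end = t_r1_end,
                 t_r2_start = t_r2_start, t_r2_end = t_r2_end, units = units),
            class = c("crn_profile_double_ramp", "crn_profile_gradient", "crn_profile"))
}

#' Bind condition profiles into a ConditionSet
#'
#' @param ... named `crn_profile` objects (e.g. `T = profile_fixed(1000)`).
#' @param t_end global simulation end time (s, > 0).
#' @param tau_r rate-update timestep for the discrete formalism (s, > 0).
#' @return Object of class `crn_condition_set`.
#' @export
condition_set <- function(..., t_end, tau_r = t_end / 100) {
  profiles <- list(...)
  if (length(profiles) == 1L && is.list(profiles[[1]]) &&
      !inherits(profiles[[1]], "crn_profile")) {
    profiles <- profiles[[1]]
  }
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))) ||
      anyDuplicated(names(profiles))) {
    stop("profiles must have unique names", call. = FALSE)
  }
  if (!all(vapply(profiles, inherits, TRUE, "crn_profile"))) {
    stop("all profiles must be crn_profile objects", call. = FALSE)
  }
  stopifnot(t_end > 0, tau_r > 0)
  structure(list(profiles = profiles, t_end = t_end, tau_r = tau_r),
            class = "crn_condition_set")
}

# Intervals over which a profile is (declared) non-constant, clipped to
# [0, t_end].  Matrix with columns a, b; zero rows for fixed profiles.
variable_intervals <- function(profile, t_end) UseMethod("variable_intervals")

#' @export
variable_intervals.crn_profile_fixed <- function(profile, t_end) {
  matrix(numeric(0), 0, 2)
}

#' @export
variable_intervals.crn_profile_linear <- function(profile, t_end) {
  b <- min(profile$t_end_profile, t_end)
  if (b <= 0) return(matrix(numeric(0), 0, 2))
  matrix(c(0, b), 1, 2)
}

#' @export
variable_intervals.crn_profile_direct <- function(profile, t_end) {
  matrix(c(0, t_end), 1, 2)
}

#' @export
variable_intervals.crn_profile_double_ramp <- function(profile, t_end) {
  iv <- rbind(c(profile$t_r1_start, profile$t_r1_end),
              c(profile$t_r2_start, profile$t_r2_end))
  iv <- iv[iv[, 1] < iv[, 2] & iv[, 1] < t_end, , drop = FALSE]
  iv[, 2] <- pmin(iv[, 2], t_end)
  iv
}

#' @export
variable_intervals.crn_profile_gradient <- function(profile, t_end) {
  matrix(c(0, t_end), 1, 2)
}

#' Solve all condition profiles over the timespan
#'
#' Fixed profiles become constants, direct profiles are evaluated, gradient
#' profiles are numerically integrated piecewise between their declared
#' interval boundaries with dense (linearly interpolable) output.
#'
#' @param cs a [condition_set()].
#' @param n_grid dense-output grid size per profile (default 2001).
#' @param rtol,atol integration tolerances for gradient profiles.
#' @return Object of class `crn_condition_solution`: evaluable via
#'   [condition_value()] for every `t` in `[0, t_end]`.
#' @export
solve_profiles <- function(cs, n_grid = 2001L, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(cs, "crn_condition_set"))
  fns <- lapply(names(cs$profiles), function(nm) {
    p <- cs$profiles[[nm]]
    if (inherits(p, "crn_profile_fixed")) {
      v <- p$value
      function(t) rep(v, length(t))
    } else if (inherits(p, "crn_profile_direct")) {
      p$f
    } else {  # gradient: integrate
      bounds <- sort(unique(c(0, cs$t_end, as.vector(variable_intervals(p, cs$t_end)))))
      bounds <- bounds[bounds >= 0 & bounds <= cs$t_end]
      grid <- sort(unique(c(bounds, seq(0, cs$t_end, length.out = n_grid))))
      sol <- deSolve::ode(
        y = c(X = p$initial), times = grid,
        func = function(t, y, parms) list(p$g(t)),
        rtol = rtol, atol = atol, method = "lsoda")
      if (any(is.na(sol[, 2]))) {
        stop("gradient profile '", nm, "' failed to integrate; check g(t)", call. = FALSE)
      }
      stats::approxfun(sol[, 1], sol[, 2], rule = 2)
    }
  })
  names(fns) <- names(cs$profiles)
  structure(list(fns = fns, t_end = cs$t_end, names = names(cs$profiles)),
            class = "crn_condition_solution")
}

#' Evaluate a solved condition at arbitrary times
#'
#' @param csol a [solve_profiles()] result.
#' @param name condition name.
#' @param t numeric vector of times in `[0, t_end]`.
#' @return Numeric vector of condition values.
#' @export
condition_value <- function(csol, name, t) {
  f <- csol$fns[[name]]
  if (is.null(f)) stop("no condition named '", name, "' in the solution", call. = FALSE)
  f(t)
}

# All condition values at one time, as a named list.
condition_values_at <- function(csol, t) {
  stats::setNames(lapply(csol$names, function(nm) csol$fns[[nm]](t)), csol$names)
}

#' Global rate-update stop grid
#'
#' Builds the union over all variable conditions of tau_r-spaced stops
#' covering only the intervals where each condition is non-constant
#' (boundary-inclusive: a stop at each interval start, every `tau_r` after,
#' and always at the interval end even when off-grid).  Fixed conditions --
#' and constant plateaus of gradient profiles -- contribute nothing.
#'
#' @param cs a [condition_set()].
#' @return Sorted, deduplicated numeric vector of stop times in
#'   `[0, t_end]`; empty when all conditions are fixed.
#' @export
make_tstops <- function(cs) {
  stopifnot(inherits(cs, "crn_condition_set"))
  stops <- numeric(0)
  for (p in cs$profiles) {
    iv <- variable_intervals(p, cs$t_end)
    for (r in seq_len(nrow(iv))) {
      a <- iv[r, 1]; b <- iv[r, 2]
      s <- seq(a, b, by = cs$tau_r)
      if (s[length(s)] < b) s <- c(s, b)
      stops <- c(stops, s)
    }
  }
  if (!length(stops)) return(numeric(0))
  stops <- sort(stops)
  tol <- max(cs$t_end, 1) * 1e-12
  stops <- stops[c(TRUE, diff(stops) > tol)]
  stops[stops >= 0 & stops <= cs$t_end]
}
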