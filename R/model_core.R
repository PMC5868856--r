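#' Species parameters for the pH-feedback growth model
#'
#' Bundles one species' pH niche and pH-drive parameters. Population growth is
#' logistic with carrying capacity `K`, multiplied by a Gaussian dependence on
#' the proton concentration `p`: growth is maximal at the preferred proton
#' concentration `p_pref`, falls off with niche width `sigma`, and the maximal
#' death rate far from the optimum is `delta`. The species changes the proton
#' concentration of its surroundings at per-density rate `c` (positive =
#' acidifier, raises `p`; negative = alkalizer, lowers `p`), optionally scaled
#' by the relative drive strength `d` used in coculture sweeps.
#'
#' @param p_pref preferred proton concentration, inside `[0, 2b]` of the
#'   environment the species is simulated in.
#' @param sigma niche width (> 0) on the proton scale.
#' @param delta maximal death rate, in (0, 1).
#' @param c proton-drive coefficient (signed; model units per density per time).
#' @param d relative drive strength (> 0); multiplies `c` in the proton
#'   dynamic, so `d = 2` means the species drives the proton concentration
#'   twice as strongly as a reference species with `d = 1`.
#' @param K carrying capacity (> 0).
#' @param name optional species label used in outputs.
#' @return An object of class `species_params`.
#' @seealso [ph_environment()], [system_rhs()], [archetype_species()]
#' @examples
#' lp <- species_params(p_pref = 8, c = 0.1, name = "Lp")
#' growth_rate_factor(8, lp)  # peak growth = 1 - delta
#' @export
species_params <- function(p_pref, sigma = 4, delta = 0.5, c = 0.1, d = 1,
                           K = 10, name = NULL) {
  sp <- structure(
    list(p_pref = as.numeric(p_pref), sigma = as.numeric(sigma),
         delta = as.numeric(delta), c = as.numeric(c), d = as.numeric(d),
         K = as.numeric(K), name = name),
    class = "species_params")
  validate_species_params(sp)
  sp
}

validate_species_params <- function(sp) {
  stopifnot(inherits(sp, "species_params"))
  for (f in c("p_pref", "sigma", "delta", "c", "d", "K")) {
    v <- sp[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("species_params: `", f, "` must be a single finite number",
           call. = FALSE)
  }
  if (sp$sigma <= 0) stop("species_params: `sigma` must be > 0", call. = FALSE)
  if (sp$K <= 0) stop("species_params: `K` must be > 0", call. = FALSE)
  if (sp$d <= 0) stop("species_params: `d` must be > 0", call. = FALSE)
  if (sp$delta <= 0 || sp$delta >= 1)
    stop("species_params: `delta` must be in (0, 1)", call. = FALSE)
  invisible(sp)
}

#' @export
print.species_params <- function(x, ...) {
  nm <- if (is.null(x$name)) "" else paste0(" '", x$name, "'")
  cat(sprintf(
    "<species_params%s> p_pref=%g sigma=%g delta=%g c=%+g d=%g K=%g\n",
    nm, x$p_pref, x$sigma, x$delta, x$c, x$d, x$K))
  invisible(x)
}

#' Environment of the pH-feedback model
#'
#' The abstract proton-concentration scale lives on `[0, 2b]`; the display
#' "pH" axis is this axis reversed (high proton concentration = low pH). A
#' quadratic boundary factor in the proton dynamic (see [proton_derivative()])
#' pins the scale to that interval. `p0` is the proton concentration of fresh
#' medium, used when diluting into fresh medium during serial transfers.
#'
#' @param b half-range of the proton scale (> 0); the scale is `[0, 2b]`.
#' @param p0 proton concentration of fresh medium, in `[0, 2b]`.
#' @return An object of class `ph_environment`.
#' @examples
#' env <- ph_environment(b = 5, p0 = 5)
#' @export
ph_environment <- function(b = 5, p0 = b) {
  env <- structure(list(b = as.numeric(b), p0 = as.numeric(p0)),
                   class = "ph_environment")
  validate_ph_environment(env)
  env
}

validate_ph_environment <- function(env) {
  stopifnot(inherits(env, "ph_environment"))
  if (!is.finite(env$b) || env$b <= 0)
    stop("ph_environment: `b` must be > 0", call. = FALSE)
  if (!is.finite(env$p0) || env$p0 < 0 || env$p0 > 2 * env$b)
    stop("ph_environment: `p0` must lie in [0, 2b]", call. = FALSE)
  invisible(env)
}

#' @export
print.ph_environment <- function(x, ...) {
  cat(sprintf("<ph_environment> proton scale [0, %g], fresh medium p0=%g\n",
              2 * x$b, x$p0))
  invisible(x)
}

#' System state (two densities, proton concentration, time)
#'
#' @param n_a,n_b species densities (>= 0).
#' @param p proton concentration.
#' @param t time (model units).
#' @return A named numeric vector of class `system_state` with elements
#'   `n_a`, `n_b`, `p`, `t`.
#' @export
system_state <- function(n_a, n_b = 0, p = 5, t = 0) {
  st <- structure(c(n_a = as.numeric(n_a), n_b = as.numeric(n_b),
                    p = as.numeric(p), t = as.numeric(t)),
                  class = "system_state")
  if (any(!is.finite(st))) stop("system_state: non-finite entry", call. = FALSE)
  if (st[["n_a"]] < 0 || st[["n_b"]] < 0)
    stop("system_state: densities must be >= 0", call. = FALSE)
  st
}

#' Gaussian pH-niche growth-rate factor
#'
#' The per-capita rate factor `exp(-(p - p_pref)^2 / sigma^2) - delta`:
#' equal to `1 - delta` at the preferred proton concentration and approaching
#' `-delta` (net death) far away from it.
#'
#' @param p proton concentration (vectorised).
#' @param sp a [species_params()] object.
#' @return Numeric vector of rate factors in `(-delta, 1 - delta]`.
#' @export
growth_rate_factor <- function(p, sp) {
  validate_species_params(sp)
  exp(-((p - sp$p_pref)^2) / sp$sigma^2) - sp$delta
}

#' Logistic density derivative under the pH niche
#'
#' `dn/dt = n (1 - n/K) * growth_rate_factor(p, sp)`.
#'
#' @param n density (>= 0; vectorised).
#' @param p proton concentration (scalar or same length as `n`).
#' @param sp a [species_params()] object.
#' @return Density rate of change.
#' @export
density_derivative <- function(n, p, sp) {
  validate_species_params(sp)
  if (any(n < 0)) stop("density_derivative: `n` must be >= 0", call. = FALSE)
  n * (1 - n / sp$K) * growth_rate_factor(p, sp)
}

#' Quadratic boundary factor of the proton dynamic
#'
#' `q(p) = p (2b - p) / b^2`: zero at both ends of the proton scale and
#' exactly 1 at the neutral midpoint `p = b`, so the drive coefficient `c`
#' reads directly as the mid-scale proton change per unit density per unit
#' time. The `1/b^2` normalization is a declared convention of this package
#' (the factor is only defined up to scale); it is exposed as
#' `boundary_norm` for sensitivity analyses.
#'
#' @param p proton concentration (vectorised).
#' @param env a [ph_environment()].
#' @param boundary_norm divisor of the raw quadratic `p (2b - p)`; default
#'   `b^2`.
#' @return Dimensionless factor, 1 at mid-scale under the default norm.
#' @export
proton_boundary_factor <- function(p, env, boundary_norm = env$b^2) {
  validate_ph_environment(env)
  p * (2 * env$b - p) / boundary_norm
}

#' Proton-concentration derivative
#'
#' `dp/dt = (c_a d_a n_a + c_b d_b n_b) * q(p)` with `q` the quadratic
#' boundary factor: bacteria drive the proton concentration in proportion to
#' their density, and the drive vanishes at the ends of the scale.
#'
#' @param n_a,n_b species densities.
#' @param sp_a,sp_b [species_params()] for the two species; pass `NULL` for
#'   `sp_b` in single-species mode (then `n_b` is ignored).
#' @param p proton concentration in `[0, 2b]`.
#' @param env a [ph_environment()].
#' @param boundary_norm see [proton_boundary_factor()].
#' @return Proton-concentration rate of change.
#' @export
proton_derivative <- function(n_a, n_b, sp_a, sp_b, p, env,
                              boundary_norm = env$b^2) {
  validate_ph_environment(env)
  if (any(p < 0) || any(p > 2 * env$b))
    stop("proton_derivative: `p` outside [0, 2b]", call. = FALSE)
  drive <- sp_a$c * sp_a$d * n_a
  if (!is.null(sp_b)) drive <- drive + sp_b$c * sp_b$d * n_b
  drive * proton_boundary_factor(p, env, boundary_norm)
}

#' Right-hand side of the coupled density-proton system
#'
#' Combines [density_derivative()] for each species with
#' [proton_derivative()]. Single-species mode is `sp_b = NULL` (the `n_b`
#' component then has zero derivative).
#'
#' @param state a [system_state()] or a numeric vector `c(n_a, n_b, p)`.
#' @param sp_a,sp_b species parameters (`sp_b = NULL` for single species).
#' @param env a [ph_environment()].
#' @param boundary_norm see [proton_boundary_factor()].
#' @return Numeric vector `c(dn_a, dn_b, dp)`.
#' @export
system_rhs <- function(state, sp_a, sp_b = NULL, env = ph_environment(),
                       boundary_norm = env$b^2) {
  n_a <- state[["n_a"]]; n_b <- state[["n_b"]]; p <- state[["p"]]
  dn_a <- density_derivative(n_a, p, sp_a)
  dn_b <- if (is.null(sp_b)) 0 else density_derivative(n_b, p, sp_b)
  dp <- proton_derivative(n_a, n_b, sp_a, sp_b, p, env, boundary_norm)
  c(dn_a = dn_a, dn_b = dn_b, dp = dp)
}

#' Built-in species archetypes
#'
#' Four parameter sets shipped in `inst/extdata/archetypes.yaml`, spanning the
#' four combinations of drive direction (acidifier/alkalizer) and whether the
#' drive is self-serving (moves the proton concentration toward the species'
#' own optimum) or self-harming:
#'
#' * `Lp` - acidifier that prefers acidic conditions (self-serving; shows a
#'   strong Allee effect at adverse starting pH).
#' * `Ca` - alkalizer that prefers alkaline conditions (self-serving; Allee).
#' * `Pv` - alkalizer that prefers acidic conditions (self-harming;
#'   ecological suicide).
#' * `Sm` - acidifier with a mildly alkaline optimum (self-harming;
#'   ecological suicide).
#'
#' @param file path to an archetype YAML file; defaults to the shipped one.
#' @return Named list with `species` (named list of [species_params()]) and
#'   `environment` (a [ph_environment()]).
#' @examples
#' arc <- archetype_species()
#' names(arc$species)
#' @export
archetype_species <- function(file = system.file("extdata", "archetypes.yaml",
                                                 package = "phfeedback")) {
  cfg <- yaml::read_yaml(file)
  env <- ph_environment(b = cfg$environment$b, p0 = cfg$environment$p0)
  species <- lapply(names(cfg$species), function(nm) {
    s <- cfg$species[[nm]]
    species_params(p_pref = s$p_pref, sigma = s$sigma, delta = s$delta,
                   c = s$c, d = s$d %||% 1, K = s$K, name = nm)
  })
  names(species) <- names(cfg$species)
  pairs <- lapply(cfg$pairs, function(pr) {
    sp_a <- species[[pr$a]]; sp_b <- species[[pr$b]]
    if (!is.null(pr$d_a)) sp_a$d <- pr$d_a
    if (!is.null(pr$d_b)) sp_b$d <- pr$d_b
    list(a = sp_a, b = sp_b)
  })
  list(species = species, environment = env, pairs = pairs)
}

#' Canonical coculture pairs of the archetype set
#'
#' The four pairings shipped with the package, named by the interaction
#' motif they produce on default sweeps: `bistability` (Lp + Ca),
#' `successive_growth` (Sm + Lp), `extended_suicide` (Pv + Lp, with the
#' suicidal alkalizer driving the proton concentration twice as strongly),
#' and `stabilization` (Pv + Sm).
#'
#' @inheritParams archetype_species
#' @return Named list of pairs; each pair is `list(a = , b = )` of
#'   [species_params()].
#' @export
archetype_pairs <- function(file = system.file("extdata", "archetypes.yaml",
                                               package = "phfeedback")) {
  archetype_species(file)$pairs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Display pH scale <-> model proton scale
#'
#' The model's abstract proton concentration `p` on `[0, 2b]` displays as a
#' reversed linear "pH" axis; by the package's declared convention the
#' endpoints are display pH 11 at `p = 0` and display pH 2 at `p = 10`
#' (with the default `b = 5`), i.e. `pH = 11 - 0.9 p`. This is a display
#' convention only -- no log/antilog chemistry is implied.
#'
#' @param p proton concentration (vectorised).
#' @param ph display pH (vectorised).
#' @param env a [ph_environment()].
#' @param ph_at_zero,ph_at_max display pH at `p = 0` and at `p = 2b`.
#' @return The mapped values.
#' @examples
#' p_to_ph(c(0, 5, 10))   # 11, 6.5, 2
#' ph_to_p(7)             # assay starting pH on the model scale
#' @export
p_to_ph <- function(p, env = ph_environment(), ph_at_zero = 11,
                    ph_at_max = 2) {
  ph_at_zero + (ph_at_max - ph_at_zero) * p / (2 * env$b)
}

#' @rdname p_to_ph
#' @export
ph_to_p <- function(ph, env = ph_environment(), ph_at_zero = 11,
                    ph_at_max = 2) {
  p <- (ph - ph_at_zero) / (ph_at_max - ph_at_zero) * 2 * env$b
  pmin(pmax(p, 0), 2 * env$b)
}
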