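## Discrete-time Mamdani fuzzy-logic counterpart of the density-proton model.
##
## Universes and membership partitions are declared in a config (shipped
## default: inst/extdata/fuzzy.yaml). Inference is min (AND), max
## (aggregation), centroid defuzzification. The engine is vectorised over
## states so whole phase-diagram grids are iterated synchronously.

trap_mf <- function(x, pts) {
  a <- pts[1]; b <- pts[2]; cc <- pts[3]; d <- pts[4]
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  down <- if (d > cc) (d - x) / (d - cc) else as.numeric(x <= cc)
  pmax(0, pmin(up, 1, down))
}

#' Fuzzy model configuration
#'
#' Loads universes, membership partitions, rule bases and iteration gains
#' from a YAML file (default: the shipped configuration). Membership
#' functions are trapezoids `(a, b, c, d)` forming a partition of unity on
#' each declared universe; the pH universe is the display scale 0-14 and
#' cell density is normalised to `[0, 1]`.
#'
#' @param file YAML path; `NULL` loads the shipped default.
#' @return A validated `fuzzy_config` list.
#' @export
fuzzy_config <- function(file = NULL) {
  file <- file %||% system.file("extdata", "fuzzy.yaml", package = "phfeedback")
  cfg <- yaml::read_yaml(file)
  for (var in names(cfg$partitions)) {
    part <- cfg$partitions[[var]]
    if (is.null(cfg$universes[[part$universe]]))
      stop("fuzzy_config: partition '", var, "' references undeclared ",
           "universe '", part$universe, "'", call. = FALSE)
    for (lab in names(part$labels))
      if (length(part$labels[[lab]]) != 4L)
        stop("fuzzy_config: membership '", var, "$", lab,
             "' must have 4 trapezoid points", call. = FALSE)
  }
  for (r in cfg$rules$density_change)
    if (!r$out %in% names(cfg$partitions$change$labels))
      stop("fuzzy_config: density rule output label '", r$out,
           "' not declared", call. = FALSE)
  for (r in cfg$rules$ph_change)
    if (!r$out %in% names(cfg$partitions$magnitude$labels))
      stop("fuzzy_config: pH rule output label '", r$out,
           "' not declared", call. = FALSE)
  structure(cfg, class = "fuzzy_config")
}

#' @export
print.fuzzy_config <- function(x, ...) {
  cat(sprintf(
    "<fuzzy_config> %d density rules, %d pH rules; gains: density=%g pH=%g\n",
    length(x$rules$density_change), length(x$rules$ph_change),
    x$gains$density, x$gains$ph))
  invisible(x)
}

#' Fuzzify a crisp value against a labelled partition
#'
#' @param value numeric vector inside the partition's universe.
#' @param partition one entry of `fuzzy_config()$partitions`, or a variable
#'   name together with `config`.
#' @param config a `fuzzy_config` (used when `partition` is a name).
#' @return Matrix of membership degrees, one row per value, one column per
#'   label.
#' @examples
#' cfg <- fuzzy_config()
#' fuzzify(c(3, 7, 12), "ph", cfg)
#' @export
fuzzify <- function(value, partition, config = fuzzy_config()) {
  if (is.character(partition)) partition <- config$partitions[[partition]]
  uni <- config$universes[[partition$universe]]
  if (any(value < uni[[1]] - 1e-9) || any(value > uni[[2]] + 1e-9))
    stop("fuzzify: value outside universe [", uni[[1]], ", ", uni[[2]], "]",
         call. = FALSE)
  out <- vapply(partition$labels, function(pts) trap_mf(value, unlist(pts)),
                numeric(length(value)))
  if (length(value) == 1L) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL,
                                                         names(partition$labels)))
  out
}

# Mamdani core: alpha is an N x R matrix of rule firing strengths, out_labels
# a length-R character vector of output labels on `partition`; returns the
# centroid of the max-aggregated clipped sets, one value per row.
mamdani_defuzz <- function(alpha, out_labels, partition, config, n_grid = 201) {
  uni <- config$universes[[partition$universe]]
  z <- seq(uni[[1]], uni[[2]], length.out = n_grid)
  mfs <- vapply(out_labels, function(lab)
    trap_mf(z, unlist(partition$labels[[lab]])), numeric(n_grid))
  agg <- matrix(0, nrow = nrow(alpha), ncol = n_grid)
  for (r in seq_len(ncol(alpha)))
    agg <- pmax(agg, outer(alpha[, r], mfs[, r], pmin))
  area <- rowSums(agg)
  fired <- area > 1e-12
  if (any(!fired))
    stop("mamdani_defuzz: no rule fired for some inputs ",
         "(universe misconfiguration)", call. = FALSE)
  as.numeric(agg %*% z) / area
}

#' Fuzzy per-capita density-change inference
#'
#' Mamdani inference for the growth rule base: growth is positive when the
#' current pH label matches the species' preferred-pH label, neutral for
#' adjacent labels, negative for distant ones, and saturates (zero change)
#' at high cell density. The crisp output is a per-capita rate on `[-1, 1]`,
#' scaled by the configured density gain per iteration.
#'
#' @param ph current pH (display scale; vectorised).
#' @param preferred_ph species' preferred pH (crisp scalar, fuzzified
#'   against the same partition).
#' @param cell_density normalised density in `[0, 1]` (vectorised with `ph`).
#' @param config a `fuzzy_config`.
#' @return Crisp per-capita density change per iteration (gain applied).
#' @export
infer_density_change <- function(ph, preferred_ph, cell_density,
                                 config = fuzzy_config()) {
  mu_ph <- fuzzify(ph, "ph", config)
  mu_pref <- fuzzify(preferred_ph, "ph", config)[1, ]
  mu_dens <- fuzzify(cell_density, "density", config)
  rules <- config$rules$density_change
  alpha <- matrix(0, nrow = length(ph), ncol = length(rules))
  for (r in seq_along(rules)) {
    ru <- rules[[r]]
    a <- rep(1, length(ph))
    if (!is.null(ru$ph)) a <- pmin(a, mu_ph[, ru$ph])
    if (!is.null(ru$preferred_ph)) a <- pmin(a, mu_pref[[ru$preferred_ph]])
    if (!is.null(ru$cell_density)) a <- pmin(a, mu_dens[, ru$cell_density])
    alpha[, r] <- a
  }
  out_labels <- vapply(rules, function(r) r$out, character(1))
  rate <- mamdani_defuzz(alpha, out_labels, config$partitions$change, config,
                         config$defuzz_points %||% 201)
  config$gains$density * rate
}

#' Fuzzy pH-change inference
#'
#' Each species contributes a pH-change magnitude inferred from its cell
#' density (more bacteria, faster change), signed by its fixed
#' `ph_change_ability` (+1 alkalizer on the display scale, -1 acidifier).
#' The second species' contribution is multiplied by `relative_strength`,
#' contributions are summed, scaled by the pH gain, and damped smoothly to
#' zero at the ends of the pH universe (the fuzzy counterpart of the ODE's
#' quadratic boundary factor).
#'
#' @param cell_density matrix (or vector) of normalised densities, one
#'   column per species.
#' @param ph current pH (display scale; vectorised).
#' @param ph_change_ability vector of +1/-1, one per species.
#' @param relative_strength multiplier on the second species' contribution.
#' @param config a `fuzzy_config`.
#' @param env a [ph_environment()]; fixes the display image of the proton
#'   scale on which the boundary damping acts.
#' @return Crisp pH change per iteration.
#' @export
infer_ph_change <- function(cell_density, ph, ph_change_ability,
                            relative_strength = 1, config = fuzzy_config(),
                            env = ph_environment()) {
  if (is.null(dim(cell_density)))
    cell_density <- matrix(cell_density, ncol = length(ph_change_ability))
  stopifnot(ncol(cell_density) == length(ph_change_ability),
            all(ph_change_ability %in% c(-1, 1)))
  rules <- config$rules$ph_change
  out_labels <- vapply(rules, function(r) r$out, character(1))
  total <- numeric(length(ph))
  for (s in seq_along(ph_change_ability)) {
    mu_dens <- fuzzify(cell_density[, s], "density", config)
    alpha <- vapply(rules, function(ru) mu_dens[, ru$cell_density],
                    numeric(nrow(mu_dens)))
    if (nrow(mu_dens) == 1L) alpha <- matrix(alpha, nrow = 1)
    mag <- mamdani_defuzz(alpha, out_labels, config$partitions$magnitude,
                          config, config$defuzz_points %||% 201)
    w <- if (s == 2L) relative_strength else 1
    total <- total + w * ph_change_ability[s] * mag
  }
  # boundary damping: the display image of the ODE's quadratic factor
  # q(p) = p (2b - p) / b^2, zero outside the mapped proton range
  damp <- proton_boundary_factor(ph_to_p(ph, env), env)
  config$gains$ph * total * pmax(damp, 0)
}

#' Map ODE species parameters onto the fuzzy model
#'
#' The preferred pH is the display image of `p_pref`; the pH-change ability
#' is the display-scale sign of the proton drive (`c > 0` raises the proton
#' concentration, i.e. lowers pH: ability -1).
#'
#' @param sp a [species_params()].
#' @param env a [ph_environment()] (fixes the display map).
#' @return List with `preferred_ph`, `ability`, `strength`
#'   (`|c| * d`, used to form relative strengths), `name`.
#' @export
fuzzy_species <- function(sp, env = ph_environment()) {
  validate_species_params(sp)
  list(preferred_ph = p_to_ph(sp$p_pref, env),
       ability = if (sp$c > 0) -1 else if (sp$c < 0) 1 else 0,
       strength = abs(sp$c) * sp$d,
       name = sp$name)
}

fuzzy_step <- function(n_a, n_b, ph, fa, fb, relative_strength, config,
                       env = ph_environment()) {
  dn_a <- infer_density_change(ph, fa$preferred_ph, n_a, config) * n_a
  dn_b <- if (is.null(fb)) 0 else
    infer_density_change(ph, fb$preferred_ph, n_b, config) * n_b
  dens <- cbind(n_a, if (is.null(fb)) NULL else n_b)
  abil <- c(fa$ability, if (is.null(fb)) NULL else fb$ability)
  dph <- infer_ph_change(dens, ph, abil, relative_strength, config, env)
  uni_d <- config$universes$density
  uni_p <- config$universes$ph
  list(n_a = pmin(pmax(n_a + dn_a, uni_d[[1]]), uni_d[[2]]),
       n_b = if (is.null(fb)) n_b else
         pmin(pmax(n_b + dn_b, uni_d[[1]]), uni_d[[2]]),
       ph = pmin(pmax(ph + dph, uni_p[[1]]), uni_p[[2]]))
}

#' Iterate the fuzzy model from one initial state
#'
#' Synchronous updates: both densities move by their inferred per-capita
#' change times current density; the pH moves by the summed signed species
#' contributions. All values are clamped to their universes.
#'
#' @param state0 named list/vector with `n_a`, `n_b` (normalised densities)
#'   and `ph` (display scale).
#' @param sp_a,sp_b [species_params()] mapped via [fuzzy_species()]
#'   (`sp_b = NULL` for single species).
#' @param env a [ph_environment()] (display map).
#' @param n_iterations number of update steps.
#' @param config a `fuzzy_config`.
#' @return Data frame `iteration, n_a, n_b, ph` with `n_iterations + 1` rows.
#' @examples
#' arc <- archetype_species()
#' tr <- fuzzy_iterate(list(n_a = 0.05, n_b = 0, ph = 4), arc$species$Lp)
#' tail(tr, 1)
#' @export
fuzzy_iterate <- function(state0, sp_a, sp_b = NULL, env = ph_environment(),
                          n_iterations = 200, config = fuzzy_config()) {
  fa <- fuzzy_species(sp_a, env)
  fb <- if (is.null(sp_b)) NULL else fuzzy_species(sp_b, env)
  rel <- if (is.null(fb) || fa$strength == 0) 1 else fb$strength / fa$strength
  n_a <- state0[["n_a"]]; n_b <- state0[["n_b"]]; ph <- state0[["ph"]]
  out <- matrix(NA_real_, nrow = n_iterations + 1L, ncol = 3L)
  out[1L, ] <- c(n_a, n_b, ph)
  for (i in seq_len(n_iterations)) {
    st <- fuzzy_step(n_a, n_b, ph, fa, fb, rel, config, env)
    n_a <- st$n_a; n_b <- st$n_b; ph <- st$ph
    out[i + 1L, ] <- c(n_a, n_b, ph)
  }
  data.frame(iteration = 0:n_iterations, n_a = out[, 1], n_b = out[, 2],
             ph = out[, 3])
}

fuzzy_sweep_core <- function(n_a0, n_b0, ph0, fa, fb, rel, n_iterations,
                             config, threshold, env = ph_environment(),
                             osc_window = 0.6, min_peaks = 2) {
  n_a <- n_a0; n_b <- n_b0; ph <- ph0
  n_keep <- ceiling(osc_window * n_iterations)
  hist_a <- matrix(NA_real_, nrow = length(n_a0), ncol = n_keep)
  hist_b <- matrix(NA_real_, nrow = length(n_a0), ncol = n_keep)
  for (i in seq_len(n_iterations)) {
    st <- fuzzy_step(n_a, n_b, ph, fa, fb, rel, config, env)
    n_a <- st$n_a; n_b <- st$n_b; ph <- st$ph
    j <- i - (n_iterations - n_keep)
    if (j >= 1) { hist_a[, j] <- n_a; hist_b[, j] <- n_b }
  }
  count_peaks <- function(H) {
    m <- ncol(H)
    inner <- H[, 2:(m - 1), drop = FALSE]
    rowSums(inner > H[, 1:(m - 2), drop = FALSE] &
              inner > H[, 3:m, drop = FALSE] & inner > threshold)
  }
  osc <- count_peaks(hist_a) >= min_peaks | count_peaks(hist_b) >= min_peaks
  list(n_a = n_a, n_b = n_b, ph = ph, osc = osc)
}

#' Single-species phase diagram with the fuzzy backend
#'
#' Same grid and classification contract as [sweep_single()] (axes in model
#' proton units; densities in model density units), run through the fuzzy
#' iteration. Densities are normalised by `K` internally.
#'
#' @param sp a [species_params()].
#' @param env a [ph_environment()].
#' @param density_grid initial densities in model units.
#' @param p0_grid initial proton concentrations (model scale).
#' @param n_iterations fuzzy iterations.
#' @param config a `fuzzy_config`.
#' @param extinction_threshold survival cutoff in model density units.
#' @return An `outcome_grid` (mode `"single"`).
#' @export
fuzzy_sweep_single <- function(sp, env = ph_environment(),
                               density_grid = log_seq(1e-4 * sp$K,
                                                      0.5 * sp$K, 21),
                               p0_grid = seq(0.5, 9.5, length.out = 21),
                               n_iterations = 200,
                               config = fuzzy_config(),
                               extinction_threshold = 1e-3 * sp$K) {
  fa <- fuzzy_species(sp, env)
  cells <- expand.grid(axis1 = density_grid, axis2 = p0_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- fuzzy_sweep_core(cells$axis1 / sp$K, rep(0, nrow(cells)),
                          p_to_ph(cells$axis2, env), fa, NULL, 1,
                          n_iterations, config,
                          threshold = extinction_threshold / sp$K, env = env)
  cells$a_survives <- res$n_a >= extinction_threshold / sp$K
  cells$b_survives <- FALSE
  cells$n_a_final <- res$n_a * sp$K
  cells$n_b_final <- 0
  cells$p_final <- ph_to_p(res$ph, env)
  cells$oscillatory <- res$osc
  new_outcome_grid(cells,
                   axes = list(axis1 = density_grid, axis2 = p0_grid,
                               axis1_name = "initial_density",
                               axis2_name = "initial_p"),
                   mode = "single")
}

#' Pairwise phase diagram with the fuzzy backend
#'
#' Same contract as [sweep_pair()]: initial densities `(f N, (1 - f) N)` in
#' model units, axes in fractions and model proton units. The second
#' species' pH drive is weighted by the pair's relative strength
#' (`|c_b| d_b / (|c_a| d_a)`).
#'
#' @inheritParams fuzzy_sweep_single
#' @param sp_a,sp_b the two species.
#' @param fraction_grid initial fractions of species A.
#' @param total_density total inoculum in model density units.
#' @return An `outcome_grid` (mode `"pair"`).
#' @export
fuzzy_sweep_pair <- function(sp_a, sp_b, env = ph_environment(),
                             fraction_grid = seq(0, 1, length.out = 21),
                             p0_grid = seq(0.5, 9.5, length.out = 21),
                             total_density = 1, n_iterations = 200,
                             config = fuzzy_config(),
                             extinction_threshold = 1e-3 * max(sp_a$K,
                                                               sp_b$K)) {
  fa <- fuzzy_species(sp_a, env)
  fb <- fuzzy_species(sp_b, env)
  rel <- if (fa$strength == 0) 1 else fb$strength / fa$strength
  K <- max(sp_a$K, sp_b$K)
  cells <- expand.grid(axis1 = fraction_grid, axis2 = p0_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- fuzzy_sweep_core(cells$axis1 * total_density / K,
                          (1 - cells$axis1) * total_density / K,
                          p_to_ph(cells$axis2, env), fa, fb, rel,
                          n_iterations, config,
                          threshold = extinction_threshold / K, env = env)
  cells$a_survives <- res$n_a >= extinction_threshold / K
  cells$b_survives <- res$n_b >= extinction_threshold / K
  cells$n_a_final <- res$n_a * K
  cells$n_b_final <- res$n_b * K
  cells$p_final <- ph_to_p(res$ph, env)
  cells$oscillatory <- res$osc
  new_outcome_grid(cells,
                   axes = list(axis1 = fraction_grid, axis2 = p0_grid,
                               axis1_name = "fraction_a",
                               axis2_name = "initial_p",
                               total_density = total_density),
                   mode = "pair")
}
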