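## Estimation of species pH niches and pH drives from growth-assay tables,
## and prediction of pairwise interaction motifs from the estimates.

#' Fit a species' pH-niche parameters from a fold-growth table
#'
#' Nonlinear least squares of log fold-growth against the Gaussian-niche
#' response: `log(fold) = A * exp(-(p - p_pref)^2 / sigma^2) + k`, where `p`
#' is the model image of the assay's starting pH (see [ph_to_p()]), `A` is
#' the effective assay duration in model time and `k = -A * delta`. The
#' estimates of `p_pref` and `sigma` are invariant to rescaling all
#' fold-growth values by a positive constant (only `k` shifts); the `delta`
#' estimate additionally assumes fold-growth is an absolute final/initial
#' ratio (fold 1 = no net growth), which is how values below 1 identify the
#' death rate.
#'
#' @param table data frame with columns `pH_initial` and `fold_growth`
#'   (replicates as repeated rows); extra columns ignored.
#' @param env a [ph_environment()] fixing the display map.
#' @param min_levels minimal number of distinct pH levels required.
#' @return A `species_profile` list: `p_pref`, `sigma`, `delta`,
#'   `assay_time` (`A`), `p_pref_ph` (display scale), `residual` (RSS of the
#'   log fit), `degenerate` (flag), `n_obs`, `converged`.
#' @examples
#' arc <- archetype_species()
#' tab <- gen_growth_vs_ph(arc$species$Lp, noise_model(growth_sd = 0),
#'                         seed = 1)
#' fit_ph_response(tab)[c("p_pref", "sigma", "delta")]
#' @export
fit_ph_response <- function(table, env = ph_environment(), min_levels = 5) {
  stopifnot(all(c("pH_initial", "fold_growth") %in% names(table)))
  if (length(unique(table$pH_initial)) < min_levels)
    stop("fit_ph_response: need >= ", min_levels, " distinct pH levels",
         call. = FALSE)
  if (any(table$fold_growth < 0))
    stop("fit_ph_response: negative fold-growth", call. = FALSE)
  p <- ph_to_p(table$pH_initial, env)
  floor_val <- min(table$fold_growth[table$fold_growth > 0], na.rm = TRUE) / 2
  y <- log(pmax(table$fold_growth, floor_val))

  prof <- list(p_pref = NA_real_, sigma = NA_real_, delta = NA_real_,
               assay_time = NA_real_, p_pref_ph = NA_real_,
               residual = NA_real_, degenerate = FALSE,
               n_obs = nrow(table), converged = FALSE)
  class(prof) <- "species_profile"
  if (stats::sd(y) < 1e-8) {   # flat response: sigma unidentifiable
    prof$degenerate <- TRUE
    return(prof)
  }
  agg <- stats::aggregate(y, list(p = p), mean)
  m0 <- agg$p[which.max(agg$x)]
  a0 <- max(agg$x) - min(agg$x)
  s0 <- max(diff(range(p)) / 3, 1)
  k0 <- min(agg$x)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-((p - m)^2) / s^2) + k,
      start = list(a = a0, m = m0, s = s0, k = k0),
      lower = c(a = 1e-6, m = -2 * env$b, s = 0.1, k = -Inf),
      upper = c(a = Inf, m = 4 * env$b, s = 10 * env$b, k = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    prof$degenerate <- TRUE
    return(prof)
  }
  cf <- stats::coef(fit)
  prof$p_pref <- unname(cf[["m"]])
  prof$sigma <- unname(cf[["s"]])
  prof$assay_time <- unname(cf[["a"]])
  prof$delta <- unname(-cf[["k"]] / cf[["a"]])
  prof$p_pref_ph <- p_to_ph(prof$p_pref, env)
  prof$residual <- sum(stats::resid(fit)^2)
  prof$converged <- TRUE
  prof
}

#' @export
print.species_profile <- function(x, ...) {
  if (x$degenerate) {
    cat("<species_profile> degenerate (flat or unfittable response)\n")
  } else {
    cat(sprintf(
      "<species_profile> p_pref=%.3f (display pH %.2f) sigma=%.3f delta=%.3f rss=%.3g\n",
      x$p_pref, x$p_pref_ph, x$sigma, x$delta, x$residual))
    if (!is.null(x$drive_sign))
      cat(sprintf("  drive: sign %+d, magnitude %.2f display-pH units\n",
                  x$drive_sign, x$drive_magnitude))
  }
  invisible(x)
}

#' Estimate a species' pH drive from endpoint measurements
#'
#' Sign and magnitude of the median pH shift between paired initial and
#' final measurements. Shifts smaller than the measurement-noise floor give
#' sign 0.
#'
#' @param initial_pH,final_pH paired display-pH measurements.
#' @param noise_floor smallest |median shift| regarded as a real drive.
#' @return List with `sign` (-1 = acidifier on the display scale, +1 =
#'   alkalizer, 0 = none), `magnitude` (|median shift|, display-pH units),
#'   and `shift` (signed median).
#' @examples
#' estimate_ph_drive(rep(7, 4), c(9.4, 9.5, 9.6, 9.5))  # alkalizer, ~2.5
#' @export
estimate_ph_drive <- function(initial_pH, final_pH, noise_floor = 0.1) {
  stopifnot(length(initial_pH) == length(final_pH))
  if (!length(initial_pH)) stop("estimate_ph_drive: empty input", call. = FALSE)
  shift <- stats::median(final_pH - initial_pH)
  sgn <- if (abs(shift) < noise_floor) 0L else as.integer(sign(shift))
  list(sign = sgn, magnitude = abs(shift), shift = shift)
}

#' Predict the pairwise interaction motif from two species profiles
#'
#' Each species is classified as self-serving or self-harming: its drive is
#' self-serving when it moves the proton concentration from the assay's
#' starting point toward the species' own estimated optimum. The unordered
#' pair of classes then maps to a motif:
#'
#' * both self-serving, opposing drives -> `bistability`;
#' * one self-harming whose drive moves the environment toward the
#'   partner's optimum -> `successive_growth` (the suicidal species
#'   conditions the environment for the partner);
#' * one self-harming whose drive moves the environment away from the
#'   partner's optimum -> `extended_suicide` (both self-harming with aligned
#'   drives also falls here);
#' * both self-harming, opposing drives -> `stabilization`;
#' * both self-serving, aligned drives -> `exclusion` (same niche
#'   construction, plain competition).
#'
#' @param profile_a,profile_b `species_profile` objects (or lists with
#'   `p_pref` and `drive_sign` on the display scale, as produced by
#'   [fit_ph_response()] + [estimate_ph_drive()]).
#' @param assay_ph display pH from which drives act (assay starting pH).
#' @param env a [ph_environment()].
#' @return Motif label (character).
#' @examples
#' lp <- list(p_pref = 8, drive_sign = -1)   # acid-lover, acidifier
#' ca <- list(p_pref = 2, drive_sign = +1)   # alkali-lover, alkalizer
#' predict_pair_motif(lp, ca)                # "bistability"
#' @export
predict_pair_motif <- function(profile_a, profile_b, assay_ph = 7,
                               env = ph_environment()) {
  for (pr in list(profile_a, profile_b))
    if (isTRUE(pr$degenerate) || is.null(pr$p_pref) ||
        is.null(pr$drive_sign) || is.na(pr$p_pref))
      stop("predict_pair_motif: degenerate or incomplete profile",
           call. = FALSE)
  p_start <- ph_to_p(assay_ph, env)
  # drive_sign is on the display-pH scale; its proton-scale image is -sign
  drive_p <- function(pr) -pr$drive_sign
  if (drive_p(profile_a) == 0 || drive_p(profile_b) == 0)
    return("coexistence")   # a non-modifier cannot set up a pH feedback
  serves_self <- function(pr)
    drive_p(pr) == sign(pr$p_pref - p_start)
  helps <- function(pr, other)
    drive_p(pr) == sign(other$p_pref - p_start)
  sa <- serves_self(profile_a); sb <- serves_self(profile_b)
  opposing <- drive_p(profile_a) != drive_p(profile_b)
  if (sa && sb) return(if (opposing) "bistability" else "exclusion")
  if (!sa && !sb && opposing) return("stabilization")
  # exactly one self-harming (or both, aligned): does the harmful drive
  # condition the environment for the partner or against it?
  harmful <- if (!sa) profile_a else profile_b
  partner <- if (!sa) profile_b else profile_a
  if (helps(harmful, partner)) "successive_growth" else "extended_suicide"
}
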