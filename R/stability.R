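## Fixed points of the 3-variable system and their linear stability.

#' Analytic Jacobian of the density-proton system
#'
#' Exact partial derivatives of [system_rhs()] at a state, in the variable
#' order `(n_a, n_b, p)`.
#'
#' @param state numeric vector or [system_state()] with `n_a`, `n_b`, `p`.
#' @param sp_a,sp_b species parameters (`sp_b = NULL` for single species).
#' @param env a [ph_environment()].
#' @param boundary_norm see [proton_boundary_factor()].
#' @return A 3x3 numeric matrix.
#' @export
jacobian_at <- function(state, sp_a, sp_b = NULL, env = ph_environment(),
                        boundary_norm = env$b^2) {
  n_a <- state[["n_a"]]; n_b <- state[["n_b"]]; p <- state[["p"]]
  b <- env$b
  g <- function(sp) exp(-((p - sp$p_pref)^2) / sp$sigma^2) - sp$delta
  gprime <- function(sp)
    -2 * (p - sp$p_pref) / sp$sigma^2 * exp(-((p - sp$p_pref)^2) / sp$sigma^2)
  q <- p * (2 * b - p) / boundary_norm
  qprime <- (2 * b - 2 * p) / boundary_norm

  J <- matrix(0, 3, 3,
              dimnames = list(c("n_a", "n_b", "p"), c("n_a", "n_b", "p")))
  J[1, 1] <- (1 - 2 * n_a / sp_a$K) * g(sp_a)
  J[1, 3] <- n_a * (1 - n_a / sp_a$K) * gprime(sp_a)
  drive <- sp_a$c * sp_a$d * n_a
  J[3, 1] <- sp_a$c * sp_a$d * q
  if (!is.null(sp_b)) {
    J[2, 2] <- (1 - 2 * n_b / sp_b$K) * g(sp_b)
    J[2, 3] <- n_b * (1 - n_b / sp_b$K) * gprime(sp_b)
    J[3, 2] <- sp_b$c * sp_b$d * q
    drive <- drive + sp_b$c * sp_b$d * n_b
  }
  J[3, 3] <- drive * qprime
  J
}

#' Classify a fixed point from its eigenvalues
#'
#' All real parts below `-tol`: `stable`; any above `tol` (all others also
#' positive): `unstable`; mixed signs: `saddle`; any real part within `tol`
#' of zero: `non_hyperbolic`.
#'
#' @param eigenvalues complex vector of Jacobian eigenvalues.
#' @param tol hyperbolicity tolerance on real parts.
#' @return One of `"stable"`, `"unstable"`, `"saddle"`, `"non_hyperbolic"`.
#' @export
classify_fixed_point <- function(eigenvalues, tol = 1e-8) {
  re <- Re(eigenvalues)
  if (any(abs(re) <= tol)) return("non_hyperbolic")
  if (all(re < 0)) return("stable")
  if (all(re > 0)) return("unstable")
  "saddle"
}

newton_polish <- function(x0, sp_a, sp_b, env, boundary_norm,
                          tol = 1e-12, max_iter = 60) {
  x <- x0
  two_b <- 2 * env$b
  for (i in seq_len(max_iter)) {
    # keep the iterate in the physical domain; rhs is undefined outside
    x[1] <- max(x[1], 0); x[2] <- max(x[2], 0)
    x[3] <- min(max(x[3], 0), two_b)
    st <- c(n_a = x[1], n_b = x[2], p = x[3])
    f <- system_rhs(st, sp_a, sp_b, env, boundary_norm)
    if (sqrt(sum(f^2)) < tol) return(list(x = x, converged = TRUE))
    J <- jacobian_at(st, sp_a, sp_b, env, boundary_norm)
    step <- tryCatch(solve(J + diag(1e-14, 3), -f), error = function(e) NULL)
    if (is.null(step)) return(list(x = x, converged = FALSE))
    if (sqrt(sum(step^2)) > 1) step <- step / sqrt(sum(step^2))  # damp
    x <- unname(x + step)
  }
  st <- c(n_a = max(x[1], 0), n_b = max(x[2], 0),
          p = min(max(x[3], 0), two_b))
  f <- system_rhs(st, sp_a, sp_b, env, boundary_norm)
  list(x = unname(st), converged = sqrt(sum(f^2)) < tol)
}

#' Locate and classify fixed points of the system
#'
#' Enumerates analytic boundary candidates -- densities at `0` or `K`,
#' proton concentration at the scale ends `0` / `2b` or at the roots of a
#' species' growth factor, `p = p_pref +/- sigma * sqrt(log(1/delta))` --
#' polishes each by damped Newton iteration on [system_rhs()] with the
#' analytic Jacobian, deduplicates, classifies each by Jacobian eigenvalues,
#' and drops candidates whose residual cannot be brought below `tol`.
#'
#' The sterile set `n_a = n_b = 0` is a continuum (every `p` is a fixed
#' point). It is represented by nodes of `sterile_p_grid`; such points are
#' always non-hyperbolic along the line, so their reported `class` is
#' `non_hyperbolic` and the column `transverse` classifies stability against
#' invasion (sign of the two growth factors).
#'
#' @param sp_a,sp_b species parameters (`sp_b = NULL` for single species).
#' @param env a [ph_environment()].
#' @param sterile_p_grid proton values at which to report sterile-line
#'   representatives.
#' @param tol residual tolerance for accepting a polished fixed point.
#' @param dedup_radius states closer than this (Euclidean) are merged.
#' @param eig_tol hyperbolicity tolerance, see [classify_fixed_point()].
#' @param boundary_norm see [proton_boundary_factor()].
#' @return A `fixed_points` data frame: `n_a, n_b, p, residual, class,
#'   transverse, sterile, re_ev1..3, im_ev1..3`.
#' @examples
#' arc <- archetype_species()
#' fps <- find_fixed_points(arc$species$Lp, arc$species$Ca, arc$environment)
#' subset(fps, class == "stable")
#' @export
find_fixed_points <- function(sp_a, sp_b = NULL, env = ph_environment(),
                              sterile_p_grid = seq(0, 2 * env$b,
                                                   length.out = 5),
                              tol = 1e-9, dedup_radius = 1e-6,
                              eig_tol = 1e-8, boundary_norm = env$b^2) {
  two_b <- 2 * env$b
  groots <- function(sp) {
    r <- sp$sigma * sqrt(log(1 / sp$delta))
    c(sp$p_pref - r, sp$p_pref + r)
  }
  p_cand <- c(0, two_b, groots(sp_a), if (!is.null(sp_b)) groots(sp_b))
  p_cand <- unique(p_cand[p_cand >= 0 & p_cand <= two_b])
  na_cand <- c(0, sp_a$K)
  nb_cand <- if (is.null(sp_b)) 0 else c(0, sp_b$K)
  cand <- expand.grid(n_a = na_cand, n_b = nb_cand, p = p_cand,
                      KEEP.OUT.ATTRS = FALSE)
  cand <- cand[!(cand$n_a == 0 & cand$n_b == 0), , drop = FALSE]

  pts <- list()
  for (i in seq_len(nrow(cand))) {
    pol <- newton_polish(as.numeric(cand[i, ]), sp_a, sp_b, env,
                         boundary_norm, tol = 1e-12)
    st <- c(n_a = pol$x[1], n_b = pol$x[2], p = pol$x[3])
    res <- sqrt(sum(system_rhs(st, sp_a, sp_b, env, boundary_norm)^2))
    if (res > tol) next
    dup <- any(vapply(pts, function(q)
      sqrt(sum((q - pol$x)^2)) < dedup_radius, logical(1)))
    if (!dup) pts[[length(pts) + 1L]] <- pol$x
  }

  row_for <- function(x, sterile = FALSE) {
    st <- c(n_a = x[1], n_b = x[2], p = x[3])
    J <- jacobian_at(st, sp_a, sp_b, env, boundary_norm)
    ev <- eigen(J, only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    res <- sqrt(sum(system_rhs(st, sp_a, sp_b, env, boundary_norm)^2))
    cls <- classify_fixed_point(ev, eig_tol)
    trans <- NA_character_
    if (sterile) {
      # direction along the sterile line is always neutral; judge invasion
      ga <- growth_rate_factor(x[3], sp_a)
      gb <- if (is.null(sp_b)) -Inf else growth_rate_factor(x[3], sp_b)
      trans <- if (max(ga, gb) < 0) "stable" else "unstable"
      cls <- "non_hyperbolic"
    }
    data.frame(n_a = x[1], n_b = x[2], p = x[3], residual = res,
               class = cls, transverse = trans, sterile = sterile,
               re_ev1 = Re(ev[1]), re_ev2 = Re(ev[2]), re_ev3 = Re(ev[3]),
               im_ev1 = Im(ev[1]), im_ev2 = Im(ev[2]), im_ev3 = Im(ev[3]))
  }

  rows <- lapply(pts, row_for)
  rows <- c(rows, lapply(sterile_p_grid, function(p)
    row_for(c(0, 0, p), sterile = TRUE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fixed_points", "data.frame")
  out
}

#' @export
print.fixed_points <- function(x, ...) {
  cat(sprintf("<fixed_points> %d points (%d sterile-line representatives)\n",
              nrow(x), sum(x$sterile)))
  print.data.frame(
    x[, c("n_a", "n_b", "p", "class", "transverse", "residual")],
    digits = 4)
  invisible(x)
}

#' Write a fixed-point report as CSV
#'
#' @param fps a `fixed_points` data frame.
#' @param path file path.
#' @param meta `#`-header metadata.
#' @return `path`, invisibly.
#' @export
write_fixed_points <- function(fps, path, meta = NULL) {
  write_csv_meta(as.data.frame(fps), path, meta)
}
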