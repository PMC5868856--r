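## Initial-condition sweeps, survival classification and interaction-motif
## labelling (phase diagrams).

#' Classify survival of both species at the end of a trajectory
#'
#' A species survives iff its final density is at least
#' `extinction_threshold` (default `1e-3 * K`, with `K = 10` the default
#' carrying capacity).
#'
#' @param traj a `trajectory`.
#' @param extinction_threshold density below which a species counts as
#'   extinct.
#' @return Logical vector `c(a = , b = )`.
#' @export
classify_survival <- function(traj, extinction_threshold = 1e-2) {
  if (!nrow(traj)) stop("classify_survival: empty trajectory", call. = FALSE)
  fin <- traj[nrow(traj), ]
  c(a = fin$n_a >= extinction_threshold, b = fin$n_b >= extinction_threshold)
}

#' Detect sustained oscillations at the end of a trajectory
#'
#' Counts strict local maxima of each species' density above the extinction
#' threshold inside the final `window` fraction of the time span; at least
#' `min_peaks` maxima for a surviving species flags oscillation.
#'
#' @param traj a `trajectory` (dense sampling required).
#' @param extinction_threshold density threshold.
#' @param window final fraction of the horizon inspected (wide enough by
#'   default to cover two periods of the slow coculture limit cycles).
#' @param min_peaks minimal number of late local maxima.
#' @return Logical scalar.
#' @export
detect_oscillation <- function(traj, extinction_threshold = 1e-2,
                               window = 0.6, min_peaks = 2) {
  t_end <- max(traj$t)
  t_start <- min(traj$t)
  late <- traj[traj$t >= t_end - window * (t_end - t_start), ]
  if (nrow(late) < 5) return(FALSE)
  count_peaks <- function(x) {
    n <- length(x)
    if (n < 3) return(0L)
    mid <- x[2:(n - 1)]
    sum(mid > x[1:(n - 2)] & mid > x[3:n] & mid > extinction_threshold)
  }
  count_peaks(late$n_a) >= min_peaks || count_peaks(late$n_b) >= min_peaks
}

new_outcome_grid <- function(df, axes, mode) {
  structure(df, class = c("outcome_grid", "data.frame"),
            axes = axes, mode = mode)
}

#' @export
print.outcome_grid <- function(x, ...) {
  cat(sprintf(
    "<outcome_grid> %s, %d cells; A survives in %d, B in %d, both in %d\n",
    attr(x, "mode"), nrow(x), sum(x$a_survives), sum(x$b_survives),
    sum(x$a_survives & x$b_survives)))
  invisible(x)
}

#' Single-species survival phase diagram
#'
#' Integrates one species alone from every combination of initial density
#' and initial proton concentration and classifies survival at the horizon.
#'
#' @param sp a [species_params()].
#' @param env a [ph_environment()].
#' @param density_grid initial densities (strictly increasing).
#' @param p0_grid initial proton concentrations (strictly increasing).
#' @param horizon batch integration time.
#' @param extinction_threshold see [classify_survival()].
#' @param n_out samples per trajectory (dense enough for oscillation checks).
#' @param rtol,atol solver tolerances.
#' @return An `outcome_grid` data frame in long format with columns
#'   `axis1` (initial density), `axis2` (initial p), `a_survives`,
#'   `b_survives` (always `FALSE` here), `n_a_final`, `n_b_final`, `p_final`,
#'   `oscillatory`.
#' @export
sweep_single <- function(sp, env = ph_environment(),
                         density_grid = log_seq(1e-4 * sp$K, 0.5 * sp$K, 21),
                         p0_grid = seq(0.5, 9.5, length.out = 21),
                         horizon = 200,
                         extinction_threshold = 1e-3 * sp$K,
                         n_out = 200, rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(density_grid) > 0, length(p0_grid) > 0,
            !is.unsorted(density_grid, strictly = TRUE),
            !is.unsorted(p0_grid, strictly = TRUE))
  cells <- expand.grid(axis1 = density_grid, axis2 = p0_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    tr <- integrate_batch(system_state(cells$axis1[i], 0, p = cells$axis2[i]),
                          sp, NULL, env, horizon = horizon, n_out = n_out,
                          rtol = rtol, atol = atol)
    fin <- tr[nrow(tr), ]
    c(fin$n_a, fin$n_b, fin$p,
      detect_oscillation(tr, extinction_threshold))
  })
  res <- do.call(rbind, res)
  cells$a_survives <- res[, 1] >= extinction_threshold
  cells$b_survives <- FALSE
  cells$n_a_final <- res[, 1]
  cells$n_b_final <- res[, 2]
  cells$p_final <- res[, 3]
  cells$oscillatory <- as.logical(res[, 4])
  new_outcome_grid(cells,
                   axes = list(axis1 = density_grid, axis2 = p0_grid,
                               axis1_name = "initial_density",
                               axis2_name = "initial_p"),
                   mode = "single")
}

#' Pairwise survival phase diagram
#'
#' Initial densities are `(f * N, (1 - f) * N)` for each fraction `f` of
#' species A and total inoculum `N`; each cell is integrated in coculture and
#' survival of both species classified at the horizon.
#'
#' @inheritParams sweep_single
#' @param sp_a,sp_b the two species.
#' @param fraction_grid initial fractions of species A, in `[0, 1]`.
#' @param total_density total initial density `N`.
#' @return An `outcome_grid` with `axis1` = fraction of A, `axis2` =
#'   initial p.
#' @export
sweep_pair <- function(sp_a, sp_b, env = ph_environment(),
                       fraction_grid = seq(0, 1, length.out = 21),
                       p0_grid = seq(0.5, 9.5, length.out = 21),
                       total_density = 1, horizon = 200,
                       extinction_threshold = 1e-3 * max(sp_a$K, sp_b$K),
                       n_out = 200, rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(fraction_grid >= 0 & fraction_grid <= 1),
            total_density > 0)
  cells <- expand.grid(axis1 = fraction_grid, axis2 = p0_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    tr <- integrate_batch(
      system_state(cells$axis1[i] * total_density,
                   (1 - cells$axis1[i]) * total_density,
                   p = cells$axis2[i]),
      sp_a, sp_b, env, horizon = horizon, n_out = n_out,
      rtol = rtol, atol = atol)
    fin <- tr[nrow(tr), ]
    c(fin$n_a, fin$n_b, fin$p,
      detect_oscillation(tr, extinction_threshold))
  })
  res <- do.call(rbind, res)
  cells$a_survives <- res[, 1] >= extinction_threshold
  cells$b_survives <- res[, 2] >= extinction_threshold
  cells$n_a_final <- res[, 1]
  cells$n_b_final <- res[, 2]
  cells$p_final <- res[, 3]
  cells$oscillatory <- as.logical(res[, 4])
  new_outcome_grid(cells,
                   axes = list(axis1 = fraction_grid, axis2 = p0_grid,
                               axis1_name = "fraction_a",
                               axis2_name = "initial_p",
                               total_density = total_density),
                   mode = "pair")
}

#' Critical initial density for survival (Allee threshold)
#'
#' Bisects the initial density between a surviving high-density start and an
#' extinct low-density start at fixed initial proton concentration. When no
#' sign change exists on the bracket the threshold is reported absent
#' (`NA` with an explanatory attribute).
#'
#' @param sp,env species and environment.
#' @param p0 initial proton concentration.
#' @param horizon batch integration time.
#' @param lower,upper density bracket.
#' @param tol relative bisection tolerance.
#' @param extinction_threshold survival cutoff.
#' @return Critical density, or `NA` with `attr(,"reason")` one of
#'   `"survives_everywhere"` / `"extinct_everywhere"`.
#' @export
allee_threshold <- function(sp, env = ph_environment(), p0, horizon = 200,
                            lower = 1e-4 * sp$K, upper = 0.5 * sp$K, tol = 1e-3,
                            extinction_threshold = 1e-3 * sp$K) {
  survives <- function(n0) {
    tr <- integrate_batch(system_state(n0, 0, p = p0), sp, NULL, env,
                          horizon = horizon, n_out = 2)
    tr$n_a[nrow(tr)] >= extinction_threshold
  }
  s_lo <- survives(lower); s_hi <- survives(upper)
  if (s_lo && s_hi) {
    out <- NA_real_; attr(out, "reason") <- "survives_everywhere"; return(out)
  }
  if (!s_lo && !s_hi) {
    out <- NA_real_; attr(out, "reason") <- "extinct_everywhere"; return(out)
  }
  # conventional case: extinct below, surviving above
  lo <- lower; hi <- upper
  while ((hi - lo) / hi > tol) {
    mid <- sqrt(lo * hi)   # bisect on the log scale, densities span decades
    if (survives(mid) == s_hi) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

## ---- motif labelling -------------------------------------------------------

#' Motif labels recognised by the classifier
#' @return Character vector of valid labels.
#' @export
motif_labels <- function() {
  c("allee", "ecological_suicide", "bistability", "successive_growth",
    "extended_suicide", "stabilization", "coexistence", "exclusion",
    "oscillatory_coexistence")
}

#' Label a single-species phase diagram
#'
#' `allee` if survival depends on initial density at some initial p (with
#' survival at high density), `ecological_suicide` if extinct in every cell,
#' `robust_growth` if surviving in every cell, otherwise `conditional_growth`
#' (survival depends on initial p only).
#'
#' @param grid an `outcome_grid` from [sweep_single()].
#' @return Character label.
#' @export
label_single_motif <- function(grid) {
  stopifnot(attr(grid, "mode") == "single")
  if (!any(grid$a_survives)) return("ecological_suicide")
  if (all(grid$a_survives)) return("robust_growth")
  dens_dependent <- vapply(split(grid, grid$axis2), function(g) {
    g <- g[order(g$axis1), ]
    any(g$a_survives) && !all(g$a_survives) &&
      g$a_survives[nrow(g)]      # survives at the top of the density axis
  }, logical(1))
  if (any(dens_dependent)) "allee" else "conditional_growth"
}

#' Label the interaction motif of a species pair
#'
#' Rule-based classification of a pairwise phase diagram against the two
#' single-species diagrams on the same initial-p axis. The rules are ordered
#' and explicit; every rule whose condition holds is recorded, and if more
#' than one matches, the first in order wins while the conflict is reported
#' via a warning and the `"matched"` attribute.
#'
#' Rules (in order), with `alone_extinct(s, p0)` meaning species `s` alone is
#' extinct at every initial density of its single-species grid at that
#' initial p:
#'
#' 1. `stabilization`: cells where both survive together although each alone
#'    is extinct at the matched initial density and p.
#' 2. `successive_growth`: cells where exactly one species survives, that
#'    species alone is extinct at that initial p, and the partner (the
#'    helper) is extinct alone there too.
#' 3. `extended_suicide`: cells where both species die together although
#'    exactly one of them alone would survive at the matched initial density
#'    and p -- the other (extinct alone as well) is the suicidal partner
#'    that drags it down.
#' 4. `bistability`: both single-winner outcomes occur (some cells only A
#'    survives, others only B), each in at least `min_cells` cells.
#' 5. `coexistence`: both species survive together in at least `min_cells`
#'    cells.
#' 6. `exclusion`: otherwise.
#'
#' `oscillatory_coexistence` overrides the label when at least `min_cells`
#' coexisting cells carry the per-cell oscillation flag and the winning rule
#' was not `stabilization`.
#'
#' @param grid_a,grid_b single-species `outcome_grid`s for species A and B
#'   (same `axis2` as the pair grid).
#' @param grid_pair pairwise `outcome_grid`.
#' @param min_cells minimal number of supporting cells per rule.
#' @return Character label with attributes `matched` (all matching rules)
#'   and `cells` (supporting cell counts).
#' @export
label_motif <- function(grid_a, grid_b, grid_pair, min_cells = 3) {
  stopifnot(attr(grid_pair, "mode") == "pair",
            attr(grid_a, "mode") == "single",
            attr(grid_b, "mode") == "single")
  p0_pair <- attr(grid_pair, "axes")$axis2
  if (!isTRUE(all.equal(attr(grid_a, "axes")$axis2, p0_pair)) ||
      !isTRUE(all.equal(attr(grid_b, "axes")$axis2, p0_pair)))
    stop("label_motif: grids do not share the initial-p axis", call. = FALSE)

  alone_extinct <- function(grid, p0) {
    vapply(p0, function(x) {
      g <- grid[abs(grid$axis2 - x) < 1e-9, ]
      nrow(g) > 0 && !any(g$a_survives)
    }, logical(1))
  }
  ax_a <- alone_extinct(grid_a, p0_pair)   # indexed like p0_pair
  ax_b <- alone_extinct(grid_b, p0_pair)
  p0_idx <- function(p0) which.min(abs(p0_pair - p0))
  ext_a_at <- function(p0) ax_a[[p0_idx(p0)]]
  ext_b_at <- function(p0) ax_b[[p0_idx(p0)]]

  # nearest single-grid survival at a matched initial density
  alone_survives_at <- function(grid, density, p0) {
    g <- grid[abs(grid$axis2 - p0) < 1e-9, ]
    if (!nrow(g) || density <= 0) return(FALSE)
    g$a_survives[which.min(abs(log(pmax(g$axis1, 1e-300)) -
                                 log(max(density, 1e-300))))]
  }

  N <- attr(grid_pair, "axes")$total_density
  cells <- grid_pair
  both <- cells$a_survives & cells$b_survives
  only_a <- cells$a_survives & !cells$b_survives
  only_b <- cells$b_survives & !cells$a_survives
  none <- !cells$a_survives & !cells$b_survives

  p0_of <- cells$axis2
  a_ext_alone <- vapply(p0_of, ext_a_at, logical(1))
  b_ext_alone <- vapply(p0_of, ext_b_at, logical(1))

  a_alone_ok <- vapply(seq_len(nrow(cells)), function(i)
    alone_survives_at(grid_a, cells$axis1[i] * N, cells$axis2[i]),
    logical(1))
  b_alone_ok <- vapply(seq_len(nrow(cells)), function(i)
    alone_survives_at(grid_b, (1 - cells$axis1[i]) * N, cells$axis2[i]),
    logical(1))
  n_stab <- sum(both & !a_alone_ok & !b_alone_ok)
  n_succ <- sum((only_a | only_b) & a_ext_alone & b_ext_alone)
  # extended suicide is judged cell-by-cell: both die together although one
  # of them alone would have survived at the matched inoculum, while the
  # other (the suicidal partner) is extinct alone there as well
  n_ext <- sum(none & (a_alone_ok != b_alone_ok))
  n_bist <- min(sum(only_a), sum(only_b))
  n_coex <- sum(both)
  n_osc <- sum(both & cells$oscillatory)

  counts <- c(stabilization = n_stab, successive_growth = n_succ,
              extended_suicide = n_ext, bistability = n_bist,
              coexistence = n_coex)
  matched <- names(counts)[counts >= min_cells]
  # coexistence is a residual category, not a conflict with a specific motif
  specific <- setdiff(matched, "coexistence")
  label <- if (length(matched)) matched[1] else "exclusion"
  if (label != "stabilization" && n_osc >= min_cells &&
      label %in% c("extended_suicide", "coexistence", "exclusion",
                   "bistability"))
    label <- if (label == "extended_suicide") label else
      "oscillatory_coexistence"
  if (length(specific) > 1)
    message("label_motif: multiple motif rules matched (",
            paste(specific, collapse = ", "), "); first in order used")
  attr(label, "matched") <- matched
  attr(label, "cells") <- c(counts, oscillatory_coexistence = n_osc)
  label
}

#' Write / read an outcome grid as long-format CSV
#'
#' @param grid an `outcome_grid`.
#' @param path file path.
#' @param meta metadata for the `#` header.
#' @return The path / the re-read `outcome_grid`.
#' @export
write_outcome_grid <- function(grid, path, meta = NULL) {
  ax <- attr(grid, "axes")
  meta <- c(list(mode = attr(grid, "mode"),
                 axis1_name = ax$axis1_name, axis2_name = ax$axis2_name),
            if (!is.null(ax$total_density))
              list(total_density = ax$total_density),
            meta)
  write_csv_meta(as.data.frame(grid), path, meta)
}

#' @rdname write_outcome_grid
#' @export
read_outcome_grid <- function(path) {
  df <- read_csv_meta(path)
  meta <- attr(df, "meta")
  axes <- list(axis1 = sort(unique(df$axis1)), axis2 = sort(unique(df$axis2)),
               axis1_name = meta$axis1_name, axis2_name = meta$axis2_name)
  if (!is.null(meta$total_density))
    axes$total_density <- as.numeric(meta$total_density)
  new_outcome_grid(df, axes = axes, mode = meta$mode)
}

#' Heatmap of an outcome grid (base graphics)
#'
#' Cell colours: white = both extinct, red = only A, blue = only B,
#' purple = both survive.
#'
#' @param x an `outcome_grid`.
#' @param ... passed to [graphics::image()].
#' @return The input, invisibly.
#' @export
plot.outcome_grid <- function(x, ...) {
  ax <- attr(x, "axes")
  code <- matrix(1 + x$a_survives + 2 * x$b_survives,
                 nrow = length(ax$axis1), ncol = length(ax$axis2))
  graphics::image(seq_along(ax$axis1), ax$axis2, code,
                  col = c("white", "#d73027", "#4575b4", "#7b3294"),
                  zlim = c(1, 4), xlab = ax$axis1_name, ylab = ax$axis2_name,
                  ...)
  invisible(x)
}
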