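#' Integrate the density-proton system over a continuous batch
#'
#' Adaptive-step integration (deSolve, `lsoda` by default) of [system_rhs()]
#' from `state0` to `horizon`, sampled on a dense regular grid. Densities are
#' clamped to zero when they underflow below the absolute tolerance, so
#' extinction is absorbing and sign flips cannot occur.
#'
#' @param state0 a [system_state()] (its `t` element is the start time).
#' @param sp_a,sp_b species parameters (`sp_b = NULL` for single species).
#' @param env a [ph_environment()].
#' @param horizon integration time (> 0), measured from `state0`'s time.
#' @param n_out number of output samples (>= 2) including both endpoints.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param method deSolve integrator name.
#' @param boundary_norm see [proton_boundary_factor()].
#' @return A `trajectory`: a data frame with columns `t, n_a, n_b, p, event`
#'   (`event` is `"none"` everywhere for a batch run).
#' @examples
#' arc <- archetype_species()
#' tr <- integrate_batch(system_state(0.5, p = 3), arc$species$Lp,
#'                       env = arc$environment, horizon = 20)
#' tail(tr, 1)
#' @export
integrate_batch <- function(state0, sp_a, sp_b = NULL, env = ph_environment(),
                            horizon = 100, n_out = 200,
                            rtol = 1e-8, atol = 1e-10, method = "lsoda",
                            boundary_norm = env$b^2) {
  stopifnot(horizon > 0, n_out >= 2)
  validate_species_params(sp_a)
  if (!is.null(sp_b)) validate_species_params(sp_b)
  validate_ph_environment(env)
  t0 <- if (inherits(state0, "system_state")) state0[["t"]] else 0
  y0 <- c(n_a = state0[["n_a"]], n_b = state0[["n_b"]], p = state0[["p"]])
  if (y0[["p"]] < 0 || y0[["p"]] > 2 * env$b)
    stop("integrate_batch: initial p outside [0, 2b]", call. = FALSE)
  # above carrying capacity the logistic mortality term changes sign and the
  # model loses meaning (densities diverge); such inocula are rejected
  if (y0[["n_a"]] > sp_a$K ||
      (!is.null(sp_b) && y0[["n_b"]] > sp_b$K))
    stop("integrate_batch: initial density above carrying capacity",
         call. = FALSE)

  # one-sided guards keep the absorbing boundaries absorbing: states pushed
  # a rounding error past n = 0 or p = {0, 2b} must not re-enter the
  # dynamics with the wrong sign (the logistic factor makes n < 0 diverge
  # in finite time when the growth factor is positive)
  rhs <- function(t, y, parms) {
    n_a <- max(y[[1L]], 0); n_b <- max(y[[2L]], 0)
    p <- y[[3L]]
    ga <- exp(-((p - sp_a$p_pref)^2) / sp_a$sigma^2) - sp_a$delta
    dn_a <- n_a * (1 - n_a / sp_a$K) * ga
    drive <- sp_a$c * sp_a$d * n_a
    dn_b <- 0
    if (!is.null(sp_b)) {
      gb <- exp(-((p - sp_b$p_pref)^2) / sp_b$sigma^2) - sp_b$delta
      dn_b <- n_b * (1 - n_b / sp_b$K) * gb
      drive <- drive + sp_b$c * sp_b$d * n_b
    }
    dp <- drive * max(p * (2 * env$b - p), 0) / boundary_norm
    list(c(dn_a, dn_b, dp))
  }

  times <- seq(t0, t0 + horizon, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("integrate_batch: solver did not converge; last state: ",
         paste(signif(sol[nrow(sol), ], 6), collapse = ", "), call. = FALSE)
  out <- as.data.frame(unclass(sol))
  names(out) <- c("t", "n_a", "n_b", "p")
  # absorb numerical underflow: tiny negatives are extinction, p stays on scale
  out$n_a <- ifelse(out$n_a < atol, pmax(out$n_a, 0), out$n_a)
  out$n_b <- ifelse(out$n_b < atol, pmax(out$n_b, 0), out$n_b)
  out$n_a[out$n_a < 0] <- 0
  out$n_b[out$n_b < 0] <- 0
  out$p <- pmin(pmax(out$p, 0), 2 * env$b)
  out$event <- "none"
  as_trajectory(out)
}

as_trajectory <- function(df) {
  stopifnot(all(c("t", "n_a", "n_b", "p", "event") %in% names(df)))
  class(df) <- c("trajectory", "data.frame")
  df
}

#' @export
print.trajectory <- function(x, ...) {
  fin <- x[nrow(x), ]
  cat(sprintf(
    "<trajectory> %d samples, t in [%g, %g]; final n_a=%.4g n_b=%.4g p=%.4g\n",
    nrow(x), x$t[1], fin$t, fin$n_a, fin$n_b, fin$p))
  invisible(x)
}

#' Fixed-step Euler integration (cross-validation oracle)
#'
#' A deliberately simple forward-Euler integrator used to cross-check the
#' adaptive solver: same right-hand side, fixed step `dt`, optional coarse
#' sampling. Not meant for production sweeps.
#'
#' @inheritParams integrate_batch
#' @param dt fixed step size.
#' @param sample_every store every `sample_every`-th step (the final state is
#'   always stored); `Inf` keeps only the endpoints.
#' @return A `trajectory` data frame.
#' @export
integrate_euler <- function(state0, sp_a, sp_b = NULL, env = ph_environment(),
                            horizon = 100, dt = 1e-4, sample_every = Inf,
                            boundary_norm = env$b^2) {
  stopifnot(horizon > 0, dt > 0)
  t0 <- if (inherits(state0, "system_state")) state0[["t"]] else 0
  n_a <- state0[["n_a"]]; n_b <- state0[["n_b"]]; p <- state0[["p"]]
  two_b <- 2 * env$b
  n_steps <- ceiling(horizon / dt)
  keep <- is.finite(sample_every)
  if (keep) {
    idx <- seq(0L, n_steps, by = as.integer(sample_every))
    if (idx[length(idx)] != n_steps) idx <- c(idx, n_steps)
    store <- matrix(NA_real_, nrow = length(idx), ncol = 4L)
    store[1L, ] <- c(t0, n_a, n_b, p)
    k <- 2L
  }
  ca <- sp_a$c * sp_a$d
  cb <- if (is.null(sp_b)) 0 else sp_b$c * sp_b$d
  for (i in seq_len(n_steps)) {
    ga <- exp(-((p - sp_a$p_pref)^2) / sp_a$sigma^2) - sp_a$delta
    dn_a <- n_a * (1 - n_a / sp_a$K) * ga
    dn_b <- 0
    if (!is.null(sp_b)) {
      gb <- exp(-((p - sp_b$p_pref)^2) / sp_b$sigma^2) - sp_b$delta
      dn_b <- n_b * (1 - n_b / sp_b$K) * gb
    }
    dp <- (ca * n_a + cb * n_b) * p * (two_b - p) / boundary_norm
    n_a <- max(n_a + dt * dn_a, 0)
    n_b <- max(n_b + dt * dn_b, 0)
    p <- min(max(p + dt * dp, 0), two_b)
    if (keep && k <= nrow(store) && i == idx[k]) {
      store[k, ] <- c(t0 + i * dt, n_a, n_b, p)
      k <- k + 1L
    }
  }
  if (!keep)
    store <- rbind(c(t0, state0[["n_a"]], state0[["n_b"]], state0[["p"]]),
                   c(t0 + n_steps * dt, n_a, n_b, p))
  out <- as.data.frame(store)
  names(out) <- c("t", "n_a", "n_b", "p")
  out$event <- "none"
  as_trajectory(out)
}

#' Serial-transfer protocol
#'
#' Growth-dilution cadence: integrate for `cycle_length` time units, then
#' dilute both densities by `dilution_factor` and reset the proton
#' concentration partially toward fresh medium, `n_cycles` times. The nominal
#' mapping of the laboratory cadence (daily 1/10x or 1/100x transfers) onto
#' the model is `cycle_length = 5` model-time units per day; the mapping is
#' a convention, not a calibration.
#'
#' @param cycle_length growth time per cycle (> 0).
#' @param dilution_factor fold dilution `D` per transfer (>= 1).
#' @param n_cycles number of growth-dilution cycles (>= 1).
#' @param p0 fresh-medium proton concentration; `NULL` means use the
#'   environment's `p0` at run time.
#' @return An object of class `transfer_protocol`.
#' @export
transfer_protocol <- function(cycle_length = 5, dilution_factor = 10,
                              n_cycles = 10, p0 = NULL) {
  stopifnot(cycle_length > 0, dilution_factor >= 1, n_cycles >= 1)
  structure(list(cycle_length = cycle_length,
                 dilution_factor = dilution_factor,
                 n_cycles = as.integer(n_cycles), p0 = p0),
            class = "transfer_protocol")
}

#' @export
print.transfer_protocol <- function(x, ...) {
  cat(sprintf(
    "<transfer_protocol> %d cycles of %g time units, 1/%gx dilution\n",
    x$n_cycles, x$cycle_length, x$dilution_factor))
  invisible(x)
}

#' Apply one dilution event to a state
#'
#' Both densities are divided by `D`; the proton concentration is mixed with
#' fresh medium as `p/D + ((D-1)/D) p0`. Time is unchanged. The pre-transfer
#' proton concentration enters the mixing formula.
#'
#' @param state a [system_state()] or named vector with `n_a`, `n_b`, `p`, `t`.
#' @param D fold dilution (>= 1); `D = 1` is the identity.
#' @param env a [ph_environment()]; supplies `p0` unless `p0` is given.
#' @param p0 fresh-medium proton concentration override.
#' @return A [system_state()].
#' @examples
#' apply_dilution(system_state(1e6, 0, p = 4), D = 10,
#'                env = ph_environment(p0 = 1))  # p' = 1.3
#' @export
apply_dilution <- function(state, D, env = ph_environment(), p0 = NULL) {
  stopifnot(D >= 1)
  p0 <- p0 %||% env$p0
  system_state(n_a = state[["n_a"]] / D,
               n_b = state[["n_b"]] / D,
               p = state[["p"]] / D + (D - 1) / D * p0,
               t = state[["t"]])
}

#' Run a serial-transfer (growth-dilution) experiment in silico
#'
#' Alternates [integrate_batch()] over one cycle with [apply_dilution()],
#' recording the pre- and post-transfer states as marked events.
#'
#' @inheritParams integrate_batch
#' @param protocol a [transfer_protocol()].
#' @param n_out_per_cycle dense samples per growth cycle.
#' @return A `trajectory` with `event` markers `pre_dilution` /
#'   `post_dilution` at each transfer (duplicated time points).
#' @export
run_serial_transfer <- function(state0, sp_a, sp_b = NULL,
                                env = ph_environment(), protocol,
                                n_out_per_cycle = 200,
                                rtol = 1e-8, atol = 1e-10,
                                boundary_norm = env$b^2) {
  stopifnot(inherits(protocol, "transfer_protocol"))
  p0 <- protocol$p0 %||% env$p0
  pieces <- vector("list", protocol$n_cycles)
  st <- if (inherits(state0, "system_state")) state0 else
    system_state(state0[["n_a"]], state0[["n_b"]], state0[["p"]],
                 t = if ("t" %in% names(state0)) state0[["t"]] else 0)
  for (cyc in seq_len(protocol$n_cycles)) {
    tr <- integrate_batch(st, sp_a, sp_b, env,
                          horizon = protocol$cycle_length,
                          n_out = n_out_per_cycle,
                          rtol = rtol, atol = atol,
                          boundary_norm = boundary_norm)
    pre <- tr[nrow(tr), ]
    pre$event <- "pre_dilution"
    tr[nrow(tr), "event"] <- "pre_dilution"
    st <- apply_dilution(
      system_state(pre$n_a, pre$n_b, pre$p, t = pre$t),
      D = protocol$dilution_factor, env = env, p0 = p0)
    post <- data.frame(t = st[["t"]], n_a = st[["n_a"]], n_b = st[["n_b"]],
                       p = st[["p"]], event = "post_dilution")
    pieces[[cyc]] <- if (cyc < protocol$n_cycles) rbind(tr, post) else
      rbind(tr, post)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  as_trajectory(out)
}

#' Write / read a trajectory as CSV with provenance header
#'
#' Columns `t, n_a, n_b, p, event`; metadata (`key: value`) is written as
#' `#`-prefixed header lines.
#'
#' @param traj a `trajectory` data frame.
#' @param path file path.
#' @param meta named character vector or list of metadata to embed.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns the `trajectory` with metadata in `attr(, "meta")`.
#' @export
write_trajectory <- function(traj, path, meta = NULL) {
  write_csv_meta(as.data.frame(traj), path, meta)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read_csv_meta(path)
  tr <- as_trajectory(df)
  attr(tr, "meta") <- attr(df, "meta")
  tr
}
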