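# Shared fixtures: archetype species and small grids used across tests.
arc <- archetype_species()
env0 <- arc$environment
LP <- arc$species$Lp
CA <- arc$species$Ca
PV <- arc$species$Pv
SM <- arc$species$Sm

small_density_grid <- log_seq(1e-3, 5, 7)
small_p0_grid <- seq(0.5, 9.5, length.out = 7)

# Direct transcription of the model equations, kept independent of the
# package's rhs implementation (oracle for system_rhs).
rhs_oracle <- function(state, sp_a, sp_b, env) {
  n_a <- state[[1]]; n_b <- state[[2]]; p <- state[[3]]
  g <- function(sp) exp(-(p - sp$p_pref)^2 / sp$sigma^2) - sp$delta
  dn_a <- n_a * (1 - n_a / sp_a$K) * g(sp_a)
  dn_b <- if (is.null(sp_b)) 0 else n_b * (1 - n_b / sp_b$K) * g(sp_b)
  drive <- sp_a$c * sp_a$d * n_a +
    if (is.null(sp_b)) 0 else sp_b$c * sp_b$d * n_b
  dp <- drive * p * (2 * env$b - p) / env$b^2
  c(dn_a, dn_b, dp)
}

# Build an outcome_grid by hand (for unit-testing the motif rules without
# running sweeps).
mock_grid <- function(cells, axis1, axis2, mode, total_density = NULL) {
  df <- expand.grid(axis1 = axis1, axis2 = axis2, KEEP.OUT.ATTRS = FALSE)
  df <- cbind(df, cells)
  axes <- list(axis1 = axis1, axis2 = axis2,
               axis1_name = if (mode == "pair") "fraction_a" else
                 "initial_density",
               axis2_name = "initial_p")
  if (!is.null(total_density)) axes$total_density <- total_density
  phfeedback:::new_outcome_grid(df, axes = axes, mode = mode)
}
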