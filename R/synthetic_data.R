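## Synthetic experiment-like datasets with known ground truth: fold-growth
## vs pH tables, endpoint-pH tables, and daily serial-transfer CFU/pH
## records with colony-count (Poisson) plating noise.

#' Measurement-noise model for synthetic datasets
#'
#' @param growth_sd lognormal sd of fold-growth measurements.
#' @param ph_sd Gaussian sd of pH-meter readings (display-pH units).
#' @param plating_fold fold dilution per step of the plating series (> 1).
#' @param plating_steps number of dilution steps (step 0 = undiluted).
#' @param plating_volume plated volume (same volume units as densities are
#'   expressed per; default 0.01 = 10 uL per mL-based density).
#' @param cells_per_unit CFU per model density unit (converts the model's
#'   abstract density to countable cells).
#' @param max_countable largest colony count per spot that can be resolved.
#' @return A `noise_model` list.
#' @export
noise_model <- function(growth_sd = 0.1, ph_sd = 0.05, plating_fold = 10,
                        plating_steps = 8, plating_volume = 0.01,
                        cells_per_unit = 1e6, max_countable = 300) {
  stopifnot(growth_sd >= 0, ph_sd >= 0, plating_fold > 1,
            plating_steps >= 1, plating_volume > 0, cells_per_unit > 0,
            max_countable >= 1)
  structure(list(growth_sd = growth_sd, ph_sd = ph_sd,
                 plating_fold = plating_fold, plating_steps = plating_steps,
                 plating_volume = plating_volume,
                 cells_per_unit = cells_per_unit,
                 max_countable = max_countable),
            class = "noise_model")
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  force(code)
}

#' Synthetic fold-growth vs initial-pH table
#'
#' Emulates a growth assay on buffered medium: the proton concentration is
#' held at its starting value (the buffer's purpose) and the low-density
#' 24-h-equivalent fold growth is `exp(T * g(p))` with `g` the species'
#' niche response and `T` the assay duration in model time. Multiplicative
#' lognormal measurement noise is applied per replicate.
#'
#' @param sp a [species_params()].
#' @param noise a [noise_model()] (only `growth_sd` used here).
#' @param pH_grid assay starting pH values (display scale).
#' @param replicates replicates per pH level.
#' @param assay_time assay duration in model time units (the nominal
#'   24-h-equivalent is one transfer cycle, 5 units).
#' @param env a [ph_environment()].
#' @param seed integer seed (fixed for reproducibility).
#' @return Data frame `species, pH_initial, replicate, fold_growth,
#'   fold_true` (ground truth alongside the noisy value).
#' @export
gen_growth_vs_ph <- function(sp, noise = noise_model(), pH_grid = 2:11,
                             replicates = 3, assay_time = 5,
                             env = ph_environment(), seed = 1) {
  validate_species_params(sp)
  tab <- expand.grid(pH_initial = pH_grid, replicate = seq_len(replicates),
                     KEEP.OUT.ATTRS = FALSE)
  p <- ph_to_p(tab$pH_initial, env)
  fold_true <- exp(assay_time * growth_rate_factor(p, sp))
  noisy <- with_seed(seed,
    fold_true * stats::rlnorm(nrow(tab), meanlog = 0, sdlog = noise$growth_sd))
  data.frame(species = sp$name %||% "species", pH_initial = tab$pH_initial,
             replicate = tab$replicate, fold_growth = noisy,
             fold_true = fold_true)
}

#' Synthetic endpoint-pH table
#'
#' Emulates the unbuffered overnight-modification assay: a standard inoculum
#' grows in batch from the assay's starting pH and the final pH is measured
#' with meter noise.
#'
#' @inheritParams gen_growth_vs_ph
#' @param start_ph assay starting pH (display scale).
#' @param replicates number of wells.
#' @param inoculum initial density (model units).
#' @param horizon batch time (one daily cycle by default).
#' @return Data frame `species, pH_initial, pH_final, replicate,
#'   pH_final_true`.
#' @export
gen_ph_endpoints <- function(sp, noise = noise_model(), start_ph = 7,
                             replicates = 4, inoculum = 0.1 * sp$K,
                             horizon = 5, env = ph_environment(), seed = 1) {
  tr <- integrate_batch(system_state(inoculum, 0, p = ph_to_p(start_ph, env)),
                        sp, NULL, env, horizon = horizon, n_out = 2)
  ph_true <- p_to_ph(tr$p[nrow(tr)], env)
  noisy <- with_seed(seed,
    ph_true + stats::rnorm(replicates, sd = noise$ph_sd))
  data.frame(species = sp$name %||% "species", pH_initial = start_ph,
             pH_final = noisy, replicate = seq_len(replicates),
             pH_final_true = ph_true)
}

#' Poisson colony counts over a dilution series and the CFU estimate
#'
#' Counts at step `k` (0-based) are Poisson with mean
#' `density * cells_per_unit * volume * fold^-k`. The CFU estimate uses the
#' first step whose count lies in the countable range (at least 1, at most
#' `max_countable` colonies), back-multiplied by its dilution; all-zero
#' counts give estimate 0 with a below-detection flag.
#'
#' @param true_density density in model units (>= 0).
#' @param noise a [noise_model()] (plating fields used).
#' @param seed integer seed.
#' @return List with `counts` (integer vector, one per step),
#'   `cfu_estimate` (density in model units), `step_used` (0-based, or NA),
#'   `below_detection` (logical).
#' @examples
#' plating_counts(0.05, seed = 42)
#' @export
plating_counts <- function(true_density, noise = noise_model(), seed = NULL) {
  stopifnot(true_density >= 0)
  k <- seq_len(noise$plating_steps) - 1L
  lambda <- true_density * noise$cells_per_unit * noise$plating_volume *
    noise$plating_fold^(-k)
  counts <- with_seed(seed, stats::rpois(length(k), lambda))
  ok <- which(counts >= 1 & counts <= noise$max_countable)
  if (length(ok)) {
    step <- ok[1L]
    est <- counts[step] * noise$plating_fold^(k[step]) /
      (noise$plating_volume * noise$cells_per_unit)
    list(counts = counts, cfu_estimate = est, step_used = k[step],
         below_detection = FALSE)
  } else {
    list(counts = counts, cfu_estimate = 0, step_used = NA_integer_,
         below_detection = all(counts == 0))
  }
}

#' Synthetic daily serial-transfer dataset with plating and meter noise
#'
#' Runs the serial-transfer simulation for ground truth and emits, at the
#' end of each growth cycle (pre-dilution), colony counts from a dilution
#' series per species plus a noisy pH reading.
#'
#' @param sp_a,sp_b species ( `sp_b = NULL` for monoculture).
#' @param env a [ph_environment()].
#' @param protocol a [transfer_protocol()].
#' @param state0 initial [system_state()].
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param well well identifier written to the records.
#' @return Data frame with one row per day and species: `day, species,
#'   well, density_true, cfu_estimate, below_detection, step_used,
#'   ph_measured, ph_true`, plus one integer column per dilution step
#'   (`count_0`, `count_1`, ...).
#' @export
gen_serial_transfer_dataset <- function(sp_a, sp_b = NULL,
                                        env = ph_environment(),
                                        protocol = transfer_protocol(),
                                        state0 = system_state(
                                          0.01 * sp_a$K,
                                          if (is.null(sp_b)) 0 else
                                            0.01 * sp_b$K,
                                          p = env$p0),
                                        noise = noise_model(), seed = 1,
                                        well = "A1") {
  traj <- run_serial_transfer(state0, sp_a, sp_b, env, protocol,
                              n_out_per_cycle = 50)
  pre <- traj[traj$event == "pre_dilution", ]
  species <- c(sp_a$name %||% "A", if (!is.null(sp_b)) sp_b$name %||% "B")
  rows <- list()
  with_seed(seed, {
    for (d in seq_len(nrow(pre))) {
      ph_true <- p_to_ph(pre$p[d], env)
      ph_meas <- ph_true + stats::rnorm(1, sd = noise$ph_sd)
      for (s in seq_along(species)) {
        dens <- if (s == 1) pre$n_a[d] else pre$n_b[d]
        pl <- plating_counts(dens, noise, seed = NULL)
        row <- data.frame(day = d, species = species[s], well = well,
                          density_true = dens,
                          cfu_estimate = pl$cfu_estimate,
                          below_detection = pl$below_detection,
                          step_used = pl$step_used,
                          ph_measured = ph_meas, ph_true = ph_true)
        cm <- as.data.frame(as.list(pl$counts))
        names(cm) <- paste0("count_", seq_along(pl$counts) - 1L)
        rows[[length(rows) + 1L]] <- cbind(row, cm)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a complete synthetic demo dataset
#'
#' Emits the growth-assay table, the endpoint-pH table and one
#' serial-transfer record per species, plus a ground-truth JSON sidecar,
#' in the CSV schemas consumed by the characterization stage.
#'
#' @param out_dir output directory.
#' @param species named list of [species_params()].
#' @param env a [ph_environment()].
#' @param protocol a [transfer_protocol()].
#' @param noise_cfg list of [noise_model()] arguments (as stored in a run
#'   config) or a `noise_model`.
#' @param seed integer seed.
#' @param meta provenance metadata for CSV headers.
#' @return Character vector of files written.
#' @export
write_synth_dataset <- function(out_dir, species, env = ph_environment(),
                                protocol = transfer_protocol(),
                                noise_cfg = noise_model(), seed = 1,
                                meta = NULL) {
  noise <- if (inherits(noise_cfg, "noise_model")) noise_cfg else
    noise_model(growth_sd = noise_cfg$growth_sd %||% 0.1,
                ph_sd = noise_cfg$ph_sd %||% 0.05,
                plating_fold = noise_cfg$plating_fold %||% 10,
                plating_steps = noise_cfg$plating_steps %||% 8,
                plating_volume = noise_cfg$plating_volume %||% 0.01,
                cells_per_unit = noise_cfg$cells_per_unit %||% 1e6,
                max_countable = noise_cfg$max_countable %||% 300)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  growth <- do.call(rbind, lapply(seq_along(species), function(i)
    gen_growth_vs_ph(species[[i]], noise, env = env, seed = seed + i)))
  endpoints <- do.call(rbind, lapply(seq_along(species), function(i)
    gen_ph_endpoints(species[[i]], noise, env = env, seed = seed + 100 + i)))
  files <- c(
    write_csv_meta(growth, file.path(out_dir, "synth_growth_vs_ph.csv"),
                   meta),
    write_csv_meta(endpoints, file.path(out_dir, "synth_ph_endpoints.csv"),
                   meta))
  for (i in seq_along(species)) {
    rec <- gen_serial_transfer_dataset(species[[i]], NULL, env, protocol,
                                       noise = noise, seed = seed + 200 + i)
    files <- c(files, write_csv_meta(
      rec, file.path(out_dir, paste0("synth_serial_",
                                     names(species)[i], ".csv")), meta))
  }
  truth <- list(environment = list(b = env$b, p0 = env$p0),
                species = lapply(species, function(s)
                  list(p_pref = s$p_pref, sigma = s$sigma, delta = s$delta,
                       c = s$c, d = s$d, K = s$K)),
                seed = seed)
  truth_path <- file.path(out_dir, "synth_ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  c(files, truth_path)
}
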