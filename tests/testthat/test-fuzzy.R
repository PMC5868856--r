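cfg <- fuzzy_config()

test_that("fuzzification hits peaks, crossovers and the partition of unity", {
  part <- cfg$partitions$ph
  peak_med <- unlist(part$labels$medium)[2]
  mu <- fuzzify(peak_med, "ph", cfg)
  expect_equal(unname(mu[1, "medium"]), 1)
  # crossover of two adjacent trapezoids: 0.5 / 0.5
  lo <- unlist(part$labels$low)
  cross <- (lo[3] + lo[4]) / 2
  mu <- fuzzify(cross, "ph", cfg)
  expect_equal(unname(mu[1, "low"]), 0.5)
  expect_equal(unname(mu[1, "medium"]), 0.5)
  # partition of unity across the pH universe
  xs <- seq(0, 14, by = 0.1)
  mus <- fuzzify(xs, "ph", cfg)
  expect_equal(unname(rowSums(mus)), rep(1, length(xs)), tolerance = 1e-12)
  expect_true(all(mus >= 0 & mus <= 1))
  expect_error(fuzzify(15, "ph", cfg), "outside universe")
})

test_that("growth inference follows the preferred-pH rules", {
  # matched label: positive; distant label: negative; swap symmetry
  up <- infer_density_change(ph = 3, preferred_ph = 3, cell_density = 0.2,
                             config = cfg)
  down <- infer_density_change(ph = 12, preferred_ph = 3,
                               cell_density = 0.2, config = cfg)
  expect_gt(up, 0)
  expect_lt(down, 0)
  swapped <- infer_density_change(ph = 3, preferred_ph = 12,
                                  cell_density = 0.2, config = cfg)
  expect_equal(swapped, down, tolerance = 1e-9)
  # saturation: at high density the matched response collapses toward zero
  sat <- infer_density_change(ph = 3, preferred_ph = 3, cell_density = 0.95,
                              config = cfg)
  expect_lt(abs(sat), abs(up) / 2)
})

test_that("pH-change inference is density-driven, signed and strength-scaled", {
  # no bacteria, no modification (exactly zero by construction)
  expect_equal(infer_ph_change(cbind(0, 0), 7, c(1, -1), 1, cfg), 0)
  # opposite abilities at equal density cancel
  expect_equal(infer_ph_change(cbind(0.4, 0.4), 7, c(1, -1), 1, cfg), 0,
               tolerance = 1e-12)
  # doubling the relative strength doubles species B's contribution
  only_b <- function(rel) infer_ph_change(cbind(0, 0.4), 7, c(1, 1), rel,
                                          config = cfg)
  expect_equal(only_b(2), 2 * only_b(1), tolerance = 1e-12)
  # denser cultures change the pH faster
  mags <- vapply(c(0.1, 0.45, 0.9),
                 function(d) infer_ph_change(cbind(d), 7, 1, 1, cfg),
                 numeric(1))
  expect_true(all(diff(mags) > 0))
  # the drive dies out at the mapped proton-scale boundaries
  expect_equal(infer_ph_change(cbind(0.9), 2, -1, 1, cfg), 0,
               tolerance = 1e-12)
  expect_equal(infer_ph_change(cbind(0.9), 11, 1, 1, cfg), 0,
               tolerance = 1e-12)
})

test_that("fuzzy iteration is deterministic, clamped and absorbing at zero", {
  st0 <- list(n_a = 0.05, n_b = 0.05, ph = 7)
  t1 <- fuzzy_iterate(st0, LP, CA, env0, n_iterations = 120, config = cfg)
  t2 <- fuzzy_iterate(st0, LP, CA, env0, n_iterations = 120, config = cfg)
  expect_identical(t1, t2)
  expect_true(all(t1$n_a >= 0 & t1$n_a <= 1))
  expect_true(all(t1$ph >= 0 & t1$ph <= 14))
  # no bacteria: pH constant over all iterations
  t0 <- fuzzy_iterate(list(n_a = 0, n_b = 0, ph = 8.3), LP, CA, env0,
                      n_iterations = 50, config = cfg)
  expect_equal(t0$ph, rep(8.3, 51))
  expect_equal(t0$n_a, rep(0, 51))
})

test_that("fuzzy single-species runs mirror the archetype fates", {
  # self-serving acidifier from its own niche: persists
  tr <- fuzzy_iterate(list(n_a = 0.05, n_b = 0, ph = 4), LP, env = env0,
                      config = cfg)
  expect_gt(tr$n_a[201], 0.5)
  # self-harming alkalizer: rises then collapses while alkalizing
  tr2 <- fuzzy_iterate(list(n_a = 0.05, n_b = 0, ph = 4), PV, env = env0,
                       config = cfg)
  expect_gt(max(tr2$n_a), 0.2)
  expect_lt(tr2$n_a[201], 1e-3)
  expect_gt(tr2$ph[201], 8)
})

test_that("fuzzy pair sweep keeps the single-species boundary contract", {
  p0g <- seq(1.4, 8.6, length.out = 5)
  dens <- 1    # total inoculum, model units
  gp <- fuzzy_sweep_pair(LP, CA, env0, fraction_grid = c(0, 0.5, 1),
                         p0_grid = p0g, total_density = dens, config = cfg)
  g1 <- fuzzy_sweep_single(LP, env0, density_grid = dens,
                           p0_grid = p0g, config = cfg)
  col_a <- gp[gp$axis1 == 1, ]
  expect_equal(col_a$a_survives, g1$a_survives)
  expect_equal(col_a$n_a_final, g1$n_a_final, tolerance = 1e-9)
  g0 <- fuzzy_sweep_single(CA, env0, density_grid = dens,
                           p0_grid = p0g, config = cfg)
  col_b <- gp[gp$axis1 == 0, ]
  expect_equal(col_b$b_survives, g0$a_survives)
  expect_equal(col_b$n_b_final, g0$n_a_final, tolerance = 1e-9)
})

test_that("misconfigured fuzzy inputs are rejected with key context", {
  bad <- tempfile(fileext = ".yaml")
  on.exit(unlink(bad))
  cfg_raw <- yaml::read_yaml(system.file("extdata", "fuzzy.yaml",
                                         package = "phfeedback"))
  cfg_raw$rules$density_change[[1]]$out <- "enormous"
  yaml::write_yaml(cfg_raw, bad)
  expect_error(fuzzy_config(bad), "enormous")
})
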