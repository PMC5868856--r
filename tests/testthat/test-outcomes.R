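test_that("survival classification uses the final state against the threshold", {
  tr <- as_traj <- function(n_a, n_b) {
    phfeedback:::as_trajectory(data.frame(
      t = 0:1, n_a = c(1, n_a), n_b = c(1, n_b), p = 5, event = "none"))
  }
  expect_equal(unname(classify_survival(as_traj(0, 0))), c(FALSE, FALSE))
  expect_equal(unname(classify_survival(as_traj(10, 0))), c(TRUE, FALSE))
  expect_equal(unname(classify_survival(as_traj(0.5, 0.02),
                                        extinction_threshold = 0.01)),
               c(TRUE, TRUE))
  empty <- phfeedback:::as_trajectory(
    data.frame(t = numeric(), n_a = numeric(), n_b = numeric(),
               p = numeric(), event = character()))
  expect_error(classify_survival(empty), "empty")
})

test_that("classification is insensitive to the threshold over two decades", {
  # archetype outcomes are far from the cutoff: same flags for
  # thresholds 1e-2 K .. 1e-4 K
  trs <- list(
    integrate_batch(system_state(2, 0, p = 8), LP, NULL, env0,
                    horizon = 150, n_out = 2),
    integrate_batch(system_state(2, 0, p = 5), PV, NULL, env0,
                    horizon = 150, n_out = 2),
    integrate_batch(system_state(1, 1, p = 3), LP, CA, env0,
                    horizon = 150, n_out = 2))
  for (tr in trs) {
    flags <- lapply(c(1e-2, 1e-3, 1e-4) * 10,
                    function(th) classify_survival(tr, th))
    expect_equal(flags[[1]], flags[[2]])
    expect_equal(flags[[2]], flags[[3]])
  }
})

test_that("single-species diagrams reproduce the archetype motifs", {
  g_lp <- sweep_single(LP, env0, density_grid = small_density_grid,
                       p0_grid = small_p0_grid, horizon = 150)
  expect_equal(label_single_motif(g_lp), "allee")
  # within each initial-p column survival is a step in density
  for (p0 in small_p0_grid) {
    col <- g_lp[abs(g_lp$axis2 - p0) < 1e-9, ]
    col <- col[order(col$axis1), ]
    expect_true(all(diff(col$a_survives) >= 0))
  }
  g_pv <- sweep_single(PV, env0, density_grid = small_density_grid,
                       p0_grid = small_p0_grid, horizon = 150)
  expect_equal(label_single_motif(g_pv), "ecological_suicide")
  expect_false(any(g_pv$a_survives))
})

test_that("allee threshold from bisection matches a brute-force scan", {
  p0 <- 2.3   # adverse (alkaline) start for the acid-loving acidifier
  thr <- allee_threshold(LP, env0, p0 = p0, horizon = 150)
  expect_false(is.na(thr))
  scan <- log_seq(1e-3, 5, 400)
  surv <- vapply(scan, function(n0) {
    tr <- integrate_batch(system_state(n0, 0, p = p0), LP, NULL, env0,
                          horizon = 150, n_out = 2)
    tr$n_a[2] >= 1e-3 * LP$K
  }, logical(1))
  flip <- which(diff(surv) == 1)
  expect_length(flip, 1)            # clean survival step
  expect_gte(thr, scan[flip])
  expect_lte(thr, scan[flip + 2])   # within one grid step of the scan
  # favourable start: no threshold, survives at every tested density
  thr2 <- allee_threshold(LP, env0, p0 = 8, horizon = 150)
  expect_true(is.na(thr2))
  expect_equal(attr(thr2, "reason"), "survives_everywhere")
})

test_that("weaker pH drive raises the minimal viable density", {
  cs <- c(0.1, 0.05, 0.025)
  thrs <- vapply(cs, function(cc) {
    sp <- species_params(p_pref = 8, c = cc, name = "buffered")
    allee_threshold(sp, env0, p0 = 3.5, horizon = 150)
  }, numeric(1))
  expect_true(all(diff(thrs) > 0))
})

test_that("motif rules label constructed diagrams as documented", {
  ax1 <- seq(0, 1, length.out = 5)     # fractions
  ax2 <- seq(2, 8, length.out = 5)     # initial p
  dens <- log_seq(0.01, 5, 5)
  blank <- function(a, b) data.frame(
    a_survives = a, b_survives = b, n_a_final = 10 * a, n_b_final = 10 * b,
    p_final = 5, oscillatory = FALSE)

  # single grids: A survives everywhere, B nowhere
  gA <- mock_grid(blank(TRUE, FALSE), dens, ax2, "single")
  gB <- mock_grid(blank(FALSE, FALSE), dens, ax2, "single")

  # pair where both die everywhere: extended suicide (B drags A down)
  gp_none <- mock_grid(blank(FALSE, FALSE), ax1, ax2, "pair",
                       total_density = 1)
  expect_equal(as.character(label_motif(gA, gB, gp_none)),
               "extended_suicide")

  # pair where both survive although both die alone: stabilization
  gp_both <- mock_grid(blank(TRUE, TRUE), ax1, ax2, "pair",
                       total_density = 1)
  expect_equal(as.character(label_motif(gB, gB, gp_both)), "stabilization")

  # only A survives in pair, both extinct alone: successive growth
  gp_onlyA <- mock_grid(blank(TRUE, FALSE), ax1, ax2, "pair",
                        total_density = 1)
  expect_equal(as.character(label_motif(gB, gB, gp_onlyA)),
               "successive_growth")

  # disjoint single-winner regions: bistability
  two_winner <- blank(rep(c(TRUE, FALSE), length.out = 25),
                      rep(c(FALSE, TRUE), length.out = 25))
  gp_bi <- mock_grid(two_winner, ax1, ax2, "pair", total_density = 1)
  expect_equal(as.character(label_motif(gA, gA, gp_bi)), "bistability")

  # both survive everywhere and both grow alone: plain coexistence
  expect_equal(as.character(label_motif(gA, gA, gp_both)), "coexistence")

  # mismatched axes are refused
  gB_off <- mock_grid(blank(FALSE, FALSE), dens, ax2 + 0.5, "single")
  expect_error(label_motif(gA, gB_off, gp_none), "axis")
})

test_that("oscillation detector needs repeated late maxima above threshold", {
  t <- seq(0, 100, length.out = 400)
  osc <- phfeedback:::as_trajectory(data.frame(
    t = t, n_a = 5 + 4 * sin(t / 3), n_b = 0, p = 5, event = "none"))
  expect_true(detect_oscillation(osc, extinction_threshold = 0.01))
  mono <- phfeedback:::as_trajectory(data.frame(
    t = t, n_a = 10 / (1 + exp(-(t - 50) / 5)), n_b = 0, p = 5,
    event = "none"))
  expect_false(detect_oscillation(mono, extinction_threshold = 0.01))
  # decaying wiggles below the threshold do not count
  tiny <- phfeedback:::as_trajectory(data.frame(
    t = t, n_a = 1e-4 * (1.5 + sin(t / 3)), n_b = 0, p = 5, event = "none"))
  expect_false(detect_oscillation(tiny, extinction_threshold = 0.01))
})

test_that("outcome grids round-trip through CSV", {
  g <- sweep_single(LP, env0, density_grid = log_seq(0.01, 5, 3),
                    p0_grid = c(3, 7), horizon = 20)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_outcome_grid(g, path, meta = list(seed = 1))
  back <- read_outcome_grid(path)
  expect_equal(as.data.frame(back), as.data.frame(g), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "mode"), "single")
  expect_equal(attr(back, "axes")$axis2, attr(g, "axes")$axis2)
})
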