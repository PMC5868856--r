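test_that("sterile medium stays on the fixed line", {
  tr <- integrate_batch(system_state(0, 0, p = 3.7), LP, CA, env0,
                        horizon = 10, n_out = 20)
  expect_equal(tr$n_a, rep(0, 20))
  expect_equal(tr$n_b, rep(0, 20))
  expect_equal(tr$p, rep(3.7, 20), tolerance = 1e-10)
})

test_that("self-harming species rises then collapses while acidifying past its optimum", {
  # Sm-like: optimum at p 3.5, started at p 1, raises the proton level
  tr <- integrate_batch(system_state(0.1, 0, p = 1), SM, NULL, env0,
                        horizon = 100, n_out = 400)
  peak <- which.max(tr$n_a)
  expect_gt(tr$n_a[peak], 5)                      # grows well first
  expect_gt(peak, 1)
  expect_lt(peak, nrow(tr))
  expect_lt(tr$n_a[nrow(tr)], 1e-3 * SM$K)        # then kills itself
  expect_true(all(diff(tr$p) >= -1e-9))           # p rises monotonically
  expect_gt(tr$p[nrow(tr)], SM$p_pref)            # past the optimum
})

test_that("adaptive endpoints agree with the fixed-step Euler oracle", {
  set.seed(21)
  for (i in 1:3) {
    st <- system_state(runif(1, 0.05, 5), runif(1, 0.05, 5),
                       p = runif(1, 1, 9))
    a <- integrate_batch(st, LP, CA, env0, horizon = 20, n_out = 2)
    e <- integrate_euler(st, LP, CA, env0, horizon = 20, dt = 1e-4)
    fa <- unlist(a[nrow(a), c("n_a", "n_b", "p")])
    fe <- unlist(e[nrow(e), c("n_a", "n_b", "p")])
    expect_lt(max(abs(fa - fe) / pmax(abs(fa), abs(fe), 1e-6)), 1e-3)
  }
})

test_that("trajectories respect the invariant bounds", {
  set.seed(22)
  for (i in 1:20) {
    n0a <- runif(1, 0, LP$K); n0b <- runif(1, 0, PV$K)
    tr <- integrate_batch(system_state(n0a, n0b, p = runif(1, 0, 10)),
                          LP, PV, env0, horizon = 60, n_out = 100)
    expect_true(all(tr$p >= -1e-7 & tr$p <= 10 + 1e-7))
    expect_true(all(tr$n_a >= 0 & tr$n_a <= max(n0a, LP$K) + 1e-6))
    expect_true(all(tr$n_b >= 0 & tr$n_b <= max(n0b, PV$K) + 1e-6))
  }
  # inocula above carrying capacity are outside the model's domain
  expect_error(integrate_batch(system_state(11, 0, p = 5), LP, NULL, env0,
                               horizon = 1),
               "carrying capacity")
})

test_that("dilution implements the fresh-medium mixing formula", {
  env <- ph_environment(b = 5, p0 = 1)
  st <- apply_dilution(system_state(1e6, 10, p = 4), D = 10, env = env)
  expect_equal(st[["p"]], 1.3)
  expect_equal(st[["n_a"]], 1e5)
  expect_equal(st[["n_b"]], 1)
  # D = 1 is the identity
  st1 <- apply_dilution(system_state(3, 4, p = 6.2, t = 7), D = 1, env = env)
  expect_equal(unname(st1), c(3, 4, 6.2, 7))
  expect_equal(apply_dilution(system_state(1e6, 0, p = 5), 100,
                              env)[["n_a"]], 1e4)
})

test_that("serial transfer alternates growth and exact dilution", {
  prot <- transfer_protocol(cycle_length = 5, dilution_factor = 10,
                            n_cycles = 4)
  tr <- run_serial_transfer(system_state(0.5, 0.5, p = 5), LP, CA, env0,
                            prot, n_out_per_cycle = 30)
  pre <- tr[tr$event == "pre_dilution", ]
  post <- tr[tr$event == "post_dilution", ]
  expect_equal(nrow(pre), 4)
  expect_equal(nrow(post), 4)
  expect_equal(post$n_a, pre$n_a / 10)
  expect_equal(post$n_b, pre$n_b / 10)
  expect_equal(post$p, pre$p / 10 + 9 / 10 * env0$p0)
  expect_equal(post$t, pre$t)       # dilution is instantaneous
  # zero densities stay zero through all cycles
  tr0 <- run_serial_transfer(system_state(0, 0, p = env0$p0), LP, CA, env0,
                             prot, n_out_per_cycle = 10)
  expect_true(all(tr0$n_a == 0 & tr0$n_b == 0))
  expect_equal(unique(round(tr0$p, 9)), env0$p0)
})

test_that("one cycle without dilution equals a plain batch", {
  prot <- transfer_protocol(cycle_length = 8, dilution_factor = 1,
                            n_cycles = 1)
  st <- system_state(0.7, 0.2, p = 6)
  tr <- run_serial_transfer(st, LP, CA, env0, prot, n_out_per_cycle = 50)
  tb <- integrate_batch(st, LP, CA, env0, horizon = 8, n_out = 50)
  keep <- tr$event != "post_dilution"
  expect_equal(tr$n_a[keep], tb$n_a, tolerance = 1e-9)
  expect_equal(tr$p[keep], tb$p, tolerance = 1e-9)
})

test_that("survival under dilution is non-monotone for a self-harming species", {
  # ecological suicide in batch; an intermediate dilution rescues, a huge
  # one outdilutes
  outcomes <- vapply(c(1, 3, 1e5), function(D) {
    prot <- transfer_protocol(cycle_length = 5, dilution_factor = D,
                              n_cycles = 12)
    tr <- run_serial_transfer(system_state(0.1, 0, p = 9), PV, NULL,
                              ph_environment(b = 5, p0 = 9), prot,
                              n_out_per_cycle = 20)
    fin <- tr[nrow(tr), ]
    fin$n_a >= 1e-3 * PV$K
  }, logical(1))
  expect_equal(outcomes, c(FALSE, TRUE, FALSE))
})

test_that("trajectory CSV round-trips with metadata", {
  tr <- integrate_batch(system_state(1, 1, p = 5), LP, CA, env0,
                        horizon = 5, n_out = 10)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trajectory(tr, path, meta = list(seed = 42, note = "demo"))
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "meta")$seed, "42")
})
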