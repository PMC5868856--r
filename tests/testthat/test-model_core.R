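test_that("growth rate factor matches its closed form", {
  sp <- species_params(p_pref = 6, sigma = 4, delta = 0.5)
  expect_equal(growth_rate_factor(6, sp), 0.5)
  expect_equal(growth_rate_factor(6 + 4, sp), exp(-1) - 0.5)
  expect_equal(growth_rate_factor(1e6, sp), -0.5, tolerance = 1e-12)
  # symmetric about the optimum, strictly decreasing away from it
  d <- seq(0.1, 12, by = 0.37)
  expect_equal(growth_rate_factor(6 + d, sp), growth_rate_factor(6 - d, sp))
  vals <- growth_rate_factor(6 + d, sp)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > -0.5 & vals <= 0.5))
})

test_that("density derivative has logistic structure and rejects negative density", {
  sp <- species_params(p_pref = 8, delta = 0.5, K = 10)
  expect_equal(density_derivative(0, 3, sp), 0)
  expect_equal(density_derivative(sp$K, 3, sp), 0)
  expect_equal(density_derivative(sp$K / 2, sp$p_pref, sp), 0.125 * sp$K)
  expect_error(density_derivative(-1, 3, sp), "must be >= 0")
})

test_that("proton derivative vanishes at the scale ends and is linear in density", {
  env <- ph_environment(b = 5)
  a <- species_params(p_pref = 8, c = 0.1)
  b <- species_params(p_pref = 2, c = -0.1)
  expect_equal(proton_derivative(3, 4, a, b, 0, env), 0)
  expect_equal(proton_derivative(3, 4, a, b, 2 * env$b, env), 0)
  # q(b) = 1 under the declared normalization: drive reads directly
  n <- 7.3
  expect_equal(proton_derivative(n, 0, a, NULL, env$b, env), 0.1 * n)
  # opposite equal drives cancel
  expect_equal(proton_derivative(n, n, a, b, 3.7, env), 0)
  # linearity in each density at fixed p
  p <- 6.1
  f <- function(na, nb) proton_derivative(na, nb, a, b, p, env)
  expect_equal(f(2, 5) + f(3, 0), f(5, 5))
  expect_equal(2 * f(1, 1), f(2, 2))
  expect_error(proton_derivative(1, 1, a, b, 11, env), "outside")
})

test_that("system rhs agrees with a direct transcription of the equations", {
  set.seed(11)
  for (i in 1:25) {
    st <- c(n_a = runif(1, 0, 12), n_b = runif(1, 0, 12),
            p = runif(1, 0, 10))
    got <- system_rhs(st, LP, CA, env0)
    expect_equal(unname(got), rhs_oracle(st, LP, CA, env0),
                 tolerance = 1e-12)
    got1 <- system_rhs(st, SM, NULL, env0)
    expect_equal(unname(got1), rhs_oracle(st, SM, NULL, env0),
                 tolerance = 1e-12)
  }
  # fixed structure: sterile medium and saturated boundary state
  expect_equal(unname(system_rhs(c(n_a = 0, n_b = 0, p = 4), LP, CA, env0)),
               c(0, 0, 0))
  expect_equal(unname(system_rhs(c(n_a = LP$K, n_b = 0, p = 10), LP, CA,
                                 env0)),
               c(0, 0, 0))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(species_params(8, sigma = 0), "sigma")
  expect_error(species_params(8, delta = 1), "delta")
  expect_error(species_params(8, K = -1), "K")
  expect_error(species_params(8, d = 0), "d")
  expect_error(ph_environment(b = -5), "b")
  expect_error(ph_environment(b = 5, p0 = 11), "p0")
  expect_error(system_state(-1, 0, 5), "densities")
})

test_that("display map is the declared reversed linear axis", {
  expect_equal(p_to_ph(c(0, 5, 10)), c(11, 6.5, 2))
  expect_equal(ph_to_p(p_to_ph(seq(0, 10, by = 0.5))),
               seq(0, 10, by = 0.5))
  expect_equal(ph_to_p(13), 0)  # clamped to the proton scale
})

test_that("shipped archetypes load with the documented drive structure", {
  expect_setequal(names(arc$species), c("Lp", "Ca", "Pv", "Sm"))
  expect_true(LP$c > 0 && LP$p_pref > env0$b)   # self-serving acidifier
  expect_true(CA$c < 0 && CA$p_pref < env0$b)   # self-serving alkalizer
  expect_true(PV$c < 0 && PV$p_pref > env0$b)   # self-harming alkalizer
  expect_true(SM$c > 0 && SM$p_pref < env0$b)   # self-harming acidifier
  prs <- archetype_pairs()
  expect_setequal(names(prs), c("bistability", "successive_growth",
                                "extended_suicide", "stabilization"))
  expect_gt(prs$extended_suicide$a$d, 1)  # suicidal partner out-drives
})
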