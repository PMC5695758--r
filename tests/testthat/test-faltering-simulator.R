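test_that("initial population is standard normal and reproducible", {
  x <- initialize_population(10000, seed = 12)
  expect_identical(x, initialize_population(10000, seed = 12))
  expect_lt(abs(mean(x)), 4 / sqrt(10000))
  expect_lt(abs(sd(x) - 1), 4 / sqrt(10000))
  expect_identical(length(initialize_population(1, seed = 1)), 1L)
  expect_error(initialize_population(0), "positive")
})

test_that("exposure assignment follows the selection rule", {
  haz0 <- c(-1, 0, 1, 2)
  expect_identical(assign_exposure(haz0, 1, "random", seed = 1),
                   rep(TRUE, 4))
  expect_identical(assign_exposure(haz0, 1, "low_haz_first"), rep(TRUE, 4))
  expect_identical(assign_exposure(haz0, 0.5, "low_haz_first"),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(assign_exposure(haz0, 0.5, "high_haz_first"),
                   c(FALSE, FALSE, TRUE, TRUE))
  big <- initialize_population(10000, seed = 2)
  expect_identical(sum(assign_exposure(big, 0.25, "random", seed = 3)), 2500L)
  expect_error(assign_exposure(haz0, 0), "p_exposed")
  expect_error(assign_exposure(haz0, 1.2), "p_exposed")
})

test_that("a decrement is a pure shift when noise is zero and all are exposed", {
  sc <- sim_scenario(n_children = 1000, p_exposed = 1, noise_fraction = 0,
                     n_replications = 1, seed = 5)
  haz <- initialize_population(1000, seed = 5)
  st <- apply_decrement(haz, exposed = rep(TRUE, 1000), scenario = sc)
  expect_equal(st$haz, haz - 0.1, tolerance = 1e-15)
  expect_identical(sd(st$haz), sd(haz))
})

test_that("exposed-group declines average decrement/p with the configured noise", {
  sc <- sim_scenario(n_children = 200000, p_exposed = 0.25,
                     n_replications = 1, seed = 6)
  haz <- initialize_population(200000, seed = 6)
  exposed <- assign_exposure(haz, 0.25, "random", seed = 7)
  st <- apply_decrement(haz, exposed = exposed, scenario = sc)
  declines <- haz[exposed] - st$haz[exposed]
  n_e <- sum(exposed)
  expect_lt(abs(mean(declines) - 0.4), 3 * 0.04 / sqrt(n_e))
  expect_equal(sd(declines), 0.04, tolerance = 0.01)
  expect_identical(st$haz[!exposed], haz[!exposed])
})

test_that("the floor censors children who cross it", {
  sc <- sim_scenario(n_children = 500, p_exposed = 1, decrement = 0.4,
                     noise_fraction = 0.1, floor = -6, n_replications = 1,
                     seed = 8)
  state <- list(haz = rep(-5.95, 500), haz0 = rep(-5.95, 500),
                exposed = rep(TRUE, 500), alive = rep(TRUE, 500))
  st <- apply_decrement(state, scenario = sc)
  expect_gt(mean(!st$alive), 0.95)
  # clamp mode holds children at the floor instead
  sc_clamp <- sim_scenario(n_children = 500, p_exposed = 1, decrement = 0.4,
                           floor = -6, floor_mode = "clamp",
                           n_replications = 1, seed = 8)
  st2 <- apply_decrement(state, scenario = sc_clamp)
  expect_true(all(st2$alive))
  expect_true(all(st2$haz >= -6))
})

test_that("trajectories are reproducible and degenerate cases behave", {
  sc <- sim_scenario(n_children = 500, p_exposed = 0.5, n_decrements = 0,
                     n_replications = 3, seed = 10)
  tr <- run_scenario(sc)
  expect_identical(nrow(tr$summary), 1L)
  expect_lt(abs(tr$summary$mean), 0.2)
  sc2 <- sim_scenario(n_children = 400, p_exposed = 0.5, n_decrements = 5,
                      n_replications = 4, seed = 11)
  expect_identical(run_scenario(sc2)$summary, run_scenario(sc2)$summary)
})

test_that("pure whole-population shift preserves the distribution shape exactly", {
  sc <- sim_scenario(n_children = 2000, p_exposed = 1, noise_fraction = 0,
                     n_decrements = 20, n_replications = 5, seed = 13)
  tr <- run_scenario(sc)
  s <- tr$summary
  expect_equal(s$sd, rep(s$sd[1], 21), tolerance = 1e-12)
  expect_equal(s$p5, s$p5[1] - 0.1 * s$step, tolerance = 1e-9)
  expect_equal(s$p95, s$p95[1] - 0.1 * s$step, tolerance = 1e-9)
  expect_equal(s$mean, s$mean[1] - 0.1 * s$step, tolerance = 1e-12)
})

test_that("the mixture-moments oracle matches its closed form and guards its domain", {
  # frozen closed-form values at step 20 for p = 1, 0.5, 0.25
  sd20 <- function(p) {
    d <- 0.1 / p
    sqrt((1 - p) + p * (1 + 20 * (0.1 * d)^2 + (20 * d)^2) - 4)
  }
  expect_equal(sd20(1), 1.0010, tolerance = 1e-4)
  expect_equal(sd20(0.5), 2.2370, tolerance = 1e-4)
  expect_equal(sd20(0.25), 3.6067, tolerance = 1e-4)
  for (p in c(0.25, 0.5, 0.75, 1)) {
    or <- mixture_moments_oracle(sim_scenario(p_exposed = p))
    expect_identical(nrow(or), 21L)
    expect_equal(or$mean, -0.1 * (0:20))
    expect_equal(or$sd[21], sd20(p))
    expect_equal(or$sd[1], 1)
  }
  expect_error(mixture_moments_oracle(
    sim_scenario(selection_rule = "low_haz_first")), "only valid")
  expect_error(mixture_moments_oracle(sim_scenario(floor = -6)), "only valid")
  expect_error(mixture_moments_oracle(sim_scenario(deficit_gradient = 0.3)),
               "only valid")
})

test_that("simulated moments agree with the oracle at spot-check steps", {
  sc <- sim_scenario(n_children = 4000, p_exposed = 0.5, n_replications = 150,
                     seed = 17)
  tr <- run_scenario(sc)
  or <- mixture_moments_oracle(sc)
  for (k in c(5, 10, 20)) {
    i <- k + 1
    expect_lt(abs(tr$summary$mean[i] - or$mean[i]), 3 * tr$summary$mc_se_mean[i])
    expect_lt(abs(tr$summary$sd[i] - or$sd[i]), 3 * tr$summary$mc_se_sd[i])
  }
})

test_that("final-step SD decreases as the exposed fraction grows", {
  finals <- vapply(c(0.25, 0.5, 0.75, 1), function(p) {
    sc <- sim_scenario(n_children = 2000, p_exposed = p, n_replications = 40,
                       seed = 19)
    tail(run_scenario(sc)$summary$sd, 1)
  }, numeric(1))
  expect_true(all(diff(finals) < 0))
})

test_that("SD trend classification distinguishes the canonical shapes", {
  expect_identical(classify_sd_trend(c(1, 1.5, 2.5)), "widening")
  expect_identical(classify_sd_trend(c(1, 0.8, 0.5)), "narrowing")
  expect_identical(classify_sd_trend(c(1, 0.8, 0.99)), "transient_narrowing")
  expect_identical(classify_sd_trend(c(1, 1.001, 0.999)), "stable")
})

test_that("simulation variants reproduce the qualitative contrasts", {
  vs <- run_variant_suite(seed = 23, n_replications = 30, n_children = 2000)
  expect_setequal(names(vs),
                  c("low_haz_first", "high_haz_first", "floor",
                    "deficit_gradient"))
  # subgroup faltering widens; concentrating it in already-short children
  # separates the mixture even further than random selection
  rand <- run_scenario(sim_scenario(n_children = 2000, p_exposed = 0.25,
                                    n_replications = 30, seed = 24))
  final_sd <- function(tr) tail(tr$summary$sd, 1)
  expect_identical(vs$low_haz_first$sd_classification, "widening")
  expect_gt(final_sd(vs$low_haz_first), final_sd(rand))
  expect_identical(vs$high_haz_first$sd_classification, "widening")
  # a floor does not induce narrowing
  expect_gt(final_sd(vs$floor), 1)
  # whole-population exposure with taller children faltering more narrows
  expect_identical(vs$deficit_gradient$sd_classification, "narrowing")
  expect_true(all(diff(vs$deficit_gradient$summary$sd) < 0))
})

test_that("exposure flags never change after baseline", {
  sc <- sim_scenario(n_children = 300, p_exposed = 0.5, n_replications = 1,
                     seed = 25)
  haz0 <- initialize_population(300, seed = 25)
  exposed <- assign_exposure(haz0, 0.5, "random", seed = 26)
  state <- list(haz = haz0, haz0 = haz0, exposed = exposed,
                alive = rep(TRUE, 300))
  for (k in 1:10) {
    state <- apply_decrement(state, scenario = sc)
    expect_identical(state$exposed, exposed)
    expect_identical(state$haz0, haz0)
  }
})
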