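test_that("gLV derivative matches hand arithmetic", {
  m <- glv_model(c(1, 1), rbind(c(-1, 0), c(0.5, -1)), taxa = c("a", "b"))
  expect_equal(unname(glv_derivative(c(1, 1), m)), c(0, 0.5))
  expect_equal(unname(glv_derivative(c(0, 0), m)), c(0, 0))

  logi <- glv_model(1, matrix(-0.5), taxa = "x")
  expect_equal(unname(glv_derivative(2, logi)), 0)
  expect_error(glv_derivative(c(1, 2, 3), m), "does not match")
})

test_that("integration reaches analytic equilibria", {
  logi <- glv_model(1, matrix(-0.5), taxa = "x")
  sim <- simulate_to_steady_state(logi, 0.1)
  expect_true(sim$converged)
  expect_lt(abs(sim$steady_state - 2), 1e-6)

  # already at equilibrium: immediate return
  m <- two_taxon_model()
  sim2 <- simulate_to_steady_state(m, attr(m, "x_star"))
  expect_true(sim2$converged)
  expect_equal(sim2$t_end, 0)
  expect_equal(unname(sim2$steady_state), unname(attr(m, "x_star")))

  # 3-taxon stable model: steady state solves r + A x = 0 (linear oracle)
  m3 <- generate_glv_community(3, connectivity = 0.6,
                               interaction_scale = 0.3, seed = 41)
  sim3 <- simulate_to_steady_state(m3, attr(m3, "x_star") * 0.3)
  expect_true(sim3$converged)
  if (all(sim3$steady_state > 0)) {
    oracle <- solve(m3$A, -m3$r)
    expect_lt(max(abs(sim3$steady_state - oracle)), 1e-6)
  }
})

test_that("clamps hold, zeros absorb, and divergence is caught", {
  m <- two_taxon_model(a_ab = 0.5)
  sim <- simulate_to_steady_state(m, c(1, 1), clamps = c(b = 0.25))
  expect_equal(unname(sim$steady_state["b"]), 0.25)
  expect_true(all(sim$trajectory[, "b"] == 0.25))

  # extinction is absorbing under both integrators
  simz <- simulate_to_steady_state(m, c(0, 1))
  expect_equal(unname(simz$steady_state["a"]), 0)
  simz2 <- simulate_to_steady_state(m, c(0, 1), method = "lsoda")
  expect_equal(unname(simz2$steady_state["a"]), 0)

  runaway <- glv_model(c(1, 1), rbind(c(-1e-4, 2), c(2, -1e-4)),
                       taxa = c("a", "b"))
  expect_error(simulate_to_steady_state(runaway, c(1, 1)), "diverged")
})

test_that("intervention score has its closed-form anchors", {
  base <- c(a = 0.5, b = 0.3, c = 0.2)
  ref <- c(a = 0.3, b = 0.4, c = 0.3)
  expect_equal(intervention_score(base, ref, ref), 1)
  expect_equal(intervention_score(base, base, ref), 0)
  expect_warning(is0 <- intervention_score(ref, ref, ref), "undefined")
  expect_equal(is0, 0)

  # hand-computed weighted Bray-Curtis case (uniform weights)
  post <- c(a = 0.4, b = 0.35, c = 0.25)
  d0 <- sum(abs(base - ref)) / sum(base + ref)      # 0.4 / 2
  d1 <- sum(abs(post - ref)) / sum(post + ref)      # 0.2 / 2
  expect_equal(d0, 0.2)
  expect_equal(d1, 0.1)
  expect_equal(intervention_score(base, post, ref), (d0 - d1) / d0)
  expect_true(d0 >= 0 && d0 <= 1 && d1 >= 0 && d1 <= 1)
})

test_that("intervention score is invariant to weight rescaling", {
  base <- c(a = 0.5, b = 0.3, c = 0.2)
  post <- c(a = 0.35, b = 0.35, c = 0.3)
  ref <- c(a = 0.3, b = 0.4, c = 0.3)
  w <- c(a = 0.2, b = 1.3, c = 0.01)
  expect_equal(intervention_score(base, post, ref, weights = w),
               intervention_score(base, post, ref, weights = 1000 * w))
})

test_that("instantaneous response has the expected signs", {
  m <- two_taxon_model(a_ab = 0.5)
  xs <- attr(m, "x_star")
  # steady state, no clamps: nothing moves
  expect_equal(max(abs(instant_response(m, xs, NULL))), 0)

  # b is a facilitator of a (a_ab > 0): removing b makes a shrink,
  # so -X' for a is positive
  resp <- instant_response(m, xs, c(b = 0))
  expect_gt(unname(resp["a"]), 0)
  expect_equal(unname(resp["b"]), 0)

  # a pure competitor: removing it lets the victim grow (-X' negative)
  comp <- glv_model(c(1.5, 1), rbind(c(-1, -0.5), c(0, -1)),
                    taxa = c("v", "k"))
  x0 <- stats::setNames(solve(comp$A, -comp$r), comp$taxa)
  resp2 <- instant_response(comp, x0, c(k = 0))
  expect_lt(unname(resp2["v"]), 0)
})

test_that("run_intervention composes clamp, simulate, and score", {
  m <- two_taxon_model(a_ab = 0.5)
  xs <- attr(m, "x_star")
  ref <- c(a = 0.8, b = 0.2)

  none <- run_intervention(m, character(0), baseline = xs, reference = ref)
  expect_equal(none$is, 0)
  expect_equal(max(abs(none$delta_x)), 0)

  out <- run_intervention(m, "b", modes = "remove", baseline = xs,
                          reference = ref)
  expect_equal(unname(out$steady_state["b"]), 0)
  expect_equal(unname(out$minus_x_prime["b"]), 0)
  expect_true(out$converged)
  expect_equal(out$delta_x, out$steady_state - xs)

  # recovery flags come from the normal-group interquartile range
  q <- rbind(Q1 = c(a = 0.45, b = 0.4), Q3 = c(a = 0.55, b = 0.6))
  out2 <- run_intervention(m, "b", modes = "add", baseline = xs,
                           reference = c(a = 0.6, b = 0.4),
                           add_levels = c(a = 1, b = 1),
                           normal_quartiles = q)
  expect_type(out2$recovered_flags, "logical")
})

test_that("removing an isolated taxon leaves the rest untouched", {
  # c has no outgoing interactions; a <-> b coupled
  A <- rbind(c(-1, 0.3, 0), c(-0.4, -1, 0), c(0.2, 0.1, -1))
  xs <- c(1, 0.8, 0.6)
  m <- glv_model(as.numeric(-A %*% xs), A, taxa = c("a", "b", "c"))
  base <- stats::setNames(xs, m$taxa)
  out <- run_intervention(m, "c", modes = "remove", baseline = base,
                          reference = c(a = 0.4, b = 0.35, c = 0.25))
  expect_lt(max(abs(out$steady_state[c("a", "b")] - base[c("a", "b")])),
            1e-8)
})

test_that("halving the step size barely changes the score", {
  sc <- make_planted_scenario(n_species = 6, n_keystones = 2, seed = 42)
  base <- attr(sc$model_diseased, "x_star")
  ref <- attr(sc$model_normal, "x_star")
  ref <- ref / sum(ref)
  k <- sc$keystones[1]
  is1 <- combination_intervention_score(
    sc$model_diseased, k, modes = sc$modes[k], baseline = base,
    reference = ref, add_levels = ref, control = list(dt = 0.05)
  )
  is2 <- combination_intervention_score(
    sc$model_diseased, k, modes = sc$modes[k], baseline = base,
    reference = ref, add_levels = ref, control = list(dt = 0.025)
  )
  expect_lt(abs(is1 - is2), 1e-4)
})

test_that("modes derive from the differential direction", {
  diff <- data.frame(taxon = c("up1", "dn1"), direction = c("up", "down"))
  modes <- intervention_modes(diff, c("up1", "dn1"))
  expect_identical(unname(modes), c("remove", "add"))
  expect_error(intervention_modes(diff, "zzz"), "missing")
})
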