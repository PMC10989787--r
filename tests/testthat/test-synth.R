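test_that("generated communities are feasible by construction", {
  m1 <- generate_glv_community(1, seed = 71)
  expect_equal(unname(m1$r), unname(attr(m1, "x_star")))
  expect_equal(unname(m1$A[1, 1]), -1)

  m <- generate_glv_community(12, connectivity = 0.2,
                              interaction_scale = 0.3, seed = 72)
  expect_equal(max(abs(m$r + m$A %*% attr(m, "x_star"))), 0)
  jac <- diag(attr(m, "x_star")) %*% m$A
  expect_lt(max(Re(eigen(jac, only.values = TRUE)$values)), 0)
  expect_length(attr(m, "taxonomy"), 12)
})

test_that("stability rejection sampling accepts most first draws", {
  first_try <- 0
  for (s in 1:20) {
    m <- generate_glv_community(20, connectivity = 0.15,
                                interaction_scale = 0.3, seed = 7000 + s)
    first_try <- first_try + (attr(m, "n_tries") == 1)
  }
  expect_gte(first_try, 10)
})

test_that("disease perturbation is planted, detectable, and reversible", {
  m <- generate_glv_community(12, connectivity = 0.2,
                              interaction_scale = 0.3, seed = 73)
  same <- perturb_to_disease(m, 0, seed = 1)
  expect_equal(same$distance, 0)
  expect_equal(same$model$A, m$A)

  dis <- perturb_to_disease(m, 2, seed = 2)
  expect_length(dis$keystones, 2)
  expect_gt(dis$distance, 0.2)
  # interactions are untouched; only driver growth rates move
  expect_equal(dis$model$A, m$A)
  changed <- which(dis$model$r != m$r)
  expect_setequal(m$taxa[changed], dis$keystones)
  # planted drivers stay detectable in the diseased equilibrium
  xd <- attr(dis$model, "x_star")
  expect_true(all(xd[dis$keystones] / sum(xd) >= 2e-3))

  # clamping the planted drivers moves the community back toward normal
  ref <- attr(m, "x_star")
  ref <- ref / sum(ref)
  cis <- combination_intervention_score(
    dis$model, dis$keystones, modes = dis$modes,
    baseline = attr(dis$model, "x_star"), reference = ref,
    add_levels = ref, weights = keystones:::true_hub_weights(m)
  )
  expect_gt(cis, 0)
})

test_that("cross-sectional sampling matches its contracts", {
  m <- generate_glv_community(10, connectivity = 0.2,
                              interaction_scale = 0.3, seed = 74)
  tab <- sample_cross_section(m, 22, depth = 10000, seed = 3)
  expect_equal(unname(colSums(tab$counts)), rep(10000, 22))
  expect_identical(tab$taxonomy, attr(m, "taxonomy"))

  # bit-reproducibility under a fixed seed
  tab2 <- sample_cross_section(m, 22, depth = 10000, seed = 3)
  expect_identical(tab$counts, tab2$counts)

  # noiseless, fully occupied proportions equal the steady-state composition
  exact <- sample_cross_section(m, 4, noise_cv = 0, occupancy = 1,
                                output = "proportions", seed = 4)
  xs <- attr(m, "x_star")
  for (s in 1:4) {
    expect_equal(unname(exact$counts[, s]), unname(xs / sum(xs)))
  }

  # CLT check under observation noise: mean relative abundance within 3
  # standard errors of the steady-state composition
  obs <- sample_cross_section(m, 500, noise_cv = 0.3, noise = "observation",
                              output = "proportions", seed = 5)
  p_hat <- rowMeans(obs$counts)
  se <- apply(obs$counts, 1, stats::sd) / sqrt(500)
  expect_true(all(abs(p_hat - xs / sum(xs)) <= 3 * se))
})

test_that("planted scenarios bundle coherent group tables", {
  sc <- make_planted_scenario(n_species = 10, n_keystones = 2, seed = 75)
  expect_s3_class(sc, "planted_scenario")
  expect_equal(ncol(sc$table_normal$counts), 16)
  expect_equal(ncol(sc$table_diseased$counts), 22)
  expect_setequal(unique(unname(sc$table$groups)),
                  c("normal", "diseased"))
  expect_identical(taxa_names(sc$table), sc$model_normal$taxa)
  # reproducible end to end
  sc2 <- make_planted_scenario(n_species = 10, n_keystones = 2, seed = 75)
  expect_identical(sc$table$counts, sc2$table$counts)
  expect_identical(sc$keystones, sc2$keystones)
})

test_that("exhaustive truth agrees with the single-species ranking", {
  sc <- make_planted_scenario(n_species = 6, n_keystones = 2, seed = 76)
  truth1 <- exhaustive_truth(sc, max_subset = 1)
  base <- attr(sc$model_diseased, "x_star")
  ref <- attr(sc$model_normal, "x_star")
  ref <- ref / sum(ref)
  w <- keystones:::true_hub_weights(sc$model_normal)
  modes <- keystones:::scenario_modes(sc, sc$model_normal$taxa)
  singles <- vapply(sc$model_normal$taxa, function(t) {
    combination_intervention_score(sc$model_diseased, t, modes = modes[t],
                                   baseline = base, reference = ref,
                                   weights = w, add_levels = ref,
                                   control = list(method = "lsoda"))
  }, numeric(1))
  expect_identical(truth1$subset, names(sort(singles, decreasing = TRUE)))
  expect_equal(truth1$cis, unname(sort(singles, decreasing = TRUE)))

  expect_error(exhaustive_truth(sc, max_subset = 6, budget = 10),
               "budget")
})

test_that("the exhaustive optimum dominates the greedy selection", {
  sc <- make_planted_scenario(n_species = 6, n_keystones = 2, seed = 77)
  truth <- exhaustive_truth(sc, max_subset = 3)
  base <- attr(sc$model_diseased, "x_star")
  ref <- attr(sc$model_normal, "x_star")
  ref <- ref / sum(ref)
  w <- keystones:::true_hub_weights(sc$model_normal)
  modes <- keystones:::scenario_modes(sc, sc$model_normal$taxa)
  sel <- select_keystones(sc$model_diseased, modes = modes, baseline = base,
                          reference = ref, weights = w, add_levels = ref,
                          max_k = 3, cis_threshold = 2)
  greedy <- if (nrow(sel)) max(sel$cis) else 0
  # the empty set (CIS 0) is part of the search space
  expect_gte(max(truth$cis[1], 0), greedy - 1e-5)
})

test_that("both integrators score every subset identically", {
  sc <- make_planted_scenario(n_species = 6, n_keystones = 2, seed = 78)
  a <- exhaustive_truth(sc, max_subset = 2, method = "lsoda")
  b <- exhaustive_truth(sc, max_subset = 2, method = "rk4")
  m <- merge(a, b, by = "subset")
  expect_equal(nrow(m), choose(6, 1) + choose(6, 2))
  expect_lt(max(abs(m$cis.x - m$cis.y)), 1e-6)
})
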