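# A diagonal (interaction-free) community where one non-candidate taxon is
# elevated: every candidate intervention renormalizes mass toward the
# offender and scores <= 0.
diagonal_trap <- function() {
  taxa <- c("x", "c1", "c2", "c3")
  A <- diag(-1, 4)
  xs <- c(3, 1, 1, 1)       # x elevated threefold
  ref <- c(x = 1, c1 = 1, c2 = 1, c3 = 1)
  ref <- ref / sum(ref)
  m <- glv_model(xs, A, taxa = taxa)  # r = x* since a_ii = -1
  list(model = m, baseline = stats::setNames(xs, taxa), reference = ref)
}

test_that("CIS is definitionally consistent with single-species IS", {
  sc <- make_planted_scenario(n_species = 6, n_keystones = 2, seed = 51)
  base <- attr(sc$model_diseased, "x_star")
  ref <- attr(sc$model_normal, "x_star")
  ref <- ref / sum(ref)
  expect_equal(
    combination_intervention_score(sc$model_diseased, character(0),
                                   baseline = base, reference = ref),
    0
  )
  k <- sc$keystones[1]
  single <- run_intervention(sc$model_diseased, k, modes = sc$modes[k],
                             baseline = base, reference = ref,
                             add_levels = ref)
  expect_equal(
    combination_intervention_score(sc$model_diseased, k,
                                   modes = sc$modes[k], baseline = base,
                                   reference = ref, add_levels = ref),
    single$is
  )
})

test_that("selection stops at the CIS threshold", {
  sc <- make_planted_scenario(n_species = 6, n_keystones = 2, seed = 52)
  base <- attr(sc$model_diseased, "x_star")
  ref <- attr(sc$model_normal, "x_star")
  ref <- ref / sum(ref)
  modes <- keystones:::scenario_modes(sc, sc$model_normal$taxa)
  # single candidate whose IS clears the threshold
  k <- sc$keystones[1]
  is_k <- combination_intervention_score(sc$model_diseased, k,
                                         modes = modes[k], baseline = base,
                                         reference = ref, add_levels = ref)
  expect_gt(is_k, 0)
  sel <- select_keystones(sc$model_diseased, candidates = k, modes = modes,
                          baseline = base, reference = ref,
                          add_levels = ref, cis_threshold = is_k / 2)
  expect_identical(sel$taxon, k)
  expect_identical(attr(sel, "stop_reason"), "threshold_reached")
})

test_that("no positive gain yields an empty selection", {
  tr <- diagonal_trap()
  # weight concentrated on the non-candidate offender: removing any
  # candidate renormalizes mass toward it, so every IS (and pair CIS) < 0
  w <- c(x = 1, c1 = 0, c2 = 0, c3 = 0)
  sel <- select_keystones(tr$model, candidates = c("c1", "c2", "c3"),
                          modes = "remove", baseline = tr$baseline,
                          reference = tr$reference, weights = w)
  expect_equal(nrow(sel), 0)
  expect_identical(attr(sel, "stop_reason"), "no_positive_gain")
  expect_true(all(attr(sel, "single_is") <= 0))
})

test_that("the cumulative CIS curve is non-decreasing without duplicates", {
  for (s in c(53, 54, 55)) {
    sc <- make_planted_scenario(n_species = 6, n_keystones = 2, seed = s)
    base <- attr(sc$model_diseased, "x_star")
    ref <- attr(sc$model_normal, "x_star")
    ref <- ref / sum(ref)
    modes <- keystones:::scenario_modes(sc, sc$model_normal$taxa)
    sel <- select_keystones(sc$model_diseased, modes = modes,
                            baseline = base, reference = ref,
                            add_levels = ref, max_k = 4, cis_threshold = 2)
    if (nrow(sel) == 0) next
    expect_false(anyDuplicated(sel$taxon) > 0)
    expect_true(all(diff(c(0, sel$cis)) >= -1e-12))
    # idempotent scoring: recomputing the final set reproduces the CIS
    recomputed <- combination_intervention_score(
      sc$model_diseased, sel$taxon, modes = modes[sel$taxon],
      baseline = base, reference = ref, add_levels = ref
    )
    expect_equal(recomputed, sel$cis[nrow(sel)], tolerance = 1e-12)
  }
})

test_that("backward elimination drops only non-contributing members", {
  sc <- make_planted_scenario(n_species = 6, n_keystones = 2, seed = 56)
  base <- attr(sc$model_diseased, "x_star")
  ref <- attr(sc$model_normal, "x_star")
  ref <- ref / sum(ref)
  modes <- keystones:::scenario_modes(sc, sc$model_normal$taxa)
  sel <- select_keystones(sc$model_diseased, modes = modes, baseline = base,
                          reference = ref, add_levels = ref, max_k = 3,
                          cis_threshold = 2)
  skip_if(nrow(sel) == 0, "selection degenerate for this scenario")

  kept <- backward_eliminate(sel, sc$model_diseased, modes = modes,
                             baseline = base, reference = ref,
                             add_levels = ref)
  expect_lte(nrow(kept), nrow(sel))
  expect_gte(kept$cis[nrow(kept)], sel$cis[nrow(sel)] - 1e-6)

  # a singleton with positive CIS is a fixed point
  single <- sel[1, , drop = FALSE]
  attr(single, "stop_reason") <- "max_k"
  class(single) <- c("keystone_selection", "data.frame")
  one <- backward_eliminate(single, sc$model_diseased, modes = modes,
                            baseline = base, reference = ref,
                            add_levels = ref)
  expect_identical(one$taxon, single$taxon)
})

test_that("an isolated padded taxon is eliminated", {
  # a facilitates b; z is isolated (no outgoing edges) and extinct in the
  # diseased state, so clamping it to zero has exactly no dynamic effect.
  # Scores run over the full taxon set to isolate dynamic contributions.
  A <- rbind(c(-1, 0, 0), c(0.4, -1, 0), c(0, 0, -1))
  xs <- c(1, 1, 0.5)                     # healthy equilibrium
  r_normal <- as.numeric(-A %*% xs)
  md <- glv_model(r_normal * c(0.2, 1, 1), A, taxa = c("a", "b", "z"))
  md$r["z"] <- -0.5                      # z lost in disease
  base <- simulate_to_steady_state(md, stats::setNames(xs, md$taxa)
                                   )$steady_state
  expect_equal(unname(base["z"]), 0)
  ref <- stats::setNames(xs / sum(xs), md$taxa)
  modes <- c(a = "add", b = "add", z = "remove")
  levels <- stats::setNames(xs, md$taxa)
  sel <- data.frame(rank = 1:2, taxon = c("a", "z"),
                    mode = c("add", "remove"), gain = c(0.1, 0),
                    cis = c(0.1, 0.1), stringsAsFactors = FALSE)
  class(sel) <- c("keystone_selection", "data.frame")
  attr(sel, "stop_reason") <- "max_k"
  out <- backward_eliminate(sel, md, modes = modes, baseline = base,
                            reference = ref, add_levels = levels,
                            exclude_targets = FALSE)
  expect_identical(out$taxon, "a")
})
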