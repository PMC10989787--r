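#' Generate a random stable gLV community
#'
#' Draws a random interaction support at the given connectivity, normal
#' off-diagonal interaction strengths, self-limitation `a_ii = -1`, and a
#' positive target steady state `x*` (log-normal, emulating the uneven
#' abundance distribution of gut communities). Growth rates are set to
#' `r = -A x*` so the interior equilibrium is feasible by construction; the
#' draw is rejected and resampled until the equilibrium is locally stable
#' (all eigenvalues of `diag(x*) A` have negative real part).
#'
#' @param n_species Number of taxa (>= 1).
#' @param connectivity Probability of each off-diagonal interaction; default
#'   0.15.
#' @param interaction_scale SD of the off-diagonal interaction strengths;
#'   default 0.3.
#' @param seed Optional integer seed.
#' @param max_tries Resampling budget for stability; default 100.
#' @return A `glv_model` with attributes `x_star` (the planted equilibrium),
#'   `taxonomy` (synthetic lineages spanning several families), and
#'   `n_tries`.
#' @export
generate_glv_community <- function(n_species, connectivity = 0.15,
                                   interaction_scale = 0.3, seed = NULL,
                                   max_tries = 100) {
  stopifnot(n_species >= 1)
  if (!is.null(seed)) set.seed(seed)
  taxa <- sprintf("OTU%02d", seq_len(n_species))
  families <- c("Lachnospiraceae", "Ruminococcaceae", "Bacteroidaceae",
                "FamilyXI", "Prevotellaceae", "Veillonellaceae")
  fam <- rep(families, length.out = n_species)
  taxonomy <- stats::setNames(
    sprintf("d__Bacteria;p__SynPhylum;c__SynClass;o__SynOrder;f__%s;g__SynGenus%02d;s__syn_sp_%02d",
            fam, seq_len(n_species), seq_len(n_species)),
    taxa
  )
  for (tries in seq_len(max_tries)) {
    x_star <- stats::rlnorm(n_species, meanlog = 0, sdlog = 0.5)
    A <- matrix(0, n_species, n_species)
    if (n_species > 1) {
      off <- which(row(A) != col(A))
      hit <- off[stats::runif(length(off)) < connectivity]
      A[hit] <- stats::rnorm(length(hit), 0, interaction_scale)
    }
    diag(A) <- -1
    r <- as.numeric(-A %*% x_star)
    jac <- diag(x_star, n_species) %*% A
    if (max(Re(eigen(jac, only.values = TRUE)$values)) < -1e-8) {
      model <- glv_model(r, A, taxa = taxa)
      attr(model, "x_star") <- stats::setNames(x_star, taxa)
      attr(model, "taxonomy") <- taxonomy
      attr(model, "n_tries") <- tries
      return(model)
    }
  }
  stop("no stable community in ", max_tries,
       " draws; try a smaller interaction_scale")
}

#' Perturb a community into a diseased variant
#'
#' Picks the `n_keystones` taxa with the highest interaction out-degree and
#' shifts their intrinsic growth rates (bloom or crash, chosen at random per
#' keystone) while leaving every interaction intact, so the planted drivers
#' drag the rest of the community to a new equilibrium through unchanged
#' interactions -- the situation in which intervening on the drivers can
#' genuinely restore the community. Perturbation magnitudes escalate across
#' attempts until the diseased equilibrium's Bray-Curtis distance from the
#' normal composition exceeds `min_distance`. Each planted keystone's
#' intended intervention mode follows its realized abundance change:
#' elevated in disease -> `"remove"`, depleted -> `"add"`.
#'
#' @param model A stable `glv_model` from [generate_glv_community()].
#' @param n_keystones Number of planted driver species; default 3.
#' @param seed Optional integer seed.
#' @param min_distance Required Bray-Curtis distance between the normal and
#'   diseased compositions; default 0.2.
#' @param max_tries Attempts before settling for the best one (with a
#'   warning); default 25.
#' @return List: `model` (diseased `glv_model`, attribute `x_star` = its
#'   steady state), `keystones` (character), `modes` (named), `distance`.
#' @export
perturb_to_disease <- function(model, n_keystones = 3, seed = NULL,
                               min_distance = 0.2, max_tries = 25) {
  stopifnot(inherits(model, "glv_model"))
  if (!is.null(seed)) set.seed(seed)
  taxa <- model$taxa
  d <- length(taxa)
  x_norm <- attr(model, "x_star")
  if (is.null(x_norm)) x_norm <- glv_equilibrium(model)
  if (n_keystones == 0) {
    dm <- model
    attr(dm, "x_star") <- x_norm
    return(list(model = dm, keystones = character(0),
                modes = stats::setNames(character(0), character(0)),
                distance = 0))
  }
  offdeg <- colSums(model$A != 0) - 1  # out-degree, diagonal excluded
  ks <- taxa[order(-offdeg, taxa)][seq_len(min(n_keystones, d))]
  ki <- match(ks, taxa)
  bray <- function(u, v) {
    u <- u / sum(u)
    v <- v / sum(v)
    sum(abs(u - v)) / sum(u + v)
  }
  best <- NULL
  for (tries in seq_len(max_tries)) {
    boost <- 1 + 0.25 * (tries - 1)
    A2 <- model$A
    r2 <- model$r
    for (k in ki) {
      if (stats::runif(1) < 0.5) {
        # bloom: raise the driver's intrinsic growth
        r2[k] <- r2[k] + stats::runif(1, 1, 2) * boost *
          max(abs(r2[k]), 0.5)
      } else {
        # deplete: shrink the driver's growth (not to extinction, so the
        # taxon stays detectable in the diseased cross section)
        r2[k] <- if (r2[k] > 0) {
          r2[k] * stats::runif(1, 0.1, 0.3) / boost
        } else {
          r2[k] * (1 + stats::runif(1, 0.5, 1.5) * boost)
        }
      }
    }
    dm <- glv_model(r2, A2, taxa = taxa)
    sim <- tryCatch(
      simulate_to_steady_state(dm, x_norm, t_max = 500),
      error = function(e) NULL
    )
    if (is.null(sim) || !sim$converged) next
    x_dis <- sim$steady_state
    if (sum(x_dis) <= 0) next
    # planted drivers must stay detectable in the diseased community,
    # otherwise the planted ground truth is not an addressable target
    if (any(x_dis[ks] / sum(x_dis) < 2e-3)) next
    dist <- bray(x_norm, x_dis)
    if (is.null(best) || dist > best$distance) {
      modes <- ifelse(x_dis[ks] > x_norm[ks], "remove", "add")
      names(modes) <- ks
      attr(dm, "x_star") <- x_dis
      attr(dm, "taxonomy") <- attr(model, "taxonomy")
      best <- list(model = dm, keystones = ks, modes = modes,
                   distance = dist)
    }
    if (dist > min_distance) break
  }
  if (is.null(best)) stop("no stable diseased variant found")
  if (best$distance <= min_distance) {
    warning("diseased community distance ",
            formatC(best$distance, digits = 3),
            " did not reach the target ", min_distance,
            "; returning the best attempt")
  }
  best
}

#' Sample a cross-sectional abundance table from a gLV community
#'
#' Under the default `noise = "equilibrium"`, every sample is an equilibrium
#' of the model in its own host: each taxon colonizes the sample with
#' probability `occupancy` (absent taxa stay at zero -- extinction is
#' absorbing), growth rates are multiplied by i.i.d. log-normal
#' environmental noise (mean 1, coefficient of variation `noise_cv`), and
#' the masked community is integrated to its steady state. The
#' assemblage-to-assemblage variation this produces is what makes the gLV
#' steady-state constraints informative across a cross section. With
#' `noise = "observation"` the log-normal noise multiplies the community
#' steady state directly (pure measurement noise, all taxa present).
#'
#' Each sample is converted to proportions and drawn as multinomial counts
#' at the given sequencing depth (`output = "counts"`);
#' `output = "proportions"` skips the count draw (the infinite-depth limit)
#' and `output = "absolute"` returns the raw equilibrium abundances without
#' compositional closure.
#'
#' @param model A `glv_model` with attribute `x_star` (else the interior
#'   equilibrium is used).
#' @param n_samples Number of samples.
#' @param noise_cv Coefficient of variation of the log-normal noise; default
#'   0.3.
#' @param depth Reads per sample; default 10000.
#' @param seed Optional integer seed.
#' @param noise `"equilibrium"` (default) or `"observation"`.
#' @param occupancy Per-taxon colonization probability under equilibrium
#'   noise; default 0.8 (1 keeps every taxon in every sample).
#' @param output `"counts"` (default), `"proportions"`, or `"absolute"`.
#' @param group Group label for every sample; default `"group"`.
#' @param sample_prefix Prefix for sample identifiers.
#' @return An `abundance_table` (relative when `output = "proportions"`).
#' @export
sample_cross_section <- function(model, n_samples, noise_cv = 0.3,
                                 depth = 10000, seed = NULL,
                                 noise = c("equilibrium", "observation"),
                                 occupancy = 0.8,
                                 output = c("counts", "proportions",
                                            "absolute"),
                                 group = "group", sample_prefix = "S") {
  noise <- match.arg(noise)
  output <- match.arg(output)
  stopifnot(inherits(model, "glv_model"))
  if (!is.null(seed)) set.seed(seed)
  taxa <- model$taxa
  d <- length(taxa)
  x_star <- attr(model, "x_star")
  if (is.null(x_star)) x_star <- glv_equilibrium(model)
  sdlog <- sqrt(log(1 + noise_cv^2))
  counts <- matrix(0, d, n_samples,
                   dimnames = list(taxa, sprintf("%s%03d", sample_prefix,
                                                 seq_len(n_samples))))
  for (s in seq_len(n_samples)) {
    eta <- stats::rlnorm(d, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    if (noise_cv == 0) eta <- rep(1, d)
    if (noise == "observation") {
      xs <- as.numeric(x_star) * eta
    } else {
      mask <- stats::runif(d) < occupancy
      if (!any(mask)) mask[sample.int(d, 1)] <- TRUE
      ms <- model
      ms$r <- model$r * eta
      xs <- simulate_to_steady_state(ms, as.numeric(x_star) * mask,
                                     t_max = 500, tol = 1e-8)$steady_state
    }
    if (sum(xs) <= 0) xs <- as.numeric(x_star) # collapsed draw: fall back
    counts[, s] <- switch(output,
      absolute = xs,
      proportions = xs / sum(xs),
      counts = stats::rmultinom(1, size = depth, prob = xs / sum(xs))
    )
  }
  abundance_table(counts, taxonomy = attr(model, "taxonomy"),
                  groups = stats::setNames(rep(group, n_samples),
                                           colnames(counts)),
                  relative = output == "proportions")
}

#' Build a complete planted-truth scenario
#'
#' Convenience wrapper emulating a two-group cross-sectional cohort:
#' generates a stable "normal" community, perturbs `n_keystones` planted
#' drivers into a "diseased" variant, and samples count tables for both
#' groups.
#'
#' @inheritParams generate_glv_community
#' @inheritParams sample_cross_section
#' @param n_keystones Number of planted drivers; default 3.
#' @param occupancy Per-taxon colonization probability; default 0.8.
#' @param n_normal,n_diseased Samples per group; defaults 16 and 22
#'   (healthy and disease cohort sizes).
#' @param seed Integer seed driving the whole scenario.
#' @return A `planted_scenario`: list with `model_normal`, `model_diseased`,
#'   `keystones`, `modes`, `distance`, `table` (merged, group labels
#'   `"normal"`/`"diseased"`), `table_normal`, `table_diseased`.
#' @export
make_planted_scenario <- function(n_species = 20, n_keystones = 3,
                                  n_normal = 16, n_diseased = 22,
                                  connectivity = 0.15,
                                  interaction_scale = 0.3, noise_cv = 0.3,
                                  depth = 10000, occupancy = 0.8,
                                  seed = NULL, noise = "equilibrium") {
  if (!is.null(seed)) set.seed(seed)
  normal <- generate_glv_community(n_species, connectivity,
                                   interaction_scale)
  dis <- suppressWarnings(perturb_to_disease(normal, n_keystones))
  tn <- sample_cross_section(normal, n_normal, noise_cv = noise_cv,
                             depth = depth, noise = noise,
                             occupancy = occupancy, group = "normal",
                             sample_prefix = "N")
  td <- sample_cross_section(dis$model, n_diseased, noise_cv = noise_cv,
                             depth = depth, noise = noise,
                             occupancy = occupancy, group = "diseased",
                             sample_prefix = "D")
  merged <- abundance_table(cbind(tn$counts, td$counts),
                            taxonomy = tn$taxonomy,
                            groups = c(tn$groups, td$groups))
  structure(
    list(model_normal = normal, model_diseased = dis$model,
         keystones = dis$keystones, modes = dis$modes,
         distance = dis$distance, table = merged, table_normal = tn,
         table_diseased = td),
    class = "planted_scenario"
  )
}

#' @export
print.planted_scenario <- function(x, ...) {
  cat("planted_scenario:", length(x$model_normal$taxa), "taxa,",
      ncol(x$table_normal$counts), "normal +",
      ncol(x$table_diseased$counts), "diseased samples; planted keystones:",
      paste(x$keystones, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive ground-truth CIS over all small subsets
#'
#' Brute-force oracle for the greedy selection: scores every candidate
#' subset up to `max_subset` species through the same intervention-scoring
#' path, but integrating the dynamics with the independently coded adaptive
#' integrator ([deSolve::ode()], `method = "lsoda"`) instead of the built-in
#' RK4.
#'
#' @param scenario A `planted_scenario`.
#' @param max_subset Largest subset size; the total number of subsets
#'   (`sum over k of choose(D, k)`) must not exceed `budget`.
#' @param candidates Candidate taxa; default all.
#' @param weights Per-taxon weights for the IS metric (default: HITS hub
#'   scores of the true normal interaction matrix).
#' @param budget Combinatorial budget; default 1e4.
#' @param method Integrator passed to [run_intervention()]; default
#'   `"lsoda"` (the oracle path).
#' @return data.frame `subset` (slash-separated taxa), `k`, `cis`, sorted by
#'   decreasing CIS.
#' @export
exhaustive_truth <- function(scenario, max_subset = 2, candidates = NULL,
                             weights = NULL, budget = 1e4,
                             method = "lsoda") {
  stopifnot(inherits(scenario, "planted_scenario"))
  if (is.null(candidates)) candidates <- scenario$model_normal$taxa
  n <- length(candidates)
  total <- sum(choose(n, seq_len(max_subset)))
  if (total > budget) {
    stop("subset budget exceeded: ", total, " subsets > ", budget)
  }
  baseline <- attr(scenario$model_diseased, "x_star")
  reference <- attr(scenario$model_normal, "x_star")
  reference <- reference / sum(reference)
  if (is.null(weights)) {
    weights <- true_hub_weights(scenario$model_normal)
  }
  modes <- scenario_modes(scenario, candidates)
  rows <- list()
  for (k in seq_len(max_subset)) {
    sets <- utils::combn(candidates, k, simplify = FALSE)
    for (set in sets) {
      cis <- combination_intervention_score(
        scenario$model_diseased, set, modes = modes[set],
        baseline = baseline, reference = reference, weights = weights,
        add_levels = reference, control = list(method = method)
      )
      rows[[length(rows) + 1]] <- data.frame(
        subset = paste(set, collapse = "/"), k = k, cis = cis,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  res[order(-res$cis), ]
}

# HITS hub scores of the true (planted) interaction matrix, used as the IS
# weights when working directly from models.
true_hub_weights <- function(model) {
  taxa <- model$taxa
  A <- model$A
  diag(A) <- 0
  e <- which(A != 0, arr.ind = TRUE)
  if (!nrow(e)) return(stats::setNames(rep(0, length(taxa)), taxa))
  net <- make_interaction_network(
    taxa,
    data.frame(source = taxa[e[, 2]], target = taxa[e[, 1]],
               weight = A[e], stringsAsFactors = FALSE)
  )
  h <- hits_scores(net)
  stats::setNames(h$hub, h$taxon)
}

# Intervention modes for arbitrary taxa in a scenario: planted modes where
# recorded, else by the realized abundance change diseased vs normal.
scenario_modes <- function(scenario, taxa) {
  xn <- attr(scenario$model_normal, "x_star")
  xd <- attr(scenario$model_diseased, "x_star")
  modes <- ifelse(xd[taxa] > xn[taxa], "remove", "add")
  names(modes) <- taxa
  known <- intersect(taxa, names(scenario$modes))
  modes[known] <- scenario$modes[known]
  modes
}
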