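#' Pipeline configuration
#'
#' Collects every tunable threshold of the keystone-identification pipeline.
#' The defaults are the standard operating points of the analysis: sample-coverage filter
#' 0.5, differential FDR 0.05, prior/edge/hub significance 0.01 with 1000
#' permutations each, enrichment FDR 0.01, and the CIS > 0.9 stopping rule.
#'
#' @param coverage Minimum sample coverage for a taxon; default 0.5.
#' @param diff_fdr Differential-abundance FDR cutoff; default 0.05.
#' @param prior_alpha SparCC prior-edge significance level; default 0.01.
#' @param edge_alpha Causal-edge significance level; default 0.01.
#' @param hub_alpha Hub significance level; default 0.01.
#' @param enrich_fdr Enrichment FDR cutoff; default 0.01.
#' @param cis_threshold CIS stopping threshold (strictly greater than);
#'   default 0.9.
#' @param n_perm_sparcc,n_perm_edges,n_perm_hubs Permutation counts; default
#'   1000 each.
#' @param max_k Maximum keystone-set size; default 10.
#' @param ridge Ridge penalty of the gLV row fits; default 0.01.
#' @param dt,t_max,tol Integrator settings; defaults 0.05, 1000, 1e-8.
#' @param seed Top-level seed from which every stage's randomness derives.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(coverage = 0.5, diff_fdr = 0.05,
                            prior_alpha = 0.01, edge_alpha = 0.01,
                            hub_alpha = 0.01, enrich_fdr = 0.01,
                            cis_threshold = 0.9, n_perm_sparcc = 1000,
                            n_perm_edges = 1000, n_perm_hubs = 1000,
                            max_k = 10, ridge = 0.01, dt = 0.05,
                            t_max = 1000, tol = 1e-8, seed = 1) {
  cfg <- list(coverage = coverage, diff_fdr = diff_fdr,
              prior_alpha = prior_alpha, edge_alpha = edge_alpha,
              hub_alpha = hub_alpha, enrich_fdr = enrich_fdr,
              cis_threshold = cis_threshold, n_perm_sparcc = n_perm_sparcc,
              n_perm_edges = n_perm_edges, n_perm_hubs = n_perm_hubs,
              max_k = max_k, ridge = ridge, dt = dt, t_max = t_max,
              tol = tol, seed = seed)
  for (f in c("coverage", "diff_fdr", "prior_alpha", "edge_alpha",
              "hub_alpha", "enrich_fdr", "cis_threshold")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(f, " must be in [0, 1]")
    }
  }
  for (f in c("n_perm_sparcc", "n_perm_edges", "n_perm_hubs")) {
    if (cfg[[f]] < 100) stop(f, " must be at least 100")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full keystone-identification pipeline
#'
#' Chains every stage on a two-group abundance table: coverage filtering,
#' differential-abundance analysis, SparCC prior per group, iterative causal
#' gLV network inference per group, HITS hub scoring (hub significance on
#' both groups; the normal group's hub scores weight the IS metric), dynamic
#' intervention simulation of every candidate, and greedy keystone
#' selection.
#'
#' @param x An `abundance_table` of counts with group labels covering
#'   `normal_label` and `case_label`.
#' @param normal_label Group label of the healthy reference.
#' @param case_label Group label of the diseased community.
#' @param config A [pipeline_config()].
#' @param candidates Candidate taxa for keystone selection; default all taxa
#'   surviving the coverage filter.
#' @param verbose Print per-stage progress.
#' @return List with elements `table` (filtered), `differential`,
#'   `prior_normal`, `prior_case`, `network_normal`, `network_case`,
#'   `model_case`, `hits_normal`, `hubs_normal`, `hubs_case`,
#'   `powerlaw_r2_normal`, `family_tallies_normal`, `baseline`, `reference`,
#'   `single_is` (named vector), `selection` (a `keystone_selection`), and
#'   `config`.
#' @export
run_keystone_pipeline <- function(x, normal_label, case_label,
                                  config = pipeline_config(),
                                  candidates = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  set.seed(config$seed)
  stage_seeds <- sample.int(2^31 - 1, 8)

  x <- subset_group(x, c(normal_label, case_label))
  filt <- filter_by_coverage(x, config$coverage)
  say("coverage filter: ", nrow(filt$counts), " taxa retained")
  rel <- to_relative(filt)

  diff <- wilcoxon_differential(rel, normal_label, case_label,
                                fdr_cut = config$diff_fdr)
  say("differential: ", sum(diff$differential), " taxa at FDR <= ",
      config$diff_fdr)

  infer_group <- function(label, seed_rho, seed_net) {
    grp_counts <- subset_group(filt, label)
    rho <- sparcc_correlations(grp_counts, seed = seed_rho)
    pv <- sparcc_pvalues(grp_counts, n_perm = config$n_perm_sparcc,
                         seed = seed_rho + 1)
    prior <- build_prior_network(rho, pv, alpha = config$prior_alpha)
    say(label, " prior: ", nrow(prior$edges), " edges")
    grp_rel <- to_relative(grp_counts)
    net <- iterate_network(grp_rel, prior, alpha = config$edge_alpha,
                           n_perm = config$n_perm_edges,
                           ridge = config$ridge, seed = seed_net)
    say(label, " network: ", nrow(net$network$edges), " edges after ",
        net$rounds, " rounds")
    list(prior = prior, net = net)
  }
  gn <- infer_group(normal_label, stage_seeds[1], stage_seeds[2])
  gc_ <- infer_group(case_label, stage_seeds[3], stage_seeds[4])

  hits_n <- hits_scores(gn$net$network)
  weights <- stats::setNames(hits_n$hub, hits_n$taxon)
  hubs_n <- if (nrow(gn$net$network$edges)) {
    hub_significance(gn$net$network, n_perm = config$n_perm_hubs,
                     alpha = config$hub_alpha, seed = stage_seeds[5])
  } else NULL
  hubs_c <- if (nrow(gc_$net$network$edges)) {
    hub_significance(gc_$net$network, n_perm = config$n_perm_hubs,
                     alpha = config$hub_alpha, seed = stage_seeds[6])
  } else NULL

  r2 <- suppressWarnings(degree_powerlaw_fit(gn$net$network))
  tallies <- family_interaction_tallies(gn$net$network)

  reference <- group_profile(rel, normal_label)
  case_profile <- group_profile(rel, case_label)
  base_sim <- simulate_to_steady_state(gc_$net$model, case_profile,
                                       t_max = config$t_max, dt = config$dt,
                                       tol = config$tol)
  baseline <- base_sim$steady_state
  if (sum(baseline) <= 0) baseline <- case_profile
  quart <- group_quartiles(rel, normal_label)

  if (is.null(candidates)) candidates <- taxa_names(filt)
  modes <- intervention_modes(diff, candidates)
  ctl <- list(dt = config$dt, t_max = config$t_max, tol = config$tol)
  say("greedy keystone selection over ", length(candidates), " candidates")
  selection <- select_keystones(
    gc_$net$model, candidates = candidates, modes = modes,
    baseline = baseline, reference = reference, weights = weights,
    cis_threshold = config$cis_threshold, max_k = config$max_k,
    add_levels = reference, normal_quartiles = quart, control = ctl
  )

  list(table = filt, differential = diff,
       prior_normal = gn$prior, prior_case = gc_$prior,
       network_normal = gn$net$network, network_case = gc_$net$network,
       model_case = gc_$net$model,
       hits_normal = hits_n, hubs_normal = hubs_n, hubs_case = hubs_c,
       powerlaw_r2_normal = r2, family_tallies_normal = tallies,
       baseline = baseline, reference = reference,
       single_is = attr(selection, "single_is"),
       selection = selection, config = config)
}
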