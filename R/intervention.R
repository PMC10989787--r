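#' Intervention score (IS)
#'
#' Fractional reduction of the HITS-weighted compositional distance to the
#' normal reference achieved by an intervention. Profiles are normalized to
#' relative abundance; with normalized weights `w` the distance is the
#' weighted Bray-Curtis dissimilarity
#' `d(u, v) = sum_i w_i |u_i - v_i| / sum_i w_i (u_i + v_i)`
#' and `IS = (d(baseline, ref) - d(post, ref)) / d(baseline, ref)`.
#' The intervention targets are excluded from the distance sums so clamped
#' taxa cannot trivially inflate the score. IS is 1 at full recovery, 0 when
#' the community is unchanged, and negative when the intervention moves the
#' community further from the reference.
#'
#' @param baseline Diseased steady-state abundance vector (named).
#' @param post Post-intervention steady-state abundance vector.
#' @param reference Normal reference profile.
#' @param weights Non-negative per-taxon weights (HITS hub scores of the
#'   normal network). `NULL` for uniform. A uniform floor `eps` is always
#'   added so no taxon has zero weight.
#' @param targets Taxa excluded from the distance sums.
#' @param eps Weight floor; default 0.01.
#' @return IS, a scalar `<= 1`. Returns 0 with a warning when the baseline
#'   already equals the reference (distance 0).
#' @export
intervention_score <- function(baseline, post, reference, weights = NULL,
                               targets = character(0), eps = 0.01) {
  taxa <- names(baseline)
  if (is.null(taxa)) stop("baseline must be named by taxon")
  post <- post[taxa]
  reference <- reference[taxa]
  if (is.null(weights)) {
    w <- rep(1, length(taxa))
  } else {
    w <- as.numeric(weights[taxa])
    w[is.na(w)] <- 0
    if (any(w < 0)) stop("weights must be non-negative")
  }
  # normalize before flooring so IS is invariant to rescaling the weights
  if (sum(w) > 0) w <- w / sum(w)
  w <- w + eps
  w <- w / sum(w)
  relprof <- function(v) {
    s <- sum(v)
    if (s > 0) v / s else v
  }
  b <- relprof(as.numeric(baseline))
  p <- relprof(as.numeric(post))
  r <- relprof(as.numeric(reference))
  keep <- !(taxa %in% targets)
  wbc <- function(u, v) {
    den <- sum(w[keep] * (u[keep] + v[keep]))
    if (den == 0) return(0)
    sum(w[keep] * abs(u[keep] - v[keep])) / den
  }
  d0 <- wbc(b, r)
  if (d0 == 0) {
    warning("baseline already at the reference; IS undefined, returning 0")
    return(0)
  }
  (d0 - wbc(p, r)) / d0
}

#' Instantaneous response to an intervention
#'
#' Applies the clamps to the baseline state, evaluates the gLV derivative,
#' and returns its negation with the clamped coordinates zeroed. Positive
#' entries mark taxa whose abundance instantly falls upon the intervention;
#' negative entries mark taxa that instantly grow.
#'
#' @param model A `glv_model`.
#' @param baseline Baseline abundance vector (named, model order).
#' @param clamps Named clamp vector (taxon -> value).
#' @return Named numeric vector, `-dx/dt` at `t = 0+`.
#' @export
instant_response <- function(model, baseline, clamps) {
  x <- state_vector(baseline, model$taxa)
  names(x) <- model$taxa
  if (length(clamps)) x[names(clamps)] <- as.numeric(clamps)
  d <- glv_derivative(x, model)
  if (length(clamps)) d[names(clamps)] <- 0
  -d
}

#' Derive intervention modes from differential direction
#'
#' Taxa elevated in the case group are removed (clamped to 0); depleted taxa
#' are added (clamped to the normal-group mean abundance).
#'
#' @param diff Result of [wilcoxon_differential()].
#' @param targets Taxa to assign modes to.
#' @return Named character vector, `"remove"` or `"add"`.
#' @export
intervention_modes <- function(diff, targets) {
  dirs <- stats::setNames(diff$direction, diff$taxon)[targets]
  if (anyNA(dirs)) {
    stop("targets missing from the differential result: ",
         paste(targets[is.na(dirs)], collapse = ", "))
  }
  stats::setNames(ifelse(dirs == "up", "remove", "add"), targets)
}

#' Run a dynamic intervention simulation (DIS)
#'
#' Clamps the target taxa in the diseased gLV model (removal clamps to 0;
#' addition clamps to the taxon's normal-group mean abundance), integrates
#' the clamped dynamics from the diseased baseline to a new steady state,
#' and scores the recovery toward the normal reference with the
#' HITS-weighted intervention score.
#'
#' @param model The diseased `glv_model`.
#' @param targets Character vector of target taxa (empty set gives IS 0).
#' @param modes Named character vector (`"remove"`/`"add"`) per target;
#'   single value recycled.
#' @param baseline Diseased steady-state abundance vector (named).
#' @param reference Normal reference profile (named).
#' @param weights Per-taxon HITS hub scores of the normal network, or
#'   `NULL` for uniform.
#' @param add_levels Clamp levels for `"add"` targets (named); defaults to
#'   `reference`.
#' @param normal_quartiles Optional 2-row matrix (`Q1`, `Q3` rows, taxa in
#'   columns) of the normal group's observed relative abundances, used for
#'   the per-taxon recovery flags.
#' @param exclude_targets Exclude targets from the IS distance sums; default
#'   `TRUE`.
#' @param control List of integrator settings (`dt`, `t_max`, `tol`,
#'   `method`).
#' @return An `intervention_result`: list with `targets`, `modes`, `is`,
#'   `steady_state`, `trajectory`, `minus_x_prime`, `delta_x`,
#'   `recovered_flags`, `converged`.
#' @export
run_intervention <- function(model, targets, modes = "remove", baseline,
                             reference, weights = NULL, add_levels = NULL,
                             normal_quartiles = NULL, exclude_targets = TRUE,
                             control = list()) {
  stopifnot(inherits(model, "glv_model"))
  taxa <- model$taxa
  baseline <- stats::setNames(state_vector(baseline, taxa), taxa)
  targets <- as.character(targets)
  if (!all(targets %in% taxa)) {
    stop("unknown target taxa: ",
         paste(setdiff(targets, taxa), collapse = ", "))
  }
  ctl <- utils::modifyList(
    list(dt = 0.05, t_max = 1000, tol = 1e-8, method = "rk4",
         record_every = 1), control)
  if (length(targets) == 0) {
    zero <- stats::setNames(numeric(length(taxa)), taxa)
    return(structure(list(targets = character(0), modes = character(0),
                          is = 0, steady_state = baseline,
                          trajectory = NULL, minus_x_prime = zero,
                          delta_x = zero, recovered_flags = NULL,
                          converged = TRUE),
                     class = "intervention_result"))
  }
  if (length(modes) == 1) modes <- stats::setNames(rep(modes,
                                                       length(targets)),
                                                   targets)
  modes <- modes[targets]
  if (!all(modes %in% c("remove", "add"))) {
    stop("modes must be 'remove' or 'add'")
  }
  if (is.null(add_levels)) add_levels <- reference
  clamps <- vapply(targets, function(t) {
    if (modes[t] == "remove") 0 else as.numeric(add_levels[t])
  }, numeric(1))
  sim <- simulate_to_steady_state(model, baseline, clamps = clamps,
                                  t_max = ctl$t_max, dt = ctl$dt,
                                  tol = ctl$tol, method = ctl$method,
                                  record_every = ctl$record_every)
  post <- sim$steady_state
  is_val <- intervention_score(
    baseline, post, reference, weights = weights,
    targets = if (exclude_targets) targets else character(0)
  )
  flags <- NULL
  if (!is.null(normal_quartiles)) {
    p <- post / max(sum(post), .Machine$double.eps)
    flags <- p >= normal_quartiles["Q1", taxa] &
      p <= normal_quartiles["Q3", taxa]
    names(flags) <- taxa
  }
  structure(
    list(targets = targets, modes = modes, is = is_val, steady_state = post,
         trajectory = sim$trajectory,
         minus_x_prime = instant_response(model, baseline, clamps),
         delta_x = post - baseline, recovered_flags = flags,
         converged = sim$converged),
    class = "intervention_result"
  )
}

#' @export
print.intervention_result <- function(x, ...) {
  cat("intervention_result: targets {",
      paste(x$targets, collapse = ", "), "} IS =",
      formatC(x$is, digits = 4, format = "f"), "\n")
  invisible(x)
}

#' Interquartile range of a group's relative abundances
#'
#' Convenience helper producing the `normal_quartiles` matrix consumed by
#' [run_intervention()].
#'
#' @param x An `abundance_table`.
#' @param label Group label (e.g. the healthy-control group).
#' @return Matrix with rows `Q1`, `Q3` and one column per taxon.
#' @export
group_quartiles <- function(x, label) {
  rel <- if (x$relative) x else to_relative(x)
  g <- subset_group(rel, label)
  q <- apply(g$counts, 1, stats::quantile, probs = c(0.25, 0.75),
             names = FALSE)
  rownames(q) <- c("Q1", "Q3")
  q
}

#' Mean relative-abundance profile of a group
#'
#' @param x An `abundance_table`.
#' @param label Group label.
#' @return Named vector of mean relative abundances.
#' @export
group_profile <- function(x, label) {
  rel <- if (x$relative) x else to_relative(x)
  g <- subset_group(rel, label)
  rowMeans(g$counts)
}
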