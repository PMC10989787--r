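#' Combination intervention score (CIS)
#'
#' IS of the simultaneous intervention on a whole target set, each target
#' clamped according to its differential-direction mode. A single target's
#' CIS equals its IS; the empty set scores 0.
#'
#' @inheritParams run_intervention
#' @param ... Passed to [run_intervention()].
#' @return CIS, a scalar `<= 1`.
#' @export
combination_intervention_score <- function(model, targets, modes = "remove",
                                           baseline, reference,
                                           weights = NULL, ...) {
  run_intervention(model, targets, modes = modes, baseline = baseline,
                   reference = reference, weights = weights, ...)$is
}

#' Greedy keystone-species selection
#'
#' Forward selection over the candidate taxa: at every step the candidate
#' with the largest marginal CIS gain joins the set. When no single
#' candidate has a positive gain, a pairwise lookahead is tried (all pairs
#' of remaining candidates; interventions on antagonistic species often only
#' pay off jointly, e.g. removing one of two blooming competitors releases
#' the other); the best positive pair joins as one step. Selection stops
#' when the cumulative CIS exceeds `cis_threshold` (strict, matching the
#' "greater than 0.9" stopping rule), when neither a single candidate nor a
#' pair yields a positive gain, or when `max_k` species are selected. Ties
#' are broken by the larger single-species IS, then by taxon identifier.
#'
#' @inheritParams run_intervention
#' @param candidates Candidate taxa (default: all model taxa).
#' @param cis_threshold Stop once cumulative CIS exceeds this; default 0.9.
#' @param max_k Maximum set size; default 10.
#' @param lookahead_trigger Pairwise lookahead runs whenever the best
#'   single-candidate gain falls at or below this (default 0.05); the step
#'   takes whichever of the best single or best pair reaches the higher
#'   CIS.
#' @param ... Passed to [run_intervention()].
#' @return A `keystone_selection`: data.frame `rank`, `taxon`, `mode`,
#'   `gain`, `cis` with attributes `stop_reason`
#'   (`"threshold_reached"`, `"no_positive_gain"`, or `"max_k"`) and
#'   `single_is` (named vector of single-species ISs).
#' @export
select_keystones <- function(model, candidates = NULL, modes = "remove",
                             baseline, reference, weights = NULL,
                             cis_threshold = 0.9, max_k = 10,
                             lookahead_trigger = 0.05, ...) {
  stopifnot(inherits(model, "glv_model"))
  if (is.null(candidates)) candidates <- model$taxa
  candidates <- as.character(candidates)
  if (!length(candidates)) stop("candidates must be non-empty")
  if (length(modes) == 1) {
    modes <- stats::setNames(rep(modes, length(candidates)), candidates)
  }
  score <- function(set) {
    combination_intervention_score(model, set, modes = modes[set],
                                   baseline = baseline,
                                   reference = reference,
                                   weights = weights, ...)
  }
  single_is <- vapply(candidates, function(t) score(t), numeric(1))
  selected <- character(0)
  cis <- 0
  curve <- numeric(0)
  gains <- numeric(0)
  stop_reason <- "max_k"
  while (length(selected) < max_k) {
    pool <- setdiff(candidates, selected)
    if (!length(pool)) {
      stop_reason <- "max_k"
      break
    }
    trial <- vapply(pool, function(t) score(c(selected, t)), numeric(1))
    gain <- trial - cis
    best <- max(gain)
    if (best <= lookahead_trigger) {
      # single steps are stalling; see whether any pair does better
      picked_pair <- NULL
      pair_best <- -Inf
      if (length(pool) >= 2 && length(selected) + 2 <= max_k) {
        pairs <- utils::combn(pool, 2, simplify = FALSE)
        pair_cis <- vapply(pairs, function(pr) score(c(selected, pr)),
                           numeric(1))
        pair_best <- max(pair_cis)
        if (pair_best > cis && pair_best > cis + best) {
          picked_pair <- pairs[[which.max(pair_cis)]]
        }
      }
      if (!is.null(picked_pair)) {
        # the pair joins as one step: both rows report the post-pair CIS,
        # with the joint gain split evenly
        joint_gain <- pair_best - cis
        selected <- c(selected, picked_pair)
        curve <- c(curve, pair_best, pair_best)
        gains <- c(gains, joint_gain / 2, joint_gain / 2)
        cis <- pair_best
        if (cis > cis_threshold) {
          stop_reason <- "threshold_reached"
          break
        }
        next
      }
      if (best <= 0) {
        stop_reason <- "no_positive_gain"
        break
      }
    }
    tied <- pool[gain >= best - 1e-12]
    if (length(tied) > 1) {
      tied <- tied[order(-single_is[tied], tied)]
    }
    pick <- tied[1]
    selected <- c(selected, pick)
    cis <- trial[pick]
    curve <- c(curve, cis)
    gains <- c(gains, gain[pick])
    if (cis > cis_threshold) {
      stop_reason <- "threshold_reached"
      break
    }
  }
  res <- data.frame(
    rank = seq_along(selected),
    taxon = selected,
    mode = if (length(selected)) unname(modes[selected]) else character(0),
    gain = gains,
    cis = curve,
    stringsAsFactors = FALSE
  )
  structure(res, class = c("keystone_selection", "data.frame"),
            stop_reason = stop_reason, single_is = single_is,
            cis_threshold = cis_threshold)
}

#' @export
print.keystone_selection <- function(x, ...) {
  cat("keystone_selection:", nrow(x), "species, final CIS =",
      if (nrow(x)) formatC(x$cis[nrow(x)], digits = 4, format = "f") else 0,
      "( stop:", attr(x, "stop_reason"), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Backward elimination of redundant keystones
#'
#' Repeatedly drops the selection member whose removal decreases the CIS the
#' least, as long as that decrease does not exceed `tol` (i.e. the member
#' contributes nothing), until a fixed point.
#'
#' @param selection A `keystone_selection`.
#' @inheritParams select_keystones
#' @param tol Maximum CIS loss considered "no decrease"; default 1e-6.
#' @param ... Passed to [run_intervention()].
#' @return A pruned `keystone_selection` (stop reason preserved; CIS curve
#'   recomputed over the remaining members in their original order).
#' @export
backward_eliminate <- function(selection, model, modes = NULL, baseline,
                               reference, weights = NULL, tol = 1e-6, ...) {
  stopifnot(inherits(selection, "keystone_selection"))
  if (is.null(modes)) {
    modes <- stats::setNames(selection$mode, selection$taxon)
  }
  score <- function(set) {
    if (!length(set)) return(0)
    combination_intervention_score(model, set, modes = modes[set],
                                   baseline = baseline,
                                   reference = reference,
                                   weights = weights, ...)
  }
  members <- selection$taxon
  current <- score(members)
  repeat {
    if (length(members) <= 1) break
    drops <- vapply(members, function(t) score(setdiff(members, t)),
                    numeric(1))
    loss <- current - drops
    k <- which.min(loss)
    if (loss[k] > tol) break
    members <- setdiff(members, members[k])
    current <- drops[k]
  }
  curve <- vapply(seq_along(members),
                  function(k) score(members[seq_len(k)]), numeric(1))
  res <- data.frame(
    rank = seq_along(members),
    taxon = members,
    mode = unname(modes[members]),
    gain = diff(c(0, curve)),
    cis = curve,
    stringsAsFactors = FALSE
  )
  structure(res, class = c("keystone_selection", "data.frame"),
            stop_reason = attr(selection, "stop_reason"),
            single_is = attr(selection, "single_is"),
            cis_threshold = attr(selection, "cis_threshold"))
}

#' Write a keystone selection report
#'
#' TSV (rank, taxon, mode, gain, cis) plus a JSON record with the stop
#' reason and single-species ISs.
#'
#' @param selection A `keystone_selection`.
#' @param path_tsv,path_json Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_keystone_selection <- function(selection, path_tsv = NULL,
                                     path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(as.data.frame(selection), path_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(keystones = as.data.frame(selection),
           stop_reason = attr(selection, "stop_reason"),
           cis_threshold = attr(selection, "cis_threshold"),
           single_is = as.list(attr(selection, "single_is"))),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(c(path_tsv, path_json))
}
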