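#' Fit a gLV interaction model to cross-sectional abundances
#'
#' Treats every sample as an (approximate) equilibrium of one shared gLV
#' model, so for each taxon `i` the samples with `x_i > 0` supply the
#' steady-state constraints `0 = r_i + sum_j a_ij x_j`. Each row of the
#' constraint system identifies `(r_i, a_i.)` only up to a positive scale,
#' so the self-limitation term is normalized to `a_ii = -1` and the row is
#' estimated as the ridge regression
#' `x_i ~ r_i + sum_{j in N(i)} a_ij x_j`,
#' where `N(i)` are the prior-network neighbors of `i`. Including all prior
#' neighbors of the response jointly adjusts for the measured confounders of
#' each putative interaction (graphical-model backdoor adjustment).
#'
#' The ridge penalty applies to the standardized off-diagonal coefficients;
#' the intercept `r_i` is unpenalized. Constant regressors are dropped from
#' the row fit (their coefficient is 0).
#'
#' @param x An `abundance_table` (relative abundances recommended).
#' @param prior A `prior_network` on the same taxa, or a list of per-taxon
#'   regressor index vectors (directed support: `support[[i]]` = sources
#'   allowed to act on taxon `i`).
#' @param ridge Ridge penalty on standardized regressors; default 0.01.
#' @param min_positive Minimum samples with `x_i > 0` for a full row fit;
#'   below this the row is fit as pure self-limitation with a warning.
#' @return A `glv_model` with attributes `support` (per-row regressor
#'   indices) and `ridge`.
#' @export
fit_glv_from_crosssection <- function(x, prior, ridge = 0.01,
                                      min_positive = 3) {
  validate_abundance_table(x)
  taxa <- taxa_names(x)
  d <- length(taxa)
  support <- if (inherits(prior, "prior_network")) {
    if (!identical(prior$taxa, taxa)) {
      stop("prior network taxa do not match the abundance table")
    }
    prior_neighbor_list(prior)
  } else {
    prior
  }
  stopifnot(length(support) == d)
  m <- x$counts
  r <- numeric(d)
  A <- matrix(0, d, d, dimnames = list(taxa, taxa))
  diag(A) <- -1
  low_n <- character(0)
  for (i in seq_len(d)) {
    pos <- which(m[i, ] > 0)
    nb <- support[[i]]
    if (length(pos) < min_positive || length(nb) == 0) {
      if (length(pos) < min_positive) low_n <- c(low_n, taxa[i])
      r[i] <- if (length(pos)) mean(m[i, pos]) else 0
      next
    }
    y <- m[i, pos]
    X <- t(m[nb, pos, drop = FALSE])
    fit <- ridge_row(X, y, ridge)
    A[i, nb] <- fit$beta
    r[i] <- fit$intercept
  }
  if (length(low_n)) {
    warning("taxa with fewer than ", min_positive,
            " positive samples fit as pure self-limitation: ",
            paste(low_n, collapse = ", "))
  }
  model <- glv_model(r, A, taxa = taxa)
  attr(model, "support") <- support
  attr(model, "ridge") <- ridge
  model
}

# Ridge regression with unpenalized intercept on standardized regressors.
# Returns coefficients on the original scale; constant columns get beta 0.
ridge_row <- function(X, y, ridge) {
  xm <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  keep <- which(xs > 1e-12)
  beta <- numeric(ncol(X))
  if (length(keep)) {
    Z <- scale(X[, keep, drop = FALSE], center = xm[keep], scale = xs[keep])
    yc <- y - mean(y)
    G <- crossprod(Z) + ridge * diag(length(keep))
    b <- tryCatch(solve(G, crossprod(Z, yc)),
                  error = function(e) stop("singular design despite ridge"))
    beta[keep] <- as.numeric(b) / xs[keep]
  }
  list(beta = beta, intercept = mean(y) - sum(beta * xm))
}

#' Permutation significance of fitted interactions
#'
#' For every supported directed edge `j -> i`, the source taxon `j`'s
#' abundances are permuted across the samples used in row `i`'s fit, the row
#' is refit, and `|a_ij|` is recorded; the add-one empirical p-value is
#' `(1 + #{|a_perm| >= |a_obs|}) / (1 + n_perm)`. With 1000 permutations the
#' smallest attainable p is 1/1001.
#'
#' @param model A fitted `glv_model` (from [fit_glv_from_crosssection()]).
#' @param x The `abundance_table` the model was fitted from.
#' @param n_perm Number of permutations; default 1000.
#' @param seed Optional integer seed.
#' @return data.frame `source`, `target`, `weight`, `p`, one row per
#'   supported directed edge.
#' @export
edge_significance <- function(model, x, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(model, "glv_model"))
  validate_abundance_table(x)
  taxa <- model$taxa
  support <- attr(model, "support")
  ridge <- attr(model, "ridge")
  if (is.null(support)) stop("model has no fitted support")
  if (!is.null(seed)) set.seed(seed)
  m <- x$counts
  out <- list()
  for (i in seq_along(taxa)) {
    nb <- support[[i]]
    if (!length(nb)) next
    pos <- which(m[i, ] > 0)
    if (length(pos) < 3) next
    y <- m[i, pos]
    X <- t(m[nb, pos, drop = FALSE])
    obs <- abs(model$A[i, nb])
    ge <- numeric(length(nb))
    for (b in seq_len(n_perm)) {
      for (k in seq_along(nb)) {
        Xp <- X
        Xp[, k] <- X[sample.int(length(pos)), k]
        bp <- ridge_row(Xp, y, ridge)$beta[k]
        if (abs(bp) >= obs[k]) ge[k] <- ge[k] + 1
      }
    }
    out[[length(out) + 1]] <- data.frame(
      source = taxa[nb], target = taxa[i],
      weight = unname(model$A[i, nb]),
      p = (1 + ge) / (1 + n_perm),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(source = character(0), target = character(0),
                      weight = numeric(0), p = numeric(0)))
  }
  do.call(rbind, out)
}

#' Iteratively prune and refit the causal interaction network
#'
#' Alternates fitting the prior-constrained gLV model, permutation-testing
#' every supported directed edge, and dropping edges with `p > alpha`, until
#' the edge set is stable or `max_rounds` is reached. The edge set never
#' grows across rounds.
#'
#' @inheritParams fit_glv_from_crosssection
#' @param alpha Edge significance level; default 0.01.
#' @param n_perm Permutations per significance round; default 1000.
#' @param max_rounds Maximum fit-test rounds; default 10.
#' @param seed Optional integer seed.
#' @return List: `model` (final `glv_model`), `network`
#'   (an `interaction_network`), `rounds` (rounds executed), `converged`.
#' @export
iterate_network <- function(x, prior, alpha = 0.01, n_perm = 1000,
                            max_rounds = 10, ridge = 0.01, seed = NULL) {
  validate_abundance_table(x)
  taxa <- taxa_names(x)
  support <- if (inherits(prior, "prior_network")) {
    prior_neighbor_list(prior)
  } else {
    prior
  }
  if (!is.null(seed)) set.seed(seed)
  model <- NULL
  sig <- NULL
  rounds <- 0
  converged <- FALSE
  repeat {
    rounds <- rounds + 1
    model <- suppressWarnings(
      fit_glv_from_crosssection(x, support, ridge = ridge)
    )
    sig <- edge_significance(model, x, n_perm = n_perm)
    keep <- sig[sig$p <= alpha, , drop = FALSE]
    new_support <- lapply(seq_along(taxa), function(i) {
      sort(match(keep$source[keep$target == taxa[i]], taxa))
    })
    if (identical(new_support, support)) {
      # the no-change round verifies stability and is counted
      rounds <- rounds + 1
      converged <- TRUE
      break
    }
    support <- new_support
    if (rounds >= max_rounds) {
      warning("edge set still changing after ", max_rounds,
              " rounds; returning the last iteration")
      model <- suppressWarnings(
        fit_glv_from_crosssection(x, support, ridge = ridge)
      )
      sig <- edge_significance(model, x, n_perm = n_perm)
      break
    }
  }
  # zero out pruned coefficients so the network equals the final support
  final <- sig[sig$p <= alpha, , drop = FALSE]
  net <- interaction_network(model, final, taxonomy = x$taxonomy)
  list(model = net$model, network = net$network, rounds = rounds,
       converged = converged)
}

# Rebuild the model restricted to significant edges and wrap it as an
# interaction_network.
interaction_network <- function(model, edges, taxonomy = NULL) {
  taxa <- model$taxa
  A <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  diag(A) <- diag(model$A)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      A[edges$target[e], edges$source[e]] <- edges$weight[e]
    }
  }
  m2 <- glv_model(model$r, A, taxa = taxa)
  attr(m2, "support") <- lapply(seq_along(taxa), function(i) {
    sort(match(edges$source[edges$target == taxa[i]], taxa))
  })
  attr(m2, "ridge") <- attr(model, "ridge")
  net <- structure(
    list(taxa = taxa,
         edges = data.frame(edges,
                            sign = ifelse(edges$weight >= 0, 1L, -1L)),
         taxonomy = taxonomy),
    class = "interaction_network"
  )
  list(model = m2, network = net)
}

#' Construct an interaction network from explicit edges
#'
#' Directed, signed, weighted graph over taxa; `source -> target` with
#' weight `a_(target,source)` from the fitted gLV model.
#'
#' @param taxa Character vector of node identifiers.
#' @param edges data.frame with columns `source`, `target`, `weight` and
#'   optionally `p`.
#' @param taxonomy Optional named lineage vector.
#' @return An `interaction_network`.
#' @export
make_interaction_network <- function(taxa, edges, taxonomy = NULL) {
  stopifnot(all(c("source", "target", "weight") %in% names(edges)))
  if (!all(edges$source %in% taxa) || !all(edges$target %in% taxa)) {
    stop("edge endpoints must be in taxa")
  }
  if (is.null(edges$p)) edges$p <- rep(NA_real_, nrow(edges))
  structure(
    list(taxa = taxa,
         edges = data.frame(edges,
                            sign = ifelse(edges$weight >= 0, 1L, -1L)),
         taxonomy = taxonomy),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", length(x$taxa), "taxa,", nrow(x$edges),
      "directed edges (", sum(x$edges$sign > 0), "positive /",
      sum(x$edges$sign < 0), "negative )\n")
  invisible(x)
}

# |weight| adjacency with M[source, target]; rows/cols in network$taxa order.
hits_adjacency <- function(network) {
  taxa <- network$taxa
  M <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  e <- network$edges
  if (nrow(e)) {
    M[cbind(match(e$source, taxa), match(e$target, taxa))] <- abs(e$weight)
  }
  M
}

#' HITS hub and authority scores
#'
#' Power iteration of the HITS algorithm on the absolute-weight adjacency
#' matrix of the directed interaction network: authorities
#' `a <- t(M) h`, hubs `h <- M a`, each normalized to unit Euclidean norm,
#' iterated until the L2 change falls below `tol` (default 1e-10) or
#' `max_iter` (default 1000). The hub score quantifies the influence a
#' species exerts on others (out-direction); the authority score the
#' influence it receives.
#'
#' @param network An `interaction_network` (or a non-negative adjacency
#'   matrix, `M[source, target]`).
#' @param tol Convergence tolerance; default 1e-10.
#' @param max_iter Iteration cap; default 1000.
#' @return data.frame `taxon`, `hub`, `authority`.
#' @export
hits_scores <- function(network, tol = 1e-10, max_iter = 1000) {
  M <- if (is.matrix(network)) network else hits_adjacency(network)
  taxa <- rownames(M)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(M)))
  d <- nrow(M)
  if (all(M == 0)) {
    warning("empty network: all HITS scores are 0")
    return(data.frame(taxon = taxa, hub = numeric(d), authority = numeric(d),
                      stringsAsFactors = FALSE))
  }
  h <- rep(1 / sqrt(d), d)
  a <- rep(1 / sqrt(d), d)
  for (it in seq_len(max_iter)) {
    a_new <- as.numeric(crossprod(M, h))
    if (sum(a_new^2) > 0) a_new <- a_new / sqrt(sum(a_new^2))
    h_new <- as.numeric(M %*% a_new)
    if (sum(h_new^2) > 0) h_new <- h_new / sqrt(sum(h_new^2))
    delta <- sqrt(sum((h_new - h)^2)) + sqrt(sum((a_new - a)^2))
    h <- h_new
    a <- a_new
    if (delta < tol) break
  }
  data.frame(taxon = taxa, hub = h, authority = a, stringsAsFactors = FALSE)
}

#' Hub species by permutation test on HITS scores
#'
#' Generates a null distribution of HITS hub scores and flags species whose
#' observed hub score is significantly higher. Two nulls:
#' `"weight_shuffle"` (default) permutes the edge weights over the existing
#' edges, keeping the topology fixed; `"rewire"` redraws the edge endpoints
#' uniformly at random (same number of edges, no self-loops) and permutes
#' the weights. Per-node `p = (1 + #{hub_perm >= hub_obs}) / (1 + n_perm)`;
#' hubs are nodes with `p <= alpha`.
#'
#' @param network An `interaction_network`.
#' @param n_perm Number of permuted networks; default 1000.
#' @param alpha Hub significance level; default 0.01.
#' @param null `"weight_shuffle"` or `"rewire"`.
#' @param seed Optional integer seed.
#' @return data.frame `taxon`, `hub`, `authority`, `p`, `is_hub`.
#' @export
hub_significance <- function(network, n_perm = 1000, alpha = 0.01,
                             null = c("weight_shuffle", "rewire"),
                             seed = NULL) {
  null <- match.arg(null)
  stopifnot(inherits(network, "interaction_network"))
  if (!nrow(network$edges)) stop("network has no edges")
  if (!is.null(seed)) set.seed(seed)
  obs <- hits_scores(network)
  taxa <- network$taxa
  d <- length(taxa)
  ne <- nrow(network$edges)
  w <- abs(network$edges$weight)
  ge <- numeric(d)
  for (b in seq_len(n_perm)) {
    M <- matrix(0, d, d)
    if (null == "weight_shuffle") {
      src <- match(network$edges$source, taxa)
      tgt <- match(network$edges$target, taxa)
      M[cbind(src, tgt)] <- sample(w)
    } else {
      src <- sample.int(d, ne, replace = TRUE)
      tgt <- sample.int(d, ne, replace = TRUE)
      loop <- src == tgt
      while (any(loop)) {
        tgt[loop] <- sample.int(d, sum(loop), replace = TRUE)
        loop <- src == tgt
      }
      M[cbind(src, tgt)] <- M[cbind(src, tgt)] + sample(w)
    }
    hp <- hits_scores(M)$hub
    ge <- ge + (hp >= obs$hub)
  }
  p <- (1 + ge) / (1 + n_perm)
  data.frame(taxon = taxa, hub = obs$hub, authority = obs$authority, p = p,
             is_hub = p <= alpha, stringsAsFactors = FALSE)
}

#' Goodness of a power-law fit to the degree distribution
#'
#' Least-squares linear fit of `log(frequency)` on `log(degree)` over the
#' nonzero-frequency total degrees (in + out, unweighted). A high R-squared
#' indicates a heterogeneous, scale-free-like degree distribution.
#'
#' @param network An `interaction_network`.
#' @return R-squared of the log-log fit, or `NA` (with a warning) when fewer
#'   than 5 distinct positive degree values exist.
#' @export
degree_powerlaw_fit <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges
  deg <- table(factor(c(e$source, e$target), levels = network$taxa))
  deg <- as.numeric(deg)
  deg <- deg[deg > 0]
  tab <- table(deg)
  if (length(tab) < 5) {
    warning("fewer than 5 distinct degree values; power-law fit undefined")
    return(NA_real_)
  }
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  fit <- stats::lm(log(f) ~ log(k))
  summary(fit)$r.squared
}

#' Per-family positive/negative interaction tallies
#'
#' Counts, for every taxonomic family, the positive and negative directed
#' edges incident to at least one member of the family. An edge joining two
#' families is counted once for each; `positive + negative` equals the
#' family's total incident edges.
#'
#' @param network An `interaction_network` with taxonomy, or pass `taxonomy`
#'   explicitly (named lineage vector; the family is the `f__` field).
#' @param taxonomy Optional named lineage vector overriding the network's.
#' @return data.frame `family`, `positive`, `negative`.
#' @export
family_interaction_tallies <- function(network, taxonomy = NULL) {
  stopifnot(inherits(network, "interaction_network"))
  if (is.null(taxonomy)) taxonomy <- network$taxonomy
  if (is.null(taxonomy)) stop("no taxonomy available")
  fam <- vapply(taxonomy, lineage_family, character(1))
  e <- network$edges
  out <- list()
  for (f in sort(unique(fam))) {
    members <- names(fam)[fam == f]
    inc <- e$source %in% members | e$target %in% members
    out[[f]] <- data.frame(family = f,
                           positive = sum(inc & e$sign > 0),
                           negative = sum(inc & e$sign < 0),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Extract the family from a lineage string: prefer the "f__" field, fall
# back to the 5th semicolon-separated field, else "unassigned".
lineage_family <- function(lineage) {
  m <- regmatches(lineage, regexpr("f__[^;]*", lineage))
  if (length(m) && nzchar(sub("f__", "", m))) return(sub("f__", "", m))
  parts <- trimws(strsplit(lineage, ";")[[1]])
  if (length(parts) >= 5 && nzchar(parts[5])) return(parts[5])
  "unassigned"
}

#' Export an interaction network
#'
#' `write_network_tsv()` writes the directed edge list (source, target,
#' weight, sign, p); `write_network_graphml()` writes GraphML via igraph.
#'
#' @param network An `interaction_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "weight", "sign")],
    directed = TRUE,
    vertices = data.frame(name = network$taxa)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
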