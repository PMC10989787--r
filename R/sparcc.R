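#' SparCC basis correlations for compositional count data
#'
#' Estimates correlations between the (unobserved) absolute "basis"
#' abundances underlying compositional sequencing counts, following the
#' SparCC procedure: per-sample fractions are drawn from a Dirichlet
#' posterior over the pseudocounted counts, the log-ratio variation matrix
#' `t_ij = var(log(x_i/x_j))` is inverted for basis variances under a
#' sparsity assumption, and the single most strongly correlated pair is
#' iteratively excluded from the variance system before the final estimate.
#' The reported matrix is the elementwise median over `n_outer` Dirichlet
#' resamples.
#'
#' @param x An `abundance_table` of counts.
#' @param n_outer Number of Dirichlet resampling iterations (median taken);
#'   default 20.
#' @param exclusion_threshold Minimum |correlation| for a pair to be excluded
#'   from the basis-variance system; default 0.1.
#' @param n_exclusion_rounds Maximum exclusion rounds per estimate; default
#'   10.
#' @param pseudocount Added to every count before forming fractions; default
#'   1. May be 0 only when all counts are positive.
#' @param resample If `FALSE`, skip Dirichlet resampling and use the
#'   pseudocounted fractions directly (one deterministic point estimate;
#'   `n_outer` is ignored).
#' @param seed Optional integer seed for the Dirichlet draws.
#' @return Symmetric correlation matrix with unit diagonal, entries clipped
#'   to \[-1, 1\], dimnames = taxa. Taxa whose relative abundance is constant
#'   across samples get zero correlations, with a warning.
#' @export
sparcc_correlations <- function(x, n_outer = 20, exclusion_threshold = 0.1,
                                n_exclusion_rounds = 10, pseudocount = 1,
                                resample = TRUE, seed = NULL) {
  validate_abundance_table(x)
  counts <- x$counts
  d <- nrow(counts)
  if (d < 4) stop("SparCC basis-variance system requires at least 4 taxa")
  w <- counts + pseudocount
  if (any(w <= 0)) {
    stop("pseudocount must make all entries positive (use pseudocount > 0)")
  }
  frac0 <- sweep(w, 2, colSums(w), "/")
  degenerate <- apply(frac0, 1, function(v) stats::sd(v) < 1e-12)
  if (!is.null(seed)) set.seed(seed)
  if (resample) {
    est <- array(NA_real_, dim = c(d, d, n_outer))
    for (b in seq_len(n_outer)) {
      f <- apply(w, 2, function(col) {
        g <- stats::rgamma(d, shape = col, rate = 1)
        g / sum(g)
      })
      est[, , b] <- sparcc_single(log(f), exclusion_threshold,
                                  n_exclusion_rounds)
    }
    rho <- apply(est, c(1, 2), stats::median)
  } else {
    rho <- sparcc_single(log(frac0), exclusion_threshold, n_exclusion_rounds)
  }
  rho <- (rho + t(rho)) / 2
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  if (any(degenerate)) {
    warning("constant taxa set to zero correlation: ",
            paste(rownames(counts)[degenerate], collapse = ", "))
    rho[degenerate, ] <- 0
    rho[, degenerate] <- 0
    diag(rho) <- 1
  }
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  rho
}

# One SparCC basis-correlation estimate from a D x S log-fraction matrix.
sparcc_single <- function(logf, exclusion_threshold, n_exclusion_rounds,
                          var_min = 1e-4) {
  d <- nrow(logf)
  cv <- stats::cov(t(logf))
  vd <- diag(cv)
  tmat <- outer(vd, vd, "+") - 2 * cv  # variation matrix var(log xi/xj)
  inc <- matrix(TRUE, d, d)            # pair inclusion in variance system
  diag(inc) <- FALSE
  excl_count <- integer(d)
  rho <- basis_correlations(tmat, inc, var_min)
  for (round in seq_len(n_exclusion_rounds)) {
    cand <- abs(rho)
    cand[!inc] <- 0
    cand[lower.tri(cand, diag = TRUE)] <- 0
    # never strip a taxon below 3 remaining partners
    for (i in which(excl_count >= d - 3)) {
      cand[i, ] <- 0
      cand[, i] <- 0
    }
    m <- max(cand)
    if (m <= exclusion_threshold) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    inc[ij[1], ij[2]] <- inc[ij[2], ij[1]] <- FALSE
    excl_count[ij[1]] <- excl_count[ij[1]] + 1L
    excl_count[ij[2]] <- excl_count[ij[2]] + 1L
    rho <- basis_correlations(tmat, inc, var_min)
  }
  rho
}

# Solve the sparsity-approximated linear system for basis variances and
# convert the variation matrix into basis correlations.
basis_correlations <- function(tmat, inc, var_min) {
  d <- nrow(tmat)
  m <- matrix(0, d, d)
  m[inc] <- 1
  diag(m) <- rowSums(inc)
  tsum <- rowSums(tmat * inc)
  omega <- tryCatch(solve(m, tsum), error = function(e) rep(var_min, d))
  omega[omega < var_min] <- var_min
  so <- sqrt(omega)
  rho <- (outer(omega, omega, "+") - tmat) / (2 * outer(so, so))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}

#' Permutation p-values for SparCC correlations
#'
#' Two-sided permutation test of each pairwise basis correlation against the
#' null of no association: in each permutation every taxon's counts are
#' independently shuffled across samples (marginals preserved, all
#' associations broken) and the correlation matrix is recomputed. Both the
#' observed and the permuted statistics use the deterministic single-pass
#' point estimate (pseudocounted fractions, no Dirichlet resampling, no
#' exclusion refinement): the exclusion iteration is a point-estimate
#' polish whose basis-variance solve can degenerate on permuted data with
#' few taxa, clipping correlations to +/-1 and corrupting the null's tail.
#' The add-one estimator
#' `p = (1 + #{|rho_perm| >= |rho_obs|}) / (1 + n_perm)` keeps p away
#' from zero; with 1000 permutations the smallest attainable p is 1/1001.
#'
#' @inheritParams sparcc_correlations
#' @param n_perm Number of permutations (>= 100); default 1000.
#' @return Symmetric matrix of p-values (diagonal 1), dimnames = taxa.
#' @export
sparcc_pvalues <- function(x, n_perm = 1000, seed = NULL, pseudocount = 1,
                           exclusion_threshold = 0.1,
                           n_exclusion_rounds = 0) {
  validate_abundance_table(x)
  if (n_perm < 100) stop("n_perm must be at least 100")
  counts <- x$counts
  d <- nrow(counts)
  s <- ncol(counts)
  obs <- abs(sparcc_correlations(x, pseudocount = pseudocount,
                                 exclusion_threshold = exclusion_threshold,
                                 n_exclusion_rounds = n_exclusion_rounds,
                                 resample = FALSE))
  if (!is.null(seed)) set.seed(seed)
  ge <- matrix(0, d, d)
  perm_tab <- x
  for (b in seq_len(n_perm)) {
    pc <- counts
    for (i in seq_len(d)) pc[i, ] <- counts[i, sample.int(s)]
    perm_tab$counts <- pc
    rp <- abs(suppressWarnings(
      sparcc_correlations(perm_tab, pseudocount = pseudocount,
                          exclusion_threshold = exclusion_threshold,
                          n_exclusion_rounds = n_exclusion_rounds,
                          resample = FALSE)
    ))
    ge <- ge + (rp >= obs)
  }
  p <- (1 + ge) / (1 + n_perm)
  diag(p) <- 1
  dimnames(p) <- dimnames(obs)
  p
}

#' Build the undirected prior network
#'
#' Keeps the taxon pairs whose permutation p-value is at or below `alpha`
#' (threshold inclusive); these pairs constrain which directed interactions
#' the causal gLV fit may assign nonzero weight.
#'
#' @param rho Symmetric correlation matrix from [sparcc_correlations()].
#' @param pvals Symmetric p-value matrix from [sparcc_pvalues()].
#' @param alpha Significance level; default 0.01.
#' @return A `prior_network`: list with `taxa`, `rho`, `pvals`, and `edges`
#'   (data.frame `taxon_i`, `taxon_j`, `rho`, `p`; unordered pairs, i < j).
#' @export
build_prior_network <- function(rho, pvals, alpha = 0.01) {
  stopifnot(identical(dim(rho), dim(pvals)))
  taxa <- rownames(rho)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(rho)))
  ut <- which(upper.tri(pvals) & pvals <= alpha, arr.ind = TRUE)
  edges <- data.frame(
    taxon_i = taxa[ut[, 1]],
    taxon_j = taxa[ut[, 2]],
    rho = rho[ut],
    p = pvals[ut],
    stringsAsFactors = FALSE
  )
  structure(list(taxa = taxa, rho = rho, pvals = pvals, edges = edges,
                 alpha = alpha),
            class = "prior_network")
}

#' @export
print.prior_network <- function(x, ...) {
  cat("prior_network:", length(x$taxa), "taxa,", nrow(x$edges),
      "edges at p <=", x$alpha, "\n")
  invisible(x)
}

# Indices of the prior neighbors of taxon i (by position in prior$taxa).
prior_neighbor_list <- function(prior) {
  d <- length(prior$taxa)
  nb <- vector("list", d)
  for (k in seq_len(d)) nb[[k]] <- integer(0)
  if (nrow(prior$edges)) {
    ii <- match(prior$edges$taxon_i, prior$taxa)
    jj <- match(prior$edges$taxon_j, prior$taxa)
    for (e in seq_along(ii)) {
      nb[[ii[e]]] <- c(nb[[ii[e]]], jj[e])
      nb[[jj[e]]] <- c(nb[[jj[e]]], ii[e])
    }
  }
  lapply(nb, sort)
}
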