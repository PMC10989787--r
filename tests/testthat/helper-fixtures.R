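# Shared fixture builders for the test suite.

# Small abundance table with explicit counts (taxa x samples).
tiny_table <- function(counts, groups = NULL, taxonomy = NULL,
                       relative = FALSE) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("t%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  }
  abundance_table(counts, taxonomy = taxonomy, groups = groups,
                  relative = relative)
}

# Write a TSV abundance matrix to a temp file and return the path.
write_tsv_fixture <- function(counts, taxa = rownames(counts),
                              samples = colnames(counts)) {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(taxon = taxa, counts, check.names = FALSE)
  colnames(df) <- c("taxon", samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Deterministic two-taxon glv model: one directed interaction b -> a.
two_taxon_model <- function(a_ab = 0.5, x_star = c(1, 1)) {
  A <- rbind(c(-1, a_ab), c(0, -1))
  r <- as.numeric(-A %*% x_star)
  m <- glv_model(r, A, taxa = c("a", "b"))
  attr(m, "x_star") <- stats::setNames(x_star, m$taxa)
  m
}

# Directed star: center -> each of `n_leaves` leaves, unit weights.
star_network <- function(n_leaves = 3, center = "hub") {
  leaves <- sprintf("leaf%02d", seq_len(n_leaves))
  make_interaction_network(
    c(center, leaves),
    data.frame(source = center, target = leaves, weight = 1,
               stringsAsFactors = FALSE)
  )
}

# Random directed weighted network (no self-loops); d and edge count are
# drawn from the seed so cases are reproducible.
random_network <- function(seed, d = NULL, n_edges = NULL) {
  set.seed(seed)
  if (is.null(d)) d <- sample(3:6, 1)
  if (is.null(n_edges)) n_edges <- sample(4:12, 1)
  taxa <- sprintf("n%02d", seq_len(d))
  src <- sample.int(d, n_edges, replace = TRUE)
  tgt <- sample.int(d, n_edges, replace = TRUE)
  keep <- src != tgt
  src <- src[keep]
  tgt <- tgt[keep]
  dup <- duplicated(cbind(src, tgt))
  src <- src[!dup]
  tgt <- tgt[!dup]
  make_interaction_network(
    taxa,
    data.frame(source = taxa[src], target = taxa[tgt],
               weight = stats::runif(length(src), 0.2, 2),
               stringsAsFactors = FALSE)
  )
}

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of
# group-a ranks (independent oracle for the rank-sum test).
enumerate_ranksum_p <- function(a, b) {
  na <- length(a)
  vals <- c(a, b)
  n <- length(vals)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# AUC by explicit enumeration of all (case, control) pairs.
enumerate_auc <- function(case, control) {
  tot <- 0
  for (x in case) for (y in control) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(case) * length(control))
}

# Hypergeometric upper-tail p by brute-force summation of choose() terms
# (independent oracle for the one-sided Fisher test).
brute_hyper_tail <- function(k, m, n_set, n_bg) {
  jmax <- min(m, n_set)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j) {
    exp(lchoose(m, j) + lchoose(n_bg - m, n_set - j) - lchoose(n_bg, n_set))
  }, numeric(1)))
}
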