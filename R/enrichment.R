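#' Read a taxon-to-KO annotation table
#'
#' Consumes the PICRUST2-style output format: a TSV with columns
#' `taxon`, `KO` (and optionally `count`). Returns the per-taxon KO sets.
#'
#' @param path TSV path (header row expected).
#' @return Named list: taxon -> character vector of KO ids.
#' @export
read_ko_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("KO table needs at least (taxon, KO) columns")
  split(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a KO-to-KEGG-module map
#'
#' TSV with columns `module`, `KO`, and optionally `name`, `class`.
#'
#' @param path TSV path (header row expected).
#' @return A `module_map`: named list, module id -> list(`kos`, `name`,
#'   `class`).
#' @export
read_module_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("module map needs at least (module, KO) columns")
  ids <- unique(as.character(df[[1]]))
  mm <- lapply(ids, function(m) {
    rows <- df[[1]] == m
    list(kos = unique(as.character(df[[2]][rows])),
         name = if (ncol(df) >= 3) df[[3]][rows][1] else m,
         class = if (ncol(df) >= 4) df[[4]][rows][1] else NA_character_)
  })
  names(mm) <- ids
  structure(mm, class = "module_map")
}

#' KEGG-module enrichment by one-sided Fisher's exact test
#'
#' For every module, tests over-representation of the module's KOs in the
#' taxon's KO set against the background universe with the one-sided
#' (enrichment-direction) Fisher's exact test, i.e. the hypergeometric upper
#' tail of the 2x2 table (in-set x in-module). P-values are BH-adjusted
#' across modules; modules with FDR at or below `fdr_cut` are flagged
#' significantly enriched.
#'
#' @param ko_set Character vector of KO ids annotated to one taxon; KOs
#'   outside `background` are ignored.
#' @param module_map A `module_map` (see [read_module_map()]) or a named
#'   list of KO-id vectors.
#' @param background KO universe; modules are intersected with it. Defaults
#'   to the union of all module KOs and `ko_set`.
#' @param fdr_cut Significance cutoff on the FDR; default 0.01.
#' @return data.frame `module`, `name`, `class`, `overlap`, `module_size`,
#'   `set_size`, `background_size`, `odds_ratio`, `p`, `fdr`, `significant`.
#' @export
fisher_module_enrichment <- function(ko_set, module_map, background = NULL,
                                     fdr_cut = 0.01) {
  kos <- if (inherits(module_map, "module_map") ||
             is.list(module_map[[1]])) {
    lapply(module_map, `[[`, "kos")
  } else {
    module_map
  }
  if (is.null(background)) {
    background <- unique(c(unlist(kos, use.names = FALSE), ko_set))
  }
  background <- unique(as.character(background))
  # KOs outside the background universe carry no information for the 2x2
  # tables and are dropped, so they change no module's p-value
  ko_set <- intersect(unique(as.character(ko_set)), background)
  n_bg <- length(background)
  n_set <- length(ko_set)
  rows <- lapply(names(kos), function(mid) {
    mod <- intersect(kos[[mid]], background)
    m <- length(mod)
    k <- length(intersect(ko_set, mod))
    # hypergeometric upper tail: P(overlap >= k)
    p <- if (n_set == 0 || m == 0) 1 else {
      stats::phyper(k - 1, m, n_bg - m, n_set, lower.tail = FALSE)
    }
    b <- n_set - k          # in set, not in module
    c_ <- m - k             # in module, not in set
    d <- n_bg - m - b       # neither
    or <- if (b == 0 || c_ == 0) Inf else (k * d) / (b * c_)
    if (k == 0) or <- 0
    data.frame(module = mid,
               name = if (inherits(module_map, "module_map"))
                 module_map[[mid]]$name else mid,
               class = if (inherits(module_map, "module_map"))
                 module_map[[mid]]$class else NA_character_,
               overlap = k, module_size = m, set_size = n_set,
               background_size = n_bg, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr <= fdr_cut
  res[order(res$p), ]
}
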