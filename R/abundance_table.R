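#' Construct an abundance table
#'
#' Container for a taxon-by-sample abundance matrix with per-taxon taxonomy
#' lineages and per-sample group labels. Rows are taxa (OTUs), columns are
#' samples; values are read counts or relative abundances.
#'
#' @param counts Numeric matrix, taxa in rows, samples in columns. Row and
#'   column names are required and must be unique; all values non-negative.
#' @param taxonomy Named character vector mapping taxon id to a lineage
#'   string (e.g. `"d__...;p__...;...;f__Lachnospiraceae;..."`). Missing taxa
#'   are filled with `"unassigned"`.
#' @param groups Named character vector mapping sample id to a group label.
#'   Missing samples are filled with `"ungrouped"`.
#' @param relative Logical; `TRUE` if the columns are relative abundances
#'   (each column must then sum to 1 within 1e-9).
#' @return An object of class `abundance_table`: a list with elements
#'   `counts`, `taxonomy`, `groups`, `relative`.
#' @export
abundance_table <- function(counts, taxonomy = NULL, groups = NULL,
                            relative = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  taxa <- rownames(counts)
  samples <- colnames(counts)
  if (is.null(taxa) || is.null(samples)) {
    stop("counts must have taxon row names and sample column names")
  }
  tax <- rep("unassigned", length(taxa))
  names(tax) <- taxa
  if (!is.null(taxonomy)) {
    hit <- intersect(names(taxonomy), taxa)
    tax[hit] <- unname(taxonomy[hit])
  }
  grp <- rep("ungrouped", length(samples))
  names(grp) <- samples
  if (!is.null(groups)) {
    hit <- intersect(names(groups), samples)
    grp[hit] <- unname(groups[hit])
  }
  x <- structure(
    list(counts = counts, taxonomy = tax, groups = grp,
         relative = isTRUE(relative)),
    class = "abundance_table"
  )
  validate_abundance_table(x)
  x
}

#' Validate an abundance table
#'
#' Checks the class invariants: non-negative finite values, unique taxon and
#' sample identifiers, complete taxonomy and group annotation, and unit
#' column sums when the table is flagged relative.
#'
#' @param x An `abundance_table`.
#' @return `x`, invisibly; errors describe the offending row/column.
#' @export
validate_abundance_table <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  counts <- x$counts
  taxa <- rownames(counts)
  samples <- colnames(counts)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon identifier(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (any(!is.finite(counts))) {
    bad <- which(!is.finite(counts), arr.ind = TRUE)[1, ]
    stop("non-finite abundance for taxon '", taxa[bad[1]],
         "' in sample '", samples[bad[2]], "'")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance for taxon '", taxa[bad[1]],
         "' in sample '", samples[bad[2]], "'")
  }
  if (!setequal(names(x$taxonomy), taxa)) {
    stop("taxonomy must cover every taxon")
  }
  if (!setequal(names(x$groups), samples)) {
    stop("groups must cover every sample")
  }
  if (x$relative) {
    cs <- colSums(counts)
    off <- which(abs(cs - 1) > 1e-9)
    if (length(off)) {
      stop("relative table has column(s) not summing to 1: ",
           paste(samples[off], collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$counts), "taxa x", ncol(x$counts),
      "samples", if (x$relative) "(relative)" else "(counts)", "\n")
  grp <- table(x$groups)
  cat("groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      "\n")
  invisible(x)
}

#' Taxon and sample accessors
#' @param x An `abundance_table`.
#' @return Character vector of taxon (resp. sample) identifiers.
#' @export
taxa_names <- function(x) rownames(x$counts)

#' @rdname taxa_names
#' @export
sample_names <- function(x) colnames(x$counts)

#' Read an abundance table
#'
#' TSV dialect: first column holds taxon identifiers, header row holds sample
#' identifiers, remaining cells are numeric abundances. BIOM files are read
#' through the `biomformat` package (JSON or HDF5, BIOM 1.0/2.1).
#'
#' @param path Path to the abundance matrix.
#' @param format `"tsv"` (default) or `"biom"`.
#' @param taxonomy_path Optional 2-column TSV (taxon, lineage), no header.
#' @param groups_path Optional 2-column TSV (sample, label), no header.
#' @param relative Logical flag forwarded to [abundance_table()].
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom"),
                                 taxonomy_path = NULL, groups_path = NULL,
                                 relative = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    counts <- as.matrix(biomformat::biom_data(b))
  } else {
    if (file.size(path) == 0) stop("empty abundance file: ", path)
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) {
      stop("malformed header in ", path,
           ": need a taxon-id column plus at least one sample column")
    }
    ids <- as.character(df[[1]])
    num <- df[, -1, drop = FALSE]
    for (j in seq_along(num)) {
      v <- suppressWarnings(as.numeric(num[[j]]))
      if (anyNA(v) && !anyNA(num[[j]])) {
        stop("non-numeric abundance in column '", colnames(num)[j],
             "' of ", path)
      }
      num[[j]] <- v
    }
    counts <- as.matrix(num)
    rownames(counts) <- ids
  }
  taxonomy <- groups <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- utils::read.delim(taxonomy_path, header = FALSE,
                            stringsAsFactors = FALSE)
    taxonomy <- stats::setNames(as.character(tx[[2]]), as.character(tx[[1]]))
  }
  if (!is.null(groups_path)) {
    gr <- utils::read.delim(groups_path, header = FALSE,
                            stringsAsFactors = FALSE)
    groups <- stats::setNames(as.character(gr[[2]]), as.character(gr[[1]]))
  }
  abundance_table(counts, taxonomy = taxonomy, groups = groups,
                  relative = relative)
}

#' Write an abundance table as TSV
#'
#' Inverse of [read_abundance_table()]: first column `taxon`, one column per
#' sample. Integer counts round-trip bit-exactly.
#'
#' @param x An `abundance_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  df <- data.frame(taxon = taxa_names(x), x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter taxa by sample coverage
#'
#' Sample coverage of a taxon is the fraction of samples in which it is
#' detected (count strictly greater than zero). Taxa with coverage below
#' `min_coverage` are dropped; the comparison is inclusive (coverage equal to
#' the threshold is retained), and the sample set is unchanged.
#'
#' @param x An `abundance_table`.
#' @param min_coverage Fraction in \[0, 1\]; default 0.5.
#' @return Filtered `abundance_table`.
#' @export
filter_by_coverage <- function(x, min_coverage = 0.5) {
  validate_abundance_table(x)
  if (!is.numeric(min_coverage) || length(min_coverage) != 1 ||
      min_coverage < 0 || min_coverage > 1) {
    stop("min_coverage must be a single number in [0, 1]")
  }
  cov <- rowMeans(x$counts > 0)
  keep <- cov >= min_coverage
  if (!any(keep)) {
    stop("coverage filter removed all taxa; relax min_coverage (",
         min_coverage, ")")
  }
  abundance_table(x$counts[keep, , drop = FALSE],
                  taxonomy = x$taxonomy[keep],
                  groups = x$groups, relative = FALSE)
}

#' Convert counts to relative abundances
#'
#' Divides every sample column by its sum and sets the `relative` flag.
#' Applying it to an already-relative table is a no-op.
#'
#' @param x An `abundance_table`.
#' @return An `abundance_table` with unit column sums.
#' @export
to_relative <- function(x) {
  validate_abundance_table(x)
  cs <- colSums(x$counts)
  zero <- which(cs <= 0)
  if (length(zero)) {
    stop("sample(s) with zero total abundance: ",
         paste(sample_names(x)[zero], collapse = ", "))
  }
  abundance_table(sweep(x$counts, 2, cs, "/"), taxonomy = x$taxonomy,
                  groups = x$groups, relative = TRUE)
}

#' Subset an abundance table to one or more groups
#'
#' @param x An `abundance_table`.
#' @param labels Group labels to keep.
#' @return An `abundance_table` with only the matching samples.
#' @export
subset_group <- function(x, labels) {
  keep <- x$groups %in% labels
  if (!any(keep)) stop("no samples with group label(s): ",
                       paste(labels, collapse = ", "))
  abundance_table(x$counts[, keep, drop = FALSE], taxonomy = x$taxonomy,
                  groups = x$groups[keep], relative = x$relative)
}
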