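#' Collapse probe-level intensities to gene level
#'
#' Microarray platforms measure several probe sets per gene. Gene-level
#' expression is taken from the probe with the maximum signal: for each gene,
#' the whole row of the probe whose mean intensity across samples is largest
#' is kept. Whole-row selection (rather than a per-sample maximum) preserves
#' the within-probe covariance structure. Ties are broken by lexicographic
#' probe id; probes absent from the map are dropped with a message.
#'
#' @param probe_data a data frame: first column probe id, then one numeric
#'   column per sample.
#' @param probe_map a data frame with columns `probe_id`, `gene_symbol`;
#'   each probe maps to exactly one gene (many probes per gene allowed).
#' @param platform platform label for the returned table.
#' @return an expression table in intensity units, one row per mapped gene.
#' @export
collapse_probes <- function(probe_data, probe_map, platform = "reference") {
  probe_data <- as_tibble(probe_data)
  names(probe_data)[1L] <- "probe_id"
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe_id)) {
    abort("probe_map assigns some probe to more than one gene")
  }
  n_unmapped <- sum(!probe_data$probe_id %in% probe_map$probe_id)
  if (n_unmapped == nrow(probe_data)) {
    abort("no probe in the matrix is present in the probe map")
  }
  if (n_unmapped > 0L) {
    inform(sprintf("collapse_probes: dropping %d unmapped probe(s)", n_unmapped))
  }
  smp <- names(probe_data)[-1L]
  collapsed <- probe_data |>
    dplyr::inner_join(as_tibble(probe_map), by = "probe_id") |>
    dplyr::mutate(.mean_signal = rowMeans(dplyr::pick(dplyr::all_of(smp)))) |>
    dplyr::arrange(.data$gene_symbol, dplyr::desc(.data$.mean_signal), .data$probe_id) |>
    dplyr::distinct(.data$gene_symbol, .keep_all = TRUE) |>
    dplyr::select(gene = "gene_symbol", dplyr::all_of(smp))
  as_expression_table(collapsed, platform = platform, unit = "intensity")
}

#' Remove low-expressed genes from a TPM table
#'
#' Genes whose mean TPM across samples is strictly below the threshold are
#' excluded; a mean of exactly the threshold is retained. Gene order is
#' preserved; the number of removed genes is attached as the
#' `removed_genes` attribute and reported.
#'
#' @param x an expression table in TPM units.
#' @param min_mean_tpm removal threshold on the mean TPM (default 2).
#' @return the filtered expression table.
#' @export
filter_low_tpm <- function(x, min_mean_tpm = 2) {
  assert_unit(x, "TPM")
  keep <- rowMeans(expr_values(x)) >= min_mean_tpm
  removed <- sum(!keep)
  if (removed > 0L) {
    inform(sprintf("filter_low_tpm: removed %d gene(s) with mean TPM < %g",
                   removed, min_mean_tpm))
  }
  out <- as_expression_table(x[keep, , drop = FALSE],
                             platform = expr_platform(x), unit = "TPM")
  attr(out, "removed_genes") <- removed
  out
}

#' Log2-transform an expression table
#'
#' Applies `value -> log2(value + pseudocount)` and relabels the unit as
#' `log2`. With the default pseudocount of 1, a TPM of 0 maps to a log2
#' value of exactly 0, so dropout zeros are visible as zeros downstream.
#'
#' @param x an expression table in intensity or TPM units.
#' @param pseudocount non-negative offset added before taking logs.
#' @return the transformed table with unit `log2`.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "gc_expr"))
  if (identical(expr_unit(x), "log2")) abort("table is already on the log2 scale")
  m <- expr_values(x)
  if (any(m < 0, na.rm = TRUE)) abort("negative expression values cannot be log2-transformed")
  new_expr_from_matrix(log2(m + pseudocount), x, unit = "log2")
}

#' Restrict two platforms to their common genes and samples
#'
#' Both tables are cut down to the genes and samples present on both
#' platforms, identically ordered (order of appearance in `a`).
#'
#' @param a,b expression tables on the log2 scale.
#' @return a list with elements `a` and `b`, the matched tables.
#' @export
intersect_platforms <- function(a, b) {
  assert_unit(a, "log2", "a")
  assert_unit(b, "log2", "b")
  genes <- intersect(expr_genes(a), expr_genes(b))
  samples <- intersect(expr_samples(a), expr_samples(b))
  if (length(genes) == 0L) abort("no genes are shared between the two platforms")
  if (length(samples) == 0L) abort("no samples are shared between the two platforms")
  take <- function(x) {
    m <- expr_values(x)[genes, samples, drop = FALSE]
    new_expr_from_matrix(m, x)
  }
  list(a = take(a), b = take(b))
}

#' Per-sample cross-platform correlation QC
#'
#' For each shared sample, the Pearson and Spearman correlations between the
#' two platforms' expression vectors over the common genes — the
#' sample-level reproducibility check run before any signature work. Samples
#' with a constant vector on either platform get missing correlations and
#' are excluded from the reported medians (attached as attributes
#' `median_pearson` / `median_spearman`).
#'
#' @param a,b matched expression tables (see [intersect_platforms()]).
#' @return a tibble with columns `sample_id`, `pearson`, `spearman`.
#' @export
sample_concordance <- function(a, b) {
  ma <- expr_values(a); mb <- expr_values(b)
  if (!identical(dim(ma), dim(mb)) || !identical(colnames(ma), colnames(mb)) ||
      !identical(rownames(ma), rownames(mb))) {
    abort("a and b must be matched tables; run intersect_platforms() first")
  }
  pearson <- col_cor(ma, mb)
  spearman <- col_cor(apply(ma, 2L, rank), apply(mb, 2L, rank))
  out <- tibble(sample_id = colnames(ma), pearson = pearson, spearman = spearman)
  attr(out, "median_pearson") <- median(pearson, na.rm = TRUE)
  attr(out, "median_spearman") <- median(spearman, na.rm = TRUE)
  out
}

# column-wise Pearson correlation between paired matrices; constant columns -> NA
col_cor <- function(A, B) {
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  den <- sqrt(colSums(A^2) * colSums(B^2))
  unname(ifelse(den == 0, NA_real_, colSums(A * B) / den))
}

# row-wise analogue, used for per-gene cross-platform correlation
row_cor <- function(A, B) {
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  den <- sqrt(rowSums(A^2) * rowSums(B^2))
  unname(ifelse(den == 0, NA_real_, rowSums(A * B) / den))
}
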