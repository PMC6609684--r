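#' Expression tables
#'
#' The package represents a genes-by-samples expression profile as a tibble
#' whose first column, `gene`, holds unique gene symbols and whose remaining
#' columns are numeric, one per sample. Two pieces of provenance travel with
#' the table as attributes: `platform` (`"reference"` for the intensity-scale
#' microarray-like platform, `"target"` for the TPM-scale RNA-seq-like one)
#' and `unit` (one of `"intensity"`, `"TPM"`, `"log2"`). Units change only
#' through the declared transforms ([log2_transform()] and friends), so a
#' score computed on a table labelled `log2` really is on the log2 scale.
#'
#' @param data a data frame with a `gene` character column followed by
#'   numeric sample columns.
#' @param platform platform label, typically `"reference"` or `"target"`.
#' @param unit expression unit: `"intensity"`, `"TPM"` or `"log2"`.
#' @return `as_expression_table()` returns the validated table with class
#'   `gc_expr`; accessors return the corresponding component.
#' @examples
#' x <- as_expression_table(
#'   tibble::tibble(gene = c("VIM", "ZEB1"), S1 = c(1, 2), S2 = c(3, 4)),
#'   platform = "target", unit = "TPM"
#' )
#' expr_unit(x)
#' expr_samples(x)
#' @export
as_expression_table <- function(data, platform, unit = c("intensity", "TPM", "log2")) {
  unit <- match.arg(unit)
  data <- as_tibble(as.data.frame(data, check.names = FALSE, optional = TRUE))
  if (ncol(data) < 2L) {
    abort("an expression table needs a `gene` column plus at least one sample column")
  }
  names(data)[1L] <- "gene"
  data$gene <- as.character(data$gene)
  dup <- unique(data$gene[duplicated(data$gene)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate gene rows: ", paste(head(dup, 5L), collapse = ", ")))
  }
  smp <- names(data)[-1L]
  if (anyDuplicated(smp)) {
    abort("duplicate sample columns in expression table")
  }
  bad <- smp[!vapply(data[smp], is.numeric, logical(1L))]
  if (length(bad) > 0L) {
    abort(paste0("non-numeric sample column(s): ", paste(head(bad, 5L), collapse = ", ")))
  }
  if (unit == "TPM") {
    neg <- vapply(data[smp], function(v) any(v < 0, na.rm = TRUE), logical(1L))
    if (any(neg)) abort("TPM values must be >= 0")
  }
  structure(data,
    class = c("gc_expr", class(data)),
    platform = platform, unit = unit
  )
}

#' @rdname as_expression_table
#' @param x a `gc_expr` expression table.
#' @export
expr_unit <- function(x) attr(x, "unit")

#' @rdname as_expression_table
#' @export
expr_platform <- function(x) attr(x, "platform")

#' @rdname as_expression_table
#' @export
expr_genes <- function(x) x$gene

#' @rdname as_expression_table
#' @export
expr_samples <- function(x) names(x)[-1L]

#' @rdname as_expression_table
#' @export
expr_values <- function(x) {
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x$gene
  m
}

# rebuild a gc_expr from a numeric matrix, inheriting labels from `template`
new_expr_from_matrix <- function(m, template, unit = expr_unit(template)) {
  out <- tibble(gene = rownames(m))
  out <- dplyr::bind_cols(out, as_tibble(m, .name_repair = "minimal"))
  as_expression_table(out, platform = expr_platform(template), unit = unit)
}

assert_unit <- function(x, unit, what = deparse(substitute(x))) {
  if (!inherits(x, "gc_expr")) {
    abort(paste0(what, " must be an expression table (see as_expression_table())"))
  }
  if (!identical(expr_unit(x), unit)) {
    abort(paste0(what, " must be in ", unit, " units, not ", expr_unit(x)))
  }
  invisible(x)
}

#' @export
print.gc_expr <- function(x, ...) {
  cat(sprintf(
    "# Expression table: %d genes x %d samples [platform %s, unit %s]\n",
    nrow(x), ncol(x) - 1L, expr_platform(x) %||% "?", expr_unit(x) %||% "?"
  ))
  NextMethod()
}
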