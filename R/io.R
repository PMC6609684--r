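#' Read and write expression tables
#'
#' Expression profiles are exchanged as tab-separated text in GEO
#' series-matrix orientation: first column gene symbol, header row of sample
#' identifiers, one numeric column per sample, decimal point, no thousands
#' separators.
#'
#' @param path path to a TSV file.
#' @param platform platform label recorded on the table.
#' @param unit expression unit of the stored values.
#' @return an expression table (see [as_expression_table()]).
#' @export
read_expression <- function(path, platform, unit = c("intensity", "TPM", "log2")) {
  unit <- match.arg(unit)
  hdr <- readr::read_tsv(path, n_max = 0L, show_col_types = FALSE,
                         name_repair = "minimal")
  if (ncol(hdr) < 2L) abort(paste0("malformed header in ", path, ": need gene column + samples"))
  # parsing problems surface as a descriptive error below, not readr's warning
  x <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      readr::col_character(),
      .default = readr::col_double()
    ),
    show_col_types = FALSE
  ))
  pr <- readr::problems(x)
  if (nrow(pr) > 0L) {
    abort(sprintf(
      "non-numeric value in %s at row %d, column %d (expected %s, got %s)",
      path, pr$row[1L], pr$col[1L], pr$expected[1L], pr$actual[1L]
    ))
  }
  as_expression_table(x, platform = platform, unit = unit)
}

#' @rdname read_expression
#' @param x an expression table.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' Read and write gene signatures (GMT)
#'
#' Signatures use the standard GMT layout: one set per line, tab-separated,
#' with set name, description, then member gene symbols. Signatures come back
#' as a long tibble with one row per (signature, gene) pair; duplicate genes
#' within a line are collapsed.
#'
#' @param path path to a `.gmt` file.
#' @return a tibble with columns `signature`, `description`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    return(tibble(signature = character(), description = character(), gene = character()))
  }
  parsed <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                    i, length(fields)))
    }
    tibble(signature = fields[1L], description = fields[2L],
           gene = unique(fields[-(1:2)]))
  })
  dplyr::bind_rows(parsed)
}

#' @rdname read_gmt
#' @param signatures a tibble with columns `signature`, `description`, `gene`.
#' @export
write_gmt <- function(signatures, path) {
  stopifnot(all(c("signature", "gene") %in% names(signatures)))
  if (!"description" %in% names(signatures)) signatures$description <- "na"
  lines <- signatures |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(
      line = paste(c(.data$signature[1L], .data$description[1L], unique(.data$gene)),
                   collapse = "\t"),
      .groups = "drop"
    )
  readr::write_lines(lines$line, path)
  invisible(path)
}

#' Read and write per-sample clinical tables
#'
#' The clinical table carries, per sample: the gold-standard molecular
#' subtype (one of `EMT`, `MSI`, `MSS/TP53+`, `MSS/TP53-`, or missing), TP53
#' somatic mutation status (`mutant` / `wild-type`, or missing), overall
#' survival time and the event flag (1 = death, 0 = censored). Missing fields
#' are encoded `NA`. Samples with a missing gold subtype are still classified
#' but are excluded from performance evaluation.
#'
#' @param path path to a TSV with columns `sample_id`, `gold_subtype`,
#'   `tp53_mutation`, `os_time`, `os_event`.
#' @return a tibble with those columns.
#' @export
read_clinical <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      gold_subtype = readr::col_character(),
      tp53_mutation = readr::col_character(),
      os_time = readr::col_double(),
      os_event = readr::col_integer()
    ),
    show_col_types = FALSE
  )
  validate_clinical(x)
}

#' @rdname read_clinical
#' @param clinical a clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path)
  invisible(path)
}

validate_clinical <- function(x) {
  need <- c("sample_id", "gold_subtype", "tp53_mutation", "os_time", "os_event")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) abort(paste0("clinical table lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(x$sample_id)) abort("duplicate sample_id in clinical table")
  if (any(x$os_time < 0, na.rm = TRUE)) abort("os_time must be >= 0")
  if (!all(x$os_event %in% c(0L, 1L, NA_integer_))) abort("os_event must be 0, 1 or NA")
  as_tibble(x)
}

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the classification pipeline. Defaults
#' are the operating points of the cross-platform ACRG reproduction: EMT
#' subtype cutoff 5.6 and MSI cutoff 5.5 on the mean-log2 signature scores, a
#' TP53 score cutoff of 6.19 used when no calibration cohort is available
#' (normally re-derived per cohort via [calibrate_tp53_cutoff()]), removal of
#' signature genes with cross-platform Pearson r below 0.4, a minimal-panel
#' correlation threshold of 0.65 with panel size 10, exclusion of genes with
#' mean TPM below 2, and a log2 pseudocount of 1 (so a TPM of 0 maps to a
#' log2 value of 0).
#'
#' @param emt_cutoff EMT signature-score cutoff; strictly greater assigns EMT.
#' @param msi_cutoff MSI signature-score cutoff.
#' @param tp53_cutoff fallback TP53 score cutoff when not calibrated.
#' @param gene_corr_threshold minimum cross-platform Pearson r for a
#'   signature gene to be retained (boundary kept).
#' @param minimal_corr_threshold correlation floor reported when selecting
#'   the minimal EMT panel.
#' @param minimal_panel_size number of genes in the minimal panel.
#' @param tpm_mean_threshold genes with mean TPM strictly below this are
#'   removed (a mean of exactly the threshold is kept).
#' @param log2_pseudocount pseudocount added before the log2 transform.
#' @param random_seed optional integer seed recorded in the config.
#' @return a list of class `gc_config`.
#' @export
pipeline_config <- function(emt_cutoff = 5.6,
                            msi_cutoff = 5.5,
                            tp53_cutoff = 6.19,
                            gene_corr_threshold = 0.4,
                            minimal_corr_threshold = 0.65,
                            minimal_panel_size = 10L,
                            tpm_mean_threshold = 2,
                            log2_pseudocount = 1,
                            random_seed = NULL) {
  cfg <- list(
    emt_cutoff = emt_cutoff, msi_cutoff = msi_cutoff, tp53_cutoff = tp53_cutoff,
    gene_corr_threshold = gene_corr_threshold,
    minimal_corr_threshold = minimal_corr_threshold,
    minimal_panel_size = as.integer(minimal_panel_size),
    tpm_mean_threshold = tpm_mean_threshold,
    log2_pseudocount = log2_pseudocount,
    random_seed = random_seed
  )
  num <- unlist(cfg[setdiff(names(cfg), "random_seed")])
  if (any(!is.finite(num))) abort("all configuration thresholds must be finite")
  if (cfg$minimal_panel_size < 1L) abort("minimal_panel_size must be >= 1")
  structure(cfg, class = "gc_config")
}

#' @rdname pipeline_config
#' @param path path of a YAML key:value file mirroring the config fields.
#' @param ... overrides applied on top of the file values (a flag-style
#'   override beats the file).
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param config a `gc_config` object.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1L))], path)
  invisible(path)
}
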