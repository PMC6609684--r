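#' Run the cross-platform subtype reproduction pipeline
#'
#' Executes the whole workflow on a paired-platform cohort: low-TPM
#' filtering of the target platform, log2 transform of both platforms,
#' restriction to common genes/samples, sample- and gene-level concordance
#' QC, correlation filtering of the EMT and MSI signatures, signature
#' scoring on the target platform, TP53 cutoff calibration on the samples
#' not captured by the EMT/MSI steps, step-wise subtype classification,
#' performance evaluation against the gold-standard subtype, and
#' Kaplan-Meier/log-rank survival by called subtype. Samples with a missing
#' gold subtype are classified but excluded from evaluation.
#'
#' @param reference expression table of the reference platform (intensity
#'   units).
#' @param target expression table of the target platform (TPM units).
#' @param signatures long signature tibble; must contain signatures named
#'   `EMT`, `MSI` and `TP53`.
#' @param clinical clinical tibble (see [read_clinical()]).
#' @param config a [pipeline_config()].
#' @param calibrate_tp53 calibrate the TP53 cutoff from mutation status
#'   (default); on calibration failure, or when `FALSE`, the config's fixed
#'   cutoff is used.
#' @return a list of class `gc_pipeline` with elements `calls`,
#'   `performance`, `survival`, `scores`, `score_concordance` (per-signature
#'   pre/post-filter score correlations), `gene_concordance`,
#'   `sample_concordance`, `filtered_signatures`, `tp53_cutoff`,
#'   `tp53_calibration`, `config`.
#' @export
run_subtype_pipeline <- function(reference, target, signatures, clinical,
                                 config = pipeline_config(),
                                 calibrate_tp53 = TRUE) {
  assert_unit(reference, "intensity", "reference")
  assert_unit(target, "TPM", "target")
  for (sig in c("EMT", "MSI", "TP53")) {
    if (!sig %in% signatures$signature) {
      abort(paste0("signature set lacks the '", sig, "' signature"))
    }
  }
  clinical <- validate_clinical(clinical)

  target_kept <- filter_low_tpm(target, config$tpm_mean_threshold)
  ref_log2 <- log2_transform(reference, config$log2_pseudocount)
  tgt_log2 <- log2_transform(target_kept, config$log2_pseudocount)
  matched <- intersect_platforms(ref_log2, tgt_log2)

  sample_qc <- sample_concordance(matched$a, matched$b)
  concordance <- gene_concordance(matched$a, matched$b,
                                  genes = unique(signatures$gene))

  pre <- score_concordance(matched$a, matched$b, signatures)
  filtered <- filter_signature(signatures, concordance,
                               threshold = config$gene_corr_threshold)
  post <- score_concordance(matched$a, matched$b, filtered)
  score_cmp <- dplyr::full_join(pre, post, by = "signature",
                                suffix = c("_before", "_after"))

  scores <- score_signatures(matched$b, filtered)

  calibration <- NULL
  tp53_cutoff <- config$tp53_cutoff
  if (isTRUE(calibrate_tp53)) {
    calibration <- tryCatch(
      calibrate_tp53_cutoff(scores, clinical, config),
      error = function(e) {
        warn(paste0("TP53 calibration failed (", conditionMessage(e),
                    "); using the fixed cutoff ", config$tp53_cutoff))
        NULL
      }
    )
    if (!is.null(calibration)) tp53_cutoff <- calibration$cutoff
  }

  calls <- classify_subtypes(scores, config, tp53_cutoff = tp53_cutoff)

  eval_data <- dplyr::inner_join(
    calls, dplyr::select(clinical, "sample_id", "gold_subtype"),
    by = "sample_id"
  )
  performance <- if (any(!is.na(eval_data$gold_subtype))) {
    evaluate_classification(eval_data, .data$gold_subtype, .data$subtype)
  } else NULL

  surv <- tryCatch(survival_by_subtype(calls, clinical),
                   error = function(e) NULL)

  structure(list(
    calls = calls,
    performance = performance,
    survival = surv,
    scores = scores,
    score_concordance = score_cmp,
    gene_concordance = concordance,
    sample_concordance = sample_qc,
    filtered_signatures = filtered,
    tp53_cutoff = tp53_cutoff,
    tp53_calibration = calibration,
    config = config
  ), class = "gc_pipeline")
}

#' @export
print.gc_pipeline <- function(x, ...) {
  cat("# Cross-platform subtype reproduction\n")
  cat(sprintf("TP53 cutoff: %.3f%s\n", x$tp53_cutoff,
              if (is.null(x$tp53_calibration)) " (fixed)" else " (calibrated)"))
  print(table(x$calls$subtype))
  if (!is.null(x$performance)) print(x$performance)
  invisible(x)
}

#' Serialize a performance report to JSON-ready values
#'
#' Flattens a `gc_performance` into plain lists/vectors suitable for
#' `jsonlite::write_json()`.
#'
#' @param performance a `gc_performance`.
#' @return a named list.
#' @export
performance_report <- function(performance) {
  stopifnot(inherits(performance, "gc_performance"))
  cm <- as.matrix(performance$confusion)
  list(
    n = performance$n,
    accuracy = performance$accuracy,
    no_information_rate = performance$nir$nir,
    nir_p_value = performance$nir$p_value,
    cohens_kappa = performance$kappa,
    confusion = list(labels = rownames(cm),
                     counts = unname(apply(cm, 1L, as.integer, simplify = FALSE))),
    per_class = purrr::transpose(as.list(performance$per_class))
  )
}
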