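#' Empirical ROC curve
#'
#' Sweeps candidate thresholds over a continuous score against a binary
#' label. Candidate thresholds are the midpoints between consecutive
#' distinct sorted scores plus `-Inf`/`Inf` sentinels; a sample is called
#' positive when its score is strictly greater than the threshold. The AUC
#' is computed by the trapezoid rule, which with midpoint thresholds equals
#' the Mann-Whitney U statistic divided by `n1 * n0` (ties credited 1/2).
#' When the empirical AUC falls below 0.5 the direction is reported in the
#' `direction` field rather than silently flipped.
#'
#' @param data a data frame holding the score and label columns.
#' @param score <[`data-masking`][rlang::args_data_masking]> numeric score column.
#' @param label <[`data-masking`][rlang::args_data_masking]> class label column.
#' @param positive the label value treated as positive; defaults to the
#'   last level (sorted) of the two observed values.
#' @return an object of class `gc_roc`: a list with `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `positive`,
#'   `direction`, `n_positive`, `n_negative`.
#' @examples
#' d <- data.frame(s = c(1, 2, 3, 4), y = c("n", "n", "p", "p"))
#' roc <- roc_curve(d, s, y, positive = "p")
#' roc$auc
#' youden_cutoff(roc) # 2.5
#' @export
roc_curve <- function(data, score, label, positive = NULL) {
  s <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ label }})
  ok <- !is.na(s) & !is.na(y)
  s <- s[ok]; y <- as.character(y[ok])
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    abort(paste0("roc_curve needs exactly two classes, found ", length(classes)))
  }
  positive <- positive %||% classes[2L]
  if (!positive %in% classes) abort(paste0("positive class '", positive, "' not observed"))
  pos <- y == positive

  u <- sort(unique(s))
  thr <- if (length(u) >= 2L) c(-Inf, (u[-1L] + u[-length(u)]) / 2, Inf) else c(-Inf, Inf)
  sens <- vapply(thr, function(t) mean(s[pos] > t), numeric(1L))
  spec <- vapply(thr, function(t) mean(s[!pos] <= t), numeric(1L))

  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1L] + sens[ord][-length(ord)]) / 2)

  structure(list(
    curve = tibble(threshold = thr, sensitivity = sens, specificity = spec),
    auc = auc,
    positive = positive,
    direction = if (auc >= 0.5) "higher-in-positive" else "higher-in-negative",
    n_positive = sum(pos),
    n_negative = sum(!pos)
  ), class = "gc_roc")
}

#' @export
print.gc_roc <- function(x, ...) {
  cat(sprintf("# ROC curve: %d thresholds, AUC %.3f (positive = %s, %s)\n",
              nrow(x$curve), x$auc, x$positive, x$direction))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Returns the threshold maximizing Youden's J = sensitivity + specificity
#' - 1 along an ROC curve; ties are broken by the smallest such threshold.
#'
#' @param roc a [roc_curve()] object.
#' @return the optimal threshold (numeric scalar).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "gc_roc"))
  j <- roc$curve$sensitivity + roc$curve$specificity - 1
  # thresholds are sorted ascending; take the first within numerical
  # tolerance of the maximum so exact ties resolve to the smallest threshold
  roc$curve$threshold[which(j >= max(j) - 1e-9)[1L]]
}

#' Step-wise molecular subtype classification
#'
#' The ACRG step-wise rule applied to per-sample signature scores: a sample
#' is `EMT` if its EMT score is strictly greater than the EMT cutoff;
#' otherwise `MSI` if its MSI score strictly exceeds the MSI cutoff;
#' otherwise `MSS/TP53+` if its TP53 score strictly exceeds the TP53 cutoff,
#' and `MSS/TP53-` if not. All comparisons are strict, so a score exactly at
#' a cutoff falls through to the next step. When a sample exceeds both the
#' EMT and MSI cutoffs the EMT step, applied first, wins; such samples are
#' counted in a message.
#'
#' @param scores a long score tibble from [score_signatures()] (columns
#'   `sample_id`, `signature`, `score`).
#' @param config a [pipeline_config()] providing the EMT/MSI cutoffs.
#' @param tp53_cutoff TP53 score cutoff, normally from
#'   [calibrate_tp53_cutoff()]; defaults to the config's fallback.
#' @param emt,msi,tp53 names of the three signatures in `scores`.
#' @return a tibble with columns `sample_id`, `subtype`, `emt_score`,
#'   `msi_score`, `tp53_score`; the cutoffs used are attached as the
#'   `cutoffs` attribute.
#' @export
classify_subtypes <- function(scores, config = pipeline_config(),
                              tp53_cutoff = config$tp53_cutoff,
                              emt = "EMT", msi = "MSI", tp53 = "TP53") {
  wide <- scores |>
    dplyr::filter(.data$signature %in% c(emt, msi, tp53)) |>
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "signature",
                       values_from = "score")
  for (sig in c(emt, msi, tp53)) {
    if (!sig %in% names(wide) || anyNA(wide[[sig]])) {
      missing_samples <- if (!sig %in% names(wide)) wide$sample_id
        else wide$sample_id[is.na(wide[[sig]])]
      abort(paste0("missing ", sig, " score for sample(s): ",
                   paste(head(missing_samples, 5L), collapse = ", ")))
    }
  }
  e <- wide[[emt]]; m <- wide[[msi]]; t53 <- wide[[tp53]]
  both <- sum(e > config$emt_cutoff & m > config$msi_cutoff)
  if (both > 0L) {
    inform(sprintf(
      "classify_subtypes: %d sample(s) exceed both the EMT and MSI cutoffs; EMT takes precedence",
      both))
  }
  label <- dplyr::case_when(
    e > config$emt_cutoff ~ "EMT",
    m > config$msi_cutoff ~ "MSI",
    t53 > tp53_cutoff ~ "MSS/TP53+",
    .default = "MSS/TP53-"
  )
  out <- tibble(
    sample_id = wide$sample_id,
    subtype = label,
    emt_score = e, msi_score = m, tp53_score = t53
  )
  attr(out, "cutoffs") <- c(emt = config$emt_cutoff, msi = config$msi_cutoff,
                            tp53 = tp53_cutoff)
  out
}

#' Calibrate the TP53 score cutoff from mutation status
#'
#' The MSS/TP53+ vs MSS/TP53- split uses a cutoff on the TP53 signature
#' score chosen where Youden's J is maximal on the ROC of the score against
#' TP53 somatic mutation status. Calibration uses only the samples not
#' already assigned EMT or MSI by the score cutoffs (the "remaining"
#' samples of the step-wise scheme), with the positive class being TP53
#' wild-type — transcriptionally active p53 drives CDKN1A/MDM2 up, so
#' wild-type samples are expected to score higher. A warning is raised when
#' the classes barely separate (maximal J < 0.2).
#'
#' @param scores a long score tibble from [score_signatures()].
#' @param clinical a clinical tibble with `sample_id` and `tp53_mutation`
#'   (`"mutant"` / `"wild-type"`).
#' @param config a [pipeline_config()] (EMT/MSI cutoffs for the exclusion
#'   step).
#' @param min_per_class minimum samples required in each mutation class.
#' @return a list of class `gc_tp53_calibration`: `cutoff`, `j` (maximal
#'   Youden index), `auc`, `roc`, `n`.
#' @export
calibrate_tp53_cutoff <- function(scores, clinical, config = pipeline_config(),
                                  min_per_class = 3L) {
  wide <- scores |>
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "signature",
                       values_from = "score") |>
    dplyr::inner_join(
      dplyr::select(clinical, "sample_id", "tp53_mutation"), by = "sample_id"
    ) |>
    dplyr::filter(
      .data$EMT <= config$emt_cutoff,
      .data$MSI <= config$msi_cutoff,
      !is.na(.data$tp53_mutation)
    )
  counts <- table(factor(wide$tp53_mutation, levels = c("mutant", "wild-type")))
  if (any(counts == 0L)) {
    abort(paste0(
      "only one TP53 mutation class among the remaining samples; ",
      "cannot calibrate - consider the fixed default cutoff ",
      pipeline_config()$tp53_cutoff
    ))
  }
  if (any(counts < min_per_class)) {
    warn(sprintf("calibrate_tp53_cutoff: a mutation class has fewer than %d samples",
                 min_per_class))
  }
  roc <- roc_curve(wide, .data$TP53, .data$tp53_mutation, positive = "wild-type")
  j <- max(roc$curve$sensitivity + roc$curve$specificity - 1)
  if (j < 0.2) {
    warn(sprintf(
      "calibrate_tp53_cutoff: TP53 score barely separates mutation classes (max J = %.2f)", j))
  }
  structure(list(
    cutoff = youden_cutoff(roc), j = j, auc = roc$auc, roc = roc,
    n = nrow(wide)
  ), class = "gc_tp53_calibration")
}

#' @export
print.gc_tp53_calibration <- function(x, ...) {
  cat(sprintf("# TP53 cutoff calibration: cutoff %.3f (J = %.2f, AUC = %.2f, n = %d)\n",
              x$cutoff, x$j, x$auc, x$n))
  invisible(x)
}
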