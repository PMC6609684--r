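#' Confusion matrix and overall accuracy
#'
#' Cross-tabulates gold-standard against predicted labels (gold in rows,
#' predictions in columns, over the union of observed labels) and reports
#' overall accuracy as trace / n.
#'
#' @param data a data frame with the two label columns.
#' @param truth <[`data-masking`][rlang::args_data_masking]> gold labels.
#' @param estimate <[`data-masking`][rlang::args_data_masking]> predictions.
#' @return `confusion_matrix()` a square contingency `table`;
#'   `accuracy_from_confusion()` a numeric scalar.
#' @export
confusion_matrix <- function(data, truth, estimate) {
  g <- as.character(dplyr::pull(data, {{ truth }}))
  p <- as.character(dplyr::pull(data, {{ estimate }}))
  if (length(g) != length(p)) abort("truth and estimate must have equal length")
  keep <- !is.na(g) & !is.na(p)
  lev <- sort(union(g[keep], p[keep]))
  table(
    gold = factor(g[keep], levels = lev),
    predicted = factor(p[keep], levels = lev)
  )
}

#' @rdname confusion_matrix
#' @param cm a square confusion matrix (gold x predicted).
#' @export
accuracy_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  sum(diag(cm)) / sum(cm)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with expected
#' agreement `p_e` from the marginal products. Returns `NA` when `p_e = 1`
#' (kappa undefined).
#'
#' @param cm a square confusion matrix.
#' @return a numeric scalar in `[-1, 1]`, or `NA`.
#' @export
cohens_kappa <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) abort("cohens_kappa needs a square confusion matrix")
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (isTRUE(all.equal(pe, 1))) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' No-information-rate test
#'
#' The no-information rate (NIR) is the frequency of the largest gold class;
#' the test asks whether the observed number of correct calls exceeds what
#' always predicting that class would achieve, via the exact one-sided
#' binomial tail `P(X >= k | n, NIR)`.
#'
#' @param gold gold-standard label vector.
#' @param n_correct number of correct predictions.
#' @return a one-row tibble with `nir`, `n`, `n_correct`, `p_value`.
#' @export
nir_test <- function(gold, n_correct) {
  gold <- gold[!is.na(gold)]
  n <- length(gold)
  if (n < 1L) abort("nir_test needs at least one gold label")
  nir <- max(table(gold)) / n
  p <- pbinom(n_correct - 1L, n, nir, lower.tail = FALSE)
  tibble(nir = nir, n = n, n_correct = as.integer(n_correct), p_value = p)
}

#' One-vs-rest sensitivity and specificity per class
#'
#' For each class c, the confusion matrix is binarized: sensitivity is
#' `M[c,c] / rowsum_c` and specificity is the fraction of non-c gold samples
#' not predicted c. A class with no gold members gets a missing sensitivity
#' (flagged via `n_gold = 0`).
#'
#' @param cm a square confusion matrix (gold x predicted).
#' @return a tibble with columns `class`, `n_gold`, `sensitivity`,
#'   `specificity`.
#' @export
per_class_sens_spec <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) abort("per_class_sens_spec needs a square matrix")
  n <- sum(cm)
  rs <- rowSums(cm); cs <- colSums(cm); d <- diag(cm)
  tibble(
    class = rownames(cm),
    n_gold = as.integer(unname(rs)),
    sensitivity = unname(ifelse(rs == 0, NA_real_, d / rs)),
    specificity = unname((n - rs - cs + d) / (n - rs))
  )
}

#' Full classification performance report
#'
#' Bundles the confusion matrix, overall accuracy, the exact binomial
#' no-information-rate test, Cohen's kappa and one-vs-rest per-class
#' sensitivity/specificity — the evaluation reported for the cross-platform
#' subtype reproduction (66% accuracy, kappa 0.55 on the original cohort).
#' Samples with a missing gold label are dropped before evaluation.
#'
#' @inheritParams confusion_matrix
#' @return an object of class `gc_performance` with fields `confusion`,
#'   `accuracy`, `nir`, `kappa`, `per_class`, `n`.
#' @export
evaluate_classification <- function(data, truth, estimate) {
  g <- as.character(dplyr::pull(data, {{ truth }}))
  p <- as.character(dplyr::pull(data, {{ estimate }}))
  keep <- !is.na(g) & !is.na(p)
  d <- tibble(gold = g[keep], predicted = p[keep])
  cm <- confusion_matrix(d, .data$gold, .data$predicted)
  acc <- accuracy_from_confusion(cm)
  structure(list(
    confusion = cm,
    accuracy = acc,
    nir = nir_test(d$gold, sum(diag(as.matrix(cm)))),
    kappa = cohens_kappa(cm),
    per_class = per_class_sens_spec(cm),
    n = nrow(d)
  ), class = "gc_performance")
}

#' @export
print.gc_performance <- function(x, ...) {
  cat(sprintf("# Classification performance on %d samples\n", x$n))
  cat(sprintf("accuracy %.3f (NIR %.3f, exact binomial p = %.3g), kappa %.3f\n",
              x$accuracy, x$nir$nir, x$nir$p_value, x$kappa))
  print(x$confusion)
  print(x$per_class)
  invisible(x)
}

#' ROC of a signature score against a gold subtype
#'
#' Dichotomizes samples into `target_label` versus the rest and evaluates
#' the signature score by ROC/AUC plus a two-sided Mann-Whitney U test
#' between the two groups.
#'
#' @param data a data frame with score and gold-label columns.
#' @param score <[`data-masking`][rlang::args_data_masking]> the score column.
#' @param truth <[`data-masking`][rlang::args_data_masking]> the gold labels.
#' @param target_label the subtype treated as positive.
#' @return a list of class `gc_score_roc` with `roc`, `auc`, `p_value`,
#'   `target_label`.
#' @export
subtype_score_roc <- function(data, score, truth, target_label) {
  s <- dplyr::pull(data, {{ score }})
  g <- as.character(dplyr::pull(data, {{ truth }}))
  keep <- !is.na(s) & !is.na(g)
  s <- s[keep]; g <- g[keep]
  is_target <- factor(ifelse(g == target_label, "target", "rest"),
                      levels = c("rest", "target"))
  if (length(unique(is_target)) < 2L) {
    abort(paste0("both '", target_label, "' and non-'", target_label,
                 "' samples are required"))
  }
  roc <- roc_curve(tibble(s = s, y = is_target), .data$s, .data$y, positive = "target")
  p <- suppressWarnings(
    wilcox.test(s[is_target == "target"], s[is_target == "rest"])$p.value
  )
  structure(list(roc = roc, auc = roc$auc, p_value = p,
                 target_label = target_label),
            class = "gc_score_roc")
}

#' Principal components versus signature scores
#'
#' Principal components of the gene-centered sample configuration (no
#' scaling to unit variance), with the Spearman correlation of each of the
#' leading components against each signature score. PC signs are not
#' identifiable; only |rho| is meaningful and the returned sign is
#' arbitrary.
#'
#' @param x a log2 expression table with at least 4 samples.
#' @param scores a long score tibble from [score_signatures()].
#' @param n_components number of leading components to report.
#' @return a list of class `gc_pca`: `pc_scores` (tibble, sample_id +
#'   components) and `association` (tibble of `component`, `signature`,
#'   `rho`, `p_value`).
#' @export
pca_signature_association <- function(x, scores, n_components = 3L) {
  assert_unit(x, "log2")
  m <- expr_values(x)
  if (ncol(m) < 4L) abort("PCA association needs at least 4 samples")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  pcs <- pc$x[, seq_len(k), drop = FALSE]
  pc_scores <- dplyr::bind_cols(tibble(sample_id = rownames(pcs)), as_tibble(pcs))
  wide <- tidyr::pivot_wider(scores, id_cols = "sample_id",
                             names_from = "signature", values_from = "score")
  merged <- dplyr::inner_join(pc_scores, wide, by = "sample_id")
  sigs <- setdiff(names(wide), "sample_id")
  assoc <- tidyr::expand_grid(component = colnames(pcs), signature = sigs) |>
    dplyr::mutate(purrr::map2_dfr(.data$component, .data$signature, function(pc_i, sig) {
      ct <- suppressWarnings(
        cor.test(merged[[pc_i]], merged[[sig]], method = "spearman")
      )
      tibble(rho = unname(ct$estimate), p_value = ct$p.value)
    }))
  structure(list(pc_scores = pc_scores, association = assoc,
                 sdev = pc$sdev[seq_len(k)]),
            class = "gc_pca")
}

#' Kaplan-Meier survival by group with log-rank test
#'
#' Product-limit survival estimates per group and the k-group log-rank test
#' (k - 1 degrees of freedom). When fewer than two groups are present, or no
#' events occurred, the estimator is still returned and the log-rank result
#' is missing, with a warning.
#'
#' @param calls a data frame with `sample_id` and a grouping column.
#' @param clinical a clinical tibble with `sample_id`, `os_time`, `os_event`.
#' @param group name of the grouping column in `calls` (default
#'   `"subtype"`).
#' @return an object of class `gc_survfit`: `fit` (a
#'   [survival::survfit] object), `logrank` (one-row tibble `statistic`,
#'   `df`, `p_value`), `data`, `group`.
#' @export
survival_by_subtype <- function(calls, clinical, group = "subtype") {
  if (!group %in% names(calls)) abort(paste0("no column '", group, "' in calls"))
  d <- dplyr::inner_join(
    dplyr::select(calls, "sample_id", dplyr::all_of(group)),
    dplyr::select(clinical, "sample_id", "os_time", "os_event"),
    by = "sample_id"
  ) |>
    dplyr::filter(!is.na(.data$os_time), !is.na(.data$os_event))
  if (nrow(d) == 0L) abort("no samples with survival data")
  d$.group <- factor(d[[group]])
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ .group, data = d)
  lr <- tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  if (nlevels(droplevels(d$.group)) < 2L) {
    warn("survival_by_subtype: a single group; log-rank test not computed")
  } else if (sum(d$os_event) == 0L) {
    warn("survival_by_subtype: all observations censored; log-rank test not computed")
  } else {
    sd <- survival::survdiff(survival::Surv(os_time, os_event) ~ .group, data = d)
    df <- length(sd$n) - 1L
    lr <- tibble(statistic = unname(sd$chisq), df = df,
                 p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
  }
  structure(list(fit = fit, logrank = lr, data = as_tibble(d), group = group),
            class = "gc_survfit")
}

#' @export
print.gc_survfit <- function(x, ...) {
  cat(sprintf("# Kaplan-Meier fit by %s (%d samples, %d events)\n",
              x$group, nrow(x$data), sum(x$data$os_event)))
  if (!is.na(x$logrank$p_value)) {
    cat(sprintf("log-rank chi-square %.3f on %d df, p = %.4g\n",
                x$logrank$statistic, x$logrank$df, x$logrank$p_value))
  }
  invisible(x)
}
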