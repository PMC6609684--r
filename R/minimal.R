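#' Rank genes by correlation with the EMT target
#'
#' Pearson correlation of each gene's log2 expression with an EMT target
#' vector, sorted in decreasing order. The default target in the pipeline is
#' the binary EMT-subtype indicator (a point-biserial correlation), because
#' the panel's purpose is subtype discrimination; the continuous EMT
#' signature score can be passed instead.
#'
#' @param x a log2 expression table.
#' @param target a per-sample target: either a numeric vector named by
#'   sample id, or a two-column data frame (`sample_id`, value).
#' @return a tibble with columns `gene`, `r`, sorted by decreasing `r`.
#' @export
rank_genes_by_emt_correlation <- function(x, target) {
  assert_unit(x, "log2")
  m <- expr_values(x)
  if (is.data.frame(target)) {
    stopifnot(ncol(target) >= 2L, "sample_id" %in% names(target))
    val_col <- setdiff(names(target), "sample_id")[1L]
    target <- setNames(as.numeric(target[[val_col]]), target$sample_id)
  }
  if (!is.null(names(target))) {
    common <- intersect(colnames(m), names(target))
    if (length(common) < 3L) abort("need at least 3 samples shared with the target")
    m <- m[, common, drop = FALSE]
    target <- target[common]
  } else if (length(target) != ncol(m)) {
    abort("unnamed target must have one value per sample")
  }
  target <- as.numeric(target)
  if (stats::sd(target) == 0) abort("the EMT target has zero variance")
  r <- unname(row_cor(m, matrix(target, nrow(m), ncol(m), byrow = TRUE)))
  tibble(gene = rownames(m), r = r) |>
    dplyr::arrange(dplyr::desc(.data$r))
}

#' Select the minimal panel genes
#'
#' Keeps the genes whose correlation with the EMT target meets the
#' threshold, then takes exactly `size` genes by rank. When fewer than
#' `size` genes reach the threshold the selection falls back to pure rank
#' order with a warning, so the panel always has the configured size
#' whenever enough genes exist.
#'
#' @param ranked a ranked correlation tibble from
#'   [rank_genes_by_emt_correlation()].
#' @param threshold correlation floor reported for the panel (default 0.65).
#' @param size panel size (default 10).
#' @return a tibble of `size` rows (fewer only if the ranked list is
#'   shorter), columns `gene`, `r`.
#' @export
select_panel <- function(ranked, threshold = 0.65, size = 10L) {
  if (nrow(ranked) == 0L) abort("the ranked gene list is empty")
  size <- as.integer(size)
  n_above <- sum(ranked$r >= threshold, na.rm = TRUE)
  if (n_above < size) {
    warn(sprintf(
      "select_panel: only %d gene(s) reach r >= %g; completing the panel by rank",
      n_above, threshold))
  }
  out <- ranked |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::slice_head(n = size)
  if (nrow(out) < size) {
    warn(sprintf("select_panel: only %d usable gene(s) available", nrow(out)))
  }
  out
}

#' Fit the linear panel prediction model
#'
#' Ordinary least squares of the 0/1 EMT-subtype indicator on the panel
#' genes' log2 expression (a linear probability model — "linear regression"
#' in the original description, deliberately not logistic). The fitted
#' linear combination is the panel prediction score.
#'
#' @param x a log2 expression table containing the panel genes.
#' @param panel_genes character vector of panel gene symbols (or a
#'   [select_panel()] tibble).
#' @param emt_indicator 0/1 (or logical) EMT membership, either named by
#'   sample id or aligned with the table's samples.
#' @return an object of class `gc_panel`: `genes`, `coefficients` (named,
#'   intercept first), `fitted` (tibble `sample_id`, `score`), `n`.
#' @export
fit_panel_model <- function(x, panel_genes, emt_indicator) {
  assert_unit(x, "log2")
  if (is.data.frame(panel_genes)) panel_genes <- panel_genes$gene
  m <- expr_values(x)
  missing <- setdiff(panel_genes, rownames(m))
  if (length(missing) > 0L) {
    abort(paste0("panel gene(s) absent from the table: ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.null(names(emt_indicator))) {
    emt_indicator <- emt_indicator[colnames(m)]
  }
  y <- as.numeric(emt_indicator)
  if (length(y) != ncol(m) || anyNA(y)) {
    abort("emt_indicator must provide a 0/1 value for every sample")
  }
  if (ncol(m) <= length(panel_genes) + 1L) {
    abort("need more samples than panel genes + 1 to fit the model")
  }
  X <- t(m[panel_genes, , drop = FALSE])
  fit <- lm(y ~ X)
  beta <- coef(fit)
  if (anyNA(beta)) {
    bad <- panel_genes[is.na(beta[-1L])]
    abort(paste0("rank-deficient design; collinear gene(s): ",
                 paste(bad, collapse = ", ")))
  }
  names(beta) <- c("(Intercept)", panel_genes)
  structure(list(
    genes = panel_genes,
    coefficients = beta,
    fitted = tibble(sample_id = colnames(m), score = unname(fit$fitted.values)),
    n = ncol(m)
  ), class = "gc_panel")
}

#' @export
print.gc_panel <- function(x, ...) {
  cat(sprintf("# %d-gene EMT panel model (fit on %d samples)\n",
              length(x$genes), x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Apply a fitted panel model to new samples
#'
#' @param object a `gc_panel`.
#' @param x a log2 expression table containing the panel genes.
#' @param ... unused.
#' @return a tibble with columns `sample_id`, `score`.
#' @export
predict.gc_panel <- function(object, x, ...) {
  assert_unit(x, "log2")
  m <- expr_values(x)
  missing <- setdiff(object$genes, rownames(m))
  if (length(missing) > 0L) {
    abort(paste0("panel gene(s) absent from the table: ",
                 paste(missing, collapse = ", ")))
  }
  s <- object$coefficients[1L] +
    drop(crossprod(m[object$genes, , drop = FALSE], object$coefficients[-1L]))
  tibble(sample_id = colnames(m), score = unname(s))
}

#' Operating point and metrics of a panel score
#'
#' ROC of the panel prediction score against the EMT indicator, the
#' Youden-optimal cutoff, and the sensitivity/specificity at that cutoff
#' plus the AUC.
#'
#' @param scores a tibble with columns `sample_id`, `score` (e.g. from
#'   [predict.gc_panel()]).
#' @param emt_indicator 0/1 or logical EMT membership, named by sample id or
#'   aligned with `scores`.
#' @return a one-row tibble `cutoff`, `sensitivity`, `specificity`, `auc`,
#'   `n`; the ROC object is attached as attribute `roc`.
#' @export
panel_cutoff_metrics <- function(scores, emt_indicator) {
  if (!is.null(names(emt_indicator))) emt_indicator <- emt_indicator[scores$sample_id]
  y <- as.integer(as.logical(emt_indicator))
  if (length(unique(y[!is.na(y)])) < 2L) {
    abort("both EMT and non-EMT samples are required")
  }
  d <- tibble(score = scores$score, y = factor(y, levels = c(0L, 1L)))
  roc <- roc_curve(d, .data$score, .data$y, positive = "1")
  cut <- youden_cutoff(roc)
  at <- roc$curve[roc$curve$threshold == cut, ]
  out <- tibble(cutoff = cut, sensitivity = at$sensitivity[1L],
                specificity = at$specificity[1L], auc = roc$auc, n = length(y))
  attr(out, "roc") <- roc
  out
}

#' Survival split by the panel score
#'
#' Dichotomizes samples at the panel cutoff (score strictly greater =
#' predicted EMT) and compares overall survival between the predicted-EMT
#' and predicted-non-EMT groups by Kaplan-Meier / log-rank. A one-sided
#' split returns the estimator with a missing log-rank result and a
#' warning.
#'
#' @param scores a tibble with `sample_id`, `score`.
#' @param cutoff the decision cutoff (e.g. from [panel_cutoff_metrics()]).
#' @param clinical a clinical tibble with survival columns.
#' @return a `gc_survfit` (see [survival_by_subtype()]).
#' @export
panel_survival_split <- function(scores, cutoff, clinical) {
  calls <- tibble(
    sample_id = scores$sample_id,
    predicted_emt = ifelse(scores$score > cutoff, "EMT-like", "non-EMT")
  )
  survival_by_subtype(calls, clinical, group = "predicted_emt")
}

#' Derive a minimal EMT panel on a cohort
#'
#' Convenience wrapper chaining correlation ranking, panel selection, the
#' linear model fit and the ROC operating point on one (training) table.
#'
#' @param x a log2 expression table.
#' @param emt_indicator 0/1 or logical EMT membership, named by sample id or
#'   aligned with the table's samples.
#' @param config a [pipeline_config()] (panel size and correlation floor).
#' @return a list of class `gc_panel_report`: `ranked`, `panel`, `model`
#'   (`gc_panel`), `metrics` (one-row tibble).
#' @export
derive_emt_panel <- function(x, emt_indicator, config = pipeline_config()) {
  if (!is.null(names(emt_indicator))) {
    ind <- emt_indicator
  } else {
    ind <- setNames(as.numeric(emt_indicator), expr_samples(x))
  }
  ranked <- rank_genes_by_emt_correlation(x, ind)
  panel <- select_panel(ranked, threshold = config$minimal_corr_threshold,
                        size = config$minimal_panel_size)
  model <- fit_panel_model(x, panel, ind)
  metrics <- panel_cutoff_metrics(model$fitted, ind)
  structure(list(ranked = ranked, panel = panel, model = model, metrics = metrics),
            class = "gc_panel_report")
}
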