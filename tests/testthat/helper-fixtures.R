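# shared fixtures: all data is generated in code at test time

# a quick expression table from a matrix (genes in rows)
expr_fixture <- function(m, unit = "log2", platform = "target",
                         genes = NULL, samples = NULL) {
  if (is.null(rownames(m))) rownames(m) <- genes %||% sprintf("G%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  tbl <- tibble::as_tibble(m, .name_repair = "minimal")
  tbl <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)), tbl)
  as_expression_table(tbl, platform = platform, unit = unit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reduced-size simulation config for fast unit tests; study-scale values are
# used in the acceptance suite
small_sim_config <- function(n_samples = 60, ..., seed = 1) {
  simulation_config(
    n_samples = n_samples,
    n_background_genes = 60,
    emt_signature_size = 24,
    msi_signature_size = 24,
    auxiliary_signature_size = 6,
    seed = seed,
    ...
  )
}

# long-format score table for classifier tests
score_fixture <- function(emt, msi, tp53, ids = sprintf("S%02d", seq_along(emt))) {
  tibble::tibble(
    sample_id = rep(ids, 3L),
    signature = rep(c("EMT", "MSI", "TP53"), each = length(ids)),
    score = c(emt, msi, tp53)
  )
}

# independent brute-force ROC/Youden oracle: enumerate every midpoint
# threshold and count
oracle_roc <- function(score, pos) {
  u <- sort(unique(score))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best_j <- -Inf; best_t <- NA_real_
  for (t in thr) {
    sens <- sum(score[pos] > t) / sum(pos)
    spec <- sum(score[!pos] <= t) / sum(!pos)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  # AUC by pairwise comparison (Mann-Whitney identity)
  cmp <- outer(score[pos], score[!pos], function(a, b) (a > b) + 0.5 * (a == b))
  list(youden = best_t, auc = mean(cmp), j = best_j)
}
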