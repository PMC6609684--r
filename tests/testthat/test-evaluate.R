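test_that("confusion matrix, accuracy, kappa and per-class metrics match caret", {
  set.seed(211)
  labels <- subtype_labels()
  for (i in 1:5) {
    d <- tibble::tibble(
      gold = sample(labels, 80, replace = TRUE),
      pred = sample(labels, 80, replace = TRUE)
    )
    cm <- confusion_matrix(d, gold, pred)
    # pairwise-count oracle
    for (a in labels) for (b in labels) {
      expect_equal(unname(cm[a, b]), sum(d$gold == a & d$pred == b))
    }
    ref <- caret::confusionMatrix(
      factor(d$pred, levels = labels), factor(d$gold, levels = labels)
    )
    expect_equal(accuracy_from_confusion(cm),
                 unname(ref$overall["Accuracy"]), tolerance = 1e-12)
    expect_equal(cohens_kappa(cm), unname(ref$overall["Kappa"]),
                 tolerance = 1e-12)
    pcs <- per_class_sens_spec(cm)
    expect_equal(pcs$sensitivity,
                 unname(ref$byClass[paste("Class:", labels), "Sensitivity"]),
                 tolerance = 1e-12)
    expect_equal(pcs$specificity,
                 unname(ref$byClass[paste("Class:", labels), "Specificity"]),
                 tolerance = 1e-12)
  }
})

test_that("kappa follows the closed form on hand-built matrices", {
  cm <- matrix(c(20, 10, 5, 15), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  # p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  expect_equal(cohens_kappa(cm), 0.4)

  diag4 <- diag(c(5, 3, 2, 8))
  expect_equal(cohens_kappa(diag4), 1)

  indep <- outer(c(10, 20, 5), c(4, 8, 2))   # predictions independent of gold
  expect_equal(cohens_kappa(indep), 0)

  expect_error(cohens_kappa(matrix(1, 2, 3)), "square")
})

test_that("the NIR test is the exact one-sided binomial tail", {
  gold <- rep(c("x", "y"), each = 10)                # NIR = 0.5, n = 20
  perfect <- nir_test(gold, 20L)
  expect_equal(perfect$p_value, 0.5^20)

  at_nir <- nir_test(gold, 10L)                      # accuracy == NIR
  expect_gt(at_nir$p_value, 0.5)

  set.seed(221)
  for (i in 1:10) {
    g <- sample(c("a", "b", "c"), 12, replace = TRUE)
    k <- sample(0:12, 1)
    nir <- max(table(g)) / 12
    manual <- sum(stats::dbinom(k:12, 12, nir))      # enumeration oracle
    expect_equal(nir_test(g, k)$p_value, manual, tolerance = 1e-12)
  }
})

test_that("accuracy decomposes as the gold-share-weighted sensitivity sum", {
  set.seed(231)
  for (i in 1:10) {
    cm <- matrix(rpois(16, 4), 4, 4,
                 dimnames = list(letters[1:4], letters[1:4]))
    pcs <- per_class_sens_spec(cm)
    shares <- rowSums(cm) / sum(cm)
    lhs <- accuracy_from_confusion(cm)
    rhs <- sum(pcs$sensitivity * shares, na.rm = TRUE)
    expect_equal(lhs, rhs, tolerance = 1e-12)
    expect_equal(cohens_kappa(cm) == 1,
                 sum(cm) == sum(diag(cm)))
  }

  empty_row <- matrix(c(0, 0, 3, 5), 2, 2, byrow = TRUE,
                      dimnames = list(c("a", "b"), c("a", "b")))
  pcs <- per_class_sens_spec(empty_row)
  expect_true(is.na(pcs$sensitivity[1]) && pcs$n_gold[1] == 0)
  expect_false(is.na(pcs$specificity[1]))
})

test_that("evaluate_classification drops missing gold labels and bundles metrics", {
  d <- tibble::tibble(
    gold = c("EMT", "EMT", "MSI", NA, "MSI"),
    pred = c("EMT", "MSI", "MSI", "EMT", "MSI")
  )
  perf <- evaluate_classification(d, gold, pred)
  expect_equal(perf$n, 4L)
  expect_equal(perf$accuracy, 0.75)
  g <- glance(perf)
  expect_equal(g$accuracy, perf$accuracy)
  expect_equal(nrow(tidy(perf)), nrow(perf$per_class))
})

test_that("signature-score ROC against gold subtypes behaves at the extremes", {
  const <- tibble::tibble(score = rep(5, 20),
                          gold = rep(c("EMT", "rest"), 10))
  r <- subtype_score_roc(const, score, gold, "EMT")
  expect_equal(r$auc, 0.5)

  set.seed(241)
  s <- c(rnorm(10, 8), rnorm(30, 5))
  d <- tibble::tibble(score = s, gold = rep(c("EMT", "other"), c(10, 30)))
  r2 <- subtype_score_roc(d, score, gold, "EMT")
  orc <- oracle_roc(s, d$gold == "EMT")
  expect_equal(r2$auc, orc$auc, tolerance = 1e-12)
  expect_equal(
    r2$p_value,
    suppressWarnings(wilcox.test(s[d$gold == "EMT"], s[d$gold != "EMT"])$p.value)
  )

  expect_error(subtype_score_roc(d, score, gold, "GHOST"), "GHOST")
})

test_that("PCA picks up a planted expression axis and ignores sample order", {
  set.seed(251)
  n <- 20; g <- 50
  axis <- rnorm(n)                        # the only planted variation
  loading <- c(rep(1, 10), rep(0, g - 10))
  m <- outer(loading, axis) + matrix(rnorm(g * n, 0, 0.01), g, n) + 5
  x <- expr_fixture(m, unit = "log2")
  sc <- tibble::tibble(sample_id = expr_samples(x), signature = "EMT",
                       score = colMeans(m[1:10, ]))
  res <- pca_signature_association(x, sc)
  rho1 <- res$association$rho[res$association$component == "PC1" &
                              res$association$signature == "EMT"]
  expect_gte(abs(rho1), 0.9)

  dup <- expr_fixture(cbind(m, m[, 1]), unit = "log2",
                      samples = c(expr_samples(x), "DUP"))
  res_dup <- pca_signature_association(dup, dplyr::bind_rows(
    sc, tibble::tibble(sample_id = "DUP", signature = "EMT", score = sc$score[1])
  ))
  pcs <- res_dup$pc_scores
  expect_equal(unlist(pcs[pcs$sample_id == "DUP", -1]),
               unlist(pcs[pcs$sample_id == expr_samples(x)[1], -1]),
               ignore_attr = TRUE, tolerance = 1e-8)

  tiny <- expr_fixture(m[, 1:3], unit = "log2")
  expect_error(pca_signature_association(tiny, sc), "4")
})

test_that("Kaplan-Meier estimator and log-rank test cover the textbook cases", {
  # hand product-limit computation: events at 1,2,3,4 in one group
  calls <- tibble::tibble(sample_id = sprintf("S%d", 1:4),
                          subtype = "EMT")
  clin <- tibble::tibble(sample_id = sprintf("S%d", 1:4),
                         os_time = 1:4, os_event = 1L)
  expect_warning(fit <- survival_by_subtype(calls, clin), "single group")
  expect_equal(tidy(fit)$estimate, c(0.75, 0.5, 0.25, 0))
  expect_true(is.na(fit$logrank$p_value))

  # no events: survival identically 1, log-rank missing
  clin0 <- clin; clin0$os_event <- 0L
  calls2 <- calls; calls2$subtype <- rep(c("A", "B"), 2)
  expect_warning(fit0 <- survival_by_subtype(calls2, clin0), "censored")
  expect_true(all(tidy(fit0)$estimate == 1))

  # two identical groups: statistic exactly 0, p = 1
  calls3 <- tibble::tibble(sample_id = sprintf("S%d", 1:8),
                           subtype = rep(c("A", "B"), each = 4))
  clin3 <- tibble::tibble(sample_id = sprintf("S%d", 1:8),
                          os_time = rep(c(1, 2, 3, 4), 2),
                          os_event = rep(1L, 8))
  fit3 <- survival_by_subtype(calls3, clin3)
  expect_equal(fit3$logrank$statistic, 0, tolerance = 1e-12)
  expect_equal(fit3$logrank$p_value, 1, tolerance = 1e-12)
  expect_equal(fit3$logrank$df, 1L)
})
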