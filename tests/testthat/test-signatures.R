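test_that("signature scores are unweighted means of member-gene log2 values", {
  x <- expr_fixture(matrix(c(2, 4, 6), 3, 1), unit = "log2",
                    genes = c("A", "B", "C"), samples = "S1")
  sigs <- tibble::tibble(signature = "SIG", gene = c("A", "B", "C"))
  expect_equal(score_signatures(x, sigs)$score, 4)

  one <- tibble::tibble(signature = "ONE", gene = "B")
  expect_equal(score_signatures(x, one)$score, 4)

  set.seed(71)
  m <- matrix(rnorm(40 * 10, 5), 40, 10)
  big <- expr_fixture(m, unit = "log2")
  genes <- sample(rownames(expr_values(big)), 20)
  got <- score_signatures(big, tibble::tibble(signature = "R", gene = genes))
  oracle <- apply(m[match(genes, rownames(expr_values(big))), ], 2, mean)
  expect_equal(got$score, unname(oracle))

  # permutation invariance in gene order, linearity in a constant shift
  perm <- score_signatures(big, tibble::tibble(signature = "R", gene = rev(genes)))
  expect_equal(perm$score, got$score)
  shifted <- expr_fixture(m + 1.5, unit = "log2")
  expect_equal(
    score_signatures(shifted, tibble::tibble(signature = "R", gene = genes))$score,
    got$score + 1.5
  )

  expect_error(
    score_signatures(x, tibble::tibble(signature = "GHOST", gene = "ZZZ")),
    "GHOST"
  )
  expect_message(
    score_signatures(x, tibble::tibble(signature = "PART", gene = c("A", "ZZZ"))),
    "absent"
  )
})

test_that("per-gene concordance matches the correlation formula oracle", {
  set.seed(81)
  m <- matrix(rnorm(25 * 12, 5), 25, 12)
  a <- expr_fixture(m, unit = "log2")
  same <- gene_concordance(a, a)
  expect_true(all(abs(same$pearson - 1) < 1e-12))

  flipped <- expr_fixture(-m, unit = "log2",
                          genes = expr_genes(a), samples = expr_samples(a))
  expect_true(all(abs(gene_concordance(a, flipped)$pearson + 1) < 1e-12))

  b_m <- m + matrix(rnorm(300), 25, 12)
  b <- expr_fixture(b_m, unit = "log2",
                    genes = expr_genes(a), samples = expr_samples(a))
  got <- gene_concordance(a, b)
  for (i in seq_len(25)) {
    expect_equal(got$pearson[i], cor(m[i, ], b_m[i, ]))
    expect_equal(got$spearman[i], cor(m[i, ], b_m[i, ], method = "spearman"))
  }
  expect_true(all(got$n_samples == 12))

  m2 <- m; m2[3, ] <- 7
  z <- gene_concordance(expr_fixture(m2, unit = "log2",
                                     genes = expr_genes(a),
                                     samples = expr_samples(a)), b)
  expect_true(is.na(z$pearson[3]) && z$constant[3])

  tiny <- expr_fixture(m[, 1:2], unit = "log2")
  expect_error(gene_concordance(tiny, tiny), "3")
})

test_that("concordance filtering keeps the boundary and obeys subset/monotone laws", {
  sigs <- tibble::tibble(signature = "EMT", description = "d",
                         gene = c("G1", "G2", "G3"))
  conc <- tibble::tibble(gene = c("G1", "G2", "G3"),
                         pearson = c(0.39, 0.40, 0.41),
                         spearman = NA_real_, n_samples = 10L, constant = FALSE)
  kept <- suppressMessages(filter_signature(sigs, conc, threshold = 0.4))
  expect_equal(kept$gene, c("G2", "G3"))          # "lower than 0.4" removed
  expect_equal(attr(kept, "removed")$gene, "G1")

  all_kept <- filter_signature(sigs, conc, threshold = -1)
  expect_equal(all_kept$gene, sigs$gene)

  expect_error(filter_signature(sigs, conc, threshold = 0.9), "lower the threshold")

  # untouched signatures pass through even with poor correlations
  tp53 <- tibble::tibble(signature = "TP53", description = "d",
                         gene = c("CDKN1A", "MDM2"))
  both <- dplyr::bind_rows(sigs, tp53)
  conc2 <- dplyr::bind_rows(conc, tibble::tibble(
    gene = c("CDKN1A", "MDM2"), pearson = c(0.1, -0.2),
    spearman = NA_real_, n_samples = 10L, constant = FALSE
  ))
  out <- suppressMessages(filter_signature(both, conc2, threshold = 0.4))
  expect_true(all(tp53$gene %in% out$gene))

  set.seed(91)
  rand_conc <- tibble::tibble(
    gene = sprintf("G%02d", 1:30),
    pearson = runif(30, -1, 1), spearman = NA_real_,
    n_samples = 10L, constant = FALSE
  )
  rand_sig <- tibble::tibble(signature = "EMT", description = "d",
                             gene = rand_conc$gene)
  for (th in c(-0.5, 0, 0.3, 0.6)) {
    got <- suppressMessages(filter_signature(rand_sig, rand_conc, threshold = th))
    expect_equal(sort(got$gene),
                 sort(rand_conc$gene[rand_conc$pearson >= th]))
    expect_true(all(got$gene %in% rand_sig$gene))
  }
  loose <- suppressMessages(filter_signature(rand_sig, rand_conc, threshold = 0.1))
  tight <- suppressMessages(filter_signature(rand_sig, rand_conc, threshold = 0.5))
  expect_true(all(tight$gene %in% loose$gene))
})

test_that("score concordance is 1 on identical platforms and low for discordant genes", {
  set.seed(101)
  m <- matrix(rnorm(30 * 10, 5), 30, 10)
  a <- expr_fixture(m, unit = "log2")
  sigs <- tibble::tibble(signature = "S", gene = expr_genes(a)[1:10])
  expect_equal(score_concordance(a, a, sigs)$pearson, 1)

  # a signature made only of planted discordant genes carries no shared signal
  rs <- vapply(1:5, function(s) {
    co <- simulate_cohort(small_sim_config(n_samples = 100, seed = 110 + s))
    matched <- intersect_platforms(log2_transform(co$reference),
                                   log2_transform(co$target))
    disc <- co$truth$gene[co$truth$signature %in% "EMT" & !co$truth$concordant]
    sc <- score_concordance(matched$a, matched$b,
                            tibble::tibble(signature = "DISC", gene = disc))
    sc$pearson
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.3)
})

test_that("filtering at 0.4 improves cross-platform score concordance", {
  improved <- vapply(1:5, function(s) {
    co <- simulate_cohort(small_sim_config(n_samples = 100,
                                           concordant_fraction = 0.5,
                                           seed = 130 + s))
    matched <- intersect_platforms(log2_transform(co$reference),
                                   log2_transform(co$target))
    sigs <- co$signatures[co$signatures$signature %in% c("EMT", "MSI"), ]
    conc <- gene_concordance(matched$a, matched$b, genes = sigs$gene)
    pre <- score_concordance(matched$a, matched$b, sigs)
    post <- score_concordance(
      matched$a, matched$b,
      suppressMessages(filter_signature(sigs, conc, threshold = 0.4))
    )
    all(post$pearson >= pre$pearson)
  }, logical(1))
  expect_gte(sum(improved), 4L)
})
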