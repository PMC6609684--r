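#' Configure a synthetic paired-platform cohort
#'
#' Defines the generative model for a cohort measured on two platforms: a
#' reference platform on a continuous intensity scale (microarray-like) and a
#' target platform in TPM (RNA-seq-like), over the same samples. Four
#' molecular subtypes are planted (`EMT`, `MSI`, `MSS/TP53+`, `MSS/TP53-`).
#' Each gene has a latent log2 baseline; EMT and MSI signature genes are
#' up-shifted by `effect_size_log2` in samples of their subtype, and the two
#' TP53 target genes (CDKN1A, MDM2) are up-shifted by `tp53_effect` in TP53
#' wild-type samples, where transcriptionally active p53 drives their
#' expression. A configurable fraction of genes is "concordant" (both
#' platforms read the same latent signal, plus platform noise); the rest are
#' "discordant" — the target platform reads an independent latent draw, so
#' their expected cross-platform correlation is ~0 and they carry no subtype
#' signal on the target platform. Target-platform zero dropout is applied to
#' low-baseline genes, mimicking degraded archival (FFPE) RNA. Survival is
#' exponential with subtype-specific hazards (EMT worst, MSI best) and
#' independent censoring.
#'
#' @param n_samples cohort size; 50 matches the archival RNA-seq study arm.
#' @param subtype_proportions named proportions over the four subtype labels;
#'   must sum to 1.
#' @param n_background_genes genes with no signature membership.
#' @param emt_signature_size,msi_signature_size planted signature sizes
#'   (118 and 120, the sizes of the EMT and MSI signatures being filtered).
#' @param auxiliary_signature_size size of the proliferation and cytokine
#'   signatures (carried for scoring/PCA association, no planted effect).
#' @param effect_size_log2 mean log2 up-shift of a signature's genes in its
#'   own subtype.
#' @param concordant_fraction fraction of genes given high cross-platform
#'   fidelity.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene log2
#'   baselines. The default mean of 5 places signature scores on the scale of
#'   the published classifier cutoffs (5.5-5.6).
#' @param biological_sd SD of the shared per-gene, per-sample latent
#'   variation (the signal both platforms can see).
#' @param sigma_reference,sigma_target platform measurement noise SDs on the
#'   log2 scale.
#' @param dropout_rate probability that a TPM entry of a dropout-eligible
#'   gene is zeroed.
#' @param dropout_expression_quantile genes with baseline at or below this
#'   quantile are dropout-eligible.
#' @param tp53_effect log2 up-shift of CDKN1A/MDM2 in TP53 wild-type samples.
#' @param tp53_wildtype_rate_non_mss probability that an EMT or MSI sample is
#'   TP53 wild-type (MSS samples are wild-type iff their subtype is
#'   MSS/TP53+).
#' @param hazard_by_subtype named exponential hazards; default orders
#'   survival MSI best, MSS intermediate, EMT worst.
#' @param censoring_rate expected fraction of samples censored.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a list of class `gc_sim_config`.
#' @export
simulation_config <- function(n_samples = 50L,
                              subtype_proportions = c("EMT" = 0.2, "MSI" = 0.2,
                                                      "MSS/TP53+" = 0.3, "MSS/TP53-" = 0.3),
                              n_background_genes = 300L,
                              emt_signature_size = 118L,
                              msi_signature_size = 120L,
                              auxiliary_signature_size = 25L,
                              effect_size_log2 = 2,
                              concordant_fraction = 0.6,
                              baseline_log2_mean = 5,
                              baseline_log2_sd = 1.2,
                              biological_sd = 1,
                              sigma_reference = 0.5,
                              sigma_target = 0.5,
                              dropout_rate = 0.1,
                              dropout_expression_quantile = 0.25,
                              tp53_effect = 2,
                              tp53_wildtype_rate_non_mss = 0.5,
                              hazard_by_subtype = c("EMT" = 0.4, "MSI" = 0.1,
                                                    "MSS/TP53+" = 0.2, "MSS/TP53-" = 0.2),
                              censoring_rate = 0.3,
                              seed = NULL) {
  labels <- subtype_labels()
  if (!setequal(names(subtype_proportions), labels)) {
    abort("subtype_proportions must be named with the four subtype labels")
  }
  if (abs(sum(subtype_proportions) - 1) > 1e-8) abort("subtype_proportions must sum to 1")
  if (any(subtype_proportions < 0)) abort("subtype_proportions must be >= 0")
  if (!setequal(names(hazard_by_subtype), labels) || any(hazard_by_subtype <= 0)) {
    abort("hazard_by_subtype needs a positive hazard per subtype label")
  }
  stopifnot(
    biological_sd > 0, sigma_reference > 0, sigma_target > 0, baseline_log2_sd > 0,
    dropout_rate >= 0, dropout_rate <= 1,
    dropout_expression_quantile >= 0, dropout_expression_quantile <= 1,
    censoring_rate >= 0, censoring_rate < 1,
    concordant_fraction >= 0, concordant_fraction <= 1
  )
  structure(list(
    n_samples = as.integer(n_samples),
    subtype_proportions = subtype_proportions[labels],
    n_background_genes = as.integer(n_background_genes),
    emt_signature_size = as.integer(emt_signature_size),
    msi_signature_size = as.integer(msi_signature_size),
    auxiliary_signature_size = as.integer(auxiliary_signature_size),
    effect_size_log2 = effect_size_log2,
    concordant_fraction = concordant_fraction,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    biological_sd = biological_sd,
    sigma_reference = sigma_reference,
    sigma_target = sigma_target,
    dropout_rate = dropout_rate,
    dropout_expression_quantile = dropout_expression_quantile,
    tp53_effect = tp53_effect,
    tp53_wildtype_rate_non_mss = tp53_wildtype_rate_non_mss,
    hazard_by_subtype = hazard_by_subtype[labels],
    censoring_rate = censoring_rate,
    seed = seed
  ), class = "gc_sim_config")
}

#' Subtype labels
#'
#' The four molecular subtype labels, in classification precedence order.
#' @return a character vector.
#' @export
subtype_labels <- function() c("EMT", "MSI", "MSS/TP53+", "MSS/TP53-")

#' Simulate a paired-platform cohort
#'
#' Draws a cohort under a [simulation_config()] model. Matrices come back in
#' native units — the reference platform as positive intensities
#' (`2^(latent + noise)`) and the target platform as TPM
#' (`max(0, 2^(latent + noise) - 1)`, so the log2(+1) transform recovers the
#' latent scale and dropout zeros land at log2 value 0). The log-normal
#' target values reproduce the positively skewed, wide-ranged distribution
#' typical of RNA-seq, with zero/robust-signal pairs against the reference
#' platform for dropout genes.
#'
#' @param config a `gc_sim_config`.
#' @return a list of class `gc_cohort` with elements `reference` and
#'   `target` (expression tables), `clinical` (tibble), `signatures` (long
#'   signature tibble), and `truth` (per-gene record of signature
#'   membership, planted concordance class and planted effect).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_samples = 20, seed = 1))
#' cohort$clinical
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "gc_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$effect_size_log2 <= 0 && config$concordant_fraction > 0) {
    warn("effect_size_log2 <= 0: planted subtypes carry no expression signal")
  }

  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  subtype <- sample(subtype_labels(), n, replace = TRUE,
                    prob = config$subtype_proportions)

  genes <- tibble(
    gene = c(
      sprintf("EMT%03d", seq_len(config$emt_signature_size)),
      sprintf("MSI%03d", seq_len(config$msi_signature_size)),
      "CDKN1A", "MDM2",
      sprintf("PRF%03d", seq_len(config$auxiliary_signature_size)),
      sprintf("CYT%03d", seq_len(config$auxiliary_signature_size)),
      sprintf("BG%04d", seq_len(config$n_background_genes))
    ),
    signature = c(
      rep("EMT", config$emt_signature_size),
      rep("MSI", config$msi_signature_size),
      rep("TP53", 2L),
      rep("PROLIF", config$auxiliary_signature_size),
      rep("CYTOKINE", config$auxiliary_signature_size),
      rep(NA_character_, config$n_background_genes)
    )
  )
  g <- nrow(genes)

  # concordance classes: exact planted counts per gene group, TP53 always
  # concordant (its two genes anchor the calibration step)
  concordant <- logical(g)
  for (grp in split(seq_len(g), genes$signature, drop = FALSE)) {
    k <- round(config$concordant_fraction * length(grp))
    concordant[sample(grp, k)] <- TRUE
  }
  bg <- which(is.na(genes$signature))
  concordant[bg] <- FALSE
  concordant[sample(bg, round(config$concordant_fraction * length(bg)))] <- TRUE
  concordant[genes$signature %in% "TP53"] <- TRUE

  baseline <- rnorm(g, config$baseline_log2_mean, config$baseline_log2_sd)

  # planted effects on the shared latent signal
  effect <- matrix(0, g, n)
  is_wt <- ifelse(
    subtype == "MSS/TP53+", TRUE,
    ifelse(subtype == "MSS/TP53-", FALSE,
           runif(n) < config$tp53_wildtype_rate_non_mss)
  )
  effect[genes$signature %in% "EMT", subtype == "EMT"] <- config$effect_size_log2
  effect[genes$signature %in% "MSI", subtype == "MSI"] <- config$effect_size_log2
  effect[genes$signature %in% "TP53", is_wt] <- config$tp53_effect

  latent <- baseline + matrix(rnorm(g * n, 0, config$biological_sd), g, n) + effect
  ref_log2 <- latent + matrix(rnorm(g * n, 0, config$sigma_reference), g, n)

  # discordant genes: the target platform reads an independent latent draw
  # carrying no subtype effect
  tgt_latent <- latent
  nd <- sum(!concordant)
  if (nd > 0L) {
    tgt_latent[!concordant, ] <- baseline[!concordant] +
      matrix(rnorm(nd * n, 0, config$biological_sd), nd, n)
  }
  tgt_log2 <- tgt_latent + matrix(rnorm(g * n, 0, config$sigma_target), g, n)
  tpm <- 2^tgt_log2 - 1
  tpm[tpm < 0] <- 0

  # zero-inflation targeted at low-baseline genes
  eligible <- rep(FALSE, g)
  if (config$dropout_rate > 0 && config$dropout_expression_quantile > 0) {
    eligible <- baseline <= quantile(baseline, config$dropout_expression_quantile)
    ne <- sum(eligible)
    if (ne > 0L) {
      drop <- matrix(runif(ne * n) < config$dropout_rate, ne, n)
      tpm[eligible, ][drop] <- 0
    }
  }

  ref <- 2^ref_log2
  dimnames(ref) <- dimnames(tpm) <- list(genes$gene, sample_ids)

  # survival: exponential event times; exponential censoring tuned so the
  # expected censored fraction equals censoring_rate within each subtype
  haz <- config$hazard_by_subtype[subtype]
  t_event <- rexp(n, haz)
  if (config$censoring_rate > 0) {
    c_rate <- haz * config$censoring_rate / (1 - config$censoring_rate)
    t_cens <- rexp(n, c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)

  clinical <- tibble(
    sample_id = sample_ids,
    gold_subtype = subtype,
    tp53_mutation = ifelse(is_wt, "wild-type", "mutant"),
    os_time = os_time,
    os_event = os_event
  )

  signatures <- genes |>
    dplyr::filter(!is.na(.data$signature)) |>
    dplyr::transmute(.data$signature, description = "planted", .data$gene)

  truth <- genes |>
    dplyr::mutate(
      concordant = concordant,
      dropout_eligible = eligible,
      effect_log2 = dplyr::case_when(
        signature %in% c("EMT", "MSI") ~ config$effect_size_log2,
        signature %in% "TP53" ~ config$tp53_effect,
        TRUE ~ 0
      )
    )

  ref_tbl <- as_expression_table(
    dplyr::bind_cols(tibble(gene = genes$gene), as_tibble(ref)),
    platform = "reference", unit = "intensity"
  )
  tgt_tbl <- as_expression_table(
    dplyr::bind_cols(tibble(gene = genes$gene), as_tibble(tpm)),
    platform = "target", unit = "TPM"
  )

  structure(list(
    reference = ref_tbl, target = tgt_tbl,
    clinical = clinical, signatures = signatures, truth = truth,
    config = config
  ), class = "gc_cohort")
}

#' Write or re-read a simulated cohort
#'
#' `write_cohort()` emits the cohort in the package's exchange formats —
#' `reference.tsv`, `target.tsv`, `clinical.tsv`, `signatures.gmt`,
#' `truth.tsv` — and `read_cohort()` loads them back.
#'
#' @param cohort a `gc_cohort`.
#' @param dir output directory (created if missing).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a list
#'   with the same named elements (minus `config`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gc_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory ", dir))
  }
  write_expression(cohort$reference, file.path(dir, "reference.tsv"))
  write_expression(cohort$target, file.path(dir, "target.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_gmt(cohort$signatures, file.path(dir, "signatures.gmt"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(
    reference = read_expression(file.path(dir, "reference.tsv"), "reference", "intensity"),
    target = read_expression(file.path(dir, "target.tsv"), "target", "TPM"),
    clinical = read_clinical(file.path(dir, "clinical.tsv")),
    signatures = read_gmt(file.path(dir, "signatures.gmt")),
    truth = readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE,
                            col_types = readr::cols(
                              gene = readr::col_character(),
                              signature = readr::col_character(),
                              concordant = readr::col_logical(),
                              dropout_eligible = readr::col_logical(),
                              effect_log2 = readr::col_double()
                            ))
  )
}
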