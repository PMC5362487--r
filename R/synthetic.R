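#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the pipeline targets: 23 tumors versus 12
#' non-neoplastic penile tissues, a miRNA panel of modest size against a
#' larger transcript panel, strongly differentially expressed features (log2
#' effects up to ~8.5, i.e. fold changes up to several hundred), regulatory
#' miRNA/mRNA pairs with strong negative within-tumor correlation, an HPV
#' positive subgroup at the cohort's observed rate, and undetermined-Cq
#' style dropout.
#'
#' @param n_tumor,n_npt Group sizes.
#' @param n_mirna,n_mrna Feature panel sizes.
#' @param n_de_mirna,n_de_mrna Number of planted differentially expressed
#'   features per layer.
#' @param n_true_pairs Number of planted regulatory miRNA/mRNA pairs; each
#'   links a DE miRNA to a DE mRNA with opposite directions.
#' @param n_decoy Number of random decoy interaction records.
#' @param effect_log2_range Range (lo, hi) of absolute log2 tumor shifts for
#'   DE features.
#' @param pair_correlation Target within-tumor correlation of a true pair, in
#'   (-1, 0).
#' @param noise_sd Per-feature Gaussian noise standard deviation (log2 units).
#' @param dropout_rate Fraction of miRNA matrix entries masked as missing.
#' @param frac_hpv_pos,frac_ln_pos Fractions of tumors that are HPV positive /
#'   lymph-node positive.
#' @param ln_effect_log2 Extra log2 shift of the lymph-node marker gene in
#'   LN-positive tumors.
#' @param seed Integer seed; a fixed seed makes the cohort bit-identical.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumor = 23L, n_npt = 12L,
                          n_mirna = 50L, n_mrna = 200L,
                          n_de_mirna = 15L, n_de_mrna = 40L,
                          n_true_pairs = 10L, n_decoy = 100L,
                          effect_log2_range = c(2, 8.5),
                          pair_correlation = -0.8,
                          noise_sd = 1, dropout_rate = 0.05,
                          frac_hpv_pos = 7 / 23, frac_ln_pos = 0.4,
                          ln_effect_log2 = 1.5,
                          seed = 1L) {
  cfg <- list(n_tumor = as.integer(n_tumor), n_npt = as.integer(n_npt),
              n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              n_de_mirna = as.integer(n_de_mirna),
              n_de_mrna = as.integer(n_de_mrna),
              n_true_pairs = as.integer(n_true_pairs),
              n_decoy = as.integer(n_decoy),
              effect_log2_range = as.numeric(effect_log2_range),
              pair_correlation = pair_correlation,
              noise_sd = noise_sd, dropout_rate = dropout_rate,
              frac_hpv_pos = frac_hpv_pos, frac_ln_pos = frac_ln_pos,
              ln_effect_log2 = ln_effect_log2,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_tumor < 2L || n_npt < 2L) stop("need >= 2 samples per group")
    if (n_de_mirna > n_mirna || n_de_mrna > n_mrna)
      stop("more DE features requested than features available")
    if (n_true_pairs > n_de_mirna || n_true_pairs > n_de_mrna)
      stop("infeasible config: n_true_pairs exceeds the DE features ",
           "available to anchor them")
    if (length(effect_log2_range) != 2L ||
        effect_log2_range[1] <= 0 ||
        effect_log2_range[2] < effect_log2_range[1])
      stop("effect_log2_range must be 0 < lo <= hi")
    if (!(pair_correlation > -1 && pair_correlation < 0))
      stop("pair_correlation must lie in (-1, 0)")
    if (noise_sd <= 0) stop("noise_sd must be positive")
    if (dropout_rate < 0 || dropout_rate >= 1)
      stop("dropout_rate must lie in [0, 1)")
  })
  cfg
}

#' Generate a synthetic paired miRNA/mRNA cohort with planted ground truth
#'
#' Baseline expression is i.i.d. normal per feature on the log2 scale. Planted
#' DE features receive an additive log2 shift in tumors with a random sign;
#' each planted regulatory pair couples a DE miRNA and a DE mRNA of opposite
#' direction through a shared per-tumor latent factor with opposite loadings,
#' so their expected within-tumor correlation equals `pair_correlation`. The
#' interaction table contains every true pair (prediction support >= 10 or
#' reporter-validated) plus random decoys with support uniform on 0..12. One
#' up-regulated gene carries an extra shift in lymph-node-positive tumors, and
#' one gene drives an exponential survival model (administratively censored at
#' 60 months). A fraction of miRNA entries is masked to emulate undetermined
#' quantification cycles.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `mirna` and `mrna`
#'   ([expr_matrix()] objects), `annotation` (data.frame), `interactions`
#'   (data.frame) and `truth` (planted ground truth: DE ids and directions,
#'   true pairs, marker ids).
#' @export
generate_cohort <- function(config = cohort_config()) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed)
  n_s <- cfg$n_tumor + cfg$n_npt
  tumor_ids <- sprintf("T%02d", seq_len(cfg$n_tumor))
  npt_ids <- sprintf("N%02d", seq_len(cfg$n_npt))
  samples <- c(tumor_ids, npt_ids)
  is_tumor <- c(rep(TRUE, cfg$n_tumor), rep(FALSE, cfg$n_npt))
  mirna_ids <- sprintf("mir-%03d", seq_len(cfg$n_mirna))
  gene_ids <- sprintf("GENE%04d", seq_len(cfg$n_mrna))

  base_layer <- function(ids) {
    mu <- stats::runif(length(ids), 6, 12)
    v <- matrix(stats::rnorm(length(ids) * n_s, mean = mu, sd = cfg$noise_sd),
                nrow = length(ids), ncol = n_s,
                dimnames = list(ids, samples))
    v
  }
  mi <- base_layer(mirna_ids)
  mr <- base_layer(gene_ids)

  plant_de <- function(v, n_de) {
    idx <- seq_len(n_de)
    dir <- sample(c(-1, 1), n_de, replace = TRUE)
    eff <- stats::runif(n_de, cfg$effect_log2_range[1], cfg$effect_log2_range[2])
    v[idx, is_tumor] <- v[idx, is_tumor] + dir * eff
    list(values = v, dir = dir, eff = eff)
  }
  de_mi <- plant_de(mi, cfg$n_de_mirna)
  de_mr <- plant_de(mr, cfg$n_de_mrna)
  mi <- de_mi$values
  mr <- de_mr$values

  # true pairs: DE miRNA i <-> DE mRNA i, mRNA direction forced opposite;
  # tumor-sample values rebuilt from a shared latent factor with opposite
  # loadings so the pair's within-tumor correlation is pair_correlation
  r <- abs(cfg$pair_correlation)
  for (i in seq_len(cfg$n_true_pairs)) {
    de_mr$dir[i] <- -de_mi$dir[i]
    z <- stats::rnorm(cfg$n_tumor)
    e1 <- stats::rnorm(cfg$n_tumor)
    e2 <- stats::rnorm(cfg$n_tumor)
    mu_mi <- mean(mi[i, !is_tumor]) + de_mi$dir[i] * de_mi$eff[i]
    mu_mr <- mean(mr[i, !is_tumor]) + de_mr$dir[i] * de_mr$eff[i]
    mi[i, is_tumor] <- mu_mi +
      cfg$noise_sd * (sqrt(r) * z + sqrt(1 - r) * e1)
    mr[i, is_tumor] <- mu_mr +
      cfg$noise_sd * (-sqrt(r) * z + sqrt(1 - r) * e2)
  }
  true_pairs <- data.frame(mirna_id = mirna_ids[seq_len(cfg$n_true_pairs)],
                           gene_id = gene_ids[seq_len(cfg$n_true_pairs)],
                           stringsAsFactors = FALSE)

  # clinical covariates (tumors only)
  n_hpv <- round(cfg$frac_hpv_pos * cfg$n_tumor)
  n_ln <- round(cfg$frac_ln_pos * cfg$n_tumor)
  hpv <- rep("negative", cfg$n_tumor)
  hpv[sample.int(cfg$n_tumor, n_hpv)] <- "positive"
  ln <- rep("absent", cfg$n_tumor)
  ln[sample.int(cfg$n_tumor, n_ln)] <- "present"
  t_stage <- sample(c("T1_2", "T3_4"), cfg$n_tumor, replace = TRUE,
                    prob = c(0.6, 0.4))
  pni <- sample(c("present", "absent"), cfg$n_tumor, replace = TRUE,
                prob = c(0.25, 0.75))
  grade <- sample(c("I", "II", "III"), cfg$n_tumor, replace = TRUE,
                  prob = c(0.25, 0.45, 0.3))

  # marker genes: up-regulated DE genes outside the true pairs. A fully null
  # cohort (n_de_mrna = 0) plants no markers at all.
  if (cfg$n_de_mrna > 0L) {
    up_free <- setdiff(which(de_mr$dir > 0), seq_len(cfg$n_true_pairs))
    if (length(up_free) < 2L) {
      # force spare DE genes upward rather than fail
      spare <- setdiff(seq_len(cfg$n_de_mrna), seq_len(cfg$n_true_pairs))
      if (length(spare) < 2L)
        stop("infeasible config: no spare DE genes for the clinical markers")
      flip <- setdiff(spare, up_free)[seq_len(2L - length(up_free))]
      mr[flip, is_tumor] <- mr[flip, is_tumor] + 2 * de_mr$eff[flip]
      de_mr$dir[flip] <- 1
      up_free <- union(up_free, flip)
    }
    ln_marker <- gene_ids[up_free[1L]]
    surv_marker <- gene_ids[up_free[2L]]
    mr[ln_marker, is_tumor][ln == "present"] <-
      mr[ln_marker, is_tumor][ln == "present"] + cfg$ln_effect_log2
    x <- mr[surv_marker, is_tumor]
    lp <- (x - mean(x)) / stats::sd(x)
  } else {
    ln_marker <- NA_character_
    surv_marker <- NA_character_
    lp <- rep(0, cfg$n_tumor)
  }

  # exponential survival with hazard increasing in the survival marker
  lambda <- log(2) / 30 * exp(lp)         # median 30 months at average marker
  t_raw <- stats::rexp(cfg$n_tumor, rate = lambda)
  event <- as.integer(t_raw <= 60)
  surv <- pmin(t_raw, 60)

  annotation <- data.frame(
    sample_id = samples,
    group = ifelse(is_tumor, "tumor", "NPT"),
    hpv = c(hpv, rep("unknown", cfg$n_npt)),
    lymph_node = c(ln, rep("unknown", cfg$n_npt)),
    t_stage = c(t_stage, rep("unknown", cfg$n_npt)),
    perineural_invasion = c(pni, rep("unknown", cfg$n_npt)),
    grade = c(grade, rep("unknown", cfg$n_npt)),
    survival_months = c(round(surv, 2), rep(NA_real_, cfg$n_npt)),
    event = c(event, rep(NA_integer_, cfg$n_npt)),
    stringsAsFactors = FALSE)

  # interaction table: true pairs (support >= 10 or validated) + decoys
  n_tp <- cfg$n_true_pairs
  tp_support <- sample(8:12, n_tp, replace = TRUE)
  tp_validated <- tp_support < 10L   # low-support true pairs enter as validated
  inter <- data.frame(mirna_id = true_pairs$mirna_id,
                      gene_id = true_pairs$gene_id,
                      support = tp_support, validated = tp_validated,
                      stringsAsFactors = FALSE)
  if (cfg$n_decoy > 0L) {
    seen <- paste(inter$mirna_id, inter$gene_id)
    dec <- data.frame(mirna_id = character(0), gene_id = character(0))
    while (nrow(dec) < cfg$n_decoy) {
      cand <- data.frame(
        mirna_id = sample(mirna_ids, cfg$n_decoy, replace = TRUE),
        gene_id = sample(gene_ids, cfg$n_decoy, replace = TRUE),
        stringsAsFactors = FALSE)
      cand <- cand[!paste(cand$mirna_id, cand$gene_id) %in% seen &
                     !duplicated(paste(cand$mirna_id, cand$gene_id)), ,
                   drop = FALSE]
      dec <- rbind(dec, cand)
      seen <- c(seen, paste(cand$mirna_id, cand$gene_id))
    }
    dec <- dec[seq_len(cfg$n_decoy), , drop = FALSE]
    dec$support <- sample(0:12, cfg$n_decoy, replace = TRUE)
    dec$validated <- FALSE
    inter <- rbind(inter, dec)
  }
  rownames(inter) <- NULL

  if (cfg$dropout_rate > 0) {
    mask <- matrix(stats::runif(length(mi)) < cfg$dropout_rate,
                   nrow = nrow(mi))
    mi[mask] <- NA_real_
  }

  truth <- list(
    de_mirna = data.frame(feature_id = mirna_ids[seq_len(cfg$n_de_mirna)],
                          direction = de_mi$dir,
                          effect_log2 = de_mi$eff, stringsAsFactors = FALSE),
    de_mrna = data.frame(feature_id = gene_ids[seq_len(cfg$n_de_mrna)],
                         direction = de_mr$dir,
                         effect_log2 = de_mr$eff, stringsAsFactors = FALSE),
    true_pairs = true_pairs,
    ln_marker_id = ln_marker,
    survival_marker_id = surv_marker)

  structure(list(mirna = expr_matrix(mi, "miRNA"),
                 mrna = expr_matrix(mr, "mRNA"),
                 annotation = annotation,
                 interactions = validate_interactions(inter),
                 truth = truth,
                 config = cfg),
            class = "synthetic_cohort")
}

#' Generate synthetic RT-qPCR Cq tables for a cohort
#'
#' Cq values are inversely proportional to log2 expression (one cycle per
#' log2 unit for a perfectly efficient assay) plus measurement noise;
#' reference assays have group-independent Cq. Assay efficiencies are drawn
#' uniformly from \[1.8, 2.0\]. A fraction of target reactions fails to cross
#' threshold (undetermined Cq, masked as missing).
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param target_ids Feature ids to assay; defaults to the planted DE miRNAs
#'   (up to 8).
#' @param n_refs Number of reference assays.
#' @param cq_noise Cq measurement noise standard deviation (cycles).
#' @return A list with `cq_targets` and `cq_refs` ([expr_matrix()] objects of
#'   kind `"qPCR-Cq"`) and `efficiencies` (named numeric vector over all
#'   assays).
#' @export
generate_qpcr <- function(cohort, target_ids = NULL, n_refs = 2L,
                          cq_noise = 0.3) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$config
  set.seed(cfg$seed + 10000L)
  if (is.null(target_ids))
    target_ids <- utils::head(cohort$truth$de_mirna$feature_id, 8L)
  expr <- rbind(unclass(cohort$mirna), unclass(cohort$mrna))
  missing_ids <- setdiff(target_ids, rownames(expr))
  if (length(missing_ids))
    stop("unknown target id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  samples <- colnames(expr)
  n_s <- length(samples)

  cq_t <- 32 - expr[target_ids, , drop = FALSE] +
    matrix(stats::rnorm(length(target_ids) * n_s, sd = cq_noise),
           nrow = length(target_ids))
  # expression dropouts and qPCR failures both show up as undetermined Cq
  if (cfg$dropout_rate > 0) {
    fail <- matrix(stats::runif(length(cq_t)) < cfg$dropout_rate,
                   nrow = nrow(cq_t))
    cq_t[fail] <- NA_real_
  }
  ref_ids <- sprintf("REF%d", seq_len(n_refs))
  cq_r <- matrix(stats::rnorm(n_refs * n_s, mean = 25, sd = cq_noise / 2),
                 nrow = n_refs, dimnames = list(ref_ids, samples))
  eff <- stats::runif(length(target_ids) + n_refs, 1.8, 2.0)
  names(eff) <- c(target_ids, ref_ids)
  list(cq_targets = expr_matrix(cq_t, "qPCR-Cq"),
       cq_refs = expr_matrix(cq_r, "qPCR-Cq"),
       efficiencies = eff)
}
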