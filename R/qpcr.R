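#' Efficiency-corrected relative quantification ratio (Pfaffl model)
#'
#' `ratio = E_target^dCq_target / geomean_j(E_ref_j^dCq_ref_j)` where
#' `dCq = mean Cq of the calibrator group - Cq of the sample` and `E` is the
#' amplification factor per cycle (2 = perfect doubling). With several
#' reference assays the per-reference denominators are combined by geometric
#' mean; with all efficiencies equal to 2 the log2 ratio reduces exactly to
#' `dCq_target - mean(dCq_refs)`.
#'
#' @param e_target Target assay efficiency (> 1 for an informative assay).
#' @param dcq_target Target delta-Cq (calibrator mean minus sample).
#' @param e_ref,dcq_ref Numeric vectors over reference assays.
#' @return The relative expression ratio (positive scalar).
#' @export
pfaffl_ratio <- function(e_target, dcq_target, e_ref, dcq_ref) {
  if (!length(e_ref)) stop("at least one reference assay is required",
                           call. = FALSE)
  if (length(e_ref) != length(dcq_ref))
    stop("e_ref and dcq_ref lengths differ", call. = FALSE)
  if (e_target <= 0 || any(e_ref <= 0))
    stop("efficiencies must be positive", call. = FALSE)
  num_log <- dcq_target * log(e_target)
  den_log <- mean(dcq_ref * log(e_ref))
  exp(num_log - den_log)
}

#' Per-sample relative expression from Cq tables
#'
#' For every sample and target assay, computes the Pfaffl ratio against the
#' calibrator group: delta-Cq values are `mean Cq over calibrator samples -
#' sample Cq`, per assay. An undetermined (missing) target Cq yields a
#' missing ratio; a sample missing all reference Cq values is flagged and its
#' ratios are missing.
#'
#' @param cq_targets,cq_refs [expr_matrix()] objects of kind `"qPCR-Cq"`
#'   (assays x samples, identical sample sets).
#' @param efficiencies Named numeric vector of amplification efficiencies for
#'   every assay in both matrices; assays absent from the vector default to 2.
#' @param calibrator_samples Character vector of sample ids forming the
#'   calibrator group (typically the non-neoplastic tissues).
#' @return A data.frame `sample_id`, `assay_id`, `ratio` (NA where
#'   unevaluable).
#' @export
relative_expression_table <- function(cq_targets, cq_refs,
                                      efficiencies = NULL,
                                      calibrator_samples) {
  if (!length(calibrator_samples))
    stop("calibrator group is empty", call. = FALSE)
  samples <- sample_ids(cq_targets)
  if (!setequal(samples, sample_ids(cq_refs)))
    stop("target and reference Cq tables cover different samples",
         call. = FALSE)
  unknown <- setdiff(calibrator_samples, samples)
  if (length(unknown))
    stop("calibrator sample(s) absent from Cq tables: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  tmat <- unclass(cq_targets)
  rmat <- unclass(cq_refs)[, samples, drop = FALSE]
  assays <- rownames(tmat)
  refs <- rownames(rmat)
  eff <- stats::setNames(rep(2, length(c(assays, refs))), c(assays, refs))
  if (!is.null(efficiencies)) {
    eff[names(efficiencies)] <- efficiencies
  }
  cal_t <- rowMeans(tmat[, calibrator_samples, drop = FALSE], na.rm = TRUE)
  cal_r <- rowMeans(rmat[, calibrator_samples, drop = FALSE], na.rm = TRUE)
  out <- expand.grid(sample_id = samples, assay_id = assays,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$ratio <- NA_real_
  no_ref <- character(0)
  for (s in samples) {
    ref_ok <- !is.na(rmat[, s])
    if (!any(ref_ok)) {
      no_ref <- c(no_ref, s)
      next
    }
    dcq_r <- cal_r[ref_ok] - rmat[ref_ok, s]
    e_r <- eff[refs[ref_ok]]
    for (a in assays) {
      cq <- tmat[a, s]
      if (is.na(cq)) next
      out$ratio[out$sample_id == s & out$assay_id == a] <-
        pfaffl_ratio(eff[[a]], cal_t[[a]] - cq, e_r, dcq_r)
    }
  }
  if (length(no_ref))
    warning("sample(s) with no reference Cq, ratios set missing: ",
            paste(no_ref, collapse = ", "))
  out
}

#' Compare relative expression between two annotation groups
#'
#' Two-sided t-test per assay, by default on log2 ratios (the scale on which
#' a parametric test is defensible), with significance stars at the
#' conventional 0.05 / 0.01 / 0.001 levels.
#'
#' @param ratios Result of [relative_expression_table()].
#' @param annotation Annotation data.frame.
#' @param variable Binary annotation column (default `"group"`).
#' @param log_scale Test log2(ratio) (default) rather than raw ratios.
#' @return A data.frame per assay: `assay_id`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b` (on the tested scale), `direction` (+1 higher in group A),
#'   `p_value`, `stars`, `tested`.
#' @export
compare_groups <- function(ratios, annotation, variable = "group",
                           log_scale = TRUE) {
  grp <- annotation_groups(annotation, variable)
  assays <- unique(ratios$assay_id)
  out <- data.frame(assay_id = assays, n_a = NA_integer_, n_b = NA_integer_,
                    mean_a = NA_real_, mean_b = NA_real_,
                    direction = NA_real_, p_value = NA_real_,
                    stars = "", tested = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(assays)) {
    r <- ratios[ratios$assay_id == assays[i], , drop = FALSE]
    val <- if (log_scale) log2(r$ratio) else r$ratio
    xa <- val[r$sample_id %in% grp[[1L]] & !is.na(val)]
    xb <- val[r$sample_id %in% grp[[2L]] & !is.na(val)]
    out$n_a[i] <- length(xa)
    out$n_b[i] <- length(xb)
    if (length(xa) < 2L || length(xb) < 2L) next
    if (stats::var(xa) == 0 && stats::var(xb) == 0) next
    tt <- stats::t.test(xa, xb, var.equal = TRUE)
    out$mean_a[i] <- mean(xa)
    out$mean_b[i] <- mean(xb)
    out$direction[i] <- if (mean(xa) >= mean(xb)) 1 else -1
    out$p_value[i] <- tt$p.value
    out$stars[i] <- significance_stars(tt$p.value)
    out$tested[i] <- TRUE
  }
  out
}

#' Conventional significance stars
#'
#' `"*"` for p < 0.05, `"**"` for p < 0.01, `"***"` for p < 0.001, `""`
#' otherwise (vectorized).
#'
#' @param p Numeric vector of p-values.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}
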