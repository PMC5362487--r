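#' Remove low-abundance features
#'
#' Features whose missing fraction exceeds `max_missing_frac` across the
#' samples of a comparison are excluded. This mirrors the standard handling of
#' low-abundance miRNAs whose quantification cycle is undetermined in more
#' than 20% of samples: a feature missing in exactly 20% of samples is
#' retained, only strictly more is excluded.
#'
#' @param m An [expr_matrix()].
#' @param groups A list of two character vectors of sample ids defining the
#'   comparison; the missing fraction is evaluated over their union.
#' @param max_missing_frac Maximum tolerated missing fraction (default 0.20).
#' @return The filtered [expr_matrix()], feature order preserved.
#' @export
filter_low_abundance <- function(m, groups, max_missing_frac = 0.20) {
  samp <- unique(unlist(groups))
  unknown <- setdiff(samp, sample_ids(m))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  frac <- rowMeans(is.na(m[, samp, drop = FALSE]))
  keep <- frac <= max_missing_frac
  if (!any(keep))
    warning("all features exceed the missing-fraction threshold; ",
            "returning an empty matrix")
  m[keep, , drop = FALSE]
}

#' Signed fold change between two log2 group means
#'
#' With `d = mean_a - mean_b`, returns `2^d` when `d >= 0` and `-2^(-d)`
#' otherwise, so down-regulation is reported as a negative fold (the
#' convention under which a 352.4-fold up-regulation and a -149.3-fold
#' down-regulation are both "FC > 2" in magnitude). Antisymmetric:
#' `signed_fold_change(a, b) == -signed_fold_change(b, a)` for `a != b`.
#'
#' @param mean_a,mean_b Log2-scale group means (vectorized).
#' @return Signed fold change(s), magnitude always >= 1.
#' @export
signed_fold_change <- function(mean_a, mean_b) {
  d <- mean_a - mean_b
  ifelse(d >= 0, 2^d, -2^(-d))
}

#' Two-group differential expression with BH-FDR
#'
#' Per-feature two-sided two-sample t-test on log2 values with pairwise
#' deletion of missing entries, Benjamini-Hochberg q-values over all tested
#' features, and a three-part significance rule: `p < p_max` AND
#' `q < fdr_max` AND `|signed_fc| >= fc_min`. The defaults reproduce the
#' miRNA screening rule (P < 0.01, FDR < 5%, FC > 2); the transcript rule is
#' obtained with `p_max = 0.001, fdr_max = 1, fc_min = 2` (a 99.9% confidence
#' criterion without an FDR gate).
#'
#' @param m An [expr_matrix()].
#' @param groups List of two character vectors of sample ids: group A then
#'   group B (fold changes are A vs B).
#' @param p_max,fdr_max,fc_min Significance thresholds.
#' @param test `"pooled_t"` (equal-variance, the classic array convention) or
#'   `"welch_t"`.
#' @return A data.frame, one row per feature, sorted by p-value (ties broken
#'   by feature id): `feature_id`, `mean_a`, `mean_b`, `signed_fc`,
#'   `p_value`, `q_value`, `significant`, `n_a`, `n_b`, `tested`, `reason`.
#'   Features with fewer than 2 non-missing values in either group, or
#'   constant within both groups, are reported untested (`p_value` NA, never
#'   significant) with the reason recorded.
#' @export
differential_expression <- function(m, groups,
                                    p_max = 0.01, fdr_max = 0.05,
                                    fc_min = 2,
                                    test = c("pooled_t", "welch_t")) {
  test <- match.arg(test)
  stopifnot(length(groups) == 2L)
  a_ids <- groups[[1L]]
  b_ids <- groups[[2L]]
  unknown <- setdiff(c(a_ids, b_ids), sample_ids(m))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  va <- unclass(m)[, a_ids, drop = FALSE]
  vb <- unclass(m)[, b_ids, drop = FALSE]
  n <- nrow(m)
  out <- data.frame(feature_id = feature_ids(m),
                    mean_a = NA_real_, mean_b = NA_real_,
                    signed_fc = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, significant = FALSE,
                    n_a = NA_integer_, n_b = NA_integer_,
                    tested = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    xa <- va[i, ][!is.na(va[i, ])]
    xb <- vb[i, ][!is.na(vb[i, ])]
    out$n_a[i] <- length(xa)
    out$n_b[i] <- length(xb)
    if (length(xa) < 2L || length(xb) < 2L) {
      out$reason[i] <- "fewer than 2 observations in a group"
      next
    }
    out$mean_a[i] <- mean(xa)
    out$mean_b[i] <- mean(xb)
    out$signed_fc[i] <- signed_fold_change(mean(xa), mean(xb))
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      out$reason[i] <- "constant within both groups"
      next
    }
    tt <- stats::t.test(xa, xb, var.equal = (test == "pooled_t"))
    out$p_value[i] <- tt$p.value
    out$tested[i] <- TRUE
  }
  tested <- out$tested
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out$significant <- tested &
    !is.na(out$p_value) & out$p_value < p_max &
    out$q_value < fdr_max &
    abs(out$signed_fc) >= fc_min
  ord <- order(out$p_value, out$feature_id, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split sample ids by annotation group
#'
#' Convenience helper returning `list(A, B)` of sample ids for a binary
#' annotation variable, suitable for [differential_expression()]. Samples
#' with unknown/missing values are dropped.
#'
#' @param annotation Annotation data.frame (see [read_annotation()]).
#' @param variable Column name, default `"group"`.
#' @param levels Optional two levels (A then B); defaults to
#'   `c("tumor", "NPT")` for `group` and the two observed levels otherwise.
#' @export
annotation_groups <- function(annotation, variable = "group",
                              levels = NULL) {
  v <- annotation[[variable]]
  if (is.null(v)) stop("no annotation column '", variable, "'", call. = FALSE)
  keep <- !is.na(v) & v != "unknown"
  v <- v[keep]
  ids <- annotation$sample_id[keep]
  if (is.null(levels)) {
    levels <- if (variable == "group") c("tumor", "NPT") else sort(unique(v))
  }
  if (length(levels) != 2L)
    stop("variable '", variable, "' does not have exactly 2 levels (got: ",
         paste(unique(v), collapse = ", "), ")", call. = FALSE)
  lapply(levels, function(l) ids[v == l])
}
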