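#' Area under the ROC curve by pair counting
#'
#' The Mann-Whitney U-statistic form of the AUC: the fraction of
#' (positive, negative) sample pairs in which the positive sample has the
#' higher value, ties counted 0.5. The orientation is fixed — the returned
#' value is the AUC of the rule "higher value predicts the positive class" —
#' so a marker that is lower in positives yields an AUC below 0.5 rather than
#' being silently flipped.
#'
#' @param values Numeric vector (missing values dropped together with their
#'   labels).
#' @param labels Logical vector (or coercible): `TRUE` = positive class.
#' @return AUC in \[0, 1\].
#' @export
marker_auc <- function(values, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  labels <- labels[ok]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(values)                     # average ranks for ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Select top discriminating markers by AUC
#'
#' Features are ranked by their direction-folded discrimination
#' `max(AUC, 1 - AUC)`, so strongly down-regulated markers compete on equal
#' footing with up-regulated ones; ties are broken by feature id
#' (lexicographic).
#'
#' @param m An [expr_matrix()].
#' @param labels Logical vector over `sample_ids(m)`: positive class.
#' @param n Number of markers to select.
#' @return A data.frame of the selected markers: `feature_id`, `auc` (raw,
#'   higher-predicts-positive orientation), `discrimination`, `orientation`
#'   (`"higher"`/`"lower"` value in positives).
#' @export
select_markers <- function(m, labels, n) {
  stopifnot(n >= 1L)
  if (n > nrow(m))
    stop("requested ", n, " markers but only ", nrow(m),
         " features are available", call. = FALSE)
  auc <- vapply(seq_len(nrow(m)), function(i)
    marker_auc(unclass(m)[i, ], labels), numeric(1))
  out <- data.frame(feature_id = feature_ids(m), auc = auc,
                    discrimination = pmax(auc, 1 - auc),
                    orientation = ifelse(auc >= 0.5, "higher", "lower"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$discrimination, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out[seq_len(n), , drop = FALSE]
}

#' Linear SVM classifier assessed by leave-one-out cross-validation
#'
#' For each sample, a linear-kernel SVM (cost `cost`) is trained on the
#' remaining samples — features standardized using training-fold statistics
#' only — and used to predict the held-out sample. Accuracy, sensitivity and
#' specificity are computed from the pooled LOOCV confusion matrix. The
#' procedure is deterministic given its input.
#'
#' @param m An [expr_matrix()] restricted to the marker panel (features x
#'   samples); missing marker values are mean-imputed within the training
#'   fold.
#' @param labels Character/factor vector over samples (2 classes).
#' @param positive_class Label treated as positive (default `"tumor"` if
#'   present, else the first level).
#' @param cost SVM cost parameter (default 1).
#' @return A list of class `classifier_report`: `marker_ids`, `predictions`
#'   (data.frame `sample_id`, `label`, `predicted`), `accuracy`,
#'   `sensitivity`, `specificity`, `positive_class`, `confusion`.
#' @export
svm_loocv <- function(m, labels, positive_class = NULL, cost = 1) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(m))
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly 2 classes required", call. = FALSE)
  if (is.null(positive_class))
    positive_class <- if ("tumor" %in% lev) "tumor" else lev[1L]
  if (min(table(labels)) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  x <- t(unclass(m))                    # samples x features
  n <- nrow(x)
  pred <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]
    tr_y <- factor(labels[-i], levels = lev)
    if (nlevels(droplevels(tr_y)) < 2L) next   # fold flagged: untrainable
    mu <- colMeans(tr_x, na.rm = TRUE)
    for (j in seq_len(ncol(tr_x))) tr_x[is.na(tr_x[, j]), j] <- mu[j]
    sdv <- apply(tr_x, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    tr_s <- sweep(sweep(tr_x, 2L, mu), 2L, sdv, "/")
    te <- x[i, ]
    te[is.na(te)] <- mu[is.na(te)]
    te_s <- (te - mu) / sdv
    fit <- e1071::svm(tr_s, tr_y, kernel = "linear", cost = cost,
                      scale = FALSE)
    pred[i] <- as.character(stats::predict(fit, rbind(te_s)))
  }
  ok <- !is.na(pred)
  if (!all(ok))
    warning(sum(!ok), " sample(s) excluded: training fold lacked a class")
  is_pos <- labels[ok] == positive_class
  pr_pos <- pred[ok] == positive_class
  tp <- sum(is_pos & pr_pos); fn <- sum(is_pos & !pr_pos)
  tn <- sum(!is_pos & !pr_pos); fp <- sum(!is_pos & pr_pos)
  structure(list(
    marker_ids = feature_ids(m),
    predictions = data.frame(sample_id = sample_ids(m), label = labels,
                             predicted = pred, stringsAsFactors = FALSE),
    accuracy = (tp + tn) / sum(ok),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    positive_class = positive_class,
    confusion = matrix(c(tp, fp, fn, tn), 2L, 2L,
                       dimnames = list(truth = c("pos", "neg"),
                                       predicted = c("pos", "neg")))),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "LOOCV linear SVM on %d markers (%s positive)\n accuracy %.3f  sensitivity %.3f  specificity %.3f\n",
    length(x$marker_ids), x$positive_class,
    x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Compare predictors of a binary outcome by AUC
#'
#' Applies [marker_auc()] uniformly to each predictor — continuous expression
#' values or ordinal clinical covariates encoded by their natural order
#' (grade I < II < III, T stage T1_2 < T3_4, invasion absent < present) — and
#' reports one AUC per predictor, sorted descending. AUCs are reported
#' unflipped, so a predictor that runs against the outcome scores below 0.5.
#'
#' @param predictors Named list of numeric vectors (aligned with `outcome`).
#' @param outcome Logical vector: `TRUE` = positive outcome class.
#' @return A data.frame `predictor`, `auc`, `n`, sorted by AUC descending.
#' @export
roc_compare <- function(predictors, outcome) {
  stopifnot(is.list(predictors), length(names(predictors)) ==
              length(predictors))
  out <- data.frame(predictor = names(predictors), auc = NA_real_,
                    n = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(predictors)) {
    v <- predictors[[i]]
    ok <- !is.na(v) & !is.na(outcome)
    out$auc[i] <- marker_auc(v[ok], outcome[ok])
    out$n[i] <- sum(ok)
  }
  out <- out[order(-out$auc, out$predictor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Encode an ordinal clinical covariate as a numeric predictor
#'
#' @param annotation Annotation data.frame.
#' @param variable One of `"grade"`, `"t_stage"`, `"perineural_invasion"`,
#'   `"lymph_node"`, `"hpv"`.
#' @return Numeric vector aligned with `annotation$sample_id` (unknowns NA).
#' @export
ordinal_covariate <- function(annotation, variable) {
  orders <- list(grade = c("I", "II", "III"),
                 t_stage = c("T1_2", "T3_4"),
                 perineural_invasion = c("absent", "present"),
                 lymph_node = c("absent", "present"),
                 hpv = c("negative", "positive"))
  if (!variable %in% names(orders))
    stop("no ordinal encoding for '", variable, "'", call. = FALSE)
  v <- annotation[[variable]]
  as.numeric(match(v, orders[[variable]]))
}

#' Screen features for association with a clinical variable
#'
#' Reuses the differential-expression machinery (same pooled t-test and BH
#' adjustment) over a binary clinical covariate, with the screening
#' thresholds p < 0.01 and FDR < 20% and no fold-change gate.
#'
#' @param m An [expr_matrix()].
#' @param annotation Annotation data.frame.
#' @param variable Binary clinical column; samples with unknown values are
#'   dropped. Each level must retain at least 2 samples.
#' @param p_max,fdr_max Thresholds (defaults 0.01 and 0.20).
#' @return A data.frame `feature_id`, `clinical_variable`, `p_value`,
#'   `q_value`, `direction` (+1 higher in the first level), `significant`.
#' @export
clinical_association <- function(m, annotation, variable,
                                 p_max = 0.01, fdr_max = 0.20) {
  grp <- annotation_groups(annotation, variable)
  small <- lengths(grp) < 2L
  if (any(small))
    stop("level with fewer than 2 samples in '", variable, "'",
         call. = FALSE)
  grp <- lapply(grp, intersect, sample_ids(m))
  de <- differential_expression(m, grp, p_max = p_max, fdr_max = fdr_max,
                                fc_min = 1)
  data.frame(feature_id = de$feature_id, clinical_variable = variable,
             p_value = de$p_value, q_value = de$q_value,
             direction = ifelse(is.na(de$signed_fc), NA_real_,
                                sign(de$signed_fc)),
             significant = de$significant, stringsAsFactors = FALSE)
}

#' Median-dichotomized survival analysis
#'
#' Samples are split at the median of the marker values — ties at the median
#' go to the low group ("below median" vs "above median") — and the two
#' groups are compared with Kaplan-Meier estimates and the log-rank test.
#'
#' @param values Named numeric vector of marker values (names = sample ids).
#' @param annotation Annotation data.frame with `survival_months` and
#'   `event`.
#' @return A list: `groups` (data.frame `sample_id`, `group`), `fit`
#'   (survfit), `chisq`, `p_value`, `n`.
#' @export
survival_by_median <- function(values, annotation) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2L)
    stop("degenerate split: all marker values are equal", call. = FALSE)
  med <- stats::median(values)
  grp <- ifelse(values <= med, "low", "high")
  if (min(table(grp)) < 2L)
    stop("median split leaves fewer than 2 samples on one side",
         call. = FALSE)
  idx <- match(names(values), annotation$sample_id)
  res <- .km_logrank(annotation$survival_months[idx],
                     annotation$event[idx], grp)
  list(groups = data.frame(sample_id = names(values), group = grp,
                           stringsAsFactors = FALSE),
       fit = res$fit, chisq = res$chisq, p_value = res$p_value, n = res$n)
}
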