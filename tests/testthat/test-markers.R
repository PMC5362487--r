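test_that("marker_auc equals the exhaustive pair-counting oracle", {
  expect_equal(marker_auc(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(marker_auc(rep(3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(marker_auc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)),
               oracle_auc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)))
  set.seed(13)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    v <- sample(1:10, n, replace = TRUE)   # ties guaranteed
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(l)) < 2) l[1:2] <- c(TRUE, FALSE)
    expect_identical(marker_auc(v, l), oracle_auc(v, l))
  }
  expect_error(marker_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC of a predictor and its negation sum to 1", {
  set.seed(14)
  v <- rnorm(30)
  l <- rep(c(TRUE, FALSE), 15)
  expect_equal(marker_auc(v, l) + marker_auc(-v, l), 1)
})

test_that("select_markers ranks by folded discrimination with id tie-breaks", {
  # f1 strongly up, f2 strongly down, f3-f5 noise
  set.seed(15)
  v <- matrix(rnorm(5 * 20), 5, 20)
  lab <- rep(c(TRUE, FALSE), each = 10)
  v[1, lab] <- v[1, lab] + 4
  v[2, lab] <- v[2, lab] - 4
  m <- toy_matrix(v)
  top <- select_markers(m, lab, 2)
  expect_setequal(top$feature_id, c("f1", "f2"))
  expect_identical(top$orientation[top$feature_id == "f2"], "lower")
  # exact ties fall back to lexicographic id order
  v2 <- rbind(b_feat = c(1, 2, 3, 4), a_feat = c(1, 2, 3, 4),
              z = c(2, 2, 2, 2))
  colnames(v2) <- paste0("s", 1:4)
  top2 <- select_markers(expr_matrix(v2, "mRNA"), c(FALSE, FALSE, TRUE, TRUE),
                         1)
  expect_identical(top2$feature_id, "a_feat")
  expect_error(select_markers(m, lab, 99), "available")
})

test_that("LOOCV SVM is perfect on wide-margin data, chance on permuted labels", {
  set.seed(16)
  n <- 30
  lab <- rep(c("tumor", "NPT"), each = n / 2)
  v <- matrix(rnorm(3 * n, sd = 0.3), 3, n)
  v[, lab == "tumor"] <- v[, lab == "tumor"] + 5
  m <- toy_matrix(v)
  rep_sep <- svm_loocv(m, lab)
  expect_equal(rep_sep$accuracy, 1)
  expect_equal(rep_sep$sensitivity, 1)
  expect_equal(rep_sep$specificity, 1)
  # metrics recomputed from emitted per-sample predictions match
  pr <- rep_sep$predictions
  expect_equal(rep_sep$accuracy, mean(pr$predicted == pr$label))
  expect_equal(sum(rep_sep$confusion), n)

  # permutation null: no signal left, accuracy lands in the chance band
  perm <- sample(lab)
  v0 <- matrix(rnorm(3 * n), 3, n)
  rep_null <- svm_loocv(toy_matrix(v0), perm)
  expect_gte(rep_null$accuracy, 0.2)
  expect_lte(rep_null$accuracy, 0.8)

  # deterministic given input
  expect_identical(svm_loocv(m, lab)$predictions, rep_sep$predictions)
})

test_that("roc_compare: closed form for binary predictors, ranked output", {
  # single-threshold predictor: AUC = (sensitivity + specificity) / 2
  outcome <- c(rep(TRUE, 10), rep(FALSE, 10))
  predictor <- c(rep(1, 7), rep(0, 3), rep(1, 2), rep(0, 8))  # sens .7 spec .8
  tab <- roc_compare(list(bin = predictor, perfect = as.numeric(outcome)),
                     outcome)
  expect_equal(tab$auc[tab$predictor == "bin"], (0.7 + 0.8) / 2)
  expect_equal(tab$auc[tab$predictor == "perfect"], 1)
  expect_identical(tab$predictor[1], "perfect")   # sorted descending
  expect_equal(tab$auc[tab$predictor == "bin"],
               oracle_auc(predictor, outcome))
})

test_that("planted LN marker outperforms noise in predicting node status", {
  aucs <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_config(seed = s))
    tum <- co$annotation[co$annotation$group == "tumor", ]
    ln_pos <- tum$lymph_node == "present"
    marker <- unclass(co$mrna)[co$truth$ln_marker_id, tum$sample_id]
    set.seed(s)
    noise <- rnorm(nrow(tum))
    marker_auc(marker, ln_pos) - marker_auc(noise, ln_pos)
  }, numeric(1))
  expect_gt(mean(aucs), 0)
})

test_that("clinical association shares the DE p-value machinery", {
  co <- generate_cohort(cohort_config(seed = 4))
  grp <- annotation_groups(co$annotation, "lymph_node")
  assoc <- clinical_association(co$mrna, co$annotation, "lymph_node")
  de <- differential_expression(co$mrna, grp, p_max = 0.01, fdr_max = 0.20,
                                fc_min = 1)
  expect_equal(assoc$p_value, de$p_value)
  expect_equal(assoc$q_value, de$q_value)
  # the planted LN marker is recovered as significant
  expect_true(assoc$significant[assoc$feature_id == co$truth$ln_marker_id])
})

test_that("null cohorts yield essentially no clinical associations", {
  n_sig <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(
      n_de_mirna = 0, n_de_mrna = 0, n_true_pairs = 0, n_decoy = 0,
      dropout_rate = 0, seed = 100 + s))
    assoc <- clinical_association(co$mrna, co$annotation, "lymph_node")
    sum(assoc$significant)
  }, numeric(1))
  expect_lte(mean(n_sig), 0.5)
})

test_that("median-split survival: ties to low, identical groups p = 1", {
  vals <- setNames(c(1, 2, 3, 4, 5, 6), paste0("p", 1:6))
  ann <- data.frame(sample_id = paste0("p", 1:6),
                    survival_months = rep(c(10, 20, 30), 2),
                    event = rep(c(1, 1, 0), 2))
  res <- survival_by_median(vals, ann)
  expect_identical(as.integer(sort(table(res$groups$group))), c(3L, 3L))
  expect_true(all(res$groups$group[vals <= median(vals)] == "low"))

  # identical survival in both split halves
  vals2 <- setNames(c(1, 1, 2, 5, 5, 6), paste0("p", 1:6))
  ann2 <- data.frame(sample_id = paste0("p", 1:6),
                     survival_months = c(10, 20, 30, 10, 20, 30),
                     event = c(1, 0, 1, 1, 0, 1))
  res2 <- survival_by_median(vals2, ann2)
  expect_equal(res2$p_value, 1, tolerance = 1e-8)

  expect_error(survival_by_median(setNames(rep(2, 6), paste0("p", 1:6)), ann),
               "degenerate")
})

test_that("the planted survival marker orders hazards as constructed", {
  worse <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_config(seed = 200 + s))
    tum <- co$annotation[co$annotation$group == "tumor", ]
    vals <- unclass(co$mrna)[co$truth$survival_marker_id, tum$sample_id]
    res <- survival_by_median(vals, tum)
    ev <- tapply(tum$event[match(res$groups$sample_id, tum$sample_id)],
                 res$groups$group, mean)
    ev["high"] - ev["low"]
  }, numeric(1))
  expect_gt(mean(worse), 0)
})
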