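test_that("candidate filter keeps >=10-of-12 support or validated pairs", {
  tab <- data.frame(mirna_id = c("a", "b", "c", "d"),
                    gene_id = c("G1", "G2", "G3", "G4"),
                    support = c(12L, 9L, 0L, 10L),
                    validated = c(FALSE, FALSE, TRUE, TRUE))
  kept <- candidate_interactions(tab)
  expect_setequal(kept$mirna_id, c("a", "c", "d"))
  # shrinking min_support never removes pairs
  for (thr in 12:0) {
    k2 <- candidate_interactions(tab, thr)
    expect_true(all(paste(kept$mirna_id, kept$gene_id) %in%
                      paste(k2$mirna_id, k2$gene_id)))
    kept <- k2
  }
})

test_that("spearman_rho matches the Pearson-on-ranks oracle", {
  expect_equal(spearman_rho(1:5, 2 * (1:5)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4)),
               oracle_spearman(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4)),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:50) {
    n <- sample(4:15, 1)
    x <- sample(1:6, n, replace = TRUE)   # forces ties
    y <- rnorm(n)
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  expect_true(is.na(spearman_rho(c(1, NA, 3, NA), c(1, 2, NA, 4))))
})

de_row <- function(id, fc, sig = TRUE) {
  data.frame(feature_id = id, mean_a = 0, mean_b = 0, signed_fc = fc,
             p_value = 0.001, q_value = 0.01, significant = sig,
             n_a = 10L, n_b = 10L, tested = TRUE, reason = NA_character_)
}

test_that("integration applies all four gates", {
  # planted miRNA up / gene down, perfectly anti-correlated over 6 samples
  mi <- toy_matrix(rbind(c(1, 2, 3, 4, 5, 6),
                         c(1, 2, 3, 4, 5, 6)), prefix_f = "mir")
  mr <- toy_matrix(rbind(c(6, 5, 4, 3, 2, 1),
                         c(1, 2, 3, 4, 5, 6)), prefix_f = "G")
  inter <- data.frame(mirna_id = c("mir1", "mir1", "mir2"),
                      gene_id = c("G1", "G2", "G1"),
                      support = c(11L, 11L, 9L), validated = FALSE)
  de_mi <- rbind(de_row("mir1", 3), de_row("mir2", 4))
  de_mr <- rbind(de_row("G1", -2), de_row("G2", -2))
  got <- integrate_pairs(de_mi, de_mr, mi, mr, inter, paste0("s", 1:6))
  # mir1-G2 fails anti-correlation (rho = +1), mir2-G1 fails support
  expect_identical(got$mirna_id, "mir1")
  expect_identical(got$gene_id, "G1")
  expect_identical(got$rho, -1)
  expect_identical(got$supported_by, "predicted")

  # rho = 0 is excluded: strict negativity
  mr0 <- toy_matrix(rbind(c(1, 2, 3, 3, 2, 1)), prefix_f = "G")
  x <- unclass(mi)["mir1", ]
  expect_identical(spearman_rho(x, unclass(mr0)["G1", ]), 0)
  got0 <- integrate_pairs(de_mi, de_row("G1", -2), mi, mr0, inter,
                          paste0("s", 1:6))
  expect_identical(nrow(got0), 0L)

  # same-sign fold changes are excluded even when anti-correlated
  got_same <- integrate_pairs(de_mi, de_row("G1", +2), mi, mr, inter,
                              paste0("s", 1:6))
  expect_identical(nrow(got_same), 0L)

  # empty DE input is an empty result, not an error
  expect_identical(nrow(integrate_pairs(de_mi[0, ], de_mr, mi, mr, inter,
                                        paste0("s", 1:6))), 0L)
})

test_that("integration result is invariant to input row order", {
  co <- generate_cohort(cohort_config(seed = 12))
  grp <- annotation_groups(co$annotation)
  de_mi <- differential_expression(co$mirna, grp)
  de_mr <- differential_expression(co$mrna, grp, p_max = 0.001, fdr_max = 1)
  p1 <- integrate_pairs(de_mi, de_mr, co$mirna, co$mrna, co$interactions,
                        grp[[1]])
  shuf <- co$interactions[sample(nrow(co$interactions)), ]
  p2 <- integrate_pairs(de_mi[sample(nrow(de_mi)), ],
                        de_mr[sample(nrow(de_mr)), ],
                        co$mirna, co$mrna, shuf, grp[[1]])
  expect_equal(p1, p2)
})

test_that("node degrees conserve the bipartite pair count", {
  expect_identical(nrow(node_degrees(data.frame(mirna_id = character(0),
                                                gene_id = character(0)))), 0L)
  pairs <- data.frame(mirna_id = c("m1", "m1", "m1", "m2"),
                      gene_id = c("G1", "G2", "G3", "G1"))
  deg <- node_degrees(pairs)
  expect_identical(deg$degree[deg$node_id == "m1"], 3L)
  expect_identical(sum(deg$degree[deg$kind == "miRNA"]), nrow(pairs))
  expect_identical(sum(deg$degree[deg$kind == "gene"]), nrow(pairs))
})

test_that("true-pair recovery degrades as pair correlation weakens", {
  recall_at <- function(rho_target) {
    mean(vapply(1:3, function(s) {
      co <- generate_cohort(cohort_config(pair_correlation = rho_target,
                                          seed = s))
      grp <- annotation_groups(co$annotation)
      de_mi <- differential_expression(filter_low_abundance(co$mirna, grp),
                                       grp)
      de_mr <- differential_expression(co$mrna, grp, p_max = 0.001,
                                       fdr_max = 1)
      pairs <- integrate_pairs(de_mi, de_mr, co$mirna, co$mrna,
                               co$interactions, grp[[1]])
      tp <- paste(co$truth$true_pairs$mirna_id, co$truth$true_pairs$gene_id)
      mean(tp %in% paste(pairs$mirna_id, pairs$gene_id))
    }, numeric(1)))
  }
  r <- vapply(c(-0.9, -0.5, -0.05), recall_at, numeric(1))
  expect_gte(r[1], r[3])
  expect_gt(r[1], 0.8)
})
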