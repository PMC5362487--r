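#' Hierarchical clustering of samples with the 1 - correlation metric
#'
#' Pairwise sample distance is `1 - r`, the correlation computed between the
#' two samples' feature vectors (pairwise-complete observations), followed by
#' agglomerative clustering with complete linkage. Cutting the tree at `k`
#' yields cluster labels numbered by order of first sample appearance in the
#' matrix, so labels are stable across runs.
#'
#' @param m An [expr_matrix()] (features x samples); zero-variance features
#'   are removed before computing correlations.
#' @param k Number of clusters to extract.
#' @param metric `"pearson"` (default) or `"spearman"` correlation.
#' @return A list with `hclust` (the tree), `assignments` (data.frame
#'   `sample_id`, `cluster`) and `dist` (the distance object).
#' @export
cluster_samples <- function(m, k, metric = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  v <- unclass(m)
  if (ncol(v) < k) stop("fewer samples than clusters", call. = FALSE)
  fvar <- apply(v, 1L, stats::var, na.rm = TRUE)
  v <- v[!is.na(fvar) & fvar > 0, , drop = FALSE]
  svar <- apply(v, 2L, stats::var, na.rm = TRUE)
  flat <- colnames(v)[is.na(svar) | svar == 0]
  if (length(flat))
    stop("sample(s) with zero variance across features: ",
         paste(flat, collapse = ", "), call. = FALSE)
  cors <- suppressWarnings(
    stats::cor(v, use = "pairwise.complete.obs", method = metric))
  d <- stats::as.dist(1 - cors)
  hc <- stats::hclust(d, method = "complete")
  raw <- stats::cutree(hc, k = k)
  # renumber clusters by first appearance in input sample order
  first <- unique(raw[colnames(v)])
  lab <- match(raw, first)
  list(hclust = hc,
       assignments = data.frame(sample_id = colnames(v),
                                cluster = as.integer(lab[match(colnames(v), names(raw))]),
                                stringsAsFactors = FALSE),
       dist = d)
}

#' Export a sample dendrogram in Newick format
#'
#' @param hc An `hclust` object (e.g. from [cluster_samples()]).
#' @return A single Newick string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Cross-tabulate clusters against a clinical variable
#'
#' Builds the k-by-levels contingency table (samples with unknown values
#' dropped) and, for each cluster, collapses to a 2x2 table (this cluster vs
#' the rest, each level vs the rest) tested with a two-sided Fisher exact
#' test.
#'
#' @param assignments Data.frame `sample_id`, `cluster`.
#' @param annotation Annotation data.frame.
#' @param variable Clinical column name (e.g. `"lymph_node"`).
#' @return A list with `table` (contingency counts) and `fisher` (data.frame
#'   `cluster`, `level`, `p_value` for every cluster/level 2x2 collapse).
#' @export
cluster_clinical_table <- function(assignments, annotation, variable) {
  v <- annotation[[variable]][match(assignments$sample_id,
                                    annotation$sample_id)]
  keep <- !is.na(v) & v != "unknown"
  if (!any(keep))
    stop("variable '", variable, "' is unknown for every clustered sample",
         call. = FALSE)
  v <- v[keep]
  cl <- assignments$cluster[keep]
  if (length(unique(v)) < 2L)
    stop("variable '", variable, "' has fewer than 2 observed levels",
         call. = FALSE)
  tab <- table(cluster = cl, level = v)
  res <- expand.grid(cluster = sort(unique(cl)), level = colnames(tab),
                     stringsAsFactors = FALSE)
  res$p_value <- vapply(seq_len(nrow(res)), function(i) {
    in_cl <- cl == res$cluster[i]
    in_lv <- v == res$level[i]
    m2 <- matrix(c(sum(in_cl & in_lv), sum(in_cl & !in_lv),
                   sum(!in_cl & in_lv), sum(!in_cl & !in_lv)), 2L, 2L)
    stats::fisher.test(m2)$p.value
  }, numeric(1))
  list(table = tab, fisher = res)
}

# shared Kaplan-Meier + log-rank machinery
.km_logrank <- function(time, event, group) {
  ok <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[ok]; event <- event[ok]; group <- as.factor(as.character(group[ok]))
  if (nlevels(group) < 2L)
    stop("need at least 2 groups with survival data", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  if (sum(event) == 0) {
    return(list(fit = fit, chisq = NA_real_, df = nlevels(group) - 1L,
                p_value = NA_real_, n = table(group),
                note = "no events observed; log-rank p undefined"))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(fit = fit, chisq = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = table(group), note = NA_character_)
}

#' Kaplan-Meier curves and log-rank test across clusters
#'
#' Product-limit survival estimates per cluster and the k-group log-rank
#' statistic (chi-square on k-1 df). A one-cluster-vs-rest comparison is also
#' reported for each cluster.
#'
#' @param assignments Data.frame `sample_id`, `cluster`.
#' @param annotation Annotation data.frame carrying `survival_months` and
#'   `event`.
#' @return A list with `overall` (fit, chisq, df, p_value) and `one_vs_rest`
#'   (data.frame `cluster`, `p_value`).
#' @export
cluster_survival <- function(assignments, annotation) {
  idx <- match(assignments$sample_id, annotation$sample_id)
  time <- annotation$survival_months[idx]
  event <- annotation$event[idx]
  overall <- .km_logrank(time, event, assignments$cluster)
  cls <- sort(unique(assignments$cluster))
  ovr <- data.frame(cluster = cls, p_value = NA_real_)
  for (i in seq_along(cls)) {
    g <- ifelse(assignments$cluster == cls[i], "this", "rest")
    ovr$p_value[i] <- tryCatch(.km_logrank(time, event, g)$p_value,
                               error = function(e) NA_real_)
  }
  list(overall = overall, one_vs_rest = ovr)
}
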