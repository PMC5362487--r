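#' Filter candidate miRNA-target interactions
#'
#' Keeps records supported by at least `min_support` of the 12 target
#' prediction tools OR experimentally validated by reporter assay (union
#' semantics, matching the "predicted and/or validated" reading).
#'
#' @param interactions Interaction data.frame (see [read_interactions()]).
#' @param min_support Minimum prediction-tool support (default 10 of 12).
#' @return The filtered interaction data.frame.
#' @export
candidate_interactions <- function(interactions, min_support = 10L) {
  interactions[interactions$support >= min_support | interactions$validated, ,
               drop = FALSE]
}

#' Spearman rank correlation with pairwise deletion
#'
#' Average ranks for ties; pairs with a missing value in either vector are
#' dropped. Returns `NA` when fewer than 3 complete pairs remain (the
#' correlation is then considered unevaluable).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Spearman's rho, or `NA_real_`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
}

#' Integrate differential expression with miRNA-target interactions
#'
#' Emits exactly those (miRNA, gene) pairs for which (i) both features are
#' significantly differentially expressed, (ii) the pair is a candidate
#' interaction (prediction support >= `min_support` or validated), (iii) the
#' Spearman correlation of their expression over `sample_set` (typically the
#' tumor samples only) is defined and strictly negative, and (iv) the two
#' signed fold changes have opposite signs ("inverted fold change").
#'
#' @param de_mirna,de_mrna Results of [differential_expression()] for the two
#'   layers; only rows with `significant == TRUE` are used.
#' @param mi_expr,m_expr The corresponding [expr_matrix()] objects.
#' @param interactions Interaction table.
#' @param sample_set Character vector of sample ids over which rho is
#'   computed.
#' @param min_support Passed to [candidate_interactions()].
#' @return A data.frame of integrated pairs sorted by rho ascending (ties by
#'   miRNA then gene id): `mirna_id`, `gene_id`, `rho`, `mirna_signed_fc`,
#'   `mrna_signed_fc`, `supported_by` (predicted/validated/both),
#'   `n_samples_used`.
#' @export
integrate_pairs <- function(de_mirna, de_mrna, mi_expr, m_expr,
                            interactions, sample_set, min_support = 10L) {
  if (!length(sample_set))
    stop("sample_set is empty", call. = FALSE)
  unknown <- setdiff(sample_set,
                     intersect(sample_ids(mi_expr), sample_ids(m_expr)))
  if (length(unknown))
    stop("sample id(s) absent from an expression matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sig_mi <- de_mirna[de_mirna$significant, , drop = FALSE]
  sig_mr <- de_mrna[de_mrna$significant, , drop = FALSE]
  empty <- data.frame(mirna_id = character(0), gene_id = character(0),
                      rho = numeric(0), mirna_signed_fc = numeric(0),
                      mrna_signed_fc = numeric(0),
                      supported_by = character(0),
                      n_samples_used = integer(0), stringsAsFactors = FALSE)
  if (nrow(sig_mi) == 0L || nrow(sig_mr) == 0L) return(empty)
  cand <- candidate_interactions(interactions, min_support)
  cand <- cand[cand$mirna_id %in% sig_mi$feature_id &
                 cand$gene_id %in% sig_mr$feature_id, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  fc_mi <- stats::setNames(sig_mi$signed_fc, sig_mi$feature_id)
  fc_mr <- stats::setNames(sig_mr$signed_fc, sig_mr$feature_id)
  res <- lapply(seq_len(nrow(cand)), function(k) {
    mi_id <- cand$mirna_id[k]
    g_id <- cand$gene_id[k]
    x <- unclass(mi_expr)[mi_id, sample_set]
    y <- unclass(m_expr)[g_id, sample_set]
    n_used <- sum(!is.na(x) & !is.na(y))
    rho <- spearman_rho(x, y)
    if (is.na(rho) || rho >= 0) return(NULL)
    if (sign(fc_mi[mi_id]) == sign(fc_mr[g_id])) return(NULL)
    data.frame(mirna_id = mi_id, gene_id = g_id, rho = rho,
               mirna_signed_fc = unname(fc_mi[mi_id]),
               mrna_signed_fc = unname(fc_mr[g_id]),
               supported_by = if (cand$support[k] >= min_support &&
                                    cand$validated[k]) "both"
                              else if (cand$validated[k]) "validated"
                              else "predicted",
               n_samples_used = n_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty), res))
  out <- out[order(out$rho, out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node degrees of the integrated bipartite network
#'
#' @param pairs Result of [integrate_pairs()].
#' @return A data.frame (`node_id`, `kind`, `degree`) sorted by degree
#'   descending then id; the miRNA degrees and gene degrees each sum to the
#'   number of pairs.
#' @export
node_degrees <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(data.frame(node_id = character(0), kind = character(0),
                      degree = integer(0), stringsAsFactors = FALSE))
  mi <- table(pairs$mirna_id)
  g <- table(pairs$gene_id)
  out <- data.frame(
    node_id = c(names(mi), names(g)),
    kind = c(rep("miRNA", length(mi)), rep("gene", length(g))),
    degree = as.integer(c(mi, g)), stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
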