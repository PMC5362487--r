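#' Construct an expression matrix
#'
#' The central container for log2-scale expression data: a numeric matrix of
#' features (rows) by samples (columns) with a feature kind tag. Missing
#' values (e.g. undetermined quantification cycles in qPCR data) are encoded
#' as `NA`, never as a sentinel number.
#'
#' @param values Numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids). `NA` entries mark missing observations.
#' @param kind One of `"miRNA"`, `"mRNA"` or `"qPCR-Cq"`.
#' @return An object of class `expr_matrix`: the validated numeric matrix with
#'   a `kind` attribute.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
#' em <- expr_matrix(m, "miRNA")
#' feature_ids(em)
#' @export
expr_matrix <- function(values, kind = c("miRNA", "mRNA", "qPCR-Cq")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("'values' must carry feature rownames and sample colnames",
         call. = FALSE)
  dup_f <- fid[duplicated(fid)]
  if (length(dup_f))
    stop("duplicated feature id(s): ", paste(unique(dup_f), collapse = ", "),
         call. = FALSE)
  dup_s <- sid[duplicated(sid)]
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  structure(values, kind = kind, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
feature_ids <- function(x) rownames(x)

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) colnames(x)

#' @rdname expr_matrix
#' @export
feature_kind <- function(x) attr(x, "kind")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d features x %d samples, %d missing\n",
              attr(x, "kind"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

# Subsetting keeps the class and kind; dropping to a vector loses both,
# which is the base-matrix behaviour callers expect.
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, kind = attr(x, "kind"),
                     class = c("expr_matrix", "matrix", "array"))
  out
}
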