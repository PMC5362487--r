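#' Read a feature-by-sample expression table
#'
#' Parses a TSV file whose first column holds feature ids and whose header row
#' holds sample ids. Empty cells and the token `"NA"` denote missing values.
#' The reader performs no transformation: values are assumed to be already
#' normalized and log2-scaled (Cq tables are on the cycle scale).
#'
#' @param path Path to a TSV file.
#' @param kind Feature kind, see [expr_matrix()].
#' @return An [expr_matrix()] preserving the file's row and column order.
#' @export
read_expression <- function(path, kind = c("miRNA", "mRNA", "qPCR-Cq")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty file: ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  ncol_expected <- length(header)
  sample_id <- header[-1L]
  if (!length(sample_id)) stop("no sample columns in ", path, call. = FALSE)
  body <- cells[-1L]
  nc <- lengths(body)
  # trailing empty cells are dropped by strsplit; pad rows that are short by
  # exactly the trailing-missing amount only when the raw line ends in tabs
  bad <- which(nc != ncol_expected)
  for (i in bad) {
    if (nc[i] < ncol_expected && grepl("\t$", lines[i + 1L])) {
      body[[i]] <- c(body[[i]], rep("", ncol_expected - nc[i]))
    } else {
      stop(sprintf("ragged row at line %d: %d fields, expected %d",
                   i + 1L, nc[i], ncol_expected), call. = FALSE)
    }
  }
  feature_id <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, length(body), length(sample_id),
                 dimnames = list(feature_id, sample_id))
  for (i in seq_along(body)) {
    raw <- body[[i]][-1L]
    miss <- raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad_cell <- which(!miss & is.na(num))
    if (length(bad_cell))
      stop(sprintf("non-numeric value '%s' at line %d, column '%s'",
                   raw[bad_cell[1L]], i + 1L, sample_id[bad_cell[1L]]),
           call. = FALSE)
    num[miss] <- NA_real_
    vals[i, ] <- num
  }
  expr_matrix(vals, kind)
}

#' Write a result table or expression matrix as TSV
#'
#' Floats are rendered with full precision (`%.17g`) so that
#' `read_expression(write_table(m))` reproduces `m` bit-for-bit for finite
#' values; missing values are emitted as the token `"NA"`.
#'
#' @param rows A data.frame with uniform named columns, or an [expr_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  fmt <- function(v) {
    if (is.double(v)) {
      out <- sprintf("%.17g", v)
      out[is.na(v)] <- "NA"
    } else {
      out <- as.character(v)
      out[is.na(v)] <- "NA"
    }
    out
  }
  if (inherits(rows, "expr_matrix") ||
      (is.matrix(rows) && is.numeric(rows))) {
    header <- c("feature_id", colnames(rows))
    body <- vapply(seq_len(nrow(rows)), function(i) {
      paste(c(rownames(rows)[i], fmt(rows[i, ])), collapse = "\t")
    }, character(1))
  } else {
    rows <- as.data.frame(rows)
    header <- names(rows)
    if (nrow(rows) == 0L) {
      body <- character(0)
    } else {
      cols <- lapply(rows, fmt)
      body <- do.call(paste, c(cols, sep = "\t"))
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"), body), con)
  invisible(path)
}

.annotation_levels <- list(
  group = c("tumor", "NPT"),
  hpv = c("positive", "negative", "unknown"),
  lymph_node = c("present", "absent", "unknown"),
  t_stage = c("T1_2", "T3_4", "unknown"),
  perineural_invasion = c("present", "absent", "unknown"),
  grade = c("I", "II", "III", "unknown")
)

#' Read a sample annotation table
#'
#' Expects columns `sample_id`, `group` (tumor/NPT), `hpv`, `lymph_node`,
#' `t_stage`, `perineural_invasion`, `grade`, `survival_months`, `event`.
#' Categorical tokens outside the documented vocabularies are rejected.
#' `event` is 0/1 (death observed); blank survival fields are allowed, but an
#' observed event requires a survival time.
#'
#' @param path Path to a TSV file.
#' @return A data.frame, one row per sample.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), check.names = FALSE)
  need <- c("sample_id", names(.annotation_levels),
            "survival_months", "event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("annotation file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  for (col in names(.annotation_levels)) {
    v <- df[[col]]
    ok <- .annotation_levels[[col]]
    bad <- which(!is.na(v) & !v %in% ok)
    if (length(bad))
      stop(sprintf("row %d: unrecognized %s token '%s'",
                   bad[1L], col, v[bad[1L]]), call. = FALSE)
    # absent entries in optional covariates are read back as explicit unknowns
    if (col != "group") v[is.na(v)] <- "unknown"
    df[[col]] <- v
  }
  if (anyNA(df$group)) stop("group is required for every sample", call. = FALSE)
  df$survival_months <- as.numeric(df$survival_months)
  if (any(!is.na(df$survival_months) & df$survival_months < 0))
    stop("negative survival_months", call. = FALSE)
  df$event <- as.integer(df$event)
  if (any(!is.na(df$event) & !df$event %in% c(0L, 1L)))
    stop("event must be 0 or 1", call. = FALSE)
  no_time <- which(!is.na(df$event) & is.na(df$survival_months))
  if (length(no_time))
    stop("sample ", df$sample_id[no_time[1L]],
         " has an event flag but no survival time", call. = FALSE)
  df
}

#' Read a miRNA-to-gene interaction table
#'
#' Expects columns `mirna_id`, `gene_id`, `support` (number of target
#' prediction tools supporting the pair, 0..12) and `validated` (TRUE/FALSE,
#' reporter-assay validated).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per unique (miRNA, gene) pair.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("mirna_id", "gene_id", "support", "validated")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("interaction file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  validate_interactions(df)
}

#' @rdname read_interactions
#' @param df A data.frame holding the four interaction columns.
#' @export
validate_interactions <- function(df) {
  df$support <- as.integer(df$support)
  if (any(is.na(df$support) | df$support < 0L | df$support > 12L)) {
    bad <- which(is.na(df$support) | df$support < 0L | df$support > 12L)[1L]
    stop(sprintf("row %d: support must be an integer in 0..12 (got '%s')",
                 bad, df$support[bad]), call. = FALSE)
  }
  df$validated <- as.logical(df$validated)
  if (anyNA(df$validated))
    stop("validated must be TRUE or FALSE", call. = FALSE)
  key <- paste(df$mirna_id, df$gene_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated interaction pair(s): ",
         paste(unique(sprintf("(%s, %s)", df$mirna_id[dup], df$gene_id[dup])),
               collapse = ", "), call. = FALSE)
  df
}
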