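# From-definition oracles, deliberately independent of the package's code
# paths (and of the stats:: routines those paths call where possible).

# two-sample t-test from the textbook formulas
oracle_t <- function(x, y, pooled = TRUE) {
  nx <- length(x); ny <- length(y)
  mx <- sum(x) / nx; my <- sum(y) / ny
  vx <- sum((x - mx)^2) / (nx - 1)
  vy <- sum((y - my)^2) / (ny - 1)
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    t <- (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2 <- vx / nx + vy / ny
    t <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# average ranks computed by hand (no rank()), then the Pearson formula
oracle_rank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# two-sided Fisher exact p for a 2x2 table by enumerating the
# hypergeometric support with fixed margins
oracle_fisher <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# AUC by exhaustive pair counting
oracle_auc <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# small expr_matrix builder for tests
toy_matrix <- function(values, kind = "miRNA", prefix_f = "f", prefix_s = "s") {
  dimnames(values) <- list(paste0(prefix_f, seq_len(nrow(values))),
                           paste0(prefix_s, seq_len(ncol(values))))
  expr_matrix(values, kind)
}
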