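# Spearman correlation between the log-derived features and the gamma
# passing rates, pooled and per treatment site.

# Average ranks computed directly (ties share the mean of their positions).
average_ranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  n <- length(x)
  while (i <= n) {
    j <- i
    while (j < n && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

pearson_from_sums <- function(a, b) {
  n <- length(a)
  am <- a - sum(a) / n
  bm <- b - sum(b) / n
  den <- sqrt(sum(am^2) * sum(bm^2))
  if (den == 0) return(NA_real_)
  sum(am * bm) / den
}

#' Pairwise Spearman correlation matrix with two-sided p-values
#'
#' Spearman rho is computed as Pearson correlation of average ranks; the
#' two-sided p-value uses the t approximation on n - 2 degrees of freedom
#' (appropriate at the cohort sizes this analysis targets). Constant columns
#' have undefined rank correlation and are reported as `NA` (flagged in the
#' `constant` field), never coerced to 0. No multiple-testing correction is
#' applied, matching a flat alpha across the matrix.
#'
#' @param table Data frame or matrix of numeric columns (>= 3 rows, no NA).
#' @param labels Optional variable names (default column names).
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return A `correlation_matrix`: `labels`, symmetric `rho` with unit
#'   diagonal, `p_two_sided`, `n`, `alpha`, and `constant` (logical per
#'   column).
#' @export
spearman_matrix <- function(table, labels = colnames(table), alpha = 0.05) {
  X <- as.matrix(table)
  if (!is.numeric(X)) stop("spearman_matrix: non-numeric input", call. = FALSE)
  n <- nrow(X)
  if (n < 3) stop("spearman_matrix: need at least 3 rows", call. = FALSE)
  if (anyNA(X)) stop("spearman_matrix: NA values present", call. = FALSE)
  p <- ncol(X)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  constant <- apply(X, 2, function(x) diff(range(x)) == 0)
  R <- apply(X, 2, average_ranks)
  rho <- matrix(NA_real_, p, p, dimnames = list(labels, labels))
  pval <- matrix(NA_real_, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        rho[i, i] <- if (constant[i]) NA_real_ else 1
        pval[i, i] <- if (constant[i]) NA_real_ else 0
        next
      }
      r <- pearson_from_sums(R[, i], R[, j])
      rho[i, j] <- rho[j, i] <- r
      if (!is.na(r)) {
        r_cl <- min(1 - 1e-15, max(-1 + 1e-15, r))
        tstat <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
        pv <- 2 * pt(-abs(tstat), df = n - 2)
        if (abs(r) >= 1) pv <- 0
        pval[i, j] <- pval[j, i] <- pv
      }
    }
  }
  structure(list(labels = labels, rho = rho, p_two_sided = pval,
                 n = n, alpha = alpha, constant = constant),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d variables, n = %d, alpha = %g\n",
              length(x$labels), x$n, x$alpha))
  invisible(x)
}

#' Per-site and pooled Spearman correlation matrices
#'
#' One correlation matrix per treatment site plus a pooled `"all"` matrix.
#' Strata with fewer than 3 rows are skipped with a warning.
#'
#' @param table Data frame of numeric feature and label columns.
#' @param site Character/factor vector of stratum labels, one per row.
#' @param alpha Significance level (default 0.05).
#' @return Named list of [spearman_matrix()] results (`all` first).
#' @export
stratified_correlations <- function(table, site, alpha = 0.05) {
  stopifnot(nrow(table) == length(site))
  out <- list(all = spearman_matrix(table, alpha = alpha))
  for (s in unique(site)) {
    rows <- site == s
    if (sum(rows) < 3) {
      warning(sprintf("stratum '%s' has %d rows (< 3); skipped",
                      s, sum(rows)), call. = FALSE)
      next
    }
    out[[s]] <- spearman_matrix(table[rows, , drop = FALSE], alpha = alpha)
  }
  out
}

#' Write a correlation matrix to CSV files
#' @param cm A `correlation_matrix`.
#' @param prefix Path prefix; writes `<prefix>_rho.csv` and `<prefix>_p.csv`.
#' @return Invisibly, the two paths.
#' @export
write_correlation <- function(cm, prefix) {
  paths <- paste0(prefix, c("_rho.csv", "_p.csv"))
  utils::write.csv(cm$rho, paths[1])
  utils::write.csv(cm$p_two_sided, paths[2])
  invisible(paths)
}
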