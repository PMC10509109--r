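#' Cross-tabulate paired risk classes
#'
#' Builds the 5x5 ordinal contingency table of risk classes under two
#' scoring conditions. Rows are the comparison condition, columns the
#' reference condition, so column marginals are the reference class
#' histogram.
#'
#' @param reference,comparison Vectors (factor or character) of risk classes
#'   in [risk_levels()], equal length.
#' @param condition_labels Character length-2: labels for the comparison
#'   (row) and reference (column) conditions.
#' @return An object of class `risk_table`: a 5x5 integer matrix with
#'   dimnames, and attributes `comparison`/`reference`.
#' @export
cross_tabulate <- function(reference, comparison,
                           condition_labels = c("comparison", "reference")) {
  lv <- risk_levels()
  reference <- as.character(reference); comparison <- as.character(comparison)
  if (length(reference) != length(comparison))
    stop("`reference` and `comparison` must have equal length", call. = FALSE)
  bad <- setdiff(unique(c(reference, comparison)), lv)
  if (length(bad))
    stop("unknown risk class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  m <- table(factor(comparison, levels = lv), factor(reference, levels = lv))
  risk_table(unclass(m)[,], condition_labels[1], condition_labels[2])
}

#' @rdname cross_tabulate
#' @param counts 5x5 matrix of non-negative counts (rows = comparison).
#' @param comparison_label,reference_label Condition labels.
#' @export
risk_table <- function(counts, comparison_label = "comparison",
                       reference_label = "reference") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(5L, 5L)) || any(counts < 0))
    stop("`counts` must be a 5x5 matrix of non-negative counts", call. = FALSE)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(risk_levels(), risk_levels())
  structure(counts, class = c("risk_table", "matrix", "array"),
            comparison = comparison_label, reference = reference_label)
}

#' @export
print.risk_table <- function(x, ...) {
  cat(sprintf("risk_table: rows = %s, columns = %s, n = %d\n",
              attr(x, "comparison"), attr(x, "reference"), sum(x)))
  m <- unclass(x); attributes(m)[c("comparison", "reference")] <- NULL
  print(m)
  invisible(x)
}

#' Cohen's kappa of a risk-class contingency table
#'
#' Unweighted by default: \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with observed
#' agreement \eqn{p_o} = trace/n and chance agreement \eqn{p_e} from the
#' marginal products. `weighted = "linear"` applies linear disagreement
#' weights (offered for sensitivity analyses; the reference results use the
#' unweighted form).
#'
#' @param table A [risk_table()] (or plain 5x5 count matrix).
#' @param weighted `"none"` (default) or `"linear"`.
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(table, weighted = c("none", "linear")) {
  weighted <- match.arg(weighted)
  m <- .as_counts(table)
  n <- sum(m)
  if (n <= 0) stop("empty table", call. = FALSE)
  k <- nrow(m)
  w <- if (weighted == "none") diag(k) else
    1 - abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  po <- sum(w * m) / n
  pe <- sum(w * outer(rowSums(m), colSums(m))) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    if (abs(po - 1) < .Machine$double.eps^0.5) return(1.0)
    stop("degenerate table: chance agreement is 1", call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Kendall's tau-b of an ordinal contingency table
#'
#' Tie-corrected rank correlation computed directly from the table:
#' \eqn{\tau_b = (P - Q)/\sqrt{(n_0 - n_r)(n_0 - n_c)}} where P and Q are
#' the concordant and discordant pair counts, \eqn{n_0 = n(n-1)/2}, and
#' \eqn{n_r, n_c} are the tied-pair counts of the row and column marginals.
#'
#' @param table A [risk_table()] (or plain count matrix).
#' @return Tau-b in [-1, 1].
#' @export
kendall_tau_b <- function(table) {
  m <- .as_counts(table)
  n <- sum(m)
  if (n <= 1) stop("need at least 2 subjects", call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  P <- 0; Q <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (m[i, j] == 0) next
    if (i < nr && j < nc) P <- P + m[i, j] * sum(m[(i + 1):nr, (j + 1):nc])
    if (i < nr && j > 1)  Q <- Q + m[i, j] * sum(m[(i + 1):nr, 1:(j - 1)])
  }
  n0 <- n * (n - 1) / 2
  tr <- sum(rowSums(m) * (rowSums(m) - 1) / 2)
  tc <- sum(colSums(m) * (colSums(m) - 1) / 2)
  denom <- sqrt((n0 - tr) * (n0 - tc))
  if (denom == 0)
    stop("tau-b undefined: all mass in a single row or column", call. = FALSE)
  (P - Q) / denom
}

#' Reclassification summary of a contingency table
#'
#' Counts subjects whose comparison class differs from their reference
#' class, split into upward (comparison above reference) and downward
#' moves.
#'
#' @param table A [risk_table()].
#' @return List with `n`, `n_reclassified`, `rate`, `n_upward`,
#'   `n_downward`.
#' @export
reclassification_summary <- function(table) {
  m <- .as_counts(table)
  n <- sum(m)
  if (n <= 0) stop("empty table", call. = FALSE)
  up <- sum(m[lower.tri(m)])    # row (comparison) index > column (reference)
  down <- sum(m[upper.tri(m)])
  list(n = n, n_reclassified = up + down, rate = (up + down) / n,
       n_upward = up, n_downward = down)
}

#' Full agreement report for a contingency table
#'
#' Kappa, tau-b, the reclassification summary, and large-sample normal
#' approximations to the p-values (H0: no association / no agreement;
#' approximate, reported for orientation only).
#'
#' @param table A [risk_table()].
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(table) {
  m <- .as_counts(table)
  n <- sum(m)
  kap <- cohen_kappa(table)
  tau <- kendall_tau_b(table)
  rec <- reclassification_summary(table)
  # Fleiss large-sample SE of kappa under H0
  pr <- rowSums(m) / n; pc <- colSums(m) / n
  pe <- sum(pr * pc)
  se0 <- sqrt((pe + pe^2 - sum(pr * pc * (pr + pc))) / (n * (1 - pe)^2))
  p_kappa <- 2 * stats::pnorm(-abs(kap / se0))
  z_tau <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  p_tau <- 2 * stats::pnorm(-abs(z_tau))
  structure(c(list(kappa = kap, tau_b = tau), rec,
              list(p_kappa = p_kappa, p_tau_b = p_tau)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("kappa = %.3f, tau-b = %.3f; %d/%d reclassified (%.1f%%): %d up, %d down\n",
              x$kappa, x$tau_b, x$n_reclassified, x$n, 100 * x$rate,
              x$n_upward, x$n_downward))
  invisible(x)
}

.as_counts <- function(table) {
  m <- unclass(as.matrix(table))
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  m
}

#' Bland-Altman analysis of paired scores
#'
#' Differences are comparison minus reference; bias is their mean and the
#' limits of agreement are bias +/- 1.96 x SD (sample SD, n - 1).
#'
#' @param reference,comparison Numeric vectors of paired scores.
#' @return List with `bias`, `sd`, `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman <- function(reference, comparison) {
  if (length(reference) != length(comparison))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(reference)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- comparison - reference
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s, loa_lower = bias - 1.96 * s,
       loa_upper = bias + 1.96 * s, n = n)
}

#' Single-measure absolute-agreement intraclass correlation
#'
#' ICC(A,1) from the two-way (subjects x raters) mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with k = 2 measurement conditions. A set of identical pairs (zero error
#' variance) returns 1.
#'
#' @param reference,comparison Numeric vectors of paired scores (n >= 3).
#' @return ICC estimate.
#' @export
icc_absolute <- function(reference, comparison) {
  if (length(reference) != length(comparison))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(reference)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  k <- 2
  y <- cbind(reference, comparison)
  grand <- mean(y)
  row_means <- rowMeans(y)
  col_means <- colMeans(y)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  if (ss_tot < .Machine$double.eps) return(1.0)  # all values identical
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < .Machine$double.eps) return(1.0)
  (msr - mse) / denom
}

#' The published 5x5 risk-class contingency tables
#'
#' The three cross-tabulations of CAC risk classes for 169 subjects:
#' 80 kVp vs 120 kVp (`t4`), 70 kVp vs 120 kVp (`t5`), and reader 2 vs
#' reader 1 on the 120 kVp scans (`t6`). Rows are the comparison condition,
#' columns the 120 kVp reference; all three share the reference column
#' marginals (49, 18, 45, 34, 23).
#'
#' @return Named list of three [risk_table()] objects `t4`, `t5`, `t6`.
#' @export
embedded_study_tables <- function() {
  t4 <- matrix(c(49, 2, 0, 0, 0,
                 0, 16, 5, 0, 0,
                 0, 0, 40, 3, 0,
                 0, 0, 0, 31, 2,
                 0, 0, 0, 0, 21), 5, 5, byrow = TRUE)
  t5 <- matrix(c(49, 6, 3, 0, 0,
                 0, 12, 6, 0, 0,
                 0, 0, 36, 7, 0,
                 0, 0, 0, 26, 6,
                 0, 0, 0, 1, 17), 5, 5, byrow = TRUE)
  t6 <- matrix(c(47, 0, 0, 0, 0,
                 2, 17, 2, 0, 0,
                 0, 1, 43, 0, 0,
                 0, 0, 0, 33, 1,
                 0, 0, 0, 1, 22), 5, 5, byrow = TRUE)
  list(t4 = risk_table(t4, "80 kVp", "120 kVp"),
       t5 = risk_table(t5, "70 kVp", "120 kVp"),
       t6 = risk_table(t6, "120 kVp reader 2", "120 kVp reader 1"))
}

#' Expand a contingency table into paired class labels
#'
#' Inverse of [cross_tabulate()] up to subject order: returns one
#' (reference, comparison) pair per subject.
#'
#' @param table A [risk_table()].
#' @return Data frame with factor columns `reference` and `comparison`.
#' @export
expand_pairs <- function(table) {
  m <- .as_counts(table)
  lv <- risk_levels()
  idx <- which(m > 0, arr.ind = TRUE)
  comparison <- rep(lv[idx[, 1]], m[idx])
  reference <- rep(lv[idx[, 2]], m[idx])
  data.frame(reference = factor(reference, levels = lv, ordered = TRUE),
             comparison = factor(comparison, levels = lv, ordered = TRUE))
}

#' Read and write paired-score / contingency-table CSV files
#'
#' `write_risk_table_csv()` stores a 5x5 table with class labels as row and
#' column headers; `read_risk_table_csv()` restores it.
#' `read_pairs_csv()` expects two columns (reference, comparison) of either
#' ordinal class labels or non-negative scores; scores are converted to
#' classes via [risk_class()].
#'
#' @param table A [risk_table()].
#' @param path CSV file path.
#' @return `read_risk_table_csv()` a [risk_table()];
#'   `read_pairs_csv()` a data frame of paired classes.
#' @export
write_risk_table_csv <- function(table, path) {
  m <- .as_counts(table)
  df <- data.frame(class = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_risk_table_csv
#' @export
read_risk_table_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  risk_table(m)
}

#' @rdname write_risk_table_csv
#' @export
read_pairs_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("need two columns (reference, comparison)", call. = FALSE)
  to_class <- function(x) {
    if (is.numeric(x)) as.character(risk_class(x))
    else as.character(x)
  }
  data.frame(reference = to_class(df[[1]]), comparison = to_class(df[[2]]))
}
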