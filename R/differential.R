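#' Two-group differential expression t statistics
#'
#' Computes a per-feature t statistic between cancer and normal samples,
#' oriented as cancer minus normal so that a positive t means higher
#' expression in cancer. The default is Welch's unequal-variance test; a
#' pooled-variance Student test is available via `var_equal = TRUE`.
#' Features with zero variance in both groups are flagged `degenerate` and
#' should be excluded downstream.
#'
#' The computation is vectorised over rows, so whole expression matrices are
#' scored in one call.
#'
#' @param x Numeric feature-by-sample matrix with sample colnames.
#' @param phen Named character vector mapping sample id to
#'   `"normal"`/`"cancer"`; every column of `x` must be labelled.
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @return A `data.frame` with columns `feature`, `t`, `p`, `sign`
#'   (+1 when t >= 0, -1 otherwise) and `degenerate`.
#' @export
ttest_two_group <- function(x, phen, var_equal = FALSE) {
  samples <- colnames(x)
  if (is.null(samples) || !all(samples %in% names(phen))) {
    stop("every sample column must be labelled in the phenotype table")
  }
  lab <- phen[samples]
  idx_c <- which(lab == "cancer")
  idx_n <- which(lab == "normal")
  n1 <- length(idx_c)
  n0 <- length(idx_n)
  if (n1 < 2L || n0 < 2L) {
    stop("need at least 2 samples per group (cancer=", n1,
         ", normal=", n0, ")")
  }
  m1 <- rowMeans(x[, idx_c, drop = FALSE])
  m0 <- rowMeans(x[, idx_n, drop = FALSE])
  v1 <- row_var(x[, idx_c, drop = FALSE], m1)
  v0 <- row_var(x[, idx_n, drop = FALSE], m0)
  degenerate <- v1 == 0 & v0 == 0
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep.int(n1 + n0 - 2, nrow(x))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    # Welch-Satterthwaite degrees of freedom
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  t_stat <- (m1 - m0) / se
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  t_stat[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  res <- data.frame(
    feature = rownames(x),
    t = t_stat,
    p = p,
    sign = ifelse(!is.na(t_stat) & t_stat < 0, -1L, 1L),
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
  rownames(res) <- res$feature
  class(res) <- c("diff_stats", "data.frame")
  res
}

row_var <- function(x, means) {
  rowSums((x - means)^2) / (ncol(x) - 1L)
}

#' Row-wise z-score normalisation
#'
#' Centres and scales every row to mean 0 and (sample, n-1 denominator)
#' standard deviation 1. Constant rows cannot be scaled and are dropped with
#' a warning.
#'
#' @param x Numeric feature-by-sample matrix.
#' @return Matrix of the same shape (minus constant rows) of z-scores.
#' @export
zscore_rows <- function(x) {
  m <- rowMeans(x)
  s <- sqrt(row_var(x, m))
  constant <- s == 0
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant row(s) from z-matrix")
    x <- x[!constant, , drop = FALSE]
    m <- m[!constant]
    s <- s[!constant]
  }
  (x - m) / s
}

#' Export differential statistics as TSV
#'
#' @param stats A `diff_stats` data.frame from [ttest_two_group()].
#' @param path Output path.
#' @export
write_diff_stats <- function(stats, path) {
  utils::write.table(stats[c("feature", "t", "p", "sign")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
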