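#' Pearson correlation of paired concentrations
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Paired concentration ratios
#'
#' Ratio of protein X to protein Y within the same P body, row by row.
#'
#' @param table A `paired_partition_table` (columns `C_x`, `C_y`).
#' @return Numeric vector of ratios, input order preserved.
#' @export
paired_ratios <- function(table) {
  stopifnot(all(c("C_x", "C_y") %in% names(table)))
  table$C_x / table$C_y
}

#' Randomized-pairing ratio null
#'
#' Ratios \eqn{C_{x,i} / C_{y,j}} with i and j drawn uniformly with
#' replacement and redrawn whenever i = j, keeping the sample size equal to
#' the input. Breaking the within-P-body pairing destroys the correlation
#' between the two proteins, so a wider ratio spread in the randomized set
#' than in the paired set is evidence of co-partitioning.
#'
#' @param table A `paired_partition_table`.
#' @param seed Integer seed.
#' @return Numeric vector of n cross-pair ratios.
#' @export
randomized_ratios <- function(table, seed = 1L) {
  stopifnot(all(c("C_x", "C_y") %in% names(table)))
  n <- nrow(table)
  if (n < 2L) stop("need at least 2 rows to cross-pair", call. = FALSE)
  withr::with_seed(seed, {
    i <- sample.int(n, n, replace = TRUE)
    j <- sample.int(n, n, replace = TRUE)
    while (any(same <- i == j)) {
      j[same] <- sample.int(n, sum(same), replace = TRUE)
    }
  })
  table$C_x[i] / table$C_y[j]
}

#' Fligner-Killeen test of variance equality
#'
#' Rank-based test of homogeneity of variances, robust to non-normality:
#' absolute deviations from group medians are ranked across the pooled
#' sample, transformed by normal quantiles, and group mean scores compared
#' with a chi-squared statistic (k - 1 df). This wraps the standard R
#' implementation (`stats::fligner.test`).
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @return A `pbq_test`: `statistic`, `p_value`, `method`, `n`.
#' @export
fligner_killeen <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  centred <- unlist(lapply(groups, function(v) v - stats::median(v)),
                    use.names = FALSE)
  if (all(abs(centred) < .Machine$double.eps^0.5 * max(abs(x), 1))) {
    # all values equal their group medians: identical groups are a
    # well-defined no-difference case; truly degenerate data are an error
    if (stats::sd(x) == 0) {
      stop("degenerate input: all values equal", call. = FALSE)
    }
    return(structure(list(statistic = 0, p_value = 1,
                          method = "Fligner-Killeen", n = lengths(groups)),
                     class = "pbq_test"))
  }
  ft <- stats::fligner.test(x, g)
  structure(list(statistic = unname(ft$statistic),
                 p_value = ft$p.value,
                 method = "Fligner-Killeen",
                 n = lengths(groups)),
            class = "pbq_test")
}

#' Wilcoxon rank-sum test (Mann-Whitney), two-sided
#'
#' Midranks for ties. For combined n <= 12 the p value is exact, by
#' enumeration of all group assignments (valid with ties); for larger
#' samples the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b Numeric samples.
#' @return A `pbq_test` with the rank-sum statistic W (sum of ranks of `a`
#'   minus its minimum, i.e. the Mann-Whitney U of `a`).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (n <= 12L) {
    # exact: enumerate all C(n, na) assignments of the midranks
    combs <- utils::combn(n, na)
    stats_all <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    mu <- na * nb / 2
    p <- mean(abs(stats_all - mu) >= abs(U - mu) - 1e-12)
    method <- "Wilcoxon rank-sum (exact enumeration)"
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "Wilcoxon rank-sum (normal approximation)"
  }
  structure(list(statistic = U, p_value = p, method = method,
                 n = c(na, nb)),
            class = "pbq_test")
}

#' @export
print.pbq_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)%s\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = ", "),
              significance_label(x$p_value)))
  invisible(x)
}

# significance labels used in the figures: *** p<0.001, **** p<0.0005
significance_label <- function(p) {
  if (p < 0.0005) " ****" else if (p < 0.001) " ***" else ""
}

#' Classify a condensate resident as highly or less concentrated
#'
#' HC (highly concentrated) proteins have PC >= 30 *and* an in-condensate
#' concentration strictly above 5 µM; everything else is LC.
#'
#' @param pc Partition coefficient.
#' @param c_pbody In-condensate concentration, µM.
#' @return `"HC"` or `"LC"`.
#' @examples
#' classify_hc_lc(133, 15) # HC
#' classify_hc_lc(13, 4.6) # LC
#' @export
classify_hc_lc <- function(pc, c_pbody) {
  stopifnot(pc > 0, c_pbody > 0)
  if (pc >= 30 && c_pbody > 5) "HC" else "LC"
}

#' Paired vs randomized co-partitioning analysis
#'
#' Computes the log-scale Pearson correlation, the paired and randomized
#' ratio sets, and the Fligner-Killeen comparison of their log-ratio
#' variances (log ratios, because raw ratios are scale-asymmetric; the raw
#' ratio variances are reported alongside).
#'
#' @param table A `paired_partition_table`.
#' @param seed Seed for the randomized pairing.
#' @return List: `r_log`, `paired`, `randomized`, `var_log_paired`,
#'   `var_log_randomized`, `var_raw_paired`, `var_raw_randomized`, `test`
#'   (a `pbq_test`).
#' @export
copartition_analysis <- function(table, seed = 1L) {
  pr <- paired_ratios(table)
  rr <- randomized_ratios(table, seed)
  list(r_log = pearson_r(log(table$C_x), log(table$C_y)),
       paired = pr, randomized = rr,
       var_log_paired = stats::var(log(pr)),
       var_log_randomized = stats::var(log(rr)),
       var_raw_paired = stats::var(pr),
       var_raw_randomized = stats::var(rr),
       test = fligner_killeen(list(log(pr), log(rr))))
}
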