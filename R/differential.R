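# Differential enrichment statistics.
#
# The rank tests are exact at small n: the signed-rank null distribution is
# built by a generating-function convolution over sign assignments (identical
# to enumerating all 2^n patterns, including mid-ranks for tied |differences|),
# and the rank-sum null by enumerating all C(n, n_a) group assignments. Both
# fall back to the usual normal approximation with tie/continuity corrections
# at larger n, where the exact distributions are indistinguishable from it.

#' Thresholds for the differential analyses
#'
#' Defaults are the study cutoffs: FDR < 0.01 with raw p < 0.0002 for
#' discriminating hyperacetylated regions, p < 0.01 for pairwise rank
#' comparisons, and the 3-standard-deviation fold-change rule for
#' treatment-induced gains/losses.
#'
#' @param fdr_max maximum Benjamini-Hochberg q value.
#' @param p_max maximum raw p value.
#' @param pairwise_p significance cutoff for pairwise rank tests.
#' @param fc_sd_mult multiplier of the log-ratio standard deviation.
#' @return object of class `differential_thresholds`.
#' @export
differential_thresholds <- function(fdr_max = 0.01, p_max = 0.0002,
                                    pairwise_p = 0.01, fc_sd_mult = 3.0) {
  for (v in c(fdr_max, p_max, pairwise_p))
    if (v <= 0 || v > 1)
      stop("differential_thresholds: p/FDR cutoffs must lie in (0, 1]",
           call. = FALSE)
  if (fc_sd_mult <= 0)
    stop("differential_thresholds: fc_sd_mult must be > 0", call. = FALSE)
  structure(list(fdr_max = fdr_max, p_max = p_max, pairwise_p = pairwise_p,
                 fc_sd_mult = fc_sd_mult),
            class = "differential_thresholds")
}

# two-sided p from a discrete null distribution given as (support, prob)
.two_sided_p <- function(support, prob, stat, eps = 1e-9) {
  lo <- sum(prob[support <= stat + eps])
  hi <- sum(prob[support >= stat - eps])
  min(1, 2 * min(lo, hi))
}

#' Exact Wilcoxon signed-rank test for paired enrichment values
#'
#' Two-sided test of a paired shift. Zero differences are dropped before
#' ranking; `|differences|` receive mid-ranks. For up to `exact_max` non-zero
#' pairs the p value is exact over all sign assignments (computed by
#' convolution, equivalent to full enumeration); beyond that a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param before,after equal-length numeric vectors paired by region.
#' @param exact_max largest number of non-zero pairs handled exactly.
#' @return list: `statistic` (sum of positive-difference ranks), `p_value`,
#'   `n_nonzero`, `exact`.
#' @examples
#' signed_rank_test(rep(0, 5), 1:5)  # p = 0.0625 = 2/2^5
#' @export
signed_rank_test <- function(before, after, exact_max = 25) {
  if (length(before) != length(after))
    stop("signed_rank_test: before/after must have equal length",
         call. = FALSE)
  d <- after - before
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("signed_rank_test: all differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # null distribution of W+ over the 2^n equally likely sign patterns;
    # doubled ranks keep mid-ranks (x.5) on an integer lattice
    r2 <- as.integer(round(2 * r))
    probs <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), probs)
      probs <- c(probs, numeric(ri)) + shifted
    }
    probs <- probs / 2^n
    support <- (seq_along(probs) - 1) / 2
    p <- .two_sided_p(support, probs, w)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = w, p_value = p, n_nonzero = n, exact = exact)
}

# cache of group-assignment index matrices, keyed by "n_a:n"
.rs_cache <- new.env(parent = emptyenv())

.rank_sum_combos <- function(n_a, n) {
  key <- paste0(n_a, ":", n)
  if (is.null(.rs_cache[[key]]))
    .rs_cache[[key]] <- combn(n, n_a)
  .rs_cache[[key]]
}

#' Exact Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of a location difference between two independent groups,
#' with mid-ranks for ties. When `n_a + n_b <= exact_max` the null
#' distribution of the group-A rank sum is built by enumerating all
#' `choose(n, n_a)` label assignments; otherwise the normal approximation
#' with tie and continuity corrections is used.
#'
#' @param group_a,group_b numeric vectors, both nonempty.
#' @param exact_max largest total sample size handled exactly.
#' @return list: `statistic` (group-A rank sum), `p_value`, `exact`.
#' @examples
#' rank_sum_test(1:5, 6:15)$p_value  # 2/3003
#' @export
rank_sum_test <- function(group_a, group_b, exact_max = 20) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("rank_sum_test: both groups must be nonempty", call. = FALSE)
  n_a <- length(group_a)
  n_b <- length(group_b)
  n <- n_a + n_b
  r <- rank(c(group_a, group_b))
  w <- sum(r[seq_len(n_a)])
  if (n <= exact_max) {
    cmb <- .rank_sum_combos(n_a, n)
    sums <- colSums(matrix(r[cmb], nrow = n_a))
    lo <- sum(sums <= w + 1e-9) / length(sums)
    hi <- sum(sums >= w - 1e-9) / length(sums)
    p <- min(1, 2 * min(lo, hi))
    exact <- TRUE
  } else {
    mu <- n_a * (n + 1) / 2
    tie_tab <- table(r)
    sigma2 <- n_a * n_b / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = w, p_value = p, exact = exact)
}

#' Row-wise exact rank-sum tests over a matrix
#'
#' Vectorized form of [rank_sum_test()] for designs where thousands of rows
#' (e.g. CpGs) share one two-group layout: the group-assignment enumeration
#' is built once and applied to all rows by matrix multiplication, in chunks.
#'
#' @param x numeric matrix; rows are tested independently.
#' @param a_cols,b_cols column indices of the two groups.
#' @param exact_max largest total group size handled exactly (larger designs
#'   fall back to per-row [rank_sum_test()] approximations).
#' @param chunk rows per multiplication block.
#' @return list: `statistic` (group-A rank sums), `p_value`.
#' @export
rank_sum_test_rows <- function(x, a_cols, b_cols, exact_max = 20,
                               chunk = 1000L) {
  n_a <- length(a_cols)
  n_b <- length(b_cols)
  n <- n_a + n_b
  xr <- t(apply(x[, c(a_cols, b_cols), drop = FALSE], 1, rank))
  if (nrow(x) == 1) xr <- matrix(xr, nrow = 1)
  w <- rowSums(xr[, seq_len(n_a), drop = FALSE])
  p <- numeric(nrow(x))
  if (n <= exact_max) {
    cmb <- .rank_sum_combos(n_a, n)
    sel <- matrix(0, n, ncol(cmb))
    sel[cbind(as.vector(cmb), rep(seq_len(ncol(cmb)), each = n_a))] <- 1
    nc <- ncol(cmb)
    for (i0 in seq(1, nrow(x), by = chunk)) {
      idx <- i0:min(i0 + chunk - 1L, nrow(x))
      sums <- xr[idx, , drop = FALSE] %*% sel
      lo <- rowSums(sums <= w[idx] + 1e-9) / nc
      hi <- rowSums(sums >= w[idx] - 1e-9) / nc
      p[idx] <- pmin(1, 2 * pmin(lo, hi))
    }
  } else {
    for (i in seq_len(nrow(x)))
      p[i] <- rank_sum_test(x[i, a_cols], x[i, b_cols],
                            exact_max = exact_max)$p_value
  }
  list(statistic = w, p_value = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q values: monotone non-decreasing in sorted-p order and bounded by
#' 1. A thin validating wrapper over [stats::p.adjust()].
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @return q values, same length and order as `p_values`.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("bh_fdr: p values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Call gained/lost regions by the 3-standard-deviation fold-change rule
#'
#' Per region, the log2 ratio `r = log2((treated + c) / (control + c))` is
#' computed on normalized enrichment with pseudocount `c`. With `m` and `s`
#' the mean and standard deviation of `r` over all regions, a region is a
#' gain iff `r > m + fc_sd_mult * s` and a loss iff `r < m - fc_sd_mult * s`.
#' The pseudocount is expressed in the units of the input; scaling both
#' columns by a constant `k` together with `c` leaves every call unchanged.
#'
#' @param control,treated numeric vectors of normalized enrichment over the
#'   same region list.
#' @param fc_sd_mult standard-deviation multiplier (default 3).
#' @param pseudocount additive constant `c` (default 1 normalized unit).
#' @param regions optional interval data frame carried into the result.
#' @return data frame with `log2fc`, `direction` (gain/loss/none) and
#'   `selected`; attributes `center` and `spread` hold `m` and `s`.
#' @export
changed_regions_fc_sd <- function(control, treated, fc_sd_mult = 3,
                                  pseudocount = 1, regions = NULL) {
  if (length(control) != length(treated))
    stop("changed_regions_fc_sd: region lists differ in length",
         call. = FALSE)
  if (fc_sd_mult <= 0)
    stop("changed_regions_fc_sd: fc_sd_mult must be > 0", call. = FALSE)
  r <- log2((treated + pseudocount) / (control + pseudocount))
  m <- mean(r)
  s <- sd(r)
  if (length(r) < 2 || is.na(s) || s == 0) {
    if (length(r) >= 1)
      warning("changed_regions_fc_sd: zero spread in log ratios; ",
              "no regions called")
    direction <- rep("none", length(r))
  } else {
    direction <- ifelse(r > m + fc_sd_mult * s, "gain",
                        ifelse(r < m - fc_sd_mult * s, "loss", "none"))
  }
  out <- data.frame(log2fc = r, direction = direction,
                    selected = direction != "none", stringsAsFactors = FALSE)
  if (!is.null(regions)) out <- cbind(regions[, c("chrom", "start", "end")], out)
  attr(out, "center") <- m
  attr(out, "spread") <- s
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over regions (restricted to
#' regions with nonzero counts in every sample) of the ratio of the sample's
#' count to the region's geometric mean across samples.
#'
#' @param raw region x sample matrix of raw counts, or a
#'   [region_count_table()].
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(raw) {
  if (inherits(raw, "region_count_table")) raw <- raw$raw
  raw <- as.matrix(raw)
  log_geo <- rowMeans(log(raw))
  use <- is.finite(log_geo)
  if (!any(use))
    stop("size_factors: no region has nonzero counts in every sample",
         call. = FALSE)
  apply(raw, 2, function(col)
    exp(median(log(col[use]) - log_geo[use])))
}

#' Negative-binomial differential test between two groups
#'
#' Counts are normalized by [size_factors()]; for each region the dispersion
#' is estimated by the method of moments from the within-group variance of
#' normalized counts, pooled across the two groups, and floored at
#' `dispersion_floor`. The test is a Wald test on the log2 fold change of
#' group means, with the NB variance `mu/s_j + alpha * mu^2` propagated to
#' the group means by the delta method. q values are Benjamini-Hochberg.
#'
#' @param raw region x sample count matrix or [region_count_table()].
#' @param groups two-level factor (or character) of length `ncol(raw)`; the
#'   fold change is `log2(mean(level 2) / mean(level 1))`.
#' @param dispersion_floor lower bound on the dispersion estimate.
#' @param pseudo_mean small constant added to group means before taking logs.
#' @return data frame: `base_mean`, `log2fc`, `statistic`, `p_value`,
#'   `q_value`, one row per region (region coordinates prepended when the
#'   input is a [region_count_table()]).
#' @export
nb_differential_test <- function(raw, groups, dispersion_floor = 1e-8,
                                 pseudo_mean = 0.5) {
  regions <- NULL
  if (inherits(raw, "region_count_table")) {
    regions <- raw$regions
    raw <- raw$raw
  }
  raw <- as.matrix(raw)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("nb_differential_test: exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2))
    stop("nb_differential_test: each group needs >= 2 samples for a ",
         "dispersion estimate", call. = FALSE)
  sf <- size_factors(raw)
  norm <- sweep(raw, 2, sf, "/")
  a <- groups == levels(groups)[1]
  b <- groups == levels(groups)[2]
  n_a <- sum(a)
  n_b <- sum(b)
  m_a <- rowMeans(norm[, a, drop = FALSE])
  m_b <- rowMeans(norm[, b, drop = FALSE])
  v_a <- apply(norm[, a, drop = FALSE], 1, var)
  v_b <- apply(norm[, b, drop = FALSE], 1, var)
  v_pool <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
  mu <- (n_a * m_a + n_b * m_b) / (n_a + n_b)
  xi <- mean(1 / sf)  # average shot-noise scale of normalized counts
  alpha <- pmax((v_pool - mu * xi) / mu^2, dispersion_floor)
  alpha[!is.finite(alpha)] <- dispersion_floor
  ma_ <- m_a + pseudo_mean
  mb_ <- m_b + pseudo_mean
  log2fc <- log2(mb_ / ma_)
  xi_a <- mean(1 / sf[a])
  xi_b <- mean(1 / sf[b])
  var_ma <- (ma_ * xi_a + alpha * ma_^2) / n_a
  var_mb <- (mb_ * xi_b + alpha * mb_^2) / n_b
  se <- sqrt(var_ma / ma_^2 + var_mb / mb_^2) / log(2)
  # standard Wald reference; with variances moment-estimated from few
  # samples this is mildly anti-conservative in the tails (see vignette)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- pmin(1, 2 * pnorm(-abs(z)))
  out <- data.frame(base_mean = mu, log2fc = log2fc, statistic = z,
                    p_value = p, q_value = bh_fdr(p))
  if (!is.null(regions))
    out <- cbind(regions[, c("chrom", "start", "end")], out)
  out
}

#' Select discriminating regions by the double p/FDR threshold
#'
#' A region is selected iff `q_value < fdr_max` AND `p_value < p_max` AND its
#' log2 fold change points in the requested direction (gain = higher in the
#' second group, e.g. hyperacetylated in high-risk samples).
#'
#' @param results data frame with `p_value`, `q_value`, `log2fc` (e.g. from
#'   [nb_differential_test()]).
#' @param thresholds a [differential_thresholds()].
#' @param direction `"gain"`, `"loss"` or `"both"`.
#' @return `results` with logical column `selected` added.
#' @export
discriminating_regions <- function(results,
                                   thresholds = differential_thresholds(),
                                   direction = c("gain", "loss", "both")) {
  direction <- match.arg(direction)
  if (!all(c("p_value", "q_value", "log2fc") %in% names(results)))
    stop("discriminating_regions: results must carry p_value, q_value, log2fc",
         call. = FALSE)
  dir_ok <- switch(direction,
                   gain = results$log2fc > 0,
                   loss = results$log2fc < 0,
                   both = rep(TRUE, nrow(results)))
  results$selected <- results$q_value < thresholds$fdr_max &
    results$p_value < thresholds$p_max & dir_ok
  results
}
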