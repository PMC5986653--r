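# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: interval operations are checked against per-base
# boolean masks, rank tests against literal enumeration of sign patterns /
# group assignments, and filters against plain-loop recomputation.

# per-base boolean mask of an interval set on a single contig of length len
mask_of <- function(iv, len, chrom = "c1") {
  m <- logical(len)
  iv <- iv[iv$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(iv))) {
    s <- max(0, iv$start[i])
    e <- min(len, iv$end[i])
    if (e > s) m[(s + 1):e] <- TRUE
  }
  m
}

# mask back to intervals (runs of TRUE)
mask_to_intervals <- function(m, chrom = "c1") {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
             end = ends[keep], stringsAsFactors = FALSE)
}

random_intervals <- function(n, len, max_w = 400, chrom = "c1") {
  s <- sample.int(len - max_w, n, replace = TRUE) - 1
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(chrom = rep(chrom, n), start = s, end = s + w,
             stringsAsFactors = FALSE)
}

# literal enumeration oracle for the two-sided signed-rank p (n <= 12)
signed_rank_enum_p <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# literal enumeration oracle for the two-sided rank-sum p (n_a + n_b <= 12)
rank_sum_enum_p <- function(a, b) {
  n_a <- length(a)
  n <- n_a + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n_a)])
  cmb <- combn(n, n_a)
  ws <- apply(cmb, 2, function(idx) sum(r[idx]))
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# plain-loop recomputation of the 3-SD fold-change calls
fc_sd_brute <- function(control, treated, mult, c0) {
  r <- numeric(length(control))
  for (i in seq_along(control))
    r[i] <- log2((treated[i] + c0) / (control[i] + c0))
  m <- sum(r) / length(r)
  s <- sqrt(sum((r - m)^2) / (length(r) - 1))
  out <- character(length(r))
  for (i in seq_along(r))
    out[i] <- if (r[i] > m + mult * s) "gain"
      else if (r[i] < m - mult * s) "loss" else "none"
  out
}

# small synthetic variant table spanning every cascade branch
variant_fixture <- function() {
  data.frame(
    chrom = "c1", pos = 1:10, ref = "A", alt = "G",
    depth =        c(50, 19, 20, 50, 50, 50, 50, NA, 50, 50),
    quality =      c(80, 80, 40, 39, 80, 80, 80, 80, 80, 80),
    consequence =  c("missense", "missense", "missense", "missense",
                     "synonymous", "missense", "missense", "missense",
                     "missense", "other"),
    maf =          c(0.01, 0.01, NA, 0.01, 0.001, 0.2, 0.04, 0.01, 0.01,
                     0.01),
    gene_id = sprintf("G%02d", 1:10),
    is_driver =    c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                     TRUE),
    confirmations = c("RNA-seq,ChIP-seq", "RNA-seq", "RNA-seq", "RNA-seq",
                      "RNA-seq", "RNA-seq", "RNA-seq", "RNA-seq", "",
                      "RNA-seq"),
    stringsAsFactors = FALSE)
}
# hand enumeration: record 1 passes all stages; 3 passes (DP=20, Phred=40
# boundaries, missing MAF treated rare); 7 kept by quality but dropped as
# non-driver; survivors = {1, 3}; record 8 is incomplete (NA depth).
variant_fixture_survivor_pos <- c(1, 3)

# count evidence tracks the same way the cascade does, via the internal
.n_confirmations_for_test <- function(x) episig:::.n_confirmations(x)
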