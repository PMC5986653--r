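calls_df <- function(chrom, pos, strand, context, meth, total)
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             meth_count = meth, total_count = total, stringsAsFactors = FALSE)

test_that("context filtering keeps only CG calls and rejects unknown labels", {
  x <- calls_df("c1", 1:4, "+", c("CG", "CHH", "CXG", "CG"), 1, 5)
  expect_equal(filter_cg_context(x)$pos, c(1, 4))
  expect_equal(nrow(filter_cg_context(calls_df("c1", 1:3, "+", "CHH", 0, 5))),
               0)
  bad <- calls_df("c1", 1, "+", "CGG", 1, 5)
  expect_error(filter_cg_context(bad), "unknown context 'CGG'")
  set.seed(81)
  ctx <- sample(c("CG", "CHH", "CXG"), 500, replace = TRUE)
  x <- calls_df("c1", 1:500, "+", ctx, 0, 5)
  expect_equal(nrow(filter_cg_context(x)), sum(ctx == "CG"))
})

test_that("strand combining sums dyad counts and conserves totals", {
  x <- calls_df("c1", c(100, 101), c("+", "-"), "CG", c(3, 2), c(5, 5))
  got <- combine_symmetric_cpgs(x)
  expect_equal(got, data.frame(chrom = "c1", pos = 100, meth_count = 5,
                               total_count = 10, beta = 0.5))
  solo <- combine_symmetric_cpgs(calls_df("c1", 100, "+", "CG", 3, 5))
  expect_equal(solo$beta, 0.6)
  # unpaired reverse call reported at the dyad's forward position
  rev_only <- combine_symmetric_cpgs(calls_df("c1", 101, "-", "CG", 2, 4))
  expect_equal(rev_only$pos, 100)
  dup <- calls_df("c1", c(100, 100), "+", "CG", 1, 5)
  expect_error(combine_symmetric_cpgs(dup), "duplicate")
  set.seed(82)
  pos <- sort(sample.int(10000, 300) * 2)
  fwd <- calls_df("c1", pos, "+", "CG", rbinom(300, 20, 0.4), 20)
  rev <- calls_df("c1", pos + 1, "-", "CG", rbinom(300, 15, 0.4), 15)
  keep <- runif(300) < 0.8  # some dyads unpaired
  comb <- combine_symmetric_cpgs(rbind(fwd, rev[keep, ]))
  expect_equal(sum(comb$meth_count),
               sum(fwd$meth_count) + sum(rev$meth_count[keep]))
  expect_equal(sum(comb$total_count),
               sum(fwd$total_count) + sum(rev$total_count[keep]))
})

test_that("coverage threshold is inclusive at 5 (equivalently coverage > 4)", {
  sites <- data.frame(chrom = "c1", pos = 1:3, meth_count = 1,
                      total_count = c(4, 5, 30), beta = 0.2)
  expect_equal(filter_coverage(sites)$total_count, c(5, 30))
  expect_equal(nrow(filter_coverage(sites[0, ])), 0)
  expect_error(filter_coverage(sites, min_total = 0), ">= 1")
  set.seed(83)
  sites$total_count <- sample(1:10, 3, replace = TRUE)
  expect_equal(nrow(filter_coverage(sites, 6)), sum(sites$total_count >= 6))
})

make_sites <- function(pos, beta)
  data.frame(chrom = rep("c1", length(pos)), pos = pos,
             meth_count = round(beta * 20),
             total_count = rep(20, length(pos)), beta = beta,
             stringsAsFactors = FALSE)

test_that("matrix building enforces discovery completeness and sample coverage", {
  g <- data.frame(sample = c("h1", "h2", "a1", "a2"),
                  group = c("hrAPL", "hrAPL", "APL", "APL"))
  per <- list(h1 = make_sites(c(10, 20, 30), 0.5),
              h2 = make_sites(c(10, 20, 30), 0.5),
              a1 = make_sites(c(10, 20), 0.5),      # pos 30 undetermined
              a2 = make_sites(c(10, 20, 30), 0.5))
  mat <- build_methylation_matrix(per, g)
  expect_equal(rownames(mat$beta), c("c1:10", "c1:20"))
  per$a1 <- make_sites(c(10, 20, 30), 0.5)
  expect_equal(nrow(build_methylation_matrix(per, g)$beta), 3)
  per$a2 <- make_sites(numeric(0), numeric(0))
  expect_error(build_methylation_matrix(per, g), "'a2'")
})

test_that("supervised CpG test: exact p values, cutoffs, and direction", {
  g <- data.frame(sample = c(paste0("h", 1:5), paste0("a", 1:10)),
                  group = rep(c("hrAPL", "APL"), c(5, 10)))
  sep <- c(runif(5, 0, 0.2), runif(10, 0.6, 1))    # complete separation
  null <- rep(0.5, 15)
  per <- lapply(seq_len(15), function(j)
    make_sites(c(100, 200), c(sep[j], null[j])))
  names(per) <- g$sample
  mat <- build_methylation_matrix(per, g)
  sig <- supervised_cpg_test(mat)
  i <- which(sig$pos == 100)
  expect_equal(sig$p_value[i], 2 / 3003)
  expect_true(sig$in_signature[i] && sig$in_stringent[i])
  expect_equal(sig$direction[i], "hypo")
  j <- which(sig$pos == 200)
  expect_equal(sig$p_value[j], 1)
  expect_false(sig$in_signature[j])
  # column order invariance
  perm <- sample(ncol(mat$beta))
  mat2 <- mat
  mat2$beta <- mat$beta[, perm]
  mat2$groups <- mat$groups[perm]
  sig2 <- supervised_cpg_test(mat2)
  expect_equal(sig2$p_value, sig$p_value)
  mat3 <- mat
  mat3$groups[mat3$groups == "hrAPL"][2:5] <- "AML"
  expect_error(supervised_cpg_test(mat3), ">= 2")
})

test_that("no CpG passes the stringent cutoff at 5 vs 10 without complete separation", {
  # full exact null distribution with distinct betas: the second-most extreme
  # rank sum already gives p = 4/3003 > 0.0007
  sums <- colSums(matrix(combn(15, 5), nrow = 5))
  p_of <- function(w) min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
  attainable <- sort(unique(vapply(min(sums):max(sums), p_of, 0)))
  expect_equal(min(attainable), 2 / 3003)
  expect_lt(2 / 3003, 0.0007)
  expect_gt(attainable[2], 0.0007)
  # randomized overlapping-group data never reach the stringent cutoff
  set.seed(84)
  for (trial in 1:50) {
    a <- runif(5)
    b <- runif(10)
    a[1] <- max(b) + 0.1  # force overlap in the rank ordering
    b[1] <- max(a[-1], 0) + 0.05
    expect_gte(rank_sum_test(a, b)$p_value, 0.0007)
  }
})

test_that("cohort refinement keeps only AML-complete CpGs", {
  g <- data.frame(sample = c("h1", "h2", "a1", "a2", "m1", "m2", "m3"),
                  group = c("hrAPL", "hrAPL", "APL", "APL", rep("AML", 3)))
  beta <- matrix(runif(21), 3, 7,
                 dimnames = list(c("c1:10", "c1:20", "c1:30"), g$sample))
  beta["c1:20", "m2"] <- NA  # missing in 1 AML column -> dropped
  cohort <- structure(list(beta = beta,
                           pos = data.frame(chrom = "c1",
                                            pos = c(10, 20, 30)),
                           groups = setNames(g$group, g$sample)),
                      class = "methylation_matrix")
  sig <- data.frame(chrom = "c1", pos = c(10, 20, 30),
                    p_value = 1e-4, mean_diff = -0.3, direction = "hypo",
                    in_signature = TRUE, in_stringent = c(TRUE, TRUE, FALSE))
  out <- refine_against_cohort(sig, cohort)
  expect_equal(out$in_final, c(TRUE, FALSE, FALSE))
  cohort$groups[] <- "APL"
  expect_error(refine_against_cohort(sig, cohort), "no AML")
})

test_that("direction partition is exhaustive and disjoint", {
  sig <- data.frame(mean_diff = c(-0.5, 0.3, -0.1, 0.2))
  parts <- classify_direction(sig)
  expect_equal(unname(parts$counts), c(2, 2))
  expect_equal(sum(parts$counts), nrow(sig))
  expect_warning(classify_direction(data.frame(mean_diff = 0)), "hyper")
})

test_that("call readers accept both TSV dialects", {
  p <- tempfile()
  x <- calls_df("c1", c(100, 101), c("+", "-"), "CG", c(3, 2), c(5, 5))
  write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_cpg_calls(p), x)
  pb <- tempfile()
  writeLines("c1\t100\t101\t60\t3\t2", pb)
  bis <- read_cpg_calls(pb, dialect = "bismark")
  expect_equal(bis$total_count, 5)
  expect_equal(bis$beta, 0.6)
})
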