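ps <- function(mark, iv, sid = "s1") peak_set(sid, mark, iv)

test_that("candidate promoters/enhancers exclude cross-marked peaks whole", {
  me3 <- ps("H3K4me3", genomic_intervals(c("chr1", "chr1"), c(100, 5000),
                                         c(600, 5400)))
  me1 <- ps("H3K4me1", genomic_intervals(c("chr1", "chr1"), c(500, 9000),
                                         c(900, 9500)))
  cand <- define_candidate_regions(me3, me1)
  # the chr1:100-600 peak overlaps the chr1:500-900 H3K4me1 peak: both out
  expect_equal(cand$promoters, data.frame(chrom = "chr1", start = 5000,
                                          end = 5400))
  expect_equal(cand$enhancers, data.frame(chrom = "chr1", start = 9000,
                                          end = 9500))
  # empty H3K4me1: every H3K4me3 peak is a promoter candidate
  cand2 <- define_candidate_regions(me3, ps("H3K4me1", genomic_intervals()))
  expect_equal(nrow(cand2$promoters), 2)
  expect_equal(nrow(cand2$enhancers), 0)
  expect_error(define_candidate_regions(me1, me3), "mark H3K4me3")
})

test_that("candidate selection equals a brute-force pairwise overlap screen and is base-disjoint", {
  set.seed(51)
  overlaps <- function(a, b)
    a$start < b$end & b$start < a$end & a$chrom == b$chrom
  for (trial in 1:20) {
    me3_iv <- merge_intervals(random_intervals(30, 20000))
    me1_iv <- merge_intervals(random_intervals(30, 20000))
    cand <- define_candidate_regions(ps("H3K4me3", me3_iv),
                                     ps("H3K4me1", me1_iv))
    keep3 <- vapply(seq_len(nrow(me3_iv)), function(i)
      !any(vapply(seq_len(nrow(me1_iv)), function(j)
        overlaps(me3_iv[i, ], me1_iv[j, ]), TRUE)), TRUE)
    expect_equal(cand$promoters, me3_iv[keep3, ], ignore_attr = TRUE)
    expect_false(any(mask_of(cand$promoters, 20000) &
                       mask_of(cand$enhancers, 20000)))
  }
})

test_that("common regions are the per-base AND across samples", {
  a <- genomic_intervals("chr1", c(0, 100), c(50, 200))
  expect_equal(common_regions(list(a, a)), a)
  b <- genomic_intervals("chr1", 300, 400)
  expect_equal(nrow(common_regions(list(a, b))), 0)
  expect_error(common_regions(list(a)), "at least 2")
  set.seed(52)
  sets <- replicate(3, random_intervals(50, 10000), simplify = FALSE)
  cr <- common_regions(sets)
  expect_equal(cr, mask_to_intervals(Reduce(`&`, lapply(sets, mask_of,
                                                        len = 10000))))
  # every common base lies inside a candidate of every sample
  for (s in sets)
    expect_true(all(mask_of(s, 10000)[mask_of(cr, 10000)]))
})

test_that("activity classification: repression dominates and the output partitions", {
  regions <- genomic_intervals(rep("chr1", 4), c(0, 100, 200, 300),
                               c(50, 150, 250, 350))
  ac <- genomic_intervals(rep("chr1", 2), c(10, 210), c(20, 220))
  me3 <- genomic_intervals(rep("chr1", 2), c(110, 210), c(120, 230))
  cls <- classify_activity(regions, "promoter", ac, me3)
  # region 1: ac only -> active; 2: me3 only; 3: both (repression dominates);
  # 4: neither -> inactive
  expect_equal(cls$activity, c("active", "inactive", "inactive", "inactive"))
  expect_equal(sum(cls$activity == "active") + sum(cls$activity == "inactive"),
               nrow(regions))
})

test_that("enrichment-cutoff mode applies thresholds and is monotone in h3k27ac_min", {
  set.seed(53)
  regions <- random_intervals(200, 1e6)
  ac <- runif(200, 0, 5)
  me3 <- runif(200, 0, 5)
  th1 <- activity_thresholds("enrichment-cutoff", h3k27ac_min = 1,
                             h3k27me3_max = 2)
  cls <- classify_activity(regions, "enhancer", ac, me3, th1)
  expect_equal(cls$activity == "active", ac >= 1 & me3 < 2)
  n_active <- function(cut) sum(classify_activity(
    regions, "enhancer", ac, me3,
    activity_thresholds("enrichment-cutoff", h3k27ac_min = cut,
                        h3k27me3_max = 2))$activity == "active")
  counts <- vapply(c(0, 0.5, 1, 2, 4), n_active, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_error(classify_activity(regions, "enhancer", ps("H3K27ac", regions),
                                 me3, th1), "enrichment-cutoff")
})

test_that("gene association applies the distance and expression gates", {
  enh <- genomic_intervals("chr1", 100000, 101000)
  ann <- data.frame(gene_id = c("near_hi", "near_lo", "far_hi"),
                    chrom = "chr1",
                    tss_pos = c(131000, 120000, 161000))
  expr <- data.frame(gene_id = rep(ann$gene_id, 2),
                     sample = rep(c("s1", "s2"), each = 3),
                     rpkm = c(75, 10, 75, 75, 10, 75))
  out <- associate_regions_to_genes(enh, ann, expr)
  # near_hi: 30 kb away, RPKM sum 150 -> associated; near_lo fails RPKM;
  # far_hi is 60 kb away
  expect_equal(out$gene_id, "near_hi")
  expect_equal(out$distance, 131000 - 100999)
  expect_warning(associate_regions_to_genes(enh, ann[0, ], expr), "empty")
  expect_error(associate_regions_to_genes(enh, ann, expr, distance_max = 0),
               "> 0")
})

test_that("gene association matches a brute-force all-pairs scan", {
  set.seed(54)
  for (trial in 1:10) {
    regions <- merge_intervals(random_intervals(20, 2e5, 2000))
    ng <- 30
    ann <- data.frame(gene_id = sprintf("g%02d", 1:ng), chrom = "c1",
                      tss_pos = sample.int(2e5, ng) - 1)
    rs <- setNames(runif(ng, 0, 10), ann$gene_id)
    out <- associate_regions_to_genes(regions, ann, rs, distance_max = 5000,
                                      rpkm_sum_min = 3)
    expected <- 0L
    for (i in seq_len(nrow(regions))) for (j in seq_len(ng)) {
      t <- ann$tss_pos[j]
      d <- if (t >= regions$start[i] && t < regions$end[i]) 0
        else min(abs(t - regions$start[i]), abs(t - (regions$end[i] - 1)))
      if (d < 5000 && rs[j] > 3) {
        expected <- expected + 1L
        expect_true(any(out$region_idx == i & out$gene_id == ann$gene_id[j]))
      }
    }
    expect_equal(nrow(out), expected)
  }
})
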