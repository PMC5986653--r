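# Promoter/enhancer definition and activity classification.
#
# Promoters are H3K4me3-marked regions, enhancers H3K4me1-marked; a region
# carrying both marks is ambiguous and excluded from both classes. Activity is
# read from H3K27ac (acetylation, activating) and H3K27me3 (polycomb,
# repressive): active = high H3K27ac AND low H3K27me3.

#' Define promoter and enhancer candidate regions for one sample
#'
#' Promoter candidates are the H3K4me3 peaks that share no base with any
#' H3K4me1 peak; enhancer candidates are the H3K4me1 peaks that share no base
#' with any H3K4me3 peak. Exclusion is whole-peak: any overlap disqualifies
#' the peak, keeping peak identity intact rather than trimming bases.
#'
#' @param h3k4me3 [peak_set()] with mark `"H3K4me3"`.
#' @param h3k4me1 [peak_set()] with mark `"H3K4me1"`.
#' @return list with interval data frames `promoters` and `enhancers`.
#' @export
define_candidate_regions <- function(h3k4me3, h3k4me1) {
  if (!inherits(h3k4me3, "peak_set") || !inherits(h3k4me1, "peak_set"))
    stop("define_candidate_regions: inputs must be peak_set objects",
         call. = FALSE)
  if (h3k4me3$mark != "H3K4me3")
    stop("define_candidate_regions: first argument must carry mark H3K4me3, got ",
         h3k4me3$mark, call. = FALSE)
  if (h3k4me1$mark != "H3K4me1")
    stop("define_candidate_regions: second argument must carry mark H3K4me1, got ",
         h3k4me1$mark, call. = FALSE)
  me3 <- gi_to_gr(h3k4me3$intervals)
  me1 <- gi_to_gr(h3k4me1$intervals)
  prom <- h3k4me3$intervals[GenomicRanges::countOverlaps(me3, me1) == 0, ,
                            drop = FALSE]
  enh <- h3k4me1$intervals[GenomicRanges::countOverlaps(me1, me3) == 0, ,
                           drop = FALSE]
  rownames(prom) <- rownames(enh) <- NULL
  list(promoters = prom, enhancers = enh)
}

#' Common candidate regions across samples
#'
#' Base-level intersection of per-sample candidate sets: every returned base
#' lies inside a candidate region of every sample.
#'
#' @param candidates_per_sample list (length >= 2) of interval data frames.
#' @return interval data frame of common regions.
#' @export
common_regions <- function(candidates_per_sample) {
  if (!is.list(candidates_per_sample) || length(candidates_per_sample) < 2)
    stop("common_regions: need candidates from at least 2 samples; ",
         "with a single sample use its candidate set directly", call. = FALSE)
  intersect_all(candidates_per_sample)
}

#' Activity-classification thresholds
#'
#' In `peak-overlap` mode a criterion is met by >= 1 bp overlap with the
#' respective peak set. In `enrichment-cutoff` mode the H3K27ac criterion is
#' `normalized enrichment >= h3k27ac_min` and the H3K27me3 criterion is
#' `normalized enrichment >= h3k27me3_max`; a region is active when the
#' H3K27ac criterion is met and the H3K27me3 criterion is not.
#'
#' @param mode `"peak-overlap"` (default) or `"enrichment-cutoff"`.
#' @param h3k27ac_min,h3k27me3_max non-negative enrichment cutoffs
#'   (RPKM-like units), used in enrichment-cutoff mode.
#' @return object of class `activity_thresholds`.
#' @export
activity_thresholds <- function(mode = c("peak-overlap", "enrichment-cutoff"),
                                h3k27ac_min = 1, h3k27me3_max = 1) {
  mode <- match.arg(mode)
  if (h3k27ac_min < 0 || h3k27me3_max < 0)
    stop("activity_thresholds: thresholds must be >= 0", call. = FALSE)
  structure(list(mode = mode, h3k27ac_min = h3k27ac_min,
                 h3k27me3_max = h3k27me3_max),
            class = "activity_thresholds")
}

#' Classify regulatory regions as active or inactive
#'
#' A region is active iff the H3K27ac criterion is met AND the H3K27me3
#' criterion is not; a region carrying both marks is inactive (repression
#' dominates). See [activity_thresholds()] for the two criterion modes.
#'
#' @param regions interval data frame of candidate regions.
#' @param region_class `"promoter"` or `"enhancer"` (scalar or per-region).
#' @param h3k27ac,h3k27me3 in peak-overlap mode, [peak_set()] objects (or
#'   interval data frames); in enrichment-cutoff mode, numeric vectors of
#'   normalized enrichment, one per region.
#' @param thresholds an [activity_thresholds()].
#' @return data frame: `chrom`, `start`, `end`, `region_class`, `activity`.
#' @export
classify_activity <- function(regions, region_class, h3k27ac, h3k27me3,
                              thresholds = activity_thresholds()) {
  validate_intervals(regions, "regions")
  if (!inherits(thresholds, "activity_thresholds"))
    stop("classify_activity: thresholds must be activity_thresholds",
         call. = FALSE)
  region_class <- rep_len(as.character(region_class), nrow(regions))
  if (!all(region_class %in% c("promoter", "enhancer")))
    stop("classify_activity: region_class must be promoter or enhancer",
         call. = FALSE)
  if (thresholds$mode == "peak-overlap") {
    as_iv <- function(p) if (inherits(p, "peak_set")) p$intervals else p
    gr <- gi_to_gr(regions)
    ac_met <- GenomicRanges::countOverlaps(gr, gi_to_gr(as_iv(h3k27ac))) > 0
    me3_met <- GenomicRanges::countOverlaps(gr, gi_to_gr(as_iv(h3k27me3))) > 0
  } else {
    if (!is.numeric(h3k27ac) || !is.numeric(h3k27me3) ||
        length(h3k27ac) != nrow(regions) || length(h3k27me3) != nrow(regions))
      stop("classify_activity: enrichment-cutoff mode needs one normalized ",
           "enrichment value per region for each mark", call. = FALSE)
    ac_met <- h3k27ac >= thresholds$h3k27ac_min
    me3_met <- h3k27me3 >= thresholds$h3k27me3_max
  }
  data.frame(chrom = regions$chrom, start = regions$start, end = regions$end,
             region_class = region_class,
             activity = ifelse(ac_met & !me3_met, "active", "inactive"),
             stringsAsFactors = FALSE)
}

#' Associate regulatory regions with genes
#'
#' A gene is associated with a region iff the minimum distance between the
#' region and the gene's TSS is below `distance_max` AND the gene's summed
#' expression across samples exceeds `rpkm_sum_min`. Distance is measured from
#' the nearest region edge to the TSS base (0 when the TSS falls inside the
#' region); all qualifying genes are associated. Defaults follow the enhancer
#' gates (< 50 kb, RPKM sum > 100); for promoters use `rpkm_sum_min = 0.5`.
#'
#' @param regions interval data frame.
#' @param annotation data frame: `gene_id`, `chrom`, `tss_pos` (0-based base).
#' @param expression data frame: `gene_id`, `sample`, `rpkm` (>= 0), or a
#'   named vector of per-gene RPKM sums.
#' @param distance_max maximum region-TSS distance in bp (> 0).
#' @param rpkm_sum_min minimum summed RPKM across samples.
#' @return data frame of associations: `region_idx`, `chrom`, `start`, `end`,
#'   `gene_id`, `distance`, `rpkm_sum`.
#' @export
associate_regions_to_genes <- function(regions, annotation, expression,
                                       distance_max = 50000,
                                       rpkm_sum_min = 100) {
  validate_intervals(regions, "regions")
  if (distance_max <= 0)
    stop("associate_regions_to_genes: distance_max must be > 0", call. = FALSE)
  empty <- data.frame(region_idx = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      gene_id = character(), distance = numeric(),
                      rpkm_sum = numeric(), stringsAsFactors = FALSE)
  if (is.null(annotation) || nrow(annotation) == 0) {
    warning("associate_regions_to_genes: empty gene annotation; ",
            "no associations made")
    return(empty)
  }
  if (is.data.frame(expression)) {
    if (any(expression$rpkm < 0))
      stop("associate_regions_to_genes: negative RPKM", call. = FALSE)
    rpkm_sum <- tapply(expression$rpkm, expression$gene_id, sum)
  } else {
    rpkm_sum <- expression
  }
  annotation$rpkm_sum <- as.numeric(rpkm_sum[annotation$gene_id])
  annotation$rpkm_sum[is.na(annotation$rpkm_sum)] <- 0
  keep <- annotation[annotation$rpkm_sum > rpkm_sum_min, , drop = FALSE]
  if (nrow(keep) == 0 || nrow(regions) == 0) return(empty)
  tss <- GenomicRanges::GRanges(keep$chrom,
                                IRanges::IRanges(keep$tss_pos + 1, width = 1))
  gr <- gi_to_gr(regions)
  hits <- GenomicRanges::findOverlaps(gr, tss,
                                      maxgap = as.integer(distance_max))
  if (length(hits) == 0) return(empty)
  ri <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  # distance from the nearest region edge base to the TSS base; 0 inside
  t <- keep$tss_pos[gi]
  s <- regions$start[ri]
  e <- regions$end[ri]
  d <- ifelse(t >= s & t < e, 0, ifelse(t < s, s - t, t - (e - 1)))
  out <- data.frame(region_idx = ri, chrom = regions$chrom[ri],
                    start = regions$start[ri], end = regions$end[ri],
                    gene_id = keep$gene_id[gi], distance = as.numeric(d),
                    rpkm_sum = keep$rpkm_sum[gi], stringsAsFactors = FALSE)
  out <- out[out$distance < distance_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}
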