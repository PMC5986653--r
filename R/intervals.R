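#' @importFrom stats median p.adjust pnorm pt rbeta rbinom rhyper rnbinom
#'   rpois runif sd var setNames
#' @importFrom utils combn read.delim write.table head
NULL

# ---- genomic intervals ------------------------------------------------------
# All coordinates are 0-based half-open (BED convention): a peak covering the
# first ten bases of a contig is start = 0, end = 10.

#' Construct a genomic interval table
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` in
#' 0-based half-open (BED) coordinates. Chromosome names are compared by
#' exact string match; no "chr" aliasing is applied unless requested at I/O
#' time.
#'
#' @param chrom character vector of contig names (nonempty strings).
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `end > start`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer()) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
}

#' Validate a genomic interval table
#'
#' Checks the interval invariants: nonempty chromosome names and
#' `start < end`. Invalid records are reported by row index.
#'
#' @param x data frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop(what, ": expected a data.frame with columns chrom, start, end",
         call. = FALSE)
  if (nrow(x) == 0) return(x)
  if (anyNA(x$chrom) || any(!nzchar(x$chrom)))
    stop(what, ": empty chromosome name at row ",
         which(is.na(x$chrom) | !nzchar(x$chrom))[1], call. = FALSE)
  bad <- which(!(x$start < x$end))
  if (length(bad))
    stop(what, ": invalid interval (start >= end) at row ", bad[1], ": ",
         x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]],
         call. = FALSE)
  if (any(x$start < 0))
    stop(what, ": negative start at row ", which(x$start < 0)[1],
         call. = FALSE)
  x
}

# GRanges bridge: GRanges is 1-based closed, BED is 0-based half-open.
gi_to_gr <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

gr_to_gi <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Merge overlapping genomic intervals
#'
#' Returns the sorted, pairwise non-overlapping set of intervals covering
#' exactly the union of the input bases. Bookended intervals (end of one equal
#' to start of the next) are joined.
#'
#' @param x interval data frame (`chrom`, `start`, `end`).
#' @return merged interval data frame.
#' @examples
#' merge_intervals(genomic_intervals(c("chr1", "chr1"), c(0, 5), c(10, 15)))
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  gr_to_gi(GenomicRanges::reduce(gi_to_gr(x)))
}

#' Intersect peak sets across samples
#'
#' Computes the common regions: maximal intervals every base of which is
#' covered by every input set. Mirrors running `intersectBed` successively
#' over per-sample peak files.
#'
#' @param sets a list of interval data frames or [peak_set()] objects.
#' @return interval data frame of common regions.
#' @export
intersect_all <- function(sets) {
  if (!is.list(sets) || length(sets) == 0 || is.data.frame(sets))
    sets <- if (is.data.frame(sets)) list(sets) else sets
  if (length(sets) == 0)
    stop("intersect_all: need at least one peak set", call. = FALSE)
  grs <- lapply(sets, function(s) {
    if (inherits(s, "peak_set")) s <- s$intervals
    GenomicRanges::reduce(gi_to_gr(s))
  })
  out <- Reduce(function(a, b) GenomicRanges::intersect(a, b), grs)
  gr_to_gi(GenomicRanges::reduce(out))
}

#' Subtract one interval set from another
#'
#' Base-level subtraction: returns the bases of `a` not covered by `b`.
#'
#' @param a,b interval data frames or [peak_set()] objects.
#' @return interval data frame.
#' @export
subtract_intervals <- function(a, b) {
  if (inherits(a, "peak_set")) a <- a$intervals
  if (inherits(b, "peak_set")) b <- b$intervals
  validate_intervals(a, "a")
  validate_intervals(b, "b")
  if (nrow(a) == 0) return(a[, c("chrom", "start", "end")])
  if (nrow(b) == 0) return(merge_intervals(a))
  gr_to_gi(GenomicRanges::setdiff(gi_to_gr(a), gi_to_gr(b)))
}

# ---- peak sets --------------------------------------------------------------

#' Histone-mark / factor peak set for one sample
#'
#' A peak set couples a sample identifier and a mark label with a merged,
#' sorted interval collection. Marks recognised by the pipeline are H3K4me1,
#' H3K4me3, H3K27ac, H3K9/14ac, H3K27me3 and PML, but any label is accepted.
#'
#' @param sample_id sample identifier.
#' @param mark mark or factor label.
#' @param intervals interval data frame; merged and sorted on construction.
#' @return an object of class `peak_set`.
#' @export
peak_set <- function(sample_id, mark, intervals) {
  stopifnot(is.character(sample_id), length(sample_id) == 1,
            is.character(mark), length(mark) == 1)
  structure(list(sample_id = sample_id, mark = mark,
                 intervals = merge_intervals(intervals)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set:", x$sample_id, "/", x$mark, "-", nrow(x$intervals),
      "merged intervals\n")
  invisible(x)
}

# ---- BED / bedGraph I/O -----------------------------------------------------

#' Read a BED3/BED6 file
#'
#' Tab-separated, 0-based half-open. Any score column is ignored; strand and
#' name are kept when present.
#'
#' @param path file path.
#' @param chr_alias if `TRUE`, strip a leading "chr" so that "chr1" and "1"
#'   compare equal; default `FALSE` (exact string match).
#' @return interval data frame (plus `name`, `strand` columns when present).
#' @export
read_bed <- function(path, chr_alias = FALSE) {
  x <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("read_bed: fewer than 3 columns in ", path)
  out <- data.frame(chrom = as.character(x[[1]]), start = as.numeric(x[[2]]),
                    end = as.numeric(x[[3]]), stringsAsFactors = FALSE)
  if (ncol(x) >= 4) out$name <- as.character(x[[4]])
  if (ncol(x) >= 6) out$strand <- as.character(x[[6]])
  if (chr_alias) out$chrom <- sub("^chr", "", out$chrom)
  validate_intervals(out, path)
}

#' Write intervals as BED
#'
#' Writes BED3, or BED6 when `name` is supplied (score written as 0,
#' strand ".") .
#'
#' @param x interval data frame.
#' @param path output path.
#' @param name optional name column (recycled).
#' @export
write_bed <- function(x, path, name = NULL) {
  validate_intervals(x)
  if (is.null(name)) {
    out <- x[, c("chrom", "start", "end")]
  } else {
    out <- data.frame(x$chrom, x$start, x$end, rep_len(name, nrow(x)),
                      0L, ".", stringsAsFactors = FALSE)
  }
  write.table(format(out, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tag-density signal track
#'
#' Couples per-interval tag counts (or coverage values) with the library size
#' used for normalization. Values may be per-base coverage, so they need not
#' sum to the library size.
#'
#' @param intervals interval data frame.
#' @param value non-negative numeric, one per interval.
#' @param library_size total mapped tags (> 0).
#' @return object of class `signal_track`.
#' @export
signal_track <- function(intervals, value, library_size) {
  validate_intervals(intervals, "signal_track")
  if (length(value) != nrow(intervals))
    stop("signal_track: one value per interval required", call. = FALSE)
  if (any(value < 0)) stop("signal_track: negative values", call. = FALSE)
  if (!is.numeric(library_size) || length(library_size) != 1 ||
      library_size <= 0)
    stop("signal_track: library_size must be a positive scalar", call. = FALSE)
  structure(list(intervals = intervals, value = as.numeric(value),
                 library_size = as.numeric(library_size)),
            class = "signal_track")
}

#' Read a bedGraph file into a signal track
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @param library_size total mapped tags; defaults to the sum of values.
#' @return a [signal_track()].
#' @export
read_bedgraph <- function(path, library_size = NULL) {
  x <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (ncol(x) < 4) stop("read_bedgraph: need 4 columns in ", path)
  iv <- data.frame(chrom = as.character(x[[1]]), start = as.numeric(x[[2]]),
                   end = as.numeric(x[[3]]), stringsAsFactors = FALSE)
  v <- as.numeric(x[[4]])
  if (is.null(library_size)) library_size <- sum(v)
  signal_track(iv, v, library_size)
}

# ---- normalized tag counting ------------------------------------------------

#' Count tags in regions with RPKM-like normalization
#'
#' Each signal record is assigned to the region containing the midpoint of its
#' interval (an unambiguous single-region assignment); the record's value adds
#' to that region's raw count. Normalization is either RPKM-like
#' (`raw / (region length in kb x library size in millions)`) or per-million
#' (`raw / library size in millions`).
#'
#' @param regions interval data frame.
#' @param track a [signal_track()].
#' @param method `"rpkm"` (default) or `"per-million"`.
#' @return data frame with `chrom`, `start`, `end`, `raw`, `normalized`.
#' @export
count_tags_normalized <- function(regions, track,
                                  method = c("rpkm", "per-million")) {
  method <- match.arg(method)
  validate_intervals(regions, "regions")
  if (!inherits(track, "signal_track"))
    stop("count_tags_normalized: track must be a signal_track", call. = FALSE)
  if (track$library_size <= 0)
    stop("count_tags_normalized: library_size must be > 0", call. = FALSE)
  raw <- numeric(nrow(regions))
  if (nrow(track$intervals) > 0 && nrow(regions) > 0) {
    mid <- floor((track$intervals$start + track$intervals$end) / 2)
    pts <- GenomicRanges::GRanges(track$intervals$chrom,
                                  IRanges::IRanges(mid + 1, width = 1))
    hits <- GenomicRanges::findOverlaps(pts, gi_to_gr(regions))
    if (length(hits)) {
      agg <- tapply(track$value[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits), sum)
      raw[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  lib_m <- track$library_size / 1e6
  norm <- if (method == "rpkm") {
    raw / (((regions$end - regions$start) / 1e3) * lib_m)
  } else {
    raw / lib_m
  }
  data.frame(chrom = regions$chrom, start = regions$start, end = regions$end,
             raw = raw, normalized = norm, stringsAsFactors = FALSE)
}

#' Region-by-sample count table
#'
#' @param regions interval data frame (rows of the table).
#' @param raw region x sample matrix of non-negative integer tag counts.
#' @param normalized matching matrix of normalized enrichment; zero exactly
#'   where `raw` is zero.
#' @return object of class `region_count_table`.
#' @export
region_count_table <- function(regions, raw, normalized = NULL) {
  validate_intervals(regions, "regions")
  raw <- as.matrix(raw)
  if (nrow(raw) != nrow(regions))
    stop("region_count_table: raw rows must match regions", call. = FALSE)
  if (any(raw < 0)) stop("region_count_table: negative counts", call. = FALSE)
  if (!is.null(normalized)) {
    normalized <- as.matrix(normalized)
    if (!all(dim(normalized) == dim(raw)))
      stop("region_count_table: shape mismatch", call. = FALSE)
    if (any((normalized == 0) != (raw == 0)))
      stop("region_count_table: normalized must be zero exactly where raw is",
           call. = FALSE)
  }
  structure(list(regions = regions, raw = raw, normalized = normalized,
                 samples = colnames(raw)),
            class = "region_count_table")
}

#' @export
print.region_count_table <- function(x, ...) {
  cat("region_count_table:", nrow(x$raw), "regions x", ncol(x$raw),
      "samples\n")
  invisible(x)
}
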