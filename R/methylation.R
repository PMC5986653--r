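# WGBS CpG processing and supervised methylation-signature derivation.
#
# Order of operations follows the processing chain: keep CG-context calls,
# combine the forward/reverse calls of each symmetric CpG dyad, apply the
# coverage threshold (>= 5 by default) to the combined counts, restrict to
# CpGs determined in every discovery sample, run the exact rank-sum test
# between the high-risk and standard-risk groups at the primary (0.005) and
# stringent (0.0007) cutoffs, and finally keep only CpGs with beta values in
# every sample of the external AML cohort.

.valid_contexts <- c("CG", "CHH", "CXG")

#' Keep CG-context cytosine calls
#'
#' Non-CpG methylation (CHH, CXG contexts) is excluded from signature
#' analysis; only symmetric CG-context calls are retained.
#'
#' @param calls data frame: `chrom`, `pos` (0-based), `strand` (+/-),
#'   `context`, `meth_count`, `total_count`.
#' @return the CG-context subset of `calls`.
#' @export
filter_cg_context <- function(calls) {
  req <- c("chrom", "pos", "strand", "context", "meth_count", "total_count")
  if (!all(req %in% names(calls)))
    stop("filter_cg_context: calls must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  bad <- which(!(calls$context %in% .valid_contexts))
  if (length(bad))
    stop("filter_cg_context: unknown context '", calls$context[bad[1]],
         "' at row ", bad[1], " (", calls$chrom[bad[1]], ":",
         calls$pos[bad[1]], ")", call. = FALSE)
  out <- calls[calls$context == "CG", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine symmetric CpG dyad calls across strands
#'
#' A forward-strand call at position `i` and a reverse-strand call at `i + 1`
#' describe the two cytosines of one CpG dyad; their methylated and total
#' counts are summed into a single site at the forward-strand position.
#' Unpaired calls pass through with their own counts (reverse-strand calls
#' are reported at the dyad's forward position, `pos - 1`). Methylated and
#' total counts are conserved exactly.
#'
#' @param calls CG-context call data frame (see [filter_cg_context()]).
#' @return data frame of CpG sites: `chrom`, `pos`, `meth_count`,
#'   `total_count`, `beta`.
#' @export
combine_symmetric_cpgs <- function(calls) {
  if (any(calls$meth_count > calls$total_count))
    stop("combine_symmetric_cpgs: meth_count exceeds total_count",
         call. = FALSE)
  if (any(calls$total_count < 1))
    stop("combine_symmetric_cpgs: total_count must be positive",
         call. = FALSE)
  if (!all(calls$strand %in% c("+", "-")))
    stop("combine_symmetric_cpgs: strand must be + or -", call. = FALSE)
  key <- paste(calls$chrom, calls$pos, calls$strand)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("combine_symmetric_cpgs: duplicate call at ", d, call. = FALSE)
  }
  dyad_pos <- ifelse(calls$strand == "+", calls$pos, calls$pos - 1)
  f <- factor(paste(calls$chrom, dyad_pos, sep = ":"))
  meth <- tapply(calls$meth_count, f, sum)
  total <- tapply(calls$total_count, f, sum)
  chrom <- tapply(calls$chrom, f, `[`, 1)
  pos <- tapply(dyad_pos, f, `[`, 1)
  out <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    meth_count = as.numeric(meth),
                    total_count = as.numeric(total),
                    stringsAsFactors = FALSE)
  out$beta <- out$meth_count / out$total_count
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the CpG coverage threshold
#'
#' Retains combined CpG sites with `total_count >= min_total`. The default of
#' 5 implements the coverage rule (equivalently stated as coverage > 4).
#'
#' @param sites CpG site data frame from [combine_symmetric_cpgs()].
#' @param min_total minimum combined coverage (>= 1).
#' @return filtered site data frame.
#' @export
filter_coverage <- function(sites, min_total = 5) {
  if (min_total < 1)
    stop("filter_coverage: min_total must be >= 1", call. = FALSE)
  out <- sites[sites$total_count >= min_total, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the discovery methylation matrix
#'
#' Rows are CpGs (indexed `chrom:pos`), columns samples. The matrix is
#' restricted to CpGs with a beta value determined in every high-risk (hrAPL)
#' and standard-risk (APL) discovery sample; AML cohort columns may be
#' missing at this stage. Array-style beta inputs (probe beta values with no
#' counts) may be supplied directly as `data.frame(chrom, pos, beta)`.
#'
#' @param per_sample named list of CpG site data frames (with `beta`).
#' @param groups data frame: `sample`, `group` (hrAPL / APL / AML); must
#'   cover all names of `per_sample` with at least two groups.
#' @return object of class `methylation_matrix`: list with `beta` (matrix,
#'   possibly NA in AML columns), `pos` (data frame `chrom`, `pos`),
#'   `groups` (named character).
#' @export
build_methylation_matrix <- function(per_sample, groups) {
  if (is.null(names(per_sample)) || any(!nzchar(names(per_sample))))
    stop("build_methylation_matrix: per_sample must be a named list",
         call. = FALSE)
  g <- setNames(as.character(groups$group), groups$sample)
  if (!all(names(per_sample) %in% names(g)))
    stop("build_methylation_matrix: group labels must cover all samples",
         call. = FALSE)
  g <- g[names(per_sample)]
  if (length(unique(g)) < 2)
    stop("build_methylation_matrix: need at least two groups", call. = FALSE)
  for (s in names(per_sample))
    if (nrow(per_sample[[s]]) == 0)
      stop("build_methylation_matrix: sample '", s,
           "' has no surviving CpGs", call. = FALSE)
  keys <- lapply(per_sample, function(d) paste(d$chrom, d$pos, sep = ":"))
  all_keys <- sort(unique(unlist(keys)))
  beta <- matrix(NA_real_, length(all_keys), length(per_sample),
                 dimnames = list(all_keys, names(per_sample)))
  for (s in names(per_sample))
    beta[keys[[s]], s] <- per_sample[[s]]$beta
  disc <- names(g)[g %in% c("hrAPL", "APL")]
  keep <- rowSums(is.na(beta[, disc, drop = FALSE])) == 0
  beta <- beta[keep, , drop = FALSE]
  if (nrow(beta) == 0)
    stop("build_methylation_matrix: no CpG is determined across all ",
         "discovery samples", call. = FALSE)
  parts <- strsplit(rownames(beta), ":", fixed = TRUE)
  pos <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    pos = as.numeric(vapply(parts, `[`, "", 2)),
                    stringsAsFactors = FALSE)
  structure(list(beta = beta, pos = pos, groups = g),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("methylation_matrix:", nrow(x$beta), "CpGs x", ncol(x$beta),
      "samples (", paste(sprintf("%s=%d", names(table(x$groups)),
                                 table(x$groups)), collapse = ", "), ")\n")
  invisible(x)
}

#' Supervised CpG signature test
#'
#' Per CpG, a two-sided exact Wilcoxon rank-sum test compares beta values of
#' the high-risk (hrAPL) group against the standard-risk (APL) group. The
#' signature set is `p < primary` (default 0.005) and the stringent set
#' `p < stringent` (default 0.0007). At the discovery group sizes of 5 vs 10,
#' the smallest attainable exact two-sided p is 2/3003, so only CpGs with
#' completely separated groups can enter the stringent set. Direction is
#' hypo when the high-risk mean beta is below the standard-risk mean.
#'
#' @param mat a [build_methylation_matrix()] result with hrAPL and APL
#'   groups of size >= 2 each.
#' @param primary,stringent two-sided p cutoffs.
#' @return data frame: `chrom`, `pos`, `p_value`, `mean_diff`
#'   (mean hrAPL beta - mean APL beta), `direction` (hypo/hyper),
#'   `in_signature`, `in_stringent`.
#' @export
supervised_cpg_test <- function(mat, primary = 0.005, stringent = 0.0007) {
  stopifnot(inherits(mat, "methylation_matrix"))
  a_cols <- which(mat$groups == "hrAPL")
  b_cols <- which(mat$groups == "APL")
  if (length(a_cols) < 2 || length(b_cols) < 2)
    stop("supervised_cpg_test: both hrAPL and APL groups need >= 2 samples",
         call. = FALSE)
  rs <- rank_sum_test_rows(mat$beta, a_cols, b_cols)
  mean_diff <- rowMeans(mat$beta[, a_cols, drop = FALSE]) -
    rowMeans(mat$beta[, b_cols, drop = FALSE])
  out <- data.frame(chrom = mat$pos$chrom, pos = mat$pos$pos,
                    p_value = rs$p_value, mean_diff = mean_diff,
                    direction = ifelse(mean_diff < 0, "hypo", "hyper"),
                    in_signature = rs$p_value < primary,
                    in_stringent = rs$p_value < stringent,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Refine the stringent signature against an external cohort
#'
#' Stringent-signature CpGs are retained only when a beta value is present
#' (non-missing) in every AML column of the cohort matrix — the completeness
#' gate over the 181-sample AML cohort in the original design.
#'
#' @param signature data frame from [supervised_cpg_test()] (rows with
#'   `in_stringent` are considered).
#' @param cohort a `methylation_matrix` whose groups include AML columns.
#' @return the final signature: stringent rows with logical `in_final` set.
#' @export
refine_against_cohort <- function(signature, cohort) {
  stopifnot(inherits(cohort, "methylation_matrix"))
  aml <- which(cohort$groups == "AML")
  if (length(aml) == 0)
    stop("refine_against_cohort: cohort has no AML columns", call. = FALSE)
  complete <- rownames(cohort$beta)[
    rowSums(is.na(cohort$beta[, aml, drop = FALSE])) == 0]
  key <- paste(signature$chrom, signature$pos, sep = ":")
  signature$in_final <- signature$in_stringent & key %in% complete
  signature
}

#' Partition a signature into hypo- and hypermethylated CpGs
#'
#' Hypo iff the high-risk mean beta is below the standard-risk mean
#' (`mean_diff < 0`); hyper otherwise. The partition is exhaustive and
#' disjoint. A selected CpG with `mean_diff` exactly zero cannot arise from
#' the exact test at the default cutoffs; it is classed hyper with a warning.
#'
#' @param signature data frame with `mean_diff`, typically restricted to
#'   selected rows.
#' @return list: `hypo` and `hyper` subsets, and `counts` (named vector).
#' @export
classify_direction <- function(signature) {
  if (any(signature$mean_diff == 0))
    warning("classify_direction: mean_diff exactly 0 on a selected CpG; ",
            "classing as hyper")
  hypo <- signature[signature$mean_diff < 0, , drop = FALSE]
  hyper <- signature[signature$mean_diff >= 0, , drop = FALSE]
  list(hypo = hypo, hyper = hyper,
       counts = c(hypo = nrow(hypo), hyper = nrow(hyper)))
}

# ---- I/O --------------------------------------------------------------------

#' Read per-sample cytosine calls
#'
#' Two dialects: `"calls"` is the native TSV with header
#' `chrom pos strand context meth_count total_count` (0-based positions);
#' `"bismark"` is the bismark-coverage-style table
#' `chrom start end beta_percent meth unmeth` whose rows are taken as
#' already strand-combined CpG sites.
#'
#' @param path TSV path.
#' @param dialect `"calls"` or `"bismark"`.
#' @return for `"calls"`, a call data frame ready for [filter_cg_context()];
#'   for `"bismark"`, a combined CpG site data frame.
#' @export
read_cpg_calls <- function(path, dialect = c("calls", "bismark")) {
  dialect <- match.arg(dialect)
  if (dialect == "calls") {
    x <- read.delim(path, stringsAsFactors = FALSE)
    req <- c("chrom", "pos", "strand", "context", "meth_count", "total_count")
    if (!all(req %in% names(x)))
      stop("read_cpg_calls: ", path, " lacks columns ",
           paste(setdiff(req, names(x)), collapse = ", "), call. = FALSE)
    x
  } else {
    x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    meth <- as.numeric(x[[5]])
    total <- meth + as.numeric(x[[6]])
    data.frame(chrom = as.character(x[[1]]), pos = as.numeric(x[[2]]),
               meth_count = meth, total_count = total, beta = meth / total,
               stringsAsFactors = FALSE)
  }
}

#' Read a cohort beta matrix
#'
#' TSV with a `cpg_id` column (`chrom:pos`) then one beta column per sample;
#' empty cells are missing values.
#'
#' @param path matrix TSV path.
#' @param groups data frame `sample`, `group` covering the matrix columns.
#' @return a `methylation_matrix`.
#' @export
read_cohort_matrix <- function(path, groups) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1] != "cpg_id")
    stop("read_cohort_matrix: first column must be cpg_id", call. = FALSE)
  beta <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- x$cpg_id
  g <- setNames(as.character(groups$group), groups$sample)
  if (!all(colnames(beta) %in% names(g)))
    stop("read_cohort_matrix: group labels must cover all matrix columns",
         call. = FALSE)
  parts <- strsplit(rownames(beta), ":", fixed = TRUE)
  pos <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    pos = as.numeric(vapply(parts, `[`, "", 2)),
                    stringsAsFactors = FALSE)
  structure(list(beta = beta, pos = pos, groups = g[colnames(beta)]),
            class = "methylation_matrix")
}

#' Write a signature table
#'
#' @param signature data frame from the signature stages.
#' @param path output TSV path.
#' @export
write_signature <- function(signature, path) {
  write.table(signature, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
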